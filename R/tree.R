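#' Construct a haplogroup definition tree
#'
#' A rooted tree of named haplogroups; each node carries the variants gained on
#' the edge leading to it ("defining variants"). The root-to-node path union is
#' the variant set expected in every member of that haplogroup — mtDNA lineages
#' accumulate variants in full linkage.
#'
#' @param nodes Data frame (or list coercible to one) with columns `name`,
#'   `parent` (NA for the root) and list-column `defining` of token vectors.
#' @param defining Optional list of token vectors (one per node), used when
#'   `nodes` lacks a `defining` column.
#' @return An object of class `haplogroup_tree`.
#' @examples
#' tr <- haplogroup_tree(data.frame(name = c("root", "H7"),
#'                                  parent = c(NA, "root")),
#'                       defining = list(character(0), "m.4793A>G"))
#' haplogroup_path_variants(tr, "H7")
#' @export
haplogroup_tree <- function(nodes, defining = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!is.null(defining)) nodes$defining <- defining
  if (!all(c("name", "parent", "defining") %in% names(nodes))) {
    stop("tree nodes need columns: name, parent, defining", call. = FALSE)
  }
  nodes$name <- as.character(nodes$name)
  nodes$parent <- as.character(nodes$parent)
  nodes$defining <- lapply(nodes$defining, normalize_tokens)
  if (anyDuplicated(nodes$name)) {
    stop(sprintf("duplicate haplogroup name: '%s'",
                 nodes$name[duplicated(nodes$name)][1]), call. = FALSE)
  }
  is_root <- is.na(nodes$parent)
  if (sum(is_root) != 1L) {
    stop(sprintf("tree must have exactly one root (found %d)", sum(is_root)), call. = FALSE)
  }
  unknown <- setdiff(nodes$parent[!is_root], nodes$name)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown parent name(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  out <- structure(list(nodes = nodes), class = "haplogroup_tree")
  # walking every root path both proves acyclicity and validates no re-gain
  for (nm in nodes$name) haplogroup_path_variants(out, nm)
  out
}

#' @export
print.haplogroup_tree <- function(x, ...) {
  cat(sprintf("haplogroup_tree: %d nodes, root '%s'\n",
              nrow(x$nodes), x$nodes$name[is.na(x$nodes$parent)]))
  invisible(x)
}

#' Names of all haplogroups in a tree
#' @param tree A `haplogroup_tree`.
#' @return Character vector of node names.
#' @export
haplogroup_names <- function(tree) tree$nodes$name

tree_parent <- function(tree, name) {
  i <- match(name, tree$nodes$name)
  if (is.na(i)) stop(sprintf("unknown haplogroup name: '%s'", name), call. = FALSE)
  tree$nodes$parent[i]
}

#' Root-to-node path of a haplogroup
#'
#' @param tree A `haplogroup_tree`.
#' @param name Node name.
#' @return Character vector of node names from root down to `name`.
#' @export
haplogroup_path <- function(tree, name) {
  path <- character(0)
  cur <- name
  n_max <- nrow(tree$nodes) + 1L
  while (!is.na(cur)) {
    if (length(path) >= n_max) {
      stop(sprintf("cycle detected in tree at node '%s'", name), call. = FALSE)
    }
    path <- c(cur, path)
    cur <- tree_parent(tree, cur)
  }
  path
}

#' Defining variants accumulated along a haplogroup's root path
#'
#' The union of edge-defining variants from the root down to `name`; every
#' member of the haplogroup is expected to carry all of them. A variant gained
#' twice on one path violates the tree invariant and is rejected.
#'
#' @param tree A `haplogroup_tree`.
#' @param name Node name.
#' @return Character vector of variant tokens.
#' @export
haplogroup_path_variants <- function(tree, name) {
  path <- haplogroup_path(tree, name)
  toks <- unlist(tree$nodes$defining[match(path, tree$nodes$name)], use.names = FALSE)
  if (anyDuplicated(toks)) {
    stop(sprintf("variant %s gained more than once on the root path of '%s'",
                 toks[duplicated(toks)][1], name), call. = FALSE)
  }
  normalize_tokens(toks)
}

#' Depth of a node (root = 0)
#' @param tree A `haplogroup_tree`.
#' @param name Node name.
#' @return Integer depth.
#' @export
haplogroup_depth <- function(tree, name) length(haplogroup_path(tree, name)) - 1L

#' Read a haplogroup tree from JSON
#'
#' Format: `{"nodes": [{"name": ..., "parent": null|"...",
#' "defining_variants": [...]}, ...]}`.
#'
#' @param path JSON file path.
#' @return A [haplogroup_tree()].
#' @export
read_tree <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$nodes)) stop("tree JSON must contain a 'nodes' array", call. = FALSE)
  nm <- vapply(j$nodes, function(n) as.character(n$name), character(1))
  pa <- vapply(j$nodes, function(n) {
    if (is.null(n$parent)) NA_character_ else as.character(n$parent)
  }, character(1))
  dv <- lapply(j$nodes, function(n) as.character(unlist(n$defining_variants)))
  haplogroup_tree(data.frame(name = nm, parent = pa, stringsAsFactors = FALSE),
                  defining = dv)
}

#' Write a haplogroup tree to JSON
#'
#' @param tree A `haplogroup_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  nodes <- lapply(seq_len(nrow(tree$nodes)), function(i) {
    list(name = tree$nodes$name[i],
         parent = if (is.na(tree$nodes$parent[i])) NULL else tree$nodes$parent[i],
         defining_variants = as.list(tree$nodes$defining[[i]]))
  })
  jsonlite::write_json(list(nodes = nodes), path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Construct a pedigree table
#'
#' @param id Character vector of unique individual ids.
#' @param generation Integer generation index (1 = parents).
#' @param status `"alive"` or `"miscarriage"`.
#' @param carrier Nuclear-modifier state: `"carrier"`, `"noncarrier"` or
#'   `"unknown"`.
#' @param mtdna mtDNA lineage: `"mutant"`, `"control"` or `"unknown"`.
#' @return An object of class `mt_pedigree` (a data frame).
#' @export
mt_pedigree <- function(id, generation, status, carrier, mtdna = "unknown") {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop(sprintf("duplicate individual id: '%s'", id[duplicated(id)][1]), call. = FALSE)
  }
  status <- match.arg(as.character(status), c("alive", "miscarriage"), several.ok = TRUE)
  carrier <- match.arg(as.character(carrier), c("carrier", "noncarrier", "unknown"),
                       several.ok = TRUE)
  mtdna <- match.arg(as.character(mtdna), c("mutant", "control", "unknown"),
                     several.ok = TRUE)
  out <- data.frame(id = id, generation = as.integer(generation),
                    status = rep_len(status, length(id)),
                    carrier = rep_len(carrier, length(id)),
                    mtdna = rep_len(mtdna, length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("mt_pedigree", "data.frame")
  out
}

#' Read a pedigree from TSV
#'
#' Columns: `id`, `generation`, `status`, `carrier`, `mtdna`.
#'
#' @param path File path.
#' @return An [mt_pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = NULL)
  need <- c("id", "generation", "status", "carrier", "mtdna")
  if (!all(need %in% names(df))) {
    stop(sprintf("pedigree header must contain columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  bad_status <- which(!df$status %in% c("alive", "miscarriage"))
  if (length(bad_status) > 0L) {
    stop(sprintf("line %d: invalid status '%s'", bad_status[1] + 1L,
                 df$status[bad_status[1]]), call. = FALSE)
  }
  mt_pedigree(df$id, as.integer(df$generation), df$status, df$carrier, df$mtdna)
}

#' Write a pedigree to TSV
#' @param ped An `mt_pedigree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  write.table(as.data.frame(ped), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
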