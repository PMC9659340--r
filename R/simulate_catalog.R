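#' Configuration for the synthetic catalog generator
#'
#' Describes a MITOMAP-like population collection: per-haplogroup record
#' counts, a Poisson rate of private mutations per sequence, recurrent
#' homoplasies that can appear off their native background, and explicit
#' "out-of-context" injections (a variant planted into an exact number of
#' records of a foreign haplogroup).
#'
#' @param seed Integer seed; identical config + seed gives identical catalogs.
#' @param counts_per_haplogroup Named integer vector: haplogroup -> record
#'   count.
#' @param private_rate Mean number of private variants per sequence
#'   (Poisson; default 0).
#' @param homoplasy_rate Per-sequence probability of carrying each designated
#'   recurrent variant when it is absent from the sequence's own haplogroup
#'   path (default 0).
#' @param homoplasy_variants Character vector of tokens designated as
#'   recurrent homoplasies (default none).
#' @param injections List of `list(variant =, haplogroup =, count =)` triples:
#'   plant `variant` into exactly `count` records of `haplogroup`.
#' @return An object of class `sim_catalog_config`.
#' @export
sim_catalog_config <- function(seed, counts_per_haplogroup, private_rate = 0,
                               homoplasy_rate = 0, homoplasy_variants = character(0),
                               injections = list()) {
  counts <- as.integer(counts_per_haplogroup)
  names(counts) <- names(counts_per_haplogroup)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts_per_haplogroup must be a named vector", call. = FALSE)
  }
  if (any(counts < 0)) stop("haplogroup counts must be >= 0", call. = FALSE)
  if (private_rate < 0 || homoplasy_rate < 0) stop("rates must be >= 0", call. = FALSE)
  homoplasy_variants <- normalize_tokens(homoplasy_variants)
  for (inj in injections) {
    if (!all(c("variant", "haplogroup", "count") %in% names(inj))) {
      stop("each injection needs fields: variant, haplogroup, count", call. = FALSE)
    }
    if (!inj$haplogroup %in% names(counts)) {
      stop(sprintf("injection targets unknown haplogroup '%s'", inj$haplogroup), call. = FALSE)
    }
    if (inj$count < 0 || inj$count > counts[[inj$haplogroup]]) {
      stop(sprintf("injected count %d exceeds haplogroup count %d for '%s'",
                   inj$count, counts[[inj$haplogroup]], inj$haplogroup), call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), counts_per_haplogroup = counts,
                 private_rate = private_rate, homoplasy_rate = homoplasy_rate,
                 homoplasy_variants = homoplasy_variants, injections = injections),
            class = "sim_catalog_config")
}

# transition partner of each base (private variants are transitions only)
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulate a population variant catalog
#'
#' Each record carries the full union of defining variants on its haplogroup's
#' root path (mtDNA lineages are in complete linkage), plus Poisson-distributed
#' private variants at rCRS positions unused by the tree, plus any configured
#' homoplasies and injections. Private variants are transitions at uniformly
#' drawn unused positions.
#'
#' @param config A [sim_catalog_config()].
#' @param tree A [haplogroup_tree()] containing every haplogroup named in the
#'   config.
#' @return A [variant_catalog()]. Bookkeeping of what was planted is attached
#'   as attribute `truth` (list with `injected_ids` per injection and
#'   `homoplasy_ids` per homoplasy variant).
#' @examples
#' tr <- haplogroup_tree(data.frame(name = c("root", "H7", "J"),
#'                                  parent = c(NA, "root", "root")),
#'                       defining = list(character(0), "m.4793A>G", "m.13708G>A"))
#' cfg <- sim_catalog_config(seed = 1, counts_per_haplogroup = c(H7 = 10, J = 5))
#' cat <- simulate_catalog(cfg, tr)
#' @export
simulate_catalog <- function(config, tree) {
  stopifnot(inherits(config, "sim_catalog_config"), inherits(tree, "haplogroup_tree"))
  hgs <- names(config$counts_per_haplogroup)
  unknown <- setdiff(hgs, haplogroup_names(tree))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown haplogroup name(s) in config: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  path_sets <- lapply(hgs, haplogroup_path_variants, tree = tree)
  names(path_sets) <- hgs
  for (inj in config$injections) {
    if (inj$variant %in% path_sets[[inj$haplogroup]]) {
      stop(sprintf("injection variant %s collides with a defining variant of '%s'",
                   inj$variant, inj$haplogroup), call. = FALSE)
    }
  }

  used_pos <- token_positions(unlist(tree$nodes$defining, use.names = FALSE))
  inj_tok <- vapply(config$injections, function(i) i$variant, character(1),
                    USE.NAMES = FALSE)
  used_pos <- unique(c(used_pos, token_positions(config$homoplasy_variants),
                       if (length(inj_tok)) token_positions(inj_tok)))
  free_pos <- setdiff(seq_len(RCRS_LENGTH), used_pos)

  set.seed(config$seed)
  counts <- config$counts_per_haplogroup[config$counts_per_haplogroup > 0]
  hg_col <- rep(names(counts), counts)
  ids <- sprintf("%s_%04d", hg_col, unlist(lapply(counts, seq_len), use.names = FALSE))
  n_rec <- length(ids)
  vars <- path_sets[hg_col]
  names(vars) <- NULL
  if (config$private_rate > 0) {
    for (i in seq_len(n_rec)) {
      n_priv <- rpois(1, config$private_rate)
      if (n_priv > 0) {
        pp <- sample(free_pos, min(n_priv, length(free_pos)))
        ref <- sample(.BASES, length(pp), replace = TRUE)
        vars[[i]] <- c(vars[[i]], variant_token(pp, ref, .TRANSITION[ref]))
      }
    }
  }

  truth <- list(injected_ids = list(), homoplasy_ids = list())
  # homoplasies: independent Bernoulli per sequence where not native
  if (length(config$homoplasy_variants) > 0 && config$homoplasy_rate > 0) {
    # variants x haplogroups: is the variant native (on-path) for that background?
    native <- vapply(path_sets, function(ps) config$homoplasy_variants %in% ps,
                     logical(length(config$homoplasy_variants)))
    native <- matrix(native, nrow = length(config$homoplasy_variants),
                     dimnames = list(NULL, names(path_sets)))
    hg_idx <- match(hg_col, colnames(native))
    hit_rec <- vector("list", length(config$homoplasy_variants))
    hit_tok <- vector("list", length(config$homoplasy_variants))
    for (k in seq_along(config$homoplasy_variants)) {
      hv <- config$homoplasy_variants[k]
      eligible <- which(!native[k, hg_idx])
      hit <- eligible[runif(length(eligible)) < config$homoplasy_rate]
      hit_rec[[k]] <- hit
      hit_tok[[k]] <- rep(hv, length(hit))
      truth$homoplasy_ids[[hv]] <- ids[hit]
    }
    extra <- split(unlist(hit_tok), unlist(hit_rec))
    for (nm in names(extra)) {
      i <- as.integer(nm)
      vars[[i]] <- c(vars[[i]], extra[[nm]])
    }
  } else {
    for (hv in config$homoplasy_variants) truth$homoplasy_ids[[hv]] <- character(0)
  }
  # injections: exact counts into the first `count` records of the haplogroup
  # (records are exchangeable; a deterministic choice keeps bookkeeping simple)
  for (inj in config$injections) {
    tgt <- which(hg_col == inj$haplogroup)[seq_len(inj$count)]
    for (i in tgt) vars[[i]] <- c(vars[[i]], inj$variant)
    truth$injected_ids[[format(parse_variant_token(inj$variant))]] <- ids[tgt]
  }

  out <- variant_catalog(ids, hg_col, vars)
  attr(out, "truth") <- truth
  out
}

#' Configuration for the pedigree generator
#'
#' @param seed Integer seed.
#' @param n_conceptions Number of conceptions to simulate (>= 1).
#' @param paternal_carrier_prob Probability each conception inherits the
#'   paternal modifier allele (default 0.5, Mendelian).
#' @param lethality_model `"none"` or `"lethal_if_noncarrier"`.
#' @param lethality_penetrance Probability a noncarrier conception is lost in
#'   utero under `lethal_if_noncarrier` (default 1).
#' @return An object of class `sim_pedigree_config`.
#' @export
sim_pedigree_config <- function(seed, n_conceptions, paternal_carrier_prob = 0.5,
                                lethality_model = c("none", "lethal_if_noncarrier"),
                                lethality_penetrance = 1) {
  lethality_model <- match.arg(lethality_model)
  if (n_conceptions < 1) stop("n_conceptions must be >= 1", call. = FALSE)
  if (paternal_carrier_prob < 0 || paternal_carrier_prob > 1 ||
      lethality_penetrance < 0 || lethality_penetrance > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_conceptions = as.integer(n_conceptions),
                 paternal_carrier_prob = paternal_carrier_prob,
                 lethality_model = lethality_model,
                 lethality_penetrance = lethality_penetrance),
            class = "sim_pedigree_config")
}

#' Simulate a two-generation pedigree
#'
#' Conceptions inherit the paternal nuclear-modifier allele independently with
#' probability `paternal_carrier_prob`; under the `lethal_if_noncarrier` model
#' noncarrier conceptions are lost in utero with the configured penetrance.
#' All conceptions inherit the maternal mtDNA (`mtdna = "mutant"`).
#'
#' @param config A [sim_pedigree_config()].
#' @return An [mt_pedigree()] with two parents (generation 1) and
#'   `n_conceptions` offspring (generation 2).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_pedigree_config"))
  set.seed(config$seed)
  n <- config$n_conceptions
  carrier <- runif(n) < config$paternal_carrier_prob
  dies <- if (config$lethality_model == "lethal_if_noncarrier") {
    !carrier & runif(n) < config$lethality_penetrance
  } else rep(FALSE, n)
  mt_pedigree(
    id = c("I1", "I2", sprintf("II%d", seq_len(n))),
    generation = c(1L, 1L, rep(2L, n)),
    status = c("alive", "alive", ifelse(dies, "miscarriage", "alive")),
    carrier = c("carrier", "noncarrier",
                ifelse(dies, "unknown", ifelse(carrier, "carrier", "noncarrier"))),
    mtdna = c("control", "mutant", rep("mutant", n))
  )
}
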