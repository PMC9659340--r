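# Haplogroup assignment and haplogroup-conditional allele frequencies.

#' Assign a haplogroup to a sequence record
#'
#' Scores every node of the tree against the record's variant set with a
#' Kulczynski-style mean of path coverage and sample-explained fractions:
#'
#' \deqn{score(node) = \frac{1}{2}\frac{|present \cap path|}{|path|} +
#'                     \frac{1}{2}\frac{|present \cap path|}{|present|}}
#'
#' with a degenerate fraction defined as 1 when its denominator is 0 (so an
#' empty record is assigned the root with score 1). Ties are broken by greater
#' path depth, then lexicographic node name. This is a deliberately simple
#' assigner — full phylotree-weighted assignment is out of scope — but it
#' recovers every node exactly on noise-free defining-variant sets.
#'
#' @param record Either a character vector of variant tokens or a one-row slice
#'   of a [variant_catalog()] (list with `sample_id` and `variants`).
#' @param tree A [haplogroup_tree()].
#' @return A list of class `hg_assignment`: `sample_id`, `haplogroup`, `score`,
#'   `unexplained` (variants in the sample not on the assigned path) and
#'   `missing` (path-defining variants absent from the sample).
#' @examples
#' tr <- haplogroup_tree(data.frame(name = c("root", "H7", "J"),
#'                                  parent = c(NA, "root", "root")),
#'                       defining = list(character(0), "m.4793A>G", "m.13708G>A"))
#' assign_haplogroup(c("m.4793A>G", "m.13708G>A"), tr)$haplogroup  # "H7"
#' @export
assign_haplogroup <- function(record, tree) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  if (nrow(tree$nodes) == 0L) stop("empty tree", call. = FALSE)
  if (is.character(record)) {
    sample_id <- NA_character_
    present <- normalize_tokens(record)
  } else {
    sample_id <- record$sample_id[[1]]
    present <- normalize_tokens(record$variants[[1]])
  }
  nms <- haplogroup_names(tree)
  scores <- numeric(length(nms))
  paths <- lapply(nms, haplogroup_path_variants, tree = tree)
  for (k in seq_along(nms)) {
    pathv <- paths[[k]]
    inter <- length(intersect(present, pathv))
    f_path <- if (length(pathv) == 0L) 1 else inter / length(pathv)
    f_samp <- if (length(present) == 0L) 1 else inter / length(present)
    scores[k] <- 0.5 * f_path + 0.5 * f_samp
  }
  depth <- vapply(nms, haplogroup_depth, integer(1), tree = tree)
  best <- order(-scores, -depth, nms)[1]
  structure(list(sample_id = sample_id,
                 haplogroup = nms[best],
                 score = scores[best],
                 unexplained = setdiff(present, paths[[best]]),
                 missing = setdiff(paths[[best]], present)),
            class = "hg_assignment")
}

#' @export
print.hg_assignment <- function(x, ...) {
  cat(sprintf("%s -> %s (score %.3f; %d unexplained, %d missing)\n",
              ifelse(is.na(x$sample_id), "<record>", x$sample_id),
              x$haplogroup, x$score, length(x$unexplained), length(x$missing)))
  invisible(x)
}

#' Assign haplogroups to every record of a catalog
#'
#' @param catalog A [variant_catalog()].
#' @param tree A [haplogroup_tree()].
#' @return Data frame with one row per record: `sample_id`, `haplogroup`,
#'   `score`, `n_unexplained`, `n_missing`.
#' @export
assign_catalog <- function(catalog, tree) {
  res <- lapply(seq_len(nrow(catalog)), function(i) {
    a <- assign_haplogroup(catalog$variants[[i]], tree)
    data.frame(sample_id = catalog$sample_id[i], haplogroup = a$haplogroup,
               score = a$score, n_unexplained = length(a$unexplained),
               n_missing = length(a$missing), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# round half-up to `digits` decimals (display convention for percentages:
# 3/348 = 0.8621% prints as 0.86%)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Haplogroup-conditional allele frequency
#'
#' Counts carriers of `variant` among the records of one haplogroup stratum
#' (or the whole catalog for stratum `"ALL"`).
#'
#' @param catalog A [variant_catalog()].
#' @param variant Variant token (string) or `mt_variant`.
#' @param haplogroup Stratum name, or `"ALL"` for the unconditional frequency.
#' @return A one-row data frame of class `frequency_result`: `variant`,
#'   `stratum`, `count`, `total`, `frequency` (fraction), `percent`
#'   (half-up, 2 decimals) and `undefined` flag (TRUE when the stratum is
#'   empty).
#' @examples
#' # 3 carriers out of 348 H7 records display as 0.86%
#' @export
conditional_allele_frequency <- function(catalog, variant, haplogroup = "ALL") {
  stopifnot(inherits(catalog, "variant_catalog"))
  tok <- if (inherits(variant, "mt_variant")) format(variant)
         else format(parse_variant_token(variant))
  in_stratum <- if (identical(haplogroup, "ALL")) rep(TRUE, nrow(catalog))
                else !is.na(catalog$haplogroup) & catalog$haplogroup == haplogroup
  total <- sum(in_stratum)
  count <- sum(vapply(catalog$variants[in_stratum], function(v) tok %in% v, logical(1)))
  freq <- if (total > 0) count / total else NA_real_
  out <- data.frame(variant = tok, stratum = haplogroup, count = count,
                    total = total, frequency = freq,
                    percent = if (total > 0) round_half_up(100 * freq, 2) else NA_real_,
                    undefined = total == 0, stringsAsFactors = FALSE)
  class(out) <- c("frequency_result", "data.frame")
  out
}

#' Allele-frequency table across variants and haplogroup strata
#'
#' One row per (variant, stratum) pair plus an `"ALL"` stratum per variant.
#' Per-stratum totals depend only on the stratum, never on the variant queried.
#'
#' @param catalog A [variant_catalog()].
#' @param variants Character vector of variant tokens.
#' @param strata Character vector of haplogroup names (default: all labels
#'   present in the catalog).
#' @return A data frame of stacked [conditional_allele_frequency()] rows.
#' @export
frequency_table <- function(catalog, variants,
                            strata = sort(unique(catalog$haplogroup[!is.na(catalog$haplogroup)]))) {
  rows <- list()
  for (v in variants) {
    for (s in c(strata, "ALL")) {
      rows[[length(rows) + 1L]] <- conditional_allele_frequency(catalog, v, s)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
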