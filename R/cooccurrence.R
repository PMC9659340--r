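# Normalized pairwise cooccurrence of mtDNA variants with an exact
# hypergeometric under-cooccurrence test. The statistic is the observed joint
# carrier frequency divided by the product of the marginal carrier
# frequencies: 1 under independence, >1 for linked variants, <1 for
# combinations depleted from the population ("out-of-context" pairs).

#' Carrier and pair counts across a catalog
#'
#' One pass over the records: per-variant carrier counts `n`, joint carrier
#' counts `n_ij` for every pair, and catalog size `N`.
#'
#' @param catalog A [variant_catalog()].
#' @param variants Character vector of variant tokens.
#' @return List with `n` (named integer vector), `n_ij` (symmetric integer
#'   matrix) and `N`.
#' @export
pair_counts <- function(catalog, variants) {
  if (nrow(catalog) == 0L) stop("catalog is empty", call. = FALSE)
  variants <- unique(normalize_tokens(variants))
  pres <- presence_matrix(catalog, variants)
  n <- as.integer(colSums(pres))
  names(n) <- variants
  nij <- crossprod(pres * 1L)
  storage.mode(nij) <- "integer"
  dimnames(nij) <- list(variants, variants)
  list(n = n, n_ij = nij, N = nrow(catalog))
}

#' Record-by-variant presence matrix
#'
#' @param catalog A [variant_catalog()].
#' @param variants Character vector of variant tokens (columns).
#' @return Logical matrix, records x variants.
#' @export
presence_matrix <- function(catalog, variants) {
  stopifnot(inherits(catalog, "variant_catalog"))
  n <- nrow(catalog)
  rec <- rep(seq_len(n), lengths(catalog$variants))
  tok <- unlist(catalog$variants, use.names = FALSE)
  j <- match(tok, variants)
  keep <- !is.na(j)
  M <- matrix(FALSE, n, length(variants),
              dimnames = list(catalog$sample_id, variants))
  M[cbind(rec[keep], j[keep])] <- TRUE
  M
}

#' Normalized cooccurrence ratio
#'
#' `(n_ij/N) / ((n_i/N) * (n_j/N))`: the observed joint carrier frequency of
#' two variants relative to the expectation under independence given their
#' marginal abundances. Equals 1 under independence, `1/frequency` under
#' perfect linkage, and 0 for mutually exclusive variants. Undefined (NA) when
#' either marginal count is 0.
#'
#' @param n_i,n_j Carrier counts of the two variants.
#' @param n_ij Joint carrier count.
#' @param N Catalog size (> 0).
#' @return Numeric ratio (NA when undefined).
#' @export
normalized_cooccurrence <- function(n_i, n_j, n_ij, N) {
  if (N <= 0) stop("N must be > 0", call. = FALSE)
  check_pair_counts(n_i, n_j, n_ij, N)
  ifelse(n_i == 0 | n_j == 0, NA_real_, (n_ij / N) / ((n_i / N) * (n_j / N)))
}

check_pair_counts <- function(n_i, n_j, n_ij, N) {
  ok <- n_i >= 0 & n_j >= 0 & n_ij >= 0 & n_i <= N & n_j <= N &
    n_ij <= pmin(n_i, n_j) & n_ij >= pmax(0, n_i + n_j - N)
  if (any(!ok)) {
    stop(sprintf("inconsistent pair counts: n_i=%s n_j=%s n_ij=%s N=%s",
                 n_i[!ok][1], n_j[!ok][1], n_ij[!ok][1], N), call. = FALSE)
  }
  invisible(TRUE)
}

#' Exact under-cooccurrence test
#'
#' One-sided lower-tail probability `P(X <= n_ij)` under the central
#' hypergeometric null: holding both marginal carrier counts fixed, variant j's
#' carriers are an unordered random sample of `n_j` of the `N` records. Small
#' values indicate the two variants co-occur less often than independence
#' predicts.
#'
#' The default is the exact lower tail, which for a discrete statistic is
#' conservative (`P(p <= a) <= a`). For null-calibration diagnostics two
#' standard de-discretized variants are available: `"mid"` replaces half the
#' probability mass at the observed count, and `"randomized"` draws
#' `P(X < n_ij) + U * P(X = n_ij)` with `U ~ Unif(0,1)`, which is exactly
#' uniform under the null. Inference defaults to `"exact"`.
#'
#' @inheritParams normalized_cooccurrence
#' @param type `"exact"` (default), `"mid"`, or `"randomized"`.
#' @return p-value in (0, 1] (vectorized over the count arguments).
#' @examples
#' under_cooccurrence_test(5, 5, 0, 10)  # 1/252
#' @export
under_cooccurrence_test <- function(n_i, n_j, n_ij, N,
                                    type = c("exact", "mid", "randomized")) {
  type <- match.arg(type)
  check_pair_counts(n_i, n_j, n_ij, N)
  if (type == "exact") return(phyper(n_ij, n_i, N - n_i, n_j))
  below <- phyper(n_ij - 1, n_i, N - n_i, n_j)
  at <- stats::dhyper(n_ij, n_i, N - n_i, n_j)
  w <- if (type == "mid") 0.5 else runif(length(at))
  below + w * at
}

#' Pairwise cooccurrence matrix over a variant panel
#'
#' Computes counts, normalized ratios, exact under-cooccurrence p-values and
#' Benjamini-Hochberg q-values for every unordered variant pair. Diagonal and
#' zero-marginal pairs are emitted as flagged-undefined rows rather than
#' dropped.
#'
#' @param catalog A [variant_catalog()].
#' @param variants Character vector of >= 2 variant tokens.
#' @param alpha Significance level recorded in metadata (default 0.05).
#' @param strata Optional character vector of haplogroup labels: when given,
#'   the matrix is computed within the sub-catalog of records carrying one of
#'   these labels (a stratified mode to guard against population structure);
#'   by default the full catalog is used, matching the population-wide
#'   analysis.
#' @return An object of class `cooccurrence_matrix`: list with `pairs` (long
#'   data frame: `variant_i`, `variant_j`, `n_i`, `n_j`, `n_ij`, `N`, `ratio`,
#'   `p`, `q`, `flag`), `ratio` (symmetric matrix), `counts` and `meta`.
#' @export
cooccurrence_matrix <- function(catalog, variants, alpha = 0.05, strata = NULL) {
  if (!is.null(strata)) {
    keep <- !is.na(catalog$haplogroup) & catalog$haplogroup %in% strata
    catalog <- variant_catalog(catalog$sample_id[keep], catalog$haplogroup[keep],
                               catalog$variants[keep])
  }
  variants <- unique(vapply(variants, function(v) format(parse_variant_token(v)),
                            character(1), USE.NAMES = FALSE))
  if (length(variants) < 2L) stop("need >= 2 variants", call. = FALSE)
  cts <- pair_counts(catalog, variants)
  idx <- combn(length(variants), 2)
  vi <- variants[idx[1, ]]; vj <- variants[idx[2, ]]
  n_i <- cts$n[vi]; n_j <- cts$n[vj]
  n_ij <- cts$n_ij[cbind(vi, vj)]
  ratio <- normalized_cooccurrence(n_i, n_j, n_ij, cts$N)
  defined <- !is.na(ratio)
  p <- rep(NA_real_, length(ratio))
  p[defined] <- under_cooccurrence_test(n_i[defined], n_j[defined], n_ij[defined], cts$N)
  q <- rep(NA_real_, length(ratio))
  q[defined] <- p.adjust(p[defined], method = "BH")
  pairs <- data.frame(variant_i = vi, variant_j = vj,
                      n_i = unname(n_i), n_j = unname(n_j), n_ij = n_ij, N = cts$N,
                      ratio = unname(ratio), p = unname(p), q = unname(q),
                      flag = ifelse(defined, "", "undefined"),
                      stringsAsFactors = FALSE)
  rmat <- matrix(NA_real_, length(variants), length(variants),
                 dimnames = list(variants, variants))
  rmat[cbind(idx[1, ], idx[2, ])] <- ratio
  rmat[cbind(idx[2, ], idx[1, ])] <- ratio
  structure(list(pairs = pairs, ratio = rmat, counts = cts,
                 meta = list(N = cts$N, n_variants = length(variants),
                             alpha = alpha, adjust = "BH", strata = strata,
                             date = format(Sys.Date()))),
            class = "cooccurrence_matrix")
}

#' @export
print.cooccurrence_matrix <- function(x, ...) {
  cat(sprintf("cooccurrence_matrix: %d variants, %d pairs, N = %d\n",
              x$meta$n_variants, nrow(x$pairs), x$meta$N))
  invisible(x)
}

#' Write a cooccurrence matrix in long format
#'
#' Columns: `variant_i`, `variant_j`, `n_i`, `n_j`, `n_ij`, `N`, `ratio`, `p`,
#' `q`, `flag`.
#'
#' @param x A `cooccurrence_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cooccurrence <- function(x, path) {
  stopifnot(inherits(x, "cooccurrence_matrix"))
  write.table(x$pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flag out-of-context variant pairs within an individual
#'
#' Screens every pair of variants carried by one record against the population
#' catalog and returns the pairs whose normalized cooccurrence falls below
#' `ratio_threshold` with BH-adjusted under-cooccurrence `q < alpha` — the
#' combinations the population suggests are depleted, i.e. a variant sitting
#' on a background where it is rarely seen. Variants absent from the catalog's
#' variant universe are skipped (reported in the `skipped` attribute).
#'
#' @param catalog A [variant_catalog()].
#' @param record Character vector of tokens or one-row catalog slice.
#' @param ratio_threshold Ratio cutoff (default 1).
#' @param alpha q-value cutoff (default 0.05).
#' @return Data frame of flagged pairs sorted by `q` ascending (possibly
#'   zero rows), with attribute `skipped` naming skipped variants.
#' @export
flag_out_of_context <- function(catalog, record, ratio_threshold = 1, alpha = 0.05) {
  toks <- if (is.character(record)) normalize_tokens(record)
          else normalize_tokens(record$variants[[1]])
  universe <- unique(unlist(catalog$variants))
  skipped <- setdiff(toks, universe)
  toks <- intersect(toks, universe)
  empty <- data.frame(variant_i = character(0), variant_j = character(0),
                      n_i = integer(0), n_j = integer(0), n_ij = integer(0),
                      N = integer(0), ratio = numeric(0), p = numeric(0),
                      q = numeric(0), flag = character(0), stringsAsFactors = FALSE)
  if (length(toks) < 2L) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }
  cm <- cooccurrence_matrix(catalog, toks, alpha = alpha)
  hits <- cm$pairs[!is.na(cm$pairs$ratio) & cm$pairs$ratio < ratio_threshold &
                     !is.na(cm$pairs$q) & cm$pairs$q < alpha, , drop = FALSE]
  hits <- hits[order(hits$q), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "skipped") <- skipped
  hits
}
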