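# Transmission-skew testing: do surviving offspring over-represent a paternal
# nuclear allele? Under Mendelian segregation each conception inherits a
# heterozygous father's allele with probability 1/2, so an excess of carriers
# among survivors is evidence that noncarriers were lost in utero.

#' One-sided binomial transmission-skew test
#'
#' Tests whether the number of carrier offspring among survivors exceeds the
#' Mendelian expectation: `p_value = P(X >= n_carriers)` with
#' `X ~ Binomial(n_total, null_p)`. One-sided by design — the hypothesis is
#' directional (survivors are enriched for the protective allele).
#'
#' @param n_carriers Number of surviving carriers.
#' @param n_total Number of survivors with known carrier state.
#' @param null_p Mendelian transmission probability (default 0.5).
#' @return A list of class `skew_test`: `n_carriers`, `n_total`, `null_p`,
#'   `p_value`.
#' @examples
#' transmission_skew_test(8, 8)$p_value  # 2^-8 = 0.00390625
#' @export
transmission_skew_test <- function(n_carriers, n_total, null_p = 0.5) {
  if (n_total < 0 || n_carriers < 0 || n_carriers > n_total) {
    stop("need 0 <= n_carriers <= n_total", call. = FALSE)
  }
  if (null_p <= 0 || null_p >= 1) stop("null_p must lie in (0, 1)", call. = FALSE)
  p <- pbinom(n_carriers - 1, n_total, null_p, lower.tail = FALSE)
  structure(list(n_carriers = as.integer(n_carriers), n_total = as.integer(n_total),
                 null_p = null_p, p_value = p),
            class = "skew_test")
}

#' @export
print.skew_test <- function(x, ...) {
  cat(sprintf("transmission skew: %d/%d carriers among survivors, one-sided p = %.6g (null p = %g)\n",
              x$n_carriers, x$n_total, x$p_value, x$null_p))
  invisible(x)
}

# log-likelihood of (n_c surviving carriers, n_n surviving noncarriers,
# n_u survivors of unknown state, m miscarriages) when conceptions are
# carrier w.p. 1/2, a genotype-independent loss occurs w.p. d, and
# noncarriers are additionally lost w.p. pen. Miscarriage genotypes are
# marginalized: P(miscarriage) = d + (1-d)/2 * pen.
loglik_lethal <- function(d, n_c, n_n, n_u, m, pen) {
  p_sc <- 0.5 * (1 - d)
  p_sn <- 0.5 * (1 - d) * (1 - pen)
  p_su <- p_sc + p_sn
  p_m <- d + 0.5 * (1 - d) * pen
  lt <- function(k, p) if (k == 0) 0 else if (p <= 0) -Inf else k * log(p)
  lt(n_c, p_sc) + lt(n_n, p_sn) + lt(n_u, p_su) + lt(m, p_m)
}

#' Log-likelihood ratio of noncarrier lethality vs Mendelian survival
#'
#' Formalizes the pedigree argument that the miscarriages carried the
#' non-protective allele. Both models share Mendelian segregation (carrier
#' probability 1/2) and a genotype-independent baseline in-utero loss
#' probability `d`, treated as a nuisance parameter and profiled out by
#' maximum likelihood in each model. The alternative adds noncarrier-specific
#' lethality with the given penetrance; the null makes survival independent of
#' genotype (penetrance 0). Miscarriage genotypes are marginalized as unknown,
#' never imputed. At penetrance 0 the two models coincide and the ratio is 0;
#' a positive value favours noncarrier lethality.
#'
#' @param pedigree An [mt_pedigree()]; generation-2 individuals are the
#'   conceptions.
#' @param penetrance Probability a noncarrier conception is lost (default 1).
#' @return A list of class `lethality_lr`: `log_lr`, `n_surviving_carriers`,
#'   `n_surviving_noncarriers`, `n_unknown_survivors`, `n_miscarriages`,
#'   `penetrance`.
#' @export
lethality_likelihood_ratio <- function(pedigree, penetrance = 1) {
  stopifnot(inherits(pedigree, "mt_pedigree"))
  off <- pedigree[pedigree$generation >= 2L, , drop = FALSE]
  surv <- off[off$status == "alive", , drop = FALSE]
  n_c <- sum(surv$carrier == "carrier")
  n_n <- sum(surv$carrier == "noncarrier")
  n_u <- sum(surv$carrier == "unknown")
  m <- sum(off$status == "miscarriage")
  if (n_c + n_n == 0L) stop("no survivor with known carrier state", call. = FALSE)
  if (penetrance < 0 || penetrance > 1) stop("penetrance must lie in [0, 1]", call. = FALSE)

  profile <- function(pen) {
    if (m == 0L) return(loglik_lethal(0, n_c, n_n, n_u, m, pen))
    # -Inf plateaus (e.g. penetrance 1 with noncarrier survivors) are capped
    # during profiling; restored to -Inf afterwards
    ll <- function(d) max(loglik_lethal(d, n_c, n_n, n_u, m, pen), -1e300)
    opt <- optimize(ll, interval = c(0, 1), maximum = TRUE, tol = 1e-10)
    # the optimum can sit on the boundary d -> 0 when lethality alone
    # explains every miscarriage
    best <- max(opt$objective, ll(0))
    if (best <= -1e299) -Inf else best
  }
  ll_alt <- profile(penetrance)
  ll_null <- profile(0)
  structure(list(log_lr = ll_alt - ll_null,
                 n_surviving_carriers = n_c, n_surviving_noncarriers = n_n,
                 n_unknown_survivors = n_u, n_miscarriages = m,
                 penetrance = penetrance),
            class = "lethality_lr")
}

#' @export
print.lethality_lr <- function(x, ...) {
  cat(sprintf("lethality LR: log LR = %.4f (penetrance %g; %d carrier / %d noncarrier survivors, %d miscarriages)\n",
              x$log_lr, x$penetrance, x$n_surviving_carriers,
              x$n_surviving_noncarriers, x$n_miscarriages))
  invisible(x)
}
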