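#' Mann-Whitney U test with tie-aware exact and normal modes
#'
#' Computes the Mann-Whitney U statistic for group `a` (with midranks for
#' ties) and a two-sided p-value. In `"exact"` mode the null distribution
#' of U is built by dynamic programming over all \eqn{\binom{n_a+n_b}{n_a}}
#' assignments of the pooled midrank multiset, so ties are handled exactly;
#' the two-sided p is the null probability of a U at least as far from its
#' mean \eqn{n_a n_b / 2} as observed. In `"normal"` mode the usual
#' normal approximation with the tie-corrected variance and a 0.5
#' continuity correction is used. `"auto"` (default) picks exact when
#' \eqn{n_a + n_b \le 20}.
#'
#' @param a,b numeric vectors (non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return list with `U` (for group `a`), `p` (two-sided), `method`.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b))
    pvStop("both samples must be non-empty", "inputError")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))                      # midranks
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (mode == "auto") mode <- if (n <= 20L) "exact" else "normal"

  if (mode == "exact") {
    ## DP over the midrank multiset: half-integer ranks doubled to stay
    ## integral. f[k+1, s+1] = number of size-k subsets with doubled-rank
    ## sum s.
    d <- as.integer(round(2 * r))
    S <- sum(d)
    f <- matrix(0, nrow = na + 1L, ncol = S + 1L)
    f[1L, 1L] <- 1
    for (x in d) {
      kmax <- min(na, which(rowSums(f) > 0) |> max()) # occupied rows
      for (k in kmax:1L) {
        nz <- which(f[k, ] > 0)
        f[k + 1L, nz + x] <- f[k + 1L, nz + x] + f[k, nz]
      }
    }
    cnt <- f[na + 1L, ]
    sums <- (which(cnt > 0) - 1L) / 2           # achievable rank sums
    ws <- cnt[cnt > 0]
    Us <- sums - na * (na + 1) / 2
    p <- sum(ws[abs(Us - mu) >= abs(U - mu) - 1e-9]) / choose(n, na)
    list(U = U, p = min(1, p), method = "exact")
  } else {
    ties <- table(r)
    tieTerm <- sum(ties^3 - ties)
    sigma2 <- na * nb / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)
    list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
  }
}

#' Compare PV and BV per-species sharing-rate distributions
#'
#' Runs a two-sided Mann-Whitney U test on the per-species sharing rates
#' of the pathogenic and benign variant classes. Both summaries must
#' cover the same species set. Species with zero alignment coverage enter
#' with rate 0 unless `includeUncovered = FALSE`. Significance is
#' declared at alpha = 0.05.
#'
#' @param summaryPV,summaryBV outputs of [sharingSummary()] on the PV and
#'   BV rows of a sharing matrix (see [subsetSharing()]).
#' @param mode test mode, see [mannWhitneyU()].
#' @param includeUncovered include species whose every cell is
#'   `no_alignment` (default TRUE).
#' @param alpha significance level (default 0.05).
#' @return list with `U`, `p`, `median_rate_pv`, `median_rate_bv`,
#'   `n_species`, `significant`, `method`.
#' @export
compareSharing <- function(summaryPV, summaryBV,
                           mode = c("auto", "exact", "normal"),
                           includeUncovered = TRUE, alpha = 0.05) {
  pv <- summaryPV$species; bv <- summaryBV$species
  if (!identical(sort(pv$species), sort(bv$species)))
    pvStop("PV and BV summaries cover different species sets",
           "inputError")
  if (!includeUncovered) {
    covPV <- pv$species[pv$no_alignment < summaryPV$overall$n_variants]
    covBV <- bv$species[bv$no_alignment < summaryBV$overall$n_variants]
    keep <- intersect(covPV, covBV)
    pv <- pv[pv$species %in% keep, , drop = FALSE]
    bv <- bv[bv$species %in% keep, , drop = FALSE]
  }
  if (nrow(pv) < 2L)
    pvStop("need at least two species per group for the rate comparison",
           "inputError")
  t <- mannWhitneyU(pv$rate, bv$rate, mode = match.arg(mode))
  list(U = t$U, p = t$p,
       median_rate_pv = stats::median(pv$rate),
       median_rate_bv = stats::median(bv$rate),
       n_species = nrow(pv),
       significant = t$p < alpha, method = t$method)
}
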