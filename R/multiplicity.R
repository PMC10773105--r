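#' Effective number of independent tests
#'
#' Correlated CNV-proxy probes make a Bonferroni correction on the raw probe
#' count overly strict. Per chromosome, the probe-probe Pearson correlation
#' matrix of signed CNV genotypes is eigen-decomposed and the chromosome's
#' effective test count is the smallest number of leading eigenvalues whose
#' sum reaches `var_frac` (99.5% by default) of the total; chromosome counts
#' are summed. A chromosome with a single variable probe contributes 1;
#' zero-variance probes are excluded and contribute 0.
#'
#' @param m a `cnv_matrix`, typically restricted to frequency-filtered and
#'   pruned probes.
#' @param var_frac eigenvalue-sum fraction defining the cut (default 0.995).
#' @return `n_eff`, the summed effective test count.
#' @export
effective_tests <- function(m, var_frac = 0.995) {
  n_eff <- 0L
  for (chr in unique(m$probes$chrom)) {
    idx <- which(m$probes$chrom == chr)
    G <- m$G[, idx, drop = FALSE]
    v <- apply(G, 2, function(x) stats::var(as.numeric(x)))
    G <- G[, v > 0, drop = FALSE]
    p <- ncol(G)
    if (p == 0L) next
    if (p == 1L) { n_eff <- n_eff + 1L; next }
    R <- sparse_cor(G)
    R[is.na(R)] <- 0
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    k <- which(cumsum(ev) >= var_frac * sum(ev))[1]
    n_eff <- n_eff + k
  }
  n_eff
}

#' Significance thresholds from the effective test count
#'
#' The genome-wide threshold is `0.05 / n_eff`; the experiment-wide threshold
#' additionally divides by the number of assessed traits. Thresholds are kept
#' at full precision; `display` rounds to 2 significant figures for
#' reporting.
#'
#' @param n_eff effective number of tests (>= 1).
#' @param n_traits number of traits assessed (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return list of class `threshold_set` with `n_eff`, `n_traits`, `gw_p`,
#'   `xw_p`.
#' @export
gwas_thresholds <- function(n_eff, n_traits = 1, alpha = 0.05) {
  stopifnot(n_eff >= 1, n_traits >= 1)
  structure(list(n_eff = n_eff, n_traits = n_traits,
                 gw_p = alpha / n_eff,
                 xw_p = alpha / (n_eff * n_traits)),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("N_eff = %s; genome-wide p <= %.2g; experiment-wide p <= %.2g (%d traits)\n",
              format(x$n_eff, big.mark = ","), x$gw_p, x$xw_p, x$n_traits))
  invisible(x)
}
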