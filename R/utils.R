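#' Derive a deterministic child seed from a master seed and a stage name
#'
#' Every stochastic stage of the pipeline draws its own seed from the single
#' master seed so that stages can be re-run independently yet reproducibly.
#' The stage name is folded into the seed with a polynomial string hash modulo
#' a Mersenne prime, keeping the result a valid 32-bit integer.
#'
#' @param master integer master seed.
#' @param stage character stage label, e.g. `"calls"` or `"phenotypes"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

#' Pearson correlation between columns of a sparse matrix
#'
#' Computed from cross-products without densifying, so that probe-by-sample
#' matrices with rare nonzero entries stay cheap. Zero-variance columns get
#' `NA` correlations.
#'
#' @param G a matrix or `Matrix` sparse matrix (samples x probes).
#' @return a dense correlation matrix (probes x probes).
#' @keywords internal
sparse_cor <- function(G) {
  n <- nrow(G)
  mu <- Matrix::colMeans(G)
  cp <- as.matrix(Matrix::crossprod(G)) / n
  cov <- cp - tcrossprod(mu)
  v <- diag(cov)
  sd <- sqrt(pmax(v, 0))
  r <- cov / tcrossprod(sd)
  r[!is.finite(r)] <- NA_real_
  r
}

# interval length under 1-based inclusive coordinates
interval_len <- function(start, end) end - start + 1

# overlap length of [s1,e1] and [s2,e2] under inclusive coordinates; 0 if none
interval_overlap_len <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
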