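#' Encode CNV calls into a probe-by-sample genotype matrix
#'
#' High-confidence calls (`|qs| > qs_cut`) are projected onto array probes:
#' a probe overlapped by a retained duplication is encoded `+1`, by a retained
#' deletion `-1`, and `0` otherwise (no CNV, or only low-quality calls).
#' Intervals are 1-based inclusive, so a call ending exactly at a probe's
#' position covers that probe. If one sample carries both a retained
#' duplication and a retained deletion over the same probe (possible with
#' nested calls), the entry is set to `0` and a warning identifies the
#' conflicts: `0` is the conservative "no confident CNV" state.
#'
#' @param calls data.frame of CNV calls with columns `sample_id`, `chrom`,
#'   `start`, `end`, `type` (`"DUP"`/`"DEL"`), `qs` in `[-1, 1]` (negative for
#'   deletions, positive for duplications).
#' @param probes data.frame probe map with columns `probe_id`, `chrom`, `pos`.
#' @param samples optional character vector fixing the sample universe (so
#'   non-carriers appear as all-zero columns); defaults to the samples present
#'   in `calls`.
#' @param qs_cut quality-score cutoff; only calls with `|qs| > qs_cut` are
#'   encoded (default 0.5).
#' @return an object of class `cnv_matrix`: a list with `G` (sparse sample x
#'   probe Matrix with entries in \{-1, 0, 1\}), `probes` (the probe map,
#'   ordered by chromosome then position) and `samples`.
#' @export
encode_probe_matrix <- function(calls, probes, samples = NULL, qs_cut = 0.5) {
  stopifnot(all(c("sample_id", "chrom", "start", "end", "type", "qs") %in% names(calls)),
            all(c("probe_id", "chrom", "pos") %in% names(probes)))
  probes <- probes[order(probes$chrom, probes$pos), , drop = FALSE]
  rownames(probes) <- NULL
  if (is.null(samples)) samples <- sort(unique(as.character(calls$sample_id)))
  samples <- as.character(samples)

  keep <- abs(calls$qs) > qs_cut
  calls <- calls[keep, , drop = FALSE]
  np <- nrow(probes); ns <- length(samples)

  trip_i <- integer(0); trip_j <- integer(0); trip_x <- integer(0)
  if (nrow(calls) > 0L) {
    samp_idx <- match(as.character(calls$sample_id), samples)
    if (anyNA(samp_idx)) stop("calls reference samples absent from `samples`")
    sign <- ifelse(calls$type == "DUP", 1L, -1L)
    # per chromosome, locate the probe index range covered by each call
    res_i <- vector("list", 0L); res_j <- vector("list", 0L); res_x <- vector("list", 0L)
    for (chr in unique(calls$chrom)) {
      pc <- which(probes$chrom == chr)
      if (length(pc) == 0L) next
      pos <- probes$pos[pc]
      cc <- which(calls$chrom == chr)
      lo <- findInterval(calls$start[cc] - 1L, pos) + 1L  # first probe with pos >= start
      hi <- findInterval(calls$end[cc], pos)              # last probe with pos <= end
      nhit <- pmax(0L, hi - lo + 1L)
      sel <- which(nhit > 0L)
      if (length(sel) == 0L) next
      pj <- pc[sequence(nhit[sel], from = lo[sel])]
      si <- rep(samp_idx[cc[sel]], nhit[sel])
      sx <- rep(sign[cc[sel]], nhit[sel])
      res_i <- c(res_i, list(si)); res_j <- c(res_j, list(pj)); res_x <- c(res_x, list(sx))
    }
    trip_i <- unlist(res_i); trip_j <- unlist(res_j); trip_x <- unlist(res_x)
  }

  if (length(trip_i) > 0L) {
    # collapse duplicate (sample, probe, sign) entries; flag DUP/DEL conflicts
    key <- paste(trip_i, trip_j, sep = ":")
    dt <- data.table::data.table(i = trip_i, j = trip_j, x = trip_x)
    agg <- dt[, list(pos_n = sum(x > 0L), neg_n = sum(x < 0L)), by = c("i", "j")]
    conflict <- agg$pos_n > 0L & agg$neg_n > 0L
    if (any(conflict)) {
      warning(sprintf(
        "%d probe/sample entr%s with both a retained duplication and deletion set to 0",
        sum(conflict), if (sum(conflict) == 1L) "y" else "ies"))
      agg <- agg[!conflict, ]
    }
    G <- Matrix::sparseMatrix(
      i = agg$i, j = agg$j,
      x = as.numeric(ifelse(agg$pos_n > 0L, 1, -1)),
      dims = c(ns, np))
  } else {
    G <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(ns, np))
  }
  dimnames(G) <- list(samples, probes$probe_id)
  structure(list(G = G, probes = probes, samples = samples),
            class = "cnv_matrix")
}

#' @export
print.cnv_matrix <- function(x, ...) {
  cat(sprintf("cnv_matrix: %d samples x %d probes, %d nonzero entries\n",
              nrow(x$G), ncol(x$G), Matrix::nnzero(x$G)))
  invisible(x)
}

#' Extract a genotype view or per-probe dosage encoding
#'
#' The stored matrix is the CNV view (`-1/0/+1`). The `dup` view masks
#' deletion carriers to `NA`; the `del` view masks duplication carriers to
#' `NA` and recodes deletions as `+1` so that the regression coefficient is
#' the effect of carrying the deletion.
#'
#' @param m a `cnv_matrix`.
#' @param probe probe id or column index.
#' @param view one of `"cnv"`, `"dup"`, `"del"`.
#' @return numeric vector of per-sample genotypes (with `NA` for masked
#'   entries under type-specific views).
#' @export
probe_genotypes <- function(m, probe, view = c("cnv", "dup", "del")) {
  view <- match.arg(view)
  g <- as.numeric(m$G[, probe])
  switch(view,
         cnv = g,
         dup = ifelse(g < 0, NA_real_, g),
         del = ifelse(g > 0, NA_real_, -g))
}

#' Per-probe CNV, duplication, and deletion frequencies
#'
#' The CNV frequency of a probe is the fraction of samples overlapped by any
#' high-confidence CNV at that probe; it decomposes exactly into duplication
#' plus deletion frequency. Probes below the frequency cutoff (strict `<`)
#' are flagged for exclusion, mirroring a 0.01% cohort-frequency filter.
#'
#' @param m a `cnv_matrix`.
#' @param freq_cut exclusion threshold on CNV frequency (default `1e-4`);
#'   probes with `cnv_freq < freq_cut` are not retained.
#' @return data.frame with `probe_id`, `dup_freq`, `del_freq`, `cnv_freq`,
#'   `retained`.
#' @export
probe_frequencies <- function(m, freq_cut = 1e-4) {
  stopifnot(nrow(m$G) > 0L)
  n <- nrow(m$G)
  dup <- Matrix::colSums(m$G > 0) / n
  del <- Matrix::colSums(m$G < 0) / n
  cnv <- dup + del
  data.frame(probe_id = colnames(m$G),
             dup_freq = as.numeric(dup),
             del_freq = as.numeric(del),
             cnv_freq = as.numeric(cnv),
             retained = as.numeric(cnv) >= freq_cut,
             stringsAsFactors = FALSE)
}

#' Windowed greedy r-squared pruning of probes
#'
#' Slides a window of `window` probes by `step` along each chromosome and,
#' within each window, removes the later (by genomic position) probe of any
#' pair whose squared Pearson correlation of CNV genotypes exceeds `r2_max`,
#' repeating until no such pair remains (the `--indep-pairwise` convention).
#' Zero-variance probes are treated as correlated with nothing and retained.
#'
#' @param m a `cnv_matrix`.
#' @param r2_max squared-correlation threshold (default 0.9999; pairs with
#'   `r^2 > r2_max` are pruned).
#' @param window window size in probes (default 500).
#' @param step slide in probes (default 250).
#' @return character vector of retained probe ids, in genomic order.
#' @export
prune_probes <- function(m, r2_max = 0.9999, window = 500L, step = 250L) {
  probes <- m$probes
  keep <- rep(TRUE, nrow(probes))
  for (chr in unique(probes$chrom)) {
    idx <- which(probes$chrom == chr)
    if (length(idx) < 2L) next
    starts <- seq(1L, length(idx), by = step)
    for (w0 in starts) {
      win <- idx[seq(w0, min(w0 + window - 1L, length(idx)))]
      win <- win[keep[win]]
      if (length(win) < 2L) next
      r2 <- sparse_cor(m$G[, win, drop = FALSE])^2
      alive <- rep(TRUE, length(win))
      repeat {
        removed <- FALSE
        for (a in seq_along(win)) {
          if (!alive[a]) next
          for (b in seq_along(win)) {
            if (b <= a || !alive[b]) next
            if (!is.na(r2[a, b]) && r2[a, b] > r2_max) {
              alive[b] <- FALSE  # drop the later probe, keep earliest proxy
              removed <- TRUE
            }
          }
        }
        if (!removed) break
      }
      keep[win[!alive]] <- FALSE
      if (w0 + window - 1L >= length(idx)) break
    }
  }
  probes$probe_id[keep]
}

#' Restrict a cnv_matrix to a subset of probes and/or samples
#'
#' @param m a `cnv_matrix`.
#' @param probes probe ids to keep (default all).
#' @param samples sample ids to keep (default all).
#' @return a `cnv_matrix`.
#' @export
subset_matrix <- function(m, probes = NULL, samples = NULL) {
  G <- m$G
  pr <- m$probes
  if (!is.null(probes)) {
    j <- match(probes, colnames(G))
    stopifnot(!anyNA(j))
    j <- sort(j)  # preserve genomic order
    G <- G[, j, drop = FALSE]
    pr <- pr[j, , drop = FALSE]
    rownames(pr) <- NULL
  }
  sm <- m$samples
  if (!is.null(samples)) {
    i <- match(samples, rownames(G))
    stopifnot(!anyNA(i))
    G <- G[i, , drop = FALSE]
    sm <- samples
  }
  structure(list(G = G, probes = pr, samples = sm), class = "cnv_matrix")
}
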