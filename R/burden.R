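#' Per-individual CNV burden in Mb and gene units
#'
#' The Mb burden of a sample is the summed length (`(end - start + 1)/1e6`,
#' 1-based inclusive) of its high-confidence autosomal calls of a given type;
#' the gene burden is the number of distinct gene intervals overlapped by at
#' least 1 bp by those calls (a gene hit by two calls of the same type counts
#' once). The CNV burden is defined as duplication burden plus deletion
#' burden in both units.
#'
#' @param calls data.frame of CNV calls (will be QS-filtered with `qs_cut`).
#' @param samples character vector of the sample universe (non-carriers get
#'   zero burden).
#' @param genes optional gene interval data.frame (`gene`, `chrom`, `start`,
#'   `end`); required for gene-unit burdens.
#' @param qs_cut quality cutoff (default 0.5; only `|qs| > qs_cut` calls
#'   count).
#' @return data.frame per sample: `sample_id`, `dup_mb`, `del_mb`, `cnv_mb`,
#'   and (with `genes`) `dup_genes`, `del_genes`, `cnv_genes`.
#' @export
compute_burden <- function(calls, samples, genes = NULL, qs_cut = 0.5) {
  calls <- calls[abs(calls$qs) > qs_cut, , drop = FALSE]
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (ty in c("DUP", "DEL")) {
    cc <- calls[calls$type == ty, , drop = FALSE]
    mb <- tapply(interval_len(cc$start, cc$end) / 1e6, cc$sample_id, sum)
    col <- if (ty == "DUP") "dup_mb" else "del_mb"
    out[[col]] <- as.numeric(ifelse(is.na(mb[samples]), 0, mb[samples]))
    if (!is.null(genes)) {
      gcount <- rep(0L, length(samples))
      if (nrow(cc) > 0L) {
        hits <- lapply(seq_len(nrow(genes)), function(k) {
          ov <- cc$chrom == genes$chrom[k] & cc$start <= genes$end[k] &
            cc$end >= genes$start[k]
          unique(cc$sample_id[ov])
        })
        tab <- table(unlist(hits))  # per sample: number of distinct genes hit
        gcount <- as.integer(ifelse(is.na(tab[samples]), 0L, tab[samples]))
      }
      out[[if (ty == "DUP") "dup_genes" else "del_genes"]] <- as.numeric(gcount)
    }
  }
  out$cnv_mb <- out$dup_mb + out$del_mb
  if (!is.null(genes)) out$cnv_genes <- out$dup_genes + out$del_genes
  out
}

#' Interval overlap predicate
#'
#' `any_1bp`: the call and region share at least one base (inclusive
#' coordinates). `reciprocal_50`: the overlap exceeds half the call's length
#' AND half the region's length (strict `>`).
#'
#' @param call_start,call_end call interval.
#' @param region_start,region_end region interval.
#' @param rule `"any_1bp"` or `"reciprocal_50"`.
#' @return logical (vectorized over calls).
#' @export
interval_overlaps <- function(call_start, call_end, region_start, region_end,
                              rule = c("any_1bp", "reciprocal_50")) {
  rule <- match.arg(rule)
  ov <- interval_overlap_len(call_start, call_end, region_start, region_end)
  if (rule == "any_1bp") return(ov >= 1)
  ov > 0.5 * interval_len(call_start, call_end) &
    ov > 0.5 * interval_len(region_start, region_end)
}

# which calls overlap any interval of a partition (respecting the partition's
# per-interval type applicability)?
calls_in_partition <- function(calls, partition, rule) {
  hit <- rep(FALSE, nrow(calls))
  for (k in seq_len(nrow(partition$intervals))) {
    iv <- partition$intervals[k, ]
    applies <- if (is.null(iv$types) || is.na(iv$types) || iv$types == "both") {
      rep(TRUE, nrow(calls))
    } else calls$type == toupper(iv$types)
    same_chr <- calls$chrom == iv$chrom
    ov <- interval_overlaps(calls$start, calls$end, iv$start, iv$end, rule)
    hit <- hit | (applies & same_chr & ov)
  }
  hit
}

#' Define a genomic burden partition
#'
#' @param name partition label (e.g. `"CNVR"`, `"GD"`, `"R1"`, `"R2"`,
#'   `"R3"`).
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `types` (`"both"`, `"DUP"`, or `"DEL"`: which burden types the interval
#'   counts toward; e.g. a duplication syndrome counts only toward the
#'   duplication burden).
#' @return a list of class `burden_partition`.
#' @export
burden_partition <- function(name, intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (is.null(intervals$types)) intervals$types <- "both"
  structure(list(name = name, intervals = intervals), class = "burden_partition")
}

#' Subset and corrected burdens over a genomic partition
#'
#' The subset burden counts only calls overlapping the partition (per the
#' overlap rule and the partition's type-applicability); the corrected
#' burden is the total minus the subset, so `subset + corrected = total`
#' holds exactly per sample, type, and unit. A call straddling two
#' partitions' regions contributes to both subset burdens.
#'
#' @param calls CNV call data.frame.
#' @param samples sample universe.
#' @param partition a [burden_partition()].
#' @param rule overlap rule (see [interval_overlaps()]).
#' @param genes optional gene intervals for gene-unit burdens.
#' @param qs_cut quality cutoff.
#' @return list with `subset`, `corrected`, and `total` burden tables.
#' @export
subset_corrected_burden <- function(calls, samples, partition,
                                    rule = c("any_1bp", "reciprocal_50"),
                                    genes = NULL, qs_cut = 0.5) {
  rule <- match.arg(rule)
  calls <- calls[abs(calls$qs) > qs_cut, , drop = FALSE]
  hit <- calls_in_partition(calls, partition, rule)
  total <- compute_burden(calls, samples, genes, qs_cut = -1)  # already filtered
  subset <- compute_burden(calls[hit, , drop = FALSE], samples, genes, qs_cut = -1)
  corrected <- total
  num <- setdiff(names(total), "sample_id")
  corrected[num] <- total[num] - subset[num]
  list(subset = subset, corrected = corrected, total = total)
}

#' GWAS-signal-corrected burden for one disease
#'
#' Removes from the burden, in a disease- and type-specific fashion, calls
#' overlapping (>= 1 bp) a CNV region associated with that disease: regions
#' associated through the mirror or U-shape models remove both CNV types,
#' duplication-only regions remove duplications, deletion-only regions
#' remove deletions. Removed calls leave the matching type burden and hence
#' the CNV (dup + del) burden.
#'
#' @param calls CNV call data.frame.
#' @param samples sample universe.
#' @param cnvr_assoc data.frame of disease-associated regions with columns
#'   `chrom`, `start`, `end`, `models` (list-column or comma-separated
#'   string of significant model names for this disease).
#' @param genes optional gene intervals.
#' @param qs_cut quality cutoff.
#' @return a corrected burden table (same layout as [compute_burden()]).
#' @export
signal_corrected_burden <- function(calls, samples, cnvr_assoc, genes = NULL,
                                    qs_cut = 0.5) {
  calls <- calls[abs(calls$qs) > qs_cut, , drop = FALSE]
  drop <- rep(FALSE, nrow(calls))
  for (k in seq_len(nrow(cnvr_assoc))) {
    rg <- cnvr_assoc[k, ]
    models <- rg$models
    if (is.list(models)) models <- models[[1]]
    else models <- strsplit(as.character(models), ",\\s*")[[1]]
    both <- any(models %in% c("mirror", "ushape"))
    types <- c(if (both || "duponly" %in% models) "DUP",
               if (both || "delonly" %in% models) "DEL")
    ov <- calls$chrom == rg$chrom &
      interval_overlaps(calls$start, calls$end, rg$start, rg$end, "any_1bp")
    drop <- drop | (ov & calls$type %in% types)
  }
  compute_burden(calls[!drop, , drop = FALSE], samples, genes, qs_cut = -1)
}

#' Associate a burden metric with disease status or disease burden
#'
#' Logistic regression for a binary disease, ordinary least squares for the
#' quantitative disease burden, with disease-relevant covariates. Variance
#' explained comes from a covariate-free model: McFadden pseudo-R-squared
#' (`1 - ll_model / ll_null`) for diseases, adjusted R-squared for the
#' disease-burden outcome.
#'
#' @param burden numeric burden metric per sample.
#' @param outcome binary status (`"case"`/`"control"`, logical, 0/1) or a
#'   numeric disease-burden count.
#' @param covariates data.frame of covariates or `NULL`.
#' @param binary `TRUE` for logistic (default guessed from the outcome).
#' @return list: `beta`, `se`, `p`, `or` (logistic only),
#'   `variance_explained`.
#' @export
burden_association <- function(burden, outcome, covariates = NULL, binary = NULL) {
  if (stats::var(burden, na.rm = TRUE) == 0) stop("zero-variance burden")
  if (is.character(outcome) || is.factor(outcome)) outcome <- as.integer(outcome == "case")
  if (is.logical(outcome)) outcome <- as.integer(outcome)
  if (is.null(binary)) binary <- all(outcome %in% c(0, 1))
  dat <- data.frame(y = outcome, burden = burden)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (binary) {
    fit <- stats::glm(y ~ ., data = dat, family = stats::binomial())
    co <- summary(fit)$coefficients["burden", ]
    fit0 <- stats::glm(y ~ burden, data = dat, family = stats::binomial())
    null0 <- stats::glm(y ~ 1, data = dat, family = stats::binomial())
    r2 <- 1 - as.numeric(stats::logLik(fit0) / stats::logLik(null0))
    list(beta = unname(co[1]), se = unname(co[2]), p = unname(co[4]),
         or = exp(unname(co[1])), variance_explained = r2)
  } else {
    fit <- stats::lm(y ~ ., data = dat)
    co <- summary(fit)$coefficients["burden", ]
    fit0 <- stats::lm(y ~ burden, data = dat)
    r2 <- summary(fit0)$adj.r.squared
    list(beta = unname(co[1]), se = unname(co[2]), p = unname(co[4]),
         or = NA_real_, variance_explained = r2)
  }
}
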