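#' Define a CNV region around a lead probe
#'
#' The region's boundaries are the positions of the most distant probes on
#' the lead's chromosome lying within `window_bp` of the lead whose squared
#' Pearson correlation with the lead genotype is at least `r2_min`. For
#' U-shape signals the correlation is computed on `|genotype|` (the U-shape
#' dosage). An isolated lead yields the single-position interval
#' `[lead, lead]`.
#'
#' @param m a `cnv_matrix`.
#' @param lead lead probe id.
#' @param model association model of the signal (determines the dosage used
#'   for tagging).
#' @param r2_min tagging threshold (default 0.5).
#' @param window_bp tagging window around the lead (default 3e6).
#' @return list with `chrom`, `start`, `end`, `lead`.
#' @export
define_cnvr <- function(m, lead, model = "mirror", r2_min = 0.5, window_bp = 3e6) {
  j <- match(lead, colnames(m$G))
  stopifnot(!is.na(j))
  lead_chrom <- m$probes$chrom[j]
  lead_pos <- m$probes$pos[j]
  g_lead <- as.numeric(m$G[, j])
  if (model == "ushape") g_lead <- abs(g_lead)
  if (stats::var(g_lead) == 0) stop("lead probe has zero variance")
  cand <- which(m$probes$chrom == lead_chrom &
                  abs(m$probes$pos - lead_pos) <= window_bp)
  tagged <- vapply(cand, function(k) {
    g <- as.numeric(m$G[, k])
    if (model == "ushape") g <- abs(g)
    if (stats::var(g) == 0) return(FALSE)
    r <- stats::cor(g_lead, g)
    !is.na(r) && r^2 >= r2_min
  }, logical(1))
  pos <- m$probes$pos[cand[tagged]]
  if (length(pos) == 0L) pos <- lead_pos  # isolated lead
  list(chrom = lead_chrom, start = min(pos), end = max(pos), lead = lead)
}

#' Merge overlapping CNV regions
#'
#' Takes per-signal intervals (with their disease/model annotations) and
#' merges any that overlap by at least 1 bp (inclusive coordinates; sharing a
#' single position counts), transitively. The merged region spans the union
#' extent (the maximal CNVR) and carries the concatenated member signals.
#'
#' @param signals data.frame with columns `chrom`, `start`, `end` and any
#'   annotation columns (e.g. `disease`, `model`, `lead`, `p`).
#' @return data.frame of merged regions: `cnvr_id`, `chrom`, `start`, `end`,
#'   `n_signals`, plus a `members` list-column of the member rows.
#' @export
merge_cnvrs <- function(signals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(signals)))
  if (nrow(signals) == 0L) {
    return(data.frame(cnvr_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), n_signals = integer(0)))
  }
  out <- list()
  for (chr in sort(unique(signals$chrom))) {
    s <- signals[signals$chrom == chr, , drop = FALSE]
    ir <- IRanges::IRanges(start = s$start, end = s$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)  # >=1 bp overlap only
    hits <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
    for (k in seq_along(red)) {
      mem <- s[grp == k, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr,
        start = min(mem$start), end = max(mem$end),
        n_signals = nrow(mem), stringsAsFactors = FALSE)
      attr(out[[length(out)]], "members") <- mem
    }
  }
  members <- lapply(out, attr, "members")
  res <- do.call(rbind, out)
  res <- cbind(cnvr_id = sprintf("CNVR%03d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  res$members <- members
  rownames(res) <- NULL
  res
}

#' Label the best and main association models of a signal
#'
#' Among the genome-wide significant models of one association, the best
#' model has the lowest p-value; the main model indicates the driving CNV
#' type: duplication-only or deletion-only when either is significant,
#' otherwise the best model. Both type-specific models being significant for
#' one association is flagged for manual review.
#'
#' @param models character vector of significant model names.
#' @param pvals their p-values.
#' @return list with `best_model`, `main_model`, `review` flag.
#' @export
label_models <- function(models, pvals) {
  stopifnot(length(models) == length(pvals), length(models) >= 1L,
            all(models %in% c("mirror", "ushape", "duponly", "delonly")))
  best <- models[which.min(pvals)]
  has_dup <- "duponly" %in% models
  has_del <- "delonly" %in% models
  review <- has_dup && has_del
  if (review) warning("both duplication-only and deletion-only significant; flagged for review")
  main <- if (has_dup && !has_del) "duponly"
          else if (has_del && !has_dup) "delonly"
          else best
  list(best_model = best, main_model = main, review = review)
}

#' Count genes overlapping a CNV region
#'
#' A gene counts if its interval overlaps the region by at least 1 bp
#' (inclusive coordinates); a gene straddling a boundary counts.
#'
#' @param cnvr list or one-row data.frame with `chrom`, `start`, `end`.
#' @param genes data.frame of gene intervals: `gene`, `chrom`, `start`,
#'   `end`.
#' @return number of overlapping genes.
#' @export
count_genes <- function(cnvr, genes) {
  g <- genes[genes$chrom == cnvr$chrom, , drop = FALSE]
  if (nrow(g) == 0L) return(0L)
  sum(g$start <= cnvr$end & g$end >= cnvr$start)
}

#' Assign CNV carriers to breakpoint categories
#'
#' Carriers are grouped by reciprocal 50% overlap between their call and a
#' category interval (the call covers > 50% of the category and vice versa);
#' calls matching no category are labeled `"atypical"`. The copy-neutral
#' group contains samples with no call at the locus at all — carriers of
#' low-quality (`|QS| <= 0.5`) calls are excluded altogether.
#'
#' @param calls CNV call data.frame (all calls, including low-quality ones).
#' @param locus list with `chrom`, `start`, `end`.
#' @param categories data.frame with `name`, `start`, `end`.
#' @param samples character vector of the full sample universe.
#' @param qs_cut quality cutoff (default 0.5).
#' @param type restrict to `"DUP"` or `"DEL"` carriers (default both).
#' @return data.frame `sample_id`, `group` (category name, `"atypical"`, or
#'   `"copy_neutral"`), `copy_number`; low-quality carriers are absent.
#' @export
carrier_groups <- function(calls, locus, categories, samples, qs_cut = 0.5,
                           type = c("DUP", "DEL")) {
  at_locus <- calls$chrom == locus$chrom & calls$start <= locus$end &
    calls$end >= locus$start
  loc_calls <- calls[at_locus, , drop = FALSE]
  lowq_ids <- unique(loc_calls$sample_id[abs(loc_calls$qs) <= qs_cut])
  hi <- loc_calls[abs(loc_calls$qs) > qs_cut & loc_calls$type %in% type, , drop = FALSE]
  grp <- rep("atypical", nrow(hi))
  for (k in seq_len(nrow(categories))) {
    ov <- interval_overlap_len(hi$start, hi$end, categories$start[k], categories$end[k])
    rec <- ov > 0.5 * interval_len(hi$start, hi$end) &
      ov > 0.5 * interval_len(categories$start[k], categories$end[k])
    grp[rec & grp == "atypical"] <- categories$name[k]
  }
  carrier <- data.frame(sample_id = hi$sample_id, group = grp,
                        copy_number = hi$copy_number, stringsAsFactors = FALSE)
  neutral_ids <- setdiff(samples, c(unique(loc_calls$sample_id)))
  rbind(carrier,
        data.frame(sample_id = neutral_ids, group = "copy_neutral",
                   copy_number = 2L, stringsAsFactors = FALSE))
}

#' Disease prevalence by carrier group with exact tests vs copy-neutral
#'
#' Prevalence `q = c/n` with standard error `sqrt(q(1-q)/n)`; each carrier
#' group is compared to the copy-neutral group by a two-sided 2x2 Fisher
#' exact test. Empty groups are skipped.
#'
#' @param groups data.frame from [carrier_groups()] (must contain a
#'   `copy_neutral` group).
#' @param status named status vector (by sample id), `"case"`/`"control"`;
#'   other values are dropped.
#' @return data.frame per group: `group`, `n`, `cases`, `q`, `se`,
#'   `fisher_p` (NA for the copy-neutral reference).
#' @export
group_prevalence <- function(groups, status) {
  st <- status[groups$sample_id]
  keep <- st %in% c("case", "control")
  groups <- groups[keep, , drop = FALSE]
  st <- st[keep]
  stopifnot("copy_neutral" %in% groups$group)
  ref_case <- sum(st == "case" & groups$group == "copy_neutral")
  ref_n <- sum(groups$group == "copy_neutral")
  rows <- lapply(unique(groups$group), function(g) {
    n <- sum(groups$group == g)
    c_ <- sum(st == "case" & groups$group == g)
    q <- c_ / n
    se <- sqrt(q * (1 - q) / n)
    fp <- if (g == "copy_neutral") NA_real_ else {
      stats::fisher.test(matrix(c(c_, n - c_, ref_case, ref_n - ref_case), nrow = 2))$p.value
    }
    data.frame(group = g, n = n, cases = c_, q = q, se = se, fisher_p = fp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
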