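#' Read / write the pipeline's tab-delimited artifacts
#'
#' Calls, probe maps, and phenotype tables travel as plain TSV in a
#' PennCNV-like dialect (1-based inclusive coordinates).
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_cnv_calls <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' @rdname read_cnv_calls
#' @param x a data.frame to write.
#' @export
write_tsv <- function(x, path) {
  drop <- vapply(x, is.list, logical(1))  # list-columns are in-memory only
  data.table::fwrite(x[, !drop, drop = FALSE], path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All thresholds default to the published analysis settings: quality cutoff
#' `|QS| > 0.5`, probe CNV frequency filter 0.01%, pruning at `r^2 >
#' 0.9999` (window 500, step 250), genotypic Fisher prefilter `p <= 0.001`
#' with at least 2 diseased carriers, tagging at `r^2 >= 0.5` within 3 Mb,
#' validation tier threshold `1e-4`, and a 99.5% eigenvalue fraction for the
#' effective test count.
#'
#' @param ... overrides of any default element.
#' @return a named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    qs_cut = 0.5, freq_cut = 1e-4, fisher_cut = 1e-3, min_cases = 2L,
    r2_prune = 0.9999, prune_window = 500L, prune_step = 250L,
    r2_tag = 0.5, window_bp = 3e6,
    tier_alpha = 1e-4, var_frac = 0.995, alpha = 0.05,
    models = c("mirror", "ushape", "duponly", "delonly"),
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the CNV-GWAS pipeline end to end
#'
#' Orchestrates encode -> frequency filter -> prune -> effective tests ->
#' prefilter -> four-model GWAS -> stepwise conditional -> CNV regions ->
#' validation tiers for one or more diseases (plus the linear disease-burden
#' scan), writing each stage's table to `out_dir` when given.
#'
#' @param calls CNV call data.frame.
#' @param probes probe map data.frame.
#' @param phenotypes phenotype table (as from [simulate_phenotypes()]):
#'   per-disease `status_*` columns, covariates, `disease_burden`.
#' @param diseases character vector of disease ids (matched against the
#'   `status_<id>` columns).
#' @param covariate_cols names of candidate covariate columns (default:
#'   `age`, `sex`, `array` and any `PC*` columns present).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for stage TSV artifacts.
#' @param include_burden also run the linear disease-burden GWAS (default
#'   TRUE).
#' @return list with `matrix`, `frequencies`, `pruned`, `n_eff`,
#'   `thresholds`, `gwas` (all records), `signals` (independent leads with
#'   CNVR and tier), `cnvrs` (merged regions).
#' @export
run_pipeline <- function(calls, probes, phenotypes, diseases,
                         covariate_cols = NULL, config = pipeline_config(),
                         out_dir = NULL, include_burden = TRUE) {
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  emit <- function(x, name) {
    if (!is.null(out_dir)) write_tsv(x, file.path(out_dir, paste0(name, ".tsv")))
    x
  }
  samples <- phenotypes$sample_id
  if (is.null(covariate_cols)) {
    covariate_cols <- intersect(c("age", "sex", "array",
                                  grep("^PC", names(phenotypes), value = TRUE)),
                                names(phenotypes))
  }

  m <- encode_probe_matrix(calls, probes, samples = samples, qs_cut = config$qs_cut)
  freqs <- emit(probe_frequencies(m, freq_cut = config$freq_cut), "probe_frequencies")
  m_f <- subset_matrix(m, probes = freqs$probe_id[freqs$retained])
  pruned <- prune_probes(m_f, r2_max = config$r2_prune,
                         window = config$prune_window, step = config$prune_step)
  m_p <- subset_matrix(m_f, probes = pruned)
  n_eff <- max(1L, effective_tests(m_p, var_frac = config$var_frac))
  n_traits <- length(diseases) + as.integer(include_burden)
  thr <- gwas_thresholds(n_eff, n_traits = n_traits, alpha = config$alpha)

  gwas_all <- list()
  signal_rows <- list()
  for (d in diseases) {
    status <- phenotypes[[paste0("status_", d)]]
    cc <- status != "excluded"
    sel <- select_covariates(status[cc], phenotypes[cc, covariate_cols, drop = FALSE])
    covs <- if (length(sel)) phenotypes[, sel, drop = FALSE] else NULL
    fr <- probe_frequencies(m_p, freq_cut = config$freq_cut)
    pf <- prefilter_probes(m_p, fr, status, fisher_cut = config$fisher_cut,
                           min_cases = config$min_cases)
    for (model in config$models) {
      pass <- pf$probe_id[pf[[model_pass_col(model)]]]
      if (length(pass) == 0L) next
      res <- run_gwas(m_p, status, covs, model, probes = pass)
      res$disease <- d
      gwas_all[[paste(d, model)]] <- res
      leads <- stepwise_conditional(m_p, status, covs, model,
                                    threshold = thr$gw_p, probes = pass)
      if (nrow(leads) == 0L) next
      for (i in seq_len(nrow(leads))) {
        iv <- define_cnvr(m_p, leads$probe_id[i], model,
                          r2_min = config$r2_tag, window_bp = config$window_bp)
        signal_rows[[length(signal_rows) + 1L]] <- data.frame(
          disease = d, model = model, lead = leads$probe_id[i],
          p = leads$p[i], beta = leads$beta[i], se = leads$se[i],
          chrom = iv$chrom, start = iv$start, end = iv$end,
          fisher_p = pf$fisher_p[match(leads$probe_id[i], pf$probe_id)],
          is_burden = FALSE, stringsAsFactors = FALSE)
      }
    }
  }

  if (include_burden) {
    burden <- phenotypes$disease_burden
    sel <- tryCatch(select_covariates(
      as.integer(burden > stats::median(burden)),
      phenotypes[, covariate_cols, drop = FALSE]), error = function(e) covariate_cols)
    covs <- if (length(sel)) phenotypes[, sel, drop = FALSE] else NULL
    for (model in config$models) {
      leads <- stepwise_conditional(m_p, covariates = covs, model = model,
                                    threshold = thr$gw_p, burden = burden)
      if (nrow(leads) == 0L) next
      for (i in seq_len(nrow(leads))) {
        iv <- define_cnvr(m_p, leads$probe_id[i], model,
                          r2_min = config$r2_tag, window_bp = config$window_bp)
        signal_rows[[length(signal_rows) + 1L]] <- data.frame(
          disease = "disease_burden", model = model, lead = leads$probe_id[i],
          p = leads$p[i], beta = leads$beta[i], se = leads$se[i],
          chrom = iv$chrom, start = iv$start, end = iv$end,
          fisher_p = NA_real_, is_burden = TRUE, stringsAsFactors = FALSE)
      }
    }
  }

  gwas <- if (length(gwas_all)) do.call(rbind, gwas_all) else NULL
  if (!is.null(gwas)) { rownames(gwas) <- NULL; emit(gwas, "gwas") }

  signals <- if (length(signal_rows)) do.call(rbind, signal_rows) else
    data.frame(disease = character(0), model = character(0), lead = character(0),
               p = numeric(0), beta = numeric(0), se = numeric(0),
               chrom = character(0), start = numeric(0), end = numeric(0),
               fisher_p = numeric(0), is_burden = logical(0))

  # validation tiers per signal
  if (nrow(signals) > 0L) {
    tiers <- integer(nrow(signals))
    for (i in seq_len(nrow(signals))) {
      s <- signals[i, ]
      if (s$is_burden) { tiers[i] <- 1L; next }
      status <- phenotypes[[paste0("status_", s$disease)]]
      cc <- status != "excluded"
      sel <- select_covariates(status[cc], phenotypes[cc, covariate_cols, drop = FALSE])
      covs <- if (length(sel)) phenotypes[cc, sel, drop = FALSE] else NULL
      dos <- encode_dosage(as.numeric(m_p$G[, s$lead]), s$model)[cc]
      enc <- stats::setNames(list(dos), s$model)
      res_p <- tryCatch(residual_regression(status[cc], covs, enc)$p,
                        error = function(e) NA_real_)
      alh <- phenotypes[[paste0("age_last_healthy_", s$disease)]][cc]
      cox_p <- tryCatch(coxph_onset(alh, as.integer(status[cc] == "case"),
                                    covs, enc)$p,
                        error = function(e) NA_real_)
      tiers[i] <- suppressWarnings(assign_tier(
        if (is.na(s$fisher_p)) Inf else s$fisher_p,
        if (is.na(res_p)) Inf else res_p,
        if (is.na(cox_p)) Inf else cox_p,
        alpha = config$tier_alpha))
    }
    signals$tier <- tiers
    signals$signal_id <- sprintf("SIG%03d", seq_len(nrow(signals)))
  } else {
    signals$tier <- integer(0)
    signals$signal_id <- character(0)
  }
  emit(signals, "signals")

  cnvrs <- merge_cnvrs(signals)
  emit(cnvrs, "cnvrs")

  list(matrix = m_p, frequencies = freqs, pruned = pruned, n_eff = n_eff,
       thresholds = thr, gwas = gwas, signals = signals, cnvrs = cnvrs)
}
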