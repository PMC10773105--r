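#' Residual-regression validation of an association signal
#'
#' Transforms the binary disease status into a continuous variable by taking
#' the response residuals `y - fitted` of the covariate-only logistic
#' regression, then regresses the residuals on each significantly associated
#' dosage encoding by ordinary least squares and reports the encoding with
#' the lowest p-value.
#'
#' @param status per-sample status (`"case"`/`"control"`; excluded samples
#'   removed beforehand) or 0/1 vector.
#' @param covariates data.frame of disease-relevant covariates (may be
#'   `NULL` for an intercept-only null model).
#' @param encodings named list of numeric dosage vectors (one per
#'   significantly associated model; `NA` entries are dropped per encoding).
#' @return list with `model` (name of the winning encoding), `beta`, `p`.
#' @export
residual_regression <- function(status, covariates, encodings) {
  stopifnot(length(encodings) >= 1L)
  y <- if (is.character(status) || is.factor(status)) as.integer(status == "case") else as.integer(status)
  dat <- if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    data.frame(y = y)
  } else cbind(y = y, as.data.frame(covariates))
  fit0 <- stats::glm(y ~ ., data = dat, family = stats::binomial())
  r <- y - stats::fitted(fit0)
  if (all(abs(r) < 1e-6)) stop("covariate-only model is saturated; residuals are all zero")
  best <- NULL
  for (nm in names(encodings)) {
    d <- encodings[[nm]]
    use <- !is.na(d)
    f <- stats::lm(r[use] ~ d[use])
    co <- summary(f)$coefficients
    if (nrow(co) < 2L) next
    rec <- list(model = nm, beta = co[2, 1], p = co[2, 4])
    if (is.null(best) || rec$p < best$p) best <- rec
  }
  if (is.null(best)) stop("no informative encoding")
  best
}

#' Cox proportional-hazards age-of-onset validation
#'
#' Fits a CoxPH model (Efron tie handling) of age at last healthy
#' measurement on each encoded dosage plus covariates and reports the
#' encoding with the lowest genotype p-value, together with its hazard
#' ratio.
#'
#' @param time age at last healthy measurement (years; > 0).
#' @param event 1 for cases (event = diagnosis), 0 for censored controls.
#' @param covariates data.frame of covariates or `NULL`.
#' @param encodings named list of numeric dosage vectors.
#' @return list with `model`, `hr`, `p`, and the fitted `coxph` object of
#'   the winning encoding.
#' @export
coxph_onset <- function(time, event, covariates = NULL, encodings) {
  stopifnot(length(encodings) >= 1L, sum(event) >= 1L)
  best <- NULL
  cov_df <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  for (nm in names(encodings)) {
    d <- encodings[[nm]]
    use <- !is.na(d) & !is.na(time) & time > 0
    if (!is.null(cov_df)) use <- use & stats::complete.cases(cov_df)
    if (length(unique(d[use])) < 2L) next  # no genotype variance
    dat <- data.frame(time = time[use], event = event[use], dosage = d[use])
    if (!is.null(cov_df)) dat <- cbind(dat, cov_df[use, , drop = FALSE])
    fit <- tryCatch(
      survival::coxph(survival::Surv(time, event) ~ ., data = dat, ties = "efron"),
      error = function(e) NULL)
    if (is.null(fit)) next
    co <- summary(fit)$coefficients
    if (!"dosage" %in% rownames(co)) next
    rec <- list(model = nm, hr = unname(co["dosage", "exp(coef)"]),
                p = unname(co["dosage", "Pr(>|z|)"]), fit = fit)
    if (is.null(best) || rec$p < best$p) best <- rec
  }
  if (is.null(best)) stop("no encoding with genotype variance among at-risk sets")
  best
}

#' Kaplan-Meier disease-free survival curves
#'
#' Product-limit estimates per group with Greenwood-variance 95% confidence
#' bands (plain/symmetric intervals).
#'
#' @param time event or censoring times.
#' @param event 1 = event, 0 = censored.
#' @param groups group labels.
#' @return a `survfit` object.
#' @export
kaplan_meier <- function(time, event, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(time))
  keep <- !is.na(time) & !is.na(event)
  survival::survfit(survival::Surv(time[keep], event[keep]) ~ groups[keep],
                    conf.type = "plain")
}

#' Assign a statistical confidence tier
#'
#' Counts how many of the three validation approaches (genotypic Fisher,
#' residual regression, CoxPH onset) reach `p <= alpha`: 3 passes is tier 1,
#' 2 is tier 2, 1 is tier 3. A signal validated by none is demoted (`NA`)
#' with a warning. Disease-burden signals, whose quantitative outcome does
#' not suffer the binary-trait caveats, are tier 1 unconditionally.
#'
#' @param fisher_p,residual_p,coxph_p validation p-values.
#' @param is_burden_signal flag; `TRUE` forces tier 1.
#' @param alpha validation threshold (default 1e-4).
#' @return integer tier (1, 2, 3) or `NA` for a demoted signal.
#' @export
assign_tier <- function(fisher_p, residual_p, coxph_p, is_burden_signal = FALSE,
                        alpha = 1e-4) {
  if (is_burden_signal) return(1L)
  k <- sum(c(fisher_p, residual_p, coxph_p) <= alpha)
  if (k == 0L) {
    warning("signal validated by none of the three approaches; demoted")
    return(NA_integer_)
  }
  c(3L, 2L, 1L)[k]
}

#' Directional replication of discovery signals
#'
#' Each discovery lead is matched to the replication-cohort probe with the
#' closest genomic position whose regression succeeded (ties broken toward
#' the smaller position). The replication p-value is adjusted for
#' directional concordance with the discovery effect: `p_old / 2` when signs
#' match, `1 - p_old / 2` when they do not. The strict replication threshold
#' is `0.05 / n_evaluable`.
#'
#' @param signals data.frame of discovery signals: `signal_id`, `chrom`,
#'   `pos` (lead probe position), `beta` (discovery effect), and optionally
#'   `cnvr_start`, `cnvr_end` restricting the probe search to the signal's
#'   region.
#' @param rep_gwas data.frame of replication association records
#'   (`probe_id`, `chrom`, `pos`, `beta`, `p`; rows with `NA` p are failed
#'   regressions).
#' @param alpha numerator of the strict threshold (default 0.05).
#' @return data.frame per signal: `signal_id`, `rep_probe`, `p_old`,
#'   `concordant`, `p_new`, `evaluable`, `replicated` (strict), with the
#'   threshold in `attr(, "threshold")`.
#' @export
replicate_signals <- function(signals, rep_gwas, alpha = 0.05) {
  ok <- rep_gwas[!is.na(rep_gwas$p), , drop = FALSE]
  rows <- lapply(seq_len(nrow(signals)), function(i) {
    s <- signals[i, ]
    cand <- ok[ok$chrom == s$chrom, , drop = FALSE]
    if (!is.null(s$cnvr_start) && !is.na(s$cnvr_start)) {
      cand <- cand[cand$pos >= s$cnvr_start & cand$pos <= s$cnvr_end, , drop = FALSE]
    }
    if (nrow(cand) == 0L) {
      return(data.frame(signal_id = s$signal_id, rep_probe = NA_character_,
                        p_old = NA_real_, concordant = NA, p_new = NA_real_,
                        evaluable = FALSE, stringsAsFactors = FALSE))
    }
    d <- abs(cand$pos - s$pos)
    # ties toward the smaller position
    best <- cand[order(d, cand$pos), ][1, ]
    conc <- sign(best$beta) == sign(s$beta)
    p_new <- if (conc) best$p / 2 else 1 - best$p / 2
    data.frame(signal_id = s$signal_id, rep_probe = best$probe_id,
               p_old = best$p, concordant = conc, p_new = p_new,
               evaluable = TRUE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  n_eval <- sum(res$evaluable)
  thr <- if (n_eval > 0) alpha / n_eval else NA_real_
  res$replicated <- res$evaluable & !is.na(res$p_new) & res$p_new <= thr
  attr(res, "threshold") <- thr
  res
}

#' Replication enrichment over a grid of significance levels
#'
#' Fold enrichment `k / (n * alpha)` of observed versus expected significant
#' replications and the one-sided binomial tail `P(X >= k)`,
#' `X ~ Binomial(n, alpha)`, evaluated at `alpha` and over the grid 0.1 down
#' to 0.005 in steps of 0.005.
#'
#' @param k_significant number of signals significant at the level.
#' @param n_evaluable number of evaluable signals.
#' @param alpha significance level of interest (default 0.05).
#' @param p_new optional vector of adjusted replication p-values; when given,
#'   `k` at each grid level is recomputed as `sum(p_new <= level)`.
#' @return list with `fold`, `binomial_p` at `alpha`, and a `grid`
#'   data.frame (`alpha`, `k`, `fold`, `binomial_p`).
#' @export
replication_enrichment <- function(k_significant, n_evaluable, alpha = 0.05,
                                   p_new = NULL) {
  stopifnot(k_significant >= 0, k_significant <= n_evaluable,
            alpha > 0, alpha < 1)
  enr <- function(k, n, a) {
    list(fold = k / (n * a),
         p = stats::binom.test(k, n, p = a, alternative = "greater")$p.value)
  }
  at <- enr(k_significant, n_evaluable, alpha)
  grid_alpha <- seq(0.1, 0.005, by = -0.005)
  grid <- do.call(rbind, lapply(grid_alpha, function(a) {
    k <- if (is.null(p_new)) k_significant else sum(p_new <= a, na.rm = TRUE)
    e <- enr(k, n_evaluable, a)
    data.frame(alpha = a, k = k, fold = e$fold, binomial_p = e$p)
  }))
  list(fold = at$fold, binomial_p = at$p, grid = grid)
}

#' Rank-based inverse normal transform
#'
#' Maps values to `qnorm((rank - 0.5) / n)` with ties sharing the average
#' rank; invariant to monotone rescaling of the input.
#'
#' @param values numeric vector (at least 2 distinct values).
#' @return standardized vector.
#' @export
inverse_normal_transform <- function(values) {
  if (length(unique(values[!is.na(values)])) < 2L) stop("constant input")
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  n <- sum(ok)
  out[ok] <- stats::qnorm((rank(values[ok], ties.method = "average") - 0.5) / n)
  out
}

#' BMI-confounding analysis of an association signal
#'
#' A signal is eligible when (i) BMI associates with the disease at
#' `p <= 0.05 / n_traits` in the covariate-adjusted disease model and (ii)
#' the lead dosage associates with inverse-normal-transformed,
#' covariate-residualized BMI at `p <= 0.05 / n_signals`. For eligible
#' signals the primary model is refit with BMI as an added covariate; the
#' change in the genotype coefficient is tested with
#' `z = (b1 - b2) / sqrt(se1^2 + se2^2)` against a standard normal
#' (two-sided, significant at `0.05 / n_eligible`), and the signal is
#' flagged as likely BMI-driven when the adjusted genotype p-value no longer
#' meets the genome-wide threshold.
#'
#' @param dosage numeric lead-probe dosage under the signal's best model
#'   (`NA`-masked samples dropped).
#' @param status per-sample status (excluded samples dropped internally).
#' @param bmi raw BMI values.
#' @param covariates data.frame of disease covariates.
#' @param bmi_covariates data.frame of covariates used to residualize BMI
#'   (defaults to `covariates`).
#' @param n_traits,n_signals,n_eligible Bonferroni denominators for the
#'   eligibility and coefficient-change tests.
#' @param gw_p genome-wide significance threshold.
#' @return list: `eligible`, `bmi_disease_p`, `dosage_bmi_p`, `beta_unadj`,
#'   `beta_adj`, `p_unadj`, `p_adj`, `t_p` (coefficient-change p),
#'   `likely_bmi_driven`, `non_evaluable` (missing BMI for > 50% of
#'   carriers).
#' @export
bmi_confounding <- function(dosage, status, bmi, covariates,
                            bmi_covariates = covariates,
                            n_traits, n_signals, n_eligible, gw_p) {
  y <- as.integer(status == "case")
  use <- status != "excluded" & !is.na(dosage)
  carriers <- use & dosage != 0
  if (mean(is.na(bmi[carriers])) > 0.5) {
    return(list(eligible = FALSE, non_evaluable = TRUE))
  }
  use <- use & !is.na(bmi)
  cov_df <- as.data.frame(covariates)[use, , drop = FALSE]
  d <- dosage[use]; yy <- y[use]; b <- bmi[use]

  # (i) BMI-disease association, covariate-adjusted
  fit_bd <- stats::glm(yy ~ ., data = cbind(data.frame(yy = yy, bmi = b), cov_df),
                       family = stats::binomial())
  bmi_disease_p <- summary(fit_bd)$coefficients["bmi", 4]

  # (ii) dosage-BMI association on INT, residualized BMI
  b_int <- inverse_normal_transform(b)
  bcov <- as.data.frame(bmi_covariates)[use, , drop = FALSE]
  b_res <- stats::resid(stats::lm(b_int ~ ., data = cbind(data.frame(b_int = b_int), bcov)))
  fit_gb <- stats::lm(b_res ~ d)
  dosage_bmi_p <- summary(fit_gb)$coefficients["d", 4]

  eligible <- bmi_disease_p <= 0.05 / n_traits && dosage_bmi_p <= 0.05 / n_signals
  out <- list(eligible = eligible, non_evaluable = FALSE,
              bmi_disease_p = bmi_disease_p, dosage_bmi_p = dosage_bmi_p)
  if (!eligible) return(out)

  X1 <- cbind(`(Intercept)` = 1, dosage = d, as.matrix(cov_df))
  X2 <- cbind(X1, bmi = b)
  f1 <- firth_logistic(yy, X1, focal = "dosage")
  f2 <- firth_logistic(yy, X2, focal = "dosage")
  z <- (f1$beta[["dosage"]] - f2$beta[["dosage"]]) /
    sqrt(f1$se[["dosage"]]^2 + f2$se[["dosage"]]^2)
  t_p <- 2 * stats::pnorm(-abs(z))
  c(out, list(beta_unadj = f1$beta[["dosage"]], beta_adj = f2$beta[["dosage"]],
              p_unadj = f1$p[["dosage"]], p_adj = f2$p[["dosage"]],
              t_p = t_p, t_significant = t_p <= 0.05 / n_eligible,
              likely_bmi_driven = f2$p[["dosage"]] > gw_p))
}
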