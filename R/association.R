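#' Two-by-three genotypic Fisher exact test
#'
#' Tests dependence between disease status (control/case) and probe
#' copy-number class (deletion / copy-neutral / duplication) with a two-sided
#' exact test: the p-value sums the probabilities of all tables with the
#' observed margins whose hypergeometric probability does not exceed the
#' observed table's. If a genotype class is absent (zero column margin) the
#' table collapses to 2x2.
#'
#' @param genotypes vector in \{-1, 0, +1\}.
#' @param status vector (`"case"`/`"control"`, logical, or 0/1).
#' @return the exact two-sided p-value.
#' @export
genotypic_fisher <- function(genotypes, status) {
  y <- if (is.character(status) || is.factor(status)) as.integer(status == "case") else as.integer(status)
  stopifnot(length(genotypes) == length(y),
            all(genotypes %in% c(-1, 0, 1)),
            sum(y == 1) >= 1, sum(y == 0) >= 1)
  g <- factor(genotypes, levels = c(-1, 0, 1))
  tab <- table(factor(y, levels = c(0, 1)), g)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]  # collapse empty classes
  if (ncol(tab) == 1L) return(1)
  stats::fisher.test(tab, workspace = 2e6)$p.value
}

#' Prefilter probes for the four association models
#'
#' A probe enters testing only if its cohort CNV frequency passes the
#' frequency filter; it is tested under the mirror and U-shape models when
#' the genotypic Fisher p is at most `fisher_cut` and at least `min_cases`
#' cases carry any CNV at the probe, under the duplication-only model when
#' additionally at least `min_cases` cases carry a duplication, and under the
#' deletion-only model when at least `min_cases` cases carry a deletion.
#'
#' @param m a `cnv_matrix` restricted to the analysis cohort.
#' @param freqs output of [probe_frequencies()] on the same matrix.
#' @param status per-sample status vector (`"case"`/`"control"`/`"excluded"`,
#'   aligned with `m$samples`); excluded samples are ignored.
#' @param fisher_cut Fisher-p cutoff (default 1e-3).
#' @param min_cases minimum diseased carriers per relevant class (default 2).
#' @return data.frame per probe: `probe_id`, `fisher_p`, carrier case counts
#'   (`cases_cnv`, `cases_dup`, `cases_del`), and pass flags `pass_mirror`,
#'   `pass_ushape`, `pass_duponly`, `pass_delonly`.
#' @export
prefilter_probes <- function(m, freqs, status, fisher_cut = 1e-3, min_cases = 2L) {
  use <- status != "excluded"
  y <- as.integer(status[use] == "case")
  G <- m$G[use, , drop = FALSE]
  np <- ncol(G)
  fisher_p <- rep(NA_real_, np)
  cases_cnv <- cases_dup <- cases_del <- integer(np)
  retained <- freqs$retained[match(colnames(G), freqs$probe_id)]
  for (j in seq_len(np)) {
    if (!retained[j]) next
    g <- as.numeric(G[, j])
    cases_dup[j] <- sum(y == 1 & g > 0)
    cases_del[j] <- sum(y == 1 & g < 0)
    cases_cnv[j] <- cases_dup[j] + cases_del[j]
    fisher_p[j] <- genotypic_fisher(g, y)
  }
  base_pass <- retained & !is.na(fisher_p) & fisher_p <= fisher_cut
  data.frame(probe_id = colnames(G),
             fisher_p = fisher_p,
             cases_cnv = cases_cnv, cases_dup = cases_dup, cases_del = cases_del,
             pass_mirror = base_pass & cases_cnv >= min_cases,
             pass_ushape = base_pass & cases_cnv >= min_cases,
             pass_duponly = base_pass & cases_dup >= min_cases,
             pass_delonly = base_pass & cases_del >= min_cases,
             stringsAsFactors = FALSE)
}

# ---- logistic regression with Firth fallback ------------------------------

# plain Newton-Raphson ML logistic fit; returns beta, se, convergence flag
ml_logistic <- function(y, X, tol = 1e-8, max_iter = 100L) {
  beta <- numeric(ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    score <- drop(crossprod(X, y - p))
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  se <- rep(NA_real_, ncol(X))
  if (converged) {
    p <- stats::plogis(drop(X %*% beta))
    info <- crossprod(X * (p * (1 - p)), X)
    cov <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(cov)) converged <- FALSE else se <- sqrt(diag(cov))
  }
  list(beta = beta, se = se, converged = converged)
}

# Firth-penalized logistic fit (Jeffreys prior); modified score iteration
# with step-halving. Returns beta and se from the penalized information.
firth_penalized <- function(y, X, tol = 1e-8, max_iter = 200L) {
  beta <- numeric(ncol(X))
  pen_loglik <- function(b) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    info <- crossprod(X * w, X)
    ld <- determinant(info, logarithm = TRUE)
    if (ld$sign <= 0) return(-Inf)
    sum(y * eta - log1p(exp(eta))) + 0.5 * as.numeric(ld$modulus)
  }
  ll <- pen_loglik(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(inv)) break
    h <- rowSums((XW %*% inv) * XW)  # hat diagonal
    score <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(inv %*% score)
    # step-halving on the penalized likelihood
    fac <- 1
    repeat {
      cand <- beta + fac * step
      llc <- pen_loglik(cand)
      if (llc >= ll - 1e-12 || fac < 1e-4) break
      fac <- fac / 2
    }
    beta_new <- beta + fac * step
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; converged <- TRUE; break }
    beta <- beta_new
    ll <- pen_loglik(beta)
  }
  p <- stats::plogis(drop(X %*% beta))
  info <- crossprod(X * (p * (1 - p)), X)
  cov <- tryCatch(solve(info), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, ncol(X)) else sqrt(diag(cov))
  list(beta = beta, se = se, converged = converged)
}

#' Logistic regression with Firth fallback
#'
#' Fits by maximum likelihood (Newton-Raphson, tolerance 1e-8, at most 100
#' iterations). The fit falls back to Firth's Jeffreys-prior penalized
#' likelihood when ML fails to converge, any ML coefficient exceeds 10 in
#' absolute value, or the exposure-by-outcome table contains an empty cell
#' for the focal column (an explicit, deterministic separation check).
#' P-values are Wald. Rank-deficient designs have collinear columns dropped
#' (coefficients reported as `NA`) with a message.
#'
#' @param y binary 0/1 outcome.
#' @param X design matrix including an intercept column.
#' @param focal index (or name) of the focal column used for the separation
#'   check; default 2 (the column after the intercept).
#' @return list with `beta`, `se`, `p` (per column), `firth` flag, and
#'   `converged`.
#' @export
firth_logistic <- function(y, X, focal = 2L) {
  y <- as.integer(y)
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("outcome is constant")
  # drop collinear columns deterministically, preferring earlier columns
  # (so a focal dosage placed last yields NA when absorbed by a conditioned
  # lead rather than silently displacing it)
  if (qr(X)$rank < ncol(X)) {
    keep <- integer(0)
    for (j in seq_len(ncol(X))) {
      if (qr(X[, c(keep, j), drop = FALSE])$rank == length(keep) + 1L) {
        keep <- c(keep, j)
      }
    }
    dropped <- setdiff(seq_len(ncol(X)), keep)
    message("dropping ", length(dropped), " collinear column(s): ",
            paste(colnames(X)[dropped], collapse = ", "))
  } else {
    keep <- seq_len(ncol(X))
  }
  Xk <- X[, keep, drop = FALSE]
  focal_idx <- if (is.character(focal)) match(focal, colnames(X)) else as.integer(focal)
  focal_in <- match(focal_idx, keep)

  # separation check on the focal exposure (when it is discrete)
  sep <- FALSE
  if (!is.na(focal_in)) {
    xf <- Xk[, focal_in]
    vals <- unique(xf)
    if (length(vals) <= 4L) {
      tab <- table(factor(y, levels = 0:1), xf)
      sep <- any(tab == 0L)
    }
  }

  fit <- ml_logistic(y, Xk)
  firth <- !fit$converged || any(abs(fit$beta) > 10) || sep
  if (firth) fit <- firth_penalized(y, Xk)

  beta <- se <- rep(NA_real_, ncol(X))
  beta[keep] <- fit$beta
  se[keep] <- fit$se
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  names(beta) <- names(se) <- names(p) <- colnames(X)
  list(beta = beta, se = se, p = p, firth = firth, converged = fit$converged)
}

# ---- GWAS drivers ---------------------------------------------------------

model_pass_col <- function(model) paste0("pass_", model)

empty_gwas_table <- function(model) {
  data.frame(probe_id = character(0), chrom = character(0), pos = numeric(0),
             model = character(0), beta = numeric(0), se = numeric(0),
             p = numeric(0), or = numeric(0), ci_low = numeric(0),
             ci_high = numeric(0), firth = logical(0), n = integer(0),
             n_case = integer(0), n_control = integer(0),
             carriers_case = integer(0), skip_reason = character(0),
             stringsAsFactors = FALSE)
}

# assemble the design and run one probe association; shared by the logistic
# and linear GWAS paths. Returns NULL with a reason when not analyzable.
fit_probe <- function(g, outcome, covar_mat, model, binary, extra = NULL) {
  dos <- encode_dosage(g, model)
  use <- !is.na(dos) & !is.na(outcome)
  if (!is.null(covar_mat)) use <- use & stats::complete.cases(covar_mat)
  dos <- dos[use]
  yy <- outcome[use]
  if (length(unique(dos)) < 2L) return(list(skip = "no informative carriers"))
  # dosage goes last: if it is collinear with a conditioned lead or a
  # covariate it is the column dropped, making its conditional p undefined
  X <- cbind(`(Intercept)` = rep(1, sum(use)))
  if (!is.null(covar_mat) && ncol(covar_mat) > 0L) X <- cbind(X, as.matrix(covar_mat)[use, , drop = FALSE])
  if (!is.null(extra)) X <- cbind(X, as.matrix(extra)[use, , drop = FALSE])
  X <- cbind(X, dosage = dos)
  if (binary) {
    if (sum(yy == 1 & dos != 0) < 2L) return(list(skip = "fewer than 2 cases among carriers"))
    if (length(unique(yy)) < 2L) return(list(skip = "outcome constant after masking"))
    fit <- firth_logistic(yy, X, focal = "dosage")
    list(beta = fit$beta[["dosage"]], se = fit$se[["dosage"]], p = fit$p[["dosage"]],
         firth = fit$firth, n = length(yy), n_case = sum(yy), n_control = sum(yy == 0),
         carriers_case = sum(yy == 1 & dos != 0))
  } else {
    if (stats::var(yy) == 0) return(list(skip = "constant outcome"))
    fit <- stats::lm.fit(X, yy)
    ok <- !is.na(fit$coefficients)
    rss <- sum(fit$residuals^2)
    df <- length(yy) - sum(ok)
    XtXinv <- tryCatch(chol2inv(chol(crossprod(X[, ok, drop = FALSE]))), error = function(e) NULL)
    if (is.null(XtXinv) || df <= 0) return(list(skip = "degenerate linear fit"))
    sigma2 <- rss / df
    se_all <- sqrt(diag(XtXinv) * sigma2)
    names(se_all) <- colnames(X)[ok]
    b <- fit$coefficients[["dosage"]]
    if (is.na(b) || !"dosage" %in% names(se_all)) {
      return(list(skip = "dosage collinear with conditioned covariates"))
    }
    s <- se_all[["dosage"]]
    list(beta = b, se = s, p = 2 * stats::pt(-abs(b / s), df),
         firth = FALSE, n = length(yy), n_case = NA_integer_, n_control = NA_integer_,
         carriers_case = NA_integer_)
  }
}

#' Run a CNV genome-wide association scan under one dosage model
#'
#' For each prefiltered probe, fits disease status on the encoded dosage plus
#' the selected covariates via logistic regression with Firth fallback.
#' Type-specific models (`duponly`, `delonly`) drop carriers of the masked
#' CNV type from that probe's regression rather than recoding them, so the
#' reference class stays copy-neutral. Effect sizes are per CNV (per
#' additional copy under the mirror model).
#'
#' @param m a `cnv_matrix`.
#' @param status per-sample status (`"case"`/`"control"`/`"excluded"`,
#'   aligned with `m$samples`).
#' @param covariates data.frame of selected covariates (aligned with
#'   `m$samples`), or `NULL`.
#' @param model one of `"mirror"`, `"ushape"`, `"duponly"`, `"delonly"`.
#' @param probes probe ids to test (typically the prefilter pass set;
#'   default: all probes in `m`).
#' @param conditioned optional matrix of numeric lead-probe dosages added as
#'   covariates (stepwise conditional analysis).
#' @return data.frame of association records: `probe_id`, `model`, `beta`,
#'   `se`, `p`, `or`, `ci_low`, `ci_high`, `firth`, `n`, `n_case`,
#'   `n_control`, `carriers_case`, `skip_reason`.
#' @export
run_gwas <- function(m, status, covariates = NULL, model = "mirror",
                     probes = NULL, conditioned = NULL) {
  stopifnot(model %in% c("mirror", "ushape", "duponly", "delonly"))
  if (is.null(probes)) probes <- colnames(m$G)
  if (length(probes) == 0L) return(empty_gwas_table(model))
  use_s <- status != "excluded"
  y <- as.integer(status == "case")
  rows <- lapply(probes, function(pid) {
    g <- as.numeric(m$G[, pid])
    g[!use_s] <- NA  # excluded samples dropped
    r <- fit_probe(g, ifelse(use_s, y, NA), covariates, model, binary = TRUE,
                   extra = conditioned)
    if (!is.null(r$skip)) {
      data.frame(probe_id = pid, model = model, beta = NA_real_, se = NA_real_,
                 p = NA_real_, or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 firth = NA, n = NA_integer_, n_case = NA_integer_,
                 n_control = NA_integer_, carriers_case = NA_integer_,
                 skip_reason = r$skip, stringsAsFactors = FALSE)
    } else {
      data.frame(probe_id = pid, model = model, beta = r$beta, se = r$se, p = r$p,
                 or = exp(r$beta),
                 ci_low = exp(r$beta - 1.959964 * r$se),
                 ci_high = exp(r$beta + 1.959964 * r$se),
                 firth = r$firth, n = r$n, n_case = r$n_case,
                 n_control = r$n_control, carriers_case = r$carriers_case,
                 skip_reason = NA_character_, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  res <- merge(res, m$probes[, c("probe_id", "chrom", "pos")], by = "probe_id", sort = FALSE)
  res[order(match(res$probe_id, probes)), c("probe_id", "chrom", "pos", "model",
      "beta", "se", "p", "or", "ci_low", "ci_high", "firth", "n", "n_case",
      "n_control", "carriers_case", "skip_reason")]
}

#' Linear CNV association scan for a quantitative disease-burden phenotype
#'
#' Same encodings and covariates as [run_gwas()] but ordinary least squares
#' on a numeric outcome (e.g. the per-sample diagnosis count); `beta` is in
#' outcome units per encoded dosage unit.
#'
#' @inheritParams run_gwas
#' @param burden numeric per-sample outcome (aligned with `m$samples`).
#' @return data.frame of association records (OR columns are `NA`).
#' @export
run_burden_gwas <- function(m, burden, covariates = NULL, model = "mirror",
                            probes = NULL, conditioned = NULL) {
  stopifnot(is.numeric(burden), model %in% c("mirror", "ushape", "duponly", "delonly"))
  if (stats::var(burden, na.rm = TRUE) == 0) stop("constant burden outcome")
  if (is.null(probes)) probes <- colnames(m$G)
  if (length(probes) == 0L) return(empty_gwas_table(model))
  rows <- lapply(probes, function(pid) {
    g <- as.numeric(m$G[, pid])
    r <- fit_probe(g, burden, covariates, model, binary = FALSE, extra = conditioned)
    if (!is.null(r$skip)) {
      data.frame(probe_id = pid, model = model, beta = NA_real_, se = NA_real_,
                 p = NA_real_, firth = FALSE, n = NA_integer_,
                 skip_reason = r$skip, stringsAsFactors = FALSE)
    } else {
      data.frame(probe_id = pid, model = model, beta = r$beta, se = r$se, p = r$p,
                 firth = FALSE, n = r$n, skip_reason = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  res <- merge(res, m$probes[, c("probe_id", "chrom", "pos")], by = "probe_id", sort = FALSE)
  res[order(match(res$probe_id, probes)), ]
}

#' Stepwise conditional analysis
#'
#' Iteratively takes the most significant probe with `p <= threshold` as a
#' lead, adds its numeric encoded dosage to the covariates, and reruns the
#' scan until no probe passes the threshold. Probes perfectly collinear with
#' a lead are absorbed by the rank-deficiency handling of the fitter.
#'
#' @inheritParams run_gwas
#' @param threshold significance threshold for declaring a lead.
#' @param burden optional numeric outcome; when supplied the scan is linear
#'   (disease-burden GWAS) instead of logistic.
#' @param max_rounds non-termination guard (default 20).
#' @return data.frame of leads in discovery order: `round`, `probe_id`, `p`,
#'   `beta`, `se` (marginal, from the round in which the lead was found).
#' @export
stepwise_conditional <- function(m, status = NULL, covariates = NULL, model = "mirror",
                                 threshold, probes = NULL, burden = NULL,
                                 max_rounds = 20L) {
  leads <- list()
  cond <- NULL
  for (round in seq_len(max_rounds)) {
    res <- if (is.null(burden)) {
      run_gwas(m, status, covariates, model, probes = probes, conditioned = cond)
    } else {
      run_burden_gwas(m, burden, covariates, model, probes = probes, conditioned = cond)
    }
    res <- res[!is.na(res$p), , drop = FALSE]
    if (!is.null(cond)) res <- res[!(res$probe_id %in% names(leads)), , drop = FALSE]
    if (nrow(res) == 0L || min(res$p) > threshold) {
      return(do.call(rbind, leads) %||%
               data.frame(round = integer(0), probe_id = character(0),
                          p = numeric(0), beta = numeric(0), se = numeric(0)))
    }
    best <- res[which.min(res$p), ]
    leads[[best$probe_id]] <- data.frame(round = round, probe_id = best$probe_id,
                                         p = best$p, beta = best$beta, se = best$se,
                                         stringsAsFactors = FALSE)
    lead_dos <- encode_dosage(as.numeric(m$G[, best$probe_id]), model)
    lead_dos[is.na(lead_dos)] <- 0  # conditioning covariate stays defined for everyone
    newcol <- matrix(lead_dos, ncol = 1,
                     dimnames = list(NULL, paste0("lead_", best$probe_id)))
    cond <- if (is.null(cond)) newcol else cbind(cond, newcol)
  }
  stop("stepwise conditional analysis did not terminate within ", max_rounds, " rounds")
}

#' Genomic inflation factor lambda
#'
#' Median of the 1-df chi-square quantile transform of the p-values divided
#' by the null median 0.4549364.
#'
#' @param pvals vector of p-values in (0, 1].
#' @return lambda.
#' @export
genomic_inflation <- function(pvals) {
  stopifnot(length(pvals) >= 100)
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must be in (0, 1]")
  chi <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}
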