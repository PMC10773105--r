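#' Define a disease from diagnosis-code inclusion/exclusion lists
#'
#' @param id disease label.
#' @param inclusion character vector of ICD-10-style codes defining cases
#'   (hospital source only). Three-character (second-level) codes match all
#'   subcodes; longer codes match exactly.
#' @param exclusion codes that disqualify a sample from being a control (any
#'   source).
#' @param self_report_exclusion self-reported condition codes equivalent to
#'   the disease: samples carrying one (without a hospital inclusion code)
#'   are excluded rather than counted as cases or controls.
#' @param sex_restriction `"none"`, `"female_only"`, or `"male_only"`;
#'   opposite-sex samples are excluded.
#' @return an object of class `disease_definition`.
#' @export
disease_definition <- function(id, inclusion, exclusion = character(0),
                               self_report_exclusion = character(0),
                               sex_restriction = c("none", "female_only", "male_only")) {
  sex_restriction <- match.arg(sex_restriction)
  structure(list(id = id, inclusion = inclusion, exclusion = exclusion,
                 self_report_exclusion = self_report_exclusion,
                 sex_restriction = sex_restriction),
            class = "disease_definition")
}

# does `codes` match any entry of `defs` under the subcode rule?
# second-level codes (3 characters) match any subcode prefix; longer codes
# match exactly.
match_codes <- function(codes, defs) {
  if (length(codes) == 0L || length(defs) == 0L) return(rep(FALSE, length(codes)))
  hit <- rep(FALSE, length(codes))
  for (d in defs) {
    if (nchar(d) == 3L) {
      hit <- hit | startsWith(codes, d)
    } else {
      hit <- hit | codes == d
    }
  }
  hit
}

#' Assign case/control/excluded status from diagnosis records
#'
#' A sample is a case if any *hospital* record matches the inclusion list;
#' case status takes precedence over all exclusion rules (exclusion lists
#' screen controls, not cases). A non-case is excluded if any record (either
#' source) matches the exclusion list, or if a self-reported record matches
#' the inclusion list (self-reported cases are not trusted as cases but
#' cannot serve as controls). Everyone else is a control. Sex-restricted
#' diseases set opposite-sex samples to excluded. Records whose code does not
#' look like an ICD-10 code (`[A-Z]` + 2 digits prefix) are dropped with a
#' message.
#'
#' @param records data.frame with columns `sample_id`, `code`, `date`
#'   (Date or coercible), `source` in `{"hospital", "self_report"}`.
#' @param defs list of [disease_definition()] objects.
#' @param samples character vector of all sample ids (samples without records
#'   are controls).
#' @param sex optional named vector (by sample id), 1 = female, 0 = male;
#'   required when any definition is sex-restricted.
#' @return data.frame: `sample_id`, one `status_<id>` column per disease, and
#'   `disease_burden` (number of case statuses).
#' @export
assign_status <- function(records, defs, samples, sex = NULL) {
  stopifnot(all(c("sample_id", "code", "source") %in% names(records)))
  ok <- grepl("^[A-Z][0-9]{2}", records$code)
  if (any(!ok)) {
    message(sum(!ok), " record(s) with unparseable code dropped")
    records <- records[ok, , drop = FALSE]
  }
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  burden <- integer(length(samples))
  for (def in defs) {
    inc <- match_codes(records$code, def$inclusion)
    exc <- match_codes(records$code, def$exclusion)
    sr_case <- inc & records$source == "self_report"
    hosp_case <- inc & records$source == "hospital"

    case_ids <- unique(records$sample_id[hosp_case])
    excl_ids <- unique(records$sample_id[exc | sr_case])

    status <- rep("control", length(samples))
    status[samples %in% excl_ids] <- "excluded"
    status[samples %in% case_ids] <- "case"  # case precedence

    if (def$sex_restriction != "none") {
      if (is.null(sex)) stop("sex vector required for sex-restricted disease ", def$id)
      wrong <- if (def$sex_restriction == "female_only") sex[samples] == 0 else sex[samples] == 1
      status[wrong] <- "excluded"
    }
    out[[paste0("status_", def$id)]] <- status
    burden <- burden + as.integer(status == "case")
  }
  out$disease_burden <- burden
  out
}

#' Age at first diagnosis in years
#'
#' The birthday is imputed to the 15th of the birth month; age is the number
#' of days from birth to the earliest inclusion-code diagnosis divided by
#' 365.25 to account for leap years.
#'
#' @param first_dx_date Date (or coercible) of the earliest inclusion-code
#'   diagnosis; if several dates are supplied per call, the earliest is used.
#' @param birth_year,birth_month birth year and month.
#' @return age in years.
#' @export
age_at_diagnosis <- function(first_dx_date, birth_year, birth_month) {
  dx <- min(as.Date(first_dx_date))
  birth <- as.Date(sprintf("%04d-%02d-15", birth_year, birth_month))
  if (dx < birth) stop("diagnosis date precedes birth date")
  as.numeric(dx - birth) / 365.25
}

#' Age at last healthy measurement
#'
#' Cases are last known healthy at diagnosis; controls at the administrative
#' cutoff date (default 2021-09-30).
#'
#' @param status `"case"` or `"control"` (excluded samples must not be
#'   queried).
#' @param age_at_dx age at diagnosis in years (cases).
#' @param birth_year,birth_month birth year/month (controls; day imputed to
#'   the 15th).
#' @param cutoff administrative censoring date.
#' @return age in years.
#' @export
age_last_healthy <- function(status, age_at_dx = NA, birth_year = NA,
                             birth_month = NA, cutoff = as.Date("2021-09-30")) {
  stopifnot(length(status) == 1L)
  if (status == "case") {
    stopifnot(is.finite(age_at_dx))
    return(age_at_dx)
  }
  if (status != "control") stop("age_last_healthy undefined for status ", status)
  birth <- as.Date(sprintf("%04d-%02d-15", birth_year, birth_month))
  if (birth > cutoff) stop("birth date after censoring cutoff")
  as.numeric(as.Date(cutoff) - birth) / 365.25
}

#' Select disease-relevant covariates by joint logistic screening
#'
#' Fits a single multivariable logistic regression of case status on all
#' candidate covariates and retains those with Wald `p <= 0.05`. Constant
#' columns are dropped before fitting. If the fit does not converge, all
#' (non-constant) covariates are retained with a warning.
#'
#' @param status character or 0/1 vector (cases vs controls; excluded samples
#'   must be removed beforehand).
#' @param covariates data.frame (or matrix) of candidate covariates.
#' @param alpha retention threshold (default 0.05).
#' @return character vector of retained covariate names.
#' @export
select_covariates <- function(status, covariates, alpha = 0.05) {
  y <- if (is.character(status) || is.factor(status)) as.integer(status == "case") else as.integer(status)
  stopifnot(sum(y == 1) >= 2, sum(y == 0) >= 2)
  X <- as.data.frame(covariates)
  cc <- stats::complete.cases(X)
  X <- X[cc, , drop = FALSE]; y <- y[cc]
  keep <- vapply(X, function(col) length(unique(col)) > 1L, logical(1))
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0L) return(character(0))
  fit <- suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, X), family = stats::binomial()))
  if (!fit$converged) {
    warning("covariate-selection regression did not converge; retaining all covariates")
    return(names(X))
  }
  p <- summary(fit)$coefficients[, 4]
  p <- p[setdiff(names(p), "(Intercept)")]
  names(X)[vapply(names(X), function(nm) {
    idx <- which(names(p) == nm)
    if (length(idx) == 0L) idx <- which(startsWith(names(p), nm))  # factor terms
    any(p[idx] <= alpha)
  }, logical(1))]
}
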