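#' Construct a genome model for cohort simulation
#'
#' A genome model bundles chromosome lengths, an ordered probe map, and the
#' CNV loci at which rare recurrent duplications/deletions segregate. It is
#' the single source of truth for the simulator: probe positions must be
#' strictly increasing within a chromosome, loci must lie within chromosome
#' bounds, and loci on the same chromosome may not overlap (recurrent loci
#' are treated as independent rearrangement hotspots).
#'
#' @param chromosomes data.frame with columns `chrom`, `length_bp`.
#' @param probes data.frame with columns `probe_id`, `chrom`, `pos`
#'   (1-based).
#' @param loci list of [cnv_locus()] objects.
#' @return an object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, probes, loci = list()) {
  stopifnot(all(c("chrom", "length_bp") %in% names(chromosomes)),
            all(c("probe_id", "chrom", "pos") %in% names(probes)))
  probes <- probes[order(probes$chrom, probes$pos), , drop = FALSE]
  rownames(probes) <- NULL
  for (chr in unique(probes$chrom)) {
    p <- probes$pos[probes$chrom == chr]
    if (any(diff(p) <= 0)) stop("probe positions must be strictly increasing within a chromosome")
    L <- chromosomes$length_bp[match(chr, chromosomes$chrom)]
    if (is.na(L) || any(p < 1 | p > L)) stop("probe positions outside chromosome bounds")
  }
  ids <- vapply(loci, function(l) l$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate locus ids")
  for (l in loci) {
    L <- chromosomes$length_bp[match(l$chrom, chromosomes$chrom)]
    if (is.na(L)) stop("locus on unknown chromosome: ", l$id)
    if (l$start < 1 || l$end > L) stop("locus outside chromosome bounds: ", l$id)
  }
  # reject overlapping loci on the same chromosome
  for (chr in unique(vapply(loci, function(l) l$chrom, character(1)))) {
    ll <- Filter(function(l) l$chrom == chr, loci)
    if (length(ll) < 2L) next
    o <- order(vapply(ll, function(l) l$start, numeric(1)))
    ll <- ll[o]
    for (k in seq_len(length(ll) - 1L)) {
      if (ll[[k + 1L]]$start <= ll[[k]]$end) {
        stop("overlapping loci on chromosome ", chr, ": ",
             ll[[k]]$id, " and ", ll[[k + 1L]]$id)
      }
    }
  }
  structure(list(chromosomes = chromosomes, probes = probes, loci = loci),
            class = "genome_model")
}

#' Define a recurrent CNV locus
#'
#' A locus is a genomic interval at which duplications and deletions recur at
#' low population frequency. Breakpoint categories are sub-intervals (e.g.
#' the common segmental-duplication-flanked configuration vs a smaller nested
#' one) sampled with the given weights; a small fraction of calls instead get
#' atypical breakpoints drawn uniformly within the locus, emulating the
#' non-recurrent minority seen around real rearrangement hotspots.
#'
#' @param id locus label.
#' @param chrom,start,end locus interval (1-based inclusive).
#' @param dup_freq,del_freq carrier frequencies in `[0, 0.05]` (rare CNVs).
#' @param categories optional data.frame with columns `name`, `start`, `end`,
#'   `weight`; sub-intervals must nest in the locus and weights sum to 1.
#'   Default: a single category spanning the whole locus.
#' @param qs_noise fraction of calls drawn with `|QS| <= 0.5` (low quality,
#'   removed by the default encoding filter). Default 0.2.
#' @param atypical_prob probability that a call gets atypical (uniform)
#'   breakpoints rather than a category's. Default 0.05.
#' @return an object of class `cnv_locus`.
#' @export
cnv_locus <- function(id, chrom, start, end, dup_freq = 0, del_freq = 0,
                      categories = NULL, qs_noise = 0.2, atypical_prob = 0.05) {
  stopifnot(start <= end,
            dup_freq >= 0, dup_freq <= 0.05,
            del_freq >= 0, del_freq <= 0.05,
            qs_noise >= 0, qs_noise <= 1)
  if (is.null(categories)) {
    categories <- data.frame(name = "full", start = start, end = end, weight = 1)
  }
  stopifnot(all(categories$start >= start), all(categories$end <= end),
            abs(sum(categories$weight) - 1) < 1e-8)
  structure(list(id = id, chrom = chrom, start = start, end = end,
                 dup_freq = dup_freq, del_freq = del_freq,
                 categories = categories, qs_noise = qs_noise,
                 atypical_prob = atypical_prob),
            class = "cnv_locus")
}

#' Specify a causal CNV effect for phenotype simulation
#'
#' @param disease disease id the effect acts on.
#' @param locus locus id carrying the CNV.
#' @param mechanism dosage mechanism generating the disease liability: one of
#'   `"mirror"` (each additional copy adds `log_odds`), `"ushape"` (any
#'   deviation from two copies adds `log_odds`), `"duponly"`, `"delonly"`.
#' @param log_odds log odds ratio per encoded dosage unit.
#' @param hazard_ratio multiplicative effect (> 0) on the disease-onset
#'   hazard per encoded unit; 1 means no effect on onset timing.
#' @param bmi_shift standardized BMI shift per encoded unit; nonzero values
#'   create a CNV -> BMI -> disease mediation path.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(disease, locus, mechanism = c("mirror", "ushape", "duponly", "delonly"),
                        log_odds = 0, hazard_ratio = 1, bmi_shift = 0) {
  mechanism <- match.arg(mechanism)
  stopifnot(hazard_ratio > 0)
  structure(list(disease = disease, locus = locus, mechanism = mechanism,
                 log_odds = log_odds, hazard_ratio = hazard_ratio,
                 bmi_shift = bmi_shift),
            class = "effect_spec")
}

#' Encode signed copy-number genotypes as model dosages
#'
#' Maps `-1/0/+1` genotypes to the dosage used by each association model:
#' mirror keeps the signed genotype (per additional copy), U-shape takes the
#' absolute value (any deviation from copy-neutral), duplication-only masks
#' deletion carriers to `NA`, and deletion-only masks duplication carriers
#' and codes deletions as `+1` so the coefficient is the effect of carrying
#' the deletion.
#'
#' @param g vector in \{-1, 0, +1\} (NAs pass through).
#' @param mechanism one of `"mirror"`, `"ushape"`, `"duponly"`, `"delonly"`.
#' @return numeric dosage vector with `NA` for masked carriers.
#' @export
encode_dosage <- function(g, mechanism) {
  stopifnot(all(g %in% c(-1, 0, 1) | is.na(g)))
  switch(mechanism,
         mirror = g,
         ushape = abs(g),
         duponly = ifelse(g < 0, NA_real_, g),
         delonly = ifelse(g > 0, NA_real_, -g),
         stop("unknown mechanism: ", mechanism))
}

#' Simulate CNV calls for a cohort
#'
#' Each sample carries at most one CNV per locus: carrier state is drawn from
#' \{none, duplication, deletion\} with the locus frequencies. Breakpoints
#' come from the locus's breakpoint categories (or are atypical with small
#' probability), and each call receives a quality score whose sign matches
#' its type; a `qs_noise` fraction of calls is low quality (`|QS| <= 0.5`)
#' and will be discarded by the default encoding filter.
#'
#' @param genome a [genome_model()].
#' @param n_samples cohort size.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return data.frame of calls: `sample_id`, `chrom`, `start`, `end`, `type`,
#'   `copy_number` (3 for DUP, 1 for DEL), `qs`.
#' @export
simulate_cnv_calls <- function(genome, n_samples, seed) {
  stopifnot(inherits(genome, "genome_model"), n_samples >= 1)
  set.seed(child_seed(seed, "calls"))
  out <- list()
  sample_ids <- sprintf("S%06d", seq_len(n_samples))
  for (l in genome$loci) {
    u <- stats::runif(n_samples)
    is_dup <- u < l$dup_freq
    is_del <- !is_dup & u < l$dup_freq + l$del_freq
    carriers <- which(is_dup | is_del)
    if (length(carriers) == 0L) next
    nc <- length(carriers)
    type <- ifelse(is_dup[carriers], "DUP", "DEL")
    atyp <- stats::runif(nc) < l$atypical_prob
    cat_idx <- sample.int(nrow(l$categories), nc, replace = TRUE,
                          prob = l$categories$weight)
    start <- l$categories$start[cat_idx]
    end <- l$categories$end[cat_idx]
    if (any(atyp)) {
      # atypical breakpoints: uniform sub-interval of the locus
      a <- sum(atyp)
      s1 <- floor(stats::runif(a, l$start, l$end))
      s2 <- ceiling(stats::runif(a, s1, l$end))
      start[atyp] <- s1
      end[atyp] <- pmax(s1, s2)
    }
    lowq <- stats::runif(nc) < l$qs_noise
    mag <- ifelse(lowq, stats::runif(nc, 0.05, 0.5), stats::runif(nc, 0.51, 1))
    qs <- ifelse(type == "DUP", mag, -mag)
    out[[l$id]] <- data.frame(
      sample_id = sample_ids[carriers],
      chrom = l$chrom, start = start, end = end, type = type,
      copy_number = ifelse(type == "DUP", 3L, 1L), qs = qs,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), type = character(0),
                      copy_number = integer(0), qs = numeric(0)))
  }
  calls <- do.call(rbind, out)
  calls <- calls[order(calls$sample_id, calls$chrom, calls$start), ]
  rownames(calls) <- NULL
  calls
}

# per-sample signed carrier state (-1/0/+1) at each locus, from raw calls
locus_genotypes <- function(calls, genome, sample_ids) {
  g <- matrix(0, nrow = length(sample_ids), ncol = length(genome$loci),
              dimnames = list(sample_ids,
                              vapply(genome$loci, function(l) l$id, character(1))))
  for (l in genome$loci) {
    hit <- calls$chrom == l$chrom & calls$start <= l$end & calls$end >= l$start
    if (!any(hit)) next
    idx <- match(calls$sample_id[hit], sample_ids)
    jcol <- match(l$id, colnames(g))
    g[cbind(idx, jcol)] <- ifelse(calls$type[hit] == "DUP", 1, -1)
  }
  g
}

#' Default covariate generator specification
#'
#' Marginals loosely follow a middle-aged population cohort: age uniform on
#' 40-70 years, 54% female, 10% on the secondary genotyping array, principal
#' components standard normal.
#'
#' @param n_pcs number of principal-component covariates (default 4).
#' @param betas named list of covariate effects on the disease log-odds scale
#'   (per unit; age is centered at 55 before applying its effect).
#' @param bmi_beta log-odds effect of standardized BMI on disease risk;
#'   together with a nonzero `bmi_shift` in an [effect_spec()] this creates
#'   the CNV -> BMI -> disease mediation path. Default 0 (BMI inert).
#' @param exclusion_frac fraction of controls relabeled `excluded`, emulating
#'   exclusion-list screening (default 0.05).
#' @return a list used by [simulate_phenotypes()].
#' @export
covariate_spec <- function(n_pcs = 4,
                           betas = list(age = 0.03, sex = 0.2, array = 0, pc = 0.05),
                           bmi_beta = 0,
                           exclusion_frac = 0.05) {
  list(n_pcs = n_pcs, betas = betas, bmi_beta = bmi_beta,
       exclusion_frac = exclusion_frac)
}

#' Simulate disease phenotypes on top of simulated CNV calls
#'
#' Disease status is drawn from a logistic model whose intercept is
#' calibrated by root-finding so that the realized prevalence matches the
#' target: logit P(case) = intercept + covariate effects + sum of CNV effects
#' on the encoded dosage (plus a BMI path when an effect has `bmi_shift !=
#' 0`: the CNV shifts standardized BMI, and BMI feeds the liability with
#' `bmi_beta`). Ages of onset for cases come from a Weibull
#' proportional-hazards model (shape 4, scale calibrated to a median onset of
#' about 65 years) with the per-sample hazard multiplied by `hazard_ratio^
#' dosage`; controls are administratively censored at their current age. A
#' fraction of controls is relabeled `excluded` to emulate exclusion-list
#' screening.
#'
#' @param calls data.frame from [simulate_cnv_calls()].
#' @param genome the [genome_model()] used to generate the calls.
#' @param effects list of [effect_spec()] objects.
#' @param covars a [covariate_spec()].
#' @param n_samples cohort size (must cover all samples in `calls`).
#' @param seed integer seed.
#' @param prevalence named numeric vector of target prevalences per disease
#'   (diseases not named in any effect may be included); must be in (0, 1).
#' @return a `data.frame` phenotype table: `sample_id`, covariates (`age`,
#'   `sex`, `array`, `PC*`, `bmi`), per-disease `status_<d>` in
#'   \{control, case, excluded\}, `onset_<d>` (years, cases only),
#'   `age_last_healthy_<d>`, and `disease_burden`.
#' @export
simulate_phenotypes <- function(calls, genome, effects, covars = covariate_spec(),
                                n_samples, seed, prevalence) {
  stopifnot(all(prevalence > 0 & prevalence < 1))
  eff_loci <- vapply(effects, function(e) e$locus, character(1))
  eff_dis <- vapply(effects, function(e) e$disease, character(1))
  locus_ids <- vapply(genome$loci, function(l) l$id, character(1))
  if (!all(eff_loci %in% locus_ids)) stop("effect references unknown locus")
  if (!all(eff_dis %in% names(prevalence))) stop("effect references disease without a target prevalence")

  set.seed(child_seed(seed, "phenotypes"))
  sample_ids <- sprintf("S%06d", seq_len(n_samples))
  age <- stats::runif(n_samples, 40, 70)
  sex <- stats::rbinom(n_samples, 1, 0.54)   # 1 = female
  array <- stats::rbinom(n_samples, 1, 0.1)
  pcs <- matrix(stats::rnorm(n_samples * covars$n_pcs), ncol = covars$n_pcs,
                dimnames = list(NULL, paste0("PC", seq_len(covars$n_pcs))))

  gl <- locus_genotypes(calls, genome, sample_ids)

  # standardized BMI with the CNV->BMI path
  bmi_z <- stats::rnorm(n_samples)
  for (e in effects) {
    if (e$bmi_shift != 0) {
      d <- encode_dosage(gl[, e$locus], e$mechanism)
      d[is.na(d)] <- 0
      bmi_z <- bmi_z + e$bmi_shift * d
    }
  }
  bmi <- 27.4 + 4.8 * bmi_z  # descriptive units for output

  b <- covars$betas
  lin_cov <- b$age * (age - 55) + b$sex * sex + b$array * array +
    as.numeric(pcs %*% rep(b$pc, covars$n_pcs))

  out <- data.frame(sample_id = sample_ids, age = age, sex = sex,
                    array = array, pcs, bmi = bmi, stringsAsFactors = FALSE)

  # Weibull PH baseline: shape 4, median onset ~65y
  wb_shape <- 4
  wb_scale <- 65 / log(2)^(1 / wb_shape)

  diseases <- names(prevalence)
  burden <- integer(n_samples)
  for (d in diseases) {
    lin <- lin_cov
    loghr <- numeric(n_samples)
    for (e in effects) {
      if (e$disease != d) next
      dos <- encode_dosage(gl[, e$locus], e$mechanism)
      dos[is.na(dos)] <- 0  # the generative mechanism ignores the other type
      lin <- lin + e$log_odds * dos
      loghr <- loghr + log(e$hazard_ratio) * dos
    }
    if (covars$bmi_beta != 0) lin <- lin + covars$bmi_beta * bmi_z
    intercept <- stats::uniroot(
      function(a) mean(stats::plogis(a + lin)) - prevalence[[d]],
      lower = -30, upper = 30, tol = 1e-10)$root
    p <- stats::plogis(intercept + lin)
    case <- stats::rbinom(n_samples, 1, p) == 1L
    status <- ifelse(case, "case", "control")
    ctrl <- which(!case)
    n_excl <- round(covars$exclusion_frac * length(ctrl))
    if (n_excl > 0) status[sample(ctrl, n_excl)] <- "excluded"

    onset <- rep(NA_real_, n_samples)
    if (any(case)) {
      u <- stats::runif(sum(case))
      onset[case] <- wb_scale * (-log(u) / exp(loghr[case]))^(1 / wb_shape)
    }
    alh <- ifelse(status == "case", onset,
                  ifelse(status == "control", age, NA_real_))
    out[[paste0("status_", d)]] <- status
    out[[paste0("onset_", d)]] <- onset
    out[[paste0("age_last_healthy_", d)]] <- alh
    burden <- burden + as.integer(case)
  }
  out$disease_burden <- burden
  out
}

#' Simulate an independent replication cohort
#'
#' Draws a second cohort from the same genome model with every CNV effect
#' (log odds, log hazard ratio, BMI shift) multiplied by `attenuation`, and
#' optionally subsamples the probe map to emulate a different genotyping
#' platform.
#'
#' @inheritParams simulate_phenotypes
#' @param n_samples replication cohort size.
#' @param attenuation effect attenuation in `[0, 1]` (1 = same effects,
#'   0 = null replication cohort).
#' @param probe_keep_frac fraction of probes retained in the replication
#'   probe map (default 1).
#' @param seed integer seed (independent of the discovery seed).
#' @return list with `calls`, `phenotypes`, and `probes` (the replication
#'   probe map).
#' @export
simulate_replication_cohort <- function(genome, effects, covars = covariate_spec(),
                                        n_samples, attenuation = 1,
                                        probe_keep_frac = 1, seed, prevalence) {
  stopifnot(attenuation >= 0, attenuation <= 1)
  eff2 <- lapply(effects, function(e) {
    effect_spec(e$disease, e$locus, e$mechanism,
                log_odds = e$log_odds * attenuation,
                hazard_ratio = exp(log(e$hazard_ratio) * attenuation),
                bmi_shift = e$bmi_shift * attenuation)
  })
  calls <- simulate_cnv_calls(genome, n_samples, seed = child_seed(seed, "replication"))
  phen <- simulate_phenotypes(calls, genome, eff2, covars, n_samples,
                              seed = child_seed(seed, "replication_phen"),
                              prevalence = prevalence)
  probes <- genome$probes
  if (probe_keep_frac < 1) {
    # systematic thinning (every k-th probe per chromosome): emulates a
    # sparser platform while guaranteeing locus coverage when the original
    # map has >= 1/probe_keep_frac probes per locus
    k <- max(2L, round(1 / probe_keep_frac))
    keep <- unlist(lapply(unique(probes$chrom), function(chr) {
      idx <- which(probes$chrom == chr)
      idx[seq(1L, length(idx), by = k)]
    }))
    probes <- probes[sort(keep), , drop = FALSE]
    rownames(probes) <- NULL
  }
  list(calls = calls, phenotypes = phen, probes = probes)
}
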