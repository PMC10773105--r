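test_that("residual regression is null-calibrated and errors on saturation", {
  # response residuals are two-valued, so p-values sit on a lattice; the
  # calibration check is therefore on rejection rates, not on a KS statistic
  set.seed(17)
  n <- 2000
  covs <- data.frame(age = runif(n, 40, 70))
  pvals <- replicate(1000, {
    y <- rbinom(n, 1, 0.1)
    gg <- numeric(n); gg[sample(n, 100)] <- 1
    residual_regression(y, covs, list(mirror = gg))$p
  })
  for (a in c(0.05, 0.1)) {
    expect_lt(abs(mean(pvals <= a) - a), 3 * sqrt(a * (1 - a) / 1000))
  }

  # saturated covariate model -> zero residuals -> error
  ysat <- c(rep(0, 50), rep(1, 50))
  xsat <- data.frame(x = ysat)
  expect_error(residual_regression(ysat, xsat, list(mirror = rnorm(100))),
               "saturated")
})

test_that("residual regression reports the lowest-p encoding with power", {
  set.seed(18)
  n <- 20000
  g <- numeric(n); g[sample(n, 100)] <- 1
  y <- rbinom(n, 1, plogis(-3 + 2.5 * g))
  res <- residual_regression(y, NULL, list(mirror = g, noise = rnorm(n)))
  expect_equal(res$model, "mirror")
  expect_lt(res$p, 1e-4)
})

test_that("CoxPH onset fit is null under no effect and Efron equals Breslow untied", {
  set.seed(19)
  n <- 2000
  time <- rexp(n, 0.02)
  event <- rbinom(n, 1, 0.3)
  g <- numeric(n); g[sample(n, 100)] <- 1
  res <- coxph_onset(time, event, NULL, list(mirror = g))
  expect_gt(res$p, 0.001)
  expect_lt(abs(log(res$hr)), 0.8)

  # all-distinct event times: tie handling is irrelevant
  dat <- data.frame(time = time, event = event, dosage = g)
  fe <- survival::coxph(survival::Surv(time, event) ~ dosage, dat, ties = "efron")
  fb <- survival::coxph(survival::Surv(time, event) ~ dosage, dat, ties = "breslow")
  expect_equal(coef(fe), coef(fb), tolerance = 1e-8)
})

test_that("CoxPH genotype p-values are uniform under the null across probes", {
  set.seed(20)
  n <- 1000
  time <- rexp(n, 0.02)
  event <- rbinom(n, 1, 0.3)
  pvals <- replicate(500, {
    g <- numeric(n); g[sample(n, 40)] <- 1
    # rare carriers occasionally give a monotone partial likelihood; the
    # p-value is still well defined
    suppressWarnings(coxph_onset(time, event, NULL, list(mirror = g))$p)
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("Kaplan-Meier matches the hand-computed product-limit estimate", {
  # events at 2, 4; censored at 3, 5, 5 -> S(4) = (4/5)(2/3)
  km <- kaplan_meier(c(2, 3, 4, 5, 5), c(1, 0, 1, 0, 0))
  s4 <- summary(km, times = 4)$surv
  expect_equal(s4, (4 / 5) * (2 / 3), tolerance = 1e-9)

  # no events -> curve stays at 1; all events at t = 1 -> step to 0
  km0 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  km1 <- kaplan_meier(rep(1, 4), rep(1, 4))
  expect_equal(min(km1$surv), 0)
})

test_that("tier assignment follows the pass-count rule over all patterns", {
  alpha <- 1e-4
  lo <- 1e-5; hi <- 0.3
  # exhaustive truth table over the 8 threshold patterns
  for (f in c(TRUE, FALSE)) for (r in c(TRUE, FALSE)) for (cx in c(TRUE, FALSE)) {
    k <- sum(f, r, cx)
    ps <- c(ifelse(f, lo, hi), ifelse(r, lo, hi), ifelse(cx, lo, hi))
    if (k == 0) {
      expect_warning(tier <- assign_tier(ps[1], ps[2], ps[3]), "demoted")
      expect_true(is.na(tier))
    } else {
      expect_equal(assign_tier(ps[1], ps[2], ps[3]), c(3L, 2L, 1L)[k])
    }
  }
  # burden signals are tier 1 unconditionally
  expect_equal(assign_tier(hi, hi, hi, is_burden_signal = TRUE), 1L)
})

test_that("directional replication adjusts p and matches nearest probes", {
  signals <- data.frame(signal_id = c("s1", "s2", "s3"),
                        chrom = c("1", "1", "2"),
                        pos = c(1000, 5000, 1000),
                        beta = c(1.2, -0.5, 0.8))
  rep_gwas <- data.frame(
    probe_id = c("r1", "r2", "r3", "r4"),
    chrom = c("1", "1", "1", "1"),
    pos = c(900, 1100, 5200, 4800),
    beta = c(0.9, -0.4, 0.3, 0.2),
    p = c(0.01, 0.02, 0.01, NA))  # r4 regression failed
  res <- replicate_signals(signals, rep_gwas)
  # s1: r1 and r2 equidistant -> tie broken toward smaller position (r1)
  expect_equal(res$rep_probe[1], "r1")
  expect_equal(res$p_new[1], 0.005)          # concordant: p/2
  # s2: nearest successful probe is r3 (r4 failed); sign mismatch
  expect_equal(res$rep_probe[2], "r3")
  expect_equal(res$p_new[2], 1 - 0.01 / 2)   # discordant: 1 - p/2
  # s3: chromosome with no probes -> non-evaluable
  expect_false(res$evaluable[3])
  expect_equal(attr(res, "threshold"), 0.05 / 2)

  # p_old = 1 boundary
  rep1 <- data.frame(probe_id = "x", chrom = "1", pos = 1000, beta = 1, p = 1)
  r1 <- replicate_signals(signals[1, ], rep1)
  expect_equal(r1$p_new, 0.5)
})

test_that("adjusted replication p is monotone and rewards concordance", {
  p_old <- seq(0.001, 0.999, length.out = 50)
  conc <- p_old / 2
  disc <- 1 - p_old / 2
  expect_true(all(diff(conc) > 0))
  expect_true(all(diff(disc) < 0))
  expect_true(all(conc < p_old))
  expect_true(all(conc > 0 & conc < 1 & disc > 0 & disc < 1))
})

test_that("replication enrichment reproduces the published fold and tail", {
  enr <- replication_enrichment(7, 49, 0.05)
  expect_equal(round(enr$fold, 1), 2.9)
  expect_equal(signif(enr$binomial_p, 2), 0.011)
  # closed forms
  e0 <- replication_enrichment(0, 49, 0.05)
  expect_equal(e0$fold, 0)
  expect_equal(e0$binomial_p, 1)
  en <- replication_enrichment(10, 10, 0.3)
  expect_equal(en$binomial_p, 0.3^10, tolerance = 1e-12)
  # grid invariants: p at k=0 is 1 everywhere; p decreases in k
  expect_true(all(replication_enrichment(0, 30, 0.05)$grid$binomial_p == 1))
  p_by_k <- vapply(0:10, function(k) replication_enrichment(k, 30, 0.05)$binomial_p,
                   numeric(1))
  expect_true(all(diff(p_by_k) < 0))
  expect_equal(replication_enrichment(3, 30, 0.05)$grid$alpha,
               seq(0.1, 0.005, by = -0.005))
})

test_that("inverse normal transform matches closed-form quantiles and rank rules", {
  got <- inverse_normal_transform(c(1, 2, 3))
  expect_equal(got, qnorm(c(1, 3, 5) / 6))
  expect_equal(round(got, 3), c(-0.967, 0, 0.967))
  # symmetric input sums to zero; monotone rescaling leaves output unchanged
  x <- c(5, 1, 3, 2, 4)
  expect_equal(sum(inverse_normal_transform(x)), 0, tolerance = 1e-12)
  expect_equal(inverse_normal_transform(exp(x)), inverse_normal_transform(x))
  expect_error(inverse_normal_transform(rep(1, 5)), "constant")
})

test_that("BMI mediation is flagged while direct effects survive adjustment", {
  g <- toy_genome(dup_freq = 0.005, del_freq = 0.005)
  run_one <- function(seed, bmi_shift, bmi_beta, log_odds) {
    n <- 100000
    calls <- simulate_cnv_calls(g, n, seed = seed)
    eff <- list(effect_spec("d1", "L1", "mirror", log_odds = log_odds,
                            bmi_shift = bmi_shift))
    ph <- simulate_phenotypes(calls, g, eff,
                              covariate_spec(bmi_beta = bmi_beta),
                              n, seed = seed, prevalence = c(d1 = 0.05))
    m <- encode_probe_matrix(calls, g$probes, samples = ph$sample_id)
    probe <- m$probes$probe_id[m$probes$chrom == "1" & m$probes$pos >= 1e7 &
                                 m$probes$pos <= 1.1e7][1]
    dos <- encode_dosage(as.numeric(m$G[, probe]), "mirror")
    bmi_confounding(dos, ph$status_d1, ph$bmi, ph[, c("age", "sex")],
                    n_traits = 2, n_signals = 1, n_eligible = 1, gw_p = 0.01)
  }
  # pure mediation: CNV -> BMI -> disease, no direct path
  med_flags <- vapply(1:8, function(s) {
    r <- run_one(100 + s, bmi_shift = 1.5, bmi_beta = 0.6, log_odds = 0)
    isTRUE(r$eligible) && isTRUE(r$likely_bmi_driven)
  }, logical(1))
  expect_gte(mean(med_flags), 0.8)

  # direct effect with BMI-inert CNV: never flagged as BMI-driven
  dir_flags <- vapply(1:8, function(s) {
    r <- run_one(200 + s, bmi_shift = 0, bmi_beta = 0.6, log_odds = 1.2)
    isTRUE(r$eligible) && isTRUE(r$likely_bmi_driven)
  }, logical(1))
  expect_lte(mean(dir_flags), 0.05)
})
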