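test_that("genotypic Fisher test matches full enumeration and handles collapse", {
  # identical rows -> independence, p = 1
  g <- c(rep(-1, 10), rep(0, 180), rep(1, 10))
  y <- rep(c(0, 1), 100)
  expect_equal(genotypic_fisher(g, y), 1, tolerance = 1e-12)

  # spec table: control (0, 20, 0), case (5, 10, 5)
  g2 <- c(rep(0, 20), rep(-1, 5), rep(0, 10), rep(1, 5))
  y2 <- c(rep(0, 20), rep(1, 20))
  tab <- table(factor(y2, levels = 0:1), factor(g2, levels = c(-1, 0, 1)))
  expect_equal(genotypic_fisher(g2, y2), fisher_enum_oracle(tab), tolerance = 1e-9)

  # zero column margin collapses to the 2x2 exact test
  g3 <- c(1, rep(0, 19))
  y3 <- c(1, rep(0, 10), rep(1, 9))
  tab3 <- table(factor(y3, levels = 0:1), factor(g3, levels = c(0, 1)))
  expect_equal(genotypic_fisher(g3, y3), fisher_enum_oracle(tab3), tolerance = 1e-9)
})

test_that("dosage encodings follow the model table and reject bad genotypes", {
  g <- c(-1, 0, 1)
  expect_equal(encode_dosage(g, "mirror"), c(-1, 0, 1))
  expect_equal(encode_dosage(g, "ushape"), c(1, 0, 1))
  expect_equal(encode_dosage(g, "duponly"), c(NA, 0, 1))
  expect_equal(encode_dosage(g, "delonly"), c(1, 0, NA))
  expect_error(encode_dosage(c(0, 2), "mirror"))
})

test_that("prefilter applies the Fisher and carrier-case rules per model", {
  set.seed(33)
  n <- 5000
  G <- matrix(0, n, 3)
  G[1:40, 1] <- 1           # probe 1: 40 duplication carriers, no deletions
  G[41:60, 2] <- 1          # probe 2: 20 duplication carriers
  # probe 3: all-zero -> frequency 0, excluded
  m <- matrix_from_genotypes(G)
  status <- rep("control", n)
  status[1:15] <- "case"                       # 15 diseased carriers at probe 1
  status[sample(100:n, 150)] <- "case"         # background cases
  fr <- probe_frequencies(m)
  pf <- prefilter_probes(m, fr, status)
  expect_lt(pf$fisher_p[1], 1e-3)
  expect_true(pf$pass_mirror[1] && pf$pass_ushape[1] && pf$pass_duponly[1])
  expect_false(pf$pass_delonly[1])  # no diseased deletion carriers
  expect_false(fr$retained[3])
  expect_false(pf$pass_mirror[3])   # frequency-excluded regardless of Fisher p

  # a probe whose carriers include a single case fails every model even with
  # a strong Fisher signal elsewhere
  status2 <- rep("control", n)
  status2[41] <- "case"                        # 1 diseased carrier at probe 2
  status2[1:40] <- "case"                      # probe 1 saturated
  pf2 <- prefilter_probes(m, fr, status2)
  expect_false(any(pf2$pass_mirror[2], pf2$pass_ushape[2],
                   pf2$pass_duponly[2], pf2$pass_delonly[2]))
})

test_that("ML logistic is null-calibrated and agrees with Firth away from separation", {
  set.seed(11)
  cover <- 0L
  for (r in 1:100) {
    x <- rbinom(1000, 1, 0.05)
    y <- rbinom(1000, 1, 0.3)
    f <- firth_logistic(y, cbind(1, x = x))
    if (abs(f$beta[["x"]]) < 3 * f$se[["x"]]) cover <- cover + 1L
  }
  expect_gte(cover, 97L)

  # well-separated balanced data without separation: fallback not triggered,
  # ML and Firth agree within 10% relative
  set.seed(12)
  x <- rnorm(500)
  y <- rbinom(500, 1, plogis(1.5 * x))
  Xd <- cbind(1, x = x)
  f_ml <- firth_logistic(y, Xd)
  expect_false(f_ml$firth)
  f_pen <- cnvgwas:::firth_penalized(y, Xd)
  expect_lt(abs(f_ml$beta[["x"]] - f_pen$beta[2]) / abs(f_ml$beta[["x"]]), 0.1)
})

test_that("complete separation triggers Firth and matches the grid-search oracle", {
  # all 5 carriers are cases
  set.seed(3)
  x <- c(rep(1, 5), rep(0, 995))
  y <- c(rep(1, 5), rbinom(995, 1, 0.1))
  f <- firth_logistic(y, cbind(1, x = x))
  expect_true(f$firth)
  expect_true(is.finite(f$beta[["x"]]))
  expect_true(f$p[["x"]] > 0 && f$p[["x"]] < 1)
  oracle <- firth_grid_oracle(y, x)
  expect_equal(round(f$beta[["x"]], 2), round(oracle[["beta"]], 2))
  # ML on the same data diverges (|beta| runaway or non-convergence)
  ml <- cnvgwas:::ml_logistic(y, cbind(1, x))
  expect_true(!ml$converged || abs(ml$beta[2]) > 10)
})

test_that("Firth fallback stays off for well-conditioned carrier counts", {
  set.seed(21)
  g <- c(rep(1, 40), rep(-1, 40), rep(0, 2000))
  y <- rbinom(length(g), 1, plogis(-1 + 0.5 * g))
  # all genotype-by-outcome cells >= 10
  expect_true(all(table(y, g) >= 10))
  f <- firth_logistic(y, cbind(1, g = g))
  expect_false(f$firth)
})

test_that("the GWAS scan recovers simulated effects and respects masking", {
  g <- toy_genome()
  n <- 100000
  calls <- simulate_cnv_calls(g, n, seed = 31)
  eff <- list(effect_spec("d1", "L1", "mirror", log_odds = 1.0))
  ph <- simulate_phenotypes(calls, g, eff, covariate_spec(), n, seed = 31,
                            prevalence = c(d1 = 0.05))
  m <- encode_probe_matrix(calls, g$probes, samples = ph$sample_id)
  probe <- m$probes$probe_id[m$probes$chrom == "1" &
                               m$probes$pos >= 1e7 & m$probes$pos <= 1.1e7][1]
  covs <- ph[, c("age", "sex")]
  res <- run_gwas(m, ph$status_d1, covs, "mirror", probes = probe)
  expect_lt(abs(res$beta - 1.0), 2 * res$se)

  # mirror and ushape coincide exactly on a probe with no deletion carriers
  gg <- as.numeric(m$G[, probe])
  dup_only_probe <- all(gg >= 0)
  if (!dup_only_probe) {
    gg2 <- pmax(gg, 0)
    m2 <- matrix_from_genotypes(matrix(gg2, ncol = 1))
    r_m <- run_gwas(m2, ph$status_d1, covs, "mirror")
    r_u <- run_gwas(m2, ph$status_d1, covs, "ushape")
    expect_equal(r_m$beta, r_u$beta)
    expect_equal(r_m$p, r_u$p)
  }

  # delonly on a duplications-only probe is skipped
  m3 <- matrix_from_genotypes(matrix(c(rep(1, 50), rep(0, 450)), ncol = 1))
  r_d <- run_gwas(m3, sim_status(rep(0, 500), 0.2), NULL, "delonly")
  expect_true(!is.na(r_d$skip_reason))
})

test_that("burden GWAS is null-calibrated and recovers a deletion effect", {
  set.seed(41)
  n <- 2000
  # null: p-values uniform across probes
  G <- matrix(0, n, 300)
  for (j in 1:300) G[sample(n, 30), j] <- sample(c(-1, 1), 30, replace = TRUE)
  m <- matrix_from_genotypes(G, chrom = rep("1", 300),
                             pos = seq(1e6, by = 1e5, length.out = 300))
  burden <- rpois(n, 2)
  res <- run_burden_gwas(m, burden, NULL, "mirror")
  ks <- suppressWarnings(ks.test(res$p[!is.na(res$p)], "punif"))
  expect_gt(ks$p.value, 0.001)

  # +3 diseases per deletion, recovered within 2 SE
  gdel <- ifelse(rbinom(n, 1, 0.02) == 1, -1, 0)
  burden2 <- rpois(n, 2) + 3 * (gdel == -1)
  m2 <- matrix_from_genotypes(matrix(gdel, ncol = 1))
  r2 <- run_burden_gwas(m2, burden2, NULL, "delonly")
  expect_lt(abs(r2$beta - 3), 2 * r2$se)

  expect_error(run_burden_gwas(m2, rep(2, n)), "constant burden")
})

test_that("stepwise conditional analysis isolates independent leads", {
  set.seed(51)
  n <- 4000
  carriers1 <- sample(n, 60)
  carriers2 <- sample(setdiff(seq_len(n), carriers1), 60)
  g1 <- numeric(n); g1[carriers1] <- 1
  g2 <- numeric(n); g2[carriers2] <- 1
  # 6 perfect proxies of locus 1 on chrom 1, locus 2 alone on chrom 2
  G <- cbind(g1, g1, g1, g1, g1, g1, g2)
  m <- matrix_from_genotypes(G, chrom = c(rep("1", 6), "2"),
                             pos = c(seq(1e6, by = 1e4, length.out = 6), 1e6))
  y <- rbinom(n, 1, plogis(-2.5 + 1.5 * g1 + 1.5 * g2))
  status <- ifelse(y == 1, "case", "control")
  leads <- stepwise_conditional(m, status, NULL, "mirror", threshold = 1e-4)
  expect_equal(nrow(leads), 2L)
  chroms <- m$probes$chrom[match(leads$probe_id, m$probes$probe_id)]
  expect_setequal(chroms, c("1", "2"))  # one lead per causal locus
  # no probe passing the threshold -> empty lead list
  y0 <- rbinom(n, 1, 0.05)
  leads0 <- stepwise_conditional(m, ifelse(y0 == 1, "case", "control"),
                                 NULL, "mirror", threshold = 1e-10)
  expect_equal(nrow(leads0), 0L)
})

test_that("genomic inflation is 1 under the null and detects enrichment", {
  expect_equal(genomic_inflation(rep(0.5, 200)), 1)
  set.seed(61)
  expect_lt(abs(genomic_inflation(runif(10000)) - 1), 0.05)
  expect_gt(genomic_inflation(runif(10000)^2), 1)
  expect_error(genomic_inflation(c(rep(0.5, 99), 1.2)), "in \\(0, 1\\]")
  expect_error(genomic_inflation(rep(0.5, 10)))
})
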