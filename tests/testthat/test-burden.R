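mk_calls <- function(...) {
  df <- data.frame(...)
  if (is.null(df$qs)) df$qs <- ifelse(df$type == "DUP", 0.9, -0.9)
  if (is.null(df$copy_number)) df$copy_number <- ifelse(df$type == "DUP", 3L, 1L)
  df
}

test_that("burden sums call lengths per type and counts distinct genes once", {
  calls <- mk_calls(
    sample_id = c("A", "A", "B", "B"),
    chrom = "1",
    start = c(1e6, 5e6, 2e6, 2.4e6),
    end = c(3e6 - 1, 5.5e6 - 1, 2.5e6, 2.9e6),
    type = c("DEL", "DUP", "DUP", "DUP"))
  genes <- data.frame(gene = c("g1", "g2", "g3"), chrom = "1",
                      start = c(1.5e6, 2.45e6, 8e6), end = c(1.6e6, 2.6e6, 8.1e6))
  b <- compute_burden(calls, samples = c("A", "B", "C"), genes = genes)
  expect_equal(b$del_mb[b$sample_id == "A"], 2.0)
  expect_equal(b$del_genes[b$sample_id == "A"], 2)  # g1 and g2 both inside the deletion
  expect_equal(b$dup_mb[b$sample_id == "A"], 0.5)
  expect_equal(b$cnv_mb[b$sample_id == "A"], 2.5)
  # B's two overlapping duplications both hit g2: counted once
  expect_equal(b$dup_genes[b$sample_id == "B"], 1)
  # sample with no calls: all zeros
  expect_true(all(b[b$sample_id == "C", -1] == 0))
  # six-metric consistency
  expect_equal(b$cnv_mb, b$dup_mb + b$del_mb)
  expect_equal(b$cnv_genes, b$dup_genes + b$del_genes)
  # gene unit without gene file -> absent, Mb still computed
  b2 <- compute_burden(calls, samples = c("A", "B"))
  expect_false("cnv_genes" %in% names(b2))
})

test_that("low-quality calls never contribute to burden", {
  calls <- mk_calls(sample_id = "A", chrom = "1", start = 1e6, end = 2e6,
                    type = "DEL", qs = -0.4)
  b <- compute_burden(calls, samples = "A")
  expect_equal(b$cnv_mb, 0)
})

test_that("Mb burden is invariant to splitting a call into abutting pieces", {
  whole <- mk_calls(sample_id = "A", chrom = "1", start = 1e6, end = 3e6, type = "DUP")
  split <- mk_calls(sample_id = c("A", "A"), chrom = "1",
                    start = c(1e6, 2e6 + 1), end = c(2e6, 3e6), type = "DUP")
  bw <- compute_burden(whole, "A")
  bs <- compute_burden(split, "A")
  expect_equal(bs$dup_mb, bw$dup_mb)
  # gene units agree when the split point crosses no gene
  genes <- data.frame(gene = "g1", chrom = "1", start = 1.2e6, end = 1.4e6)
  expect_equal(compute_burden(split, "A", genes)$dup_genes,
               compute_burden(whole, "A", genes)$dup_genes)
})

test_that("overlap rules follow the 1-bp and reciprocal-50 conventions", {
  # inclusive coordinates: [0,100] and [100,200] share bp 100
  expect_true(interval_overlaps(0, 100, 100, 200, "any_1bp"))
  expect_false(interval_overlaps(0, 100, 101, 200, "any_1bp"))
  # 1 Mb call inside a 10 Mb region: any_1bp yes, reciprocal no
  expect_true(interval_overlaps(2e6, 3e6 - 1, 1e6, 11e6 - 1, "any_1bp"))
  expect_false(interval_overlaps(2e6, 3e6 - 1, 1e6, 11e6 - 1, "reciprocal_50"))
  # [0,100] vs [40,140]: overlap 61 > 50.5 on both sides
  expect_true(interval_overlaps(0, 100, 40, 140, "reciprocal_50"))
  # just under half: fails
  expect_false(interval_overlaps(0, 100, 51, 151, "reciprocal_50"))
})

test_that("subset + corrected = total exactly, per sample, type, and unit", {
  set.seed(23)
  g <- toy_genome(dup_freq = 0.02, del_freq = 0.02)
  calls <- simulate_cnv_calls(g, 3000, seed = 23)
  samples <- sprintf("S%06d", 1:3000)
  genes <- data.frame(gene = paste0("g", 1:6), chrom = rep(c("1", "2"), each = 3),
                      start = rep(c(1.0e7, 1.04e7, 2.0e7), 2),
                      end = rep(c(1.02e7, 1.06e7, 2.05e7), 2))
  genes$chrom <- c("1", "1", "1", "2", "2", "2")
  genes$start <- c(1.0e7, 1.04e7, 3e7, 2.0e7, 2.04e7, 3e7)
  genes$end <- c(1.02e7, 1.06e7, 3.1e7, 2.02e7, 2.06e7, 3.1e7)
  part <- burden_partition("GD", data.frame(chrom = "1", start = 1e7, end = 1.1e7))
  for (rule in c("any_1bp", "reciprocal_50")) {
    r <- subset_corrected_burden(calls, samples, part, rule, genes = genes)
    num <- setdiff(names(r$total), "sample_id")
    for (col in num) {
      expect_equal(r$subset[[col]] + r$corrected[[col]], r$total[[col]])
    }
    expect_equal(r$subset$cnv_mb, r$subset$dup_mb + r$subset$del_mb)
    expect_equal(r$corrected$cnv_genes, r$corrected$dup_genes + r$corrected$del_genes)
  }
  # no call overlaps the partition -> subset all zero
  far <- burden_partition("none", data.frame(chrom = "1", start = 4e7, end = 4.1e7))
  r0 <- subset_corrected_burden(calls, samples, far, "any_1bp")
  expect_true(all(r0$subset$cnv_mb == 0))
  expect_equal(r0$corrected$cnv_mb, r0$total$cnv_mb)
})

test_that("type-applicability restricts partition subsets to the matching burden", {
  calls <- mk_calls(sample_id = c("A", "A"), chrom = "1",
                    start = c(1e6, 1e6), end = c(2e6, 2e6),
                    type = c("DUP", "DEL"))
  dup_syndrome <- burden_partition("GD", data.frame(chrom = "1", start = 1e6,
                                                    end = 2e6, types = "DUP"))
  r <- subset_corrected_burden(calls, "A", dup_syndrome, "any_1bp")
  expect_gt(r$subset$dup_mb, 0)
  expect_equal(r$subset$del_mb, 0)  # deletion not counted toward a DUP syndrome
})

test_that("GWAS-signal correction removes calls type- and disease-specifically", {
  calls <- mk_calls(sample_id = c("A", "B", "C"), chrom = "1",
                    start = c(1e6, 1e6, 5e6), end = c(2e6, 2e6, 6e6),
                    type = c("DEL", "DUP", "DEL"))
  samples <- c("A", "B", "C")
  total <- compute_burden(calls, samples)

  # no associated CNVR: corrected equals total
  none <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                     models = character(0))
  expect_equal(signal_corrected_burden(calls, samples, none), total)

  # delonly-associated CNVR over [1e6, 2e6]
  assoc <- data.frame(chrom = "1", start = 1.5e6, end = 2.5e6, models = "delonly")
  corr <- signal_corrected_burden(calls, samples, assoc)
  expect_equal(corr$del_mb[corr$sample_id == "A"], 0)     # deletion removed
  expect_equal(corr$cnv_mb[corr$sample_id == "A"], 0)
  expect_equal(corr$dup_mb[corr$sample_id == "B"],
               total$dup_mb[total$sample_id == "B"])      # duplication retained
  expect_equal(corr$del_mb[corr$sample_id == "C"],
               total$del_mb[total$sample_id == "C"])      # outside the CNVR

  # mirror-associated CNVR removes both types
  assoc2 <- data.frame(chrom = "1", start = 1.5e6, end = 2.5e6, models = "mirror,ushape")
  corr2 <- signal_corrected_burden(calls, samples, assoc2)
  expect_equal(corr2$dup_mb[corr2$sample_id == "B"], 0)
  expect_equal(corr2$del_mb[corr2$sample_id == "A"], 0)
})

test_that("burden association reports effects and variance explained", {
  set.seed(24)
  n <- 20000
  burden_mb <- rexp(n, 2)
  y <- rbinom(n, 1, plogis(-3 + 0.4 * burden_mb))
  res <- burden_association(burden_mb, y)
  expect_lt(abs(res$beta - 0.4), 2 * res$se)
  expect_gt(res$variance_explained, 0)

  # independent outcome: pseudo-R^2 near zero
  y0 <- rbinom(n, 1, 0.1)
  res0 <- burden_association(burden_mb, y0)
  expect_lt(res0$variance_explained, 1e-3)

  # near-deterministic outcome: pseudo-R^2 approaches 1
  yd <- as.integer(burden_mb > median(burden_mb))
  resd <- suppressWarnings(burden_association(burden_mb, yd))
  expect_gt(resd$variance_explained, 0.5)

  # quantitative outcome uses adjusted R^2; covariates pass through
  db <- rpois(n, 2) + 0.5 * burden_mb
  resq <- burden_association(burden_mb, db, covariates = data.frame(age = runif(n)))
  expect_lt(abs(resq$beta - 0.5), 2 * resq$se)
  expect_gt(resq$variance_explained, 0)
  expect_error(burden_association(rep(1, n), y), "zero-variance")
})
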