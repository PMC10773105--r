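# Shared fixtures: small genomes and cohorts built in code at test time.

# Two-chromosome genome with probes clustered around each CNV locus so that
# encoded matrices have informative probe columns.
toy_genome <- function(dup_freq = 0.005, del_freq = 0.005, qs_noise = 0.2,
                       probes_per_locus = 8, n_background_probes = 20) {
  chroms <- data.frame(chrom = c("1", "2"), length_bp = c(5e7, 5e7))
  loci <- list(
    cnv_locus("L1", "1", 1e7, 1.1e7, dup_freq = dup_freq, del_freq = del_freq,
              qs_noise = qs_noise),
    cnv_locus("L2", "2", 2e7, 2.1e7, dup_freq = dup_freq, del_freq = del_freq,
              qs_noise = qs_noise))
  probes <- list()
  for (l in loci) {
    pos <- round(seq(l$start, l$end, length.out = probes_per_locus))
    probes[[l$id]] <- data.frame(
      probe_id = paste0("p_", l$id, "_", seq_along(pos)),
      chrom = l$chrom, pos = pos)
  }
  for (chr in chroms$chrom) {
    pos <- round(seq(2e6, 4.8e7, length.out = n_background_probes))
    probes[[paste0("bg", chr)]] <- data.frame(
      probe_id = paste0("p_bg", chr, "_", seq_along(pos)),
      chrom = chr, pos = pos)
  }
  pm <- do.call(rbind, probes)
  pm <- pm[!duplicated(pm[c("chrom", "pos")]), ]
  genome_model(chroms, pm, loci)
}

# cnv_matrix from explicit genotype columns (samples x probes), one probe per
# chromosome unless chrom given.
matrix_from_genotypes <- function(G, chrom = NULL, pos = NULL) {
  np <- ncol(G)
  if (is.null(chrom)) chrom <- rep("1", np)
  if (is.null(pos)) pos <- seq(1e6, by = 1e5, length.out = np)
  probes <- data.frame(probe_id = paste0("p", seq_len(np)), chrom = chrom, pos = pos)
  samples <- sprintf("S%06d", seq_len(nrow(G)))
  Gs <- Matrix::Matrix(G, sparse = TRUE)
  dimnames(Gs) <- list(samples, probes$probe_id)
  structure(list(G = Gs, probes = probes, samples = samples), class = "cnv_matrix")
}

# quick case/control vector with a given carrier enrichment
sim_status <- function(g, base = 0.05, log_or = 0, seed = 1) {
  set.seed(seed)
  p <- plogis(qlogis(base) + log_or * g)
  ifelse(rbinom(length(g), 1, p) == 1, "case", "control")
}
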