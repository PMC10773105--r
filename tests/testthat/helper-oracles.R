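# Independent oracles used to cross-check package computations. These are
# deliberately naive (full enumeration, brute force, grid search) and never
# share code with the implementation they validate.

# Exact two-sided p of a 2x3 (or 2x2) table by full enumeration over all
# tables with the observed margins; two-sided by probability-mass ordering
# (sum of probabilities <= observed, with fisher.test's relative tolerance).
fisher_enum_oracle <- function(tab) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  logp_table <- function(x1) {
    # x1: first-row counts; prob = prod choose(cs, x1) / choose(n, rs[1])
    sum(lchoose(cs, x1)) - lchoose(n, rs[1])
  }
  p_obs <- exp(logp_table(tab[1, ]))
  total <- 0
  if (ncol(tab) == 2L) {
    for (a in 0:min(rs[1], cs[1])) {
      b <- rs[1] - a
      if (b < 0 || b > cs[2]) next
      pr <- exp(logp_table(c(a, b)))
      if (pr <= p_obs * (1 + 1e-7)) total <- total + pr
    }
  } else {
    for (a in 0:min(rs[1], cs[1])) {
      for (b in 0:min(rs[1] - a, cs[2])) {
        cc <- rs[1] - a - b
        if (cc < 0 || cc > cs[3]) next
        pr <- exp(logp_table(c(a, b, cc)))
        if (pr <= p_obs * (1 + 1e-7)) total <- total + pr
      }
    }
  }
  min(1, total)
}

# Firth-penalized logistic MLE by pure grid search, for a binary exposure
# (intercept + 0/1 carrier indicator). Uses aggregated counts so the grid is
# cheap; refines the grid twice around the optimum.
firth_grid_oracle <- function(y, x) {
  stopifnot(all(x %in% c(0, 1)))
  n0 <- sum(x == 0); n1 <- sum(x == 1)
  y0 <- sum(y[x == 0]); y1 <- sum(y[x == 1])
  pll <- function(b0, b1) {
    eta0 <- b0; eta1 <- b0 + b1
    p0 <- plogis(eta0); p1 <- plogis(eta1)
    ll <- y0 * eta0 - n0 * log1p(exp(eta0)) + y1 * eta1 - n1 * log1p(exp(eta1))
    w0 <- p0 * (1 - p0); w1 <- p1 * (1 - p1)
    det <- (n0 * w0) * (n1 * w1)  # det of 2x2 information for this design
    ll + 0.5 * log(det)
  }
  grid_pass <- function(b0r, b1r) {
    best <- c(NA, NA, -Inf)
    for (b0 in b0r) for (b1 in b1r) {
      v <- pll(b0, b1)
      if (v > best[3]) best <- c(b0, b1, v)
    }
    best
  }
  b <- grid_pass(seq(-8, 8, by = 0.1), seq(-8, 8, by = 0.1))
  b <- grid_pass(seq(b[1] - 0.1, b[1] + 0.1, by = 0.01),
                 seq(b[2] - 0.1, b[2] + 0.1, by = 0.01))
  b <- grid_pass(seq(b[1] - 0.01, b[1] + 0.01, by = 0.001),
                 seq(b[2] - 0.01, b[2] + 0.01, by = 0.001))
  c(intercept = b[1], beta = b[2])
}

# All-pairs brute-force pruning oracle (no windows): repeatedly drop the
# later-position probe of the first pair with r^2 above the threshold.
prune_bruteforce_oracle <- function(G, pos, r2_max) {
  alive <- rep(TRUE, ncol(G))
  repeat {
    idx <- which(alive)
    if (length(idx) < 2L) break
    r2 <- suppressWarnings(cor(as.matrix(G[, idx, drop = FALSE])))^2
    removed <- FALSE
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        if (!is.na(r2[a, b]) && r2[a, b] > r2_max) {
          drop <- if (pos[idx[a]] > pos[idx[b]]) idx[a] else idx[b]
          alive[drop] <- FALSE
          removed <- TRUE
          break
        }
      }
      if (removed) break
    }
    if (!removed) break
  }
  which(alive)
}

# Effective-test oracle: direct eigen-decomposition of the full correlation
# matrix of one chromosome's probes (zero-variance columns removed).
neff_eigen_oracle <- function(G, var_frac = 0.995) {
  G <- as.matrix(G)
  v <- apply(G, 2, var)
  G <- G[, v > 0, drop = FALSE]
  if (ncol(G) == 0L) return(0L)
  if (ncol(G) == 1L) return(1L)
  ev <- eigen(cor(G), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  which(cumsum(ev) >= var_frac * sum(ev))[1]
}

# Union-find transitive interval merging oracle (inclusive coordinates,
# >= 1 bp shared).
merge_union_find_oracle <- function(start, end) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i, par) { while (par[i] != i) i <- par[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && start[i] <= end[j] && start[j] <= end[i]) {
      parent[find(i, parent)] <- find(j, parent)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1), par = parent)
  do.call(rbind, lapply(unique(roots), function(r) {
    m <- roots == r
    data.frame(start = min(start[m]), end = max(end[m]))
  }))
}
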