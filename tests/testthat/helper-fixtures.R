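# Shared fixtures and independent oracles. Oracles deliberately use naive
# definitional computations, never the implementation under test.

toy_manifest <- function(n = 6, chrom = NULL) {
  if (is.null(chrom)) chrom <- rep(c("chr1", "chrX", "chrY"), length.out = n)
  probe_manifest(data.frame(
    probe_id = sprintf("cg%04d", seq_len(n)),
    chrom = chrom,
    pos = seq(1000L, by = 1000L, length.out = n),
    strand = rep(c("+", "-"), length.out = n),
    probe_type = rep(c("InfiniumII", "InfiniumI_Red"), length.out = n),
    probe_class = "cg"))
}

toy_sheet <- function(n = 4) {
  sample_sheet(data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    annotated_sex = rep(c("XX", "XY"), length.out = n),
    batch = rep(c("b1", "b2"), length.out = n)))
}

toy_beta <- function(man, sheet, seed = 1) {
  set.seed(seed)
  matrix(runif(nrow(man) * nrow(sheet)), nrow(man),
         dimnames = list(man$probe_id, sheet$sample_id))
}

toy_dataset <- function(n_probes = 6, n_samples = 4, seed = 1) {
  man <- toy_manifest(n_probes)
  sheet <- toy_sheet(n_samples)
  methyl_dataset(man, sheet, beta = toy_beta(man, sheet, seed))
}

# --- independent oracles ------------------------------------------------

# Spearman rho as rank-then-Pearson with average ranks
oracle_spearman <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

oracle_rmse <- function(a, b) sqrt(mean((a - b)^2))

# BH by the literal step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(p[o[i:m]] * m / seq(i, m)))
  }
  q
}

# brute-force per-base interval overlap
oracle_overlap <- function(pos, starts, ends, chrom_q, chrom_s) {
  vapply(seq_along(pos), function(i)
    any(chrom_s == chrom_q[i] & starts <= pos[i] & ends >= pos[i]),
    logical(1))
}

# full enumeration of r x c exact test over all compositions of n into the
# r*c cells (rejecting those with wrong margins); tiny totals only. This is
# deliberately a different enumeration strategy from the implementation's
# margin-constrained recursion.
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1))
  out <- vector("list", n + 1)
  for (v in 0:n) {
    rest <- compositions(n - v, k - 1)
    out[[v + 1]] <- cbind(v, rest)
  }
  do.call(rbind, out)
}

oracle_exact_rxc <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  prob <- function(t) exp(sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) -
                            lgamma(n + 1) - sum(lgamma(t + 1)))
  p_obs <- prob(tab)
  grid <- compositions(n, length(tab))
  tot <- 0
  for (i in seq_len(nrow(grid))) {
    t <- matrix(grid[i, ], nrow(tab))
    if (!all(rowSums(t) == rs) || !all(colSums(t) == cs)) next
    pt_ <- prob(t)
    if (pt_ <= p_obs * (1 + 1e-7)) tot <- tot + pt_
  }
  tot
}
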