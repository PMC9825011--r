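## Synthetic array-like cohorts with known ground truth.
##
## The generator emulates the structure of a mixed-sex placental 450K cohort:
## XX/XY dosage differences in X/Y fluorescence, background-only Y signal in
## XX samples (beta ~ 0.5, high detection p), Xi/Xa promoter averaging at
## XCI-subject promoters in XX, 65 trimodal rs genotyping probes, per-probe
## failure and low-bead-count artifacts, batch labels, and a case/control
## phenotype with a gestational-age covariate.

#' Simulation configuration
#'
#' Defaults encode the stated world every test runs in: 50 XX + 50 XY
#' samples; 416 chrY probes of which 79 are constant in XY (the 450K chrY
#' census); 65 rs genotyping probes with allele frequency 0.5; per-channel
#' background ~10% of foreground total so XX samples show nY near 0.1;
#' XCI-subject promoters at beta_Xa = 0.05 / beta_Xi = 0.85 so XX promoter
#' beta averages ~0.45.
#'
#' @param n_auto number of autosomal cg probes.
#' @param n_x_genes number of chrX genes with simulated promoters.
#' @param cpgs_per_promoter promoter CpGs per chrX gene.
#' @param n_x_body chrX gene-body probes.
#' @param n_y chrY probes.
#' @param n_rs rs (SNP genotyping) probes.
#' @param n_xx,n_xy samples per karyotype.
#' @param n_mosaic number of 45,X/46,XX mosaic samples (replace XX samples).
#' @param mosaic_fraction 45,X cell fraction in mosaic samples.
#' @param fg_scale median foreground total intensity.
#' @param fg_sdlog lognormal sdlog of foreground intensity.
#' @param bg_mean per-channel background intensity mean.
#' @param bg_sdlog lognormal sdlog of background intensity.
#' @param beta_offset offset used when betas are computed from intensities.
#' @param beta_xa,beta_xi active/inactive-X promoter methylation levels.
#' @param escape_frac fraction of chrX genes escaping XCI.
#' @param bio_sd per-sample biological beta variation of variable probes.
#' @param variable_frac fraction of autosomal/chrX probes that vary.
#' @param y_constant_n number of chrY probes constant in XY samples;
#'   default 19% of `n_y` (79 of the default 416).
#' @param bad_probe_rate fraction of probes failing (background-only signal).
#' @param low_bead_rate fraction of probes with low mean bead count.
#' @param bead_lambda,low_bead_lambda Poisson means for bead counts.
#' @param snp_maf allele frequency of rs probes (HWE genotypes).
#' @param batches batch labels cycled over samples within sex.
#' @param batch_logfc_sd per-probe sd of log2 fold change applied to the
#'   methylated channel in non-reference batches (0 = no batch effect).
#' @param case_frac fraction of samples assigned the case phenotype.
#' @param seed mandatory integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_auto = 800, n_x_genes = 40, cpgs_per_promoter = 3,
                       n_x_body = 180, n_y = 416, n_rs = 65,
                       n_xx = 50, n_xy = 50, n_mosaic = 0,
                       mosaic_fraction = 0.5,
                       fg_scale = 10000, fg_sdlog = 0.15,
                       bg_mean = 500, bg_sdlog = 0.2,
                       beta_offset = 100,
                       beta_xa = 0.05, beta_xi = 0.85, escape_frac = 0.2,
                       bio_sd = 0.05, variable_frac = 0.7,
                       y_constant_n = NULL,
                       bad_probe_rate = 0.01,
                       low_bead_rate = 0.01, bead_lambda = 14,
                       low_bead_lambda = 2.5,
                       snp_maf = 0.5,
                       batches = c("batch1", "batch2"),
                       batch_logfc_sd = 0,
                       case_frac = 0.5,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(y_constant_n)) y_constant_n <- round(0.19 * n_y)
  cfg <- as.list(environment())
  stopifnot(n_auto > 0, n_x_genes > 0, n_x_body > 0, n_y > 0, n_rs >= 10,
            n_xx > 0, n_xy > 0, n_mosaic >= 0, n_mosaic <= n_xx,
            mosaic_fraction >= 0, mosaic_fraction <= 1,
            y_constant_n <= n_y, bad_probe_rate >= 0, bad_probe_rate <= 1,
            snp_maf > 0, snp_maf < 1, case_frac >= 0, case_frac <= 1)
  class(cfg) <- "sim_config"
  cfg
}

## chrX coordinate pools avoiding PAR1/PAR2 but allowing XTR by chance
X_BODY_RANGES <- rbind(c(2700000L, 88000000L), c(92500000L, 154900000L))

sim_manifest <- function(cfg) {
  n_prom <- cfg$n_x_genes * cfg$cpgs_per_promoter
  n_tot <- cfg$n_auto + n_prom + cfg$n_x_body + cfg$n_y + cfg$n_rs
  pid <- sprintf("cg%08d", seq_len(n_tot))

  auto_chr <- sample(paste0("chr", 1:22), cfg$n_auto, replace = TRUE)
  auto_pos <- sample.int(2e8, cfg$n_auto, replace = TRUE) + 1e6

  tss <- sort(sample.int(8e7, cfg$n_x_genes)) + 3e6
  prom_pos <- as.integer(rep(tss, each = cfg$cpgs_per_promoter) +
                           seq_len(cfg$cpgs_per_promoter) * 50L)
  gene <- sprintf("XGENE%03d", seq_len(cfg$n_x_genes))

  pick <- sample.int(2, cfg$n_x_body, replace = TRUE)
  body_pos <- X_BODY_RANGES[pick, 1] +
    vapply(X_BODY_RANGES[pick, 2] - X_BODY_RANGES[pick, 1],
           function(w) sample.int(w, 1L), integer(1))
  y_pos <- sample(2700000:28000000, cfg$n_y)
  rs_chr <- sample(paste0("chr", 1:22), cfg$n_rs, replace = TRUE)
  rs_pos <- sample.int(2e8, cfg$n_rs, replace = TRUE) + 1e6

  df <- data.frame(
    probe_id = pid,
    chrom = c(auto_chr, rep("chrX", n_prom + cfg$n_x_body),
              rep("chrY", cfg$n_y), rs_chr),
    pos = as.integer(c(auto_pos, prom_pos, body_pos, y_pos, rs_pos)),
    strand = sample(c("+", "-"), n_tot, replace = TRUE),
    probe_type = sample(c("InfiniumI_Red", "InfiniumI_Grn", "InfiniumII"),
                        n_tot, replace = TRUE, prob = c(0.15, 0.15, 0.7)),
    probe_class = c(rep("cg", n_tot - cfg$n_rs), rep("rs", cfg$n_rs)),
    gene = c(rep(NA, cfg$n_auto), rep(gene, each = cfg$cpgs_per_promoter),
             rep(NA, cfg$n_x_body + cfg$n_y + cfg$n_rs)),
    region = c(rep(NA, cfg$n_auto), rep("promoter", n_prom),
               rep("body", cfg$n_x_body), rep(NA, cfg$n_y + cfg$n_rs)),
    stringsAsFactors = FALSE
  )
  ## rs probe ids follow the platform convention
  df$probe_id[df$probe_class == "rs"] <- sprintf("rs%08d", seq_len(cfg$n_rs))
  df$group <- c(rep("auto", cfg$n_auto), rep("x_promoter", n_prom),
                rep("x_body", cfg$n_x_body), rep("y", cfg$n_y),
                rep("rs", cfg$n_rs))
  df
}

## bimodal-ish draw of per-probe mean methylation
draw_probe_means <- function(n) {
  kind <- sample.int(3, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  mu <- numeric(n)
  mu[kind == 1] <- runif(sum(kind == 1), 0.02, 0.15)
  mu[kind == 2] <- runif(sum(kind == 2), 0.80, 0.95)
  mu[kind == 3] <- runif(sum(kind == 3), 0.20, 0.80)
  mu
}

#' Simulate a methylation array cohort with ground truth
#'
#' @param cfg a [sim_config()].
#' @return list with elements `dataset` (a [methyl_dataset()] carrying
#'   signals, beta, detection p and bead counts), and `truth` (probe table,
#'   sample table, SNP genotype matrix, background parameters, spike
#'   registry, config).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  man <- sim_manifest(cfg)
  np <- nrow(man)
  n <- cfg$n_xx + cfg$n_xy
  sid <- sprintf("S%03d", seq_len(n))
  karyotype <- c(rep("XX", cfg$n_xx), rep("XY", cfg$n_xy))
  mosaic <- rep(FALSE, n)
  if (cfg$n_mosaic > 0) mosaic[seq_len(cfg$n_mosaic)] <- TRUE

  batch <- unlist(lapply(split(seq_len(n), karyotype), function(i)
    rep_len(cfg$batches, length(i))))[order(unlist(split(seq_len(n), karyotype)))]
  phenotype <- unlist(lapply(split(seq_len(n), karyotype), function(i) {
    k <- round(length(i) * cfg$case_frac)
    sample(c(rep("case", k), rep("control", length(i) - k)))
  }))[order(unlist(split(seq_len(n), karyotype)))]
  gest_age <- round(rnorm(n, 39.4, 1.1), 1)

  ## per-probe truth
  variable <- rbinom(np, 1, cfg$variable_frac) == 1
  mu <- draw_probe_means(np)
  is_y <- man$group == "y"
  ## chrY: exactly y_constant_n probes constant in XY
  y_idx <- which(is_y)
  variable[y_idx] <- TRUE
  const_y <- sample(y_idx, cfg$y_constant_n)
  variable[const_y] <- FALSE
  mu[is_y] <- runif(sum(is_y), 0.1, 0.9)

  ## XCI states for chrX promoter genes
  genes <- unique(na.omit(man$gene))
  n_esc <- round(length(genes) * cfg$escape_frac)
  xci_state <- setNames(c(rep("escape", n_esc),
                          rep("subject", length(genes) - n_esc)), genes)
  is_prom <- man$group == "x_promoter"
  prom_state <- xci_state[man$gene[is_prom]]
  variable[is_prom] <- FALSE   # promoter CpGs sit at their XCI-defined level

  ## mean beta by karyotype
  mu_xx <- mu
  mu_xy <- mu
  mu_xy[is_prom] <- cfg$beta_xa
  mu_xx[is_prom] <- ifelse(prom_state == "subject",
                           (cfg$beta_xa + cfg$beta_xi) / 2, cfg$beta_xa)
  ## chrY has no true methylation state in XX (background only)
  mu_xx[is_y] <- NA

  bad <- rbinom(np, 1, cfg$bad_probe_rate) == 1
  low_bead <- rbinom(np, 1, cfg$low_bead_rate) == 1

  ## rs genotypes: HWE with maf, shared beta clusters
  is_rs <- man$group == "rs"
  geno <- matrix(rbinom(cfg$n_rs * n, 2, cfg$snp_maf), nrow = cfg$n_rs,
                 dimnames = list(man$probe_id[is_rs], sid))

  ## true per-probe, per-sample beta
  beta_true <- matrix(NA_real_, np, n, dimnames = list(man$probe_id, sid))
  for (j in seq_len(n)) {
    m0 <- if (karyotype[j] == "XX") mu_xx else mu_xy
    b <- m0
    v <- variable & !is.na(m0)
    b[v] <- b[v] + rnorm(sum(v), 0, cfg$bio_sd)
    beta_true[, j] <- pmin(pmax(b, 0.001), 0.999)
  }
  gmeans <- c(`0` = 0.03, `1` = 0.5, `2` = 0.97)
  gsd <- c(`0` = 0.015, `1` = 0.03, `2` = 0.015)
  g <- geno + 1
  beta_true[is_rs, ] <- pmin(pmax(
    gmeans[g] + rnorm(length(geno), 0, gsd[g]), 0.001), 0.999)

  ## copy-number scale of the foreground: chrX halved in XY; chrY absent in
  ## XX (background only); mosaics lose a fraction of one X
  dose <- matrix(1, np, n)
  is_x <- man$chrom == "chrX"
  dose[is_x, karyotype == "XY"] <- 0.5
  if (any(mosaic))
    dose[is_x, mosaic] <- 1 - cfg$mosaic_fraction / 2
  present <- matrix(TRUE, np, n)
  present[is_y, karyotype == "XX"] <- FALSE
  present[bad, ] <- FALSE

  fg <- matrix(rlnorm(np * n, log(cfg$fg_scale), cfg$fg_sdlog), np, n) * dose
  fg[!present] <- 0
  bgM <- matrix(rlnorm(np * n, log(cfg$bg_mean), cfg$bg_sdlog), np, n)
  bgU <- matrix(rlnorm(np * n, log(cfg$bg_mean), cfg$bg_sdlog), np, n)
  b0 <- beta_true
  b0[is.na(b0)] <- 0.5   # unused when absent; keeps arithmetic defined
  meth <- b0 * fg + bgM
  unmeth <- (1 - b0) * fg + bgU
  dimnames(meth) <- dimnames(unmeth) <- dimnames(beta_true)

  ## batch effect on the methylated channel (log2 scale), reference batch 1
  if (cfg$batch_logfc_sd > 0 && length(cfg$batches) > 1) {
    for (b in cfg$batches[-1]) {
      gam <- rnorm(np, 0, cfg$batch_logfc_sd)
      cols <- batch == b
      meth[, cols] <- meth[, cols] * 2^gam
    }
  }

  negctrl <- data.frame(sample_id = sid,
                        mu_bg = 2 * cfg$bg_mean * exp(cfg$bg_sdlog^2 / 2),
                        sd_bg = sqrt(2 * (exp(cfg$bg_sdlog^2) - 1) *
                                       (cfg$bg_mean * exp(cfg$bg_sdlog^2 / 2))^2))
  beta <- compute_beta(meth, unmeth, cfg$beta_offset)
  detp <- compute_detection_p(meth, unmeth, negctrl)
  lam <- ifelse(low_bead, cfg$low_bead_lambda, cfg$bead_lambda)
  beads <- matrix(rpois(np * n, rep(lam, n)), np, n,
                  dimnames = dimnames(beta_true))

  samples <- data.frame(sample_id = sid, annotated_sex = karyotype,
                        batch = batch, phenotype = phenotype,
                        gest_age = gest_age, stringsAsFactors = FALSE)
  manifest <- man[, c("probe_id", "chrom", "pos", "strand", "probe_type",
                      "probe_class", "gene", "region")]
  ds <- methyl_dataset(manifest, samples, beta = beta,
                       signals = list(meth = meth, unmeth = unmeth),
                       detp = detp, beads = beads)

  xci_full <- rep(NA_character_, np)
  xci_full[is_prom] <- prom_state
  probe_truth <- data.frame(
    probe_id = man$probe_id, chrom = man$chrom, group = man$group,
    gene = man$gene,
    xci_state = xci_full,
    variable = variable, bad = bad, low_bead = low_bead,
    constant_in_xy = seq_len(np) %in% const_y,
    mu_xx = mu_xx, mu_xy = mu_xy, stringsAsFactors = FALSE)
  sample_truth <- data.frame(
    sample_id = sid, karyotype = karyotype, mosaic = mosaic,
    batch = batch, phenotype = phenotype, gest_age = gest_age,
    contam_frac = 0, stringsAsFactors = FALSE)

  list(dataset = ds,
       truth = list(probes = probe_truth, samples = sample_truth,
                    genotypes = geno, negctrl = negctrl,
                    promoter_map = split(man$probe_id[is_prom],
                                         man$gene[is_prom]),
                    spikes = NULL, config = cfg))
}

#' Mix intensities of sample pairs to emulate contamination
#'
#' Both channels of each target sample are replaced by the convex combination
#' `(1-f) * target + f * donor`; betas and detection p-values are recomputed
#' so rs-probe betas of mixed samples shift toward intermediate values.
#'
#' @param sim result of [simulate_cohort()].
#' @param pairs data.frame with columns `target`, `donor`, `fraction`
#'   (0 < f <= 0.5).
#' @return mutated copy of `sim` with updated truth.
#' @export
inject_contamination <- function(sim, pairs) {
  stopifnot(all(c("target", "donor", "fraction") %in% names(pairs)))
  ds <- sim$dataset
  if (any(pairs$target == pairs$donor))
    stop("target and donor must differ")
  if (any(pairs$fraction <= 0 | pairs$fraction > 0.5))
    stop("contamination fraction must be in (0, 0.5]")
  sid <- colnames(ds$signals$meth)
  bad <- setdiff(c(pairs$target, pairs$donor), sid)
  if (length(bad)) stop("unknown samples: ", paste(bad, collapse = ", "))
  meth <- ds$signals$meth
  unmeth <- ds$signals$unmeth
  for (i in seq_len(nrow(pairs))) {
    tg <- pairs$target[i]; dn <- pairs$donor[i]; f <- pairs$fraction[i]
    meth[, tg] <- (1 - f) * ds$signals$meth[, tg] + f * ds$signals$meth[, dn]
    unmeth[, tg] <- (1 - f) * ds$signals$unmeth[, tg] + f * ds$signals$unmeth[, dn]
  }
  cfg <- sim$truth$config
  beta <- compute_beta(meth, unmeth, cfg$beta_offset)
  detp <- compute_detection_p(meth, unmeth, sim$truth$negctrl)
  sim$dataset <- methyl_dataset(ds$manifest, ds$samples, beta = beta,
                                signals = list(meth = meth, unmeth = unmeth),
                                detp = detp, beads = ds$beads)
  idx <- match(pairs$target, sim$truth$samples$sample_id)
  sim$truth$samples$contam_frac[idx] <- pairs$fraction
  sim
}

#' Spike differential-methylation effects into a simulated cohort
#'
#' Case-group betas of the listed probes are shifted by `delta_beta` within
#' the given stratum. Intensities are rewritten so that recomputing beta from
#' the channels reproduces the spiked value exactly (total intensity held
#' fixed); shifts that would leave `[0,1]` are clipped and the registry
#' records the effective shift.
#'
#' @param sim result of [simulate_cohort()].
#' @param spec data.frame with columns `probe_id`, `stratum` (`XX`/`XY`),
#'   `delta_beta`; the case group is `phenotype == "case"`.
#' @return mutated copy of `sim` with updated spike registry.
#' @export
spike_effects <- function(sim, spec) {
  stopifnot(all(c("probe_id", "stratum", "delta_beta") %in% names(spec)))
  if (anyDuplicated(spec[c("probe_id", "stratum")]))
    stop("overlapping spikes on one probe")
  if (any(abs(spec$delta_beta) > 1)) stop("|delta_beta| must be <= 1")
  ds <- sim$dataset
  bad <- setdiff(spec$probe_id, ds$manifest$probe_id)
  if (length(bad)) stop("unknown probes: ", paste(bad, collapse = ", "))
  cfg <- sim$truth$config
  meth <- ds$signals$meth
  unmeth <- ds$signals$unmeth
  st <- sim$truth$samples
  spec$effective_delta <- spec$delta_beta
  for (i in seq_len(nrow(spec))) {
    p <- spec$probe_id[i]
    cols <- st$sample_id[st$karyotype == spec$stratum[i] &
                           st$phenotype == "case"]
    if (!length(cols)) next
    tot <- meth[p, cols] + unmeth[p, cols]
    denom <- tot + cfg$beta_offset
    b_old <- meth[p, cols] / denom
    b_max <- tot / denom
    b_new <- pmin(pmax(b_old + spec$delta_beta[i], 0), b_max)
    spec$effective_delta[i] <- mean(b_new - b_old)
    meth[p, cols] <- b_new * denom
    unmeth[p, cols] <- tot - meth[p, cols]
  }
  beta <- compute_beta(meth, unmeth, cfg$beta_offset)
  detp <- compute_detection_p(meth, unmeth, sim$truth$negctrl)
  sim$dataset <- methyl_dataset(ds$manifest, ds$samples, beta = beta,
                                signals = list(meth = meth, unmeth = unmeth),
                                detp = detp, beads = ds$beads)
  sim$truth$spikes <- rbind(sim$truth$spikes, spec)
  sim
}
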