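sim_small <- function(seed, ...) {
  simulate_cohort(sim_config(seed = seed, n_auto = 200, n_x_genes = 10,
                             n_x_body = 40, n_y = 80, n_xx = 15, n_xy = 15, ...))
}

test_that("normalized intensities reflect chromosome dosage", {
  sim <- sim_small(1)
  intens <- normalized_sex_intensities(sim$dataset)
  kt <- sim$truth$samples$karyotype
  # XX: nX ~ 1, nY ~ background fraction (~0.1); XY: halved X, full Y
  expect_true(all(abs(intens$nX[kt == "XX"] - 1) < 0.1))
  expect_true(all(intens$nY[kt == "XX"] < 0.2))
  expect_true(all(intens$nY[kt == "XX"] > 0.03))
  expect_true(all(intens$nX[kt == "XY"] < 0.65))
  expect_true(all(intens$nY[kt == "XY"] > 0.6))
  # trivial ratio check: identical medians give 1 by construction
  ds <- sim$dataset
  ds$signals$meth[] <- 100; ds$signals$unmeth[] <- 100
  i2 <- normalized_sex_intensities(ds)
  expect_equal(i2$nX, rep(1, nrow(i2)))
  # no chrY in manifest is a configuration error
  keep <- ds$manifest$chrom != "chrY"
  ds2 <- methyl_dataset(ds$manifest[keep, ], ds$samples,
                        signals = list(meth = ds$signals$meth[keep, ],
                                       unmeth = ds$signals$unmeth[keep, ]),
                        beta = ds$beta[keep, ])
  expect_error(normalized_sex_intensities(ds2), "chrY")
})

test_that("sex inference recovers karyotype and never silently assigns", {
  pts <- data.frame(sample_id = c("a", "b", "c"),
                    nX = c(1.0, 0.55, 0.75), nY = c(0.1, 0.9, 0.08))
  calls <- infer_sex(pts)
  expect_equal(calls$inferred, c("XX", "XY", "anomaly"))
  expect_match(calls$anomaly_note[3], "mosaic")
  expect_error(infer_sex(data.frame(sample_id = "a", nX = NaN, nY = 0.1)),
               "non-finite")
  # mosaic simulated sample lands in the anomaly region
  sim <- sim_small(5, n_mosaic = 2, mosaic_fraction = 0.5)
  calls <- infer_sex(normalized_sex_intensities(sim$dataset))
  mos <- sim$truth$samples$mosaic
  expect_true(all(calls$inferred[mos] == "anomaly"))
  expect_equal(calls$inferred[!mos],
               sim$truth$samples$karyotype[!mos])
})

test_that("sex inference is 100% correct on non-mosaic samples across seeds", {
  for (seed in 1:5) {
    sim <- sim_small(seed)
    calls <- infer_sex(normalized_sex_intensities(sim$dataset))
    expect_equal(calls$inferred, sim$truth$samples$karyotype,
                 label = paste("seed", seed))
  }
})

test_that("genotype EM is monotone, fits clean trimodal data, scores mixtures", {
  set.seed(10)
  n_snp <- 40; n_s <- 30
  g <- matrix(rbinom(n_snp * n_s, 2, 0.5), n_snp,
              dimnames = list(sprintf("rs%02d", 1:n_snp), sprintf("s%02d", 1:n_s)))
  mu <- c(0.02, 0.5, 0.98)[g + 1]
  betas <- matrix(pmin(pmax(mu + rnorm(length(g), 0, 0.02), 0.001), 0.999),
                  n_snp, dimnames = dimnames(g))
  fit <- call_genotypes(betas)
  expect_true(!is.unsorted(fit$model$loglik))          # EM monotonicity
  expect_true(all(fit$qc$snp_outliers < -4))           # clean cohort
  expect_false(any(fit$qc$contaminated))
  # posterior arithmetic spot-check by brute-force density evaluation
  w <- fit$model$weights; sh <- fit$model$shapes
  x <- betas[1, 1]
  dens <- c(dbeta(x, sh$AA[1], sh$AA[2]), dbeta(x, sh$AB[1], sh$AB[2]),
            dbeta(x, sh$BB[1], sh$BB[2]), 1)
  expect_equal(fit$posterior_outlier[1, 1],
               (w[4] * dens[4]) / sum(w * dens), tolerance = 1e-8,
               ignore_attr = TRUE)
  # hard calls match simulated genotypes where called
  called <- !is.na(fit$genotypes)
  expect_gt(mean(called), 0.9)
  expect_equal(fit$genotypes[called],
               c("AA", "AB", "BB")[g + 1][called])
  # a 50:50 mixture of two discordant donors scores as contaminated
  mixed <- cbind(betas, mix = 0.5 * betas[, 1] + 0.5 * betas[, 2])
  fit2 <- call_genotypes(mixed)
  expect_gt(fit2$qc$snp_outliers[n_s + 1], -4)
  expect_true(fit2$qc$contaminated[n_s + 1])
})

test_that("snp_outliers increases with contamination fraction", {
  sim <- sim_small(21)
  scores <- sapply(c(0.1, 0.25, 0.5), function(f) {
    s2 <- inject_contamination(sim, data.frame(target = "S001",
                                               donor = "S020", fraction = f))
    rs <- grep("^rs", rownames(s2$dataset$beta), value = TRUE)
    fit <- call_genotypes(s2$dataset$beta[rs, ])
    fit$qc$snp_outliers[fit$qc$sample_id == "S001"]
  })
  expect_true(all(diff(scores) > 0))
})

test_that("outlier weight of zero gives -Inf scores", {
  set.seed(2)
  betas <- matrix(runif(20 * 12), 20,
                  dimnames = list(paste0("rs", 1:20), paste0("s", 1:12)))
  expect_warning(fit <- call_genotypes(betas, max_iter = 1), "did not converge")
  p0 <- fit$posterior_outlier
  p0[] <- 0
  lo <- log(p0) - log1p(-p0)
  expect_true(all(colMeans(lo) == -Inf))
})

test_that("duplicate detection is symmetric-safe and spares unrelated donors", {
  set.seed(33)
  g <- matrix(sample(c("AA", "AB", "BB"), 65 * 10, TRUE,
                     prob = c(0.25, 0.5, 0.25)), 65,
              dimnames = list(sprintf("rs%02d", 1:65), sprintf("s%02d", 1:10)))
  g <- cbind(g, dup = g[, 1])                          # an exact duplicate
  dup <- detect_duplicates(g)
  expect_equal(nrow(dup), 1)
  expect_setequal(unlist(dup[1, c("sample1", "sample2")]), c("s01", "dup"))
  expect_equal(dup$agreement, 1)
  # expected unrelated agreement under HWE at maf 0.5 is 0.375; far below 0.9
  pair_agr <- mean(g[, 1] == g[, 2])
  expect_lt(pair_agr, 0.7)
  # fully-missing vectors are excluded, and no self-pairs ever
  g2 <- g; g2[, 2] <- NA
  dup2 <- detect_duplicates(g2)
  expect_false(any(dup2$sample1 == dup2$sample2))
  expect_false("s02" %in% c(dup2$sample1, dup2$sample2))
})

test_that("sex concordance reporting distinguishes mismatch/imputed/anomaly", {
  sheet <- sample_sheet(data.frame(
    sample_id = c("a", "b", "c", "d"),
    annotated_sex = c("XX", "XX", "unknown", "XY"),
    batch = "b1"))
  calls <- data.frame(sample_id = c("a", "b", "c", "d"),
                      nX = 1, nY = 0.1,
                      inferred = c("XX", "XY", "XX", "anomaly"),
                      anomaly_note = c(NA, NA, NA, "note"))
  conc <- check_sex_concordance(calls, sheet)
  expect_equal(conc$status, c("concordant", "mismatch", "imputed", "anomaly"))
})
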