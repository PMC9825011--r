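mk_detp <- function(vals, chrom) {
  n <- length(chrom)
  m <- matrix(vals, n, byrow = TRUE,
              dimnames = list(sprintf("cg%03d", seq_len(n)),
                              sprintf("s%03d", seq_len(length(vals) / n))))
  m
}

test_that("detection-p exceedance uses a strict threshold boundary", {
  chrom <- rep("chr1", 2)
  detp <- matrix(0.001, 2, 100,
                 dimnames = list(c("cg001", "cg002"), sprintf("s%03d", 1:100)))
  detp[1, 1] <- 0.02            # exactly 1% of samples
  detp[2, 1:2] <- 0.02          # 2% of samples
  sexes <- rep(c("XX", "XY"), 50)
  fl <- flag_detection_failures(detp, chrom, sexes, filter_config())
  expect_false(fl$flagged[1])   # 0.01 is NOT > 0.01
  expect_true(fl$flagged[2])
})

test_that("chrY detection flags depend on stratification exactly as expected", {
  chrom <- c("chrY", "chr1")
  detp <- matrix(0.001, 2, 100,
                 dimnames = list(c("cgY", "cgA"), sprintf("s%03d", 1:100)))
  sexes <- rep(c("XX", "XY"), each = 50)
  detp["cgY", sexes == "XX"] <- 0.5   # fails in every XX, clean in every XY
  mixed <- flag_detection_failures(detp, chrom, sexes,
                                   filter_config(stratify_detp_chrY = FALSE))
  strat <- flag_detection_failures(detp, chrom, sexes, filter_config())
  expect_true(mixed$flagged[1])       # 50% > 1%
  expect_false(strat$flagged[1])      # 0% in XY
  expect_equal(strat$stratum[1], "XY")
  # autosome/chrX flags identical across modes (only chrY may differ)
  sim <- simulate_cohort(sim_config(seed = 8, n_auto = 150, n_x_genes = 8,
                                    n_x_body = 30, n_y = 40, n_xx = 12, n_xy = 12))
  ds <- sim$dataset; kt <- sim$truth$samples$karyotype
  a <- flag_detection_failures(ds$detp, ds$manifest$chrom, kt, filter_config())
  b <- flag_detection_failures(ds$detp, ds$manifest$chrom, kt,
                               filter_config(stratify_detp_chrY = FALSE))
  nonY <- chrom_group(ds$manifest$chrom) != "chrY"
  expect_identical(a$flagged[nonY], b$flagged[nonY])
  # stratified mode with no XY samples must error
  expect_error(flag_detection_failures(detp, chrom, rep("XX", 100),
                                       filter_config()),
               "no XY samples")
})

test_that("bead-count flags are never stratified and treat NA as failing", {
  beads <- matrix(10L, 3, 100,
                  dimnames = list(c("a", "b", "c"), sprintf("s%03d", 1:100)))
  beads["b", 1:2] <- 2L           # 2% below bead_min
  beads["c", 1] <- NA             # 1% -> not > 1%
  fl <- flag_low_beadcount(beads, filter_config())
  expect_equal(fl$flagged, c(FALSE, TRUE, FALSE))
  beads["c", 2] <- NA
  expect_true(flag_low_beadcount(beads, filter_config())$flagged[3])
})

test_that("non-variability uses the centile range within the right stratum", {
  n_s <- 40
  sexes <- rep(c("XX", "XY"), each = n_s / 2)
  set.seed(4)
  beta <- rbind(
    const = rep(0.3, n_s),
    spread = rep(seq(0.15, 0.35, length.out = 10), 4),  # q10-q90 range 0.10
    ychr = c(runif(n_s / 2, 0.35, 0.65), rep(0.2, n_s / 2))
  )
  colnames(beta) <- sprintf("s%02d", 1:n_s)
  chrom <- c("chr1", "chr2", "chrY")
  fl <- flag_nonvariable(beta, chrom, sexes, filter_config())
  expect_true(fl$nonvariable[1])
  expect_false(fl$nonvariable[2])
  # chrY probe: constant in XY, noisy in XX
  expect_true(fl$nonvariable[3])
  mixed <- flag_nonvariable(beta, chrom, sexes,
                            filter_config(stratify_nonvar_chrY = FALSE))
  expect_false(mixed$nonvariable[3])
  # external list: final flag requires membership in BOTH sets
  both <- flag_nonvariable(beta, chrom, sexes,
                           filter_config(external_nonvariable_list = "spread"))
  expect_false(any(both$flagged))
  both2 <- flag_nonvariable(beta, chrom, sexes,
                            filter_config(external_nonvariable_list = c("const")))
  expect_equal(both2$flagged, c(TRUE, FALSE, FALSE))
  expect_error(flag_nonvariable(beta[, 1:5], chrom, sexes[1:5],
                                filter_config()), "fewer than")
})

test_that("apply_filters removes flagged and rs probes, leaves input untouched", {
  sim <- simulate_cohort(sim_config(seed = 12, n_auto = 100, n_x_genes = 6,
                                    n_x_body = 20, n_y = 30, n_xx = 12, n_xy = 12))
  ds <- sim$dataset
  rep_ <- build_filter_report(ds, sexes = sim$truth$samples$karyotype)
  n_before <- nrow(ds$manifest)
  out <- apply_filters(ds, rep_, drop_rs = TRUE)
  n_removed <- sum(rep_$flags$remove |
                     rep_$flags$probe_class == "rs")
  expect_equal(nrow(out$dataset$manifest), n_before - n_removed)
  expect_false(any(out$dataset$manifest$probe_class == "rs"))
  expect_equal(nrow(ds$manifest), n_before)   # original untouched
  # zero flags + keep rs = identity
  rep0 <- rep_
  rep0$flags$remove <- FALSE
  out0 <- apply_filters(ds, rep0, drop_rs = FALSE)
  expect_identical(dim(out0$dataset), dim(ds))
  # exclusion lists produce reason codes
  victims <- ds$manifest$probe_id[1:3]
  cfg <- filter_config(exclusion_lists = list(nonspecific = victims))
  rep2 <- build_filter_report(ds, sexes = sim$truth$samples$karyotype, cfg = cfg)
  got <- rep2$flags[rep2$flags$probe_id %in% victims, ]
  expect_true(all(grepl("exclusion:nonspecific", got$reason)))
  expect_true(all(got$remove))
})

test_that("filter report counts equal column sums per context", {
  sim <- simulate_cohort(sim_config(seed = 13, n_auto = 120, n_x_genes = 6,
                                    n_x_body = 20, n_y = 40, n_xx = 12, n_xy = 12))
  rep_ <- build_filter_report(sim$dataset, sexes = sim$truth$samples$karyotype)
  fl <- rep_$flags[rep_$flags$probe_class %in% c("cg", "ch"), ]
  for (ctx in colnames(rep_$counts)) {
    expect_equal(rep_$counts["detp", ctx], sum(fl$detp[fl$context == ctx]))
    expect_equal(rep_$counts["remove", ctx], sum(fl$remove[fl$context == ctx]))
  }
  # serialization writes both artifacts
  dir <- withr::local_tempdir()
  paths <- write_filter_report(rep_, file.path(dir, "fr"))
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[2])
  expect_equal(js$remove$chrY, unname(rep_$counts["remove", "chrY"]))
})
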