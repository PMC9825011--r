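test_that("built-in PAR/XTR coordinates behave at boundaries", {
  man <- probe_manifest(data.frame(
    probe_id = c("inXTR", "parEdge", "inPAR1"),
    chrom = "chrX", pos = c(90000000L, 60000L, 60001L),
    strand = "+", probe_type = "InfiniumII", probe_class = "cg"))
  hits <- overlap_regions(man, par_xtr_regions(), mode = "cpg_position")
  expect_true(any(hits$probe_id == "inXTR" & hits$name == "XTR"))
  expect_false("parEdge" %in% hits$probe_id)     # one base short of PAR1
  expect_true(any(hits$probe_id == "inPAR1" & hits$name == "PAR1"))
})

test_that("overlap matches a brute-force per-base oracle on random instances", {
  set.seed(99)
  for (rep_i in 1:10) {
    n_p <- 200; n_r <- 30
    chrom_q <- sample(c("chrX", "chrY"), n_p, TRUE)
    man <- probe_manifest(data.frame(
      probe_id = sprintf("cg%03d", 1:n_p), chrom = chrom_q,
      pos = sample.int(1e6, n_p), strand = "+",
      probe_type = "InfiniumII", probe_class = "cg"))
    st <- sample.int(1e6, n_r)
    regions <- data.frame(chrom = sample(c("chrX", "chrY"), n_r, TRUE),
                          start = st, end = st + sample.int(5e4, n_r))
    hits <- overlap_regions(man, regions, mode = "cpg_position")
    got <- man$probe_id %in% hits$probe_id
    want <- oracle_overlap(man$pos, regions$start, regions$end,
                           man$chrom, regions$chrom)
    expect_identical(got, want)
  }
})

test_that("footprint construction follows probe chemistry and strand", {
  man <- probe_manifest(data.frame(
    probe_id = c("t2plus", "t1plus", "t2minus", "t1minus"),
    chrom = "chrX", pos = 1000L,
    strand = c("+", "+", "-", "-"),
    probe_type = c("InfiniumII", "InfiniumI_Red", "InfiniumII", "InfiniumI_Grn"),
    probe_class = "cg"))
  fp <- build_footprints(man)
  expect_equal(fp$fp_start, c(951L, 952L, 1000L, 999L))
  expect_equal(fp$fp_end, c(1000L, 1001L, 1049L, 1048L))
  expect_equal(fp$zone_start, c(996L, 997L, 1000L, 999L))
  expect_equal(fp$zone_end, c(1000L, 1001L, 1004L, 1003L))
  expect_true(all(fp$fp_end - fp$fp_start + 1L == 50L))
  expect_true(all(fp$zone_end - fp$zone_start + 1L == 5L))
})

test_that("polymorphic flags respect the 3' critical zone", {
  man <- probe_manifest(data.frame(
    probe_id = "p1", chrom = "chrY", pos = 1000L, strand = "+",
    probe_type = "InfiniumII", probe_class = "cg"))
  fp <- build_footprints(man)   # footprint [951,1000], zone [996,1000]
  check <- function(snp_pos) flag_polymorphic(
    fp, data.frame(chrom = "chrY", pos = snp_pos))
  terminal <- check(1000L)
  expect_true(terminal$polymorphic & terminal$polymorphic_critical)
  inside <- check(980L)         # 20 bases from the 3' end
  expect_true(inside$polymorphic)
  expect_false(inside$polymorphic_critical)
  outside <- check(1010L)
  expect_false(outside$polymorphic | outside$polymorphic_critical)
  # critical implies polymorphic on random instances
  set.seed(7)
  man2 <- probe_manifest(data.frame(
    probe_id = sprintf("p%03d", 1:100), chrom = "chrY",
    pos = sample.int(1e5, 100) + 100L,
    strand = sample(c("+", "-"), 100, TRUE),
    probe_type = sample(c("InfiniumII", "InfiniumI_Red"), 100, TRUE),
    probe_class = "cg"))
  snps <- data.frame(chrom = "chrY", pos = sample.int(1e5, 300) + 100L,
                     maf = runif(300))
  pm <- flag_polymorphic(build_footprints(man2), snps)
  expect_true(all(!pm$polymorphic_critical | pm$polymorphic))
  # MAF filter can only shrink the flagged set
  pm2 <- flag_polymorphic(build_footprints(man2), snps, maf_min = 0.5)
  expect_true(all(!pm2$polymorphic | pm$polymorphic))
  expect_lte(sum(pm2$polymorphic), sum(pm$polymorphic))
})

test_that("annotate_xy assembles flags with provenance and is order-independent", {
  man <- probe_manifest(data.frame(
    probe_id = c("ctprom", "plain", "both", "auto1"),
    chrom = c("chrX", "chrX", "chrX", "chr1"),
    pos = c(5000L, 3000000L, 90000000L, 1000L),
    strand = "+", probe_type = "InfiniumII", probe_class = "cg"))
  res <- list(
    ct_genes = data.frame(chrom = "chrX", start = 6000L, end = 9000L,
                          strand = "+", gene = "MAGEA_TOY"),
    repeats = data.frame(chrom = "chrX", start = 89999000L, end = 90001000L,
                         class = "LINE", family = "L1"),
    snps = data.frame(chrom = "chrX", pos = 4999L))
  ann <- annotate_xy(man, res)
  expect_equal(nrow(ann), 3)                       # chrX/chrY probes only
  row <- ann[ann$probe_id == "ctprom", ]
  expect_true(row$ct_promoter)                     # 5000 in [4500, 6500]
  expect_equal(row$ct_gene, "MAGEA_TOY")
  expect_true(row$polymorphic)
  b <- ann[ann$probe_id == "both", ]
  expect_true(b$in_XTR && b$repeat_overlap)        # flags are independent
  expect_equal(b$repeat_class, "LINE")
  p <- ann[ann$probe_id == "plain", ]
  expect_false(any(unlist(p[c("in_PAR1", "in_PAR2", "in_XTR", "ct_promoter",
                              "repeat_overlap", "polymorphic")])))
  expect_false(any(ann$in_PAR1 & ann$in_PAR2))
  # idempotent and row-order independent
  man2 <- man[c(3, 1, 4, 2), ]; class(man2) <- class(man)
  ann2 <- annotate_xy(man2, res)
  ann2 <- ann2[match(ann$probe_id, ann2$probe_id), ]
  rownames(ann2) <- NULL
  expect_equal(ann, ann2)
  # missing resources produce NA columns with a warning
  expect_warning(ann3 <- annotate_xy(man, res[c("ct_genes", "snps")]),
                 "repeats")
  expect_true(all(is.na(ann3$repeat_overlap)))
})

test_that("promoter windows follow gene strand", {
  man <- probe_manifest(data.frame(
    probe_id = c("upminus", "downminus"),
    chrom = "chrX", pos = c(10400L, 8600L),
    strand = "+", probe_type = "InfiniumII", probe_class = "cg"))
  ## minus-strand gene with TSS at end = 10000: window [9500, 11500]
  res <- list(ct_genes = data.frame(chrom = "chrX", start = 9000L,
                                    end = 10000L, strand = "-",
                                    gene = "G1"))
  ann <- suppressWarnings(annotate_xy(man, res))
  expect_true(ann$ct_promoter[ann$probe_id == "upminus"])
  expect_false(ann$ct_promoter[ann$probe_id == "downminus"])
})
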