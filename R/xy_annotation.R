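## Annotation of X/Y probes against regions that confound sex-chromosome
## analyses: pseudoautosomal regions (PAR1/PAR2), the X-transposed region
## (XTR), cancer-testis gene promoters, repeat elements, and SNPs within
## the probe footprint (with the critical 3' last-5-bp zone).
##
## All coordinates are 1-based inclusive hg19 (UCSC-style printed ranges);
## BED input (0-based half-open) is converted on read.

#' Built-in PAR and XTR regions (hg19)
#'
#' The pseudoautosomal regions and the X-transposed region on both sex
#' chromosomes. PAR1/PAR2 carry X/Y-shared sequence; the XTR is X sequence
#' duplicated onto the Y with ~99% identity and is prone to
#' cross-hybridization.
#'
#' @return data.frame `name`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
par_xtr_regions <- function() {
  data.frame(
    name  = c("PAR1", "PAR2", "XTR", "PAR1", "PAR2", "XTR"),
    chrom = c("chrX", "chrX", "chrX", "chrY", "chrY", "chrY"),
    start = c(60001, 154931044, 88400000, 10001, 59034050, 3440000),
    end   = c(2699520, 155260560, 92000000, 2649520, 59363566, 5750000),
    stringsAsFactors = FALSE)
}

#' Construct a genomic region set
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional label
#'   columns (`name`, `gene`, `class`, `family`, `strand`, `maf`).
#' @param name label for the set.
#' @param convention `"onebased"` (1-based inclusive, default) or `"bed"`
#'   (0-based half-open; converted on read).
#' @return data.frame of class `region_set` in 1-based inclusive coordinates.
#' @export
region_set <- function(df, name = "regions",
                       convention = c("onebased", "bed")) {
  convention <- match.arg(convention)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (convention == "bed") {
    df$start <- df$start + 1L
    message("region set '", name, "': converted BED coordinates to 1-based inclusive")
  }
  if (any(df$start > df$end)) stop("region start > end")
  attr(df, "set_name") <- name
  class(df) <- c("region_set", "data.frame")
  df
}

as_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

#' Overlap probes with a region set
#'
#' `cpg_position` mode tests containment of the interrogated CpG
#' coordinate; `footprint` mode tests intersection of the 50-base probe
#' footprint with each region. Deterministic and order-independent.
#'
#' @param manifest [probe_manifest()].
#' @param regions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optional label columns.
#' @param mode `"cpg_position"` (default) or `"footprint"`.
#' @return data.frame of hit pairs: `probe_id`, `region_index`, plus any
#'   region label columns.
#' @export
overlap_regions <- function(manifest, regions,
                            mode = c("cpg_position", "footprint")) {
  mode <- match.arg(mode)
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  unknown <- !regions$chrom %in% CHROMS
  if (any(unknown)) {
    warning(sum(unknown), " region record(s) on unknown chromosomes skipped")
    regions <- regions[!unknown, , drop = FALSE]
  }
  if (mode == "cpg_position") {
    q <- as_granges(manifest$chrom, manifest$pos, manifest$pos)
  } else {
    fp <- build_footprints(manifest)
    q <- as_granges(fp$chrom, fp$fp_start, fp$fp_end)
  }
  s <- as_granges(regions$chrom, regions$start, regions$end)
  ov <- GenomicRanges::findOverlaps(q, s)
  hits <- data.frame(probe_id = manifest$probe_id[S4Vectors::queryHits(ov)],
                     region_index = S4Vectors::subjectHits(ov),
                     stringsAsFactors = FALSE)
  lab <- setdiff(names(regions), c("chrom", "start", "end"))
  for (cc in lab) hits[[cc]] <- regions[[cc]][hits$region_index]
  hits
}

#' Probe footprints and 3' critical zones from manifest fields
#'
#' Approximates the 50-base genomic footprint of each probe from its CpG
#' position, strand and Infinium design: a type II probe's 3' end sits at
#' the interrogated cytosine; a type I probe's 3' end sits at the adjacent
#' base (the single-base-extension site). The `three_prime_zone` is the 5
#' footprint positions nearest the 3' end — the zone where underlying SNPs
#' interfere most with hybridization. True probe alignments can be
#' substituted via a user-supplied footprint table wherever one is
#' accepted.
#'
#' @param manifest [probe_manifest()].
#' @return data.frame `probe_id`, `chrom`, `fp_start`, `fp_end`,
#'   `zone_start`, `zone_end` (all 1-based inclusive; footprint length 50,
#'   zone length 5).
#' @export
build_footprints <- function(manifest) {
  if (any(is.na(manifest$strand))) stop("manifest strand is required")
  pos <- manifest$pos
  typeI <- manifest$probe_type %in% c("InfiniumI_Red", "InfiniumI_Grn")
  plus <- manifest$strand == "+"
  ## 3' terminal coordinate of the footprint
  end3 <- ifelse(plus, ifelse(typeI, pos + 1L, pos),
                       ifelse(typeI, pos - 1L, pos))
  fp_start <- ifelse(plus, end3 - 49L, end3)
  fp_end <- ifelse(plus, end3, end3 + 49L)
  zone_start <- ifelse(plus, end3 - 4L, end3)
  zone_end <- ifelse(plus, end3, end3 + 4L)
  data.frame(probe_id = manifest$probe_id, chrom = manifest$chrom,
             strand = manifest$strand,
             fp_start = as.integer(fp_start), fp_end = as.integer(fp_end),
             zone_start = as.integer(zone_start),
             zone_end = as.integer(zone_end),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag probes whose footprint contains a SNP
#'
#' `polymorphic` marks any SNP inside the 50-base footprint;
#' `polymorphic_critical` marks SNPs inside the 3' last-5-bp zone, the
#' region most sensitive to interference by sequence polymorphisms. An
#' optional minor-allele-frequency filter restricts to common SNPs.
#'
#' @param footprints result of [build_footprints()].
#' @param snps data.frame of single positions: `chrom`, `pos` (1-based),
#'   optional `maf`.
#' @param maf_min optional minimum minor allele frequency (e.g. 0.01);
#'   records without `maf` pass the filter.
#' @return data.frame `probe_id`, `polymorphic`, `polymorphic_critical`,
#'   `n_snps_footprint`, `n_snps_zone`.
#' @export
flag_polymorphic <- function(footprints, snps, maf_min = NULL) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos") %in% names(snps)))
  if (!is.null(maf_min) && "maf" %in% names(snps))
    snps <- snps[is.na(snps$maf) | snps$maf >= maf_min, , drop = FALSE]
  s <- as_granges(snps$chrom, snps$pos, snps$pos)
  fp <- as_granges(footprints$chrom, footprints$fp_start, footprints$fp_end)
  zn <- as_granges(footprints$chrom, footprints$zone_start, footprints$zone_end)
  n_fp <- GenomicRanges::countOverlaps(fp, s)
  n_zn <- GenomicRanges::countOverlaps(zn, s)
  data.frame(probe_id = footprints$probe_id,
             polymorphic = n_fp > 0, polymorphic_critical = n_zn > 0,
             n_snps_footprint = n_fp, n_snps_zone = n_zn,
             row.names = NULL, stringsAsFactors = FALSE)
}

collapse_labels <- function(ids, all_ids, labels) {
  out <- rep(NA_character_, length(all_ids))
  if (!length(ids)) return(out)
  agg <- tapply(labels, ids, function(v) paste(unique(v), collapse = ","))
  out[match(names(agg), all_ids)] <- unname(agg)
  out
}

#' Annotate X and Y chromosome probes
#'
#' Builds the extended per-probe annotation: PAR1/PAR2/XTR membership
#' (built-in hg19 coordinates, applied automatically), cancer-testis
#' promoter status (promoter = TSS-`promoter_window[1]` ..
#' TSS+`promoter_window[2]` on the gene strand), repeat-element overlap
#' with class/family provenance, SNP interference flags, and membership in
#' supplied exclusion lists. Missing resources yield NA columns with a
#' warning.
#'
#' @param manifest [probe_manifest()]; only chrX/chrY probes are annotated.
#' @param resources list with optional elements: `ct_genes` (data.frame
#'   `chrom`, `start`, `end`, `strand`, `gene`), `repeats` (data.frame
#'   `chrom`, `start`, `end`, optional `class`, `family`), `snps`
#'   (data.frame `chrom`, `pos`, optional `maf`), `exclusion_lists`
#'   (named list of probe-id vectors, e.g. `nonspecific`).
#' @param promoter_window c(upstream, downstream) in bp around the TSS.
#' @param maf_min optional MAF filter passed to [flag_polymorphic()].
#' @return data.frame of class `probe_annotation`: one row per chrX/chrY
#'   probe with logical flags and label provenance.
#' @export
annotate_xy <- function(manifest, resources = list(),
                        promoter_window = c(1500, 500), maf_min = NULL) {
  xy <- manifest[manifest$chrom %in% c("chrX", "chrY"), , drop = FALSE]
  class(xy) <- class(manifest)
  out <- data.frame(probe_id = xy$probe_id, chrom = xy$chrom, pos = xy$pos,
                    stringsAsFactors = FALSE)

  regs <- par_xtr_regions()
  hits <- overlap_regions(xy, regs, mode = "cpg_position")
  for (nm in c("PAR1", "PAR2", "XTR"))
    out[[paste0("in_", nm)]] <- out$probe_id %in%
      hits$probe_id[hits$name == nm]

  if (!is.null(resources$ct_genes)) {
    ct <- as.data.frame(resources$ct_genes, stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "start", "end", "strand", "gene") %in% names(ct)))
    tss <- ifelse(ct$strand == "+", ct$start, ct$end)
    prom <- data.frame(chrom = ct$chrom,
                       start = ifelse(ct$strand == "+",
                                      tss - promoter_window[1],
                                      tss - promoter_window[2]),
                       end = ifelse(ct$strand == "+",
                                    tss + promoter_window[2],
                                    tss + promoter_window[1]),
                       gene = ct$gene, stringsAsFactors = FALSE)
    h <- overlap_regions(xy, prom, mode = "cpg_position")
    out$ct_promoter <- out$probe_id %in% h$probe_id
    out$ct_gene <- collapse_labels(h$probe_id, out$probe_id, h$gene)
  } else {
    warning("ct_genes resource missing; ct_promoter emitted as NA")
    out$ct_promoter <- NA
    out$ct_gene <- NA_character_
  }

  if (!is.null(resources$repeats)) {
    rp <- as.data.frame(resources$repeats, stringsAsFactors = FALSE)
    h <- overlap_regions(xy, rp, mode = "cpg_position")
    out$repeat_overlap <- out$probe_id %in% h$probe_id
    out$repeat_class <- if ("class" %in% names(h))
      collapse_labels(h$probe_id, out$probe_id, h$class) else NA_character_
    out$repeat_family <- if ("family" %in% names(h))
      collapse_labels(h$probe_id, out$probe_id, h$family) else NA_character_
  } else {
    warning("repeats resource missing; repeat_overlap emitted as NA")
    out$repeat_overlap <- NA
    out$repeat_class <- out$repeat_family <- NA_character_
  }

  if (!is.null(resources$snps)) {
    fp <- build_footprints(xy)
    pm <- flag_polymorphic(fp, resources$snps, maf_min = maf_min)
    out$polymorphic <- pm$polymorphic
    out$polymorphic_critical <- pm$polymorphic_critical
  } else {
    warning("snps resource missing; polymorphic flags emitted as NA")
    out$polymorphic <- out$polymorphic_critical <- NA
  }

  out$nonspecific_listed <- FALSE
  out$nonspecific_source <- NA_character_
  for (nm in names(resources$exclusion_lists)) {
    inlist <- out$probe_id %in% resources$exclusion_lists[[nm]]
    out$nonspecific_listed <- out$nonspecific_listed | inlist
    out$nonspecific_source <- ifelse(
      inlist, ifelse(is.na(out$nonspecific_source), nm,
                     paste(out$nonspecific_source, nm, sep = ",")),
      out$nonspecific_source)
  }
  class(out) <- c("probe_annotation", "data.frame")
  out
}
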