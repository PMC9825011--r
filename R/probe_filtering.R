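## Probe filtering with sex stratification where it matters: detection
## p-value and non-variability on chrY are assessed in XY samples only (by
## default); bead count is never stratified.

#' Filtering configuration
#'
#' Thresholds follow common array practice: a probe fails detection if
#' p > `detp_threshold` in strictly more than `detp_sample_frac` of the
#' applicable samples; fails bead count if count < `bead_min` in strictly
#' more than `bead_sample_frac` of samples; is non-variable if its
#' 10th-90th centile beta range is below `nonvar_range` in the applicable
#' stratum.
#'
#' @param detp_threshold detection p-value threshold.
#' @param detp_sample_frac exceedance fraction for detection failures
#'   (0.01 for a large cohort; 0.05 is a common choice for small cohorts).
#' @param bead_min minimum bead count.
#' @param bead_sample_frac exceedance fraction for bead-count failures.
#' @param nonvar_range beta range below which a probe is non-variable.
#' @param nonvar_quantiles quantile pair defining the range (default
#'   10th/90th centiles; `c(0,1)` gives the plain range).
#' @param stratify_detp_chrY assess chrY detection failures in XY only.
#' @param stratify_detp_chrX assess chrX detection failures per sex (off by
#'   default; stratification makes no difference on chrX).
#' @param stratify_nonvar_chrY assess chrY non-variability in XY only.
#' @param external_nonvariable_list optional probe-id vector; when given,
#'   non-variable removal requires membership in BOTH the cohort-derived
#'   set and this list.
#' @param exclusion_lists named list of probe-id vectors (e.g.
#'   `list(nonspecific = ..., polymorphic = ...)`) removed outright.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(detp_threshold = 0.01, detp_sample_frac = 0.01,
                          bead_min = 3, bead_sample_frac = 0.01,
                          nonvar_range = 0.05,
                          nonvar_quantiles = c(0.10, 0.90),
                          stratify_detp_chrY = TRUE,
                          stratify_detp_chrX = FALSE,
                          stratify_nonvar_chrY = TRUE,
                          external_nonvariable_list = NULL,
                          exclusion_lists = list()) {
  stopifnot(detp_threshold >= 0, detp_threshold <= 1,
            detp_sample_frac >= 0, detp_sample_frac < 1,
            bead_min >= 0, bead_sample_frac >= 0, bead_sample_frac < 1,
            nonvar_range > 0, length(nonvar_quantiles) == 2,
            nonvar_quantiles[1] < nonvar_quantiles[2])
  cfg <- as.list(environment())
  class(cfg) <- "filter_config"
  cfg
}

## exceedance fraction per probe over a sample subset; NA counts as failing
exceed_frac <- function(fail, cols) {
  f <- fail[, cols, drop = FALSE]
  rowMeans(f)
}

#' Flag probes failing detection p-value
#'
#' For autosomes (and chrX unless stratified) the exceedance fraction is
#' computed over all samples; for chrY, over XY samples only when
#' `stratify_detp_chrY` — otherwise background-only measurements in XX
#' samples flag nearly every chrY probe. Missing p-values count as failing.
#'
#' @param detp probes x samples detection p-value matrix.
#' @param chrom per-probe chromosome labels aligned to `detp` rows.
#' @param sexes per-sample `XX`/`XY` aligned to `detp` columns.
#' @param cfg [filter_config()].
#' @return data.frame `probe_id`, `flagged`, `frac_failed`, `stratum`.
#' @export
flag_detection_failures <- function(detp, chrom, sexes, cfg = filter_config()) {
  stopifnot(nrow(detp) == length(chrom), ncol(detp) == length(sexes))
  grp <- chrom_group(chrom)
  fail <- is.na(detp) | detp > cfg$detp_threshold
  frac <- numeric(nrow(detp))
  stratum <- rep("all", nrow(detp))
  all_cols <- seq_len(ncol(detp))
  xy_cols <- which(sexes == "XY")
  xx_cols <- which(sexes == "XX")
  if (cfg$stratify_detp_chrY && any(grp == "chrY")) {
    if (!length(xy_cols))
      stop("chrY detection stratification requested but cohort has no XY samples")
    frac[grp == "chrY"] <- exceed_frac(fail, xy_cols)[grp == "chrY"]
    stratum[grp == "chrY"] <- "XY"
  } else {
    frac[grp == "chrY"] <- exceed_frac(fail, all_cols)[grp == "chrY"]
  }
  if (cfg$stratify_detp_chrX && any(grp == "chrX")) {
    ## flag if failing in either sex stratum (union policy)
    fx <- pmax(exceed_frac(fail, xx_cols), exceed_frac(fail, xy_cols))
    frac[grp == "chrX"] <- fx[grp == "chrX"]
    stratum[grp == "chrX"] <- "per-sex"
  } else {
    frac[grp == "chrX"] <- exceed_frac(fail, all_cols)[grp == "chrX"]
  }
  frac[grp == "autosome"] <- exceed_frac(fail, all_cols)[grp == "autosome"]
  data.frame(probe_id = rownames(detp),
             flagged = frac > cfg$detp_sample_frac,
             frac_failed = frac, stratum = stratum,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag probes with low bead counts
#'
#' Never sex-stratified: bead detection is independent of hybridization
#' signal, so the proportion of low-bead probes does not differ by sex on
#' any chromosome. Missing counts are treated as below `bead_min`
#' (conservative).
#'
#' @param beads probes x samples bead count matrix.
#' @param cfg [filter_config()].
#' @return data.frame `probe_id`, `flagged`, `frac_failed`.
#' @export
flag_low_beadcount <- function(beads, cfg = filter_config()) {
  fail <- is.na(beads) | beads < cfg$bead_min
  frac <- rowMeans(fail)
  data.frame(probe_id = rownames(beads),
             flagged = frac > cfg$bead_sample_frac,
             frac_failed = frac, row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag non-variable probes
#'
#' A probe is non-variable when its `nonvar_quantiles` beta range (default
#' 10th-90th centile) is strictly below `nonvar_range` in the applicable
#' stratum: all samples for autosomes/chrX, XY samples only for chrY when
#' stratified — in a mixed cohort the background betas (~0.5) of chrY
#' probes in XX samples mask genuinely constant probes. If an external
#' non-variable list is configured, final flags require membership in both
#' the cohort-derived set and the list.
#'
#' @param beta probes x samples beta matrix.
#' @param chrom per-probe chromosome labels.
#' @param sexes per-sample `XX`/`XY`.
#' @param cfg [filter_config()].
#' @param min_stratum_n minimum samples required in the evaluated stratum.
#' @return data.frame `probe_id`, `nonvariable` (cohort-derived),
#'   `flagged` (after external-list intersection), `beta_range`, `stratum`.
#' @export
flag_nonvariable <- function(beta, chrom, sexes, cfg = filter_config(),
                             min_stratum_n = 10) {
  stopifnot(nrow(beta) == length(chrom), ncol(beta) == length(sexes))
  grp <- chrom_group(chrom)
  qrange <- function(rows, cols, label) {
    if (length(cols) < min_stratum_n)
      stop("stratum '", label, "' has fewer than ", min_stratum_n, " samples")
    apply(beta[rows, cols, drop = FALSE], 1, function(v) {
      q <- quantile(v, cfg$nonvar_quantiles, na.rm = TRUE, names = FALSE)
      q[2] - q[1]
    })
  }
  rng <- numeric(nrow(beta))
  stratum <- rep("all", nrow(beta))
  all_cols <- seq_len(ncol(beta))
  nonY <- grp != "chrY"
  if (any(nonY)) rng[nonY] <- qrange(nonY, all_cols, "all")
  if (any(grp == "chrY")) {
    if (cfg$stratify_nonvar_chrY) {
      rng[grp == "chrY"] <- qrange(grp == "chrY", which(sexes == "XY"), "XY")
      stratum[grp == "chrY"] <- "XY"
    } else {
      rng[grp == "chrY"] <- qrange(grp == "chrY", all_cols, "all")
    }
  }
  nonvar <- rng < cfg$nonvar_range
  flagged <- nonvar
  if (!is.null(cfg$external_nonvariable_list))
    flagged <- nonvar & rownames(beta) %in% cfg$external_nonvariable_list
  data.frame(probe_id = rownames(beta), nonvariable = nonvar,
             flagged = flagged, beta_range = rng, stratum = stratum,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the full per-probe filter report
#'
#' Runs every configured criterion on a dataset and assembles the
#' Table-2-style report: per-probe, per-criterion flags, reason codes, and
#' counts by chromosome context. Count denominators are cg/ch probes only;
#' rs and control probes are tracked separately (and dropped by
#' [apply_filters()] by default).
#'
#' @param ds [methyl_dataset()].
#' @param sexes per-sample `XX`/`XY` (e.g. inferred sex); defaults to the
#'   annotated sex in the sample sheet.
#' @param cfg [filter_config()].
#' @return list of class `filter_report`: `flags` (data.frame), `counts`
#'   (criterion x context), `config`.
#' @export
build_filter_report <- function(ds, sexes = NULL, cfg = filter_config()) {
  stopifnot(inherits(ds, "methyl_dataset"))
  if (is.null(sexes)) sexes <- ds$samples$annotated_sex
  man <- ds$manifest
  flags <- data.frame(probe_id = man$probe_id, chrom = man$chrom,
                      context = chrom_group(man$chrom),
                      probe_class = man$probe_class,
                      stringsAsFactors = FALSE)
  flags$detp <- FALSE; flags$beads <- FALSE; flags$nonvariable <- FALSE
  if (!is.null(ds$detp)) {
    dp <- flag_detection_failures(ds$detp, man$chrom, sexes, cfg)
    flags$detp <- dp$flagged[match(flags$probe_id, dp$probe_id)]
  }
  if (!is.null(ds$beads)) {
    bc <- flag_low_beadcount(ds$beads, cfg)
    flags$beads <- bc$flagged[match(flags$probe_id, bc$probe_id)]
  }
  if (!is.null(ds$beta)) {
    nv <- flag_nonvariable(ds$beta, man$chrom, sexes, cfg)
    flags$nonvariable <- nv$flagged[match(flags$probe_id, nv$probe_id)]
  }
  for (nm in names(cfg$exclusion_lists))
    flags[[paste0("exclusion_", nm)]] <- flags$probe_id %in% cfg$exclusion_lists[[nm]]

  crit_cols <- setdiff(names(flags),
                       c("probe_id", "chrom", "context", "probe_class"))
  flags$remove <- Reduce(`|`, flags[crit_cols])
  flags$reason <- apply(flags[crit_cols], 1, function(v)
    paste(sub("^exclusion_", "exclusion:", crit_cols[which(v)]), collapse = ";"))

  cgch <- flags$probe_class %in% c("cg", "ch")
  ctx <- factor(flags$context[cgch], levels = c("autosome", "chrX", "chrY"))
  counts <- t(vapply(c(crit_cols, "remove"), function(cc) {
    k <- tapply(flags[[cc]][cgch], ctx, sum)
    ifelse(is.na(k), 0, k)
  }, numeric(3)))
  structure(list(flags = flags, counts = counts, config = cfg),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", sum(x$flags$remove), "of", nrow(x$flags),
      "probes flagged for removal\n")
  print(x$counts)
  invisible(x)
}

#' Apply a filter report to a dataset
#'
#' Returns a new dataset without the flagged probes (and, by default,
#' without rs genotyping probes, which are QC-only); the input is untouched.
#'
#' @param ds [methyl_dataset()].
#' @param report [build_filter_report()] result aligned to `ds`.
#' @param drop_rs drop rs-class probes regardless of flags.
#' @return list with `dataset` (filtered) and `report`.
#' @export
apply_filters <- function(ds, report, drop_rs = TRUE) {
  stopifnot(inherits(ds, "methyl_dataset"), inherits(report, "filter_report"))
  fl <- report$flags
  if (!setequal(fl$probe_id, ds$manifest$probe_id))
    stop("report is not aligned to the dataset")
  drop <- fl$probe_id[fl$remove]
  if (drop_rs)
    drop <- union(drop, ds$manifest$probe_id[ds$manifest$probe_class == "rs"])
  keep <- setdiff(ds$manifest$probe_id, drop)
  if (!length(keep)) stop("filtering would remove every probe")
  sub <- function(m) if (is.null(m)) NULL else m[intersect(keep, rownames(m)), , drop = FALSE]
  signals <- if (!is.null(ds$signals))
    list(meth = sub(ds$signals$meth), unmeth = sub(ds$signals$unmeth))
  out <- methyl_dataset(ds$manifest[ds$manifest$probe_id %in% keep, ],
                        ds$samples, beta = sub(ds$beta), signals = signals,
                        detp = sub(ds$detp), beads = sub(ds$beads))
  list(dataset = out, report = report)
}

#' Serialize a filter report
#'
#' Writes the per-probe flag table as TSV and the per-context count summary
#' as JSON.
#'
#' @param report [build_filter_report()] result.
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>_counts.json`.
#' @return invisibly, the two paths.
#' @export
write_filter_report <- function(report, prefix) {
  stopifnot(inherits(report, "filter_report"))
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, "_counts.json")
  data.table::fwrite(report$flags, tsv, sep = "\t")
  jsonlite::write_json(
    lapply(seq_len(nrow(report$counts)), function(i)
      as.list(report$counts[i, ])) |> setNames(rownames(report$counts)),
    js, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(tsv, js))
}
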