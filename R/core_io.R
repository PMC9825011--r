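#' @importFrom stats median pnorm quantile rnorm runif rbinom rpois rlnorm
#'   setNames complete.cases pt p.adjust cor sd var aggregate optim dbeta
#'   na.omit model.matrix lm.fit kmeans r2dtable
#' @importFrom utils head modifyList
NULL

CHROMS <- c(paste0("chr", 1:22), "chrX", "chrY")

#' Chromosome context of a chromosome label
#'
#' Collapses `chr1..chr22` to `"autosome"`, keeps `"chrX"` and `"chrY"`.
#' Most filtering and evaluation steps in this package operate per context
#' because the X and Y behave differently from the autosomes in mixed-sex
#' cohorts.
#'
#' @param chrom character vector of chromosome labels (`chr1`..`chr22`,
#'   `chrX`, `chrY`).
#' @return character vector in `{"autosome","chrX","chrY"}`.
#' @export
chrom_group <- function(chrom) {
  out <- ifelse(chrom == "chrX", "chrX", ifelse(chrom == "chrY", "chrY", "autosome"))
  out[!chrom %in% CHROMS] <- NA_character_
  out
}

## ---- constructors -----------------------------------------------------

#' Construct a probe manifest
#'
#' @param df data.frame with columns `probe_id`, `chrom`, `pos`, `strand`,
#'   `probe_type`, `probe_class`. Extra columns are preserved as opaque
#'   annotation. Coordinates are 1-based hg19 CpG positions.
#' @return validated data.frame of class `probe_manifest`.
#' @export
probe_manifest <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("probe_id", "chrom", "pos", "strand", "probe_type", "probe_class")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("manifest missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    stop("manifest probe_id values must be unique")
  if (!all(df$chrom %in% CHROMS))
    stop("manifest contains unknown chromosome labels: ",
         paste(unique(df$chrom[!df$chrom %in% CHROMS]), collapse = ", "))
  df$pos <- as.integer(df$pos)
  if (any(is.na(df$pos)) || any(df$pos < 1))
    stop("manifest pos must be integer >= 1")
  if (!all(df$strand %in% c("+", "-")))
    stop("manifest strand must be '+' or '-'")
  if (!all(df$probe_type %in% c("InfiniumI_Red", "InfiniumI_Grn", "InfiniumII")))
    stop("unknown probe_type values")
  if (!all(df$probe_class %in% c("cg", "ch", "rs", "control")))
    stop("unknown probe_class values")
  rownames(df) <- NULL
  class(df) <- c("probe_manifest", "data.frame")
  df
}

#' Construct a sample sheet
#'
#' @param df data.frame with columns `sample_id`, `annotated_sex`
#'   (`XX`/`XY`/`unknown`), `batch`, plus arbitrary covariate columns.
#' @return validated data.frame of class `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("sample_id", "annotated_sex", "batch")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("sample sheet missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("sample_id values must be unique")
  if (!all(df$annotated_sex %in% c("XX", "XY", "unknown")))
    stop("annotated_sex must be one of XX, XY, unknown")
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

check_matrix <- function(m, what, probe_ids, sample_ids) {
  if (is.null(m)) return(NULL)
  if (!is.matrix(m)) m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " matrix must carry probe rownames and sample colnames")
  bad <- setdiff(rownames(m), probe_ids)
  if (length(bad))
    stop(what, " matrix contains probes absent from manifest: ",
         paste(head(bad, 5), collapse = ", "))
  bad <- setdiff(colnames(m), sample_ids)
  if (length(bad))
    stop(what, " matrix contains samples absent from sample sheet: ",
         paste(head(bad, 5), collapse = ", "))
  m
}

#' Bundle methylation array components into an aligned dataset
#'
#' The central container: manifest, optional raw signals (`meth`/`unmeth`),
#' beta values, detection p-values, bead counts and the sample sheet, all
#' reordered to a single canonical probe and sample order (the manifest's and
#' the sample sheet's). At least one of `signals`/`beta` must be present.
#'
#' @param manifest [probe_manifest()].
#' @param samples [sample_sheet()].
#' @param beta probes x samples matrix of beta values in `[0,1]` (or NULL).
#' @param signals list with `meth` and `unmeth` intensity matrices (or NULL).
#' @param detp detection p-value matrix (or NULL).
#' @param beads bead count matrix (or NULL).
#' @return object of class `methyl_dataset`.
#' @export
methyl_dataset <- function(manifest, samples, beta = NULL, signals = NULL,
                           detp = NULL, beads = NULL) {
  manifest <- probe_manifest(manifest)
  samples <- sample_sheet(samples)
  if (is.null(beta) && is.null(signals))
    stop("at least one of beta or signals must be provided")
  pid <- manifest$probe_id
  sid <- samples$sample_id

  align <- function(m, what) {
    m <- check_matrix(m, what, pid, sid)
    if (is.null(m)) return(NULL)
    missing_s <- setdiff(sid, colnames(m))
    if (length(missing_s))
      stop(what, " matrix lacks samples present in sample sheet: ",
           paste(head(missing_s, 5), collapse = ", "))
    keep <- intersect(pid, rownames(m))
    m[keep, sid, drop = FALSE]
  }
  if (!is.null(signals)) {
    stopifnot(is.list(signals), all(c("meth", "unmeth") %in% names(signals)))
    signals$meth <- align(signals$meth, "meth")
    signals$unmeth <- align(signals$unmeth, "unmeth")
    if (!identical(dim(signals$meth), dim(signals$unmeth)) ||
        !identical(rownames(signals$meth), rownames(signals$unmeth)))
      stop("meth and unmeth matrices must be identically indexed")
    if (any(signals$meth < 0, na.rm = TRUE) || any(signals$unmeth < 0, na.rm = TRUE))
      stop("negative intensities are not allowed")
    signals <- signals[c("meth", "unmeth")]
  }
  beta <- align(beta, "beta")
  if (!is.null(beta) && any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0,1]")
  detp <- align(detp, "detp")
  if (!is.null(detp) && any(detp < 0 | detp > 1, na.rm = TRUE))
    stop("detection p-values must lie in [0,1]")
  beads <- align(beads, "beads")
  if (!is.null(beads)) {
    if (any(beads < 0, na.rm = TRUE) || any(beads != round(beads), na.rm = TRUE))
      stop("bead counts must be non-negative integers")
  }

  ## matrices may cover a subset of manifest probes but must agree with each other
  mats <- Filter(Negate(is.null),
                 list(beta = beta, detp = detp, beads = beads,
                      meth = if (!is.null(signals)) signals$meth))
  rn <- lapply(mats, rownames)
  if (length(rn) > 1L && !all(vapply(rn[-1], identical, logical(1), rn[[1]])))
    stop("all matrices must cover the same probe set")
  keep <- pid %in% rn[[1]]
  manifest2 <- manifest[keep, , drop = FALSE]
  class(manifest2) <- class(manifest)

  structure(list(manifest = manifest2, samples = samples, beta = beta,
                 signals = signals, detp = detp, beads = beads),
            class = "methyl_dataset")
}

#' @export
print.methyl_dataset <- function(x, ...) {
  cat("methyl_dataset:", nrow(x$manifest), "probes x", nrow(x$samples), "samples\n")
  grp <- table(chrom_group(x$manifest$chrom))
  cat("  contexts:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  cat("  components:",
      paste(names(Filter(Negate(is.null), x[c("beta", "signals", "detp", "beads")])),
            collapse = ", "), "\n")
  cat("  sexes (annotated):",
      paste(names(table(x$samples$annotated_sex)),
            table(x$samples$annotated_sex), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.methyl_dataset <- function(x) c(nrow(x$manifest), nrow(x$samples))

## ---- file io ----------------------------------------------------------

sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_matrix_file <- function(path) {
  dt <- data.table::fread(path, sep = sep_for(path), header = TRUE,
                          data.table = FALSE, na.strings = c("NA", ""))
  if (names(dt)[1] != "probe_id")
    stop("matrix file ", path, " must have 'probe_id' as first column")
  ids <- dt[[1]]
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(dt[-1], is.numeric, logical(1)))[1]
    stop("non-numeric values in ", path, ", column '", names(dt)[-1][bad], "'")
  }
  rownames(m) <- ids
  m
}

write_matrix_file <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = sep_for(path), na = "NA", quote = FALSE)
}

#' Read a methylation dataset from delimited text files
#'
#' @param manifest_path path to the probe manifest (TSV or CSV by extension).
#' @param matrix_paths named list/vector of matrix file paths; recognised
#'   names: `beta`, `meth`, `unmeth`, `detp`, `beads`. Matrices carry
#'   `probe_id` as first column and sample ids as header.
#' @param samplesheet_path path to the sample sheet.
#' @return [methyl_dataset()].
#' @export
read_dataset <- function(manifest_path, matrix_paths, samplesheet_path) {
  manifest <- data.table::fread(manifest_path, sep = sep_for(manifest_path),
                                data.table = FALSE)
  samples <- data.table::fread(samplesheet_path, sep = sep_for(samplesheet_path),
                               data.table = FALSE)
  matrix_paths <- as.list(matrix_paths)
  known <- c("beta", "meth", "unmeth", "detp", "beads")
  bad <- setdiff(names(matrix_paths), known)
  if (length(bad)) stop("unknown matrix names: ", paste(bad, collapse = ", "))
  mats <- lapply(matrix_paths, read_matrix_file)
  signals <- NULL
  if (!is.null(mats$meth) || !is.null(mats$unmeth)) {
    if (is.null(mats$meth) || is.null(mats$unmeth))
      stop("meth and unmeth must be supplied together")
    signals <- list(meth = mats$meth, unmeth = mats$unmeth)
  }
  methyl_dataset(manifest, samples, beta = mats$beta, signals = signals,
                 detp = mats$detp, beads = mats$beads)
}

#' Write a methylation dataset as delimited text files
#'
#' Inverse of [read_dataset()]: writes `manifest.tsv`, `samples.tsv` and one
#' TSV per matrix component into `dir`.
#'
#' @param ds [methyl_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of files written.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "methyl_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(manifest = file.path(dir, "manifest.tsv"),
             samples = file.path(dir, "samples.tsv"))
  data.table::fwrite(as.data.frame(ds$manifest), files[["manifest"]], sep = "\t")
  data.table::fwrite(as.data.frame(ds$samples), files[["samples"]], sep = "\t")
  for (nm in c("beta", "detp", "beads")) {
    if (!is.null(ds[[nm]])) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      write_matrix_file(ds[[nm]], f)
      files[[nm]] <- f
    }
  }
  if (!is.null(ds$signals)) {
    for (nm in c("meth", "unmeth")) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      write_matrix_file(ds$signals[[nm]], f)
      files[[nm]] <- f
    }
  }
  invisible(files)
}
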