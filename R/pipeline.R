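## End-to-end orchestration: simulate/read -> qc -> filter -> annotate ->
## optional batch-correction evaluation -> differential methylation / XCI,
## with every artifact written under a run directory together with a run
## manifest (config digest, seed, package version).

## tiny rolling-hash digest so the run manifest can fingerprint the config
## without a hashing dependency (mod 2^31-1 keeps exact double arithmetic)
config_digest <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default pipeline configuration
#'
#' Returns the fully-populated default configuration; pass overrides as a
#' (possibly nested) list. Unknown top-level keys are rejected so typos
#' fail loudly. The `"aca-reanalysis"` preset raises both exceedance
#' fractions to 5%, the setting used for small cohorts.
#'
#' @param overrides named list merged over the defaults.
#' @param preset NULL or `"aca-reanalysis"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = list(), preset = NULL) {
  cfg <- list(
    seed = 1L,
    out_dir = tempfile("methylxy_run_"),
    simulate = list(enabled = TRUE),       # sim_config overrides
    input = list(manifest = NULL, matrices = list(), samplesheet = NULL),
    qc = list(cutoff = -4,
              thresholds = list(x_hi = 0.8, x_lo = 0.65, y_lo = 0.3, y_hi = 0.6),
              use_inferred_sex = TRUE),
    filter = list(detp_threshold = 0.01, detp_sample_frac = 0.01,
                  bead_min = 3, bead_sample_frac = 0.01,
                  nonvar_range = 0.05, stratify_detp_chrY = TRUE,
                  stratify_nonvar_chrY = TRUE, drop_rs = TRUE),
    annotate = list(enabled = TRUE, resources = list()),
    evaluate = list(combat = FALSE),
    analysis = list(enabled = TRUE, phenotype = "phenotype",
                    covariates = "gest_age", xci = TRUE)
  )
  if (!is.null(preset)) {
    if (preset == "aca-reanalysis") {
      cfg$filter$detp_sample_frac <- 0.05
      cfg$filter$bead_sample_frac <- 0.05
    } else stop("unknown preset: ", preset)
  }
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (nm in names(overrides)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(overrides[[nm]]))
      modifyList(cfg[[nm]], overrides[[nm]]) else overrides[[nm]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the yaml package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(raw)
}

#' Run the full sex-chromosome-aware processing pipeline
#'
#' Stage order is enforced: QC sex calls are computed before any
#' sex-stratified filtering; filtering precedes annotation and analysis.
#' Every numeric artifact is a delimited table or JSON summary under
#' `out_dir`, and `run_manifest.json` records the seed, config digest and
#' thresholds actually applied. Given identical inputs and seed, reruns are
#' byte-identical.
#'
#' @param config a [pipeline_config()], a list of overrides, or a path to a
#'   JSON/YAML config file.
#' @return invisibly, a list with the in-memory stage results and the
#'   output paths.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
  else if (inherits(config, "pipeline_config")) config
  else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## -- input -----------------------------------------------------------
  truth <- NULL
  ds <- stage("input", {
    if (isTRUE(cfg$simulate$enabled)) {
      sc_args <- cfg$simulate[setdiff(names(cfg$simulate), "enabled")]
      sc_args$seed <- sc_args$seed %||% cfg$seed
      sim <- simulate_cohort(do.call(sim_config, sc_args))
      truth <- sim$truth
      sim$dataset
    } else {
      read_dataset(cfg$input$manifest, cfg$input$matrices, cfg$input$samplesheet)
    }
  })

  ## -- qc --------------------------------------------------------------
  qc <- stage("qc", qc_report(ds, thresholds = cfg$qc$thresholds,
                              cutoff = cfg$qc$cutoff))
  paths$qc <- file.path(cfg$out_dir, "qc_report.tsv")
  data.table::fwrite(qc$samples, paths$qc, sep = "\t")
  sexes <- if (isTRUE(cfg$qc$use_inferred_sex)) {
    s <- qc$samples$inferred
    ## anomalies cannot enter sex-stratified steps; drop them
    keep <- s %in% c("XX", "XY")
    if (!all(keep)) {
      ds <- methyl_dataset(ds$manifest, ds$samples[keep, ],
                           beta = ds$beta[, keep, drop = FALSE],
                           signals = list(meth = ds$signals$meth[, keep, drop = FALSE],
                                          unmeth = ds$signals$unmeth[, keep, drop = FALSE]),
                           detp = ds$detp[, keep, drop = FALSE],
                           beads = ds$beads[, keep, drop = FALSE])
    }
    s[keep]
  } else ds$samples$annotated_sex

  ## -- filter ----------------------------------------------------------
  f_args <- cfg$filter[setdiff(names(cfg$filter), "drop_rs")]
  fcfg <- do.call(filter_config, f_args)
  rep_ <- stage("filter", build_filter_report(ds, sexes = sexes, cfg = fcfg))
  filtered <- stage("filter", apply_filters(ds, rep_,
                                            drop_rs = isTRUE(cfg$filter$drop_rs)))
  paths$filter <- file.path(cfg$out_dir, "filter_report")
  write_filter_report(rep_, paths$filter)

  ## -- annotate --------------------------------------------------------
  ann <- NULL
  if (isTRUE(cfg$annotate$enabled)) {
    ann <- stage("annotate", suppressWarnings(
      annotate_xy(filtered$dataset$manifest, cfg$annotate$resources)))
    paths$annotation <- file.path(cfg$out_dir, "xy_annotation.tsv")
    data.table::fwrite(ann, paths$annotation, sep = "\t")
  }

  ## -- optional batch-correction evaluation ----------------------------
  conc <- NULL
  if (isTRUE(cfg$evaluate$combat)) {
    conc <- stage("evaluate", {
      fds <- filtered$dataset
      M <- beta_to_m(fds$beta)
      Madj <- combat_adjust(M, fds$samples$batch)
      ct <- per_sample_concordance(fds$beta, m_to_beta(Madj),
                                   fds$manifest, sexes)
      paths$concordance <<- file.path(cfg$out_dir, "concordance.tsv")
      data.table::fwrite(ct, paths$concordance, sep = "\t")
      paths$concordance_summary <<- file.path(cfg$out_dir, "concordance_summary.json")
      jsonlite::write_json(summarize_concordance(ct), paths$concordance_summary,
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      ct
    })
  }

  ## -- analysis --------------------------------------------------------
  dm <- NULL; xci <- NULL
  if (isTRUE(cfg$analysis$enabled)) {
    dm <- stage("dmc", stratified_dmc(filtered$dataset,
                                      phenotype = cfg$analysis$phenotype,
                                      covariates = cfg$analysis$covariates,
                                      sexes = sexes))
    dm <- dm[order(dm$q, dm$p), ]
    paths$dm <- file.path(cfg$out_dir, "dm_results.tsv")
    data.table::fwrite(dm, paths$dm, sep = "\t")
    if (isTRUE(cfg$analysis$xci) && !is.null(truth)) {
      xci <- stage("xci", call_xci(filtered$dataset$beta, truth$promoter_map,
                                   sexes, annotation = ann))
      paths$xci <- file.path(cfg$out_dir, "xci_calls.tsv")
      data.table::fwrite(xci, paths$xci, sep = "\t")
    }
  }

  manifest <- list(package = "methylXY",
                   version = as.character(utils::packageVersion("methylXY")),
                   seed = cfg$seed, config_digest = config_digest(unclass(cfg)),
                   thresholds = cfg$filter, qc = cfg$qc[c("cutoff", "thresholds")],
                   stages = names(Filter(Negate(is.null),
                                         list(qc = qc, filter = rep_, annotate = ann,
                                              evaluate = conc, dmc = dm, xci = xci))))
  paths$run_manifest <- file.path(cfg$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, paths$run_manifest, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(config = cfg, dataset = filtered$dataset, truth = truth,
                 qc = qc, filter = rep_, annotation = ann, concordance = conc,
                 dm = dm, xci = xci, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
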