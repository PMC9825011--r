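## Sample-level quality control: sex inference from X/Y fluorescence,
## contamination scoring via a 4-component genotype mixture on the rs
## genotyping probes, duplicate-donor detection, and concordance with the
## annotated sex.

#' Normalized X and Y chromosome intensities per sample
#'
#' For each sample, nX is the median total fluorescence intensity (M + U)
#' over chrX probes divided by the median over autosomal probes; nY is the
#' chrY analogue. In XY samples nY sits near the autosomal level; in XX
#' samples chrY probes measure only background so nY is small (~0.1 under
#' typical background fractions).
#'
#' @param ds [methyl_dataset()] carrying signals.
#' @return data.frame with columns `sample_id`, `nX`, `nY`.
#' @export
normalized_sex_intensities <- function(ds) {
  stopifnot(inherits(ds, "methyl_dataset"))
  if (is.null(ds$signals))
    stop("sex inference requires raw signals (meth/unmeth)")
  grp <- chrom_group(ds$manifest$chrom)
  use <- ds$manifest$probe_class %in% c("cg", "ch")
  if (!any(grp == "chrY" & use))
    stop("manifest contains no chrY probes; cannot compute nY")
  if (!any(grp == "chrX" & use))
    stop("manifest contains no chrX probes; cannot compute nX")
  total <- ds$signals$meth + ds$signals$unmeth
  med <- function(rows) apply(total[rows, , drop = FALSE], 2, median, na.rm = TRUE)
  a <- med(grp == "autosome" & use)
  if (any(!is.finite(a)) || any(a <= 0))
    stop("degenerate autosomal intensities; cannot normalize")
  data.frame(sample_id = colnames(total),
             nX = med(grp == "chrX" & use) / a,
             nY = med(grp == "chrY" & use) / a,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Infer sample sex from normalized X/Y intensities
#'
#' Default decision rule: XX if nY < `y_lo` and nX > `x_hi`; XY if
#' nY > `y_hi` and nX < `x_lo`; anything else is an anomaly (e.g., a
#' suspected 45,X/46,XX mosaic with intermediate X intensity) and is never
#' silently assigned. An alternative nearest-centroid mode assigns every
#' sample to the closer of the two cluster centroids (useful on real data
#' where thresholds may need tuning).
#'
#' @param intens data.frame from [normalized_sex_intensities()].
#' @param thresholds list with `x_hi`, `x_lo`, `y_lo`, `y_hi`.
#' @param method `"thresholds"` (default) or `"centroid"`.
#' @return data.frame with `sample_id`, `nX`, `nY`, `inferred`
#'   (`XX`/`XY`/`anomaly`), `anomaly_note`.
#' @export
infer_sex <- function(intens,
                      thresholds = list(x_hi = 0.8, x_lo = 0.65,
                                        y_lo = 0.3, y_hi = 0.6),
                      method = c("thresholds", "centroid")) {
  method <- match.arg(method)
  stopifnot(all(c("sample_id", "nX", "nY") %in% names(intens)))
  if (any(!is.finite(intens$nX)) || any(!is.finite(intens$nY)))
    stop("non-finite normalized intensities")
  nX <- intens$nX; nY <- intens$nY
  if (method == "thresholds") {
    th <- thresholds
    inferred <- ifelse(nY < th$y_lo & nX > th$x_hi, "XX",
                ifelse(nY > th$y_hi & nX < th$x_lo, "XY", "anomaly"))
  } else {
    cl <- stats::kmeans(cbind(nX, nY), centers = rbind(c(1, 0.1), c(0.55, 1)))
    inferred <- c("XX", "XY")[cl$cluster]
  }
  note <- rep(NA_character_, length(inferred))
  amb <- inferred == "anomaly"
  note[amb & nX > thresholds$x_lo & nX < thresholds$x_hi & nY < thresholds$y_lo] <-
    "intermediate X intensity; possible 45,X/46,XX mosaic"
  note[amb & is.na(note)] <- "intensities outside XX/XY decision regions"
  data.frame(sample_id = intens$sample_id, nX = nX, nY = nY,
             inferred = inferred, anomaly_note = note,
             row.names = NULL, stringsAsFactors = FALSE)
}

## ---- genotype mixture model -------------------------------------------

## weighted Beta log-likelihood maximized over (log a, log b)
fit_beta_weighted <- function(x, w, shape0) {
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -sum(w * dbeta(x, a, b, log = TRUE))
  }
  out <- tryCatch(optim(log(shape0), nll, method = "Nelder-Mead",
                        control = list(maxit = 200)),
                  error = function(e) NULL)
  if (is.null(out)) return(shape0)
  exp(out$par)
}

#' Fit a genotype mixture to rs-probe betas and score contamination
#'
#' Pools every (probe, sample) beta of the genotyping probes and fits, by
#' EM, a 4-component mixture: Beta components near 0, 0.5 and 1 (AA/AB/BB
#' genotype clusters) plus a Uniform(0,1) outlier component that absorbs
#' intermediate values produced by inter-sample contamination. The
#' per-sample contamination score `snp_outliers` is the mean natural-log
#' odds of outlier membership over that sample's SNPs; samples scoring
#' above `cutoff` (-4, on the natural-log scale) are flagged contaminated.
#' The M-step updates Beta shapes by weighted maximum likelihood (ECM), so
#' the observed-data log-likelihood is non-decreasing across iterations.
#'
#' @param snp_betas SNP-probe x sample matrix of betas in `[0,1]`.
#' @param max_iter maximum EM iterations.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param cutoff contamination cutoff on the snp_outliers score.
#' @param call_min posterior required for a hard genotype call.
#' @return list with `model` (weights, shapes, loglik trace), `qc`
#'   (per-sample `snp_outliers`, `contaminated`), `genotypes` (hard-call
#'   character matrix), `posterior_outlier` (probe x sample matrix).
#' @export
call_genotypes <- function(snp_betas, max_iter = 500, tol = 1e-6,
                           cutoff = -4, call_min = 0.9) {
  stopifnot(is.matrix(snp_betas), nrow(snp_betas) >= 10)
  if (any(snp_betas < 0 | snp_betas > 1, na.rm = TRUE))
    stop("betas must lie in [0,1]")
  eps <- 1e-6
  x_all <- pmin(pmax(snp_betas, eps), 1 - eps)
  obs <- which(!is.na(x_all))
  x <- x_all[obs]

  shapes <- list(AA = c(1, 20), AB = c(20, 20), BB = c(20, 1))
  w <- c(AA = 0.3, AB = 0.3, BB = 0.3, outlier = 0.1)
  dens <- function(sh) cbind(AA = dbeta(x, sh$AA[1], sh$AA[2]),
                             AB = dbeta(x, sh$AB[1], sh$AB[2]),
                             BB = dbeta(x, sh$BB[1], sh$BB[2]),
                             outlier = 1)
  loglik <- function(d, w) sum(log(d %*% w))

  d <- dens(shapes)
  ll <- loglik(d, w)
  ll_trace <- ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ## E-step
    num <- sweep(d, 2, w, "*")
    post <- num / rowSums(num)
    ## M-step (ECM: accept a shape update only if it improves its weighted LL)
    w_new <- colMeans(post)
    w_new <- w_new / sum(w_new)
    shapes_new <- shapes
    for (k in names(shapes)) {
      cand <- fit_beta_weighted(x, post[, k], shapes[[k]])
      old_q <- sum(post[, k] * dbeta(x, shapes[[k]][1], shapes[[k]][2], log = TRUE))
      new_q <- sum(post[, k] * dbeta(x, cand[1], cand[2], log = TRUE))
      if (is.finite(new_q) && new_q > old_q) shapes_new[[k]] <- cand
    }
    d_new <- dens(shapes_new)
    ll_new <- loglik(d_new, w_new)
    if (ll_new < ll - 1e-8) {
      ## ECM guarantees this cannot happen; guard numerically anyway
      break
    }
    delta <- ll_new - ll
    shapes <- shapes_new; w <- w_new; d <- d_new; ll <- ll_new
    ll_trace <- c(ll_trace, ll)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations; returning best fit")

  num <- sweep(d, 2, w, "*")
  post <- num / rowSums(num)

  p_out <- matrix(NA_real_, nrow(snp_betas), ncol(snp_betas),
                  dimnames = dimnames(snp_betas))
  p_out[obs] <- post[, "outlier"]
  logodds <- log(p_out) - log1p(-p_out)
  snp_outliers <- colMeans(logodds, na.rm = TRUE)

  gt <- matrix(NA_character_, nrow(snp_betas), ncol(snp_betas),
               dimnames = dimnames(snp_betas))
  gpost <- post[, c("AA", "AB", "BB")]
  best <- max.col(gpost)
  bestp <- gpost[cbind(seq_len(nrow(gpost)), best)]
  calls <- ifelse(bestp > call_min, c("AA", "AB", "BB")[best], NA_character_)
  gt[obs] <- calls

  list(model = list(weights = w, shapes = shapes, loglik = ll_trace,
                    converged = converged, cutoff = cutoff),
       qc = data.frame(sample_id = colnames(snp_betas),
                       snp_outliers = snp_outliers,
                       contaminated = snp_outliers > cutoff,
                       row.names = NULL, stringsAsFactors = FALSE),
       genotypes = gt,
       posterior_outlier = p_out)
}

#' Detect duplicate donors from hard genotype calls
#'
#' Reports sample pairs whose non-missing genotype agreement is at least
#' `min_agreement`. Two unrelated donors at allele frequency 0.5 agree at
#' ~37.5% of SNPs in expectation, so the default 0.9 cleanly separates
#' duplicates from unrelated pairs.
#'
#' @param genotypes character matrix of hard calls (SNPs x samples) as
#'   returned by [call_genotypes()].
#' @param min_agreement minimum agreement fraction to report.
#' @param min_compared minimum number of jointly called SNPs for a pair to
#'   be comparable (contaminated mixtures lose calls at discordant SNPs,
#'   which would otherwise inflate agreement over the concordant remainder).
#' @return data.frame `sample1`, `sample2`, `agreement`, `n_compared`,
#'   sorted by agreement descending.
#' @export
detect_duplicates <- function(genotypes, min_agreement = 0.9,
                              min_compared = 10) {
  sid <- colnames(genotypes)
  n <- length(sid)
  res <- list()
  for (i in seq_len(n - 1)) {
    gi <- genotypes[, i]
    for (j in seq((i + 1), n)) {
      ok <- !is.na(gi) & !is.na(genotypes[, j])
      if (sum(ok) < min_compared) next
      agr <- mean(gi[ok] == genotypes[ok, j])
      if (agr >= min_agreement)
        res[[length(res) + 1]] <- data.frame(sample1 = sid[i], sample2 = sid[j],
                                             agreement = agr,
                                             n_compared = sum(ok),
                                             stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(sample1 = character(), sample2 = character(),
                      agreement = numeric(), n_compared = integer()))
  out <- do.call(rbind, res)
  out[order(-out$agreement), , drop = FALSE]
}

#' Reconcile inferred sex with the annotated sex
#'
#' Never mutates data: returns one row per sample with a status of
#' `concordant`, `mismatch` (annotation disagrees with data-derived sex),
#' `imputed` (annotation unknown) or `anomaly` (always reported regardless
#' of annotation; such samples should be removed before sex-stratified
#' processing).
#'
#' @param calls data.frame from [infer_sex()].
#' @param sheet [sample_sheet()].
#' @return data.frame `sample_id`, `annotated`, `inferred`, `status`,
#'   `anomaly_note`.
#' @export
check_sex_concordance <- function(calls, sheet) {
  idx <- match(calls$sample_id, sheet$sample_id)
  if (any(is.na(idx)))
    stop("samples absent from sheet: ",
         paste(calls$sample_id[is.na(idx)], collapse = ", "))
  ann <- sheet$annotated_sex[idx]
  status <- ifelse(calls$inferred == "anomaly", "anomaly",
            ifelse(ann == "unknown", "imputed",
            ifelse(ann == calls$inferred, "concordant", "mismatch")))
  data.frame(sample_id = calls$sample_id, annotated = ann,
             inferred = calls$inferred, status = status,
             anomaly_note = calls$anomaly_note,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-call QC report for a dataset
#'
#' Runs intensity-based sex inference, the genotype mixture model on rs
#' probes, duplicate detection and sex-concordance checking; returns the
#' merged per-sample table plus the model objects.
#'
#' @param ds [methyl_dataset()] with signals and rs probes.
#' @param thresholds sex-inference thresholds, see [infer_sex()].
#' @param cutoff contamination cutoff, see [call_genotypes()].
#' @return list with `samples` (merged QC table), `sex_calls`,
#'   `genotype_fit`, `duplicates`, `concordance`.
#' @export
qc_report <- function(ds, thresholds = list(x_hi = 0.8, x_lo = 0.65,
                                            y_lo = 0.3, y_hi = 0.6),
                      cutoff = -4) {
  intens <- normalized_sex_intensities(ds)
  calls <- infer_sex(intens, thresholds)
  conc <- check_sex_concordance(calls, ds$samples)
  rs <- ds$manifest$probe_id[ds$manifest$probe_class == "rs"]
  fit <- NULL; dup <- NULL
  tab <- merge(calls, conc[, c("sample_id", "status")], by = "sample_id")
  if (length(rs) >= 10) {
    fit <- call_genotypes(ds$beta[rs, , drop = FALSE], cutoff = cutoff)
    dup <- detect_duplicates(fit$genotypes)
    tab <- merge(tab, fit$qc, by = "sample_id")
  }
  tab <- tab[match(ds$samples$sample_id, tab$sample_id), ]
  rownames(tab) <- NULL
  list(samples = tab, sex_calls = calls, genotype_fit = fit,
       duplicates = dup, concordance = conc)
}
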