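## Sex-stratified differential methylation on M-values with covariates and
## Benjamini-Hochberg FDR, effect sizes on the beta scale, and XCI
## escape/subject calling from promoter methylation.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1. NA
#' p-values are excluded from m and returned as NA.
#'
#' @param p vector of p-values in `[0,1]` (NA allowed).
#' @return vector of q-values, same length and order.
#' @export
adjust_fdr <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(q)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0,1]")
  m <- length(pv)
  o <- order(pv)
  qv <- pv[o] * m / seq_len(m)
  qv <- rev(cummin(rev(qv)))
  qv <- pmin(qv, 1)
  q[ok[o]] <- qv
  q
}

## vectorized per-row OLS of Y (probes x samples) on design X (samples x k);
## returns coef, se, t, p for column `which_col`
rowwise_ols <- function(Y, X, which_col) {
  n <- ncol(Y); k <- ncol(X)
  df <- n - k
  XtXi <- solve(crossprod(X))
  H <- X %*% XtXi                      # n x k
  coefs <- Y %*% H                     # probes x k
  fitted <- coefs %*% t(X)
  rss <- rowSums((Y - fitted)^2)
  sigma2 <- rss / df
  se <- sqrt(sigma2 * XtXi[which_col, which_col])
  tt <- coefs[, which_col] / se
  list(coef = coefs[, which_col], se = se, t = tt,
       p = 2 * pt(abs(tt), df, lower.tail = FALSE), df = df)
}

#' Sex-stratified differential methylation
#'
#' Per-CpG ordinary least squares on M-values within each sex stratum, with
#' a two-sided t-test on the phenotype coefficient and BH correction applied
#' within each stratum x chromosome family (X-in-XX, X-in-XY, Y-in-XY by
#' default). chrY probes are only ever modelled in the XY stratum — Y
#' chromosome data are meaningless in samples without a Y. The effect size
#' `delta_beta` is the difference of group mean betas
#' (reference level minus case level) for a two-level phenotype, and NA for
#' a numeric phenotype.
#'
#' @param ds [methyl_dataset()] (cg/ch probes are analysed).
#' @param phenotype name of the phenotype column in the sample sheet
#'   (two-level factor/character, or numeric).
#' @param covariates character vector of covariate column names (e.g.
#'   gestational age).
#' @param sexes per-sample `XX`/`XY`; defaults to annotated sex.
#' @param strata named list mapping stratum to the chromosomes analysed in
#'   it.
#' @return data.frame of class `dm_result`: `probe_id`, `chrom`, `stratum`,
#'   `coef` (M scale), `delta_beta`, `t`, `p`, `q`.
#' @export
stratified_dmc <- function(ds, phenotype, covariates = character(),
                           sexes = NULL,
                           strata = list(XX = "chrX", XY = c("chrX", "chrY"))) {
  stopifnot(inherits(ds, "methyl_dataset"))
  if (is.null(sexes)) sexes <- ds$samples$annotated_sex
  sheet <- ds$samples
  miss <- setdiff(c(phenotype, covariates), names(sheet))
  if (length(miss)) stop("missing sample-sheet columns: ",
                         paste(miss, collapse = ", "))
  if (any(vapply(strata, function(ch) "chrY" %in% ch, logical(1)) &
          names(strata) == "XX"))
    stop("chrY cannot be analysed in the XX stratum")
  man <- ds$manifest
  res <- list()
  for (st in names(strata)) {
    cols <- which(sexes == st)
    probes <- man$probe_id[man$chrom %in% strata[[st]] &
                             man$probe_class %in% c("cg", "ch")]
    if (!length(probes) || !length(cols)) next
    ph <- sheet[[phenotype]][cols]
    dat <- data.frame(.pheno = ph)
    for (cv in covariates) dat[[cv]] <- sheet[[cv]][cols]
    X <- stats::model.matrix(~ ., data = dat)
    if (ncol(X) + 1 > length(cols))
      stop("stratum ", st, " has too few samples (", length(cols),
           ") for the design (", ncol(X), " columns)")
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      stop("rank-deficient design in stratum ", st, "; aliased: ",
           paste(colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]],
                 collapse = ", "))
    B <- ds$beta[probes, cols, drop = FALSE]
    M <- beta_to_m(B)
    if (anyNA(M)) {
      fit <- lapply(seq_len(nrow(M)), function(i) {
        ok <- !is.na(M[i, ])
        if (sum(ok) <= ncol(X)) return(c(NA, NA, NA))
        f <- stats::lm.fit(X[ok, , drop = FALSE], M[i, ok])
        s2 <- sum(f$residuals^2) / f$df.residual
        XtXi <- solve(crossprod(X[ok, , drop = FALSE]))
        se <- sqrt(s2 * XtXi[2, 2])
        tt <- f$coefficients[2] / se
        c(f$coefficients[2], tt, 2 * pt(abs(tt), f$df.residual, lower.tail = FALSE))
      })
      fit <- do.call(rbind, fit)
      coef <- fit[, 1]; tt <- fit[, 2]; pp <- fit[, 3]
    } else {
      f <- rowwise_ols(M, X, 2L)
      coef <- f$coef; tt <- f$t; pp <- f$p
    }
    db <- rep(NA_real_, length(probes))
    if (!is.numeric(ph)) {
      lev <- levels(factor(ph))
      if (length(lev) == 2) {
        ref <- lev[1]
        db <- rowMeans(B[, ph == ref, drop = FALSE], na.rm = TRUE) -
          rowMeans(B[, ph != ref, drop = FALSE], na.rm = TRUE)
      }
    }
    d <- data.frame(probe_id = probes, chrom = man$chrom[match(probes, man$probe_id)],
                    stratum = st, coef = coef, delta_beta = db,
                    t = tt, p = pp, stringsAsFactors = FALSE)
    ## BH within stratum x chromosome-context family
    d$q <- NA_real_
    for (ctx in unique(chrom_group(d$chrom))) {
      i <- chrom_group(d$chrom) == ctx
      d$q[i] <- adjust_fdr(d$p[i])
    }
    res[[st]] <- d
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("dm_result", "data.frame")
  out
}

#' Call XCI status of X-linked genes from promoter methylation
#'
#' Uses average CpG-island promoter methylation: a gene escapes XCI when
#' its promoter is hypomethylated in both sexes (both means < `low`), and
#' is subject to XCI when the XY promoter mean is < `low` while the XX mean
#' sits in the intermediate band `[subject_lo, subject_hi]` — the averaged
#' signature of a hypomethylated active X and a hypermethylated inactive X.
#' Anything else is indeterminate. Cancer-testis promoter probes are
#' excluded when an annotation table is supplied, since their promoter
#' methylation does not track XCI status.
#'
#' @param beta probes x samples beta matrix.
#' @param promoter_map named list: gene -> character vector of promoter
#'   probe ids.
#' @param sexes per-sample `XX`/`XY` aligned to columns.
#' @param thresholds list with `low`, `subject_lo`, `subject_hi`.
#' @param annotation optional [annotate_xy()] table; probes with
#'   `ct_promoter == TRUE` are excluded.
#' @param min_cpgs minimum surviving promoter CpGs per gene.
#' @return data.frame of class `xci_calls`: `gene`, `n_cpgs`,
#'   `mean_beta_XX`, `mean_beta_XY`, `call`.
#' @export
call_xci <- function(beta, promoter_map, sexes,
                     thresholds = list(low = 0.2, subject_lo = 0.3,
                                       subject_hi = 0.7),
                     annotation = NULL, min_cpgs = 2) {
  stopifnot(ncol(beta) == length(sexes))
  if (!any(sexes == "XX") || !any(sexes == "XY"))
    stop("both sexes must be represented")
  exclude <- character()
  if (!is.null(annotation))
    exclude <- annotation$probe_id[!is.na(annotation$ct_promoter) &
                                     annotation$ct_promoter]
  out <- list()
  for (g in names(promoter_map)) {
    probes <- setdiff(intersect(promoter_map[[g]], rownames(beta)), exclude)
    if (length(probes) < min_cpgs) {
      warning("gene ", g, " has fewer than ", min_cpgs,
              " surviving promoter CpGs; omitted")
      next
    }
    mxx <- mean(beta[probes, sexes == "XX", drop = FALSE], na.rm = TRUE)
    mxy <- mean(beta[probes, sexes == "XY", drop = FALSE], na.rm = TRUE)
    th <- thresholds
    call <- if (mxx < th$low && mxy < th$low) "escape"
    else if (mxy < th$low && mxx >= th$subject_lo && mxx <= th$subject_hi)
      "subject"
    else "indeterminate"
    out[[g]] <- data.frame(gene = g, n_cpgs = length(probes),
                           mean_beta_XX = mxx, mean_beta_XY = mxy,
                           call = call, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(structure(data.frame(gene = character(), n_cpgs = integer(),
                                mean_beta_XX = numeric(),
                                mean_beta_XY = numeric(), call = character()),
                     class = c("xci_calls", "data.frame")))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("xci_calls", "data.frame")
  res
}
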