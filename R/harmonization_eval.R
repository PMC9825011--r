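## Quantifying what normalization or batch correction did to X/Y data:
## per-sample Spearman rho and RMSE by chromosome context, a parametric
## empirical-Bayes batch adjustment (ComBat-style), cohort splits, and an
## exact test of batch/sex balance.

#' Per-sample concordance between two beta matrices
#'
#' For every sample and chromosome context (autosome, chrX, chrY), the
#' Spearman rank correlation and root-mean-square error between the two
#' matrices, computed over pairwise-complete probes. chrY rows are computed
#' for XY samples only — comparing background noise in XX samples is not
#' meaningful. Ties receive average ranks.
#'
#' @param pre,post probes x samples beta matrices with identical dimnames
#'   (e.g. raw vs normalized, or pre vs post batch correction).
#' @param manifest [probe_manifest()] covering the rows.
#' @param sexes per-sample `XX`/`XY` aligned to columns.
#' @return data.frame of class `concordance_table`: `sample_id`, `context`,
#'   `sex`, `rho`, `rmse`, `n_probes`.
#' @export
per_sample_concordance <- function(pre, post, manifest, sexes) {
  stopifnot(identical(dim(pre), dim(post)),
            identical(dimnames(pre), dimnames(post)),
            ncol(pre) == length(sexes))
  grp <- chrom_group(manifest$chrom[match(rownames(pre), manifest$probe_id)])
  rows <- list(autosome = which(grp == "autosome"),
               chrX = which(grp == "chrX"),
               chrY = which(grp == "chrY"))
  out <- list()
  for (ctx in names(rows)) {
    idx <- rows[[ctx]]
    if (!length(idx)) next
    for (j in seq_len(ncol(pre))) {
      if (ctx == "chrY" && sexes[j] != "XY") next
      a <- pre[idx, j]; b <- post[idx, j]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 2) {
        warning("fewer than 2 complete pairs for sample ", colnames(pre)[j],
                ", context ", ctx)
        out[[length(out) + 1]] <- data.frame(
          sample_id = colnames(pre)[j], context = ctx, sex = sexes[j],
          rho = NA_real_, rmse = NA_real_, n_probes = sum(ok))
        next
      }
      out[[length(out) + 1]] <- data.frame(
        sample_id = colnames(pre)[j], context = ctx, sex = sexes[j],
        rho = cor(a[ok], b[ok], method = "spearman"),
        rmse = sqrt(mean((a[ok] - b[ok])^2)),
        n_probes = sum(ok), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("concordance_table", "data.frame")
  res
}

#' Summarise a concordance table
#'
#' Per-context (and per-sex for chrX) min/median/max of rho and RMSE — the
#' ranges normalization evaluations report.
#'
#' @param ct [per_sample_concordance()] result.
#' @return data.frame, one row per context x sex.
#' @export
summarize_concordance <- function(ct) {
  sp <- split(ct, list(ct$context, ct$sex), drop = TRUE)
  res <- do.call(rbind, lapply(sp, function(d) data.frame(
    context = d$context[1], sex = d$sex[1], n = nrow(d),
    rho_min = min(d$rho, na.rm = TRUE),
    rho_median = median(d$rho, na.rm = TRUE),
    rho_max = max(d$rho, na.rm = TRUE),
    rmse_min = min(d$rmse, na.rm = TRUE),
    rmse_median = median(d$rmse, na.rm = TRUE),
    rmse_max = max(d$rmse, na.rm = TRUE))))
  rownames(res) <- NULL
  res
}

## ---- parametric empirical-Bayes batch adjustment ----------------------

#' Batch adjustment by the parametric empirical-Bayes location/scale model
#'
#' Per-probe standardization, EB-shrunken per-batch location and scale
#' estimates (normal/inverse-gamma conjugate priors with moment-matched
#' hyperparameters), and back-transformation — the canonical parametric
#' ComBat algorithm. Operates on M-values by default usage; the function is
#' scale-agnostic. With a single batch the input is returned unchanged
#' (there is no batch effect to estimate).
#'
#' @param m probes x samples matrix (typically M-values).
#' @param batch per-sample batch labels (>= 2 samples per batch).
#' @param covariates optional data.frame of biological covariates to
#'   protect (must not be confounded with batch).
#' @return adjusted matrix, same shape and dimnames as `m`.
#' @export
combat_adjust <- function(m, batch, covariates = NULL) {
  stopifnot(is.matrix(m), ncol(m) == length(batch))
  if (anyNA(m)) stop("missing values are not supported; impute or subset first")
  batch <- factor(batch)
  K <- nlevels(batch)
  if (K == 1) return(m)
  n_k <- table(batch)
  if (any(n_k < 2)) stop("every batch needs >= 2 samples; offending: ",
                         paste(names(n_k)[n_k < 2], collapse = ", "))
  n <- ncol(m)
  Xb <- stats::model.matrix(~ 0 + batch)
  Xc <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    Xc <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  }
  X <- cbind(Xb, Xc)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("design is confounded (batch aliased with covariates): ",
         paste(aliased, collapse = ", "))
  }
  B <- solve(crossprod(X), crossprod(X, t(m)))          # (K+p) x probes
  grand <- crossprod(as.numeric(n_k) / n, B[seq_len(K), , drop = FALSE])
  resid <- m - t(X %*% B)
  var_pooled <- rowMeans(resid^2)
  if (any(var_pooled <= 0))
    var_pooled[var_pooled <= 0] <- .Machine$double.eps
  stand_mean <- matrix(grand, nrow(m), n)
  if (!is.null(Xc))
    stand_mean <- stand_mean + t(Xc %*% B[-seq_len(K), , drop = FALSE])
  s <- (m - stand_mean) / sqrt(var_pooled)

  gamma_hat <- t(vapply(levels(batch), function(b)
    rowMeans(s[, batch == b, drop = FALSE]), numeric(nrow(m))))
  delta_hat <- t(vapply(levels(batch), function(b)
    apply(s[, batch == b, drop = FALSE], 1, var), numeric(nrow(m))))

  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, var)
  aprior <- apply(delta_hat, 1, function(d) {
    mn <- mean(d); s2 <- var(d); (2 * s2 + mn^2) / s2
  })
  bprior <- apply(delta_hat, 1, function(d) {
    mn <- mean(d); s2 <- var(d); (mn * s2 + mn^3) / s2
  })

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  eb_ok <- nrow(m) >= 2 && all(is.finite(aprior)) && all(is.finite(bprior)) &&
    all(is.finite(t2)) && all(t2 > 0)
  if (eb_ok) {
    for (k in seq_len(K)) {
      nb <- as.numeric(n_k[k])
      g_old <- gamma_hat[k, ]; d_old <- delta_hat[k, ]
      sk <- s[, batch == levels(batch)[k], drop = FALSE]
      for (it in seq_len(100)) {
        g_new <- (t2[k] * nb * gamma_hat[k, ] + d_old * gamma_bar[k]) /
          (t2[k] * nb + d_old)
        sse <- rowSums((sk - g_new)^2)
        d_new <- (0.5 * sse + bprior[k]) / (nb / 2 + aprior[k] - 1)
        change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                      abs(d_new - d_old) / d_old)
        g_old <- g_new; d_old <- d_new
        if (change < 1e-5) break
      }
      gamma_star[k, ] <- g_old
      delta_star[k, ] <- d_old
    }
  }

  out <- s
  for (k in seq_len(K)) {
    cols <- batch == levels(batch)[k]
    out[, cols] <- (s[, cols, drop = FALSE] - gamma_star[k, ]) /
      sqrt(delta_star[k, ])
  }
  out <- out * sqrt(var_pooled) + stand_mean
  dimnames(out) <- dimnames(m)
  out
}

#' Cohort splits for batch-correction evaluation
#'
#' Returns the full cohort, sex-stratified halves, and seeded random halves
#' balanced by sex (each sex sampled half-and-half), each with the exact
#' p-value for batch x split-membership independence — the balance check
#' required before applying batch correction.
#'
#' @param sheet [sample_sheet()] (or any data.frame with `sample_id`,
#'   `batch` and the sex column).
#' @param seed integer seed for the random halves.
#' @param sex_col column holding `XX`/`XY` labels.
#' @return named list of splits; each has `name`, `sample_ids`,
#'   `sex_table`, `balance_p`.
#' @export
make_splits <- function(sheet, seed, sex_col = "annotated_sex") {
  stopifnot(all(c("sample_id", "batch", sex_col) %in% names(sheet)))
  sex <- sheet[[sex_col]]
  if (!any(sex == "XX") || !any(sex == "XY"))
    stop("both sex strata must be non-empty")
  set.seed(seed)
  half_id <- rep(NA_character_, nrow(sheet))
  for (sx in c("XX", "XY")) {
    idx <- which(sex == sx)
    a <- sample(idx, floor(length(idx) / 2))
    half_id[a] <- "A"
    half_id[setdiff(idx, a)] <- "B"
  }
  mk <- function(name, ids, tab) {
    list(name = name, sample_ids = ids,
         sex_table = table(sex[sheet$sample_id %in% ids]),
         balance_p = exact_balance_test(tab))
  }
  sex_batch <- table(sheet$batch, sex)
  half_batch <- table(sheet$batch, half_id)
  list(
    full = mk("full", sheet$sample_id, sex_batch),
    XX_only = mk("XX_only", sheet$sample_id[sex == "XX"], sex_batch),
    XY_only = mk("XY_only", sheet$sample_id[sex == "XY"], sex_batch),
    random_half_A = mk("random_half_A", sheet$sample_id[half_id == "A"], half_batch),
    random_half_B = mk("random_half_B", sheet$sample_id[half_id == "B"], half_batch)
  )
}

## ---- exact r x c independence test ------------------------------------

log_table_prob <- function(tab, lr, lc, ln) {
  sum(lr) + sum(lc) - ln - sum(lgamma(tab + 1))
}

## enumerate all tables with the given margins, accumulating probability of
## tables at most as probable as the observed one; aborts (returns NA) when
## more than `budget` tables are visited
enumerate_tables <- function(rs, cs, logp_obs, lr, lc, ln, budget = 2e5) {
  r <- length(rs); cc <- length(cs)
  count <- 0L
  psum <- 0
  tab <- matrix(0L, r, cc)
  rec_row <- function(i, rem_cols) {
    if (count > budget) return(NA_real_)
    if (i == r) {
      tab[r, ] <<- rem_cols
      count <<- count + 1L
      lp <- log_table_prob(tab, lr, lc, ln)
      if (lp <= logp_obs + 1e-7) psum <<- psum + exp(lp)
      return(0)
    }
    fill_cell <- function(j, left, cols) {
      if (count > budget) return(NA_real_)
      if (j == cc) {
        if (left > cols[cc]) return(0)
        tab[i, cc] <<- left
        cols[cc] <- cols[cc] - left
        return(rec_row(i + 1L, cols))
      }
      lo <- max(0L, left - sum(cols[(j + 1):cc]))
      hi <- min(left, cols[j])
      if (lo > hi) return(0)
      for (v in lo:hi) {
        tab[i, j] <<- v
        cols2 <- cols
        cols2[j] <- cols2[j] - v
        bad <- fill_cell(j + 1L, left - v, cols2)
        if (is.na(bad)) return(NA_real_)
      }
      0
    }
    fill_cell(1L, rs[i], rem_cols)
  }
  bad <- rec_row(1L, cs)
  if (is.na(bad) || count > budget) return(NA_real_)
  psum
}

#' Exact test of independence for an r x c contingency table
#'
#' Two-sided Fisher-style exact p-value by full enumeration of tables with
#' the observed margins (summing the null probability of every table at
#' most as probable as the observed one). When enumeration exceeds the
#' workload budget, a seeded Monte-Carlo estimate over tables drawn with
#' fixed margins is returned instead, with the standard error attached as
#' an attribute.
#'
#' @param tab matrix of non-negative integer counts.
#' @param mc_reps Monte-Carlo replicates for the fallback.
#' @param seed seed for the Monte-Carlo fallback.
#' @return p-value (with attributes `method`, and `mc_se` when estimated).
#' @export
exact_balance_test <- function(tab, mc_reps = 1e5, seed = 1) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  n <- sum(tab)
  if (n == 0) stop("empty table")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    warning("degenerate table (zero margin); p = 1")
    return(structure(1, method = "degenerate"))
  }
  lr <- lgamma(rs + 1); lc <- lgamma(cs + 1); ln <- lgamma(n + 1)
  logp_obs <- log_table_prob(tab, lr, lc, ln)
  p <- enumerate_tables(as.integer(rs), as.integer(cs), logp_obs, lr, lc, ln)
  if (!is.na(p))
    return(structure(min(p, 1), method = "enumeration"))
  set.seed(seed)
  sim <- stats::r2dtable(mc_reps, as.integer(rs), as.integer(cs))
  lp <- vapply(sim, log_table_prob, numeric(1), lr = lr, lc = lc, ln = ln)
  hit <- lp <= logp_obs + 1e-7
  p <- mean(hit)
  structure(p, method = "monte-carlo",
            mc_se = sqrt(p * (1 - p) / mc_reps))
}
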