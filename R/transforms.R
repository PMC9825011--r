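## Elementary methylation transforms: beta, M-value, detection p.

#' Beta values from methylated/unmethylated intensities
#'
#' beta = M / (M + U + offset). The offset (Illumina convention, default 100)
#' regularises the ratio at low total intensity.
#'
#' @param meth,unmeth non-negative intensity matrices of identical shape.
#' @param offset non-negative regularisation constant.
#' @return matrix of beta values in `[0,1]`; missing intensities propagate.
#' @export
compute_beta <- function(meth, unmeth, offset = 100) {
  stopifnot(identical(dim(meth), dim(unmeth)), offset >= 0)
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE))
    stop("negative intensities are not allowed")
  meth / (meth + unmeth + offset)
}

#' Convert beta values to M-values
#'
#' M = log2(beta / (1 - beta)) with beta clipped to `[clip, 1 - clip]` so the
#' result is always finite.
#'
#' @param beta matrix (or vector) of beta values in `[0,1]`.
#' @param clip clipping bound in `(0, 0.5)`.
#' @return M-values, same shape as `beta`.
#' @export
beta_to_m <- function(beta, clip = 0.001) {
  stopifnot(clip > 0, clip < 0.5)
  b <- pmin(pmax(beta, clip), 1 - clip)
  log2(b / (1 - b))
}

#' Convert M-values back to beta values
#'
#' Inverse logit on the log2 scale; recovers the clipped beta exactly.
#'
#' @param m M-value matrix or vector.
#' @return beta values in `(0,1)`.
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

#' Detection p-values from a per-sample background model
#'
#' For each probe and sample, the total intensity M + U is compared to a
#' Gaussian background distribution estimated from negative-control probes:
#' p = 1 - Phi((M + U - mu_bg) / sd_bg). High p means the probe's signal is
#' indistinguishable from background fluorescence (a failed measurement). A
#' single pooled background per sample (both channels combined) is used; a
#' precomputed detection-p matrix can always be substituted in the dataset.
#'
#' @param meth,unmeth intensity matrices.
#' @param negctrl data.frame with columns `sample_id`, `mu_bg`, `sd_bg`
#'   (background total-intensity mean and sd per sample).
#' @return matrix of detection p-values in `[0,1]`.
#' @export
compute_detection_p <- function(meth, unmeth, negctrl) {
  stopifnot(identical(dim(meth), dim(unmeth)))
  req <- c("sample_id", "mu_bg", "sd_bg")
  if (!all(req %in% names(negctrl)))
    stop("negctrl must have columns sample_id, mu_bg, sd_bg")
  sid <- colnames(meth)
  missing_s <- setdiff(sid, negctrl$sample_id)
  if (length(missing_s))
    stop("no background summary for samples: ", paste(missing_s, collapse = ", "))
  idx <- match(sid, negctrl$sample_id)
  mu <- negctrl$mu_bg[idx]
  sd_ <- negctrl$sd_bg[idx]
  if (any(sd_ <= 0)) stop("sd_bg must be > 0 for every sample")
  total <- meth + unmeth
  z <- sweep(sweep(total, 2, mu, "-"), 2, sd_, "/")
  p <- pnorm(z, lower.tail = FALSE)
  dimnames(p) <- dimnames(meth)
  p
}
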