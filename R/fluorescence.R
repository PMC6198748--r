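#' Call denatured-collagen fluorescence positivity
#'
#' Qualitative yes/no call of whether a ruptured fibril is fluorescent above
#' background after collagen-hybridizing-peptide staining: the fibril is
#' positive when its mean fluorescence exceeds the background mean by more
#' than `k_sigma` background standard deviations. The margin is the distance
#' of the fibril mean from the threshold in background-sd units, so the call
#' is invariant to any common rescaling of the image.
#'
#' @param image A `fluor_image` (see [make_fluorescence_image()]) or a numeric
#'   matrix of fluorescence counts.
#' @param fibril_mask,background_mask Disjoint, non-empty logical matrices.
#' @param k_sigma Threshold multiplier; default 3.
#' @return List `positive` (logical), `margin` (numeric), `fibril_mean`,
#'   `background_mean`, `background_sd`.
#' @export
classify_fibril <- function(image, fibril_mask, background_mask, k_sigma = 3) {
  fl <- if (inherits(image, "fluor_image")) image$fluorescence else image
  if (!any(fibril_mask) || !any(background_mask)) stop("masks must be non-empty")
  if (any(fibril_mask & background_mask)) stop("masks must be disjoint")
  mf <- mean(fl[fibril_mask])
  mb <- mean(fl[background_mask])
  sb <- stats::sd(fl[background_mask])
  if (!is.finite(sb)) sb <- 0
  if (sb == 0) {
    positive <- mf > mb
    margin <- if (positive) Inf else 0
  } else {
    thr <- mb + k_sigma * sb
    positive <- mf > thr
    margin <- (mf - thr) / sb
  }
  list(positive = positive, margin = margin, fibril_mean = mf,
       background_mean = mb, background_sd = sb)
}

#' Fibril footprint from the brightfield channel
#'
#' The brightfield silhouette shows the fibril darker than the field; pixels
#' below `mean - k * sd` of the channel, dilated by `dilate_px`, form the mask.
#'
#' @param image A `fluor_image` or brightfield matrix.
#' @param k Threshold multiplier; default 2.
#' @param dilate_px Square dilation half-width in pixels; default 1.
#' @return Logical matrix.
#' @export
mask_from_brightfield <- function(image, k = 2, dilate_px = 1) {
  bf <- if (inherits(image, "fluor_image")) image$brightfield else image
  m <- bf < mean(bf) - k * stats::sd(bf)
  if (dilate_px > 0 && any(m)) {
    out <- m
    for (dr in -dilate_px:dilate_px) for (dc in -dilate_px:dilate_px) {
      if (dr == 0 && dc == 0) next
      sh <- matrix(FALSE, nrow(m), ncol(m))
      rs <- seq_len(nrow(m)) - dr; cs <- seq_len(ncol(m)) - dc
      okr <- rs >= 1 & rs <= nrow(m); okc <- cs >= 1 & cs <= ncol(m)
      sh[okr, okc] <- m[rs[okr], cs[okc]]
      out <- out | sh
    }
    m <- out
  }
  m
}
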