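#' Least-squares background plane subtraction
#'
#' Fits a plane to the pixels outside the fibril mask and subtracts it from the
#' whole map, levelling substrate tilt.
#'
#' @param map A `heightmap`.
#' @param mask Logical matrix of fibril pixels; default: pixels above half the
#'   map's robust maximum are treated as fibril.
#' @return A `heightmap` with the plane removed.
#' @export
.dilate <- function(m, k) {
  if (k <= 0 || !any(m)) return(m)
  out <- m
  for (dr in -k:k) for (dc in -k:k) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(FALSE, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)) - dr; cs <- seq_len(ncol(m)) - dc
    okr <- rs >= 1 & rs <= nrow(m); okc <- cs >= 1 & cs <= ncol(m)
    sh[okr, okc] <- m[rs[okr], cs[okc]]
    out <- out | sh
  }
  out
}

subtract_plane <- function(map, mask = NULL) {
  H <- map$heights
  if (is.null(mask)) {
    # glass level from the outermost rows (the fibril runs axially through the
    # map interior); exclude the whole footprint, including low flanks
    edge <- H[c(1:min(3, nrow(H)), max(1, nrow(H) - 2):nrow(H)), ]
    bg <- stats::median(edge)
    spread <- stats::mad(edge)
    thr <- bg + max(5 * spread, 0.05 * (max(H) - bg))
    mask <- .dilate(H > thr, 3L)
  }
  idx <- which(!mask)
  if (length(idx) < 3) stop("too few background pixels to fit a plane")
  rc <- arrayInd(idx, dim(H))
  fit <- stats::lsfit(rc, H[idx])
  r <- row(H); c <- col(H)
  H <- H - (fit$coefficients[1] + fit$coefficients[2] * r +
              fit$coefficients[3] * c)
  map$heights <- H
  map
}

#' Trace the fibril centerline on a height map
#'
#' Ridge following for a mostly axial (left-to-right) fibril: within each
#' column whose maximum exceeds `min_height`, the centerline row is the height-
#' weighted centroid of the pixels near the column maximum, then the row track
#' is smoothed by a short running mean. Coordinates are pixel centres, arc
#' length in nm from the first traced column.
#'
#' @param map A `heightmap`.
#' @param min_height Minimum column maximum (nm) for a column to count as
#'   containing the fibril; default half the map maximum.
#' @param smooth_px Running-mean width (columns) applied to the row track.
#' @return data.frame `col`, `row` (pixel indices, row fractional), `x_nm`,
#'   `y_nm`, `s_nm` (arc length), `height_nm` (height at the centerline).
#' @export
trace_centerline <- function(map, min_height = NULL, smooth_px = 5) {
  H <- map$heights
  px <- map$pixel_nm
  if (is.null(min_height)) min_height <- 0.5 * max(H)
  colmax <- apply(H, 2, max)
  cols <- which(colmax >= min_height)
  if (length(cols) < 2) stop("no fibril ridge found above min_height")
  cols <- seq(min(cols), max(cols))  # contiguous span
  rows <- vapply(cols, function(j) {
    h <- H[, j]
    top <- which.max(h)
    win <- seq(max(1, top - 3), min(nrow(H), top + 3))
    w <- pmax(h[win], 0)
    if (sum(w) == 0) return(as.numeric(top))
    sum(win * w) / sum(w)
  }, numeric(1))
  rows <- zoo::rollapply(rows, width = smooth_px, FUN = mean, partial = TRUE)
  x <- (cols - 0.5) * px
  y <- (rows - 0.5) * px
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  hgt <- vapply(seq_along(cols), function(i) {
    r0 <- floor(rows[i]); fr <- rows[i] - r0
    r1 <- min(r0 + 1, nrow(H))
    (1 - fr) * H[max(r0, 1), cols[i]] + fr * H[r1, cols[i]]
  }, numeric(1))
  data.frame(col = cols, row = rows, x_nm = x, y_nm = y, s_nm = s,
             height_nm = hgt)
}

#' Average cross-sectional profile over a short fibril segment
#'
#' Background-plane-subtracts the map, traces the centerline, and averages the
#' cross-profiles (columns re-centred on the centerline) over the first
#' `segment_nm` of the fibril. Intended for the straight imaging segment used
#' for area measurement.
#'
#' @param map A `heightmap`.
#' @param segment_nm Length of fibril to average over; default 500.
#' @param halfwidth_nm Half-width of the reported profile; default 2.5x the
#'   fibril's apparent radius.
#' @param plane Subtract the background plane first; default TRUE.
#' @return data.frame `offset_nm` (signed perpendicular offset), `height_nm`
#'   (mean height), with attribute `n_profiles` (number of scanlines averaged).
#' @export
average_profile <- function(map, segment_nm = 500, halfwidth_nm = NULL,
                            plane = TRUE) {
  if (plane) map <- subtract_plane(map)
  cl <- trace_centerline(map)
  use <- cl$s_nm <= segment_nm
  if (sum(use) < 2) stop("segment shorter than 2 scanlines; enlarge segment_nm")
  px <- map$pixel_nm
  H <- map$heights
  peak <- max(cl$height_nm[use])
  if (is.null(halfwidth_nm)) halfwidth_nm <- 2.5 * peak
  off <- seq(-halfwidth_nm, halfwidth_nm, by = px)
  rows_all <- seq_len(nrow(H))
  profs <- vapply(which(use), function(i) {
    yq <- cl$row[i] + off / px
    stats::approx(rows_all, H[, cl$col[i]], xout = yq, rule = 2)$y
  }, numeric(length(off)))
  out <- data.frame(offset_nm = off, height_nm = rowMeans(profs))
  attr(out, "n_profiles") <- sum(use)
  out
}

#' Cross-sectional area from an averaged profile
#'
#' Trapezoidal integral of the height above zero across the profile. With the
#' fibril adsorbed on glass this slightly overestimates the true cross-section
#' (tip convolution is not corrected).
#'
#' @param profile data.frame `offset_nm`, `height_nm` (baseline-corrected).
#' @return Area in um^2.
#' @export
cross_sectional_area <- function(profile) {
  h <- pmax(profile$height_nm, 0)
  if (all(h == 0)) {
    warning("profile is all zero; returning zero area")
    return(0)
  }
  pracma::trapz(profile$offset_nm, h) / 1e6   # nm^2 -> um^2
}

#' D-band period of a fibril
#'
#' Estimates the dominant axial period of the centerline height signal: the
#' signal is mean-removed, Hann-windowed, zero-padded, and the periodogram
#' peak is refined by parabolic interpolation over three frequency bins. A
#' period is reported only if the peak rises clearly above the spectral noise
#' floor.
#'
#' @param map A `heightmap`, or a `data.frame` from [trace_centerline()].
#' @param min_period_nm,max_period_nm Search band for the period; defaults
#'   30-150 nm bracket the conserved collagen D-band range.
#' @param peak_snr Minimum ratio of peak power to the median in-band power;
#'   below it "no periodicity detected" is raised. Default 10.
#' @return Period in nm.
#' @export
dband_period <- function(map, min_period_nm = 30, max_period_nm = 150,
                         peak_snr = 10) {
  cl <- if (is.data.frame(map)) map else trace_centerline(map)
  h <- cl$height_nm
  # axial coordinate from a strongly low-passed path: raw tracing wiggle
  # inflates the arc length and would bias the period upward
  ylp <- zoo::rollapply(cl$y_nm, width = min(25, length(h)), FUN = mean,
                        partial = TRUE)
  s <- c(0, cumsum(sqrt(diff(cl$x_nm)^2 + diff(ylp)^2)))
  ds <- stats::median(diff(s))
  n <- length(h)
  if (n * ds < 10 * max_period_nm)
    warning("centerline shorter than ~10 periods; estimate may be unstable")
  x <- (h - mean(h)) * (0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)))
  nfft <- 2^ceiling(log2(n * 8))
  P <- Mod(stats::fft(c(x, rep(0, nfft - n))))^2
  freq <- seq(0, nfft - 1) / (nfft * ds)
  band <- which(freq >= 1 / max_period_nm & freq <= 1 / min_period_nm)
  if (length(band) < 3) stop("search band too narrow for the trace length")
  k <- band[which.max(P[band])]
  if (P[k] < peak_snr * stats::median(P[band]))
    stop("no periodicity detected above the spectral noise floor")
  # parabolic refinement on log power
  if (k > 1 && k < nfft) {
    lp <- log(pmax(P[(k - 1):(k + 1)], .Machine$double.xmin))
    den <- lp[1] - 2 * lp[2] + lp[3]
    delta <- if (den < 0) 0.5 * (lp[1] - lp[3]) / den else 0
  } else delta <- 0
  1 / ((k - 1 + delta) / (nfft * ds))
}

#' Detect kinks along a fibril centerline
#'
#' A kink is a sharp bend of the centerline: at each arc position the tangent
#' direction is estimated by least squares over the trailing and leading
#' `window_nm`, and positions where the direction change exceeds
#' `angle_threshold_deg` are marked, with non-maximum suppression within one
#' window. Undamaged segments are the intervals between consecutive damage
#' sites (including the two anchored ends) longer than one window.
#'
#' @param map A `heightmap`, or a `data.frame` from [trace_centerline()].
#' @param angle_threshold_deg Bend angle that qualifies as a kink; default 20.
#' @param window_nm Tangent-estimation window; default 200.
#' @return A `kink_annotation`: list `positions_nm`, `count`,
#'   `mean_spacing_nm` (`NA` when fewer than 2 kinks), `undamaged_segments`
#'   (data.frame `start_nm`, `end_nm`).
#' @export
detect_kinks <- function(map, angle_threshold_deg = 20, window_nm = 200) {
  cl <- if (is.data.frame(map)) map else trace_centerline(map)
  s <- cl$s_nm; x <- cl$x_nm; y <- cl$y_nm
  L <- s[length(s)]
  if (L < 2 * window_nm) stop("centerline shorter than two windows")
  tang <- function(idx) {
    if (length(idx) < 2) return(NA_real_)
    atan2(stats::cov(x[idx], y[idx]), stats::var(x[idx])) # slope angle via LS
  }
  w <- max(3L, round(window_nm / stats::median(diff(s))))
  n <- length(s)
  if (n < 2 * w + 2) stop("centerline shorter than two windows")
  dtheta <- rep(NA_real_, n)
  for (i in seq.int(w + 1L, n - w)) {
    a <- tang(i:(i + w)) - tang((i - w):i)
    dtheta[i] <- abs(atan2(sin(a), cos(a))) * 180 / pi
  }
  cand <- which(!is.na(dtheta) & dtheta > angle_threshold_deg)
  # non-maximum suppression within one window
  pos <- numeric(0)
  while (length(cand) > 0) {
    best <- cand[which.max(dtheta[cand])]
    pos <- c(pos, s[best])
    cand <- cand[abs(s[cand] - s[best]) > window_nm]
  }
  pos <- sort(pos)
  count <- length(pos)
  spacing <- if (count >= 2) mean(diff(pos)) else NA_real_
  bounds <- c(0, pos, L)
  seg <- data.frame(start_nm = bounds[-length(bounds)], end_nm = bounds[-1])
  seg <- seg[seg$end_nm - seg$start_nm > window_nm, , drop = FALSE]
  structure(list(positions_nm = pos, count = count,
                 mean_spacing_nm = spacing, undamaged_segments = seg),
            class = "kink_annotation")
}

#' @export
print.kink_annotation <- function(x, ...) {
  cat(sprintf("Kinks: %d", x$count))
  if (x$count >= 2) cat(sprintf(", mean spacing %.0f nm", x$mean_spacing_nm))
  cat(sprintf("; %d undamaged segment(s)\n", nrow(x$undamaged_segments)))
  invisible(x)
}

#' Height loss between pre- and post-rupture maps
#'
#' Mean centerline height before rupture, absolute loss after, and the loss as
#' a percentage of the pre-rupture height. Both maps are plane-subtracted and
#' centerline-traced independently.
#'
#' @param before,after `heightmap`s of the same fibril before and after the
#'   tensile test.
#' @return Named list `mean_before_nm`, `loss_nm`, `normalized_loss_pct`.
#' @export
height_loss <- function(before, after) {
  hb <- mean(trace_centerline(subtract_plane(before))$height_nm)
  ha <- mean(trace_centerline(subtract_plane(after))$height_nm)
  if (hb <= 0) stop("pre-rupture mean height must be positive")
  loss <- hb - ha
  list(mean_before_nm = hb, loss_nm = loss,
       normalized_loss_pct = 100 * loss / hb)
}
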