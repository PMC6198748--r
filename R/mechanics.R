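#' Detect the rupture instant in a lateral-force trace
#'
#' Rupture appears as a sudden, precipitous fall in load: the largest
#' single-sample drop in the trace. The drop is accepted only if it exceeds
#' `threshold` times the noise level of the post-drop (pure friction) window;
#' for noiseless traces any strictly positive drop qualifies.
#'
#' @param force_uN Numeric force trace (uN), or a data.frame with a `force_uN`
#'   column.
#' @param threshold Multiple of the post-drop standard deviation the drop must
#'   exceed; default 5.
#' @return Index of the last sample before the drop.
#' @export
detect_rupture <- function(force_uN, threshold = 5) {
  if (is.data.frame(force_uN)) force_uN <- force_uN$force_uN
  n <- length(force_uN)
  if (n < 3) stop("force trace must have at least 3 samples")
  steps <- diff(force_uN)
  k <- which.min(steps)
  drop <- -steps[k]
  post <- force_uN[seq(k + 1, n)]
  noise <- if (length(post) >= 2) stats::sd(post) else 0
  if (drop <= 0 || (noise > 0 && drop <= threshold * noise))
    stop("no rupture detected: no force drop exceeds the noise threshold")
  k
}

#' Subtract the post-rupture friction background
#'
#' The tip-glass friction appears as a constant noisy level; its mean over the
#' post-rupture window is subtracted from the whole trace.
#'
#' @inheritParams detect_rupture
#' @param rupture_index Index from [detect_rupture()].
#' @param min_window Minimum number of post-rupture samples required to
#'   estimate the background; default 10.
#' @return The background-subtracted force trace (same type as the input).
#' @export
subtract_background <- function(force_uN, rupture_index, min_window = 10) {
  df <- NULL
  if (is.data.frame(force_uN)) { df <- force_uN; force_uN <- df$force_uN }
  n <- length(force_uN)
  if (rupture_index < 1 || rupture_index >= n) stop("rupture_index out of range")
  post <- force_uN[seq(rupture_index + 1, n)]
  if (length(post) < min_window)
    stop(sprintf("post-rupture window has %d samples; at least %d required",
                 length(post), min_window))
  out <- force_uN - mean(post)
  if (!is.null(df)) { df$force_uN <- out; out <- df }
  out
}

#' Adjacent averaging
#'
#' Centered moving average of odd width (default 5 points, the smoothing used
#' on the raw force data); windows shrink symmetrically at the edges.
#'
#' @inheritParams detect_rupture
#' @param window Odd window width; `1` is the identity.
#' @return Smoothed trace (same type as the input).
#' @export
smooth_adjacent <- function(force_uN, window = 5) {
  df <- NULL
  if (is.data.frame(force_uN)) { df <- force_uN; force_uN <- df$force_uN }
  if (window %% 2 != 1 || window < 1) stop("window must be odd and >= 1")
  out <- if (window == 1) force_uN else
    zoo::rollapply(force_uN, width = window, FUN = mean, partial = TRUE)
  if (!is.null(df)) { df$force_uN <- out; out <- df }
  out
}

#' Synchronize force and video records at the rupture instant
#'
#' Shifts the video time axis so that the last frame with the fibril present
#' coincides with the last force sample before the load drop, then linearly
#' interpolates the midpoint deflection onto the force timestamps. Force
#' samples outside the (shifted) video span are dropped.
#'
#' @param force data.frame `time_s`, `force_uN` (500 Hz typical).
#' @param video data.frame `time_s`, `deflection_um` (20 fps typical).
#' @param rupture_force_index Index from [detect_rupture()].
#' @param rupture_frame_index Index of the last video frame in which the
#'   fibril is present (a human call on real video; annotated by the
#'   generator for synthetic data).
#' @return data.frame `time_s`, `deflection_um`, `force_uN`, with attribute
#'   `rupture_index` giving the rupture row in the aligned series.
#' @export
synchronize <- function(force, video, rupture_force_index, rupture_frame_index) {
  if (rupture_force_index < 1 || rupture_force_index > nrow(force) ||
      rupture_frame_index < 1 || rupture_frame_index > nrow(video))
    stop("rupture indices must lie within their traces")
  shift <- force$time_s[rupture_force_index] - video$time_s[rupture_frame_index]
  tv <- video$time_s + shift
  keep <- force$time_s >= min(tv) & force$time_s <= max(tv)
  if (!any(keep)) stop("force and video records do not overlap after alignment")
  t_out <- force$time_s[keep]
  defl <- stats::approx(tv, video$deflection_um, xout = t_out)$y
  out <- data.frame(time_s = t_out, deflection_um = defl,
                    force_uN = force$force_uN[keep])
  attr(out, "rupture_index") <- sum(keep & seq_len(nrow(force)) <= rupture_force_index)
  out
}

#' Bowstring strain from midpoint deflection
#'
#' A fibril of anchored length `L0` pulled laterally at its midpoint by `d`
#' forms two straight arms of length `sqrt((L0/2)^2 + d^2)`; the engineering
#' strain is
#' \deqn{\varepsilon = \frac{2\sqrt{(L_0/2)^2 + d^2} - L_0}{L_0} \times 100\%}
#'
#' @param deflection_um Midpoint deflection d in um (>= 0; vector allowed).
#' @param length_um Anchored segment length L0 in um.
#' @return Strain in percent.
#' @export
bowstring_strain <- function(deflection_um, length_um) {
  if (any(deflection_um < 0)) stop("deflection must be non-negative")
  if (length_um <= 0) stop("segment length must be positive")
  100 * (2 * sqrt((length_um / 2)^2 + deflection_um^2) - length_um) / length_um
}

#' Fibril tension from lateral probe force in bowstring geometry
#'
#' The lateral force is the sum of the transverse components of the two arm
#' tensions: `F = 2 T d / sqrt((L0/2)^2 + d^2)`, hence
#' \deqn{T = \frac{F \sqrt{(L_0/2)^2 + d^2}}{2 d}}
#' Tension diverges as `d -> 0`, so evaluation is restricted to strictly
#' positive deflections (in practice, to deflections beyond full-tension
#' onset).
#'
#' @param force_uN Lateral force in uN (vector allowed).
#' @param deflection_um Midpoint deflection in um (> 0).
#' @param length_um Segment length L0 in um.
#' @return Tension in uN.
#' @export
bowstring_tension <- function(force_uN, deflection_um, length_um) {
  if (any(deflection_um <= 0)) stop("deflection must be strictly positive")
  force_uN * sqrt((length_um / 2)^2 + deflection_um^2) / (2 * deflection_um)
}

#' Estimate full-tension onset from the force-deflection record
#'
#' Before the bowstring is taut the probe sees only friction; after, the force
#' rises with deflection. The onset is located as the breakpoint of a
#' two-segment fit (constant before, straight line after) minimizing the
#' residual sum of squares over candidate breakpoints.
#'
#' @param aligned Aligned series from [synchronize()] (pre-rupture rows are
#'   used; pass the rupture row via `rupture_index`, default the attribute set
#'   by [synchronize()]).
#' @param rupture_index Last pre-rupture row.
#' @param n_candidates Number of evenly spaced candidate breakpoints.
#' @return The row index of the first sample at full tension.
#' @export
estimate_full_tension <- function(aligned,
                                  rupture_index = attr(aligned, "rupture_index"),
                                  n_candidates = 200) {
  d <- aligned$deflection_um[seq_len(rupture_index)]
  f <- aligned$force_uN[seq_len(rupture_index)]
  n <- length(d)
  if (n < 10) stop("too few pre-rupture samples to locate full tension")
  cands <- unique(pmax(3, pmin(n - 3, round(seq(3, n - 3,
                                                length.out = n_candidates)))))
  rss <- vapply(cands, function(k) {
    r1 <- f[1:k] - mean(f[1:k])
    fit <- stats::lsfit(d[(k + 1):n], f[(k + 1):n])
    sum(r1^2) + sum(fit$residuals^2)
  }, numeric(1))
  cands[which.min(rss)] + 1L
}

#' Assemble a stress-strain curve from an aligned pull record
#'
#' Converts the aligned (deflection, force) series to (strain %, stress MPa):
#' strain from [bowstring_strain()], stress as [bowstring_tension()] divided by
#' the dry cross-sectional area (uN / um^2 = MPa). Samples before full-tension
#' onset (a mix of bending and stretching) and after rupture are discarded, so
#' the curve typically starts at a few percent strain rather than zero.
#'
#' @inheritParams estimate_full_tension
#' @param full_tension_index First row at full tension; default estimated by
#'   [estimate_full_tension()]. A manual override may be supplied.
#' @param dry_area_um2 Dry cross-sectional area in um^2.
#' @param length_um Segment length L0 in um.
#' @return A `stress_strain_curve`: data.frame `strain_pct`, `stress_MPa`,
#'   strictly increasing in strain, last row = rupture point.
#' @export
build_stress_strain <- function(aligned, dry_area_um2, length_um,
                                rupture_index = attr(aligned, "rupture_index"),
                                full_tension_index = NULL) {
  if (dry_area_um2 <= 0) stop("dry area must be positive")
  if (is.null(full_tension_index))
    full_tension_index <- estimate_full_tension(aligned, rupture_index)
  if (full_tension_index >= rupture_index)
    stop("full-tension onset must precede rupture; no retained data points")
  rows <- seq(full_tension_index, rupture_index)
  d <- aligned$deflection_um[rows]
  f <- aligned$force_uN[rows]
  ok <- d > 0
  strain <- bowstring_strain(d[ok], length_um)
  stress <- bowstring_tension(f[ok], d[ok], length_um) / dry_area_um2
  keep <- c(TRUE, diff(strain) > 0)
  curve <- data.frame(strain_pct = strain[keep], stress_MPa = stress[keep])
  if (nrow(curve) == 0) stop("no data points retained for the curve")
  class(curve) <- c("stress_strain_curve", "data.frame")
  curve
}

#' Mechanical parameters of a stress-strain curve
#'
#' Computes the four descriptors of a single-fibril tensile test:
#' \itemize{
#'   \item rupture strain and rupture stress: the last point of the curve (the
#'     last datum before the load falls to zero);
#'   \item toughness: the integral of the curve from 0 % strain to rupture
#'     (MPa over fractional strain = MJ/m^3), by trapezoidal quadrature plus a
#'     linear extrapolation of the initial data down to 0 % strain (the curve
#'     starts above 0 % because pre-full-tension data are discarded); the
#'     extrapolation slope is the least-squares slope over the first
#'     `extrap_window_pct` of strain, and a negative extrapolated stress is
#'     clamped at its zero crossing;
#'   \item high-strain modulus and its standard error: least-squares slope of
#'     stress against fractional strain over the last `modulus_window_pct` of
#'     strain preceding rupture.
#' }
#'
#' @param curve A `stress_strain_curve` from [build_stress_strain()] (or any
#'   data.frame with `strain_pct`, `stress_MPa`).
#' @param modulus_window_pct Width of the high-strain fit window, percentage
#'   points of strain; default 10.
#' @param extrap_window_pct Width of the initial window used for the
#'   extrapolation slope; default 2.
#' @return A `mechanical_summary`: list `rupture_strain_pct`,
#'   `rupture_stress_MPa`, `toughness_MJm3`, `modulus_MPa`,
#'   `modulus_error_MPa`.
#' @export
summarize_curve <- function(curve, modulus_window_pct = 10,
                            extrap_window_pct = 2) {
  strain <- curve$strain_pct
  stress <- curve$stress_MPa
  n <- length(strain)
  if (n < 3) stop("curve must have at least 3 points")
  eps_r <- strain[n]
  sig_r <- stress[n]

  # high-strain modulus over the last modulus_window_pct of strain
  in_win <- strain >= eps_r - modulus_window_pct
  if (sum(in_win) < 2) stop("fewer than 2 points in the high-strain window")
  if (eps_r - modulus_window_pct < strain[1])
    warning("curve spans less than the modulus window; fitting all available points")
  fit <- stats::lm(stress[in_win] ~ I(strain[in_win] / 100))
  modulus <- unname(stats::coef(fit)[2])
  # suppressed: summary.lm warns on exact fits, which are legitimate here
  modulus_err <- unname(suppressWarnings(
    summary(fit)$coefficients[2, "Std. Error"]))
  if (!is.finite(modulus_err)) modulus_err <- 0

  # toughness: trapezoid over the data + linear extrapolation to 0 % strain
  tough <- pracma::trapz(strain / 100, stress)
  ext <- strain <= strain[1] + extrap_window_pct
  slope <- if (sum(ext) >= 2) {
    unname(stats::coef(stats::lm(stress[ext] ~ I(strain[ext] / 100)))[2])
  } else modulus
  sig0 <- stress[1] - slope * strain[1] / 100
  if (sig0 >= 0) {
    tough <- tough + (sig0 + stress[1]) / 2 * strain[1] / 100
  } else if (slope > 0) {
    eps0 <- strain[1] / 100 - stress[1] / slope  # zero crossing, fractional
    tough <- tough + stress[1] / 2 * (strain[1] / 100 - eps0)
  }

  structure(list(rupture_strain_pct = eps_r, rupture_stress_MPa = sig_r,
                 toughness_MJm3 = tough, modulus_MPa = modulus,
                 modulus_error_MPa = modulus_err),
            class = "mechanical_summary")
}

#' @export
print.mechanical_summary <- function(x, ...) {
  cat(sprintf("Rupture strain  : %.2f %%\n", x$rupture_strain_pct))
  cat(sprintf("Rupture stress  : %.1f MPa (dry-area basis)\n", x$rupture_stress_MPa))
  cat(sprintf("Toughness       : %.2f MJ/m^3\n", x$toughness_MJm3))
  cat(sprintf("Modulus (high strain): %.1f +/- %.1f MPa\n",
              x$modulus_MPa, x$modulus_error_MPa))
  invisible(x)
}

#' Full mechanics pipeline for one pull experiment
#'
#' Runs the complete force-to-curve workflow: rupture detection, background
#' subtraction over the post-rupture window, 5-point adjacent averaging of the
#' pre-rupture segment (smoothing is not applied across the rupture step, which
#' would drag the last pre-rupture samples toward the background), rupture-
#' instant synchronization of force and video, full-tension onset estimation,
#' bowstring conversion, and summary statistics.
#'
#' @param experiment A `pull_experiment` (see [make_pull_experiment()]), or a
#'   list with the same `force` / `video` / `segment_length_um` /
#'   `dry_area_um2` fields read from files.
#' @param smooth_window Adjacent-averaging width; default 5.
#' @param rupture_threshold Passed to [detect_rupture()].
#' @param full_tension_index Optional manual override of full-tension onset.
#' @param rupture_frame_index Last video frame with the fibril present;
#'   defaults to the experiment's annotation.
#' @return List with `curve` (a `stress_strain_curve`), `summary` (a
#'   `mechanical_summary`), `rupture_force_index`, `full_tension_index`.
#' @export
analyze_pull <- function(experiment, smooth_window = 5, rupture_threshold = 5,
                         full_tension_index = NULL,
                         rupture_frame_index = experiment$rupture_frame_index) {
  force <- experiment$force
  ri <- detect_rupture(force$force_uN, threshold = rupture_threshold)
  force <- subtract_background(force, ri)
  force$force_uN[1:ri] <- smooth_adjacent(force$force_uN[1:ri], smooth_window)
  aligned <- synchronize(force, experiment$video, ri, rupture_frame_index)
  if (is.null(full_tension_index))
    full_tension_index <- estimate_full_tension(aligned)
  curve <- build_stress_strain(aligned, experiment$dry_area_um2,
                               experiment$segment_length_um,
                               full_tension_index = full_tension_index)
  list(curve = curve, summary = summarize_curve(curve),
       rupture_force_index = ri, full_tension_index = full_tension_index)
}

#' Upper bound on the bending force in bowstring loading
#'
#' Before full tension the fibril is loaded in bending. Modelling it as a
#' centrally loaded beam with both ends fixed (the ends are glued),
#' `F = 192 E I d / L0^3` with `I = pi r^4 / 4`; a simply supported option
#' (`48 E I d / L0^3`) is available.
#'
#' @param E_GPa Bending modulus in GPa.
#' @param radius_nm Fibril radius in nm.
#' @param length_um Segment length in um.
#' @param deflection_um Midpoint deflection in um.
#' @param boundary `"clamped"` (default) or `"supported"`.
#' @return Bending force in nN.
#' @export
#' @examples
#' bending_force_estimate(0.17, 100, 50, 5)  # ~0.1 nN
bending_force_estimate <- function(E_GPa, radius_nm, length_um, deflection_um,
                                   boundary = c("clamped", "supported")) {
  boundary <- match.arg(boundary)
  if (E_GPa <= 0 || radius_nm <= 0 || length_um <= 0 || deflection_um < 0)
    stop("inputs must be positive (deflection non-negative)")
  coef <- if (boundary == "clamped") 192 else 48
  E <- E_GPa * 1e9                      # Pa
  I <- pi * (radius_nm * 1e-9)^4 / 4    # m^4
  F_N <- coef * E * I * (deflection_um * 1e-6) / (length_um * 1e-6)^3
  F_N * 1e9                             # nN
}

#' Rescale dry-area stresses to a hydrated-area basis
#'
#' Stresses are reported against the dry cross-section; in buffer the fibril
#' radius swells by a factor of about 2, so the cross-sectional area grows by
#' about 4 and hydrated-basis stresses are the dry values divided by the
#' squared swelling factor.
#'
#' @param dry_stress_MPa Stress on the dry-area basis (vector allowed).
#' @param radius_swell_factor Radius swelling factor; default 2.
#' @return Stress on the hydrated-area basis, MPa.
#' @export
hydrated_stress_rescale <- function(dry_stress_MPa, radius_swell_factor = 2) {
  if (radius_swell_factor <= 0) stop("swelling factor must be positive")
  dry_stress_MPa / radius_swell_factor^2
}
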