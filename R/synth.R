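#' Linear fibril constitutive law
#'
#' Convenience constructor for a linear stress-strain law `sigma = E * eps`
#' (eps as a fraction), expressed on the percent-strain axis used throughout.
#'
#' @param modulus_MPa Elastic modulus E in MPa.
#' @return A function mapping strain in percent to stress in MPa.
#' @export
linear_modulus_curve <- function(modulus_MPa) {
  force(modulus_MPa)
  function(strain_pct) modulus_MPa * strain_pct / 100
}

#' Ground truth for one synthetic collagen fibril
#'
#' Bundles every parameter the analysis pipeline is supposed to recover:
#' geometry (dry radius, segment length), axial structure (D-band period and
#' modulation depth, kink positions and bend angle), optics (anisotropy
#' parameter and in-plane fibril angle), and mechanics (constitutive law,
#' rupture strain, slack deflection before full tension).
#'
#' Defaults describe a typical dry tendon fibril: 100 nm radius, 50 um prepared
#' segment, 67 nm D-banding with 4 nm peak-to-peak modulation, anisotropy 1.5,
#' a linear 500 MPa law rupturing at 20 % strain, and 5 um of midpoint
#' deflection taken up before the bowstring reaches full tension.
#'
#' @param dry_radius_nm Dry fibril radius in nm (> 0).
#' @param segment_length_um Prepared segment length L0 in um.
#' @param dband_period_nm Axial D-band period in nm.
#' @param dband_depth_nm Peak-to-peak height modulation of the D-banding, nm.
#' @param rho_true True SHG anisotropy parameter (> 0).
#' @param fibril_angle_phi_deg In-plane fibril angle for pol-stacks, degrees.
#' @param rupture_strain_pct Strain at rupture, percent, in (0, 100).
#' @param modulus_curve Function strain (%) -> stress (MPa); monotone.
#' @param kink_positions_nm Strictly increasing axial positions of post-rupture
#'   kinks, nm, within `[0, segment_length]`.
#' @param kink_angle_deg Bend angle rendered at each kink, degrees.
#' @param slack_deflection_um Midpoint deflection taken up before the fibril is
#'   taut, um.
#' @return Object of class `fibril_ground_truth` (a validated list).
#' @export
fibril_ground_truth <- function(dry_radius_nm = 100,
                                segment_length_um = 50,
                                dband_period_nm = 67,
                                dband_depth_nm = 4,
                                rho_true = 1.5,
                                fibril_angle_phi_deg = 30,
                                rupture_strain_pct = 20,
                                modulus_curve = linear_modulus_curve(500),
                                kink_positions_nm = c(15000, 30000),
                                kink_angle_deg = 30,
                                slack_deflection_um = 5) {
  if (dry_radius_nm <= 0) stop("dry_radius_nm must be positive")
  if (segment_length_um <= 0) stop("segment_length_um must be positive")
  if (rupture_strain_pct <= 0 || rupture_strain_pct >= 100)
    stop("rupture_strain_pct must lie in (0, 100)")
  if (rho_true <= 0) stop("rho_true must be positive")
  if (!is.function(modulus_curve)) stop("modulus_curve must be a function")
  kp <- kink_positions_nm
  if (length(kp) > 0) {
    if (any(diff(kp) <= 0)) stop("kink positions must be strictly increasing")
    if (any(kp < 0) || any(kp > segment_length_um * 1000))
      stop("kink positions must lie within [0, segment length]")
  }
  structure(list(dry_radius_nm = dry_radius_nm,
                 segment_length_um = segment_length_um,
                 dband_period_nm = dband_period_nm,
                 dband_depth_nm = dband_depth_nm,
                 rho_true = rho_true,
                 fibril_angle_phi_deg = fibril_angle_phi_deg,
                 rupture_strain_pct = rupture_strain_pct,
                 modulus_curve = modulus_curve,
                 kink_positions_nm = kp,
                 kink_angle_deg = kink_angle_deg,
                 slack_deflection_um = slack_deflection_um),
            class = "fibril_ground_truth")
}

#' Dry cross-sectional area implied by a half-cylindrical fibril
#' @param truth A [fibril_ground_truth()].
#' @return Area pi r^2 / 2 in um^2.
#' @export
dry_area_um2 <- function(truth) {
  pi * (truth$dry_radius_nm / 1000)^2 / 2
}

#' Synthetic SHG polarization stack
#'
#' Renders one image per polarization angle from the SHG intensity law
#' (see [shg_forward_model()]): fibril pixels carry
#' `amplitude * forward_model(rho, phi, alpha)` expected counts, background
#' pixels carry `background` expected counts. With `noise = "poisson"` every
#' pixel is replaced by a Poisson draw of its expected count (photon shot
#' noise); with `noise = "none"` expected counts are returned exactly.
#'
#' @param rho_field Numeric matrix of per-pixel anisotropy values: positive on
#'   the fibril footprint, 0 elsewhere. Negative values are rejected.
#' @param phi_deg Fibril angle in degrees.
#' @param angles_deg Polarization angle axis; default the acquisition protocol
#'   0-240 degrees in 10-degree steps (25 images).
#' @param amplitude Expected peak-proportionality counts on the fibril (> 0).
#' @param background Expected background counts; default 0.
#' @param noise `"none"` or `"poisson"`.
#' @param pixel_nm Pixel size recorded in the stack metadata; default 200.
#' @param seed Integer seed for the noise draws.
#' @return A `polstack`: list with `images` (list of matrices), `angles_deg`,
#'   `pixel_nm`.
#' @export
make_polstack <- function(rho_field, phi_deg,
                          angles_deg = seq(0, 240, by = 10),
                          amplitude = 1000, background = 0,
                          noise = c("none", "poisson"),
                          pixel_nm = 200, seed = NULL) {
  noise <- match.arg(noise)
  if (length(angles_deg) == 0) stop("angle axis must be non-empty")
  if (amplitude <= 0) stop("amplitude must be positive")
  if (any(!is.finite(rho_field)) || any(rho_field < 0))
    stop("rho_field must be finite and non-negative (positive on the fibril)")
  if (!is.null(seed)) set.seed(seed)
  on_fib <- rho_field > 0
  images <- lapply(angles_deg, function(alpha) {
    img <- matrix(background, nrow(rho_field), ncol(rho_field))
    if (any(on_fib))
      img[on_fib] <- amplitude *
        shg_forward_model(rho_field[on_fib], phi_deg, alpha)
    if (noise == "poisson")
      img[] <- stats::rpois(length(img), lambda = img)
    img
  })
  structure(list(images = images, angles_deg = angles_deg, pixel_nm = pixel_nm),
            class = "polstack")
}

#' @export
print.polstack <- function(x, ...) {
  cat(sprintf("SHG pol-stack: %d images (%g-%g deg), %dx%d px, %g nm/px\n",
              length(x$images), min(x$angles_deg), max(x$angles_deg),
              nrow(x$images[[1]]), ncol(x$images[[1]]), x$pixel_nm))
  invisible(x)
}

# Fine-step centerline of the rendered fibril: heading alternates by
# kink_angle at each kink position. Returns x, y (nm), arc s (nm), heading.
.synth_centerline <- function(truth, base_angle_deg, step_nm) {
  L <- truth$segment_length_um * 1000
  s <- seq(0, L, by = step_nm)
  nbend <- vapply(s, function(si) sum(truth$kink_positions_nm <= si), numeric(1))
  heading <- (base_angle_deg + truth$kink_angle_deg * (nbend %% 2)) * pi / 180
  if (any(abs(heading) >= pi / 4))
    stop("base angle + kink angle must stay below 45 degrees for raster rendering")
  x <- cumsum(c(0, cos(heading[-1]) * step_nm))
  y <- cumsum(c(0, sin(heading[-1]) * step_nm))
  list(x = x, y = y, s = s, heading = heading)
}

#' Synthetic AFM height map of a (possibly kinked) fibril
#'
#' Renders a half-cylindrical fibril of radius `dry_radius_nm` lying on a flat
#' substrate, with its centerline bending by `kink_angle_deg` at every kink
#' position and its height modulated axially by a sinusoid of period
#' `dband_period_nm` (peak-to-peak depth `dband_depth_nm` at the crest, scaled
#' with the local cross-profile so fibril edges stay at zero). Gaussian surface
#' noise is added everywhere.
#'
#' @param truth A [fibril_ground_truth()].
#' @param pixel_nm Pixel size in nm; default 8. Must resolve the D-band
#'   (`dband_period_nm > 2 * pixel_nm`).
#' @param noise_sd_nm Standard deviation of additive surface noise, nm.
#' @param base_angle_deg Overall fibril orientation in the raster; the heading
#'   (base plus bends) must stay below 45 degrees.
#' @param margin_px Blank margin around the fibril footprint, pixels.
#' @param size_px Optional `c(nrow, ncol)`; if the fibril footprint does not
#'   fit, generation is rejected with a sizing message. Default: auto-sized.
#' @param seed Integer seed.
#' @return A `heightmap`: list with `heights` (matrix, rows = y, cols = x, nm),
#'   `pixel_nm`.
#' @export
make_afm_map <- function(truth, pixel_nm = 8, noise_sd_nm = 0.5,
                         base_angle_deg = 0, margin_px = 8,
                         size_px = NULL, seed = NULL) {
  if (pixel_nm <= 0) stop("pixel_nm must be positive")
  if (truth$dband_period_nm <= 2 * pixel_nm)
    stop("D-band period must exceed twice the pixel size")
  cl <- .synth_centerline(truth, base_angle_deg, step_nm = pixel_nm / 2)
  r <- truth$dry_radius_nm
  need_nc <- ceiling((max(cl$x) - min(cl$x)) / pixel_nm) + 2 * margin_px
  need_nr <- ceiling((max(cl$y) - min(cl$y) + 2 * r) / pixel_nm) + 2 * margin_px
  if (is.null(size_px)) {
    nr <- need_nr; nc <- need_nc
  } else {
    nr <- size_px[1]; nc <- size_px[2]
    if (nr < need_nr || nc < need_nc)
      stop(sprintf(paste0("fibril footprint (%d x %d px) exceeds the requested ",
                          "raster (%d x %d px); enlarge size_px"),
                   need_nr, need_nc, nr, nc))
  }
  x0 <- min(cl$x) - margin_px * pixel_nm
  y0 <- min(cl$y) - r - margin_px * pixel_nm
  xs <- (seq_len(nc) - 0.5) * pixel_nm + x0
  ys <- (seq_len(nr) - 0.5) * pixel_nm + y0
  yc <- stats::approx(cl$x, cl$y, xout = xs, rule = 2)$y
  sc <- stats::approx(cl$x, cl$s, xout = xs, rule = 2)$y
  hd <- stats::approx(cl$x, cl$heading, xout = xs, rule = 2)$y
  mod_rel <- truth$dband_depth_nm / (2 * r)  # relative crest modulation
  H <- matrix(0, nr, nc)
  inx <- xs >= min(cl$x) & xs <= max(cl$x)
  for (j in which(inx)) {
    u <- (ys - yc[j]) * cos(hd[j])          # perpendicular offset from axis
    prof <- r^2 - u^2
    hit <- prof > 0
    H[hit, j] <- sqrt(prof[hit]) *
      (1 + mod_rel * sin(2 * pi * sc[j] / truth$dband_period_nm))
  }
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd_nm > 0)
    H <- H + matrix(stats::rnorm(nr * nc, sd = noise_sd_nm), nr, nc)
  structure(list(heights = H, pixel_nm = pixel_nm), class = "heightmap")
}

#' @export
print.heightmap <- function(x, ...) {
  cat(sprintf("AFM height map: %d x %d px at %g nm/px, max height %.1f nm\n",
              nrow(x$heights), ncol(x$heights), x$pixel_nm, max(x$heights)))
  invisible(x)
}

#' Synthetic bowstring pull-to-rupture experiment
#'
#' Simulates the two records of a bowstring tensile test: the lateral-force
#' trace sampled at `force_rate_hz` and the video-derived midpoint-deflection
#' trace at `video_rate_fps`. The AFM tip ramps at `pull_speed_um_s`; once the
#' midpoint deflection exceeds the slack deflection the fibril is taut and its
#' tension (from the constitutive law at the bowstring strain, times the dry
#' area) projects onto the tip as `F = 2 T d / sqrt((L0/2)^2 + d^2)`, on top of
#' a Gaussian tip-glass friction background. At the ground-truth rupture strain
#' the fibril term vanishes between two adjacent force samples; a trailing
#' window of pure friction is retained.
#'
#' @param truth A [fibril_ground_truth()].
#' @param friction_level_uN Mean friction background, uN.
#' @param friction_sd_uN Friction noise standard deviation, uN.
#' @param force_rate_hz Force sampling rate; default 500.
#' @param video_rate_fps Video frame rate; default 20.
#' @param pull_speed_um_s Tip velocity; default 1.
#' @param post_rupture_s Length of the retained post-rupture friction window.
#' @param duration_s Optional total record length; rejected if the rupture
#'   strain is not reached within it. Default: auto-sized.
#' @param seed Integer seed.
#' @return A `pull_experiment`: list with data.frames `force` (`time_s`,
#'   `force_uN`) and `video` (`time_s`, `deflection_um`), plus
#'   `segment_length_um`, `dry_area_um2`, `rupture_frame_index` (video
#'   annotation: last frame in which the fibril is present), and `truth`.
#' @export
make_pull_experiment <- function(truth,
                                 friction_level_uN = 1,
                                 friction_sd_uN = 0.05,
                                 force_rate_hz = 500,
                                 video_rate_fps = 20,
                                 pull_speed_um_s = 1,
                                 post_rupture_s = 2,
                                 duration_s = NULL,
                                 seed = NULL) {
  if (force_rate_hz <= 0 || video_rate_fps <= 0 || pull_speed_um_s <= 0)
    stop("rates and pull speed must be positive")
  L0 <- truth$segment_length_um
  half <- L0 / 2
  area <- dry_area_um2(truth)
  d_slack <- truth$slack_deflection_um
  arc <- function(d) 2 * sqrt(half^2 + d^2)
  arc_s <- arc(d_slack)
  arc_r <- arc_s * (1 + truth$rupture_strain_pct / 100)
  d_r <- sqrt((arc_r / 2)^2 - half^2)
  t_r <- d_r / pull_speed_um_s
  if (is.null(duration_s)) {
    duration_s <- t_r + post_rupture_s
  } else if (duration_s <= t_r) {
    stop(sprintf(paste0("rupture strain %.3g%% is reached only at t = %.3g s; ",
                        "increase duration_s (%.3g s) or lower the strain"),
                 truth$rupture_strain_pct, t_r, duration_s))
  }
  if (!is.null(seed)) set.seed(seed)
  tf <- seq(0, duration_s, by = 1 / force_rate_hz)
  d <- pull_speed_um_s * tf
  taut <- d > d_slack & tf < t_r
  eps_pct <- numeric(length(tf))
  eps_pct[taut] <- 100 * (arc(d[taut]) - arc_s) / arc_s
  tension <- numeric(length(tf))
  tension[taut] <- truth$modulus_curve(eps_pct[taut]) * area   # MPa*um^2 = uN
  f_fib <- numeric(length(tf))
  f_fib[taut] <- 2 * tension[taut] * d[taut] / sqrt(half^2 + d[taut]^2)
  friction <- friction_level_uN +
    if (friction_sd_uN > 0) stats::rnorm(length(tf), sd = friction_sd_uN) else 0
  force <- data.frame(time_s = tf, force_uN = f_fib + friction)
  tv <- seq(0, duration_s, by = 1 / video_rate_fps)
  video <- data.frame(time_s = tv, deflection_um = pull_speed_um_s * tv)
  structure(list(force = force, video = video,
                 segment_length_um = L0, dry_area_um2 = area,
                 rupture_frame_index = max(which(tv < t_r)),
                 truth = truth),
            class = "pull_experiment")
}

#' @export
print.pull_experiment <- function(x, ...) {
  cat(sprintf(paste0("Bowstring pull experiment: L0 = %g um, dry area %.4g um^2, ",
                     "%d force samples, %d frames\n"),
              x$segment_length_um, x$dry_area_um2,
              nrow(x$force), nrow(x$video)))
  invisible(x)
}

#' Synthetic two-channel fluorescence image
#'
#' The fluorescence channel is `background_level` everywhere plus
#' `fibril_level - background_level` on the fibril footprint, with additive
#' Gaussian noise. The brightfield channel is a deterministic silhouette of
#' the footprint (darker fibril on a bright field).
#'
#' @param mask Logical matrix: the fibril footprint.
#' @param fibril_level,background_level Expected counts (>= 0).
#' @param noise_sd Gaussian noise standard deviation, counts.
#' @param laser_power_mw Metadata only, never used for normalization.
#' @param seed Integer seed.
#' @return A `fluor_image`: list with matrices `brightfield`, `fluorescence`
#'   and `laser_power_mw`.
#' @export
make_fluorescence_image <- function(mask, fibril_level, background_level,
                                    noise_sd = 0, laser_power_mw = 12,
                                    seed = NULL) {
  if (fibril_level < 0 || background_level < 0)
    stop("intensity levels must be non-negative")
  if (!is.logical(mask)) stop("mask must be a logical matrix")
  if (!is.null(seed)) set.seed(seed)
  fl <- background_level + (fibril_level - background_level) * mask
  if (noise_sd > 0)
    fl <- fl + matrix(stats::rnorm(length(mask), sd = noise_sd),
                      nrow(mask), ncol(mask))
  bf <- matrix(200, nrow(mask), ncol(mask)) - 120 * mask
  structure(list(brightfield = bf, fluorescence = fl,
                 laser_power_mw = laser_power_mw),
            class = "fluor_image")
}
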