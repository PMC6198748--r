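test_that("rupture detection finds the largest precipitous drop", {
  set.seed(1)
  f <- c(seq(1, 5, length.out = 200), rep(1, 100) + rnorm(100, sd = 0.02))
  expect_equal(detect_rupture(f), 200)
  # monotone ramp with no drop errors
  expect_error(detect_rupture(seq(0, 1, length.out = 50)), "no rupture")
  # two drops: the larger wins
  f2 <- c(rep(5, 50), rep(4, 50), rep(1, 50))
  expect_equal(detect_rupture(f2), 100)
  expect_error(detect_rupture(c(1, 2)), "3 samples")
})

test_that("background subtraction zeroes the post-rupture friction level", {
  f <- c(rep(7, 50), rep(2, 50))
  out <- subtract_background(f, 50)
  expect_equal(mean(out[51:100]), 0)
  expect_equal(out[1:50], rep(5, 50))
  # background already zero: trace unchanged
  g <- c(rep(3, 30), rep(0, 30))
  expect_equal(subtract_background(g, 30), g)
  # pure friction: post-subtraction mean within sampling error of zero
  set.seed(2)
  fr <- rnorm(2000, mean = 1, sd = 0.1)
  out2 <- subtract_background(fr, 1000)
  expect_lt(abs(mean(out2[1001:2000])), 3 * 0.1 / sqrt(1000))
  expect_error(subtract_background(f, 95), "at least")
})

test_that("adjacent averaging is a centered shrinking-window mean", {
  expect_equal(smooth_adjacent(rep(4, 20)), rep(4, 20))
  x <- rnorm(10)
  expect_equal(smooth_adjacent(x, window = 1), x)
  # interior impulse of height h spreads to a h/5 plateau over 5 samples
  im <- rep(0, 21); im[11] <- 10
  sm <- smooth_adjacent(im, 5)
  expect_equal(sm[9:13], rep(2, 5))
  expect_equal(sm[c(8, 14)], c(0, 0))
  expect_error(smooth_adjacent(x, window = 4), "odd")
})

test_that("bowstring geometry formulas are exact", {
  expect_equal(bowstring_strain(0, 50), 0)
  expect_equal(bowstring_strain(5, 50), 100 * (2 * sqrt(625 + 25) - 50) / 50)
  expect_equal(bowstring_strain(5, 50), 1.9804, tolerance = 1e-4)
  d <- seq(0, 20, by = 0.5)
  expect_true(all(diff(bowstring_strain(d, 50)) > 0))
  expect_error(bowstring_strain(-1, 50), "non-negative")
  # 45-degree arms: F = 2 uN gives T = sqrt(2)
  expect_equal(bowstring_tension(2, 25, 50), sqrt(2))
  expect_equal(bowstring_tension(0, 5, 50), 0)
  expect_error(bowstring_tension(1, 0, 50), "positive")
})

test_that("synchronization aligns rupture instants and interpolates deflection", {
  # identical time bases with aligned ruptures: identity
  t <- seq(0, 1, by = 0.01)
  force <- data.frame(time_s = t, force_uN = sin(t))
  video <- data.frame(time_s = t, deflection_um = t * 2)
  al <- synchronize(force, video, 50, 50)
  expect_equal(al$deflection_um, video$deflection_um)
  expect_equal(al$force_uN, force$force_uN)
  expect_equal(attr(al, "rupture_index"), 50)
  # generator closure: recovered pairs match the forward model
  tr <- fibril_ground_truth(segment_length_um = 20, rupture_strain_pct = 10,
                            kink_positions_nm = numeric(0),
                            slack_deflection_um = 0)
  ex <- make_pull_experiment(tr, friction_level_uN = 0, friction_sd_uN = 0,
                             seed = 1)
  ri <- detect_rupture(ex$force$force_uN)
  al2 <- synchronize(ex$force, ex$video, ri, ex$rupture_frame_index)
  # tip ramps at 1 um/s; alignment shifts time by less than one frame
  expect_lt(max(abs(al2$deflection_um - al2$time_s)), 1 / 20)
  expect_error(synchronize(force, video, 500, 50), "within")
})

test_that("stress-strain assembly reproduces a linear constitutive law", {
  tr <- fibril_ground_truth(segment_length_um = 30, rupture_strain_pct = 15,
                            slack_deflection_um = 0,
                            modulus_curve = linear_modulus_curve(400),
                            kink_positions_nm = numeric(0))
  ex <- make_pull_experiment(tr, friction_level_uN = 0, friction_sd_uN = 0,
                             seed = 1)
  ri <- detect_rupture(ex$force$force_uN)
  # exactly aligned series (generator time bases coincide), so the bowstring
  # conversion itself can be checked without frame-quantization error
  al <- data.frame(time_s = ex$force$time_s,
                   deflection_um = ex$force$time_s * 1,
                   force_uN = ex$force$force_uN)
  attr(al, "rupture_index") <- ri
  cv <- build_stress_strain(al, ex$dry_area_um2, ex$segment_length_um,
                            full_tension_index = 30)
  expect_true(all(diff(cv$strain_pct) > 0))
  # sigma = E * eps throughout
  expect_equal(cv$stress_MPa, 400 * cv$strain_pct / 100, tolerance = 1e-9)
  # last point is the rupture point
  expect_equal(cv$strain_pct[nrow(cv)], max(cv$strain_pct))
  # unit arithmetic: tension 1 uN over 0.05 um^2 is 20 MPa
  expect_equal(bowstring_tension(2 * 5 / sqrt(15^2 + 5^2), 5, 30) / 0.05, 20)
  expect_error(build_stress_strain(al, -1, 30), "positive")
})

test_that("curve summary matches analytic oracles", {
  # exact line sigma = 100 * eps (fraction), sampled 5..30 % strain
  eps <- seq(5, 30, by = 0.25)
  curve <- data.frame(strain_pct = eps, stress_MPa = 100 * eps / 100)
  sm <- summarize_curve(curve)
  expect_equal(sm$modulus_MPa, 100)
  expect_equal(sm$modulus_error_MPa, 0)
  expect_equal(sm$rupture_strain_pct, 30)
  expect_equal(sm$rupture_stress_MPa, 30)
  expect_equal(sm$toughness_MJm3, 0.5 * 30 * 0.30)  # triangle, exact
  # plateau sigma0 over [eps1, eps2] after a linear rise from zero strain
  eps1 <- 10; eps2 <- 25; sig0 <- 8
  rise <- data.frame(strain_pct = seq(2, eps1, by = 0.1))
  rise$stress_MPa <- sig0 * rise$strain_pct / eps1
  plat <- data.frame(strain_pct = seq(eps1 + 0.1, eps2, by = 0.1),
                     stress_MPa = sig0)
  sm2 <- summarize_curve(rbind(rise, plat))
  analytic <- 0.5 * sig0 * eps1 / 100 + sig0 * (eps2 - eps1) / 100
  expect_equal(sm2$toughness_MJm3, analytic, tolerance = 1e-3)
  expect_error(summarize_curve(curve[1:2, ]), "at least 3")
})

test_that("summary is invariant to uniform time shifts of the experiment", {
  tr <- fibril_ground_truth(segment_length_um = 30, rupture_strain_pct = 15,
                            kink_positions_nm = numeric(0),
                            slack_deflection_um = 1)
  ex <- make_pull_experiment(tr, friction_sd_uN = 0.02, seed = 4)
  shifted <- ex
  shifted$force$time_s <- shifted$force$time_s + 3
  shifted$video$time_s <- shifted$video$time_s + 3
  expect_equal(analyze_pull(ex)$summary, analyze_pull(shifted)$summary)
})

test_that("noiseless pull experiments recover the ground-truth parameters", {
  ex <- closure_pull(E_MPa = 500, rupture_strain_pct = 20,
                     segment_length_um = 50)
  res <- analyze_pull(ex)
  sm <- res$summary
  # one video frame at 1 um/s near rupture corresponds to this strain step
  d_r <- sqrt((50 * 1.2 / 2)^2 - 25^2)
  frame_strain <- (bowstring_strain(d_r, 50) -
                     bowstring_strain(d_r - 1 / 20, 50))
  expect_lt(abs(sm$rupture_strain_pct - 20), frame_strain)
  expect_lt(abs(sm$rupture_stress_MPa - 100) / 100, 0.01)
  expect_lt(abs(sm$toughness_MJm3 - 10) / 10, 0.01)
  expect_lt(abs(sm$modulus_MPa - 500) / 500, 0.01)
})

test_that("recovered rupture stress converges as friction noise vanishes", {
  tr <- fibril_ground_truth(segment_length_um = 30, rupture_strain_pct = 15,
                            kink_positions_nm = numeric(0),
                            slack_deflection_um = 1)
  bias <- vapply(c(0.05, 0.005), function(sd) {
    errs <- vapply(1:5, function(s) {
      ex <- make_pull_experiment(tr, friction_sd_uN = sd, seed = s)
      abs(analyze_pull(ex)$summary$rupture_stress_MPa -
            tr$modulus_curve(15))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(bias[2], bias[1])
})

test_that("bending-force upper bound follows clamped-beam mechanics", {
  expect_equal(bending_force_estimate(0.17, 100, 50, 0), 0)
  f <- bending_force_estimate(0.17, 100, 50, 5)
  expect_equal(f, 192 * 0.17e9 * pi * (1e-7)^4 / 4 * 5e-6 / (50e-6)^3 * 1e9)
  # r^4 scaling and the boundary-condition factor of 4
  expect_equal(bending_force_estimate(0.17, 200, 50, 5), 16 * f)
  expect_equal(bending_force_estimate(0.17, 100, 50, 5, "supported"), f / 4)
})

test_that("dry-to-hydrated rescaling divides stress by the squared swelling factor", {
  expect_equal(hydrated_stress_rescale(100), 25)
  expect_equal(hydrated_stress_rescale(42, 1), 42)
  expect_equal(hydrated_stress_rescale(8, 2), 8 / 4)
  expect_error(hydrated_stress_rescale(1, 0), "positive")
})
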