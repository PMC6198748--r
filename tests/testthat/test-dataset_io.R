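test_that("identifier convention is a validated bijection", {
  ids <- character(0)
  for (a in 1:2) for (t in c("e", "f")) for (f in c(1, 7, 12)) {
    id <- fibril_id(a, t, f)
    p <- parse_fibril_id(id)
    expect_equal(p$animal, a)
    expect_equal(p$tendon, t)
    expect_equal(p$fibril, f)
    expect_false(p$control)
    ids <- c(ids, id)
  }
  expect_equal(anyDuplicated(ids), 0L)
  expect_equal(fibril_id(1, "e", 1), "1e1")
  expect_true(parse_fibril_id("2f11c")$control)
  expect_error(fibril_id(1, "x", 1), "tendon")
  expect_error(parse_fibril_id("e11"), "identifier")
  expect_error(parse_fibril_id("1g1"), "identifier")
})

test_that("tensile table round trips losslessly and validates its schema", {
  sm <- list(rupture_strain_pct = 19.926835201, rupture_stress_MPa = 100.07,
             toughness_MJm3 = 10.0000001, modulus_MPa = 501.13,
             modulus_error_MPa = 1 / 3)
  rec <- rbind(tensile_record(1, "e", 1, 50, 0.0157, 1, sm),
               tensile_record(2, "f", 3, 48.5, 0.021, 2, sm))
  f <- withr::local_tempfile()
  write_tensile_table(rec, f)
  back <- read_tensile_table(f)
  expect_equal(back, rec)
  expect_identical(back$toughness_MJm3, rec$toughness_MJm3)  # full precision
  # empty record list: header-only file
  fe <- withr::local_tempfile()
  write_tensile_table(NULL, fe)
  expect_length(readLines(fe), 1)
  expect_equal(nrow(read_tensile_table(fe)), 0)
  # invalid tendon code is rejected with row and column named
  bad <- rec; bad$tendon[2] <- "x"
  fb <- withr::local_tempfile()
  fibrilmech:::write_full_precision(bad, fb)
  expect_error(read_tensile_table(fb), "row 2.*tendon")
})

test_that("stress-strain files follow the naming convention and round trip", {
  curve <- data.frame(strain_pct = c(5.1, 6.2, 7.9),
                      stress_MPa = c(10.123456789012, 20, 31.5))
  d <- withr::local_tempdir()
  path <- write_stress_strain(curve, "1e1", d)
  expect_equal(basename(path), "1e1")
  expect_length(readLines(path), 4)        # header + 3 data lines
  back <- read_stress_strain(path)
  expect_equal(back$strain_pct, curve$strain_pct)
  expect_identical(back$stress_MPa, curve$stress_MPa)
  expect_error(write_stress_strain(curve, "bogus", d), "identifier")
  nonmono <- curve; nonmono$strain_pct <- c(5, 5, 6)
  expect_error(write_stress_strain(nonmono, "1e1", d), "increasing")
})

test_that("post-rupture table round trips the A-O schema", {
  rec <- data.frame(animal = 1L, tendon = "e", fibril_number = 1L,
                    rupture_location = "middle",
                    mean_height_before_nm = 199.5, height_loss_nm = 20.25,
                    normalized_height_loss_pct = 10.15, n_damage_sites = 12L,
                    kink_spacing_nm = 2345.6, fluorescent = "Yes",
                    shg_intensity_ratio = 0.71, rho_peak_ruptured = 1.48,
                    rho_fwhm_ruptured = 0.22, rho_peak_control = 1.52,
                    rho_fwhm_control = 0.18, stringsAsFactors = FALSE)
  f <- withr::local_tempfile()
  write_post_rupture_table(rec, f)
  expect_equal(read_post_rupture_table(f), rec)
  expect_error(write_post_rupture_table(rec[, 1:5], f), "A-O")
})

test_that("pull experiments and image stacks survive file round trips", {
  d <- withr::local_tempdir()
  tr <- fibril_ground_truth(segment_length_um = 30, rupture_strain_pct = 15,
                            kink_positions_nm = numeric(0),
                            slack_deflection_um = 1)
  ex <- make_pull_experiment(tr, friction_sd_uN = 0.02, seed = 4)
  write_pull_experiment(ex, file.path(d, "1e1"))
  back <- read_pull_experiment(file.path(d, "1e1"), ex$segment_length_um,
                               ex$dry_area_um2, ex$rupture_frame_index)
  expect_equal(back$force, ex$force)
  expect_equal(back$video, ex$video)
  expect_equal(analyze_pull(back)$summary, analyze_pull(ex)$summary)
  # pol-stack TIFF + sidecar
  st <- make_polstack(matrix(c(0, 1.5), 8, 10), 30, amplitude = 500)
  write_polstack(st, file.path(d, "1e1.tif"))
  st2 <- read_polstack(file.path(d, "1e1.tif"))
  expect_length(st2$images, 25)
  expect_equal(st2$angles_deg, st$angles_deg)
  expect_equal(st2$pixel_nm, 200)
  expect_lt(max(abs(st2$images[[7]] - st$images[[7]])), 1e-3)
  # height map TIFF
  m <- make_afm_map(straight_truth(2), noise_sd_nm = 0.3, seed = 1)
  write_heightmap(m, file.path(d, "m.tif"))
  m2 <- read_heightmap(file.path(d, "m.tif"))
  expect_equal(m2$pixel_nm, 8)
  expect_lt(max(abs(m2$heights - m$heights)), 1e-4)
  # fluorescence TIFF
  msk <- band_mask(16, 16, 7:9)
  fl <- make_fluorescence_image(msk, 150, 50, noise_sd = 5, seed = 2)
  write_fluor_image(fl, file.path(d, "f.tif"))
  fl2 <- read_fluor_image(file.path(d, "f.tif"))
  expect_equal(fl2$laser_power_mw, 12)
  expect_lt(max(abs(fl2$fluorescence - fl$fluorescence)), 1e-3)
})

make_pipeline_fibril <- function(a, t, f, seed, with_shg = TRUE) {
  tr <- fibril_ground_truth(segment_length_um = 20, rupture_strain_pct = 15,
                            kink_positions_nm = c(6000, 12000),
                            slack_deflection_um = 1)
  out <- list(animal = a, tendon = t, fibril = f, cantilever_number = 1,
              rupture_location = "middle",
              pull = make_pull_experiment(tr, friction_sd_uN = 0.02,
                                          seed = seed),
              afm_before = make_afm_map(straight_truth(3), noise_sd_nm = 0.4,
                                        seed = seed),
              afm_after = make_afm_map(tr, noise_sd_nm = 0.4, seed = seed + 1),
              fluor = make_fluorescence_image(band_mask(30, 30, 14:16),
                                              150, 50, 10, seed = seed + 2))
  if (with_shg) {
    rf <- matrix(0, 30, 40); rf[14:17, ] <- 1.5
    out$polstack <- make_polstack(rf, 30, amplitude = 5000,
                                  noise = "poisson", seed = seed + 3)
    rfc <- matrix(0, 30, 40); rfc[14:17, ] <- 1.5
    out$polstack_control <- make_polstack(rfc, 30, amplitude = 6000,
                                          noise = "poisson", seed = seed + 4)
  }
  out
}

test_that("pipeline processes a cohort, isolates failures, and is deterministic", {
  d <- withr::local_tempdir()
  fibs <- list(make_pipeline_fibril(1, "e", 1, 10),
               make_pipeline_fibril(1, "e", 2, 20),
               make_pipeline_fibril(2, "f", 1, 30),
               make_pipeline_fibril(2, "f", 2, 40, with_shg = FALSE))
  cfg <- list(out_dir = file.path(d, "run1"), fibrils = fibs)
  rep1 <- run_pipeline(cfg)
  # 4 stress-strain files + the two summary tables + log
  expect_setequal(list.files(file.path(d, "run1")),
                  c("1e1", "1e2", "2f1", "2f2", "tensile_data.tsv",
                    "post_rupture_data.tsv", "pipeline_log.tsv"))
  expect_equal(nrow(rep1$tensile), 4)
  expect_equal(nrow(rep1$post_rupture), 4)
  # mechanics results are sane and kinks were found on the post-rupture maps
  expect_true(all(abs(rep1$tensile$rupture_strain_pct - 15) < 2))
  expect_true(all(rep1$post_rupture$n_damage_sites == 2))
  expect_true(all(rep1$post_rupture$fluorescent == "Yes"))
  # the fibril without pol-stacks has empty SHG columns; the others do not
  expect_true(is.na(rep1$post_rupture$rho_peak_ruptured[4]))
  expect_true(all(is.finite(rep1$post_rupture$rho_peak_ruptured[1:3])))
  expect_true(all(abs(rep1$post_rupture$rho_peak_ruptured[1:3] - 1.5) < 0.1))
  expect_true(all(abs(rep1$post_rupture$shg_intensity_ratio[1:3] - 5/6) < 0.05))
  # rerun with the same config: byte-identical tables
  cfg2 <- cfg; cfg2$out_dir <- file.path(d, "run2")
  run_pipeline(cfg2)
  for (fn in c("tensile_data.tsv", "post_rupture_data.tsv", "1e1")) {
    expect_identical(readLines(file.path(d, "run1", fn)),
                     readLines(file.path(d, "run2", fn)))
  }
})
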