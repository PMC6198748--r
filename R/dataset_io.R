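# Full-precision tab-delimited writer shared by all table writers: numbers are
# serialized with %.17g so read.delim round-trips are lossless for doubles.
write_full_precision <- function(df, file) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Fibril identifier convention
#'
#' Identifiers concatenate animal number, tendon code and fibril number:
#' animal 1, common digital extensor tendon (`e`), fibril 1 is `"1e1"`.
#' The superficial digital flexor is coded `f`. A control pol-stack carries a
#' trailing `c`.
#'
#' @param animal Positive integer animal number.
#' @param tendon `"e"` (common digital extensor) or `"f"` (superficial digital
#'   flexor).
#' @param fibril Positive integer fibril number.
#' @return `fibril_id`: the identifier string. `parse_fibril_id`: list
#'   `animal`, `tendon`, `fibril`, `control`.
#' @export
#' @examples
#' fibril_id(1, "e", 1)        # "1e1"
#' parse_fibril_id("2f11c")
fibril_id <- function(animal, tendon, fibril) {
  if (!tendon %in% c("e", "f")) stop("tendon code must be 'e' or 'f'")
  if (animal != round(animal) || animal < 1 || fibril != round(fibril) ||
      fibril < 1) stop("animal and fibril numbers must be positive integers")
  paste0(animal, tendon, fibril)
}

#' @rdname fibril_id
#' @param id Identifier string, e.g. `"1e1"` or `"1e1c"` for a control stack.
#' @export
parse_fibril_id <- function(id) {
  m <- regmatches(id, regexec("^([0-9]+)([ef])([0-9]+)(c?)$", id))[[1]]
  if (length(m) == 0) stop(sprintf("'%s' is not a valid fibril identifier", id))
  list(animal = as.integer(m[2]), tendon = m[3], fibril = as.integer(m[4]),
       control = m[5] == "c")
}

.tensile_cols <- c("animal", "tendon", "fibril_number", "length_um",
                   "dry_area_um2", "cantilever_number", "rupture_strain_pct",
                   "rupture_stress_MPa", "toughness_MJm3", "modulus_MPa",
                   "modulus_error_MPa")

#' Write / read the tensile summary table
#'
#' Mirrors the deposition's tensile worksheet (columns A-K: animal, tendon
#' e/f, fibril number, prepared segment length um, dry cross-sectional area
#' um^2, cantilever number, rupture strain %, rupture stress MPa on the
#' dry-area basis, toughness MJ/m^3, high-strain modulus MPa, modulus error
#' MPa) as tab-delimited text. Round trips are lossless at full double
#' precision.
#'
#' @param records data.frame with the eleven documented columns (see
#'   [tensile_record()] for assembling one row).
#' @param file Path.
#' @return `write_tensile_table`: `file`, invisibly. `read_tensile_table`: the
#'   validated data.frame.
#' @export
write_tensile_table <- function(records, file) {
  if (is.null(records) || nrow(records) == 0) {
    records <- as.data.frame(setNames(rep(list(numeric(0)),
                                          length(.tensile_cols)),
                                      .tensile_cols))
  }
  if (!identical(names(records), .tensile_cols))
    stop("records must have exactly the documented A-K columns")
  write_full_precision(records, file)
}

#' @rdname write_tensile_table
#' @export
read_tensile_table <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = c(tendon = "character"))
  if (!identical(names(df), .tensile_cols))
    stop("file does not match the tensile-table A-K schema")
  if (nrow(df) > 0) {
    bad <- which(!df$tendon %in% c("e", "f"))
    if (length(bad) > 0)
      stop(sprintf("row %d, column 'tendon': invalid code '%s'",
                   bad[1], df$tendon[bad[1]]))
    for (cn in setdiff(.tensile_cols, "tendon")) {
      nonnum <- which(!is.finite(suppressWarnings(as.numeric(df[[cn]]))) &
                        !is.na(df[[cn]]))
      if (length(nonnum) > 0)
        stop(sprintf("row %d, column '%s': not numeric", nonnum[1], cn))
    }
  }
  df
}

#' Assemble one tensile-table row
#'
#' @param animal,tendon,fibril Identifier fields (see [fibril_id()]).
#' @param length_um,dry_area_um2 Specimen dimensions.
#' @param cantilever_number Cantilever used.
#' @param summary A `mechanical_summary` from [summarize_curve()].
#' @return One-row data.frame in the tensile-table schema.
#' @export
tensile_record <- function(animal, tendon, fibril, length_um, dry_area_um2,
                           cantilever_number, summary) {
  fibril_id(animal, tendon, fibril)  # validates
  data.frame(animal = as.integer(animal), tendon = tendon,
             fibril_number = as.integer(fibril), length_um = length_um,
             dry_area_um2 = dry_area_um2,
             cantilever_number = as.integer(cantilever_number),
             rupture_strain_pct = summary$rupture_strain_pct,
             rupture_stress_MPa = summary$rupture_stress_MPa,
             toughness_MJm3 = summary$toughness_MJm3,
             modulus_MPa = summary$modulus_MPa,
             modulus_error_MPa = summary$modulus_error_MPa,
             stringsAsFactors = FALSE)
}

.post_rupture_cols <- c("animal", "tendon", "fibril_number", "rupture_location",
                        "mean_height_before_nm", "height_loss_nm",
                        "normalized_height_loss_pct", "n_damage_sites",
                        "kink_spacing_nm", "fluorescent",
                        "shg_intensity_ratio", "rho_peak_ruptured",
                        "rho_fwhm_ruptured", "rho_peak_control",
                        "rho_fwhm_control")

#' Write / read the post-rupture imaging summary table
#'
#' Mirrors the deposition's post-rupture worksheet (columns A-O: identifier
#' triple, rupture location annotation, pre-rupture height and height loss,
#' damage-site count and spacing, fluorescence call, SHG intensity ratio, and
#' the anisotropy distribution peak/FWHM for ruptured and control portions).
#'
#' @param records data.frame with the fifteen documented columns.
#' @param file Path.
#' @export
write_post_rupture_table <- function(records, file) {
  if (is.null(records) || nrow(records) == 0)
    records <- as.data.frame(setNames(rep(list(numeric(0)),
                                          length(.post_rupture_cols)),
                                      .post_rupture_cols))
  if (!identical(names(records), .post_rupture_cols))
    stop("records must have exactly the documented A-O columns")
  write_full_precision(records, file)
}

#' @rdname write_post_rupture_table
#' @export
read_post_rupture_table <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = c(tendon = "character"))
  if (!identical(names(df), .post_rupture_cols))
    stop("file does not match the post-rupture A-O schema")
  df
}

#' Write / read a stress-strain curve file
#'
#' Two-column tab-delimited text, strain in percent then stress in MPa, named
#' by the fibril identifier (e.g. a file called `1e1`), matching the deposited
#' curve files.
#'
#' @param curve A `stress_strain_curve` (or data.frame `strain_pct`,
#'   `stress_MPa`).
#' @param id Fibril identifier; becomes the file name.
#' @param dir Directory to write into.
#' @return `write_stress_strain`: the file path, invisibly.
#'   `read_stress_strain`: a `stress_strain_curve`.
#' @export
write_stress_strain <- function(curve, id, dir = ".") {
  parse_fibril_id(id)  # validates the naming convention
  if (any(diff(curve$strain_pct) <= 0))
    stop("strain must be strictly increasing")
  path <- file.path(dir, id)
  write_full_precision(data.frame(strain_pct = curve$strain_pct,
                                  stress_MPa = curve$stress_MPa), path)
  invisible(path)
}

#' @rdname write_stress_strain
#' @param file Path to a curve file.
#' @export
read_stress_strain <- function(file) {
  df <- utils::read.delim(file)
  if (!identical(names(df), c("strain_pct", "stress_MPa")))
    stop("file does not match the two-column stress-strain schema")
  class(df) <- c("stress_strain_curve", "data.frame")
  df
}

#' Write / read a pull experiment as two delimited text tables
#'
#' `<prefix>_force.tsv` holds `time_s`, `force_uN`; `<prefix>_video.tsv` holds
#' `time_s`, `deflection_um`.
#'
#' @param experiment A `pull_experiment`.
#' @param prefix Path prefix for the two files.
#' @export
write_pull_experiment <- function(experiment, prefix) {
  write_full_precision(experiment$force, paste0(prefix, "_force.tsv"))
  write_full_precision(experiment$video, paste0(prefix, "_video.tsv"))
  invisible(prefix)
}

#' @rdname write_pull_experiment
#' @param segment_length_um,dry_area_um2 Specimen dimensions (carried in the
#'   tensile worksheet, not in the trace files).
#' @param rupture_frame_index Video annotation of the last frame with the
#'   fibril present, if known.
#' @export
read_pull_experiment <- function(prefix, segment_length_um, dry_area_um2,
                                 rupture_frame_index = NULL) {
  structure(list(force = utils::read.delim(paste0(prefix, "_force.tsv")),
                 video = utils::read.delim(paste0(prefix, "_video.tsv")),
                 segment_length_um = segment_length_um,
                 dry_area_um2 = dry_area_um2,
                 rupture_frame_index = rupture_frame_index,
                 truth = NULL),
            class = "pull_experiment")
}

# TIFF payloads are stored as 32-bit float pages scaled to [0,1]; the sidecar
# text file carries the scale, the pixel size and (for pol-stacks) the angle
# axis, so physical units survive the round trip.
.write_tiff_scaled <- function(pages, file, sidecar_lines) {
  sc <- max(1e-300, max(vapply(pages, max, numeric(1))))
  tiff::writeTIFF(lapply(pages, function(p) pmin(pmax(p / sc, 0), 1)),
                  file, bits.per.sample = 32L)
  writeLines(c(sprintf("scale\t%.17g", sc), sidecar_lines),
             paste0(file, ".meta.tsv"))
  invisible(file)
}

.read_tiff_scaled <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE)
  meta <- utils::read.delim(paste0(file, ".meta.tsv"), header = FALSE,
                            col.names = c("key", "value"),
                            stringsAsFactors = FALSE)
  sc <- as.numeric(meta$value[meta$key == "scale"][1])
  list(pages = lapply(pages, function(p) p * sc), meta = meta)
}

#' Write / read an SHG pol-stack as multi-page TIFF with angle sidecar
#'
#' The 25 grey-scale images are stored as one multi-page TIFF; the sidecar
#' `<file>.meta.tsv` records the intensity scale, pixel size (200 nm for the
#' acquisition emulated here) and the polarization-angle axis.
#'
#' @param stack A `polstack`.
#' @param file Path (conventionally named `<id>` or `<id>c` for controls).
#' @export
write_polstack <- function(stack, file) {
  .write_tiff_scaled(stack$images, file,
                     c(sprintf("pixel_nm\t%.17g", stack$pixel_nm),
                       sprintf("angle_deg\t%.17g", stack$angles_deg)))
}

#' @rdname write_polstack
#' @export
read_polstack <- function(file) {
  r <- .read_tiff_scaled(file)
  structure(list(images = r$pages,
                 angles_deg = as.numeric(r$meta$value[r$meta$key == "angle_deg"]),
                 pixel_nm = as.numeric(r$meta$value[r$meta$key == "pixel_nm"][1])),
            class = "polstack")
}

#' Write / read an AFM height map as TIFF with scale sidecar
#' @param map A `heightmap`.
#' @param file Path.
#' @export
write_heightmap <- function(map, file) {
  h <- map$heights
  off <- min(h)
  .write_tiff_scaled(list(h - off), file,
                     c(sprintf("pixel_nm\t%.17g", map$pixel_nm),
                       sprintf("offset_nm\t%.17g", off)))
}

#' @rdname write_heightmap
#' @export
read_heightmap <- function(file) {
  r <- .read_tiff_scaled(file)
  off <- as.numeric(r$meta$value[r$meta$key == "offset_nm"][1])
  structure(list(heights = r$pages[[1]] + off,
                 pixel_nm = as.numeric(r$meta$value[r$meta$key == "pixel_nm"][1])),
            class = "heightmap")
}

#' Write / read a two-channel fluorescence image as TIFF
#' @param image A `fluor_image`.
#' @param file Path.
#' @export
write_fluor_image <- function(image, file) {
  .write_tiff_scaled(list(image$brightfield, image$fluorescence), file,
                     c(sprintf("laser_power_mw\t%.17g", image$laser_power_mw)))
}

#' @rdname write_fluor_image
#' @export
read_fluor_image <- function(file) {
  r <- .read_tiff_scaled(file)
  structure(list(brightfield = r$pages[[1]], fluorescence = r$pages[[2]],
                 laser_power_mw =
                   as.numeric(r$meta$value[r$meta$key == "laser_power_mw"][1])),
            class = "fluor_image")
}

#' Run the full per-fibril analysis pipeline
#'
#' Orchestrates mechanics, AFM morphometry, SHG polarimetry and the
#' fluorescence call for a cohort of fibrils and writes the deposition-schema
#' outputs: the tensile summary table, one stress-strain file per fibril, the
#' post-rupture summary table, and a structured log. A stage failure (or a
#' missing input) for one fibril leaves that fibril's columns empty and the
#' pipeline continues with the remaining fibrils. Given identical inputs and
#' config the outputs are byte-identical.
#'
#' @param config A list, or the path of a YAML file. Fields: `out_dir`
#'   (created if absent) and `fibrils`, a list whose elements each contain
#'   `animal`, `tendon`, `fibril`, optional `cantilever_number`,
#'   `rupture_location`, and inputs `pull` (a `pull_experiment` or a file
#'   prefix for [read_pull_experiment()], with `segment_length_um` and
#'   `dry_area_um2` alongside when read from file), `afm_before`, `afm_after`
#'   (`heightmap`s or TIFF paths), `polstack`, `polstack_control` (`polstack`s
#'   or TIFF paths), `fluor` (`fluor_image` or TIFF path).
#' @return Invisibly, a list with `tensile` and `post_rupture` data.frames,
#'   `files` (paths written), and `errors` (per-fibril stage failures).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  errors <- list()
  tens <- list(); post <- list(); files <- character(0)

  load_in <- function(x, reader, ...) {
    if (is.null(x)) NULL
    else if (is.character(x)) reader(x, ...)
    else x
  }
  note <- function(id, stage, msg) {
    errors[[id]] <<- c(errors[[id]], stats::setNames(msg, stage))
    log_lines <<- c(log_lines, sprintf("%s\t%s\tERROR\t%s", id, stage, msg))
  }

  for (fb in config$fibrils) {
    id <- fibril_id(fb$animal, fb$tendon, fb$fibril)
    log_lines <- c(log_lines, sprintf("%s\tstart", id))

    # --- mechanics ---
    mech <- NULL
    pull <- if (is.character(fb$pull)) {
      read_pull_experiment(fb$pull, fb$segment_length_um, fb$dry_area_um2,
                           fb$rupture_frame_index)
    } else fb$pull
    if (!is.null(pull)) {
      mech <- tryCatch(analyze_pull(pull),
                       error = function(e) { note(id, "mechanics",
                                                  conditionMessage(e)); NULL })
    }
    if (!is.null(mech)) {
      sm <- mech$summary
      tens[[id]] <- tensile_record(fb$animal, fb$tendon, fb$fibril,
                                   pull$segment_length_um, pull$dry_area_um2,
                                   fb$cantilever_number %||% NA_integer_, sm)
      cf <- write_stress_strain(mech$curve, id, out_dir)
      files <- c(files, cf)
      log_lines <- c(log_lines,
                     sprintf("%s\tmechanics\tok\trupture %.4g%% %.4g MPa", id,
                             sm$rupture_strain_pct, sm$rupture_stress_MPa))
    }

    # --- AFM morphometry ---
    hl <- list(mean_before_nm = NA_real_, loss_nm = NA_real_,
               normalized_loss_pct = NA_real_)
    kk <- list(count = NA_integer_, mean_spacing_nm = NA_real_)
    before <- load_in(fb$afm_before, read_heightmap)
    after <- load_in(fb$afm_after, read_heightmap)
    if (!is.null(before) && !is.null(after)) {
      hl <- tryCatch(height_loss(before, after),
                     error = function(e) { note(id, "afm_height",
                                                conditionMessage(e)); hl })
    }
    if (!is.null(after)) {
      kk <- tryCatch(detect_kinks(after),
                     error = function(e) { note(id, "afm_kinks",
                                                conditionMessage(e)); kk })
    }

    # --- SHG ---
    shg_ratio <- NA_real_
    pk_r <- fw_r <- pk_c <- fw_c <- NA_real_
    st <- load_in(fb$polstack, read_polstack)
    stc <- load_in(fb$polstack_control, read_polstack)
    if (!is.null(st)) {
      res <- tryCatch({
        mm <- max_intensity_map(st)
        msk <- shg_fibril_mask(mm)
        dist <- rho_distribution(rho_map(st, msk))
        pk_r <- dist$peak; fw_r <- dist$fwhm
        if (!is.null(stc)) {
          mmc <- max_intensity_map(stc)
          mskc <- shg_fibril_mask(mmc)
          distc <- rho_distribution(rho_map(stc, mskc))
          pk_c <- distc$peak; fw_c <- distc$fwhm
          shg_ratio <- intensity_ratio(mm, mmc, msk, mskc)
        }
        TRUE
      }, error = function(e) { note(id, "shg", conditionMessage(e)); FALSE })
      if (res) log_lines <- c(log_lines,
                              sprintf("%s\tshg\tok\trho peak %.4g", id, pk_r))
    }

    # --- fluorescence ---
    fl_call <- NA_character_
    fim <- load_in(fb$fluor, read_fluor_image)
    if (!is.null(fim)) {
      fl_call <- tryCatch({
        fmask <- mask_from_brightfield(fim)
        bmask <- !fmask
        if (classify_fibril(fim, fmask, bmask)$positive) "Yes" else "No"
      }, error = function(e) { note(id, "fluorescence",
                                    conditionMessage(e)); NA_character_ })
    }

    post[[id]] <- data.frame(
      animal = as.integer(fb$animal), tendon = fb$tendon,
      fibril_number = as.integer(fb$fibril),
      rupture_location = fb$rupture_location %||% NA_character_,
      mean_height_before_nm = hl$mean_before_nm,
      height_loss_nm = hl$loss_nm,
      normalized_height_loss_pct = hl$normalized_loss_pct,
      n_damage_sites = kk$count, kink_spacing_nm = kk$mean_spacing_nm,
      fluorescent = fl_call, shg_intensity_ratio = shg_ratio,
      rho_peak_ruptured = pk_r, rho_fwhm_ruptured = fw_r,
      rho_peak_control = pk_c, rho_fwhm_control = fw_c,
      stringsAsFactors = FALSE)
  }

  tensile <- if (length(tens)) do.call(rbind, c(tens, list(make.row.names = FALSE))) else NULL
  post_rupture <- if (length(post)) do.call(rbind, c(post, list(make.row.names = FALSE))) else NULL
  f1 <- file.path(out_dir, "tensile_data.tsv")
  f4 <- file.path(out_dir, "post_rupture_data.tsv")
  write_tensile_table(tensile, f1)
  write_post_rupture_table(post_rupture, f4)
  lg <- file.path(out_dir, "pipeline_log.tsv")
  writeLines(log_lines, lg)
  invisible(list(tensile = tensile, post_rupture = post_rupture,
                 files = c(f1, f4, lg, files), errors = errors))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
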