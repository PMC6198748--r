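#' Lateral spring constant of a board-shaped AFM cantilever
#'
#' Converts the thermally calibrated vertical spring constant of a board-shaped
#' cantilever into the lateral (torsional) spring constant that governs in-plane
#' tip forces:
#' \deqn{K_L = \frac{2 L^2 K_z}{3 (1+\nu) H^2}}
#' where `L` is the cantilever length, `H` the tip height (including half the
#' board thickness) and `nu` the Poisson ratio of the cantilever material.
#'
#' @param length_um Cantilever length L in micrometres.
#' @param tip_height_um Tip height H in micrometres, measured from the torsion
#'   axis (i.e. including half the board thickness).
#' @param kz_Nm Vertical spring constant in N/m.
#' @param nu Poisson ratio of the cantilever material; defaults to 0.27, the
#'   value for silicon <111>.
#' @return Lateral spring constant in N/m.
#' @details The formula is dimensionally homogeneous in (L, H): any consistent
#'   unit rescaling of both lengths leaves the result unchanged.
#' @seealso [lateral_sensitivity()], [cantilever_spec()]
#' @export
#' @examples
#' lateral_spring_constant(225, 17.5, 40)  # ~3.5e3 N/m
lateral_spring_constant <- function(length_um, tip_height_um, kz_Nm, nu = 0.27) {
  stopifnot(is.numeric(length_um), is.numeric(tip_height_um), is.numeric(kz_Nm))
  if (any(length_um <= 0) || any(tip_height_um <= 0) || any(kz_Nm <= 0))
    stop("cantilever geometry and vertical spring constant must be positive")
  if (any(nu < 0) || any(nu >= 0.5))
    stop("Poisson ratio must lie in [0, 0.5)")
  2 * length_um^2 * kz_Nm / (3 * (1 + nu) * tip_height_um^2)
}

#' Lateral deflection sensitivity of a board-shaped AFM cantilever
#'
#' Converts the vertical photodiode sensitivity measured on a hard substrate
#' into the lateral sensitivity:
#' \deqn{S_L = \frac{3 H S_z}{2 L}}
#'
#' @inheritParams lateral_spring_constant
#' @param sz_nmV Vertical deflection sensitivity in nm/V.
#' @return Lateral deflection sensitivity in nm/V.
#' @export
#' @examples
#' lateral_sensitivity(17.5, 100, 225)  # ~11.7 nm/V
lateral_sensitivity <- function(tip_height_um, sz_nmV, length_um) {
  stopifnot(is.numeric(tip_height_um), is.numeric(sz_nmV), is.numeric(length_um))
  if (any(tip_height_um <= 0) || any(sz_nmV <= 0) || any(length_um <= 0))
    stop("tip height, vertical sensitivity and length must be positive")
  3 * tip_height_um * sz_nmV / (2 * length_um)
}

#' Cantilever calibration record
#'
#' Bundles the measured geometry and vertical calibration of a tensile-testing
#' cantilever with the derived lateral spring constant and sensitivity. The
#' derived fields always satisfy the two calibration formulas exactly.
#'
#' @inheritParams lateral_spring_constant
#' @inheritParams lateral_sensitivity
#' @param number Integer cantilever number (identifier in the spec sheet).
#' @param manufacturer,model,type,material Free-text metadata columns.
#' @return An object of class `cantilever_spec`: a list with fields
#'   `number`, `manufacturer`, `model`, `type`, `material`, `length_um`,
#'   `tip_height_um`, `kz_Nm`, `sz_nmV`, `nu`, `kl_Nm`, `sl_nmV`.
#' @export
cantilever_spec <- function(length_um, tip_height_um, kz_Nm, sz_nmV,
                            nu = 0.27, number = 1L,
                            manufacturer = "synthetic", model = "synthetic",
                            type = "board", material = "Si") {
  kl <- lateral_spring_constant(length_um, tip_height_um, kz_Nm, nu)
  sl <- lateral_sensitivity(tip_height_um, sz_nmV, length_um)
  structure(list(number = as.integer(number), manufacturer = manufacturer,
                 model = model, type = type, material = material,
                 length_um = length_um, tip_height_um = tip_height_um,
                 kz_Nm = kz_Nm, sz_nmV = sz_nmV, nu = nu,
                 kl_Nm = kl, sl_nmV = sl),
            class = "cantilever_spec")
}

#' @export
print.cantilever_spec <- function(x, ...) {
  cat(sprintf("Cantilever %d (%s %s)\n", x$number, x$manufacturer, x$model))
  cat(sprintf("  L = %g um, H = %g um, nu = %g\n",
              x$length_um, x$tip_height_um, x$nu))
  cat(sprintf("  Kz = %g N/m, Sz = %g nm/V\n", x$kz_Nm, x$sz_nmV))
  cat(sprintf("  KL = %.4g N/m, SL = %.4g nm/V\n", x$kl_Nm, x$sl_nmV))
  invisible(x)
}

#' Convert lateral photodiode signal to force
#'
#' Applies the calibrated conversion `F = K_L * S_L * signal`, resolving units
#' so the result is in micronewtons (K_L in N/m, S_L in nm/V: 1 N/m * 1 nm/V *
#' 1 V = 1 nN).
#'
#' @param signal_V Lateral photodiode signal in volts (vector allowed).
#' @param spec A [cantilever_spec()] with derived fields populated.
#' @return Lateral force in uN, same length as `signal_V`.
#' @export
lateral_force <- function(signal_V, spec) {
  if (!inherits(spec, "cantilever_spec"))
    stop("`spec` must be a cantilever_spec")
  if (is.null(spec$kl_Nm) || is.null(spec$sl_nmV) ||
      !is.finite(spec$kl_Nm) || !is.finite(spec$sl_nmV))
    stop("derived fields kl_Nm / sl_nmV are missing from the cantilever spec")
  # N/m * nm/V * V = nN; report uN
  spec$kl_Nm * spec$sl_nmV * signal_V / 1000
}

#' Invert [lateral_force()]: force in uN back to photodiode volts
#' @param force_uN Lateral force in uN.
#' @inheritParams lateral_force
#' @return Signal in volts.
#' @export
lateral_signal <- function(force_uN, spec) {
  if (!inherits(spec, "cantilever_spec"))
    stop("`spec` must be a cantilever_spec")
  force_uN * 1000 / (spec$kl_Nm * spec$sl_nmV)
}

# Spec-sheet columns A-I (delimited-text mirror of the deposition worksheet).
.cantilever_sheet_cols <- c("cantilever_number", "manufacturer", "model",
                            "type", "material", "length_um", "tip_height_um",
                            "vertical_spring_Nm", "lateral_spring_Nm")

#' Write / read a cantilever spec sheet
#'
#' Mirrors the deposition's cantilever worksheet (columns A-I: number,
#' manufacturer, model, type, material, length um, tip height um, vertical
#' spring N/m, lateral spring N/m) as tab-delimited text.
#'
#' @param specs A list of [cantilever_spec()] objects.
#' @param file Path to write to / read from.
#' @return `write_cantilever_sheet` returns `file` invisibly;
#'   `read_cantilever_sheet` returns a data.frame with columns A-I.
#' @export
write_cantilever_sheet <- function(specs, file) {
  if (inherits(specs, "cantilever_spec")) specs <- list(specs)
  rows <- lapply(specs, function(s) {
    data.frame(cantilever_number = s$number, manufacturer = s$manufacturer,
               model = s$model, type = s$type, material = s$material,
               length_um = s$length_um, tip_height_um = s$tip_height_um,
               vertical_spring_Nm = s$kz_Nm, lateral_spring_Nm = s$kl_Nm,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) df <- as.data.frame(setNames(rep(list(character(0)),
                                                    length(.cantilever_sheet_cols)),
                                                .cantilever_sheet_cols))
  write_full_precision(df, file)
  invisible(file)
}

#' @rdname write_cantilever_sheet
#' @export
read_cantilever_sheet <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!identical(names(df), .cantilever_sheet_cols))
    stop("cantilever sheet columns do not match the expected A-I schema")
  df
}
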