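# Acquisition protocol and tissue parameter containers.

#' Acquisition protocol for a long-TR multi-echo spoiled gradient-echo scan
#'
#' Bundles the sequence metadata that governs all signal physics: repetition
#' time, nominal flip angle, the scanner-dependent calibration factor relating
#' effective to nominal flip angle, the echo-time train, voxel geometry and
#' field strength. Echo times are held in milliseconds at the interface and
#' converted to seconds inside physics computations.
#'
#' @param tr_s repetition time in seconds (default 10, the long-TR regime in
#'   which WM/GM steady-state saturation is negligible).
#' @param flip_deg nominal excitation flip angle in degrees (default 90).
#' @param cal_factor ratio of effective to nominal flip angle, a fixed scanner
#'   property (default 0.8, typical of automatic transmitter calibration).
#' @param te_ms strictly increasing echo times in milliseconds. If `NULL`,
#'   generated as `te1_ms + dte_ms * (0:(n_echoes-1))`.
#' @param te1_ms,dte_ms,n_echoes echo-train generator: first echo time,
#'   echo spacing (ms) and number of echoes (defaults 3.87, 4.08, 32).
#' @param voxel_mm voxel dimensions (dx, dy, dz) in mm; dz is the excited
#'   slice thickness entering the through-slice dephasing factor.
#' @param field_t static field strength in tesla (used only to convert ppm
#'   off-resonance to Hz).
#' @return an object of class `acq_protocol`.
#' @export
acq_protocol <- function(tr_s = 10, flip_deg = 90, cal_factor = 0.8,
                         te_ms = NULL, te1_ms = 3.87, dte_ms = 4.08,
                         n_echoes = 32L, voxel_mm = c(1.04, 1.38, 1.5),
                         field_t = 3.0) {
  if (is.null(te_ms)) te_ms <- te1_ms + dte_ms * (seq_len(n_echoes) - 1)
  stopifnot(tr_s > 0, flip_deg > 0, flip_deg <= 180,
            cal_factor > 0, cal_factor <= 1.5,
            all(te_ms > 0), all(diff(te_ms) > 0),
            length(voxel_mm) == 3, all(voxel_mm > 0), field_t > 0)
  structure(list(tr_s = tr_s, flip_deg = flip_deg, cal_factor = cal_factor,
                 te_ms = as.numeric(te_ms), voxel_mm = as.numeric(voxel_mm),
                 field_t = field_t, gamma = GAMMA_PROTON),
            class = "acq_protocol")
}

#' Effective flip angle of a protocol
#' @param protocol an [acq_protocol()].
#' @return degrees, `cal_factor * flip_deg`.
#' @export
flip_effective <- function(protocol) protocol$cal_factor * protocol$flip_deg

#' @export
print.acq_protocol <- function(x, ...) {
  cat(sprintf("mGRE protocol: TR %.3g s, flip %g deg (eff. %g), %d echoes TE %.2f..%.2f ms\n",
              x$tr_s, x$flip_deg, flip_effective(x), length(x$te_ms),
              x$te_ms[1], x$te_ms[length(x$te_ms)]))
  cat(sprintf("  voxel %.2f x %.2f x %.2f mm, %g T\n",
              x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3], x$field_t))
  invisible(x)
}

#' Write / read a protocol JSON sidecar
#'
#' The sidecar stores `tr_s`, `flip_deg`, `cal_factor`, `te_ms`, `voxel_mm`
#' and `field_T`, matching the metadata that accompanies exported scanner data.
#'
#' @param protocol an [acq_protocol()].
#' @param path JSON file path.
#' @return `path` invisibly (writer); an `acq_protocol` (reader).
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(
    list(tr_s = protocol$tr_s, flip_deg = protocol$flip_deg,
         cal_factor = protocol$cal_factor, te_ms = protocol$te_ms,
         voxel_mm = protocol$voxel_mm, field_T = protocol$field_t),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  acq_protocol(tr_s = j$tr_s, flip_deg = j$flip_deg, cal_factor = j$cal_factor,
               te_ms = j$te_ms, voxel_mm = j$voxel_mm,
               field_t = j$field_T %||% j$field_t %||% 3.0)
}

#' Tissue parameter set
#'
#' Relaxation and water-content parameters for one tissue class, used by the
#' phantom generator and the forward signal model.
#'
#' @param water_pct MR-visible water content, percent of voxel volume (0-100).
#' @param t1 longitudinal relaxation time, seconds.
#' @param t2star effective transverse relaxation time, milliseconds.
#' @param freq_offset_ppm static-field off-resonance in ppm (converted to Hz
#'   at the protocol's field strength).
#' @param label tissue label, one of "WM", "GM", "CSF", "background", "custom".
#' @return an object of class `tissue_params`.
#' @export
tissue_params <- function(water_pct, t1, t2star, freq_offset_ppm = 0,
                          label = "custom") {
  stopifnot(water_pct >= 0, water_pct <= 100, t1 > 0, t2star > 0)
  label <- match.arg(label, c("WM", "GM", "CSF", "background", "custom"))
  structure(list(water_pct = water_pct, t1 = t1, t2star = t2star,
                 freq_offset_ppm = freq_offset_ppm, label = label),
            class = "tissue_params")
}

#' Default brain tissue parameter table
#'
#' WM/GM water contents follow invasive and in-vivo consensus values
#' (WM ~69%, GM ~83%); CSF is treated as pure water. T2* defaults are the
#' 3T class means (WM 50.0 ms, GM 55.7 ms).
#' @return named list of [tissue_params()] (WM, GM, CSF, background).
#' @export
brain_tissue_defaults <- function() {
  list(WM  = tissue_params(69,  0.9, 50.0,  label = "WM"),
       GM  = tissue_params(83,  1.4, 55.7,  label = "GM"),
       CSF = tissue_params(100, 4.3, 200.0, label = "CSF"),
       background = tissue_params(0, 1, 1, label = "background"))
}
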