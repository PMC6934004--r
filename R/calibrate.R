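# CSF-based calibration: the mode of the cerebrospinal-fluid intensity
# distribution is an internal standard for 100% water, after accounting for
# the residual T1 saturation of CSF at TR = 10 s (steady-state factor ~0.93
# at 3T with an effective flip angle of 0.8 x 90 deg; 1.0 is used at 1.5T
# where full relaxation is assumed).

#' CSF intensity mode
#'
#' Histogram mode (with parabolic interpolation, over the central 99% of the
#' intensity range) of all voxels whose CSF posterior probability exceeds
#' 0.98. The mode -- not the mean -- is used because the full CSF
#' distribution is broad and asymmetric while the ventricle-like peak is
#' narrow and well defined.
#'
#' @param s0_corrected bias-corrected TE = 0 intensity array.
#' @param csf_prob CSF posterior probability array (same shape).
#' @param bins histogram bins (default 128).
#' @param prob_threshold CSF probability cut (default 0.98).
#' @param min_voxels minimum number of qualifying voxels (default 100).
#' @return the CSF mode in signal units, with attribute `n_csf_voxels`.
#' @export
csf_mode <- function(s0_corrected, csf_prob, bins = 128L,
                     prob_threshold = 0.98, min_voxels = 100L) {
  sel <- csf_prob > prob_threshold & is.finite(s0_corrected)
  n <- sum(sel)
  if (n < min_voxels) {
    stop(sprintf(paste0("only %d voxels have CSF probability > %.2f ",
                        "(need >= %d); enlarge the ROI or lower the threshold"),
                 n, prob_threshold, min_voxels))
  }
  m <- hist_mode(s0_corrected[sel], bins = bins, trim = 0.99)
  attr(m, "n_csf_voxels") <- n
  m
}

#' Steady-state factor for CSF under a protocol
#'
#' `steady_state_factor(TR, csf_t1, cal_factor * flip_nominal)`; rounded only
#' at reporting time. An explicit `override` (e.g. 1.0 for a 1.5T full
#' relaxation assumption) bypasses the computation.
#'
#' @param protocol an [acq_protocol()].
#' @param csf_t1 CSF longitudinal relaxation time, seconds (default 4.3,
#'   field-independent literature value).
#' @param override optional fixed factor.
#' @return dimensionless factor in (0, 1].
#' @export
compute_csf_ss_factor <- function(protocol, csf_t1 = 4.3, override = NULL) {
  if (!is.null(override)) {
    stopifnot(override > 0, override <= 1)
    return(override)
  }
  steady_state_factor(protocol$tr_s, csf_t1, flip_effective(protocol))
}

#' Calibration record
#'
#' @param csf_mode CSF intensity mode, signal units.
#' @param ss_factor_csf CSF steady-state factor (default 0.93).
#' @param csf_t1 CSF T1 used, seconds.
#' @param n_csf_voxels number of CSF voxels entering the mode.
#' @param histogram_bins bins used for the mode.
#' @return a `calibration_record`; `scale` is percent per signal unit,
#'   `ss_factor_csf * 100 / csf_mode`, so a voxel at exactly the CSF mode
#'   maps to `ss_factor_csf * 100` (93% at 3T: the CSF signal is genuinely
#'   saturated) and unsaturated tissue of true water W maps to W.
#' @export
calibration_record <- function(csf_mode, ss_factor_csf = 0.93, csf_t1 = 4.3,
                               n_csf_voxels = NA_integer_,
                               histogram_bins = 128L) {
  stopifnot(csf_mode > 0, ss_factor_csf > 0, ss_factor_csf <= 1)
  structure(list(csf_mode = as.numeric(csf_mode),
                 ss_factor_csf = ss_factor_csf, csf_t1 = csf_t1,
                 n_csf_voxels = n_csf_voxels, histogram_bins = histogram_bins,
                 scale = ss_factor_csf * 100 / as.numeric(csf_mode)),
            class = "calibration_record")
}

#' Convert corrected intensities to percent water content
#'
#' `h2o = s0_corrected * scale`. Values above `clip_max` are clipped for
#' display and the clip count recorded (never silent). An optional
#' `rescale_csf` re-divides CSF-classified voxels by the steady-state factor
#' so they display near 100%; off by default to keep a single global linear
#' map.
#'
#' @param s0_corrected bias-corrected intensity array.
#' @param record a [calibration_record()].
#' @param masks optional named list of logical arrays (brain/WM/GM/CSF).
#' @param clip_max display clip, percent (default 120).
#' @param rescale_csf logical (default FALSE), see above.
#' @param provenance optional list of processing parameters carried along.
#' @return a `water_map`: `h2o` (percent array), `calibration`, `masks`,
#'   `n_clipped`, `provenance`.
#' @export
calibrate_map <- function(s0_corrected, record, masks = NULL, clip_max = 120,
                          rescale_csf = FALSE, provenance = list()) {
  stopifnot(inherits(record, "calibration_record"))
  h2o <- s0_corrected * record$scale
  if (rescale_csf && !is.null(masks$CSF)) {
    h2o[masks$CSF] <- h2o[masks$CSF] / record$ss_factor_csf
  }
  n_clipped <- sum(h2o > clip_max, na.rm = TRUE)
  h2o <- pmin(h2o, clip_max)
  h2o <- pmax(h2o, 0)
  structure(list(h2o = h2o, calibration = record, masks = masks,
                 n_clipped = n_clipped, clip_max = clip_max,
                 provenance = provenance),
            class = "water_map")
}

#' @export
print.water_map <- function(x, ...) {
  cat(sprintf("water map: %s voxels, CSF mode %.4g -> scale %.4g %%/unit (ss factor %.3f)\n",
              paste(dim(x$h2o), collapse = "x"), x$calibration$csf_mode,
              x$calibration$scale, x$calibration$ss_factor_csf))
  if (x$n_clipped > 0) cat(sprintf("  %d voxels clipped at %g%%\n", x$n_clipped, x$clip_max))
  invisible(x)
}

#' Write a water map and its calibration record
#' @param map a `water_map`.
#' @param dir output directory.
#' @param prefix file prefix.
#' @param voxel_mm voxel size for the NIfTI header.
#' @return named list of paths, invisibly.
#' @export
write_water_map <- function(map, dir, prefix = "h2o", voxel_mm = c(1, 1, 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_map <- file.path(dir, paste0(prefix, "_pct.nii.gz"))
  write_nifti(map$h2o, p_map, voxdim = voxel_mm)
  p_json <- file.path(dir, paste0(prefix, "_calibration.json"))
  rec <- map$calibration
  jsonlite::write_json(list(csf_mode = rec$csf_mode,
                            ss_factor_csf = rec$ss_factor_csf,
                            csf_t1 = rec$csf_t1,
                            n_csf_voxels = rec$n_csf_voxels,
                            histogram_bins = rec$histogram_bins,
                            scale = rec$scale, n_clipped = map$n_clipped),
                       p_json, auto_unbox = TRUE, digits = NA)
  invisible(list(map = p_map, calibration = p_json))
}
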