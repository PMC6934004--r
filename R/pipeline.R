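# End-to-end composition: decay fit -> bias removal -> CSF calibration ->
# tissue statistics, plus the command-line front end.

#' Run the single-scan water-mapping pipeline in memory
#'
#' Composes the full chain on an `echo_series`: voxel-wise decay fit (with
#' optional background-gradient/sinc correction), joint segmentation and
#' bias-field removal, CSF-mode calibration, and tissue statistics.
#'
#' @param series an `echo_series`.
#' @param correct_gradients estimate background gradients from phase and
#'   sinc-correct the through-slice dephasing (default TRUE when phase data
#'   are present).
#' @param bias_correct run the mixture-model bias estimation (default TRUE).
#'   When FALSE, `csf_prob` must be supplied (e.g. phantom ground truth) and
#'   the S0 map is used uncorrected.
#' @param n_classes,basis_order,seg_seed,fg_frac segmentation controls, see
#'   [segment_and_debias()].
#' @param seg_passes number of segmentation/bias passes (default 2, mirroring
#'   the two-run unified-segmentation practice): each pass re-estimates the
#'   mixture and a residual field on the corrected image; the fields compose
#'   multiplicatively. A second pass removes most residual curvature left by
#'   the first.
#' @param cal_bins histogram bins for the CSF mode (default 128).
#' @param csf_prob_threshold CSF posterior probability cut for the
#'   calibration voxels (default 0.98). At low SNR a broad mixture component
#'   can cap posteriors just below 0.98 and empty the selection; lowering the
#'   cut (e.g. 0.9) is the documented remedy.
#' @param ss_factor CSF steady-state factor override; default computed from
#'   the protocol and `csf_t1` via [compute_csf_ss_factor()].
#' @param csf_t1 CSF T1 in seconds (default 4.3).
#' @param csf_prob optional CSF probability array overriding the segmentation
#'   (required when `bias_correct = FALSE`).
#' @param masks optional tissue masks overriding those derived from the
#'   segmentation.
#' @param max_echoes,weights_mode,phi0_subtract decay-fit controls, see
#'   [fit_volume()].
#' @param stats_bins,stats_range tissue-statistics controls.
#' @return list with elements `decay` (`decay_maps`), `seg`
#'   (`segmentation_result` or NULL), `s0_corrected`, `record`
#'   (`calibration_record`), `map` (`water_map`), `stats` (`tissue_stats`
#'   or NULL when no WM/GM masks exist).
#' @export
map_water <- function(series, correct_gradients = !is.null(series$phase),
                      bias_correct = TRUE, n_classes = 4L, basis_order = 4L,
                      seg_passes = 2L, seg_seed = 1L, fg_frac = 0.05,
                      cal_bins = 128L,
                      csf_prob_threshold = 0.98,
                      ss_factor = NULL, csf_t1 = 4.3, csf_prob = NULL,
                      masks = NULL, max_echoes = NULL,
                      weights_mode = "intensity2", phi0_subtract = TRUE,
                      stats_bins = 64L, stats_range = c(40, 110)) {
  decay <- fit_volume(series, correct_gradients = correct_gradients,
                      weights_mode = weights_mode, max_echoes = max_echoes,
                      phi0_subtract = phi0_subtract)
  s0 <- decay$s0
  s0[!decay$valid] <- 0
  seg <- NULL
  bias_total <- NULL
  if (bias_correct) {
    s0c <- s0
    for (pass in seq_len(max(seg_passes, 1L))) {
      seg <- segment_and_debias(s0c, n_classes = n_classes,
                                basis_order = basis_order, seed = seg_seed,
                                fg_frac = fg_frac)
      s0c <- apply_bias_correction(s0c, seg)
      bias_total <- if (is.null(bias_total)) seg$bias else bias_total * seg$bias
    }
    if (is.null(csf_prob)) {
      if (n_classes < 3L) {
        stop("n_classes < 3: supply csf_prob explicitly for calibration")
      }
      csf_prob <- tissue_posteriors(seg)$CSF
    }
    if (is.null(masks) && n_classes >= 3L) {
      masks <- tissue_masks(seg)
      masks$brain <- brain_mask(seg)
    }
  } else {
    if (is.null(csf_prob)) {
      stop("bias_correct = FALSE requires a csf_prob array for calibration")
    }
    s0c <- s0
  }
  ssf <- ss_factor %||% compute_csf_ss_factor(series$protocol, csf_t1)
  cm <- csf_mode(s0c, csf_prob, bins = cal_bins,
                 prob_threshold = csf_prob_threshold)
  record <- calibration_record(cm, ss_factor_csf = ssf, csf_t1 = csf_t1,
                               n_csf_voxels = attr(cm, "n_csf_voxels"),
                               histogram_bins = cal_bins)
  map <- calibrate_map(s0c, record, masks = masks)
  stats <- if (!is.null(masks) && all(c("WM", "GM") %in% names(masks))) {
    tissue_statistics(map, bins = stats_bins, range = stats_range)
  } else NULL
  list(decay = decay, seg = seg, bias = bias_total, s0_corrected = s0c,
       record = record, map = map, stats = stats)
}

# ---- command-line front end -------------------------------------------------

#' Simulate a phantom acquisition to disk
#'
#' @param config named list: `out_dir` (required), `kind` ("brain" or
#'   "revolver"), `grid` (length-3 integer), `noise_sd`, `snr` (overrides
#'   noise_sd via [noise_sd_for_snr()]), `seed`, `bias` ("flat" or "dct"),
#'   `bias_log_sd`, `b0_kind` ("none"/"ramp"/"hotspot"), `b0_gz`, `jitter_sd`,
#'   plus protocol fields `tr_s`, `flip_deg`, `cal_factor`, `n_echoes`,
#'   `te1_ms`, `dte_ms`.
#' @return invisibly, the list of written paths (magnitude/phase NIfTI,
#'   protocol sidecar, ground-truth NIfTI bundle and truth manifest JSON).
#' @export
cmd_simulate <- function(config) {
  cfg <- config
  stopifnot(!is.null(cfg$out_dir))
  kind <- cfg$kind %||% "brain"
  grid <- as.integer(cfg$grid %||% c(64L, 64L, 24L))
  seed <- as.integer(cfg$seed %||% 1L)
  bias_kind <- cfg$bias %||% "flat"
  bspec_t <- field_spec(bias_kind, log_sd = cfg$bias_log_sd %||% 0.05,
                        seed = seed + 11L)
  bspec_r <- field_spec(bias_kind, log_sd = cfg$bias_log_sd %||% 0.05,
                        seed = seed + 23L)
  b0 <- b0_spec(cfg$b0_kind %||% "none", gz = cfg$b0_gz %||% 0)
  spec <- phantom_spec(kind = kind, grid_shape = grid,
                       jitter_sd = cfg$jitter_sd %||% 0,
                       bias_transmit = bspec_t, bias_receive = bspec_r,
                       b0 = b0, noise_sd = cfg$noise_sd %||% 0, seed = seed)
  truth <- if (kind == "brain") make_brain_phantom(spec) else make_revolver_phantom(spec)
  protocol <- acq_protocol(tr_s = cfg$tr_s %||% 10, flip_deg = cfg$flip_deg %||% 90,
                           cal_factor = cfg$cal_factor %||% 0.8,
                           n_echoes = as.integer(cfg$n_echoes %||% 32L),
                           te1_ms = cfg$te1_ms %||% 3.87,
                           dte_ms = cfg$dte_ms %||% 4.08,
                           voxel_mm = spec$voxel_mm)
  noise_sd <- spec$noise_sd
  if (!is.null(cfg$snr)) noise_sd <- noise_sd_for_snr(truth, protocol, cfg$snr)
  series <- simulate_echo_series(truth, protocol, noise_sd = noise_sd, seed = seed)
  paths <- write_echo_series(series, cfg$out_dir)
  # ground-truth bundle
  tdir <- file.path(cfg$out_dir, "truth")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("water_map", "t1_map", "t2star_map", "bias_transmit_map",
               "bias_receive_map", "gz_map")) {
    p <- file.path(tdir, paste0(nm, ".nii.gz"))
    write_nifti(truth[[nm]], p, voxdim = truth$voxel_mm)
    paths[[nm]] <- p
  }
  p_lab <- file.path(tdir, "label_map.nii.gz")
  write_nifti(truth$label_map + 0, p_lab, voxdim = truth$voxel_mm)
  paths$label_map <- p_lab
  p_manifest <- file.path(tdir, "truth_manifest.json")
  jsonlite::write_json(list(kind = kind, grid = grid, labels = truth$labels,
                            noise_sd = noise_sd, seed = seed),
                       p_manifest, auto_unbox = TRUE, digits = NA)
  paths$manifest <- p_manifest
  write_resolved_config(cfg, file.path(cfg$out_dir, "simulate_config.json"))
  invisible(paths)
}

#' Run the mapping pipeline on files
#'
#' @param config named list: `magnitude`, `protocol` (paths, required),
#'   `phase` (path, required unless `correct_gradients` is FALSE),
#'   `out_dir` (required), plus `correct_gradients`, `n_classes`,
#'   `basis_order`, `cal_bins`, `ss_factor`, `csf_t1`, `seed`, `max_echoes`.
#' @return invisibly, the pipeline result of [map_water()] with an extra
#'   `paths` element.
#' @export
cmd_map <- function(config) {
  cfg <- config
  stopifnot(!is.null(cfg$magnitude), !is.null(cfg$protocol), !is.null(cfg$out_dir))
  correct <- cfg$correct_gradients %||% TRUE
  if (correct && is.null(cfg$phase)) {
    stop("gradient correction requires phase volumes; pass phase= or set correct_gradients FALSE")
  }
  series <- read_echo_series(cfg$magnitude, cfg$phase, cfg$protocol)
  t0 <- proc.time()[["elapsed"]]
  res <- map_water(series, correct_gradients = correct,
                   n_classes = as.integer(cfg$n_classes %||% 4L),
                   basis_order = as.integer(cfg$basis_order %||% 4L),
                   seg_seed = as.integer(cfg$seed %||% 1L),
                   cal_bins = as.integer(cfg$cal_bins %||% 128L),
                   ss_factor = cfg$ss_factor, csf_t1 = cfg$csf_t1 %||% 4.3,
                   max_echoes = cfg$max_echoes)
  elapsed <- proc.time()[["elapsed"]] - t0
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_decay_maps(res$decay, cfg$out_dir)
  paths <- c(paths, write_water_map(res$map, cfg$out_dir,
                                    voxel_mm = series$voxel_mm))
  if (!is.null(res$seg)) {
    p_bias <- file.path(cfg$out_dir, "bias_field.nii.gz")
    write_nifti(res$bias, p_bias, voxdim = series$voxel_mm)
    paths$bias <- p_bias
    p_seg <- file.path(cfg$out_dir, "segmentation_report.json")
    jsonlite::write_json(list(class_params = res$seg$class_params,
                              n_iter = res$seg$n_iter,
                              converged = res$seg$converged),
                         p_seg, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    paths$segmentation <- p_seg
  }
  if (!is.null(res$stats)) {
    p_stats <- file.path(cfg$out_dir, "tissue_stats.csv")
    utils::write.csv(res$stats$classes, p_stats, row.names = FALSE)
    paths$stats <- p_stats
  }
  write_resolved_config(c(cfg, list(elapsed_s = elapsed)),
                        file.path(cfg$out_dir, "map_config.json"))
  res$paths <- paths
  invisible(res)
}

#' Protocol optimization report
#'
#' Prints, for a grid of TR values: the maximum flip angle keeping saturation
#' below the limit, the saturation at 90 degrees, and the relative SNR per
#' unit time at that maximum flip; plus the TR achieving 1% saturation at 90
#' degrees and the CSF steady-state factor of the configured protocol.
#'
#' @param config named list: `t1` (seconds, default 2), `sat_limit`
#'   (fraction, default 0.007), `tr_grid` (seconds, default 5..11),
#'   `csf_t1` (default 4.3) plus protocol fields as in [cmd_simulate()].
#' @return invisibly, a data frame of the table plus attributes.
#' @export
cmd_protocol <- function(config = list()) {
  cfg <- config
  t1 <- cfg$t1 %||% 2
  limit <- cfg$sat_limit %||% 0.007
  tr_grid <- cfg$tr_grid %||% seq(5, 11, by = 1)
  if (length(tr_grid) == 0) stop("empty TR grid")
  protocol <- acq_protocol(tr_s = cfg$tr_s %||% 10, flip_deg = cfg$flip_deg %||% 90,
                           cal_factor = cfg$cal_factor %||% 0.8)
  tab <- data.frame(
    tr_s = tr_grid,
    flip_max_deg = vapply(tr_grid, flip_max_for_saturation, numeric(1),
                          t1 = t1, level = limit),
    saturation_90_pct = 100 * vapply(tr_grid, saturation_level, numeric(1),
                                     t1 = t1, flip_eff = 90))
  tab$snr_per_time <- mapply(snr_per_unit_time, tab$tr_s, t1, tab$flip_max_deg)
  tr1pct <- tr_for_saturation(0.01, t1, 90)
  csf_factor <- compute_csf_ss_factor(protocol, cfg$csf_t1 %||% 4.3)
  cat(sprintf("T1 = %g s, saturation limit %.2f%%\n", t1, 100 * limit))
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("TR at 1%% saturation (90 deg): %.1f s\n", tr1pct))
  cat(sprintf("CSF steady-state factor for configured protocol: %.2f\n", csf_factor))
  attr(tab, "tr_1pct") <- tr1pct
  attr(tab, "csf_factor") <- csf_factor
  invisible(tab)
}

write_resolved_config <- function(cfg, path) {
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Command-line entry point
#'
#' Dispatches `simulate`, `map` or `protocol` subcommands. Options are
#' `--key value` pairs matching the config fields of the `cmd_*` functions;
#' `--grid` takes a comma-separated triple. Exit codes: 0 success, 1 usage
#' error, 2 stage failure.
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return exit code, invisibly.
#' @export
watermap_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: watermap <simulate|map|protocol> [--key value ...]"
  if (length(args) < 1L) {
    message(usage)
    return(invisible(1L))
  }
  sub <- args[1]
  if (!sub %in% c("simulate", "map", "protocol")) {
    message(usage)
    return(invisible(1L))
  }
  rest <- args[-1]
  if (length(rest) %% 2 != 0 || (length(rest) && !all(grepl("^--", rest[c(TRUE, FALSE)])))) {
    message("options must be --key value pairs\n", usage)
    return(invisible(1L))
  }
  cfg <- list()
  if (length(rest)) {
    keys <- sub("^--", "", rest[c(TRUE, FALSE)])
    vals <- rest[c(FALSE, TRUE)]
    for (i in seq_along(keys)) {
      v <- vals[i]
      v <- if (grepl(",", v)) {
        as.numeric(strsplit(v, ",")[[1]])
      } else if (!is.na(suppressWarnings(as.numeric(v)))) {
        as.numeric(v)
      } else if (v %in% c("TRUE", "FALSE", "true", "false")) {
        toupper(v) == "TRUE"
      } else v
      cfg[[keys[i]]] <- v
    }
  }
  known <- list(simulate = cmd_simulate, map = cmd_map, protocol = cmd_protocol)
  allowed <- list(
    simulate = c("out_dir", "kind", "grid", "noise_sd", "snr", "seed", "bias",
                 "bias_log_sd", "b0_kind", "b0_gz", "jitter_sd", "tr_s",
                 "flip_deg", "cal_factor", "n_echoes", "te1_ms", "dte_ms"),
    map = c("magnitude", "phase", "protocol", "out_dir", "correct_gradients",
            "n_classes", "basis_order", "cal_bins", "ss_factor", "csf_t1",
            "seed", "max_echoes"),
    protocol = c("t1", "sat_limit", "tr_grid", "csf_t1", "tr_s", "flip_deg",
                 "cal_factor"))
  unknown <- setdiff(names(cfg), allowed[[sub]])
  if (length(unknown)) {
    message("unknown option(s) for '", sub, "': ", paste(unknown, collapse = ", "))
    return(invisible(1L))
  }
  res <- tryCatch({
    known[[sub]](cfg)
    0L
  }, error = function(e) {
    message("[", sub, "] stage failure: ", conditionMessage(e))
    2L
  })
  invisible(res)
}
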