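# Voxel-wise extrapolation to TE = 0: background-gradient estimation from
# phase, echo selection under the 0.8*pi dephasing rule, sinc correction of
# through-slice dephasing, and (weighted) log-linear mono-exponential fitting.

# shift an array forward by one index along `axis`, replicating the last slab
shift_fwd <- function(a, axis) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- c(seq(2L, d[axis]), d[axis])
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' Estimate background field gradients from multi-echo phase images
#'
#' For each voxel and spatial direction, the wrapped forward phase difference
#' at each included echo is divided by `gamma * dx_i * TE_n` and averaged over
#' echoes. Only echoes whose magnitude is at least half the first-echo
#' magnitude (voxel-wise) are used. With `phi0_subtract = TRUE` (default) the
#' first echo's phase is subtracted voxel-wise first and `TE_n` is replaced by
#' `TE_n - TE_1`, which removes the TE-independent receive phase offset; the
#' literal per-echo form (divide by `TE_n` itself) is retained as a mode for
#' fidelity testing.
#'
#' Edge voxels (last index along each axis) copy their inner neighbour's
#' gradient; no 3D phase unwrapping is performed -- per-difference wrapping to
#' (-pi, pi] suffices for the small per-voxel phase steps the method assumes.
#'
#' @param series an `echo_series` with phase data.
#' @param phi0_subtract logical, see above.
#' @return list of 3D arrays `gx`, `gy`, `gz` (T/m) and `valid` (logical:
#'   at least one qualifying echo contributed).
#' @export
estimate_background_gradients <- function(series, phi0_subtract = TRUE) {
  stopifnot(inherits(series, "echo_series"), !is.null(series$phase))
  te_s <- series$protocol$te_ms / 1000
  n_echo <- length(te_s)
  if (n_echo < 2L) stop("need at least 2 echoes to estimate gradients")
  gamma <- series$protocol$gamma
  dx_m <- series$protocol$voxel_mm / 1000
  mag <- series$magnitude
  phs <- series$phase
  dims <- dim(mag)[1:3]

  include <- mag >= 0.5 * as.vector(mag[, , , 1])   # recycles first echo over echo dim
  if (phi0_subtract) {
    phs <- wrap_phase(phs - as.vector(phs[, , , 1]))
    te_eff <- te_s - te_s[1]
    echo_set <- seq(2L, n_echo)
  } else {
    te_eff <- te_s
    echo_set <- seq_len(n_echo)
  }

  one_axis <- function(axis) {
    num <- array(0, dim = dims)
    cnt <- array(0, dim = dims)
    for (n in echo_set) {
      p <- phs[, , , n, drop = FALSE]
      dim(p) <- dims
      dphi <- wrap_phase(shift_fwd(p, axis) - p)
      ok <- include[, , , n, drop = FALSE]
      dim(ok) <- dims
      g <- dphi / (gamma * dx_m[axis] * te_eff[n])
      num <- num + ifelse(ok, g, 0)
      cnt <- cnt + ok
    }
    out <- ifelse(cnt > 0, num / pmax(cnt, 1), 0)
    # edge slab copies inner neighbour
    d <- dims
    idx_last <- lapply(d, seq_len); idx_last[[axis]] <- d[axis]
    idx_prev <- lapply(d, seq_len); idx_prev[[axis]] <- d[axis] - 1L
    out_last <- do.call(`[`, c(list(out), idx_prev, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), idx_last, list(value = out_last)))
    list(g = out, cnt = cnt)
  }
  rx <- one_axis(1L); ry <- one_axis(2L); rz <- one_axis(3L)
  list(gx = rx$g, gy = ry$g, gz = rz$g,
       valid = rx$cnt > 0 | ry$cnt > 0 | rz$cnt > 0)
}

#' Per-voxel echo count under the dephasing limit
#'
#' The largest prefix of echoes whose through-slice dephasing
#' `gamma * |gz| * dz * TE_n` does not exceed `0.8 * pi`, optionally capped at
#' a maximum echo count. Fewer than 3 echoes makes the voxel's fit invalid
#' downstream.
#'
#' @param series an `echo_series`.
#' @param gz 3D array of through-slice gradients, T/m.
#' @param max_echoes optional cap on the echo count (default: all echoes).
#' @param dephase_limit dephasing threshold in radians (default `0.8 * pi`).
#' @return integer 3D array of per-voxel echo counts.
#' @export
select_echoes <- function(series, gz, max_echoes = NULL,
                          dephase_limit = 0.8 * pi) {
  te_s <- series$protocol$te_ms / 1000
  n_echo <- length(te_s)
  max_echoes <- min(max_echoes %||% n_echo, n_echo)
  dz_m <- series$protocol$voxel_mm[3] / 1000
  gamma <- series$protocol$gamma
  te_max <- dephase_limit / pmax(gamma * abs(gz) * dz_m, .Machine$double.xmin)
  counts <- findInterval(te_max, te_s)   # number of TEs <= te_max
  counts <- pmin(counts, max_echoes)
  out <- array(as.integer(counts), dim = dim(gz))
  out
}

# Vectorized weighted log-linear fit. S: nvox x nE matrix of (corrected)
# signals; include: logical matrix of echoes to use. Returns per-voxel
# s0, t2star (ms, capped), rss (log domain), n_used, valid, capped.
fit_loglinear_core <- function(S, te_ms, include, weights_mode = "intensity2",
                               t2_cap = 2000, t2_floor = 1) {
  ok <- include & is.finite(S) & (S > 0)
  logS <- ifelse(ok, log(pmax(S, .Machine$double.xmin)), 0)
  w <- if (weights_mode == "intensity2") ifelse(ok, S^2, 0) else ifelse(ok, 1, 0)
  te <- matrix(te_ms, nrow(S), length(te_ms), byrow = TRUE)
  sw <- rowSums(w)
  swx <- rowSums(w * te)
  swy <- rowSums(w * logS)
  swxx <- rowSums(w * te^2)
  swxy <- rowSums(w * te * logS)
  denom <- sw * swxx - swx^2
  slope <- ifelse(abs(denom) > 0, (sw * swxy - swx * swy) / denom, 0)
  intercept <- ifelse(sw > 0, (swy - slope * swx) / sw, 0)
  t2 <- ifelse(slope < 0, -1 / slope, Inf)
  capped <- !is.finite(t2) | t2 > t2_cap | t2 < t2_floor
  t2 <- pmin(pmax(t2, t2_floor), t2_cap)
  s0 <- exp(intercept)
  resid <- ifelse(ok, logS - (intercept + slope * te), 0)
  rss <- rowSums(resid^2)
  n_used <- rowSums(ok)
  valid <- n_used >= 3L
  list(s0 = s0, t2star = t2, rss = rss, n_used = n_used,
       valid = valid, capped = capped & valid)
}

#' Mono-exponential decay fit for one voxel
#'
#' Weighted least squares on `log(signal)` versus TE: the slope gives
#' `-1/T2*`, the intercept `log(S0)`. Intensity-squared weighting (default)
#' is the maximum-likelihood approximation for log-transformed data whose
#' noise is signal-independent. Non-positive signals are excluded; fewer than
#' 3 remaining echoes invalidates the fit. A flat (non-decaying) signal yields
#' T2* capped at `t2_cap` with the fit still valid.
#'
#' @param te echo times, ms.
#' @param signal magnitudes, same length.
#' @param weights_mode "intensity2" (default) or "uniform".
#' @param t2_cap,t2_floor T2* cap and floor, ms (defaults 2000 and 1).
#' @param refine "none" (default) or "nls": refine the log-linear solution by
#'   nonlinear least squares on the linear-domain model.
#' @return list with `s0`, `t2star` (ms), `rss` (log-domain), `n_used`,
#'   `valid`, `capped`.
#' @export
fit_monoexponential <- function(te, signal, weights_mode = c("intensity2", "uniform"),
                                t2_cap = 2000, t2_floor = 1,
                                refine = c("none", "nls")) {
  weights_mode <- match.arg(weights_mode)
  refine <- match.arg(refine)
  stopifnot(length(te) == length(signal))
  S <- matrix(signal, nrow = 1)
  inc <- matrix(TRUE, 1, length(signal))
  fit <- fit_loglinear_core(S, te, inc, weights_mode, t2_cap, t2_floor)
  out <- lapply(fit, function(v) v[1])
  if (refine == "nls" && out$valid && !out$capped) {
    ok <- is.finite(signal) & signal > 0
    obj <- function(p) sum((signal[ok] - p[1] * exp(-te[ok] / p[2]))^2)
    opt <- stats::optim(c(out$s0, out$t2star), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000))
    out$s0 <- opt$par[1]
    out$t2star <- min(max(opt$par[2], t2_floor), t2_cap)
    out$rss <- opt$value
  }
  out
}

#' Sinc-corrected mono-exponential fit for one voxel
#'
#' Divides each echo by the through-slice dephasing factor
#' `sinc(gamma/2 * gz * dz * TE)` and then fits the mono-exponential model.
#' Echoes whose |sinc factor| falls below 1e-6 are dropped (the 0.8*pi echo
#' selection normally guarantees the factor stays well away from its null).
#'
#' @inheritParams fit_monoexponential
#' @param gz through-slice gradient, T/m.
#' @param dz slice thickness, mm.
#' @param gamma gyromagnetic ratio, rad/s/T.
#' @return as [fit_monoexponential()].
#' @export
sinc_corrected_fit <- function(te, signal, gz, dz,
                               weights_mode = c("intensity2", "uniform"),
                               gamma = GAMMA_PROTON, t2_cap = 2000,
                               t2_floor = 1) {
  weights_mode <- match.arg(weights_mode)
  fac <- sinc(gamma / 2 * gz * (dz / 1000) * (te / 1000))
  keep <- abs(fac) > 1e-6
  corrected <- ifelse(keep, signal / ifelse(keep, fac, 1), NA_real_)
  fit_monoexponential(te[keep], corrected[keep], weights_mode,
                      t2_cap = t2_cap, t2_floor = t2_floor)
}

#' Fit the decay model over a whole volume
#'
#' Runs, in order: background-gradient estimation from phase (when
#' `correct_gradients` and phase data are available), per-voxel echo selection
#' under the 0.8*pi through-slice dephasing rule, sinc correction of each
#' included echo, and the vectorized weighted log-linear fit. Only the
#' through-slice gradient gz enters the sinc correction; in-plane gradients
#' are estimated and reported but not corrected.
#'
#' @param series an `echo_series`.
#' @param correct_gradients logical: estimate gradients and sinc-correct
#'   (requires phase data).
#' @param weights_mode,t2_cap,t2_floor as [fit_monoexponential()].
#' @param max_echoes optional cap on echoes entering the fit (e.g. a reduced
#'   subset ~T2* for tissue; CSF-calibrated studies should include many).
#' @param phi0_subtract see [estimate_background_gradients()].
#' @return a `decay_maps` object: 3D arrays `s0`, `t2star` (ms), `r2star`
#'   (1/s), `gx`/`gy`/`gz` (T/m), `echoes_used`, `rss`, `valid`, `capped`.
#' @export
fit_volume <- function(series, correct_gradients = TRUE,
                       weights_mode = c("intensity2", "uniform"),
                       max_echoes = NULL, phi0_subtract = TRUE,
                       t2_cap = 2000, t2_floor = 1) {
  stopifnot(inherits(series, "echo_series"))
  weights_mode <- match.arg(weights_mode)
  mag <- series$magnitude
  dims <- dim(mag)[1:3]
  n_echo <- dim(mag)[4]
  te_ms <- series$protocol$te_ms
  stopifnot(n_echo == length(te_ms))
  nvox <- prod(dims)
  S <- matrix(mag, nvox, n_echo)

  zero <- array(0, dim = dims)
  if (correct_gradients) {
    if (is.null(series$phase)) {
      stop("gradient correction requested but the series has no phase data")
    }
    grads <- estimate_background_gradients(series, phi0_subtract = phi0_subtract)
    counts <- select_echoes(series, grads$gz, max_echoes = max_echoes)
    dz_m <- series$protocol$voxel_mm[3] / 1000
    gamma <- series$protocol$gamma
    fac <- outer(as.vector(grads$gz), te_ms / 1000,
                 function(g, t) sinc(gamma / 2 * g * dz_m * t))
    usable <- abs(fac) > 1e-6
    S <- ifelse(usable, S / ifelse(usable, fac, 1), NA_real_)
  } else {
    grads <- list(gx = zero, gy = zero, gz = zero)
    counts <- array(min(max_echoes %||% n_echo, n_echo), dim = dims)
  }
  include <- outer(as.vector(counts), seq_len(n_echo), `>=`)
  fit <- fit_loglinear_core(S, te_ms, include, weights_mode, t2_cap, t2_floor)

  shape <- function(v) array(v, dim = dims)
  t2 <- shape(fit$t2star)
  structure(list(s0 = shape(fit$s0), t2star = t2, r2star = 1000 / t2,
                 gx = grads$gx, gy = grads$gy, gz = grads$gz,
                 echoes_used = shape(as.integer(fit$n_used)),
                 rss = shape(fit$rss),
                 valid = shape(fit$valid), capped = shape(fit$capped),
                 voxel_mm = series$voxel_mm, affine = series$affine,
                 protocol = series$protocol),
            class = "decay_maps")
}

#' Write decay maps as NIfTI volumes
#' @param maps a `decay_maps` object.
#' @param dir output directory.
#' @param prefix file prefix.
#' @return named list of paths, invisibly.
#' @export
write_decay_maps <- function(maps, dir, prefix = "decay") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (nm in c("s0", "t2star", "r2star", "gx", "gy", "gz", "echoes_used",
               "valid")) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".nii.gz"))
    write_nifti(maps[[nm]] + 0, p, voxdim = maps$voxel_mm, affine = maps$affine)
    out[[nm]] <- p
  }
  invisible(out)
}
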