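# Shared fixtures, built in code at test time.

default_protocol <- function(n_echoes = 32L) {
  acq_protocol(tr_s = 10, flip_deg = 90, cal_factor = 0.8,
               te1_ms = 3.87, dte_ms = 4.08, n_echoes = n_echoes,
               voxel_mm = c(2, 2, 1.5))
}

small_brain <- function(grid = c(32L, 32L, 16L), ...) {
  make_brain_phantom(phantom_spec("brain", grid_shape = grid, ...))
}

# the multiplicative field the segmentation stage should recover: receive
# field times the transmit field's effect through sin(alpha_eff * B1+)
# (tissue steady-state factors are ~1 and drop out)
effective_bias_field <- function(truth, protocol) {
  a <- pi / 180 * flip_effective(protocol)
  sin(a * truth$bias_transmit_map) / sin(a) * truth$bias_receive_map
}

# hand-built echo series defined on the full grid (no background), so phase
# is meaningful at every voxel
constructed_series <- function(dims, protocol, s0 = 100, t2star = 60,
                               gz = 0, phi0 = 0, b0_from_gz = TRUE) {
  n_echo <- length(protocol$te_ms)
  te_s <- protocol$te_ms / 1000
  zpos <- (seq_len(dims[3]) - (dims[3] + 1) / 2) * protocol$voxel_mm[3] / 1000
  mag <- array(0, dim = c(dims, n_echo))
  phs <- array(0, dim = c(dims, n_echo))
  phi0_arr <- if (length(phi0) == 1) array(phi0, dim = dims) else phi0
  for (n in seq_len(n_echo)) {
    mag[, , , n] <- s0 * exp(-protocol$te_ms[n] / t2star)
    b0 <- if (b0_from_gz) {
      array(rep(zpos * gz, each = dims[1] * dims[2]), dim = dims)
    } else array(0, dim = dims)
    phs[, , , n] <- wrap_phase(phi0_arr + protocol$gamma * b0 * te_s[n])
  }
  structure(list(magnitude = mag, phase = phs, protocol = protocol,
                 affine = diag(c(protocol$voxel_mm, 1)),
                 voxel_mm = protocol$voxel_mm),
            class = "echo_series")
}

# per-label class means of a map
class_means <- function(x, label_map, labels) {
  vapply(labels, function(l) mean(x[label_map == l]), numeric(1))
}
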