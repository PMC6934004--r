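# Multiplicative inhomogeneity removal via intensity-only Gaussian-mixture
# segmentation with a smooth bias field.
#
# The combined transmit/receive inhomogeneity of the TE = 0 intensity map is
# multiplicative and spatially smooth, so it is modeled as the exponential of
# a low-order 3D cosine (DCT) expansion. Tissue intensities after correction
# are modeled as a K-class Gaussian mixture (long-TR contrast is proton
# density, so WM < GM < CSF in mean intensity). The two are estimated jointly
# by EM with an interleaved damped Gauss-Newton update of the log-bias
# coefficients; the DC component is removed and the remaining basis columns
# are mean-centered over the fitted region, so the estimated field has unit
# geometric mean by construction (gauge fixing). This is an intensity-only
# stand-in for atlas-registered unified segmentation: no spatial priors.

# binary erosion with the 6-connected neighbourhood, n passes
erode_mask <- function(m, n = 1L) {
  for (i in seq_len(n)) {
    out <- m
    for (axis in 1:3) {
      out <- out & shift_fwd(m, axis)
      # backward shift: reuse shift_fwd on the reversed axis
      idx <- lapply(dim(m), seq_len)
      idx[[axis]] <- rev(idx[[axis]])
      rev_m <- do.call(`[`, c(list(m), idx, list(drop = FALSE)))
      rev_s <- shift_fwd(rev_m, axis)
      out <- out & do.call(`[`, c(list(rev_s), idx, list(drop = FALSE)))
    }
    m <- out
  }
  m
}

mixture_loglik <- function(y, mu, sigma, w) {
  dens <- matrix(0, length(y), length(mu))
  for (k in seq_along(mu)) {
    dens[, k] <- w[k] * stats::dnorm(y, mu[k], sigma[k])
  }
  tot <- rowSums(dens)
  sum(log(pmax(tot, .Machine$double.xmin)))
}

# initial class means: quantile-based on the first attempt, k-means++-style
# seeded draws on a subsample for restarts
init_class_means <- function(y, K, seed, attempt) {
  if (attempt == 1L) {
    qs <- stats::quantile(y, probs = (seq_len(K) - 0.5) / K, names = FALSE)
    if (all(diff(qs) > 0)) return(qs)
  }
  with_seed(seed * 131L + attempt, {
    ys <- sample(y, min(4000L, length(y)))
    centers <- numeric(K)
    centers[1] <- ys[sample.int(length(ys), 1)]
    for (k in seq(2L, K)) {
      d2 <- apply(outer(ys, centers[seq_len(k - 1L)], `-`)^2, 1, min)
      centers[k] <- ys[sample.int(length(ys), 1, prob = d2 + 1e-12)]
    }
    sort(centers)
  })
}

# one EM run from given initial means; returns the final state and loglik.
# pen: diagonal penalty weights (bending-energy style, per coefficient);
# the objective maximized is loglik - 0.5 * c' diag(pen) c.
run_em_bias <- function(y0, A, ncoef, n_classes, max_iter, tol, var_floor, mu0,
                        pen = rep(0, ncoef)) {
  nfg <- length(y0)
  estimate_bias <- ncoef > 0L
  mu <- mu0
  sigma <- rep(stats::sd(y0) / n_classes, n_classes)
  wgt <- rep(1 / n_classes, n_classes)
  cvec <- rep(0, ncoef)
  b <- rep(0, nfg)
  y <- y0
  floored <- FALSE
  pen_set <- !estimate_bias || all(pen == 0)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  resp <- matrix(1 / n_classes, nfg, n_classes)
  for (iter in seq_len(max_iter)) {
    # E-step
    dens <- matrix(0, nfg, n_classes)
    for (k in seq_len(n_classes)) {
      dens[, k] <- wgt[k] * stats::dnorm(y, mu[k], sigma[k])
    }
    tot <- pmax(rowSums(dens), .Machine$double.xmin)
    resp <- dens / tot
    # M-step
    nk <- colSums(resp)
    wgt <- nk / nfg
    mu <- colSums(resp * y) / pmax(nk, .Machine$double.eps)
    v <- colSums(resp * (y - rep(mu, each = nfg))^2) / pmax(nk, .Machine$double.eps)
    if (any(v < var_floor)) {
      v <- pmax(v, var_floor)
      floored <- TRUE
    }
    sigma <- sqrt(v)
    # bias step: damped Gauss-Newton on the responsibility-weighted objective
    if (estimate_bias) {
      wv <- resp %*% (1 / v)                    # sum_k r_jk / v_k
      mv <- (resp %*% (mu / v)) / wv            # precision-weighted target mean
      wv <- as.vector(wv); mv <- as.vector(mv)
      # residual r_j = mv_j - y_j; d y_j / d c = -y_j * A_j  =>  design X = -y*A
      X <- -y * A
      r <- mv - y
      XtWX <- crossprod(X, wv * X)
      XtWr <- crossprod(X, wv * r)
      if (!pen_set) {
        # fix the penalty scale once, relative to the first Hessian
        pen <- pen * mean(diag(XtWX))
        pen_set <- TRUE
      }
      H <- XtWX + diag(pen, ncoef)
      g <- XtWr - pen * cvec
      step <- tryCatch(solve(H + diag(1e-8 * max(diag(H)), ncoef), g),
                       error = function(e) matrix(0, ncoef, 1))
      penalized <- function(yv, cv) {
        mixture_loglik(yv, mu, sigma, wgt) - 0.5 * sum(pen * cv^2)
      }
      ll_cur <- penalized(y, cvec)
      lambda <- 1
      for (h in seq_len(10L)) {
        c_try <- cvec + lambda * as.vector(step)
        b_try <- as.vector(A %*% c_try)
        b_try <- b_try - mean(b_try)            # keep unit geometric mean
        y_try <- y0 * exp(-b_try)
        if (penalized(y_try, c_try) >= ll_cur - 1e-12 * abs(ll_cur)) {
          cvec <- c_try; b <- b_try; y <- y_try
          break
        }
        lambda <- lambda / 2
      }
    }
    ll <- mixture_loglik(y, mu, sigma, wgt) - 0.5 * sum(pen * cvec^2)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, wgt = wgt, resp = resp, cvec = cvec, b = b,
       trace = trace, converged = converged, iter = iter, floored = floored,
       loglik = trace[length(trace)])
}

#' Joint Gaussian-mixture segmentation and bias-field estimation
#'
#' Expectation-maximization over class responsibilities, class parameters and
#' the log-bias DCT coefficients. Each iteration: (a) E-step responsibilities
#' of the bias-corrected intensities; (b) M-step for means, variances and
#' mixing weights; (c) one damped Gauss-Newton step on the log-bias
#' coefficients maximizing the same objective (step accepted only if the
#' mixture log-likelihood does not decrease, halving otherwise). Stops when
#' the relative log-likelihood change falls below `tol` or after `max_iter`
#' iterations. The fit is restricted to a loose foreground mask (intensity
#' above `fg_frac` of the robust maximum) so air does not dominate the
#' mixture.
#'
#' Classes are reported in ascending order of corrected mean intensity; for
#' brain data with `n_classes = 4` this is non-brain, WM, GM, CSF
#' (proton-density ordering).
#'
#' @param s0 3D array of TE = 0 intensities (the decay-fit S0 map).
#' @param n_classes number of Gaussian classes (default 4).
#' @param basis_order DCT components per axis for the log-bias field
#'   (default 4).
#' @param max_iter maximum EM iterations (default 200).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param seed integer seed governing the restart initializations (the first
#'   attempt is deterministic intensity-quantile placement; restarts use
#'   k-means++-style seeded draws).
#' @param n_restarts number of EM starts; the run with the best final
#'   penalized log-likelihood wins. Default 1 (the deterministic quantile
#'   init): raw likelihood can favour degenerate labelings in which the
#'   field absorbs tissue contrast, so extra likelihood-ranked restarts are
#'   opt-in rather than the default.
#' @param fg_frac foreground threshold as a fraction of the robust (99.8th
#'   percentile) maximum (default 0.05).
#' @param erode_fit passes of 6-neighbourhood erosion applied to the
#'   foreground before fitting (default 1): object-surface voxels carry
#'   corrupted decay fits and would smear the mixture. Posteriors and the
#'   field are still evaluated on the full foreground.
#' @param bias_reg bias-field regularization strength: a bending-energy style
#'   penalty proportional to `(kx^2+ky^2+kz^2)^2` on each log-bias DCT
#'   coefficient, scaled relative to the Gauss-Newton Hessian so high-order
#'   field curvature is discouraged without touching coil-scale smooth
#'   components (default 0.1; 0 disables).
#' @param estimate_bias logical; `FALSE` fits a plain mixture (bias fixed at 1).
#' @return a `segmentation_result`: `prob` (4D array, class posteriors over
#'   the full volume; zero outside the foreground), `bias` (3D, strictly
#'   positive, unit geometric mean over the foreground), `log_bias_coeffs`,
#'   `class_params` (mean, sd, weight per class, ascending means),
#'   `loglik_trace`, `n_iter`, `converged`, `foreground`.
#' @export
segment_and_debias <- function(s0, n_classes = 4L, basis_order = 4L,
                               max_iter = 200L, tol = 1e-6, seed = 1L,
                               n_restarts = 1L, fg_frac = 0.05,
                               bias_reg = 0.1, erode_fit = 1L,
                               estimate_bias = TRUE) {
  stopifnot(length(dim(s0)) == 3L, n_classes >= 2L)
  dims <- dim(s0)
  finite <- is.finite(s0)
  if (!any(finite & s0 > 0)) stop("s0 contains no positive finite voxels")
  robust_max <- stats::quantile(s0[finite], 0.998, names = FALSE)
  fg <- finite & (s0 > fg_frac * robust_max)
  # the mixture and field are FIT on an eroded foreground: object-surface
  # voxels carry corrupted decay fits (their gradient estimates borrow
  # phase from signal-free neighbours) and would smear the classes; the
  # result is then evaluated on the full foreground
  fit_region <- if (erode_fit > 0) erode_mask(fg, erode_fit) else fg
  if (sum(fit_region) < 10L * n_classes) fit_region <- fg
  y0 <- as.vector(s0)[as.vector(fit_region)]
  nfg <- length(y0)
  if (nfg < 10L * n_classes) stop("too few foreground voxels to fit a mixture")

  # design matrix for the log-bias field: drop DC, centre columns over the
  # fit region (gauge: unit geometric mean field there)
  grid_all <- voxel_grid(dims)
  coords <- grid_all[as.vector(fit_region), , drop = FALSE]
  if (estimate_bias) {
    A <- dct_design(coords, dims, basis_order)[, -1, drop = FALSE]
    A_center <- colMeans(A)
    A <- sweep(A, 2, A_center)
    ncoef <- ncol(A)
    # bending-energy style penalty profile: weight grows with the squared
    # total spatial order, so high-order curvature is discouraged while
    # coil-scale smooth components pass almost freely. Scaled inside the EM
    # run relative to the Gauss-Newton Hessian (bias_reg = 0.1 puts the
    # highest single-axis order at ~10% of the Hessian diagonal).
    ko <- expand.grid(kx = 0:(basis_order - 1), ky = 0:(basis_order - 1),
                      kz = 0:(basis_order - 1))[-1, , drop = FALSE]
    dmax <- max((basis_order - 1)^2, 1)
    pen <- bias_reg * (ko$kx^2 + ko$ky^2 + ko$kz^2)^2 / dmax^2
  } else {
    A <- NULL
    ncoef <- 0L
    pen <- numeric(0)
  }
  var_floor <- 1e-6 * stats::var(y0)

  best <- NULL
  for (attempt in seq_len(n_restarts)) {
    run <- run_em_bias(y0, A, ncoef, n_classes, max_iter, tol, var_floor,
                       init_class_means(y0, n_classes, seed, attempt), pen)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  mu <- best$mu; sigma <- best$sigma; wgt <- best$wgt
  resp <- best$resp; cvec <- best$cvec; b <- best$b
  trace <- best$trace; converged <- best$converged; iter <- best$iter
  floored <- best$floored
  if (floored) warning("degenerate class variance floored during EM")
  if (!converged) warning("EM did not converge within max_iter; returning last iterate")

  # order classes by ascending corrected mean
  ord <- order(mu)
  mu <- mu[ord]; sigma <- sigma[ord]; wgt <- wgt[ord]

  # evaluate the field and posteriors over the full foreground
  fgv <- which(as.vector(fg))
  if (estimate_bias) {
    A_fg <- dct_design(grid_all[fgv, , drop = FALSE], dims, basis_order)[, -1, drop = FALSE]
    b_fg <- as.vector(sweep(A_fg, 2, A_center) %*% cvec)
  } else {
    b_fg <- rep(0, length(fgv))
  }
  y_fg <- as.vector(s0)[fgv] * exp(-b_fg)
  dens <- matrix(0, length(fgv), n_classes)
  for (k in seq_len(n_classes)) {
    dens[, k] <- wgt[k] * stats::dnorm(y_fg, mu[k], sigma[k])
  }
  resp_fg <- dens / pmax(rowSums(dens), .Machine$double.xmin)

  prob <- array(0, dim = c(dims, n_classes))
  nvox <- prod(dims)
  for (k in seq_len(n_classes)) {
    pk <- numeric(nvox)
    pk[fgv] <- resp_fg[, k]
    prob[, , , k] <- array(pk, dim = dims)
  }
  bias <- array(1, dim = dims)
  bias[fgv] <- exp(b_fg)
  structure(list(prob = prob, bias = bias, log_bias_coeffs = cvec,
                 class_params = data.frame(mean = mu, sd = sigma, weight = wgt),
                 loglik_trace = trace, n_iter = iter, converged = converged,
                 foreground = fg, fit_region = fit_region,
                 n_classes = n_classes, basis_order = basis_order),
            class = "segmentation_result")
}

#' Apply the estimated bias field
#'
#' @param s0 3D intensity array.
#' @param seg a `segmentation_result`.
#' @return bias-corrected array `s0 / bias`.
#' @export
apply_bias_correction <- function(s0, seg) {
  s0 / seg$bias
}

# Identify which mixture classes are WM, GM and CSF. The highest-mean class
# is CSF (proton-density contrast); WM and GM are the classes whose means sit
# closest to the expected PD pattern relative to CSF (WM ~ 69/93, GM ~ 83/93
# of the saturated-CSF intensity). Rank order alone is brittle when a spare
# class latches onto boundary/junk voxels between the tissue modes.
tissue_prob_indices <- function(seg) {
  K <- seg$n_classes
  if (K < 3L) stop("need at least 3 classes to identify WM/GM/CSF")
  mu <- seg$class_params$mean
  csf <- which.max(mu)
  rel <- mu / mu[csf]
  rest <- setdiff(seq_len(K), csf)
  wm <- rest[which.min(abs(rel[rest] - 69 / 93))]
  rest <- setdiff(rest, wm)
  gm <- rest[which.min(abs(rel[rest] - 83 / 93))]
  if (!(mu[wm] < mu[gm] && mu[gm] < mu[csf])) {
    # fall back to rank order if the pattern match degenerates
    ord <- order(mu)
    return(c(WM = ord[K - 2L], GM = ord[K - 1L], CSF = ord[K]))
  }
  c(WM = wm, GM = gm, CSF = csf)
}

#' Brain mask from tissue posteriors
#'
#' A voxel belongs to the brain mask iff any of the WM/GM/CSF posterior
#' probabilities exceeds 0.25.
#'
#' @param seg a `segmentation_result` (or a 4D probability array whose last
#'   three classes are WM, GM, CSF in that order).
#' @return logical 3D array.
#' @export
brain_mask <- function(seg) {
  idx <- tissue_index_of(seg)
  prob <- if (inherits(seg, "segmentation_result")) seg$prob else seg
  pmax3 <- pmax(prob[, , , idx["WM"]], prob[, , , idx["GM"]],
                prob[, , , idx["CSF"]])
  pmax3 > 0.25
}

#' Tissue posterior probabilities
#'
#' Extracts the WM/GM/CSF posterior volumes from a segmentation. With
#' `renormalize = TRUE` (default) the three are renormalized to sum to 1
#' per voxel -- the posterior conditional on the voxel being brain tissue.
#' In an atlas-driven segmentation the non-tissue classes are spatially
#' disjoint from the brain, so tissue posteriors already sum to ~1 there;
#' an intensity-only mixture has no such spatial information and any extra
#' class overlaps the tissue intensity range, capping raw posteriors. The
#' conditional form restores the intended semantics of high-confidence
#' tissue rules.
#'
#' @param seg a `segmentation_result`, or a 4D probability array whose last
#'   three classes are WM, GM, CSF.
#' @param renormalize logical, see above.
#' @return named list of 3D arrays `WM`, `GM`, `CSF`.
#' @export
tissue_posteriors <- function(seg, renormalize = TRUE) {
  idx <- tissue_index_of(seg)
  prob <- if (inherits(seg, "segmentation_result")) seg$prob else seg
  p <- list(WM = prob[, , , idx["WM"]], GM = prob[, , , idx["GM"]],
            CSF = prob[, , , idx["CSF"]])
  if (renormalize) {
    tot <- p$WM + p$GM + p$CSF
    safe <- tot > 0
    for (nm in names(p)) {
      p[[nm]] <- ifelse(safe, p[[nm]] / ifelse(safe, tot, 1), 0)
    }
  }
  p
}

# tissue class indices for either a segmentation_result (pattern-matched) or
# a bare probability array (convention: last three classes are WM, GM, CSF)
tissue_index_of <- function(seg) {
  if (inherits(seg, "segmentation_result")) return(tissue_prob_indices(seg))
  K <- dim(seg)[4]
  if (K < 3L) stop("need at least 3 classes")
  c(WM = K - 2L, GM = K - 1L, CSF = K)
}

#' Exclusive high-confidence tissue masks
#'
#' `mask_X = 1` iff `P_X >= 0.98` and both other tissue probabilities are
#' below 0.98, for X, Y, Z ranging over WM, GM, CSF in all permutations.
#'
#' @inheritParams brain_mask
#' @param renormalize use tissue-conditional posteriors (default TRUE), see
#'   [tissue_posteriors()].
#' @return named list of logical 3D arrays `WM`, `GM`, `CSF`.
#' @export
tissue_masks <- function(seg, renormalize = TRUE) {
  p <- tissue_posteriors(seg, renormalize = renormalize)
  out <- list()
  for (x in names(p)) {
    others <- setdiff(names(p), x)
    out[[x]] <- (p[[x]] >= 0.98) & (p[[others[1]]] < 0.98) & (p[[others[2]]] < 0.98)
  }
  out
}
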