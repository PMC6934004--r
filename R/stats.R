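# Tissue-class distribution summaries, test-retest variability, the oedema
# threshold rule, and generic distribution comparison.

# least-squares Gaussian fit to a histogram; returns center, sigma; falls
# back to moment estimates if the optimizer fails or the class is degenerate
fit_gaussian_hist <- function(centers, counts) {
  m0 <- sum(counts)
  if (m0 == 0) return(c(center = NA_real_, sigma = NA_real_))
  mu0 <- sum(centers * counts) / m0
  sd0 <- sqrt(max(sum(counts * (centers - mu0)^2) / m0, 1e-12))
  amp0 <- max(counts)
  obj <- function(p) {
    sum((counts - p[1] * exp(-(centers - p[2])^2 / (2 * p[3]^2)))^2)
  }
  opt <- tryCatch(
    stats::optim(c(amp0, mu0, sd0), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 2000)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$par[2]) || opt$par[3] <= 0) {
    return(c(center = mu0, sigma = sd0))
  }
  c(center = opt$par[2], sigma = abs(opt$par[3]))
}

FWHM_FACTOR <- 2 * sqrt(2 * log(2))

#' Per-tissue water-content statistics
#'
#' For each exclusive tissue mask: a histogram over `range` with `bins` bins,
#' a least-squares Gaussian fit to the histogram giving a center and FWHM
#' (`FWHM = 2*sqrt(2*ln 2) * sigma`), the arithmetic mean and sd, and the
#' voxel count. Also reports the GM/WM ratio of class means, which is
#' independent of the calibration scale.
#'
#' @param map a `water_map` with `masks` containing `WM`, `GM` (and
#'   optionally `CSF`), or an `h2o`-like array combined with `masks=`.
#' @param bins histogram bins (default 64; 64 and 128 give identical
#'   conclusions on healthy-range data).
#' @param range histogram range in percent (default c(40, 110)).
#' @param masks overrides the map's masks.
#' @return a `tissue_stats` object: data frame `classes` (mean, sd,
#'   gaussian_fit_mean, gaussian_fit_fwhm, n_voxels per class),
#'   `ratio_gm_wm`, and per-class histograms.
#' @export
tissue_statistics <- function(map, bins = 64L, range = c(40, 110),
                              masks = NULL) {
  h2o <- if (inherits(map, "water_map")) map$h2o else map
  masks <- masks %||% (if (inherits(map, "water_map")) map$masks else NULL)
  if (is.null(masks)) stop("tissue masks are required")
  masks <- masks[intersect(c("WM", "GM", "CSF"), names(masks))]
  edges <- seq(range[1], range[2], length.out = bins + 1L)
  centers <- (edges[-1] + edges[-(bins + 1L)]) / 2
  rows <- list(); hists <- list()
  for (cls in names(masks)) {
    v <- h2o[masks[[cls]]]
    v <- v[is.finite(v)]
    if (length(v) == 0L) {
      warning("empty tissue class omitted: ", cls)
      next
    }
    vin <- v[v >= range[1] & v <= range[2]]
    counts <- tabulate(pmin(pmax(findInterval(vin, edges, rightmost.closed = TRUE),
                                 1L), bins), nbins = bins)
    gf <- fit_gaussian_hist(centers, counts)
    rows[[cls]] <- data.frame(class = cls, mean = mean(v), sd = stats::sd(v),
                              gaussian_fit_mean = unname(gf["center"]),
                              gaussian_fit_fwhm = unname(FWHM_FACTOR * gf["sigma"]),
                              n_voxels = length(v))
    hists[[cls]] <- list(bin_edges = edges, counts = counts)
  }
  classes <- do.call(rbind, rows)
  ratio <- if (all(c("WM", "GM") %in% classes$class)) {
    classes$mean[classes$class == "GM"] / classes$mean[classes$class == "WM"]
  } else NA_real_
  structure(list(classes = classes, ratio_gm_wm = ratio, histograms = hists,
                 bins = bins, range = range),
            class = "tissue_stats")
}

#' @export
print.tissue_stats <- function(x, ...) {
  print(x$classes, row.names = FALSE)
  cat(sprintf("mean(GM)/mean(WM) = %.3f\n", x$ratio_gm_wm))
  invisible(x)
}

#' Voxel-wise test-retest statistics
#'
#' Per-voxel mean and standard deviation of water content across repeated,
#' pre-aligned maps, restricted to a brain mask. No registration is performed:
#' the grids must already be aligned (synthetic repeats are aligned by
#' construction; scanner repeats must be coregistered upstream).
#'
#' @param maps list of `water_map`s (or plain arrays) on identical grids.
#' @param brain logical mask; defaults to the first map's `brain` mask, else
#'   everything.
#' @param bins bins for the sd-mode estimator (default 128).
#' @return list: `mean` and `sd` arrays, and `summary` with `mean_sd`
#'   (mean of the voxel-wise sd within the mask), `mode_sd` (its histogram
#'   mode, shared estimator with the CSF calibration), and `n_maps`.
#' @export
voxelwise_retest <- function(maps, brain = NULL, bins = 128L) {
  arrs <- lapply(maps, function(m) if (inherits(m, "water_map")) m$h2o else m)
  if (length(arrs) < 2L) stop("need at least 2 maps")
  d1 <- dim(arrs[[1]])
  for (a in arrs) if (!identical(dim(a), d1)) {
    stop("maps are on different grids; no registration is performed here")
  }
  if (is.null(brain)) {
    brain <- if (inherits(maps[[1]], "water_map") && !is.null(maps[[1]]$masks$brain)) {
      maps[[1]]$masks$brain
    } else array(TRUE, dim = d1)
  }
  n <- length(arrs)
  stack <- array(unlist(arrs), dim = c(d1, n))
  mean_map <- apply(stack, 1:3, mean)
  sd_map <- sqrt(apply(stack, 1:3, stats::var))
  sds <- sd_map[brain]
  list(mean = mean_map, sd = sd_map,
       summary = list(mean_sd = mean(sds, na.rm = TRUE),
                      mode_sd = hist_mode(sds[is.finite(sds)], bins = bins),
                      n_maps = n))
}

#' Oedema threshold mask
#'
#' Flags voxels whose water content exceeds `wm_mean + k * wm_sd` (default
#' k = 1.5), restricted to the brain mask. With healthy WM at ~69.8 +/- 2.8%
#' this puts the threshold at 74.0%, well below typical tumor or stroke
#' oedema values (~77-90%).
#'
#' @param map a `water_map` (or array).
#' @param wm_mean,wm_sd white-matter mean and sd, percent.
#' @param k threshold multiplier (default 1.5).
#' @param brain optional logical mask (defaults to the map's brain mask, else
#'   everything).
#' @return logical 3D array.
#' @export
oedema_mask <- function(map, wm_mean, wm_sd, k = 1.5, brain = NULL) {
  stopifnot(wm_sd >= 0)
  h2o <- if (inherits(map, "water_map")) map$h2o else map
  if (is.null(brain)) {
    brain <- if (inherits(map, "water_map") && !is.null(map$masks$brain)) {
      map$masks$brain
    } else array(TRUE, dim = dim(h2o))
  }
  (h2o > wm_mean + k * wm_sd) & brain
}

#' Compare two water-content distributions
#'
#' A thin wrapper over the standard two-sample Kolmogorov-Smirnov test on
#' voxel samples, or balanced one-way ANOVA on per-subject means. Reported
#' only; never used as an internal pass/fail gate.
#'
#' @param a,b numeric vectors: voxel samples (ks) or per-subject means
#'   (anova).
#' @param method "ks_two_sample" or "anova_means".
#' @return list with `statistic` and `p_value`.
#' @export
compare_distributions <- function(a, b, method = c("ks_two_sample", "anova_means")) {
  method <- match.arg(method)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) stop("degenerate input samples")
  if (method == "ks_two_sample") {
    res <- suppressWarnings(stats::ks.test(a, b))
    list(statistic = unname(res$statistic), p_value = res$p.value)
  } else {
    grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
    res <- stats::oneway.test(c(a, b) ~ grp, var.equal = TRUE)
    list(statistic = unname(res$statistic), p_value = res$p.value)
  }
}
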