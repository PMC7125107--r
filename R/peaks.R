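# Peak detection on weighted Ks age distributions: weighted histogram +
# smoothing spline (generalized cross-validation), local-maximum search, and
# percentile bootstrap confidence intervals for peak locations.

.as_weighted <- function(samples, weights = NULL) {
  if (is.data.frame(samples)) {
    if (!"ks" %in% names(samples)) stop("samples data frame needs a `ks` column")
    w <- if ("weight" %in% names(samples)) samples$weight else rep(1, nrow(samples))
    data.frame(ks = samples$ks, weight = w)
  } else {
    if (is.null(weights)) weights <- rep(1, length(samples))
    data.frame(ks = as.numeric(samples), weight = weights)
  }
}

#' Fit a smoothed density curve to weighted Ks samples
#'
#' Samples are binned into a weighted histogram over `range` at `bin_width`
#' and a smooth curve is fitted to the bin counts, evaluated at the bin
#' midpoints and normalized to density scale. Two smoothers are available:
#'
#' * `"gam"` (default): a penalized regression spline with an adaptive
#'   smoothness basis, fitted to the bin counts under a quasi-Poisson model
#'   with REML smoothness selection. Count noise in sparse bins is modelled
#'   on the right scale, so the distribution tail does not sprout spurious
#'   wiggles while sharp WGD peaks are preserved.
#' * `"spline"`: a cubic smoothing spline ([stats::smooth.spline()]) fitted
#'   directly to bin heights with generalized cross-validation (or fixed
#'   `spar`). Fast; adequate inside a narrow window around one peak, where
#'   it is used for bootstrap replicate fits.
#'
#' Fitted negatives are clipped to zero. The curve shape is invariant to
#' rescaling all weights by a constant.
#'
#' @param samples Data frame with `ks` and optional `weight`, or a numeric
#'   vector (then `weights` may be supplied).
#' @param range Analysis range `c(lo, hi)`.
#' @param bin_width Histogram bin width (default 0.01).
#' @param smoother `"gam"` or `"spline"`.
#' @param spar Optional fixed smoothing parameter for the `"spline"` path
#'   (implies `smoother = "spline"`).
#' @param weights Optional weights when `samples` is a numeric vector.
#' @return Object of class `density_curve`: list with `grid` (bin midpoints),
#'   `height` (non-negative fitted density), `smoothing` (method record),
#'   `bin_width`, `range`, `n`, `total_weight`.
#' @export
fit_density <- function(samples, range = c(0.05, 5), bin_width = 0.01,
                        smoother = c("gam", "spline"), spar = NULL,
                        weights = NULL) {
  smoother <- if (!is.null(spar)) "spline" else match.arg(smoother)
  df <- .as_weighted(samples, weights)
  if (length(range) != 2L || !all(is.finite(range)) || range[2] <= range[1])
    stop("degenerate range")
  df <- df[df$ks >= range[1] & df$ks <= range[2] & !is.na(df$ks), , drop = FALSE]
  if (nrow(df) < 50L)
    stop("insufficient data: need >= 50 samples in range, got ", nrow(df))
  tw <- sum(df$weight)
  if (tw <= 0) stop("insufficient data: total weight must be positive")
  breaks <- seq(range[1], range[2], by = bin_width)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  nb <- length(breaks) - 1L
  if (nb < 4L) stop("degenerate range: fewer than 4 bins")
  bin <- findInterval(df$ks, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- vapply(split(df$weight, factor(bin, levels = seq_len(nb))), sum, 0)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  if (smoother == "gam" && nb >= 12L) {
    k <- min(50L, nb - 2L)
    bs <- if (k >= 20L) "ad" else "cr"
    fit <- suppressWarnings(
      mgcv::gam(counts ~ s(mids, k = k, bs = bs),
                family = stats::quasipoisson(), method = "REML"))
    y <- as.numeric(stats::predict(fit, type = "response"))
    smoothing <- list(method = "gam", basis = bs, k = k, edf = sum(fit$edf))
  } else {
    fit <- if (is.null(spar)) stats::smooth.spline(mids, counts) else
      stats::smooth.spline(mids, counts, spar = spar)
    y <- stats::predict(fit, mids)$y
    smoothing <- list(method = "smooth.spline", spar = fit$spar, df = fit$df,
                      criterion = if (is.null(spar)) "GCV" else "fixed")
  }
  y <- pmax(0, y) / (tw * bin_width)
  structure(list(grid = mids, height = unname(y), smoothing = smoothing,
                 bin_width = bin_width, range = range,
                 n = nrow(df), total_weight = tw),
            class = "density_curve")
}

#' Locate local maxima of a density curve
#'
#' A grid point is a peak when its height strictly exceeds every height in a
#' window of `window_half_width` grid steps to its left and is at least as
#' high as every height in the window to its right (so a plateau reports its
#' leftmost point). Boundary grid points are never peaks.
#'
#' @param curve A `density_curve`, or a numeric height vector.
#' @param window_half_width Window half-width in grid steps (default 3).
#' @return For a `density_curve`: data frame with `index`, `location`,
#'   `height`, ordered by ascending location. For a numeric vector: integer
#'   indices.
#' @export
find_peaks <- function(curve, window_half_width = 3) {
  h <- if (inherits(curve, "density_curve")) curve$height else as.numeric(curve)
  n <- length(h)
  w <- as.integer(window_half_width)
  idx <- integer(0)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      left <- h[seq(max(1L, i - w), i - 1L)]
      right <- h[seq(i + 1L, min(n, i + w))]
      if (all(h[i] > left) && all(h[i] >= right)) idx <- c(idx, i)
    }
  }
  if (inherits(curve, "density_curve")) {
    data.frame(index = idx, location = curve$grid[idx], height = curve$height[idx])
  } else idx
}

# local minima flanking a grid index: same window rule applied to -height,
# with curve boundaries acting as fallback minima
.flanking_minima <- function(curve, at_index, window_half_width = 3) {
  mins <- find_peaks(-curve$height, window_half_width = window_half_width)
  lo_idx <- mins[mins < at_index]
  hi_idx <- mins[mins > at_index]
  c(lo = if (length(lo_idx)) curve$grid[max(lo_idx)] else NA_real_,
    hi = if (length(hi_idx)) curve$grid[min(hi_idx)] else NA_real_)
}

#' Bootstrap confidence interval for a Ks peak location
#'
#' The peak's window is bounded by the nearest flanking local minima of the
#' fitted density (falling back to `peak +/- 0.2` where no minimum exists).
#' In-window samples are resampled with replacement `n_boot` times, with
#' resampling probability proportional to sample weight; each replicate's
#' mode is located by refitting the density inside the window (the fast
#' `"spline"` smoother of [fit_density()]) and taking the highest peak
#' (grid argmax when the replicate curve is monotone). The 95% CI is the
#' 2.5/97.5 percentile of replicate modes.
#'
#' @param samples Data frame with `ks` and optional `weight`.
#' @param peak Peak location (Ks), typically from [find_peaks()].
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed (bootstrap is reproducible under a fixed seed).
#' @param bin_width Histogram bin width for replicate fits.
#' @param range Full analysis range used for the original fit.
#' @param window Optional fixed window `c(lo, hi)` overriding the flanking
#'   minima.
#' @param spar Optional fixed smoothing parameter for replicate fits.
#' @param curve Optional precomputed [fit_density()] curve over `range` (as
#'   when the peak was found), avoiding a refit.
#' @return Object of class `peak_estimate`: list with `location`, `height`,
#'   `window`, `ci95`, `n_boot`, `boot_locations`, `n_in_window`, and
#'   `flags$ci_undefined` (set when fewer than 50 in-window samples).
#' @export
bootstrap_peak_ci <- function(samples, peak, n_boot = 100, seed = 1L,
                              bin_width = 0.01, range = c(0.05, 5),
                              window = NULL, spar = NULL, curve = NULL) {
  df <- .as_weighted(samples)
  if (peak < min(df$ks) || peak > max(df$ks))
    stop("peak lies outside the sample range")
  if (n_boot < 2) stop("n_boot must be >= 2")
  if (is.null(curve))
    curve <- fit_density(df, range = range, bin_width = bin_width, spar = spar)
  on_window <- function(x) fit_density(x, range = window, bin_width = bin_width,
                                       smoother = "spline", spar = spar)
  at <- which.min(abs(curve$grid - peak))
  if (is.null(window)) {
    fm <- .flanking_minima(curve, at)
    window <- c(if (is.na(fm["lo"])) peak - 0.2 else fm[["lo"]],
                if (is.na(fm["hi"])) peak + 0.2 else fm[["hi"]])
  }
  window[1] <- max(window[1], range[1])
  window[2] <- min(window[2], range[2])
  # keep the window wide enough for a spline fit
  min_w <- 10 * bin_width
  if (diff(window) < min_w) window <- peak + c(-0.5, 0.5) * min_w
  inw <- df[df$ks >= window[1] & df$ks <= window[2], , drop = FALSE]
  res <- structure(list(location = peak, height = curve$height[at],
                        window = unname(window), ci95 = c(NA_real_, NA_real_),
                        n_boot = 0L, boot_locations = numeric(0),
                        n_in_window = nrow(inw),
                        flags = list(ci_undefined = FALSE)),
                   class = "peak_estimate")
  if (nrow(inw) < 50L) {
    warning("CI undefined: only ", nrow(inw), " samples in the peak window")
    res$flags$ci_undefined <- TRUE
    return(res)
  }
  set.seed(as.integer(seed))
  prob <- inw$weight / sum(inw$weight)
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(inw), nrow(inw), replace = TRUE, prob = prob)
    rep_curve <- on_window(inw[idx, , drop = FALSE])
    pk <- find_peaks(rep_curve)
    if (nrow(pk) > 0) pk$location[which.max(pk$height)] else
      rep_curve$grid[which.max(rep_curve$height)]
  }, 0)
  res$ci95 <- unname(stats::quantile(boots, c(0.025, 0.975)))
  res$n_boot <- as.integer(n_boot)
  res$boot_locations <- boots
  res
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat(sprintf("Ks peak at %.3f (window [%.3f, %.3f]; 95%% CI [%.3f, %.3f], %d bootstraps)\n",
              x$location, x$window[1], x$window[2], x$ci95[1], x$ci95[2], x$n_boot))
  invisible(x)
}

#' Mode of a Ks sample by kernel density estimation
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth, evaluated on a
#' grid of approximately 0.001 Ks steps spanning the data range; returns the
#' grid point of maximum density. Used for ortholog divergence peaks.
#'
#' @param values Numeric Ks sample (>= 20 values).
#' @param weights Optional non-negative weights.
#' @return The mode (numeric scalar).
#' @export
kde_mode <- function(values, weights = NULL) {
  values <- as.numeric(values)
  if (length(values) < 20L)
    stop("need >= 20 values for a KDE mode, got ", length(values))
  rng <- range(values)
  npts <- max(2L, as.integer(round(diff(rng) / 0.001)) + 1L)
  if (diff(rng) == 0) return(rng[1])
  w <- if (is.null(weights)) NULL else weights / sum(weights)
  d <- suppressWarnings(stats::density(values, bw = stats::bw.nrd0(values),
                                       weights = w, from = rng[1], to = rng[2],
                                       n = npts))
  d$x[which.max(d$y)]
}
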