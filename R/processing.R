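#' Raw melt curve
#'
#' @param id Curve identifier.
#' @param primer Primer label.
#' @param temperatures Temperature grid, degC (>= 50 points, equal spacing).
#' @param fluorescence Fluorescence per grid point, a.u.
#' @return A `melt_curve` object.
#' @export
melt_curve <- function(id, primer, temperatures, fluorescence) {
  if (length(temperatures) != length(fluorescence)) {
    stop("temperatures and fluorescence must have equal length")
  }
  if (length(temperatures) < 50) stop("melt curve needs >= 50 grid points")
  if (!all(is.finite(temperatures)) || !all(is.finite(fluorescence))) {
    stop("melt curve contains non-finite values")
  }
  steps <- diff(temperatures)
  if (any(steps <= 0) || diff(range(steps)) > 1e-6) {
    stop("temperatures must be strictly increasing on a uniform grid")
  }
  structure(list(id = id, primer = primer, temperatures = temperatures,
                 fluorescence = fluorescence),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve> %s [%s] %.1f..%.1f degC (%d points)\n",
              x$id, x$primer, min(x$temperatures), max(x$temperatures),
              length(x$temperatures)))
  invisible(x)
}

#' Fingerprint-extraction configuration
#'
#' Bundles all tunables of the normalization -> derivative -> peak-calling
#' stages and of downstream fingerprint matching.
#'
#' @param pre_region,post_region Pre-/post-melt normalization windows as
#'   `c(lo, hi)` degC; `NULL` means the first/last 2 degC of the grid.
#' @param smooth_window Savitzky-Golay window, degC.
#' @param sg_order Savitzky-Golay polynomial order.
#' @param min_prominence Minimum peak prominence as a fraction of the
#'   derivative maximum.
#' @param min_height Minimum absolute peak height, derivative units.
#' @param min_separation Minimum Tm separation between called peaks, degC.
#' @param tolerance Tm matching tolerance, degC.
#' @param lambda Penalty per unmatched peak in the fingerprint distance.
#' @param reject_threshold Distance above which a query is UNCLASSIFIED.
#' @param uniqueness_threshold Distance above which two reference
#'   fingerprints count as distinguishable.
#' @return An `hrm_config` object.
#' @export
hrm_config <- function(pre_region = NULL, post_region = NULL,
                       smooth_window = 1.1, sg_order = 5,
                       min_prominence = 0.05, min_height = 0.08,
                       min_separation = 0.8, tolerance = 0.3,
                       lambda = 1, reject_threshold = 0.5,
                       uniqueness_threshold = 0.25) {
  stopifnot(smooth_window > 0, sg_order >= 2,
            min_prominence >= 0, min_height >= 0, min_separation >= 0,
            tolerance > 0, lambda > 0, reject_threshold > 0,
            uniqueness_threshold >= 0)
  structure(list(pre_region = pre_region, post_region = post_region,
                 smooth_window = smooth_window, sg_order = sg_order,
                 min_prominence = min_prominence, min_height = min_height,
                 min_separation = min_separation, tolerance = tolerance,
                 lambda = lambda, reject_threshold = reject_threshold,
                 uniqueness_threshold = uniqueness_threshold),
            class = "hrm_config")
}

region_indices <- function(temps, region, what) {
  if (region[1] >= region[2]) stop(what, " region must be an interval")
  if (region[1] < min(temps) - 1e-9 || region[2] > max(temps) + 1e-9) {
    stop(what, " region lies outside the temperature grid")
  }
  idx <- which(temps >= region[1] - 1e-9 & temps <= region[2] + 1e-9)
  if (length(idx) < 5) stop(what, " region must cover >= 5 grid points")
  idx
}

#' Pre-/post-melt normalization
#'
#' Rescales fluorescence affinely so that the mean over the pre-melt window
#' maps to 1 and the mean over the post-melt window maps to 0, removing
#' between-well baseline and gain differences.
#'
#' @param curve A [melt_curve()].
#' @param pre_region,post_region Normalization windows `c(lo, hi)` in degC;
#'   defaults are the first and last 2 degC of the grid. The pre window
#'   must lie entirely below the post window and they must not overlap.
#' @return A `normalized_curve` with fields `temperatures`, `values`.
#' @export
normalize_curve <- function(curve, pre_region = NULL, post_region = NULL) {
  temps <- curve$temperatures
  if (is.null(pre_region)) pre_region <- c(min(temps), min(temps) + 2)
  if (is.null(post_region)) post_region <- c(max(temps) - 2, max(temps))
  if (pre_region[2] >= post_region[1]) {
    stop("pre-melt region must lie entirely below the post-melt region")
  }
  pre_idx <- region_indices(temps, pre_region, "pre-melt")
  post_idx <- region_indices(temps, post_region, "post-melt")
  pre_mean <- mean(curve$fluorescence[pre_idx])
  post_mean <- mean(curve$fluorescence[post_idx])
  if (abs(pre_mean - post_mean) < 1e-12) stop("degenerate curve")
  values <- (curve$fluorescence - post_mean) / (pre_mean - post_mean)
  structure(list(id = curve$id, primer = curve$primer,
                 temperatures = temps, values = values,
                 pre_region = pre_region, post_region = post_region),
            class = "normalized_curve")
}

#' Smoothed negative-derivative melt curve
#'
#' Estimates `-dF/dT` of a normalized curve with a Savitzky-Golay
#' smoothing-differentiation filter. Half a window is trimmed from each end
#' so only interior points, where the polynomial fit is centred, are
#' reported.
#'
#' @param nc A `normalized_curve`.
#' @param smooth_window Filter window, degC (>= 3 grid steps).
#' @param sg_order Polynomial order (must be below the window point count).
#' @return A `derivative_curve` with fields `temperatures`, `values`.
#' @export
derivative_curve <- function(nc, smooth_window = 1.1, sg_order = 5) {
  temps <- nc$temperatures
  step <- temps[2] - temps[1]
  n_pts <- round(smooth_window / step)
  if (n_pts %% 2 == 0) n_pts <- n_pts + 1
  if (n_pts < 3) stop("smoothing window must span >= 3 grid steps")
  if (length(temps) < n_pts) stop("curve shorter than the smoothing window")
  if (sg_order >= n_pts) stop("polynomial order must be below window size")
  deriv <- -signal::sgolayfilt(nc$values, p = sg_order, n = n_pts, m = 1,
                               ts = step)
  half <- (n_pts - 1) / 2
  keep <- (half + 1):(length(temps) - half)
  structure(list(id = nc$id, primer = nc$primer,
                 temperatures = temps[keep], values = deriv[keep]),
            class = "derivative_curve")
}

melt_fingerprint_new <- function(peaks, primer, id, valid = nrow(peaks) > 0) {
  structure(list(primer = primer, id = id, peaks = peaks, valid = valid),
            class = "melt_fingerprint")
}

#' Construct a melting fingerprint from known peak temperatures
#'
#' Convenience constructor for fingerprints given directly as Tm lists
#' (e.g. a published consensus) rather than extracted from curves.
#'
#' @param tms Numeric vector of peak temperatures, degC.
#' @param primer Primer label.
#' @param id Source identifier.
#' @param heights Optional peak heights.
#' @return A `melt_fingerprint`.
#' @export
melt_fingerprint <- function(tms, primer = NA_character_, id = "manual",
                             heights = NULL) {
  o <- order(tms)
  tms <- tms[o]
  if (length(tms) > 1 && any(diff(tms) <= 0)) {
    stop("peak temperatures must be strictly increasing")
  }
  h <- if (is.null(heights)) rep(NA_real_, length(tms)) else heights[o]
  peaks <- data.frame(tm = tms, height = h, prominence = h,
                      width = NA_real_)
  melt_fingerprint_new(peaks, primer, id)
}

#' @export
print.melt_fingerprint <- function(x, ...) {
  cat(sprintf("<melt_fingerprint> %s [%s] %d peak(s)%s\n", x$id,
              x$primer, nrow(x$peaks), if (x$valid) "" else " (invalid)"))
  if (nrow(x$peaks) > 0) {
    cat("  Tm:", paste(sprintf("%.1f", x$peaks$tm), collapse = ", "),
        "degC\n")
  }
  invisible(x)
}

fingerprint_tms <- function(fp) {
  if (inherits(fp, "melt_fingerprint")) fp$peaks$tm else as.numeric(fp)
}

# Topographic prominence of local maximum `i` of series `y`: height above
# the higher of the two lowest saddles separating it from taller terrain.
peak_prominence <- function(y, i) {
  h <- y[i]
  left_base <- {
    j <- i
    lo <- h
    while (j > 1 && y[j - 1] <= h) {
      j <- j - 1
      lo <- min(lo, y[j])
    }
    if (j == 1) min(y[1:i]) else lo
  }
  right_base <- {
    j <- i
    lo <- h
    while (j < length(y) && y[j + 1] <= h) {
      j <- j + 1
      lo <- min(lo, y[j])
    }
    if (j == length(y)) min(y[i:length(y)]) else lo
  }
  h - max(left_base, right_base)
}

# Width of peak i at half prominence, by linear interpolation.
peak_width <- function(x, y, i, prominence) {
  target <- y[i] - prominence / 2
  left <- x[i]
  for (j in seq(i, 2)) {
    if (y[j - 1] < target) {
      left <- x[j - 1] + (x[j] - x[j - 1]) * (target - y[j - 1]) /
        (y[j] - y[j - 1])
      break
    }
  }
  right <- x[i]
  for (j in seq(i, length(x) - 1)) {
    if (y[j + 1] < target) {
      right <- x[j] + (x[j + 1] - x[j]) * (target - y[j + 1]) /
        (y[j] - y[j + 1])
      break
    }
  }
  right - left
}

#' Call melting peaks on a derivative curve
#'
#' Finds local maxima of `-dF/dT`, filters them by absolute height,
#' topographic prominence (as a fraction of the curve maximum) and minimum
#' mutual separation (taller peaks win), and refines each Tm below grid
#' resolution by 3-point parabolic interpolation. Plateau maxima are
#' resolved to their leftmost grid point.
#'
#' @param dc A `derivative_curve`.
#' @param min_prominence Minimum prominence as a fraction of `max(dc$values)`.
#' @param min_separation Minimum Tm distance between reported peaks, degC.
#' @param min_height Minimum absolute height, derivative units.
#' @return A `melt_fingerprint`; zero peaks yield a fingerprint flagged
#'   invalid rather than an error.
#' @export
call_peaks <- function(dc, min_prominence = 0.05, min_separation = 0.8,
                       min_height = 0.08) {
  x <- dc$temperatures
  y <- dc$values
  n <- length(y)
  empty <- function() {
    melt_fingerprint_new(
      data.frame(tm = numeric(0), height = numeric(0),
                 prominence = numeric(0), width = numeric(0)),
      dc$primer, dc$id, valid = FALSE)
  }
  if (n < 3) return(empty())
  # strict rise on the left, non-rise on the right: leftmost plateau point
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] &
                  y[2:(n - 1)] >= y[3:n]) + 1
  if (length(cand) == 0) return(empty())
  prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
  keep <- y[cand] >= min_height & prom >= min_prominence * max(y)
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) == 0) return(empty())
  # enforce separation, tallest first
  ord <- order(y[cand], decreasing = TRUE)
  selected <- integer(0)
  sel_prom <- numeric(0)
  for (k in ord) {
    i <- cand[k]
    if (all(abs(x[i] - x[selected]) >= min_separation - 1e-9)) {
      selected <- c(selected, i)
      sel_prom <- c(sel_prom, prom[k])
    }
  }
  o <- order(x[selected])
  selected <- selected[o]
  sel_prom <- sel_prom[o]
  refine <- function(i) {
    # plateau maxima stay at their leftmost grid point; only strict
    # interior maxima are interpolated
    if (i <= 1 || i >= n || y[i + 1] >= y[i]) return(c(x[i], y[i]))
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (abs(denom) < 1e-15) return(c(x[i], y[i]))
    delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
    delta <- max(-0.5, min(0.5, delta))
    c(x[i] + delta * (x[2] - x[1]),
      y[i] - 0.25 * (y[i - 1] - y[i + 1]) * delta)
  }
  ref <- t(vapply(selected, refine, numeric(2)))
  widths <- vapply(seq_along(selected), function(k) {
    peak_width(x, y, selected[k], sel_prom[k])
  }, numeric(1))
  peaks <- data.frame(tm = ref[, 1], height = ref[, 2],
                      prominence = sel_prom, width = widths)
  melt_fingerprint_new(peaks, dc$primer, dc$id)
}

#' Extract a melting fingerprint from a raw curve
#'
#' Composition of [normalize_curve()], [derivative_curve()] and
#' [call_peaks()] under one configuration object.
#'
#' @param curve A [melt_curve()].
#' @param config An [hrm_config()].
#' @return A `melt_fingerprint`.
#' @export
extract_fingerprint <- function(curve, config = hrm_config()) {
  nc <- normalize_curve(curve, config$pre_region, config$post_region)
  dc <- derivative_curve(nc, config$smooth_window, config$sg_order)
  call_peaks(dc, config$min_prominence, config$min_separation,
             config$min_height)
}

#' Extract fingerprints for every curve in a set
#'
#' @param cs A `curve_set`.
#' @param config An [hrm_config()].
#' @return List of `melt_fingerprint` objects, aligned with `cs$meta` rows.
#' @export
extract_fingerprints <- function(cs, config = hrm_config()) {
  lapply(cs$curves, extract_fingerprint, config = config)
}
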