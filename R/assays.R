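# Photometric enzyme-assay arithmetic and growth-curve fitting: specific
# activities under the 2-umol-electron unit definition, Table-style fold
# changes, and log-linear fits for mu and doubling time.

# Closed-form simple linear regression.  Unlike lm()+summary(), this gives
# an exactly zero slope on constant input and stays quiet on perfect fits.
least_squares_line <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  slope <- sum(xc * yc) / sum(xc^2)
  ss_tot <- sum(yc^2)
  ss_res <- sum((yc - slope * xc)^2)
  list(
    slope = slope,
    intercept = mean(y) - slope * mean(x),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  )
}

#' Construct a spectrophotometric assay trace
#'
#' @param times Time points in minutes, strictly increasing.
#' @param absorbance Absorbance readings at the assay wavelength.
#' @param epsilon Extinction coefficient in mM^-1 cm^-1 (6.3 for NAD(P)H at
#'   340 nm, 13.1 for ferredoxin at 430 nm).
#' @param path_length Cuvette path length in cm.
#' @param volume Assay volume in mL.
#' @param protein_mass Protein in the assay, mg.
#' @param electrons_per_chromophore Electrons carried per chromophore
#'   reduced (2 for NAD(P)H; configurable for ferredoxin, default 2 to
#'   match the ledger's electron-pair convention).
#' @return An `assay_trace` object.
#' @export
assay_trace <- function(times, absorbance, epsilon, path_length = 1,
                        volume = 1, protein_mass, electrons_per_chromophore = 2) {
  stopifnot(length(times) == length(absorbance), length(times) >= 2)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (path_length <= 0 || volume <= 0) stop("path length and volume must be positive")
  if (protein_mass <= 0) stop("protein mass must be positive")
  if (electrons_per_chromophore < 1) stop("electrons per chromophore must be >= 1")
  structure(
    list(
      times = as.double(times), absorbance = as.double(absorbance),
      epsilon = epsilon, path_length = path_length, volume = volume,
      protein_mass = protein_mass,
      electrons_per_chromophore = electrons_per_chromophore
    ),
    class = "assay_trace"
  )
}

#' Specific enzyme activity from an absorbance trace
#'
#' Least-squares slope of absorbance against time (A/min) over the chosen
#' window, converted by Beer-Lambert to a concentration rate
#' (slope / (epsilon * path), mM/min = umol/mL/min), scaled by the assay
#' volume to umol chromophore/min, to umol electrons/min via the electrons
#' per chromophore, to units (1 U = 2 umol electrons/min), and finally
#' divided by the protein mass.  A falling absorbance gives a negative
#' signed activity with `direction = "consuming"`.
#'
#' @param trace An [assay_trace()].
#' @param window Optional integer index range `c(first, last)` of the
#'   linear region; default uses the full trace.  At least 3 points.
#' @return List with `activity_u_per_mg`, `slope_a_per_min`, `direction`
#'   (`"producing"`, `"consuming"` or `"flat"`), and `r_squared`.
#' @export
specific_activity <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "assay_trace"))
  idx <- if (is.null(window)) seq_along(trace$times) else seq(window[1], window[2])
  if (length(idx) < 3) stop("need at least 3 points in the linear window")
  ls <- least_squares_line(trace$times[idx], trace$absorbance[idx])
  slope <- ls$slope
  r2 <- ls$r_squared
  conc_rate <- slope / (trace$epsilon * trace$path_length)   # mM/min
  umol_per_min <- conc_rate * trace$volume                   # umol chromophore/min
  umol_e_per_min <- umol_per_min * trace$electrons_per_chromophore
  units <- umol_e_per_min / 2                                # 1 U = 2 umol e-/min
  list(
    activity_u_per_mg = units / trace$protein_mass,
    slope_a_per_min = slope,
    direction = if (slope > 0) "producing" else if (slope < 0) "consuming" else "flat",
    r_squared = r2
  )
}

#' Fold change between two specific activities
#'
#' @param a,b Activities in U/mg; `b` is the reference and must be nonzero.
#' @param rounded If `TRUE`, round to the nearest integer (half away from
#'   zero) for parity with prose-style "15-fold" statements.
#' @return Dimensionless fold change `a / b`.
#' @export
fold_change <- function(a, b, rounded = FALSE) {
  if (!is.numeric(a) || !is.numeric(b)) stop("activities must be numeric")
  if (any(b == 0)) stop("reference activity must be nonzero")
  fc <- a / b
  if (rounded) round_half_away(fc) else fc
}

#' Construct a growth curve
#'
#' @param times Time points in hours.
#' @param od600 Optical density at 600 nm.
#' @return A `growth_curve` object.
#' @export
growth_curve <- function(times, od600) {
  stopifnot(length(times) == length(od600), length(times) >= 2)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.double(times), od600 = as.double(od600)),
            class = "growth_curve")
}

#' Fit exponential growth: specific growth rate and doubling time
#'
#' Ordinary least squares of ln(OD) against time over the fit window gives
#' the specific growth rate mu (h^-1); the doubling time is ln(2)/mu.  With
#' `window = "auto"` the fit uses the longest window (>= `min_points`
#' points) whose log-linear R^2 is at least `r2_min`.
#'
#' @param curve A [growth_curve()].
#' @param window Integer index range `c(first, last)`, `NULL` for the full
#'   curve, or `"auto"`.
#' @param r2_min,min_points Auto-window parameters.
#' @return List with `mu` (h^-1), `doubling_time_h` (NA with a flag when
#'   mu <= 0), `r_squared`, `window`, and `flag` (`"ok"` or
#'   `"non-exponential"`).
#' @export
fit_growth <- function(curve, window = NULL, r2_min = 0.99, min_points = 4) {
  stopifnot(inherits(curve, "growth_curve"))
  n <- length(curve$times)
  fit_idx <- function(idx) {
    od <- curve$od600[idx]
    if (any(od <= 0)) stop("non-positive OD in fit window")
    ls <- least_squares_line(curve$times[idx], log(od))
    list(mu = ls$slope, r2 = ls$r_squared)
  }
  if (identical(window, "auto")) {
    best <- NULL
    for (len in seq(n, min_points)) {
      for (start in seq_len(n - len + 1)) {
        idx <- seq(start, start + len - 1)
        if (any(curve$od600[idx] <= 0)) next
        f <- fit_idx(idx)
        if (f$r2 >= r2_min && f$mu > 0) {
          best <- c(start, start + len - 1)
          break
        }
      }
      if (!is.null(best)) break
    }
    if (is.null(best)) stop("no window of >= ", min_points, " points reaches R^2 >= ", r2_min)
    window <- best
  }
  idx <- if (is.null(window)) seq_len(n) else seq(window[1], window[2])
  if (length(idx) < 3) stop("fit window must contain at least 3 points")
  f <- fit_idx(idx)
  ok <- f$mu > 0
  list(
    mu = if (ok) f$mu else 0,
    doubling_time_h = if (ok) log(2) / f$mu else NA_real_,
    r_squared = f$r2,
    window = c(idx[1], idx[length(idx)]),
    flag = if (ok) "ok" else "non-exponential"
  )
}
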