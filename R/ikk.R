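#' Construct a numerically defined IKK activity curve
#'
#' IKK activity enters the feedback model as an input: a piecewise-linear
#' function of time given by (time, activity) points, with a constant basal
#' activity before the first point and the final tabulated value held after
#' the last point. Activity is a dimensionless fraction of the maximum.
#'
#' @param time_min Strictly increasing times in minutes.
#' @param activity Non-negative activity fractions, same length.
#' @param basal Pre-stimulus activity level (default the first tabulated
#'   activity).
#' @return Object of class `ikk_curve`.
#' @export
ikk_curve <- function(time_min, activity, basal = activity[1]) {
  stopifnot(length(time_min) >= 1L, length(time_min) == length(activity))
  if (any(diff(time_min) <= 0)) stop("times must be strictly increasing")
  if (any(activity < 0) || basal < 0) stop("activities must be >= 0")
  structure(list(time_min = as.numeric(time_min),
                 activity = as.numeric(activity),
                 basal = as.numeric(basal)),
            class = "ikk_curve")
}

#' Evaluate an IKK activity curve
#'
#' Linear interpolation between tabulated points; `basal` before the first
#' point; the last tabulated value held beyond the final time.
#'
#' @param curve An [ikk_curve()].
#' @param t Times in minutes (vectorised).
#' @return Activity fractions.
#' @export
ikk_activity <- function(curve, t) {
  stopifnot(inherits(curve, "ikk_curve"))
  if (length(curve$time_min) == 0L) stop("empty IKK curve")
  out <- stats::approx(curve$time_min, curve$activity, xout = t,
                       rule = 2)$y
  out[t < curve$time_min[1]] <- curve$basal
  out
}

#' TNFa-induced IKK activity profile (synthetic reconstruction)
#'
#' A reconstruction of the canonical chronic-TNFa IKK activity profile used
#' by the precursor models of this signalling module: low basal activity, a
#' sharp peak of full activation within ~5 minutes of stimulation, decay to a
#' plateau of ~10 percent of maximum that persists for the rest of the time
#' course. Shipped because the numerically tabulated curve this emulates is
#' not machine-readable; treat it as a synthetic stand-in with the same
#' qualitative features.
#'
#' @return An `ikk_curve`.
#' @export
default_ikk_curve <- function() {
  ikk_curve(
    time_min = c(0, 5, 10, 20, 30, 45, 60, 90, 120, 240, 360),
    activity = c(0.01, 1.0, 0.75, 0.3, 0.12, 0.06, 0.035, 0.022, 0.017, 0.016, 0.016),
    basal = 0.01)
}

#' A constant (basal-only) IKK curve
#'
#' @param level Constant activity level.
#' @param t_end Final tabulated time (min).
#' @return An `ikk_curve` flat at `level`.
#' @export
constant_ikk_curve <- function(level = 0.01, t_end = 1000) {
  ikk_curve(time_min = c(0, t_end), activity = c(level, level), basal = level)
}

#' @export
print.ikk_curve <- function(x, ...) {
  cat(sprintf("IKK activity curve: %d points over %g-%g min, basal %.3g, peak %.3g\n",
              length(x$time_min), min(x$time_min), max(x$time_min),
              x$basal, max(x$activity)))
  invisible(x)
}

#' Read an IKK curve from delimited text
#'
#' Two columns `time_min` and `ikk_activity`; an optional header comment line
#' `# basal=<value>` sets the pre-stimulus level.
#'
#' @param path File path.
#' @return An `ikk_curve`.
#' @export
read_ikk_curve <- function(path) {
  raw <- readLines(path)
  basal <- NA_real_
  m <- regmatches(raw, regexpr("^#\\s*basal\\s*=\\s*([0-9.eE+-]+)", raw))
  if (length(m[m != ""])) {
    basal <- as.numeric(sub("^#\\s*basal\\s*=\\s*", "", m[m != ""][1]))
  }
  tab <- utils::read.delim(textConnection(raw), comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("time_min", "ikk_activity") %in% names(tab)))
  if (is.na(basal)) basal <- tab$ikk_activity[1]
  ikk_curve(tab$time_min, tab$ikk_activity, basal = basal)
}

#' Write an IKK curve to delimited text
#'
#' @param curve An `ikk_curve`.
#' @param path Output path.
#' @export
write_ikk_curve <- function(curve, path) {
  stopifnot(inherits(curve, "ikk_curve"))
  lines <- c(sprintf("# basal=%.10g", curve$basal),
             "time_min\tikk_activity",
             sprintf("%.10g\t%.10g", curve$time_min, curve$activity))
  writeLines(lines, path)
  invisible(path)
}
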