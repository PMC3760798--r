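#' Reference secondary chemical shifts for a fully formed alpha-helix
#'
#' The chemical-shift deviation (observed minus sequence-corrected random
#' coil) expected for a 100 percent helical residue: 2.8 ppm for C-alpha and
#' 2.1 ppm for the carbonyl carbon.
#'
#' @param ca_ppm,co_ppm Full-helix CSD references in ppm (both > 0).
#' @return Named list with `ca_ppm` and `co_ppm`.
#' @export
reference_shifts <- function(ca_ppm = 2.8, co_ppm = 2.1) {
  stopifnot(ca_ppm > 0, co_ppm > 0)
  list(ca_ppm = ca_ppm, co_ppm = co_ppm)
}

#' Estimate the helical population of a residue window from secondary shifts
#'
#' Averages the C-alpha and carbonyl chemical-shift deviations over a residue
#' window, divides each mean by its full-helix reference, and combines the two
#' per-nucleus estimates. The fractional population is clamped to [0, 1]; the
#' `clamped` attribute records whether clamping occurred. Residues missing one
#' nucleus contribute to the other's mean only (flagged via the
#' `partial_residues` attribute).
#'
#' @param shifts Data frame with columns `residue_index`, `csd_ca_ppm`,
#'   `csd_co_ppm` (NA allowed for a missing nucleus).
#' @param window Integer vector of residue indices, or length-2 range
#'   `c(first, last)` when `as_range = TRUE`.
#' @param refs A [reference_shifts()] list.
#' @param combine `"average"` (mean of the two per-nucleus estimates,
#'   default) or `"pooled"` (sum of mean CSDs over sum of references).
#' @param as_range Interpret `window` of length 2 as an inclusive range.
#' @return Fraction in [0, 1] with attributes `unclamped`, `clamped`,
#'   `partial_residues`.
#' @export
helix_population <- function(shifts, window, refs = reference_shifts(),
                             combine = c("average", "pooled"),
                             as_range = length(window) == 2L) {
  combine <- match.arg(combine)
  stopifnot(is.data.frame(shifts),
            all(c("residue_index", "csd_ca_ppm", "csd_co_ppm") %in%
                  names(shifts)))
  if (anyDuplicated(shifts$residue_index))
    stop("residue indices must be unique")
  if (as_range) window <- seq(window[1], window[2])
  if (length(window) == 0L) stop("empty residue window")
  sel <- shifts[shifts$residue_index %in% window, ]
  if (nrow(sel) == 0L) stop("window not covered by the shift table")
  partial <- sel$residue_index[xor(is.na(sel$csd_ca_ppm),
                                   is.na(sel$csd_co_ppm))]
  mean_ca <- mean(sel$csd_ca_ppm, na.rm = TRUE)
  mean_co <- mean(sel$csd_co_ppm, na.rm = TRUE)
  est <- switch(combine,
                average = mean(c(mean_ca / refs$ca_ppm,
                                 mean_co / refs$co_ppm), na.rm = TRUE),
                pooled = (mean_ca + mean_co) / (refs$ca_ppm + refs$co_ppm))
  out <- min(max(est, 0), 1)
  attr(out, "unclamped") <- est
  attr(out, "clamped") <- est < 0 || est > 1
  attr(out, "partial_residues") <- partial
  out
}

#' Classify backbone dynamics from heteronuclear NOE values
#'
#' Per-residue three-way classification of [1H]-15N heteronuclear NOEs:
#' `disordered` for values at or below the lower threshold (zero or negative
#' NOEs indicate dynamic disorder), `flexible` between the thresholds (values
#' around 0.3-0.5 mark high ns-timescale flexibility), `rigid` at or above
#' the upper threshold (well-ordered backbone).
#'
#' @param noes Data frame with columns `residue_index` and `noe`, or a bare
#'   numeric vector of NOE values.
#' @param thresholds Length-2 numeric `c(disordered_max, rigid_min)` with
#'   `thresholds[1] < thresholds[2]` (default `c(0, 0.6)`).
#' @return Factor with levels disordered/flexible/rigid (named by residue
#'   index when available).
#' @export
classify_dynamics <- function(noes, thresholds = c(0, 0.6)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2])
  if (is.data.frame(noes)) {
    stopifnot(all(c("residue_index", "noe") %in% names(noes)))
    if (anyDuplicated(noes$residue_index))
      stop("residue indices must be unique")
    vals <- stats::setNames(noes$noe, noes$residue_index)
  } else {
    vals <- noes
  }
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  cls <- ifelse(vals <= thresholds[1], "disordered",
                ifelse(vals < thresholds[2], "flexible", "rigid"))
  factor(stats::setNames(cls, names(vals)),
         levels = c("disordered", "flexible", "rigid"))
}

#' Read a secondary chemical-shift table
#'
#' Delimited text with columns `residue_index`, `residue_name`,
#' `csd_ca_ppm`, `csd_co_ppm`.
#'
#' @param path File path.
#' @return Data frame sorted by residue index.
#' @export
read_shift_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("residue_index", "csd_ca_ppm", "csd_co_ppm") %in%
                  names(tab)))
  tab[order(tab$residue_index), ]
}
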