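ISOFORMS <- c("a", "b", "e") # IkBalpha, IkBbeta, IkBepsilon

#' Construct a model parameter set for the IkB-NF-kB feedback module
#'
#' Builds the full rate-constant set for the ordinary-differential-equation
#' model of the IKK-IkB-NF-kB signalling module: three IkB isoforms (alpha,
#' beta, epsilon), each with an mRNA species, free protein and NF-kB-bound
#' complex in both compartments, plus free NF-kB in cytoplasm and nucleus.
#' Units: concentrations in uM, time in minutes, IKK activity as a
#' dimensionless fraction of its maximum.
#'
#' The default values are a reconstruction in the style of the published
#' precursor models of this signalling module (see the packaged parameter
#' file, provenance `"precursor_default"`). Call [adapt_parameters()] before
#' simulating: it applies the module's adaptations (1.8x IkB mRNA turnover and
#' additive basal + saturable induced transcription for IkBalpha/epsilon).
#'
#' @param ... Named overrides of any top-level field (see Details in the
#'   package vignette). Per-isoform fields are length-3 named vectors
#'   (`a`, `b`, `e`); transcription is a list of per-isoform lists with
#'   `k_basal`, `k_induced_max`, `K_half`, `h`.
#' @return An object of class `nfkb_params`.
#' @export
model_parameters <- function(...) {
  p <- list(
    total_nfkb = 0.1,        # uM, cytoplasmic-volume-equivalent total
    nfkb_scale = 1,          # multiplier on total_nfkb (abundance scan)
    kmrna_scale = 1,         # multiplier on the induced IkBa mRNA term only
    volume_ratio = 3.3,      # cytoplasmic:nuclear volume
    transcription = list(
      a = list(k_basal = 2e-5, k_induced_max = 3.6e-2,   K_half = 0.6, h = 2),
      b = list(k_basal = 1e-5, k_induced_max = 0,      K_half = 0.6, h = 2),
      e = list(k_basal = 5e-6, k_induced_max = 7e-3,   K_half = 0.6, h = 2)),
    translation = c(a = 0.24, b = 0.24, e = 0.24),         # 1/min
    mrna_degradation = c(a = 0.029, b = 0.0077, e = 0.017),# 1/min, base rates
    mrna_degradation_factor = NA_real_,                    # set on adaptation
    deg_free_basal = c(a = 0.12, b = 0.18, e = 0.18),      # free IkB, 1/min
    deg_free_ikk = c(a = 0.18, b = 0.06, e = 0.09),        # x IKK activity
    deg_bound_basal = c(a = 6e-5, b = 6e-5, e = 6e-5),     # bound IkB, 1/min
    deg_bound_ikk = c(a = 0.36, b = 0.12, e = 0.18),       # x IKK activity
    assoc = c(a = 30, b = 30, e = 30),                     # 1/(uM min)
    dissoc = c(a = 0.003, b = 0.003, e = 0.003),           # 1/min
    imp_nfkb = 5.4, exp_nfkb = 0.0048,                     # 1/min
    imp_ikb = c(a = 0.36, b = 0.009, e = 0.09),
    exp_ikb = c(a = 0.012, b = 0.012, e = 0.012),
    exp_complex = c(a = 0.84, b = 0.42, e = 0.42),
    adapted = FALSE,
    provenance = "precursor_default")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  validate_params(structure(p, class = "nfkb_params"))
}

validate_params <- function(p) {
  stopifnot(inherits(p, "nfkb_params"))
  rate_vecs <- c("translation", "mrna_degradation", "deg_free_basal",
                 "deg_free_ikk", "deg_bound_basal", "deg_bound_ikk",
                 "assoc", "dissoc", "imp_ikb", "exp_ikb", "exp_complex")
  for (f in rate_vecs) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 3L || any(v < 0) ||
        !all(ISOFORMS %in% names(v)))
      stop("field '", f, "' must be a non-negative named vector over a, b, e")
  }
  stopifnot(p$total_nfkb >= 0, p$nfkb_scale > 0,
            p$kmrna_scale > 0, p$kmrna_scale <= 1,
            p$volume_ratio > 0, p$imp_nfkb >= 0, p$exp_nfkb >= 0)
  for (i in ISOFORMS) {
    tx <- p$transcription[[i]]
    stopifnot(tx$k_basal >= 0, tx$k_induced_max >= 0,
              tx$K_half > 0, tx$h > 0)
  }
  if (p$transcription$b$k_induced_max != 0)
    stop("IkBbeta transcription must be constitutive (k_induced_max = 0)")
  p
}

#' Apply the feedback-module adaptations to a base parameter set
#'
#' Converts a base (precursor-style) parameter set into the adapted model used
#' throughout this package: every IkB mRNA degradation rate is multiplied by
#' 1.8 (in line with direct mRNA half-life measurements), and IkBalpha and
#' IkBepsilon transcription is fixed to the additive form
#' \eqn{k_{basal} + k_{induced}\,(N/K)^h / (1 + (N/K)^h)} (additive Pol II
#' recruitment), evaluating to `k_basal` at zero nuclear NF-kB. The adaptation
#' is recorded in the parameter set and may be applied only once.
#'
#' @param base An unadapted `nfkb_params` object.
#' @param mrna_factor Multiplier on the IkB mRNA degradation rates
#'   (default 1.8).
#' @return The adapted `nfkb_params`.
#' @export
adapt_parameters <- function(base, mrna_factor = 1.8) {
  stopifnot(inherits(base, "nfkb_params"))
  if (isTRUE(base$adapted) || !is.na(base$mrna_degradation_factor))
    stop("parameters are already adapted; the adaptation is applied once")
  stopifnot(mrna_factor > 0)
  base$mrna_degradation <- base$mrna_degradation * mrna_factor
  base$mrna_degradation_factor <- mrna_factor
  base$adapted <- TRUE
  validate_params(base)
}

#' Transcription rate of an IkB isoform given nuclear NF-kB
#'
#' Additive basal + saturable induced production:
#' \eqn{k_{basal} + s\,k_{induced}\,(N/K)^h/(1+(N/K)^h)}, where the scale s is
#' `kmrna_scale` for IkBalpha and 1 otherwise.
#'
#' @param params Adapted `nfkb_params`.
#' @param isoform One of `"a"`, `"b"`, `"e"`.
#' @param nuclear_nfkb Nuclear NF-kB concentration (uM), scalar or vector.
#' @return mRNA production rate (uM/min).
#' @export
transcription_rate <- function(params, isoform, nuclear_nfkb) {
  stopifnot(isoform %in% ISOFORMS, all(nuclear_nfkb >= 0))
  tx <- params$transcription[[isoform]]
  s <- if (isoform == "a") params$kmrna_scale else 1
  x <- (nuclear_nfkb / tx$K_half)^tx$h
  tx$k_basal + s * tx$k_induced_max * x / (1 + x)
}

#' @export
print.nfkb_params <- function(x, ...) {
  cat("IkB-NF-kB feedback module parameters\n")
  cat(sprintf("  total NF-kB %.3g uM (x%.3g), kmrna_scale %.4g, volume ratio %.3g\n",
              x$total_nfkb, x$nfkb_scale, x$kmrna_scale, x$volume_ratio))
  cat(sprintf("  adapted: %s (mRNA degradation factor %s), provenance: %s\n",
              x$adapted,
              ifelse(is.na(x$mrna_degradation_factor), "unset",
                     format(x$mrna_degradation_factor)),
              x$provenance))
  invisible(x)
}

# flatten/unflatten for the key-value parameter file dialect
flatten_params <- function(p) {
  out <- list()
  for (f in names(p)) {
    v <- p[[f]]
    if (f == "transcription") {
      for (i in ISOFORMS) for (k in names(v[[i]]))
        out[[paste("transcription", i, k, sep = ".")]] <- v[[i]][[k]]
    } else if (is.numeric(v) && length(v) == 3L) {
      for (i in ISOFORMS) out[[paste(f, i, sep = ".")]] <- v[[i]]
    } else {
      out[[f]] <- v
    }
  }
  out
}

#' Write a parameter set to a key-value file
#'
#' Flat two-column tab-separated text: dotted keys (e.g.
#' `transcription.a.k_basal`, `assoc.b`) and values. `provenance` and
#' `adapted` round-trip with the numeric fields.
#'
#' @param params An `nfkb_params` object.
#' @param path Output file path.
#' @export
write_parameters <- function(params, path) {
  fl <- flatten_params(params)
  lines <- c("key\tvalue",
             vapply(names(fl), function(k) {
               paste0(k, "\t", format(fl[[k]], digits = 15))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter set from a key-value file
#'
#' @param path File written by [write_parameters()] (or hand-edited in the
#'   same dialect).
#' @return An `nfkb_params` object.
#' @export
read_parameters <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("key", "value") %in% names(tab)))
  kv <- stats::setNames(tab$value, tab$key)
  p <- model_parameters() # template for structure
  p$adapted <- FALSE
  p$mrna_degradation_factor <- NA_real_
  for (key in names(kv)) {
    val <- kv[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (parts[1] == "transcription") {
      p$transcription[[parts[2]]][[parts[3]]] <- as.numeric(val)
    } else if (length(parts) == 2L) {
      p[[parts[1]]][[parts[2]]] <- as.numeric(val)
    } else if (key == "provenance") {
      p$provenance <- val
    } else if (key == "adapted") {
      p$adapted <- as.logical(val)
    } else if (key == "mrna_degradation_factor") {
      p$mrna_degradation_factor <- suppressWarnings(as.numeric(val))
    } else {
      p[[key]] <- as.numeric(val)
    }
  }
  validate_params(p)
}

#' Default adapted parameter set
#'
#' Convenience wrapper: the packaged reconstruction of the precursor-style
#' parameter file with the module adaptations applied.
#'
#' @return An adapted `nfkb_params`.
#' @export
default_parameters <- function() {
  adapt_parameters(model_parameters())
}
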