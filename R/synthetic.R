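# Seeded synthetic-data generators. Each generator sets its own RNG stream
# from the supplied seed (restoring the caller's RNG state on exit) so that
# identical (seed, arguments) give byte-identical output.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Generate noisy normalized time-course data from the model
#'
#' Simulates the feedback module at a known (true) scale, normalizes the
#' nuclear NF-kB curve with the activation convention and the total IkBa
#' curve with the depletion convention, samples both at the requested times
#' and adds independent Gaussian noise on the normalized scale. Emulates
#' densitometry-derived time courses for parameter-recovery studies.
#'
#' @param params Adapted `nfkb_params`.
#' @param curve An `ikk_curve`.
#' @param true_scale Scale at which the data are generated.
#' @param kind `"kmrna_scale"` or `"nfkb_scale"` (which parameter the truth
#'   applies to).
#' @param times Sampling times in minutes.
#' @param sigma Gaussian noise SD on the normalized scale (default 0.05).
#' @param seed Integer seed (NULL leaves the RNG state alone).
#' @param t_end,dt_out Simulation window (min).
#' @return A `timecourse_data` data frame with attribute `true_scale`.
#' @export
gen_timecourse <- function(params, curve, true_scale,
                           kind = c("kmrna_scale", "nfkb_scale"),
                           times = seq(10, 120, by = 10), sigma = 0.05,
                           seed = NULL, t_end = 240, dt_out = 1) {
  kind <- match.arg(kind)
  stopifnot(sigma >= 0, all(times >= 0), all(times <= t_end))
  p <- params
  p[[kind]] <- true_scale
  traj <- simulate_nfkb(p, curve, t_end = t_end, dt_out = dt_out)
  clean <- c(normalized_model_at(traj, "nuclear_nfkb", times),
             normalized_model_at(traj, "total_ikba", times))
  noisy <- with_seed(seed, clean + stats::rnorm(length(clean), 0, sigma))
  out <- timecourse_data(
    observable = rep(c("nuclear_nfkb", "total_ikba"), each = length(times)),
    time_min = rep(times, 2), value_normalized = noisy)
  attr(out, "true_scale") <- true_scale
  attr(out, "kind") <- kind
  out
}

#' Generate noisy one-site ITC injection heats
#'
#' Forward-simulates per-injection heats with [predict_heats()] and applies
#' multiplicative Gaussian noise (instrument-like relative error).
#'
#' @param params List with `n`, `kd_nM`, `dh_kcal`.
#' @param schedule An [itc_schedule()] (default [default_itc_schedule()]).
#' @param rel_sigma Relative noise SD (default 0.02).
#' @param seed Integer seed.
#' @return Numeric vector of heats (ucal) with attribute `true_params`.
#' @export
gen_itc <- function(params, schedule = default_itc_schedule(),
                    rel_sigma = 0.02, seed = NULL) {
  stopifnot(rel_sigma >= 0)
  clean <- predict_heats(params, schedule)
  noisy <- with_seed(seed,
                     clean * (1 + stats::rnorm(length(clean), 0, rel_sigma)))
  attr(noisy, "true_params") <- params
  noisy
}

#' Generate an expression table with planted group structure
#'
#' Builds a long-format fold-induction table for wild type, the two
#' interaction-defective mutants and an empty-vector control, with genes
#' planted in dependence groups A (defective in both mutants), B (defective
#' in the TAD-interaction mutant only), C (phospho-site mutant only) and D
#' (neither). Wild-type log2 fold inductions at the activation time are drawn
#' uniformly above the activation threshold; defective mutant genotypes are
#' attenuated by `effect` log2 units; replicate noise is log-normal (Gaussian
#' on the log2 scale).
#'
#' @param group_sizes Named integer vector, planted genes per group
#'   (default `c(A = 20, B = 25, C = 6, D = 48)`).
#' @param effect Log2 attenuation of a defective genotype (default 3).
#' @param replicates Replicates per gene x genotype x time (default 3).
#' @param sigma Replicate noise SD in log2 units (default 0.25).
#' @param seed Integer seed.
#' @param time Activation time point in minutes (default 60).
#' @param wt_log2_range Range of planted wild-type log2 fold inductions at
#'   the activation time (default `c(2, 5)`, i.e. 4- to 32-fold).
#' @return Expression table with attribute `truth` (data frame gene/group).
#' @export
gen_expression <- function(group_sizes = c(A = 20, B = 25, C = 6, D = 48),
                           effect = 3, replicates = 3, sigma = 0.25,
                           seed = NULL, time = 60,
                           wt_log2_range = c(2, 5)) {
  stopifnot(all(group_sizes >= 0), replicates >= 2, sigma >= 0, effect >= 0,
            all(c("A", "B", "C", "D") %in% names(group_sizes)))
  n <- sum(group_sizes)
  groups <- rep(names(group_sizes), group_sizes)
  genes <- sprintf("gene%03d", seq_len(n))
  with_seed(seed, {
    wt_log2 <- stats::runif(n, wt_log2_range[1], wt_log2_range[2])
    mean_log2 <- function(genotype) {
      defect <- switch(genotype,
                       wt = rep(0, n),
                       TA2 = ifelse(groups %in% c("A", "B"), effect, 0),
                       S276A = ifelse(groups %in% c("A", "C"), effect, 0),
                       empty = wt_log2) # empty vector: no induction
      wt_log2 - defect
    }
    rows <- list()
    for (gt in c("wt", "TA2", "S276A", "empty")) {
      mu <- mean_log2(gt)
      for (r in seq_len(replicates)) {
        noise <- stats::rnorm(n, 0, sigma)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = genes, genotype = gt, time_min = time, replicate = r,
          fold_induction = 2^(mu + noise), stringsAsFactors = FALSE)
        # calibrator rows: fold induction 1 at t = 0 by construction
        rows[[length(rows) + 1L]] <- data.frame(
          gene = genes, genotype = gt, time_min = 0, replicate = r,
          fold_induction = 2^stats::rnorm(n, 0, sigma),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- data.frame(gene = genes, group = groups,
                                     stringsAsFactors = FALSE)
    out
  })
}

#' Generate a secondary chemical-shift table with a planted helicity
#'
#' Per-residue C-alpha and carbonyl CSDs drawn around `helicity` times the
#' full-helix reference values with Gaussian noise, emulating a partially
#' formed helix in an otherwise disordered chain (residues outside `window`
#' get zero-mean CSDs).
#'
#' @param helicity Planted fractional helical population in [0, 1].
#' @param window Residue index range `c(first, last)` of the helical segment.
#' @param sigma_ppm Noise SD in ppm (default 0.05).
#' @param seed Integer seed.
#' @param refs A [reference_shifts()] list.
#' @param flank Number of non-helical residues added on each side
#'   (default 3).
#' @return Shift-table data frame with attribute `true_helicity`.
#' @export
gen_csd_table <- function(helicity, window, sigma_ppm = 0.05, seed = NULL,
                          refs = reference_shifts(), flank = 3) {
  stopifnot(helicity >= 0, helicity <= 1, sigma_ppm >= 0,
            length(window) == 2L, window[1] <= window[2])
  idx <- seq(window[1] - flank, window[2] + flank)
  helical <- idx >= window[1] & idx <= window[2]
  with_seed(seed, {
    ca <- ifelse(helical, helicity * refs$ca_ppm, 0) +
      stats::rnorm(length(idx), 0, sigma_ppm)
    co <- ifelse(helical, helicity * refs$co_ppm, 0) +
      stats::rnorm(length(idx), 0, sigma_ppm)
    out <- data.frame(residue_index = idx,
                      residue_name = rep("X", length(idx)),
                      csd_ca_ppm = ca, csd_co_ppm = co,
                      stringsAsFactors = FALSE)
    attr(out, "true_helicity") <- helicity
    out
  })
}
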