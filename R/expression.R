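#' Fold induction by the delta-delta-Ct method
#'
#' Relative qPCR quantification against a reference gene and a calibrator
#' time point: \eqn{2^{-\Delta\Delta Ct}} with
#' \eqn{\Delta\Delta Ct = (Ct_{gene,t} - Ct_{ref,t}) -
#' (Ct_{gene,0} - Ct_{ref,0})}.
#'
#' @param ct_gene_t,ct_ref_t Ct values of the target and reference gene at
#'   the measured time point.
#' @param ct_gene_0,ct_ref_0 Ct values at the calibrator (t = 0) point.
#' @return Fold induction over basal levels.
#' @examples
#' ddct_fold(24, 18, 27, 18)  # 2^3 = 8
#' @export
ddct_fold <- function(ct_gene_t, ct_ref_t, ct_gene_0, ct_ref_0) {
  vals <- c(ct_gene_t, ct_ref_t, ct_gene_0, ct_ref_0)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  2^(-((ct_gene_t - ct_ref_t) - (ct_gene_0 - ct_ref_0)))
}

#' Validate an expression table
#'
#' Long-format expression data: one row per gene x genotype x time x
#' replicate with the fold induction over that genotype's own t = 0
#' calibrator.
#'
#' @param table Data frame with columns `gene`, `genotype`, `time_min`,
#'   `replicate`, `fold_induction`.
#' @return The table, invisibly validated.
#' @export
as_expression_table <- function(table) {
  needed <- c("gene", "genotype", "time_min", "replicate", "fold_induction")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  stopifnot(all(table$fold_induction >= 0))
  table
}

#' Genes activated in the reference genotype
#'
#' A gene is called TNFa-activated when its mean wild-type fold induction at
#' the stated time reaches the threshold ("at least n-fold" is inclusive).
#' Genes without wild-type data at that time are excluded with a warning.
#'
#' @param table Expression table (see [as_expression_table()]).
#' @param threshold Fold-induction threshold (default 2).
#' @param time Time point in minutes (default 60).
#' @param genotype Reference genotype label (default `"wt"`).
#' @return Character vector of activated gene names.
#' @export
call_activated <- function(table, threshold = 2, time = 60,
                           genotype = "wt") {
  table <- as_expression_table(table)
  wt <- table[table$genotype == genotype & table$time_min == time, ]
  all_genes <- unique(table$gene)
  absent <- setdiff(all_genes, unique(wt$gene))
  if (length(absent))
    warning("no ", genotype, " data at ", time, " min for: ",
            paste(absent, collapse = ", "))
  means <- tapply(wt$fold_induction, wt$gene, mean)
  names(means)[means >= threshold]
}

#' Call an expression defect of a mutant genotype for one gene
#'
#' One-sided Welch comparison of log2 fold inductions (reference greater than
#' mutant) at the stated confidence level. The gene is called defective when
#' the one-sided lower confidence bound on the mean log2 difference excludes
#' zero and the observed mean defect reaches `min_effect` (log2 units); the
#' effect-size floor keeps marginal fluctuations in unaffected genes from
#' being called as defects (set it to 0 for the bare interval rule).
#'
#' @param table Expression table.
#' @param gene Gene name.
#' @param mutant Mutant genotype label (e.g. `"TA2"` or `"S276A"`).
#' @param confidence Confidence level (default 0.95).
#' @param time Time point in minutes (default 60).
#' @param reference Reference genotype (default `"wt"`).
#' @param min_effect Minimum mean log2 defect to call (default 0.5).
#' @return Logical `defective` with attributes `lower_bound` (one-sided
#'   confidence bound on the log2 difference), `estimate` (mean difference)
#'   and `p_value`.
#' @export
call_defect <- function(table, gene, mutant, confidence = 0.95, time = 60,
                        reference = "wt", min_effect = 0.5) {
  table <- as_expression_table(table)
  stopifnot(confidence > 0, confidence < 1, min_effect >= 0)
  sel <- function(gt) {
    v <- table$fold_induction[table$gene == gene & table$genotype == gt &
                                table$time_min == time]
    if (length(v) < 2L)
      stop(sprintf("need >= 2 replicates for %s/%s at %g min",
                   gene, gt, time))
    log2(pmax(v, .Machine$double.eps))
  }
  ref <- sel(reference)
  mut <- sel(mutant)
  est <- mean(ref) - mean(mut)
  if (stats::sd(ref) < 1e-12 && stats::sd(mut) < 1e-12) {
    # replicates without variance (noiseless synthetic data): the interval
    # collapses onto the point estimate
    lower <- est
    p_val <- if (est > 0) 0 else 1
    defective <- est > 0 && est >= min_effect
    return(structure(defective, lower_bound = lower, estimate = est,
                     p_value = p_val))
  }
  tt <- stats::t.test(ref, mut, alternative = "greater",
                      conf.level = confidence)
  lower <- tt$conf.int[1]
  defective <- is.finite(lower) && lower > 0 && est >= min_effect
  structure(defective, lower_bound = lower, estimate = est,
            p_value = tt$p.value)
}

#' Assign TNFa-activated genes to dependence groups A-D
#'
#' Classifies each activated gene by its expression defects in the two
#' interaction-defective mutants relative to wild type: group A is defective
#' in both mutants, B only in the TAD-interaction mutant, C only in the
#' phospho-site mutant, D in neither. Output is sorted by the wild-type minus
#' TA2-mutant mean log2 difference at the activation time point (largest
#' first). A second pass at a relaxed confidence level reports the group each
#' gene would switch to.
#'
#' @param table Expression table.
#' @param genes Genes to classify (default [call_activated()] on the table).
#' @param mutants Length-2 character: the TAD-interaction and phospho-site
#'   mutant genotype labels (default `c("TA2", "S276A")`).
#' @param confidence Primary confidence level (default 0.95).
#' @param relaxed Relaxed confidence level for the relabel pass
#'   (default 0.67; `NA` to skip).
#' @param time Time point in minutes (default 60).
#' @param min_effect Passed to [call_defect()].
#' @param p_adjust `"none"` (default, per-gene confidence) or a method for
#'   [stats::p.adjust()] (e.g. `"BH"`) applied to the defect p-values before
#'   calling.
#' @return Object of class `group_assignment`: data frame with columns
#'   `gene`, `group`, `defect_ta2`, `defect_s276a`, `sort_key`,
#'   `group_at_relaxed`, sorted by `sort_key` decreasing. Genes that could
#'   not be tested carry group NA (reported unclassified).
#' @export
assign_groups <- function(table, genes = NULL, mutants = c("TA2", "S276A"),
                          confidence = 0.95, relaxed = 0.67, time = 60,
                          min_effect = 0.5, p_adjust = "none") {
  table <- as_expression_table(table)
  stopifnot(length(mutants) == 2L)
  if (is.null(genes)) genes <- call_activated(table, time = time)
  calls <- function(conf) {
    lapply(mutants, function(m) {
      lapply(genes, function(g) {
        tryCatch(call_defect(table, g, m, confidence = conf, time = time,
                             min_effect = min_effect),
                 error = function(e) NA)
      })
    })
  }
  primary <- calls(confidence)
  if (p_adjust != "none") {
    for (j in 1:2) {
      p <- vapply(primary[[j]], function(x)
        if (is.logical(x) && !is.na(x)) attr(x, "p_value") else NA_real_,
        numeric(1))
      padj <- stats::p.adjust(p, method = p_adjust)
      for (k in seq_along(primary[[j]])) {
        x <- primary[[j]][[k]]
        if (is.logical(x) && !is.na(x)) {
          est <- attr(x, "estimate")
          primary[[j]][[k]] <- structure(
            padj[k] < (1 - confidence) && est >= min_effect,
            lower_bound = attr(x, "lower_bound"), estimate = est,
            p_value = padj[k])
        }
      }
    }
  }
  group_of <- function(d1, d2) {
    if (is.na(d1) || is.na(d2)) return(NA_character_)
    if (d1 && d2) "A" else if (d1) "B" else if (d2) "C" else "D"
  }
  d_ta2 <- vapply(primary[[1]], function(x) as.logical(x)[1], logical(1))
  d_s276a <- vapply(primary[[2]], function(x) as.logical(x)[1], logical(1))
  grp <- mapply(group_of, d_ta2, d_s276a)
  sort_key <- vapply(primary[[1]], function(x)
    if (is.logical(x) && !is.na(x)) attr(x, "estimate") else NA_real_,
    numeric(1))
  group_relaxed <- rep(NA_character_, length(genes))
  if (!is.na(relaxed)) {
    rel <- calls(relaxed)
    group_relaxed <- mapply(group_of,
                            vapply(rel[[1]], function(x) as.logical(x)[1],
                                   logical(1)),
                            vapply(rel[[2]], function(x) as.logical(x)[1],
                                   logical(1)))
  }
  out <- data.frame(gene = genes, group = grp, defect_ta2 = d_ta2,
                    defect_s276a = d_s276a, sort_key = sort_key,
                    group_at_relaxed = group_relaxed,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$sort_key), ]
  rownames(out) <- NULL
  structure(out, class = c("group_assignment", "data.frame"),
            confidence = confidence, relaxed = relaxed, time = time)
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("Gene grouping at %d min (confidence %.2f, relaxed %.2f)\n",
              attr(x, "time"), attr(x, "confidence"), attr(x, "relaxed")))
  counts <- table(factor(x$group, levels = c("A", "B", "C", "D")))
  cat(sprintf("  A (both defective): %d; B (TAD-interaction only): %d; C (phospho-site only): %d; D (neither): %d",
              counts["A"], counts["B"], counts["C"], counts["D"]))
  n_un <- sum(is.na(x$group))
  if (n_un) cat(sprintf("; unclassified: %d", n_un))
  cat("\n")
  switched <- !is.na(x$group) & !is.na(x$group_at_relaxed) &
    x$group != x$group_at_relaxed
  if (any(switched))
    cat(sprintf("  %d gene(s) switch group at the relaxed confidence\n",
                sum(switched)))
  NextMethod()
  invisible(x)
}

#' Read an expression table from delimited text
#'
#' Columns `gene`, `genotype`, `time_min`, `replicate`, `fold_induction`.
#'
#' @param path File path.
#' @return Validated expression table.
#' @export
read_expression_table <- function(path) {
  as_expression_table(utils::read.delim(path, comment.char = "#",
                                        stringsAsFactors = FALSE))
}
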