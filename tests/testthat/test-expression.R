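test_that("delta-delta-Ct fold induction follows the closed form", {
  expect_equal(ddct_fold(20, 18, 20, 18), 1)      # ddCt = 0
  expect_equal(ddct_fold(19, 18, 20, 18), 2)      # ddCt = -1
  expect_equal(ddct_fold(24, 18, 27, 18), 8)      # 2^3
  expect_error(ddct_fold(NA, 18, 27, 18), "finite")
})

test_that("activation calls are inclusive at the threshold and use wt means", {
  tab <- data.frame(
    gene = rep(c("g1", "g2", "g3"), each = 4),
    genotype = "wt", time_min = 60, replicate = rep(1:4, 3),
    fold_induction = c(2, 2, 2, 2,          # exactly 2-fold: included
                       1.9, 1.9, 1.9, 1.9,  # below: excluded
                       1.0, 1.0, 3.2, 3.2)) # mean 2.1: included
  act <- call_activated(tab)
  expect_setequal(act, c("g1", "g3"))
  # raising the threshold never adds genes
  for (th in c(2, 2.5, 3, 4)) {
    act_hi <- call_activated(tab, threshold = th)
    expect_true(all(act_hi %in% act))
    act <- act_hi
  }
})

test_that("defect calls agree with an independently computed Welch bound", {
  wt <- c(4.0, 4.1, 3.9)
  mut <- c(1.0, 1.1, 0.9)
  tab <- data.frame(
    gene = "g", genotype = rep(c("wt", "TA2"), each = 3),
    time_min = 60, replicate = rep(1:3, 2),
    fold_induction = 2^c(wt, mut))
  d <- call_defect(tab, "g", "TA2", confidence = 0.95)
  expect_true(as.logical(d))
  # oracle: one-sided Welch lower bound computed from first principles
  se <- sqrt(stats::var(wt) / 3 + stats::var(mut) / 3)
  df <- se^4 / ((stats::var(wt) / 3)^2 / 2 + (stats::var(mut) / 3)^2 / 2)
  lower <- (mean(wt) - mean(mut)) - stats::qt(0.95, df) * se
  expect_equal(attr(d, "lower_bound"), lower, tolerance = 1e-9)
  expect_equal(attr(d, "estimate"), 3)
})

test_that("identical replicates are never called defective", {
  tab <- data.frame(
    gene = "g", genotype = rep(c("wt", "TA2"), each = 3),
    time_min = 60, replicate = rep(1:3, 2),
    fold_induction = rep(c(4.1, 3.9, 4.0), 2))
  expect_false(as.logical(call_defect(tab, "g", "TA2")))
  one_rep <- tab[c(1, 4), ]
  expect_error(call_defect(one_rep, "g", "TA2"), "replicates")
})

test_that("defects at 95 percent confidence are nested within 67 percent", {
  tab <- gen_expression(seed = 31)
  genes <- call_activated(tab)
  for (m in c("TA2", "S276A")) {
    d95 <- vapply(genes, function(g)
      as.logical(call_defect(tab, g, m, confidence = 0.95)), logical(1))
    d67 <- vapply(genes, function(g)
      as.logical(call_defect(tab, g, m, confidence = 0.67)), logical(1))
    expect_true(all(d67[d95]))
  }
})

test_that("group assignment partitions activated genes into A-D", {
  tab <- gen_expression(seed = 17)
  ga <- assign_groups(tab)
  expect_s3_class(ga, "group_assignment")
  expect_identical(nrow(ga), 99L)
  expect_true(all(ga$group %in% c("A", "B", "C", "D")))
  # groups are consistent with the two defect calls
  expect_identical(ga$group == "A", ga$defect_ta2 & ga$defect_s276a)
  expect_identical(ga$group == "B", ga$defect_ta2 & !ga$defect_s276a)
  expect_identical(ga$group == "C", !ga$defect_ta2 & ga$defect_s276a)
  expect_identical(ga$group == "D", !ga$defect_ta2 & !ga$defect_s276a)
  # sorted by the wt - TA2 difference, largest first
  expect_true(all(diff(ga$sort_key) <= 0))
})

test_that("planted group structure is recovered accurately", {
  accs <- vapply(1:5, function(s) {
    tab <- gen_expression(seed = 100 + s)
    truth <- attr(tab, "truth")
    ga <- assign_groups(tab)
    m <- merge(ga, truth, by = "gene")
    mean(m$group.x == m$group.y)
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})

test_that("noiseless large-effect tables are classified exactly", {
  tab <- gen_expression(effect = 4, sigma = 0, seed = 1)
  truth <- attr(tab, "truth")
  ga <- assign_groups(tab)
  m <- merge(ga, truth, by = "gene")
  expect_true(all(m$group.x == m$group.y))
})

test_that("relabelling at relaxed confidence only moves genes toward defects", {
  tab <- gen_expression(seed = 55)
  ga <- assign_groups(tab, relaxed = 0.67)
  moved <- !is.na(ga$group_at_relaxed) & ga$group != ga$group_at_relaxed
  # a defect present at 95 percent cannot vanish at 67 percent
  rank_ok <- function(g95, g67, mutant_col) {
    defect95 <- g95 %in% mutant_col
    defect67 <- g67 %in% mutant_col
    !defect95 | defect67
  }
  expect_true(all(rank_ok(ga$group, ga$group_at_relaxed, c("A", "B")) |
                    !moved))
  expect_true(all(rank_ok(ga$group, ga$group_at_relaxed, c("A", "C")) |
                    !moved))
})

test_that("expression tables round-trip through delimited text", {
  tab <- gen_expression(seed = 2, group_sizes = c(A = 2, B = 2, C = 2, D = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_expression_table(path)
  expect_equal(back$fold_induction, tab$fold_induction, tolerance = 1e-9)
})
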