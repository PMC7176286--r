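# A 3-timepoint dataset crafted so SLRs are known exactly: T1 is flat 5,
# later timepoints add chosen deltas per subject/probe.
make_slr_fixture <- function(deltas1, deltas2 = NULL,
                             group = rep("A", ncol(deltas1))) {
  np <- nrow(deltas1); ns <- ncol(deltas1)
  tps <- if (is.null(deltas2)) c("T0", "T1") else c("T0", "T1", "T2")
  values <- array(5, dim = c(np, ns, length(tps)))
  values[, , 2] <- 5 + deltas1
  if (!is.null(deltas2)) values[, , 3] <- 5 + deltas1 + deltas2
  subjects <- sprintf("s%d", seq_len(ns))
  ds <- expression_dataset(
    values, probes = data.frame(probe_id = sprintf("pr%02d", seq_len(np)),
                                gene_symbol = sprintf("G%02d", seq_len(np))),
    subjects = subjects, groups = stats::setNames(group, subjects),
    timepoints = tps)
  compute_slr(ds, make_intervals(tps))
}

test_that("signal log ratios are end-minus-start log2 differences", {
  slr <- make_slr_fixture(deltas1 = matrix(c(1, 0, -1), 3, 2))
  expect_equal(unname(slr$slr[, 1, 1]), c(1, 0, -1))   # 2x up, none, 2x down
  expect_equal(unname(slr$group_mean[, 1, "A"]), c(1, 0, -1))
})

test_that("interval endpoints must exist in the dataset", {
  slr <- make_slr_fixture(matrix(0, 2, 2))
  ds_tps <- c("T0", "T1")
  bad <- make_intervals(c("T0", "TX"))
  values <- array(5, dim = c(2, 2, 2))
  ds <- expression_dataset(
    values, probes = data.frame(probe_id = c("a", "b"),
                                gene_symbol = c("a", "b")),
    subjects = c("s1", "s2"),
    groups = c(s1 = "A", s2 = "A"), timepoints = ds_tps)
  expect_error(compute_slr(ds, bad), "endpoint not in dataset")
})

test_that("paired t selection matches stats::t.test and the thresholds", {
  x <- c(1.1, 0.9, 1.05, 0.95)
  slr <- make_slr_fixture(deltas1 = matrix(x, 1, 4, byrow = TRUE))
  de <- select_de_probes(slr, "A", interval = "T0-T1", m = 1)
  ref <- stats::t.test(x)   # independent route
  expect_equal(de$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(de$t, 21.9, tolerance = 1e-2)
  expect_equal(de$p_raw, ref$p.value, tolerance = 1e-12)
  expect_true(de$selected)
  expect_identical(de$de_sign, 1)
  # below the fold-change threshold: never selected, whatever the p
  slr2 <- make_slr_fixture(matrix(0.5, 1, 4))
  de2 <- select_de_probes(slr2, "A", interval = "T0-T1", m = 1)
  expect_false(de2$selected)
  # mean zero by symmetry: t = 0
  slr3 <- make_slr_fixture(matrix(c(1, -1, 1, -1), 1, 4, byrow = TRUE))
  de3 <- select_de_probes(slr3, "A", interval = "T0-T1", m = 1)
  expect_equal(de3$t, 0)
  expect_false(de3$selected)
})

test_that("mean SLR of exactly 1 qualifies (inclusive threshold)", {
  slr <- make_slr_fixture(matrix(c(1.02, 0.98, 1.01, 0.99), 1, 4,
                                 byrow = TRUE))
  de <- select_de_probes(slr, "A", interval = "T0-T1", m = 1)
  expect_equal(de$mean_slr, 1.0)
  expect_true(de$selected)
})

test_that("Bonferroni uses the probe count per interval family", {
  deltas <- matrix(c(1.1, 0.9, 1.05, 0.95), 1, 4, byrow = TRUE)
  deltas <- rbind(deltas, matrix(0, 49, 4))
  slr <- make_slr_fixture(deltas)
  de <- select_de_probes(slr, "A", interval = "T0-T1")
  expect_equal(de$p_adj[1], min(1, de$p_raw[1] * 50))
})

test_that("zero-variance nonzero differences are flagged with t = Inf", {
  slr <- make_slr_fixture(matrix(1.5, 1, 3))
  de <- select_de_probes(slr, "A", interval = "T0-T1", m = 1)
  expect_true(de$zero_var)
  expect_identical(de$t, Inf)
  expect_identical(de$p_raw, 0)
  expect_true(de$selected)
})

test_that("moderated variant shrinks toward the family variance", {
  deltas <- rbind(c(1.5, 1.4, 1.6, 1.5), c(1.5, 0.1, 2.9, 1.5))
  slr <- make_slr_fixture(deltas)
  plain <- select_de_probes(slr, "A", interval = "T0-T1", m = 1)
  mod <- select_de_probes(slr, "A", interval = "T0-T1", m = 1,
                          method = "moderated", prior_df = 4)
  # low-variance probe is penalized, high-variance probe helped
  expect_lt(abs(mod$t[1]), abs(plain$t[1]))
  expect_gt(abs(mod$t[2]), abs(plain$t[2]))
  expect_equal(mod$df, c(7, 7))
})

test_that("discretization compares each subject to the group mean, strictly", {
  # probe 1 positive-DE with SLRs 1.5 / 1.2 / 1.15 / 0.95 (mean 1.2)
  # probe 2 negative-DE with SLRs -2.0 / -1.3 / -1.2 / -0.7 (mean -1.3)
  deltas <- rbind(c(1.5, 1.2, 1.15, 0.95), c(-2.0, -1.3, -1.2, -0.7))
  slr <- make_slr_fixture(deltas)
  de <- select_de_probes(slr, "A", interval = "T0-T1", m = 1)
  expect_identical(de$de_sign, c(1, -1))
  disc <- discretize(slr, de, "A")
  expect_identical(unname(disc[1, , "T0-T1"]),
                   c(2L, 0L, 0L, 0L))  # 1.2 == mean -> 0 (strict)
  expect_identical(unname(disc[2, , "T0-T1"]), c(1L, 0L, 0L, 0L))
  expect_true(all(disc %in% 0:2))
})

test_that("unselected probes stay no-change for every subject", {
  deltas <- rbind(c(0.6, 0.4, 0.5), c(1.5, 1.2, 0.9))
  slr <- make_slr_fixture(deltas)
  de <- select_de_probes(slr, "A", interval = "T0-T1", m = 1)
  disc <- discretize(slr, de, "A")
  expect_false(de$selected[1])
  expect_identical(unname(disc[1, , "T0-T1"]), c(0L, 0L, 0L))
})

test_that("identical SLRs across subjects give all no-change states", {
  slr <- make_slr_fixture(matrix(1.5, 1, 4))
  de <- select_de_probes(slr, "A", interval = "T0-T1", m = 1)
  disc <- discretize(slr, de, "A")
  expect_true(all(disc[1, , "T0-T1"] == 0L))
})

test_that("adding a subject-level constant leaves SLRs, t and states unchanged", {
  set.seed(11)
  for (rep in 1:5) {
    deltas <- matrix(stats::rnorm(5 * 4, 1, 0.5), 5, 4)
    values <- array(5, dim = c(5, 4, 2))
    values[, , 2] <- 5 + deltas
    shifted <- values
    shifted[, 2, ] <- shifted[, 2, ] + stats::rnorm(1, 0, 3)
    mk <- function(v) {
      subjects <- sprintf("s%d", 1:4)
      expression_dataset(
        v, probes = data.frame(probe_id = sprintf("p%d", 1:5),
                               gene_symbol = sprintf("G%d", 1:5)),
        subjects = subjects,
        groups = stats::setNames(rep("A", 4), subjects),
        timepoints = c("T0", "T1"))
    }
    iv <- make_intervals(c("T0", "T1"))
    s1 <- compute_slr(mk(values), iv); s2 <- compute_slr(mk(shifted), iv)
    expect_equal(s1$slr, s2$slr)
    d1 <- select_de_probes(s1, "A"); d2 <- select_de_probes(s2, "A")
    expect_equal(d1$t, d2$t)
    expect_identical(discretize(s1, d1, "A"), discretize(s2, d2, "A"))
  }
})

test_that("union feature selection pools intervals and groups", {
  deltas1 <- rbind(c(1.5, 1.4, 1.6, 1.5), matrix(0, 2, 4))
  deltas2 <- rbind(matrix(0, 1, 4), c(-1.5, -1.4, -1.6, -1.5),
                   matrix(0, 1, 4))
  slr <- make_slr_fixture(deltas1, deltas2)
  de <- select_de_probes(slr, "A", m = 1)
  expect_setequal(selected_probes(de), c("pr01", "pr02"))
})
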