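#' Define the time intervals of a study
#'
#' Consecutive timepoint pairs become the mining intervals (they are
#' non-overlapping and cover the sequence order used by the miner). With
#' `include_overall = TRUE` an additional first-to-last interval is added
#' with `selection_only = TRUE`: it participates in feature selection (the
#' union rule) but not in sequence building, because it overlaps the
#' consecutive intervals.
#'
#' @param timepoints ordered character vector of timepoint labels (>= 2).
#' @param labels optional labels for the mining intervals (default
#'   `"from-to"`).
#' @param include_overall add the overall selection-only interval.
#' @param overall_label label of the overall interval.
#' @return an `IntervalSet` data.frame with columns `from`, `to`, `label`,
#'   `selection_only`.
#' @export
make_intervals <- function(timepoints, labels = NULL,
                           include_overall = length(timepoints) > 2L,
                           overall_label = "overall") {
  stopifnot(length(timepoints) >= 2L)
  n <- length(timepoints) - 1L
  from <- timepoints[seq_len(n)]
  to <- timepoints[seq_len(n) + 1L]
  if (is.null(labels)) labels <- paste(from, to, sep = "-")
  stopifnot(length(labels) == n)
  df <- data.frame(from = from, to = to, label = labels,
                   selection_only = FALSE, stringsAsFactors = FALSE)
  if (include_overall)
    df <- rbind(df, data.frame(from = timepoints[1L],
                               to = timepoints[length(timepoints)],
                               label = overall_label, selection_only = TRUE,
                               stringsAsFactors = FALSE))
  class(df) <- c("IntervalSet", "data.frame")
  df
}

#' Intervals used for sequence building
#' @param intervals an `IntervalSet`.
#' @return the subset with `selection_only = FALSE`.
#' @export
mining_intervals <- function(intervals) {
  intervals[!intervals$selection_only, , drop = FALSE]
}

#' Compute signal log ratios per subject, probe and interval
#'
#' The signal log ratio (SLR) of a probe over an interval is the log2
#' expression at the interval end minus at the start, i.e. the log2 fold
#' change: an SLR of 1 is a two-fold increase, -1 a two-fold reduction.
#' Group means (the discretization thresholds) are the arithmetic means of
#' the subject SLRs within each group.
#'
#' @param dataset an `ExpressionDataset` (log2 scale).
#' @param intervals an `IntervalSet`; every endpoint must be a dataset
#'   timepoint.
#' @return an `SLRMatrix`: list with `slr` array
#'   `[probe, subject, interval]`, `group_mean` array
#'   `[probe, interval, group]`, plus `groups`, `intervals`, `probes`.
#' @export
compute_slr <- function(dataset, intervals) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  bad <- setdiff(unique(c(intervals$from, intervals$to)), dataset$timepoints)
  if (length(bad))
    stop("interval endpoint not in dataset: ", paste(bad, collapse = ", "))
  np <- nrow(dataset$probes); ns <- length(dataset$subjects)
  ni <- nrow(intervals)
  slr <- array(NA_real_, dim = c(np, ns, ni),
               dimnames = list(dataset$probes$probe_id, dataset$subjects,
                               intervals$label))
  for (k in seq_len(ni)) {
    slr[, , k] <- dataset$values[, , match(intervals$to[k], dataset$timepoints)] -
      dataset$values[, , match(intervals$from[k], dataset$timepoints)]
  }
  grps <- unique(dataset$groups)
  gm <- array(NA_real_, dim = c(np, ni, length(grps)),
              dimnames = list(dataset$probes$probe_id, intervals$label, grps))
  for (g in grps) {
    sel <- dataset$groups == g
    for (k in seq_len(ni))
      gm[, k, g] <- rowMeans(slr[, sel, k, drop = FALSE])
  }
  structure(list(slr = slr, group_mean = gm, groups = dataset$groups,
                 intervals = intervals, probes = dataset$probes),
            class = "SLRMatrix")
}

#' Select differentially expressed probes per interval and group
#'
#' One-sample paired t-test of the group subjects' SLRs against zero,
#' two-sided, per probe and interval. A probe is selected when the
#' Bonferroni-adjusted p-value is below `alpha` AND the absolute mean SLR
#' is at least `lfc` (inclusive: a mean SLR of exactly 1 qualifies). The
#' Bonferroni family size `m` defaults to the number of probes, applied
#' separately per interval and group.
#'
#' `method = "moderated"` replaces the per-probe variance with an
#' empirical-Bayes shrunk variance (prior variance = mean of per-probe
#' variances within the interval/group family, prior df `prior_df`),
#' adding `prior_df` degrees of freedom.
#'
#' Zero-variance differences with a nonzero mean give t = +/-Inf with
#' p_raw = 0 by convention and are flagged in `zero_var`.
#'
#' @param slr an `SLRMatrix` from [compute_slr()].
#' @param group group label to test.
#' @param interval interval label(s); default all intervals.
#' @param alpha significance level on the adjusted p-value.
#' @param lfc minimum absolute mean SLR (log2 fold-change units).
#' @param m Bonferroni family size; default the number of probes.
#' @param method `"plain"` paired t (default) or `"moderated"`.
#' @param prior_df prior degrees of freedom for the moderated variant.
#' @return a `DEResult` data.frame with one row per (probe, interval):
#'   `probe_id, interval, group, n, mean_slr, t, df, p_raw, p_adj,
#'   selected, de_sign, zero_var`.
#' @export
select_de_probes <- function(slr, group, interval = NULL, alpha = 0.05,
                             lfc = 1.0, m = NULL,
                             method = c("plain", "moderated"),
                             prior_df = 4) {
  stopifnot(inherits(slr, "SLRMatrix"))
  method <- match.arg(method)
  if (!group %in% slr$groups) stop("unknown group: ", group)
  subj <- which(slr$groups == group)
  if (length(subj) < 2L) stop("group ", group, " has < 2 subjects")
  if (is.null(interval)) interval <- slr$intervals$label
  if (!all(interval %in% slr$intervals$label))
    stop("unknown interval label(s)")
  np <- dim(slr$slr)[1L]
  if (is.null(m)) m <- np
  n <- length(subj)
  out <- vector("list", length(interval))
  for (j in seq_along(interval)) {
    k <- match(interval[j], slr$intervals$label)
    x <- slr$slr[, subj, k, drop = FALSE]
    dim(x) <- c(np, n)
    if (anyNA(x)) stop("NA SLR values in group ", group)
    mu <- rowMeans(x)
    s2 <- rowSums((x - mu)^2) / (n - 1L)
    df <- rep(n - 1, np)
    if (method == "moderated") {
      s2 <- (prior_df * mean(s2) + (n - 1L) * s2) / (prior_df + n - 1L)
      df <- df + prior_df
    }
    se <- sqrt(s2 / n)
    zero_var <- se == 0
    t <- ifelse(zero_var, ifelse(mu == 0, 0, sign(mu) * Inf), mu / se)
    p_raw <- ifelse(zero_var, ifelse(mu == 0, 1, 0),
                    2 * stats::pt(abs(t), df = df, lower.tail = FALSE))
    p_adj <- pmin(1, p_raw * m)
    selected <- p_adj < alpha & abs(mu) >= lfc
    out[[j]] <- data.frame(
      probe_id = slr$probes$probe_id, interval = interval[j], group = group,
      n = n, mean_slr = mu, t = t, df = df, p_raw = p_raw, p_adj = p_adj,
      selected = selected,
      de_sign = ifelse(selected, sign(mu), 0),
      zero_var = zero_var, stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Probes selected in any interval or group
#'
#' Union-of-intervals feature selection: a probe enters downstream
#' analysis if selected in ANY of the supplied DE results.
#'
#' @param ... one or more `DEResult` data.frames.
#' @return character vector of selected probe ids.
#' @export
selected_probes <- function(...) {
  des <- list(...)
  sort(unique(unlist(lapply(des, function(d) d$probe_id[d$selected]))))
}

#' Discretize SLRs into up / down / no-change states
#'
#' Three-state discretization per subject, probe and interval, relative to
#' the group-mean SLR. For probes selected with a positive mean SLR
#' (de_sign +1): state 2 (increase) iff the subject's SLR is strictly
#' greater than the group mean, else 0. For de_sign -1: state 1 (decrease)
#' iff strictly smaller than the group mean, else 0. Probes not selected
#' in an interval carry state 0 for every subject. Equality with the mean
#' is always no-change.
#'
#' @param slr an `SLRMatrix`.
#' @param de a `DEResult` for the same group.
#' @param group group label.
#' @return a `DiscreteMatrix`: integer array
#'   `[probe, subject-in-group, interval]` of states in \{0, 1, 2\}, with
#'   attributes `group`, `subjects`, `probes`.
#' @export
discretize <- function(slr, de, group) {
  stopifnot(inherits(slr, "SLRMatrix"), inherits(de, "DEResult"))
  if (!all(de$group == group))
    stop("DE result group does not match: ", unique(de$group)[1L])
  subj <- names(slr$groups)[slr$groups == group]
  ivs <- unique(de$interval)
  np <- dim(slr$slr)[1L]
  st <- array(0L, dim = c(np, length(subj), length(ivs)),
              dimnames = list(slr$probes$probe_id, subj, ivs))
  for (iv in ivs) {
    k <- match(iv, slr$intervals$label)
    d <- de[de$interval == iv, ]
    sgn <- d$de_sign[match(slr$probes$probe_id, d$probe_id)]
    gm <- slr$group_mean[, k, group]
    x <- slr$slr[, subj, k, drop = FALSE]
    dim(x) <- c(np, length(subj))
    up <- which(sgn == 1)
    dn <- which(sgn == -1)
    if (length(up))
      st[up, , iv] <- 2L * (x[up, , drop = FALSE] > gm[up])
    if (length(dn))
      st[dn, , iv] <- 1L * (x[dn, , drop = FALSE] < gm[dn])
  }
  structure(st, group = group, subjects = subj, probes = slr$probes,
            class = "DiscreteMatrix")
}
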