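# Synthetic longitudinal expression studies with planted, time-lagged
# regulation events. The generator emulates the discovery design of a
# two-arm dietary-intervention cohort: two groups of subjects, three
# timepoints (baseline, post-intervention, post-stabilization), one log2
# expression profile per subject and timepoint, and a set of planted
# LHS-then-RHS gene events carried by a known fraction of subjects.

#' Describe a planted sequential rule
#'
#' Carriers of the rule get the LHS effect added to the LHS gene's probe
#' from the second timepoint onward and the RHS effect from the third
#' timepoint onward, so each change is specific to one interval.
#'
#' @param lhs_gene,rhs_gene gene symbols (must exist in the simulated
#'   probe set).
#' @param lhs_dir,rhs_dir `"up"` or `"down"`.
#' @param penetrance fraction of the group's subjects carrying the rule,
#'   in `[0, 1]`.
#' @param effect absolute effect size in log2 units; to survive feature
#'   selection the group-mean SLR `penetrance * effect` must reach the
#'   selection threshold (default |SLR| >= 1).
#' @param group restrict the rule to one group label; `NULL` plants it in
#'   every group.
#' @return a `planted_rule` list.
#' @export
planted_rule <- function(lhs_gene, lhs_dir = c("up", "down"),
                         rhs_gene, rhs_dir = c("up", "down"),
                         penetrance = 0.6, effect = 2.0, group = NULL) {
  lhs_dir <- match.arg(lhs_dir); rhs_dir <- match.arg(rhs_dir)
  stopifnot(penetrance >= 0, penetrance <= 1, effect >= 0)
  structure(list(lhs_gene = normalize_gene_symbol(lhs_gene),
                 lhs_dir = lhs_dir,
                 rhs_gene = normalize_gene_symbol(rhs_gene),
                 rhs_dir = rhs_dir, penetrance = penetrance,
                 effect = effect, group = group),
            class = "planted_rule")
}

#' Simulation configuration
#'
#' Defaults mirror the discovery study design: 24 + 22 subjects in two
#' intervention arms, three timepoints, a desk-scale probe panel,
#' baseline log2 intensities around 7 with between-subject sd 1, and
#' i.i.d. technical noise with sd 0.2.
#'
#' @param groups named integer vector: subjects per group.
#' @param n_timepoints number of timepoints (>= 3 when rules are planted).
#' @param n_probes number of probes (one gene per probe, `G0001`...).
#' @param baseline_mean,baseline_sd log2 baseline distribution.
#' @param noise_sd sd of the i.i.d. log2 noise per measurement.
#' @param rules list of [planted_rule()]s.
#' @param seed integer RNG seed; the simulation is a pure function of the
#'   configuration including this seed.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(groups = c(VLCD = 24L, LCD = 22L),
                       n_timepoints = 3L, n_probes = 200L,
                       baseline_mean = 7, baseline_sd = 1,
                       noise_sd = 0.2, rules = list(), seed = 1L) {
  stopifnot(length(groups) >= 1L, !is.null(names(groups)),
            n_timepoints >= 2L, n_probes >= 1L, noise_sd >= 0)
  if (length(rules) && n_timepoints < 3L)
    stop("planted rules need >= 3 timepoints (two intervals)")
  structure(list(groups = groups, n_timepoints = as.integer(n_timepoints),
                 n_probes = as.integer(n_probes),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, rules = rules,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

sim_gene_names <- function(n_probes) {
  w <- max(4L, nchar(as.character(n_probes)))
  sprintf("G%0*d", w, seq_len(n_probes))
}

sim_probe_ids <- function(n_probes) {
  w <- max(4L, nchar(as.character(n_probes)))
  sprintf("p%0*d", w, seq_len(n_probes))
}

#' Simulate an expression dataset with planted rules
#'
#' Baseline values are Normal(`baseline_mean`, `baseline_sd`) per
#' subject-probe, constant over time, plus i.i.d. Normal(0, `noise_sd`)
#' noise per measurement. Carriers of each planted rule are a
#' deterministic shuffle of the group's subjects truncated to
#' `round(penetrance * n)`; they receive the LHS effect (signed by
#' direction) at timepoints >= 2 and the RHS effect at timepoints >= 3,
#' shifting all later timepoints so the change is interval-specific.
#' Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (an `ExpressionDataset`) and `truth` (a
#'   `SimTruth`: per rule the exact carrier subjects and expected
#'   sequential support; also carries the config).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  genes <- sim_gene_names(config$n_probes)
  probe_ids <- sim_probe_ids(config$n_probes)
  subjects <- unlist(lapply(names(config$groups), function(g)
    sprintf("%s_%02d", g, seq_len(config$groups[[g]]))))
  groups <- rep(names(config$groups), config$groups)
  names(groups) <- subjects
  timepoints <- paste0("T", seq_len(config$n_timepoints) - 1L)
  np <- config$n_probes; ns <- length(subjects); nt <- config$n_timepoints

  baseline <- matrix(stats::rnorm(np * ns, config$baseline_mean,
                                  config$baseline_sd), nrow = np)
  values <- array(stats::rnorm(np * ns * nt, 0, config$noise_sd),
                  dim = c(np, ns, nt))
  for (t in seq_len(nt)) values[, , t] <- values[, , t] + baseline

  truth_rules <- vector("list", length(config$rules))
  for (ri in seq_along(config$rules)) {
    r <- config$rules[[ri]]
    li <- match(r$lhs_gene, genes); rhi <- match(r$rhs_gene, genes)
    if (is.na(li) || is.na(rhi))
      stop("planted rule references a nonexistent probe/gene: ",
           r$lhs_gene, " -> ", r$rhs_gene)
    gsel <- if (is.null(r$group)) names(config$groups) else r$group
    if (!all(gsel %in% names(config$groups)))
      stop("planted rule restricted to unknown group: ", r$group)
    carriers <- character(0)
    for (g in gsel) {
      gs <- subjects[groups == g]
      k <- round(r$penetrance * length(gs))
      picked <- sample(gs)[seq_len(k)]
      carriers <- c(carriers, picked)
    }
    ci <- match(carriers, subjects)
    lsign <- if (r$lhs_dir == "up") 1 else -1
    rsign <- if (r$rhs_dir == "up") 1 else -1
    if (length(ci)) {
      values[li, ci, 2:nt] <- values[li, ci, 2:nt] + lsign * r$effect
      if (nt >= 3L)
        values[rhi, ci, 3:nt] <- values[rhi, ci, 3:nt] + rsign * r$effect
    }
    truth_rules[[ri]] <- list(
      rule = r, carriers = carriers,
      expected_seq_sup = vapply(gsel, function(g)
        sum(groups[carriers] == g) / sum(groups == g), numeric(1)))
  }

  dataset <- expression_dataset(
    values,
    probes = data.frame(probe_id = probe_ids, gene_symbol = genes,
                        stringsAsFactors = FALSE),
    subjects = subjects, groups = groups, timepoints = timepoints)
  truth <- structure(list(rules = truth_rules, config = config),
                     class = "SimTruth")
  list(dataset = dataset, truth = truth)
}

#' Simulate annotations and a TF table consistent with the planted truth
#'
#' Each planted gene pair shares a dedicated term in the chosen namespace
#' and gets a TF-table row whose mode is consistent with the planted
#' directions (same direction: Activation; opposite: Repression). Decoy
#' terms and decoy TF rows are drawn among non-planted genes only, so
#' decoys never share terms with planted pairs.
#'
#' @param truth a `SimTruth` from [simulate_dataset()].
#' @param n_terms decoy terms per namespace.
#' @param namespace namespace carrying the planted shared terms.
#' @param seed RNG seed for the decoy draws.
#' @return list with `annotations` (list of four `AnnotationTable`s) and
#'   `tf_table` (a `TFTable`).
#' @export
simulate_annotations <- function(truth, n_terms = 20L, namespace = "BP",
                                 seed = 1L) {
  stopifnot(inherits(truth, "SimTruth"))
  set.seed(seed)
  genes <- sim_gene_names(truth$config$n_probes)
  planted <- unique(unlist(lapply(truth$rules, function(tr)
    c(tr$rule$lhs_gene, tr$rule$rhs_gene))))
  decoys <- setdiff(genes, planted)
  namespaces <- c("BP", "MF", "CC", "SP")
  anns <- lapply(namespaces, function(ns) {
    pairs_gene <- character(0); pairs_term <- character(0)
    if (ns == namespace) {
      for (ri in seq_along(truth$rules)) {
        tr <- truth$rules[[ri]]$rule
        term <- sprintf("%s:PLANT%03d", ns, ri)
        pairs_gene <- c(pairs_gene, tr$lhs_gene, tr$rhs_gene)
        pairs_term <- c(pairs_term, term, term)
      }
    }
    for (ti in seq_len(n_terms)) {
      k <- sample(2:4, 1L)
      gs <- sample(decoys, min(k, length(decoys)))
      pairs_gene <- c(pairs_gene, gs)
      pairs_term <- c(pairs_term, rep(sprintf("%s:DECOY%03d", ns, ti),
                                      length(gs)))
    }
    annotation_table(ns, split(pairs_term, pairs_gene))
  })
  names(anns) <- namespaces

  tf <- character(0); tg <- character(0); md <- character(0)
  for (tr in truth$rules) {
    r <- tr$rule
    tf <- c(tf, r$lhs_gene); tg <- c(tg, r$rhs_gene)
    md <- c(md, if (r$lhs_dir == r$rhs_dir) "Activation" else "Repression")
  }
  n_decoy_tf <- min(length(decoys) %/% 2L, max(3L, n_terms %/% 2L))
  if (n_decoy_tf > 0) {
    pool <- sample(decoys, 2L * n_decoy_tf)
    tf <- c(tf, pool[seq_len(n_decoy_tf)])
    tg <- c(tg, pool[n_decoy_tf + seq_len(n_decoy_tf)])
    md <- c(md, sample(c("Activation", "Repression", "Unknown"),
                       n_decoy_tf, replace = TRUE))
  }
  list(annotations = anns, tf_table = tf_table(tf, tg, md))
}

#' Write a simulated study to disk as pipeline inputs
#'
#' Emits the expression matrix TSV, sample sheet, probe map, one GMT per
#' namespace, the TF table TSV and the planted truth as JSON.
#'
#' @param sim output of [simulate_dataset()].
#' @param ann output of [simulate_annotations()] (optional).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, ann = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  sample_ids <- as.vector(outer(ds$subjects, ds$timepoints, paste, sep = "."))
  mat <- do.call(cbind, lapply(ds$timepoints, function(t)
    ds$values[, , match(t, ds$timepoints)]))
  # columns are subject-major within each timepoint; reorder to sample_ids
  colnames(mat) <- as.vector(outer(ds$subjects, ds$timepoints, paste,
                                   sep = "."))
  out <- data.frame(probe_id = ds$probes$probe_id, mat[, sample_ids],
                    check.names = FALSE)
  utils::write.table(out, file.path(dir, "matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sheet <- data.frame(
    sample_id = sample_ids,
    subject = rep(ds$subjects, times = length(ds$timepoints)),
    timepoint = rep(ds$timepoints, each = length(ds$subjects)),
    group = rep(unname(ds$groups), times = length(ds$timepoints)))
  utils::write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$probes, file.path(dir, "probe_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(ann)) {
    for (ns in names(ann$annotations)) {
      tab <- ann$annotations[[ns]]
      terms <- sort(unique(unlist(tab$terms)))
      lines <- vapply(terms, function(tm) {
        gs <- names(tab$terms)[vapply(tab$terms, function(x) tm %in% x,
                                      logical(1))]
        paste(c(tm, "simulated", sort(gs)), collapse = "\t")
      }, character(1))
      writeLines(lines, file.path(dir, paste0(tolower(ns), ".gmt")))
    }
    utils::write.table(ann$tf_table, file.path(dir, "tf_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  truth <- lapply(sim$truth$rules, function(tr)
    list(lhs_gene = tr$rule$lhs_gene, lhs_dir = tr$rule$lhs_dir,
         rhs_gene = tr$rule$rhs_gene, rhs_dir = tr$rule$rhs_dir,
         penetrance = tr$rule$penetrance, effect = tr$rule$effect,
         group = tr$rule$group, carriers = tr$carriers,
         expected_seq_sup = as.list(tr$expected_seq_sup)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
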