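# End-to-end pipeline driver: preprocessing (feature selection +
# discretization), per-group sequence databases, sequential rule mining,
# very-strong filtering, optional contrast mining, biological scoring,
# XML match report and circular plots. Outputs are a pure function of
# (inputs, config, seed); rerunning a config reproduces the rule tables
# byte for byte.

config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("seqruleged_config_error",
                                             "error", "condition")))
}

#' Build and validate a pipeline configuration
#'
#' Accepts a YAML file path or a list. Recognized fields: `matrix`,
#' `samples`, `probe_map`, `annotations` (named list namespace -> path),
#' `tf_table`, `groups` (default: all groups in the sample sheet),
#' `alpha`, `lfc`, `min_seq_sup` / `min_seq_conf` (scalar or named per
#' group), `very_strong` (variant or `"none"`), `not_sup_threshold`,
#' `max_itemset`, `de_method`, `prior_df`, `drop_incomplete`,
#' `input_scale`, `plot_color_by`, `plots`, `seed`.
#'
#' @param x YAML path or list.
#' @return a validated `PipelineConfig` list.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1L) yaml::read_yaml(x) else x
  if (!is.list(cfg)) config_error("config must be a list or a YAML file")
  defaults <- list(probe_map = NULL, annotations = list(), tf_table = NULL,
                   groups = NULL, alpha = 0.05, lfc = 1.0,
                   min_seq_sup = 0.45, min_seq_conf = 0.4,
                   very_strong = "cf_only", not_sup_threshold = NULL,
                   max_itemset = 4L, de_method = "plain", prior_df = 4,
                   drop_incomplete = FALSE, input_scale = "log2",
                   plot_color_by = "cf", plots = TRUE, seed = 1L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  unknown <- setdiff(names(cfg), c(names(defaults), "matrix", "samples"))
  if (length(unknown))
    config_error("unknown config field(s): ", paste(unknown, collapse = ", "))
  for (nm in c("matrix", "samples"))
    if (is.null(cfg[[nm]])) config_error("config field required: ", nm)
  if (!cfg$very_strong %in% c("cf_only", "literal", "counter_reciprocal",
                              "none"))
    config_error("unknown very_strong variant: ", cfg$very_strong)
  if (!cfg$de_method %in% c("plain", "moderated"))
    config_error("unknown de_method: ", cfg$de_method)
  if (!cfg$input_scale %in% c("log2", "linear"))
    config_error("unknown input_scale: ", cfg$input_scale)
  bad_ns <- setdiff(names(cfg$annotations), c("BP", "MF", "CC", "SP"))
  if (length(bad_ns))
    config_error("unknown annotation namespace(s): ",
                 paste(bad_ns, collapse = ", "))
  class(cfg) <- "PipelineConfig"
  cfg
}

group_threshold <- function(value, group) {
  if (length(value) == 1L && is.null(names(value))) return(as.numeric(value))
  if (!group %in% names(value))
    config_error("no threshold configured for group ", group)
  as.numeric(value[[group]])
}

subset_discrete <- function(discrete, probe_ids) {
  keep <- dimnames(discrete)[[1L]] %in% probe_ids
  out <- discrete[keep, , , drop = FALSE]
  pr <- attr(discrete, "probes")
  structure(out, group = attr(discrete, "group"),
            subjects = attr(discrete, "subjects"),
            probes = pr[pr$probe_id %in% probe_ids, , drop = FALSE],
            class = "DiscreteMatrix")
}

#' Run the full pipeline
#'
#' Executes preprocessing, mining, optional contrast mining, biological
#' scoring and plotting, writing every intermediate to `out_dir`:
#' `de_<group>.tsv`, `seqdb_<group>.spmf`, `codebook.tsv`,
#' `rules_<group>.tsv`, `contrast_only_<group>.tsv`, `report_<group>.xml`,
#' `network_<group>.svg`, a copy of the config and `run.log`. Any stage
#' failure aborts with the stage name and cause.
#'
#' @param config a [pipeline_config()] (or something coercible).
#' @param out_dir output directory.
#' @return named list of the per-group `RuleSet`s, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("seqruleged %s",
                         as.character(utils::packageVersion("seqruleged"))),
                 sprintf("R %s", as.character(getRversion())),
                 sprintf("seed: %d", config$seed),
                 sprintf("thresholds: min_seq_sup=%s min_seq_conf=%s",
                         paste(format(config$min_seq_sup), collapse = ","),
                         paste(format(config$min_seq_conf), collapse = ",")),
                 sprintf("alpha=%g lfc=%g very_strong=%s", config$alpha,
                         config$lfc, config$very_strong))
  stage <- function(name, expr) {
    tryCatch(expr, seqruleged_config_error = function(e) stop(e),
             error = function(e)
               stop("pipeline stage '", name, "' failed: ",
                    conditionMessage(e), call. = FALSE))
  }

  dataset <- stage("read", read_expression_matrix(
    config$matrix, config$samples, probe_map = config$probe_map,
    drop_incomplete = config$drop_incomplete,
    input_scale = config$input_scale))
  groups <- config$groups %||% unique(unname(dataset$groups))
  missing <- setdiff(groups, dataset$groups)
  if (length(missing))
    config_error("group(s) not in sample sheet: ",
                 paste(missing, collapse = ", "))

  intervals <- make_intervals(dataset$timepoints)
  slr <- stage("slr", compute_slr(dataset, intervals))

  de_by_group <- list()
  for (g in groups) {
    de <- stage("feature-selection",
                select_de_probes(slr, g, alpha = config$alpha,
                                 lfc = config$lfc,
                                 method = config$de_method,
                                 prior_df = config$prior_df))
    de_by_group[[g]] <- de
    utils::write.table(de, file.path(out_dir, paste0("de_", g, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sel <- do.call(selected_probes, unname(de_by_group))
  log_lines <- c(log_lines, sprintf("selected probes (union): %d",
                                    length(sel)))
  if (!length(sel))
    stop("pipeline stage 'feature-selection' failed: no probe passed ",
         "selection in any interval or group", call. = FALSE)
  codebook <- make_codebook(
    dataset$probes[dataset$probes$probe_id %in% sel, , drop = FALSE])
  write_codebook(codebook, file.path(out_dir, "codebook.tsv"))

  seqdbs <- list(); rules <- list()
  for (g in groups) {
    disc <- stage("discretize",
                  subset_discrete(discretize(slr, de_by_group[[g]], g), sel))
    db <- stage("sequence-db", build_sequence_db(disc, intervals, g,
                                                 codebook))
    seqdbs[[g]] <- db
    write_spmf(db, file.path(out_dir, paste0("seqdb_", g, ".spmf")))
    ms <- group_threshold(config$min_seq_sup, g)
    mc <- group_threshold(config$min_seq_conf, g)
    rs <- stage("mine", mine_sequential_rules(db, ms, mc,
                                              max_itemset = config$max_itemset))
    if (config$very_strong != "none")
      rs <- stage("very-strong",
                  filter_very_strong(rs, ms, variant = config$very_strong,
                                     not_sup_threshold =
                                       config$not_sup_threshold))
    log_lines <- c(log_lines, sprintf(
      "group %s: |SD|=%d, %d rules (thresholds %.3g/%.3g)",
      g, n_sequences(db), nrow(rs), ms, mc))
    rules[[g]] <- rs
  }

  anns <- list()
  if (length(config$annotations))
    anns <- stage("annotations", lapply(names(config$annotations),
      function(ns) read_annotation(config$annotations[[ns]], ns)))
  tft <- if (!is.null(config$tf_table))
    stage("tf-table", read_tf_table(config$tf_table)) else NULL

  for (g in groups) {
    if (nrow(rules[[g]]) && (length(anns) || !is.null(tft)))
      rules[[g]] <- stage("biomeasures",
                          annotate_rules(rules[[g]], anns, tft))
    write_rules(rules[[g]], file.path(out_dir, paste0("rules_", g, ".tsv")))
    if (nrow(rules[[g]]) && length(anns))
      write_match_report(rules[[g]], anns,
                         file.path(out_dir, paste0("report_", g, ".xml")))
    if (isTRUE(config$plots) && nrow(rules[[g]]))
      stage("plot", plot_rule_network(
        rules[[g]], file.path(out_dir, paste0("network_", g, ".svg")),
        color_by = config$plot_color_by, seed = config$seed))
  }

  if (length(groups) == 2L) {
    ct <- stage("contrast", mine_contrast(
      seqdbs[[groups[1L]]], seqdbs[[groups[2L]]],
      group_threshold(config$min_seq_sup, groups[1L]),
      group_threshold(config$min_seq_conf, groups[1L]),
      max_itemset = config$max_itemset))
    write_rules(ct$only_a, file.path(out_dir,
                                     paste0("contrast_only_", groups[1L],
                                            ".tsv")))
    write_rules(ct$only_b, file.path(out_dir,
                                     paste0("contrast_only_", groups[2L],
                                            ".tsv")))
    log_lines <- c(log_lines, sprintf("contrast: %d only-%s, %d only-%s",
                                      nrow(ct$only_a), groups[1L],
                                      nrow(ct$only_b), groups[2L]))
  }

  cfg_out <- config
  class(cfg_out) <- NULL
  cfg_out <- cfg_out[!vapply(cfg_out, is.null, logical(1))]
  yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(rules)
}
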