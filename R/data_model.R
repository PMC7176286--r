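#' Normalize gene symbols
#'
#' Single shared normalization used by every module: uppercase and strip
#' surrounding whitespace. Applied to gene symbols on every read so that
#' annotation lookups, TF-table joins and cross-cohort rule matching all
#' agree on the same key.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalize_gene_symbol <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Construct an expression dataset
#'
#' Container for a normalized log2 expression study indexed by
#' (probe, subject, timepoint), with a group label per subject. Timepoints
#' are strictly ordered; at least two are required so that intervals exist.
#'
#' @param values numeric array `[probe, subject, timepoint]` with dimnames.
#' @param probes data.frame with columns `probe_id`, `gene_symbol`.
#' @param subjects character vector of subject ids.
#' @param groups named character vector mapping subject -> group label.
#' @param timepoints ordered character vector of timepoint labels.
#' @return an object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(values, probes, subjects, groups, timepoints) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (length(timepoints) < 2L)
    stop("an expression dataset needs at least 2 ordered timepoints")
  if (anyDuplicated(timepoints)) stop("duplicated timepoint labels")
  if (!all(subjects %in% names(groups)))
    stop("every subject needs a group label")
  if (!all(is.finite(values)))
    stop("non-finite expression values in dataset")
  probes$gene_symbol <- normalize_gene_symbol(probes$gene_symbol)
  dimnames(values) <- list(probes$probe_id, subjects, timepoints)
  structure(
    list(values = values, probes = probes, subjects = subjects,
         groups = groups[subjects], timepoints = timepoints),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf(
    "ExpressionDataset: %d probes x %d subjects x %d timepoints (%s)\n",
    nrow(x$probes), length(x$subjects), length(x$timepoints),
    paste(x$timepoints, collapse = " -> ")))
  for (g in unique(x$groups))
    cat(sprintf("  group %-8s %d subjects\n", g, sum(x$groups == g)))
  invisible(x)
}

#' Read an expression matrix and sample sheet
#'
#' The matrix is a TSV of probes (rows) by samples (columns); the first
#' column holds probe ids. The sample sheet maps each sample column to a
#' (subject, timepoint, group) triple with columns
#' `sample_id, subject, timepoint, group`. Column order in the matrix is
#' irrelevant. Timepoints are ordered by first appearance in the sample
#' sheet. Input is assumed to be on the log2 scale; pass
#' `input_scale = "linear"` to log2-transform on load.
#'
#' Subjects missing one or more timepoints are an error by default; with
#' `drop_incomplete = TRUE` they are excluded with a warning (complete-case
#' analysis).
#'
#' @param matrix_path path to the expression TSV.
#' @param samplesheet_path path to the sample sheet TSV.
#' @param probe_map optional path to a 2-column TSV `probe_id, gene_symbol`;
#'   without it the gene symbol defaults to the probe id.
#' @param drop_incomplete drop subjects with incomplete timepoint series
#'   instead of erroring.
#' @param input_scale `"log2"` (default) or `"linear"`.
#' @return an [expression_dataset()].
#' @export
read_expression_matrix <- function(matrix_path, samplesheet_path,
                                   probe_map = NULL,
                                   drop_incomplete = FALSE,
                                   input_scale = c("log2", "linear")) {
  input_scale <- match.arg(input_scale)
  mat <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(mat) < 2L) stop("expression matrix needs probe ids plus >= 1 sample")
  probe_ids <- as.character(mat[[1L]])
  if (anyDuplicated(probe_ids)) stop("duplicated probe ids in matrix")
  sheet <- utils::read.delim(samplesheet_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject", "timepoint", "group")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  sheet$sample_id <- as.character(sheet$sample_id)
  missing_cols <- setdiff(sheet$sample_id, names(mat)[-1L])
  if (length(missing_cols))
    stop("missing sample column in matrix: ",
         paste(missing_cols, collapse = ", "))

  expr <- as.matrix(mat[, sheet$sample_id, drop = FALSE])
  if (!is.numeric(expr)) stop("non-numeric cell in expression matrix")
  if (input_scale == "linear") {
    if (any(expr <= 0)) stop("linear input must be strictly positive for log2")
    expr <- log2(expr)
  }

  timepoints <- unique(sheet$timepoint)
  subjects <- unique(sheet$subject)
  counts <- table(factor(sheet$subject, levels = subjects))
  complete <- names(counts)[counts == length(timepoints)]
  incomplete <- setdiff(subjects, complete)
  if (length(incomplete)) {
    if (!drop_incomplete)
      stop("subjects with incomplete timepoint series: ",
           paste(incomplete, collapse = ", "),
           " (use drop_incomplete = TRUE to exclude them)")
    warning("dropping subjects with incomplete timepoint series: ",
            paste(incomplete, collapse = ", "))
    subjects <- complete
  }
  if (!length(subjects)) stop("no subjects with complete timepoint series")

  groups <- vapply(subjects, function(s) {
    g <- unique(sheet$group[sheet$subject == s])
    if (length(g) != 1L) stop("subject ", s, " has inconsistent group labels")
    g
  }, character(1))

  values <- array(NA_real_,
                  dim = c(length(probe_ids), length(subjects),
                          length(timepoints)))
  for (i in seq_len(nrow(sheet))) {
    s <- sheet$subject[i]
    if (!s %in% subjects) next
    values[, match(s, subjects), match(sheet$timepoint[i], timepoints)] <-
      expr[, sheet$sample_id[i]]
  }

  genes <- probe_ids
  if (!is.null(probe_map)) {
    pm <- utils::read.delim(probe_map, stringsAsFactors = FALSE)
    if (ncol(pm) < 2L) stop("probe map needs 2 columns: probe_id, gene_symbol")
    idx <- match(probe_ids, as.character(pm[[1L]]))
    genes <- ifelse(is.na(idx), probe_ids, as.character(pm[[2L]])[idx])
  }
  expression_dataset(
    values,
    probes = data.frame(probe_id = probe_ids,
                        gene_symbol = normalize_gene_symbol(genes),
                        stringsAsFactors = FALSE),
    subjects = subjects, groups = groups, timepoints = timepoints)
}

#' Read a gene-set annotation table
#'
#' Accepts GMT (term, description, genes...) or a 2-column TSV
#' (gene, term). Builds a gene -> term-set map for one namespace;
#' genes absent from the file get an empty term set on lookup
#' (see [annotation_terms()]).
#'
#' @param path annotation file.
#' @param namespace one of `"BP"`, `"MF"`, `"CC"`, `"SP"`.
#' @param format `"auto"` (by extension), `"gmt"` or `"tsv"`.
#' @return an object of class `AnnotationTable`.
#' @export
read_annotation <- function(path, namespace = c("BP", "MF", "CC", "SP"),
                            format = c("auto", "gmt", "tsv")) {
  namespace <- match.arg(namespace)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  pairs_gene <- character(0)
  pairs_term <- character(0)
  if (format == "gmt") {
    for (ln in lines) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(f) < 3L)
        stop("malformed GMT line (need term, description, >=1 gene): ", ln)
      pairs_gene <- c(pairs_gene, f[-(1:2)])
      pairs_term <- c(pairs_term, rep(f[1L], length(f) - 2L))
    }
  } else {
    start <- 1L
    f1 <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(f1) >= 2L &&
        tolower(f1[1L]) %in% c("gene", "gene_symbol", "symbol")) start <- 2L
    for (ln in lines[seq.int(start, length(lines))]) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(f) < 2L) stop("malformed annotation line (need gene, term): ", ln)
      pairs_gene <- c(pairs_gene, f[1L])
      pairs_term <- c(pairs_term, f[2L])
    }
  }
  annotation_table(namespace,
                   split(pairs_term, normalize_gene_symbol(pairs_gene)))
}

#' Construct an annotation table from a gene -> terms list
#'
#' @param namespace one of `"BP"`, `"MF"`, `"CC"`, `"SP"`.
#' @param terms named list mapping gene symbol to a character vector of
#'   term identifiers.
#' @return an object of class `AnnotationTable`.
#' @export
annotation_table <- function(namespace, terms) {
  stopifnot(namespace %in% c("BP", "MF", "CC", "SP"))
  names(terms) <- normalize_gene_symbol(names(terms))
  terms <- lapply(terms, function(x) sort(unique(as.character(x))))
  structure(list(namespace = namespace, terms = terms),
            class = "AnnotationTable")
}

#' Look up the terms annotated to a gene
#'
#' Unannotated genes yield an empty character vector, never an error.
#'
#' @param annotation an `AnnotationTable`.
#' @param gene a gene symbol (normalized internally).
#' @return character vector of term ids.
#' @export
annotation_terms <- function(annotation, gene) {
  t <- annotation$terms[[normalize_gene_symbol(gene)]]
  if (is.null(t)) character(0) else t
}

#' @export
print.AnnotationTable <- function(x, ...) {
  cat(sprintf("AnnotationTable [%s]: %d genes, %d terms\n", x$namespace,
              length(x$terms), length(unique(unlist(x$terms)))))
  invisible(x)
}

#' Construct a TF-target table
#'
#' Rows are (tf, target, mode) with mode in Activation / Repression /
#' Unknown. Duplicate (tf, target) pairs are merged: an informative mode
#' (Activation or Repression) beats Unknown; conflicting Activation vs
#' Repression rows are both kept, so a direction match later succeeds if
#' either mode matches.
#'
#' @param tf,target,mode character vectors of equal length.
#' @return an object of class `TFTable` (a data.frame).
#' @export
tf_table <- function(tf, target, mode) {
  mode <- normalize_tf_mode(mode)
  df <- unique(data.frame(tf = normalize_gene_symbol(tf),
                          target = normalize_gene_symbol(target),
                          mode = mode, stringsAsFactors = FALSE))
  key <- paste(df$tf, df$target)
  drop <- df$mode == "Unknown" &
    key %in% key[df$mode != "Unknown"]
  df <- df[!drop, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("TFTable", "data.frame")
  df
}

normalize_tf_mode <- function(mode) {
  m <- tolower(trimws(as.character(mode)))
  out <- rep("Unknown", length(m))
  out[m %in% c("activation", "activate", "up", "upregulation")] <- "Activation"
  out[m %in% c("repression", "repress", "down", "downregulation")] <- "Repression"
  unknown_in <- !(m %in% c("activation", "activate", "up", "upregulation",
                           "repression", "repress", "down", "downregulation",
                           "unknown", ""))
  if (any(unknown_in))
    warning("unrecognized TF regulation mode(s) set to Unknown: ",
            paste(unique(mode[unknown_in]), collapse = ", "))
  out
}

#' Read a TF-target regulation table
#'
#' TSV with at least three columns: TF, target gene, regulation mode
#' (TRRUST-style). Mode strings are matched case-insensitively;
#' unrecognized modes become Unknown with a warning. Duplicates are merged
#' as described in [tf_table()].
#'
#' @param path TSV path.
#' @return a `TFTable`.
#' @export
read_tf_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, header = FALSE)
  # tolerate a header row
  if (nrow(df) && tolower(trimws(df[1, 1])) %in% c("tf", "#tf"))
    df <- df[-1L, , drop = FALSE]
  if (ncol(df) < 3L)
    stop("TF table needs >= 3 columns: tf, target, mode")
  tf_table(df[[1L]], df[[2L]], df[[3L]])
}

# ---- rule table persistence -------------------------------------------------

RULE_TABLE_COLS <- c("group", "lhs", "rhs", "sup_count", "seq_sup", "seq_conf",
                     "lift", "cf", "conviction", "bp", "mf", "cc", "sp", "tf")

#' Serialize a rule set to a plain rule table
#'
#' Items are rendered as `probe/GENE=state` joined by `&`, mirroring the
#' tabular rule notation used throughout the package.
#'
#' @param ruleset a `RuleSet` (see [mine_sequential_rules()]) or an already
#'   plain `RuleTable`.
#' @return a `RuleTable` data.frame with the canonical columns.
#' @export
rules_to_table <- function(ruleset) {
  if (inherits(ruleset, "RuleTable")) return(ruleset)
  stopifnot(inherits(ruleset, "RuleSet"))
  cb <- attr(ruleset, "codebook")
  lab <- function(codes) paste(item_label(codes, cb), collapse = "&")
  grab <- function(col) {
    if (col %in% names(ruleset)) ruleset[[col]] else
      rep(NA_real_, nrow(ruleset))
  }
  df <- data.frame(
    group = if ("group" %in% names(ruleset)) ruleset$group else
      rep(attr(ruleset, "group") %||% NA_character_, nrow(ruleset)),
    lhs = vapply(ruleset$lhs, lab, character(1)),
    rhs = vapply(ruleset$rhs, lab, character(1)),
    sup_count = ruleset$sup_seq,
    seq_sup = ruleset$seq_sup, seq_conf = ruleset$seq_conf,
    lift = ruleset$lift, cf = ruleset$cf, conviction = ruleset$conviction,
    bp = grab("bp"), mf = grab("mf"), cc = grab("cc"), sp = grab("sp"),
    tf = grab("tf"), stringsAsFactors = FALSE)
  class(df) <- c("RuleTable", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA"
    else if (is.infinite(v)) if (v > 0) "Inf" else "-Inf"
    else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' Write rules to TSV or JSON-lines
#'
#' `write_rules()` followed by [read_rules()] is the identity on every rule
#' field, including infinite conviction (serialized as the literal `Inf`).
#'
#' @param ruleset a `RuleSet` or `RuleTable`.
#' @param path output path.
#' @param format `"tsv"` or `"jsonl"`.
#' @export
write_rules <- function(ruleset, path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  tab <- rules_to_table(ruleset)
  num <- setdiff(RULE_TABLE_COLS, c("group", "lhs", "rhs"))
  if (format == "tsv") {
    out <- tab
    for (cl in num) out[[cl]] <- fmt_num(out[[cl]])
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(paste(RULE_TABLE_COLS, collapse = "\t"), con)
    if (nrow(out))
      writeLines(do.call(paste, c(unname(as.list(out[RULE_TABLE_COLS])),
                                  sep = "\t")), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    for (i in seq_len(nrow(tab))) {
      row <- as.list(tab[i, RULE_TABLE_COLS])
      for (cl in num)
        if (!is.na(row[[cl]]) && is.infinite(row[[cl]]))
          row[[cl]] <- if (row[[cl]] > 0) "Inf" else "-Inf"
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA,
                                  na = "null"), con)
    }
  }
  invisible(path)
}

#' Read a rule table written by [write_rules()]
#'
#' @param path input path.
#' @param format `"auto"` (by extension), `"tsv"` or `"jsonl"`.
#' @return a `RuleTable` data.frame.
#' @export
read_rules <- function(path, format = c("auto", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "tsv"
  num <- setdiff(RULE_TABLE_COLS, c("group", "lhs", "rhs"))
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (!all(RULE_TABLE_COLS %in% names(tab)))
      stop("not a rule table: missing columns")
    for (cl in num) tab[[cl]] <- as.numeric(tab[[cl]])
  } else {
    lines <- readLines(path, warn = FALSE)
    rows <- lapply(lines[nzchar(lines)], function(ln) {
      x <- jsonlite::fromJSON(ln)
      for (cl in num) {
        v <- x[[cl]]
        x[[cl]] <- if (is.null(v)) NA_real_ else
          if (is.character(v)) as.numeric(v) else as.numeric(v)
      }
      as.data.frame(x[RULE_TABLE_COLS], stringsAsFactors = FALSE)
    })
    tab <- if (length(rows)) do.call(rbind, rows) else
      stats::setNames(as.data.frame(matrix(nrow = 0, ncol =
        length(RULE_TABLE_COLS))), RULE_TABLE_COLS)
  }
  tab <- tab[, RULE_TABLE_COLS, drop = FALSE]
  class(tab) <- c("RuleTable", "data.frame")
  tab
}

#' Parse a serialized itemset label
#'
#' Splits `"probe/GENE=state&probe/GENE=state"` into a data.frame with
#' columns `probe_id`, `gene`, `state`.
#'
#' @param label a single serialized itemset string.
#' @return data.frame with one row per item.
#' @export
parse_item_label <- function(label) {
  if (!nzchar(label))
    return(data.frame(probe_id = character(0), gene = character(0),
                      state = integer(0)))
  parts <- strsplit(label, "&", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^\\s*([^/]+)/(.+?)\\s*=\\s*([12])\\s*$", parts))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed item label: ", parts[bad][1L])
  data.frame(probe_id = vapply(m, `[`, character(1), 2L),
             gene = normalize_gene_symbol(vapply(m, `[`, character(1), 3L)),
             state = as.integer(vapply(m, `[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}
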