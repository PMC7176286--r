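# Biological quality measures per rule: four annotation-based ranking
# scores (BP, MF, CC for GO-style namespaces, SP for pathways) and a
# TF measure from a TF-target regulation table. Lower annotation scores
# mean the rule's genes share terms across the LHS/RHS divide and so is a
# better candidate for a causal, biologically coherent interaction.

#' Cross-term matches between the two sides of a rule
#'
#' A term counts as a cross match only when it annotates at least one LHS
#' gene AND at least one RHS gene (gene-level deduplication first: two
#' probes of one gene count once). For each cross term the covered genes
#' are the rule genes carrying it; the coverage fraction of the best term,
#' `f_best = max |covered| / |distinct rule genes|`, drives the category.
#'
#' @param lhs_genes,rhs_genes character vectors of gene symbols.
#' @param annotation an `AnnotationTable`.
#' @return a `MatchSet` data.frame (`term`, `n_covered`, list-column
#'   `covered`) with attribute `f_best` (NA when no cross term exists).
#' @export
find_matches <- function(lhs_genes, rhs_genes, annotation) {
  lhs_genes <- unique(normalize_gene_symbol(lhs_genes))
  rhs_genes <- unique(normalize_gene_symbol(rhs_genes))
  all_genes <- unique(c(lhs_genes, rhs_genes))
  terms_by_gene <- lapply(all_genes, annotation_terms,
                          annotation = annotation)
  names(terms_by_gene) <- all_genes
  cross <- intersect(unique(unlist(terms_by_gene[lhs_genes])),
                     unique(unlist(terms_by_gene[rhs_genes])))
  cross <- sort(cross)
  covered <- lapply(cross, function(tm)
    all_genes[vapply(terms_by_gene, function(t) tm %in% t, logical(1))])
  ms <- data.frame(term = cross,
                   n_covered = vapply(covered, length, integer(1)),
                   stringsAsFactors = FALSE)
  ms$covered <- covered
  attr(ms, "f_best") <- if (length(cross))
    max(ms$n_covered) / length(all_genes) else NA_real_
  attr(ms, "n_genes") <- length(all_genes)
  class(ms) <- c("MatchSet", "data.frame")
  ms
}

#' Category of a rule from its cross matches
#'
#' Categories run from 1 (best) to 5 (worst) on the best coverage
#' fraction: 1 when some term covers every rule gene (`f_best = 1`);
#' 2 when `0.75 <= f_best < 1`; 3 when `0.5 <= f_best < 0.75`; 4 for any
#' remaining cross match; 5 when no term spans both sides. Band
#' boundaries are configurable via `bands`.
#'
#' @param matchset a `MatchSet` from [find_matches()].
#' @param bands decreasing numeric thresholds for categories 1..3.
#' @return integer category in 1..5.
#' @export
assign_category <- function(matchset, bands = c(1, 0.75, 0.5)) {
  f <- attr(matchset, "f_best")
  if (is.na(f)) return(5L)
  if (f >= bands[1L]) 1L
  else if (f >= bands[2L]) 2L
  else if (f >= bands[3L]) 3L
  else 4L
}

#' Points of a rule from its cross matches
#'
#' Each cross match is weighted by the number of rule genes it covers;
#' the rule's points are the sum over its cross terms.
#'
#' @param matchset a `MatchSet`.
#' @return integer number of points (0 when no cross match).
#' @export
compute_points <- function(matchset) {
  as.integer(sum(matchset$n_covered))
}

rule_side_genes <- function(ruleset, i, side) {
  cb <- attr(ruleset, "codebook")
  if (is.null(cb)) stop("rule set items lack gene symbols (no codebook)")
  item_genes(ruleset[[side]][[i]], cb)
}

#' Annotation ranking scores for a rule set
#'
#' Scores are corpus-relative within the rule set: with category `CAT(r)`
#' and points `NP(r)`, the score is
#' `CAT(r) + (1 - NP(r) / (maxNP in CAT(r) + 1))`, where the maximum is
#' taken over the rules of the same category in this set. Scores lie in
#' (1, 6]; lower is better; a category-5 rule with no matches scores
#' exactly 6.
#'
#' @param ruleset a `RuleSet`.
#' @param annotation an `AnnotationTable`.
#' @param namespace which field to write (`"BP"`, `"MF"`, `"CC"`, `"SP"`);
#'   defaults to the annotation's namespace.
#' @param bands category bands, see [assign_category()].
#' @return the `RuleSet` with the lowercase namespace column filled and a
#'   `score_detail` attribute (data.frame `category`, `np`, `score`).
#' @export
score_ruleset <- function(ruleset, annotation, namespace = NULL,
                          bands = c(1, 0.75, 0.5)) {
  if (!nrow(ruleset)) stop("empty rule set")
  if (is.null(namespace)) namespace <- annotation$namespace
  stopifnot(namespace %in% c("BP", "MF", "CC", "SP"))
  cat_np <- vapply(seq_len(nrow(ruleset)), function(i) {
    ms <- find_matches(rule_side_genes(ruleset, i, "lhs")$gene,
                       rule_side_genes(ruleset, i, "rhs")$gene, annotation)
    c(assign_category(ms, bands), compute_points(ms))
  }, integer(2))
  category <- cat_np[1L, ]
  np <- cat_np[2L, ]
  max_np <- vapply(category, function(ct) max(np[category == ct]), integer(1))
  score <- category + (1 - np / (max_np + 1))
  ruleset[[tolower(namespace)]] <- score
  attr(ruleset, "score_detail") <-
    data.frame(category = category, np = np, score = score)
  ruleset
}

#' TF measure of a single rule
#'
#' Milestone levels against a TF-target table: 1 when some LHS gene is a
#' listed TF; 2 when additionally some RHS gene is a listed target of
#' that TF; 3 when additionally the regulation mode matches the discrete
#' states (Activation: target state equals the TF state; Repression:
#' states differ; Unknown never direction-matches). The score is the
#' highest level attained over all (LHS TF, RHS target) pairs, 0 when no
#' LHS gene is a TF.
#'
#' @param lhs,rhs data.frames with columns `gene` and `state`
#'   (1 = down, 2 = up).
#' @param tf_table a `TFTable`.
#' @return integer score in 0..3.
#' @export
rule_tf_score <- function(lhs, rhs, tf_table) {
  lhs$gene <- normalize_gene_symbol(lhs$gene)
  rhs$gene <- normalize_gene_symbol(rhs$gene)
  lhs_tf <- lhs[lhs$gene %in% tf_table$tf, , drop = FALSE]
  if (!nrow(lhs_tf)) return(0L)
  best <- 1L
  for (i in seq_len(nrow(lhs_tf))) {
    rows <- tf_table[tf_table$tf == lhs_tf$gene[i], , drop = FALSE]
    hits <- rhs[rhs$gene %in% rows$target, , drop = FALSE]
    if (!nrow(hits)) next
    best <- max(best, 2L)
    for (j in seq_len(nrow(hits))) {
      modes <- rows$mode[rows$target == hits$gene[j]]
      same <- hits$state[j] == lhs_tf$state[i]
      if (("Activation" %in% modes && same) ||
          ("Repression" %in% modes && !same))
        return(3L)
    }
  }
  best
}

#' Fill the five biological measures of a rule set
#'
#' Convenience wrapper: runs [score_ruleset()] for every supplied
#' annotation namespace and [rule_tf_score()] for the TF table.
#'
#' @param ruleset a `RuleSet`.
#' @param annotations named or unnamed list of `AnnotationTable`s (their
#'   own namespaces are used).
#' @param tf_table optional `TFTable`.
#' @param bands category bands, see [assign_category()].
#' @return the annotated `RuleSet`.
#' @export
annotate_rules <- function(ruleset, annotations = list(), tf_table = NULL,
                           bands = c(1, 0.75, 0.5)) {
  for (ann in annotations)
    ruleset <- score_ruleset(ruleset, ann, bands = bands)
  if (!is.null(tf_table)) {
    ruleset$tf <- vapply(seq_len(nrow(ruleset)), function(i)
      rule_tf_score(rule_side_genes(ruleset, i, "lhs"),
                    rule_side_genes(ruleset, i, "rhs"), tf_table),
      integer(1))
  }
  ruleset
}

#' Write the XML match-detail report
#'
#' One `<rule>` element per rule, carrying the frequentist metrics and
#' biological measures as attributes, with one nested `<match>` element
#' per cross term per namespace listing the covered genes.
#'
#' @param ruleset a `RuleSet` (scored or not).
#' @param annotations list of `AnnotationTable`s to detail matches for.
#' @param path output XML path.
#' @return the path, invisibly.
#' @export
write_match_report <- function(ruleset, annotations, path) {
  doc <- xml2::xml_new_root("rules",
                            group = as.character(attr(ruleset, "group")))
  num_attr <- function(x) {
    if (is.null(x) || is.na(x)) "NA" else fmt_num(x)
  }
  for (i in seq_len(nrow(ruleset))) {
    rule <- xml2::xml_add_child(
      doc, "rule", id = as.character(i),
      lhs = ruleset$lhs_label[i], rhs = ruleset$rhs_label[i],
      seq_sup = num_attr(ruleset$seq_sup[i]),
      seq_conf = num_attr(ruleset$seq_conf[i]),
      lift = num_attr(ruleset$lift[i]), cf = num_attr(ruleset$cf[i]),
      conviction = num_attr(ruleset$conviction[i]),
      bp = num_attr(ruleset$bp[i]), mf = num_attr(ruleset$mf[i]),
      cc = num_attr(ruleset$cc[i]), sp = num_attr(ruleset$sp[i]),
      tf = num_attr(ruleset$tf[i]))
    lhs_g <- rule_side_genes(ruleset, i, "lhs")$gene
    rhs_g <- rule_side_genes(ruleset, i, "rhs")$gene
    for (ann in annotations) {
      ms <- find_matches(lhs_g, rhs_g, ann)
      for (k in seq_len(nrow(ms)))
        xml2::xml_add_child(rule, "match", namespace = ann$namespace,
                            term = ms$term[k],
                            genes = paste(sort(ms$covered[[k]]),
                                          collapse = ","))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
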