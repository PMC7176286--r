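# Two-phase sequential rule mining over multi-subject sequence databases:
# an Apriori pass over sequences flattened to transactions (temporal order
# ignored) generates candidate rules, then sequential cut-point counting
# keeps exactly the rules meeting the sequential thresholds. The pruning is
# sound because for any rule the sequential support can never exceed the
# flattened association support, nor the sequential confidence the
# association confidence.

flatten_transactions <- function(seqdb) {
  lapply(seqdb$sequences, function(s) sort(unique(unlist(s))))
}

iset_key <- function(items) paste(items, collapse = " ")

#' Mine frequent itemsets from flattened sequences (Apriori)
#'
#' Each sequence is flattened to the union of its itemsets; a levelwise
#' Apriori search returns all and only the itemsets whose fraction of
#' transactions is at least `min_sup_frac`.
#'
#' @param seqdb a `SequenceDatabase`.
#' @param min_sup_frac minimum support fraction in (0, 1].
#' @param max_size maximum itemset size explored (lattice truncation is
#'   reported with a message); `Inf` for no cap.
#' @return data.frame with list-column `items` (sorted integer codes),
#'   `count` and `frac`.
#' @export
mine_frequent_itemsets <- function(seqdb, min_sup_frac, max_size = Inf) {
  if (!length(seqdb$sequences)) stop("empty sequence database")
  stopifnot(min_sup_frac > 0, min_sup_frac <= 1)
  tx <- flatten_transactions(seqdb)
  nt <- length(tx)
  min_count <- ceiling(min_sup_frac * nt - 1e-9)

  counts1 <- table(unlist(tx))
  items1 <- sort(as.integer(names(counts1)[counts1 >= min_count]))
  level <- lapply(items1, function(i) i)
  level_counts <- as.integer(counts1[as.character(items1)])

  all_sets <- level
  all_counts <- level_counts
  k <- 1L
  while (length(level) >= 2L && k < max_size) {
    cands <- list()
    keys <- vapply(level, function(s) iset_key(s[-length(s)]), character(1))
    freq_keys <- new.env(parent = emptyenv())
    for (s in level) assign(iset_key(s), TRUE, envir = freq_keys)
    for (grp in split(seq_along(level), keys)) {
      if (length(grp) < 2L) next
      for (a in seq_along(grp)) for (b in seq_along(grp)) {
        if (a >= b) next
        s1 <- level[[grp[a]]]; s2 <- level[[grp[b]]]
        cand <- sort(unique(c(s1, s2)))
        if (length(cand) != k + 1L) next
        # Apriori prune: every k-subset must be frequent
        ok <- all(vapply(seq_along(cand), function(d)
          exists(iset_key(cand[-d]), envir = freq_keys), logical(1)))
        if (ok) cands[[length(cands) + 1L]] <- cand
      }
    }
    if (!length(cands)) break
    cands <- unique(cands)
    cnt <- vapply(cands, function(cand)
      sum(vapply(tx, function(t) all(cand %in% t), logical(1))), integer(1))
    keep <- cnt >= min_count
    level <- cands[keep]
    level_counts <- cnt[keep]
    all_sets <- c(all_sets, level)
    all_counts <- c(all_counts, level_counts)
    k <- k + 1L
  }
  if (length(level) >= 2L && k >= max_size && is.finite(max_size))
    message("itemset lattice truncated at size ", max_size)
  data.frame(items = I(all_sets), count = all_counts,
             frac = all_counts / nt)
}

#' Generate candidate rules from frequent itemsets
#'
#' Every frequent itemset of size >= 2 is split into all ordered pairs of
#' non-empty disjoint (LHS, RHS) parts; candidates whose association
#' confidence `count(itemset) / count(LHS)` reaches `min_conf` are kept.
#'
#' @param frequent output of [mine_frequent_itemsets()].
#' @param min_conf minimum association confidence.
#' @param max_lhs,max_rhs optional caps on part sizes.
#' @return data.frame with list-columns `lhs`, `rhs` and columns
#'   `assoc_count`, `lhs_count`, `assoc_conf`.
#' @export
generate_candidate_rules <- function(frequent, min_conf,
                                     max_lhs = Inf, max_rhs = Inf) {
  sup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(frequent)))
    assign(iset_key(frequent$items[[i]]), frequent$count[i], envir = sup)
  lhs <- list(); rhs <- list()
  ac <- integer(0); lc <- integer(0)
  for (i in seq_len(nrow(frequent))) {
    full <- frequent$items[[i]]
    kk <- length(full)
    if (kk < 2L) next
    cnt <- frequent$count[i]
    for (mask in seq_len(2L^kk - 2L)) {
      pick <- as.logical(bitwAnd(mask, 2L^(seq_len(kk) - 1L)))
      l <- full[pick]; r <- full[!pick]
      if (length(l) > max_lhs || length(r) > max_rhs) next
      lcount <- get(iset_key(l), envir = sup)
      if (cnt / lcount >= min_conf - 1e-12) {
        lhs[[length(lhs) + 1L]] <- l
        rhs[[length(rhs) + 1L]] <- r
        ac <- c(ac, cnt); lc <- c(lc, lcount)
      }
    }
  }
  data.frame(lhs = I(lhs), rhs = I(rhs), assoc_count = ac, lhs_count = lc,
             assoc_conf = if (length(ac)) ac / lc else numeric(0))
}

#' Test whether a sequence contains a rule in temporal order
#'
#' TRUE iff there is a cut point k such that every LHS item occurs in
#' itemsets 1..k and every RHS item in itemsets k+1..n. Items within the
#' LHS (or RHS) need not share an itemset nor respect any internal order;
#' a single-itemset sequence can never contain a rule (no cut exists).
#'
#' @param sequence list of integer item-code vectors (ordered itemsets).
#' @param lhs,rhs integer item-code vectors.
#' @return logical.
#' @export
sequence_contains <- function(sequence, lhs, rhs) {
  n <- length(sequence)
  if (n < 2L) return(FALSE)
  pre <- integer(0)
  for (k in seq_len(n - 1L)) {
    pre <- c(pre, sequence[[k]])
    if (all(lhs %in% pre)) {
      suf <- unlist(sequence[(k + 1L):n])
      return(all(rhs %in% suf))
    }
  }
  FALSE
}

#' Sequential counts of a rule in a database
#'
#' @param seqdb a `SequenceDatabase`.
#' @param lhs,rhs integer item-code vectors.
#' @return list with `sup_seq` (sequences containing LHS before RHS),
#'   `sup_lhs`, `sup_rhs` (sequences containing the itemset anywhere),
#'   `notsup` (sequences containing neither side) and `n`.
#' @export
rule_counts <- function(seqdb, lhs, rhs) {
  rule_counts_tx(seqdb$sequences, flatten_transactions(seqdb), lhs, rhs)
}

rule_counts_tx <- function(sequences, tx, lhs, rhs) {
  has_l <- vapply(tx, function(t) all(lhs %in% t), logical(1))
  has_r <- vapply(tx, function(t) all(rhs %in% t), logical(1))
  both <- which(has_l & has_r)
  ss <- sum(vapply(both, function(i)
    sequence_contains(sequences[[i]], lhs, rhs), logical(1)))
  list(sup_seq = as.integer(ss), sup_lhs = sum(has_l), sup_rhs = sum(has_r),
       notsup = sum(!has_l & !has_r), n = length(tx))
}

#' Frequentist quality metrics of a sequential rule
#'
#' From the sequential counts: `seq_sup = sup_seq / n`,
#' `seq_conf = sup_seq / sup_lhs`,
#' `lift = seq_sup / ((sup_lhs/n) * (sup_rhs/n))`,
#' certainty factor `cf = (seq_conf - s)/(1 - s)` when `seq_conf > s`,
#' `(seq_conf - s)/s` when `seq_conf < s`, 0 at equality (with
#' `s = sup_rhs/n`), and
#' `conviction = (1 - s)/(1 - seq_conf)`, defined as `+Inf` when
#' `seq_conf = 1` (perfect implication, including the 0/0 case).
#' All metrics keep the meaning and domain of their association-rule
#' counterparts, with sequence-containment fractions in place of
#' transaction supports.
#'
#' @param sup_seq,sup_lhs,sup_rhs,n integer count vectors (recycled).
#' @return data.frame `seq_sup, seq_conf, lift, cf, conviction`.
#' @export
compute_rule_metrics <- function(sup_seq, sup_lhs, sup_rhs, n) {
  if (any(sup_lhs == 0)) stop("sup_lhs must be positive")
  if (any(sup_seq > pmin(sup_lhs, sup_rhs)) || any(pmax(sup_lhs, sup_rhs) > n))
    stop("inconsistent rule counts")
  seq_sup <- sup_seq / n
  seq_conf <- sup_seq / sup_lhs
  s <- sup_rhs / n
  lift <- ifelse(sup_rhs == 0, NaN, seq_sup / ((sup_lhs / n) * s))
  cf <- ifelse(abs(seq_conf - s) <= 1e-12, 0,
               ifelse(seq_conf > s, (seq_conf - s) / (1 - s),
                      (seq_conf - s) / s))
  conviction <- ifelse(seq_conf >= 1 - 1e-12, Inf, (1 - s) / (1 - seq_conf))
  data.frame(seq_sup = seq_sup, seq_conf = seq_conf, lift = lift, cf = cf,
             conviction = conviction)
}

new_ruleset <- function(df, seqdb) {
  cb <- seqdb$codebook
  labf <- function(codes) {
    if (is.null(cb)) paste(codes, collapse = "&")
    else paste(item_label(codes, cb), collapse = "&")
  }
  df$lhs_label <- vapply(df$lhs, labf, character(1))
  df$rhs_label <- vapply(df$rhs, labf, character(1))
  df$group <- rep(seqdb$group, nrow(df))
  o <- order(-df$seq_conf, -df$seq_sup, df$lhs_label, df$rhs_label)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_sequences") <- n_sequences(seqdb)
  attr(df, "codebook") <- cb
  attr(df, "group") <- seqdb$group
  class(df) <- c("RuleSet", "data.frame")
  df
}

#' @export
print.RuleSet <- function(x, n = 10L, ...) {
  cat(sprintf("RuleSet [%s]: %d rules over %d sequences\n",
              attr(x, "group"), nrow(x), attr(x, "n_sequences")))
  if (nrow(x)) {
    show <- utils::head(x[, c("lhs_label", "rhs_label", "sup_seq", "seq_sup",
                              "seq_conf", "lift", "cf", "conviction")], n)
    print.data.frame(show, digits = 3)
    if (nrow(x) > n) cat("... and", nrow(x) - n, "more rules\n")
  }
  invisible(x)
}

#' Mine sequential rules from a sequence database
#'
#' Phase 1 runs Apriori on the flattened sequences with
#' `min_sup_frac = min_seq_sup` and association confidence
#' `min_conf = min_seq_conf` (a sound pruning bound: sequential support
#' and confidence can never exceed their flattened counterparts).
#' Phase 2 computes the sequential counts of every candidate and keeps
#' exactly the rules with `seq_sup >= min_seq_sup` and
#' `seq_conf >= min_seq_conf`, with all five metrics filled. Output order
#' is deterministic: decreasing (seq_conf, seq_sup), then lexicographic
#' LHS / RHS labels.
#'
#' @param seqdb a `SequenceDatabase`.
#' @param min_seq_sup,min_seq_conf sequential thresholds in (0, 1].
#' @param max_lhs,max_rhs optional caps on rule part sizes.
#' @param max_itemset cap on explored itemset size (default 4).
#' @return a `RuleSet` data.frame: list-columns `lhs`/`rhs`, counts
#'   `sup_seq`, `sup_lhs`, `sup_rhs`, `notsup`, metrics `seq_sup`,
#'   `seq_conf`, `lift`, `cf`, `conviction`, plus `notsup_frac`, labels
#'   and `group`; attributes `n_sequences`, `codebook`, `group`.
#' @export
mine_sequential_rules <- function(seqdb, min_seq_sup, min_seq_conf,
                                  max_lhs = Inf, max_rhs = Inf,
                                  max_itemset = 4L) {
  if (!length(seqdb$sequences)) stop("empty sequence database")
  stopifnot(min_seq_sup > 0, min_seq_sup <= 1,
            min_seq_conf > 0, min_seq_conf <= 1)
  freq <- mine_frequent_itemsets(seqdb, min_seq_sup, max_size = max_itemset)
  cand <- generate_candidate_rules(freq, min_seq_conf, max_lhs, max_rhs)
  n <- n_sequences(seqdb)
  cols <- c("sup_seq", "sup_lhs", "sup_rhs", "notsup")
  if (nrow(cand)) {
    tx <- flatten_transactions(seqdb)
    cnts <- lapply(seq_len(nrow(cand)), function(i)
      rule_counts_tx(seqdb$sequences, tx, cand$lhs[[i]], cand$rhs[[i]]))
    for (cl in cols)
      cand[[cl]] <- vapply(cnts, function(x) as.integer(x[[cl]]), integer(1))
    keep <- cand$sup_seq / n >= min_seq_sup - 1e-12 &
      cand$sup_seq / cand$sup_lhs >= min_seq_conf - 1e-12
    cand <- cand[keep, , drop = FALSE]
  } else {
    for (cl in cols) cand[[cl]] <- integer(0)
  }
  met <- compute_rule_metrics(cand$sup_seq, cand$sup_lhs, cand$sup_rhs,
                              rep(n, nrow(cand)))
  df <- cbind(cand[, c("lhs", "rhs", cols)], met)
  df$notsup_frac <- df$notsup / n
  new_ruleset(df, seqdb)
}

#' Filter very strong sequential rules
#'
#' A very strong rule passes the support condition together with evidence
#' for its counter-reciprocal (not-RHS implies not-LHS), discarding
#' misleading rules. Variants:
#' \describe{
#'   \item{`cf_only` (default)}{`seq_sup > min_seq_sup` and `cf > 0`.}
#'   \item{`literal`}{additionally `notsup_frac > 1 - min_seq_sup`, where
#'     `notsup_frac` is the fraction of sequences containing neither LHS
#'     nor RHS.}
#'   \item{`counter_reciprocal`}{additionally
#'     `notsup_frac > not_sup_threshold` (user-set).}
#' }
#'
#' @param ruleset a `RuleSet`.
#' @param min_seq_sup the support threshold.
#' @param variant filtering variant.
#' @param not_sup_threshold required for `counter_reciprocal`.
#' @return the filtered `RuleSet`.
#' @export
filter_very_strong <- function(ruleset, min_seq_sup,
                               variant = c("cf_only", "literal",
                                           "counter_reciprocal"),
                               not_sup_threshold = NULL) {
  variant <- match.arg(variant)
  keep <- ruleset$seq_sup > min_seq_sup & ruleset$cf > 0
  if (variant != "cf_only") {
    if (is.null(ruleset$notsup_frac) || anyNA(ruleset$notsup_frac))
      stop("notsup fraction not computable for this rule set")
    thr <- if (variant == "literal") 1 - min_seq_sup else {
      if (is.null(not_sup_threshold))
        stop("counter_reciprocal variant needs not_sup_threshold")
      not_sup_threshold
    }
    keep <- keep & ruleset$notsup_frac > thr
  }
  out <- ruleset[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("n_sequences", "codebook", "group"))
    attr(out, a) <- attr(ruleset, a)
  class(out) <- class(ruleset)
  out
}

codebooks_compatible <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  identical(a$probe_index, b$probe_index) &&
    identical(a$probe_id, b$probe_id) &&
    identical(attr(a, "width"), attr(b, "width"))
}

rule_passes <- function(seqdb, lhs, rhs, min_seq_sup, min_seq_conf) {
  ct <- rule_counts(seqdb, lhs, rhs)
  conf <- if (ct$sup_lhs == 0) 0 else ct$sup_seq / ct$sup_lhs
  ct$sup_seq / ct$n >= min_seq_sup - 1e-12 && conf >= min_seq_conf - 1e-12
}

#' Contrast mining between two experimental groups
#'
#' Returns the rules exclusive to each group: a rule is in `only_a` iff it
#' passes both thresholds in database A and fails at least one of them in
#' database B (and symmetrically). Rules passing in both groups appear in
#' neither output, so the two sets are always disjoint.
#'
#' @param seqdb_a,seqdb_b `SequenceDatabase`s sharing the same item
#'   codebook.
#' @param min_seq_sup,min_seq_conf sequential thresholds.
#' @param ... passed to [mine_sequential_rules()].
#' @return list with `RuleSet`s `only_a` and `only_b`.
#' @export
mine_contrast <- function(seqdb_a, seqdb_b, min_seq_sup, min_seq_conf, ...) {
  if (!codebooks_compatible(seqdb_a$codebook, seqdb_b$codebook))
    stop("incompatible item codebooks between the two databases")
  ra <- mine_sequential_rules(seqdb_a, min_seq_sup, min_seq_conf, ...)
  rb <- mine_sequential_rules(seqdb_b, min_seq_sup, min_seq_conf, ...)
  excl <- function(rules, other_db) {
    if (!nrow(rules)) return(rules)
    pass_other <- vapply(seq_len(nrow(rules)), function(i)
      rule_passes(other_db, rules$lhs[[i]], rules$rhs[[i]],
                  min_seq_sup, min_seq_conf), logical(1))
    out <- rules[!pass_other, , drop = FALSE]
    rownames(out) <- NULL
    for (a in c("n_sequences", "codebook", "group"))
      attr(out, a) <- attr(rules, a)
    class(out) <- class(rules)
    out
  }
  list(only_a = excl(ra, seqdb_b), only_b = excl(rb, seqdb_a))
}

rule_gene_key <- function(ruleset, side, ignore_state) {
  cb <- attr(ruleset, "codebook")
  if (is.null(cb)) stop("rule set items lack gene symbols (no codebook)")
  vapply(ruleset[[side]], function(codes) {
    g <- item_genes(codes, cb)
    key <- if (ignore_state) g$gene else paste0(g$gene, "=", g$state)
    paste(sort(unique(key)), collapse = "&")
  }, character(1))
}

#' Match replicated rules across rule sets
#'
#' Two rules from different datasets replicate when their LHS gene sets
#' and RHS gene sets coincide after dropping probe identifiers (states are
#' kept unless `ignore_state = TRUE`, which also matches e.g. a down->down
#' rule in one cohort with an up->up rule in another). Returns the
#' replication groups of size >= 2 that span >= 2 datasets.
#'
#' @param rulesets named list of >= 2 `RuleSet`s with gene symbols.
#' @param ignore_state drop the up/down states before matching.
#' @return list of data.frames, one per replication group, with columns
#'   `dataset`, `rule` (row index in its rule set), `lhs_genes`,
#'   `rhs_genes`.
#' @export
match_rules <- function(rulesets, ignore_state = FALSE) {
  if (length(rulesets) < 2L)
    stop("replication matching needs >= 2 rule sets")
  if (is.null(names(rulesets)) || any(!nzchar(names(rulesets))))
    names(rulesets) <- paste0("dataset", seq_along(rulesets))
  tabs <- lapply(names(rulesets), function(ds) {
    rs <- rulesets[[ds]]
    if (!nrow(rs)) return(NULL)
    data.frame(dataset = ds, rule = seq_len(nrow(rs)),
               lhs_genes = rule_gene_key(rs, "lhs", ignore_state),
               rhs_genes = rule_gene_key(rs, "rhs", ignore_state),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, tabs)
  if (is.null(all) || !nrow(all)) return(list())
  groups <- split(all, paste(all$lhs_genes, "->", all$rhs_genes))
  keep <- vapply(groups, function(g)
    nrow(g) >= 2L && length(unique(g$dataset)) >= 2L, logical(1))
  out <- unname(groups[keep])
  lapply(out, function(g) { rownames(g) <- NULL; g })
}
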