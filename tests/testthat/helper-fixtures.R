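# Shared fixtures: toy sequence databases, a random database generator
# and a brute-force rule enumerator used as the independent oracle for
# the miner. The oracle works on bitmask semantics (cut-point scan over
# prefix/suffix unions) and shares no code with the mining path.

toy_codebook <- function(n = 4L, width = 3L) {
  make_codebook(data.frame(
    probe_id = paste0("p", LETTERS[seq_len(n)]),
    gene_symbol = paste0("G", LETTERS[seq_len(n)])), width = width)
}

# DB+ : three <{A_up},{B_dn}> sequences plus one <{C_up},{D_dn}>
toy_db_plus <- function() {
  cb <- toy_codebook()
  A <- encode_item(2, 0, 3); B <- encode_item(1, 1, 3)
  C <- encode_item(2, 2, 3); D <- encode_item(1, 3, 3)
  sequence_database(c(rep(list(list(A, B)), 3), list(list(C, D))),
                    group = "plus", codebook = cb)
}

# DB- : A_up -> B_dn holds in order in only 2 of 4 sequences while both
# sides are globally frequent (sup_lhs 3, sup_rhs 4)
toy_db_minus <- function() {
  cb <- toy_codebook()
  A <- encode_item(2, 0, 3); B <- encode_item(1, 1, 3)
  sequence_database(list(list(A, B), list(A, B), list(B, A), list(B, B)),
                    group = "minus", codebook = cb)
}

random_seqdb <- function(seed, max_items = 8L, max_seq = 6L,
                         max_itemsets = 3L) {
  set.seed(seed)
  n_items <- sample(2:max_items, 1L)
  items <- seq_len(n_items) * 10L + 1L   # arbitrary codes, not 1..n
  n_seq <- sample(2:max_seq, 1L)
  sequences <- lapply(seq_len(n_seq), function(i) {
    n_sets <- sample(1:max_itemsets, 1L)
    lapply(seq_len(n_sets), function(k)
      items[stats::runif(n_items) < 0.35])
  })
  sequence_database(sequences, group = paste0("rnd", seed))
}

# Brute-force enumerator: tests every (lhs, rhs) pair of disjoint
# non-empty item subsets by direct cut-point scanning on bitmasks.
oracle_mine <- function(db, min_sup, min_conf) {
  empty <- data.frame(lhs_key = character(0), rhs_key = character(0),
                      sup_seq = integer(0), sup_lhs = integer(0),
                      sup_rhs = integer(0), notsup = integer(0))
  items <- sort(unique(unlist(db$sequences)))
  m <- length(items)
  n <- length(db$sequences)
  if (m == 0L) return(empty)
  masks <- seq_len(2L^m - 1L)
  bits <- 2L^(seq_len(m) - 1L)
  cont <- matrix(0L, length(masks), length(masks))
  hasm <- matrix(FALSE, length(masks), n)
  for (j in seq_len(n)) {
    s <- db$sequences[[j]]
    isets <- vapply(s, function(it)
      sum(bits[match(it, items)]), numeric(1))
    pre <- Reduce(bitwOr, isets, accumulate = TRUE)
    suf <- rev(Reduce(bitwOr, rev(isets), accumulate = TRUE))
    hasm[, j] <- bitwAnd(masks, bitwNot(as.integer(pre[length(pre)]))) == 0L
    if (length(isets) >= 2L) {
      cj <- matrix(FALSE, length(masks), length(masks))
      for (k in seq_len(length(isets) - 1L)) {
        okL <- bitwAnd(masks, bitwNot(as.integer(pre[k]))) == 0L
        okR <- bitwAnd(masks, bitwNot(as.integer(suf[k + 1L]))) == 0L
        cj <- cj | outer(okL, okR, "&")
      }
      cont <- cont + cj
    }
  }
  sup_any <- rowSums(hasm)
  disjoint <- outer(masks, masks, function(a, b) bitwAnd(a, b) == 0L)
  seq_sup_ok <- cont / n >= min_sup - 1e-12
  conf_ok <- cont / sup_any >= min_conf - 1e-12   # rows = lhs
  pass <- which(disjoint & seq_sup_ok & conf_ok, arr.ind = TRUE)
  if (!nrow(pass)) return(empty)
  mask_items <- function(mk) items[bitwAnd(mk, bits) > 0L]
  out <- data.frame(
    lhs_key = vapply(masks[pass[, 1L]], function(mk)
      paste(mask_items(mk), collapse = " "), character(1)),
    rhs_key = vapply(masks[pass[, 2L]], function(mk)
      paste(mask_items(mk), collapse = " "), character(1)),
    sup_seq = as.integer(cont[pass]),
    sup_lhs = as.integer(sup_any[pass[, 1L]]),
    sup_rhs = as.integer(sup_any[pass[, 2L]]),
    notsup = vapply(seq_len(nrow(pass)), function(i)
      sum(!hasm[pass[i, 1L], ] & !hasm[pass[i, 2L], ]), integer(1)),
    stringsAsFactors = FALSE)
  out[order(out$lhs_key, out$rhs_key), , drop = FALSE]
}

ruleset_keys <- function(rs) {
  data.frame(
    lhs_key = vapply(rs$lhs, paste, character(1), collapse = " "),
    rhs_key = vapply(rs$rhs, paste, character(1), collapse = " "),
    sup_seq = rs$sup_seq, sup_lhs = rs$sup_lhs, sup_rhs = rs$sup_rhs,
    notsup = rs$notsup, stringsAsFactors = FALSE)
}

# Minimal hand-built RuleSet for the biological measures and plotting
make_test_ruleset <- function(lhs, rhs, codebook, group = "test",
                              n_sequences = 10L, metrics = NULL) {
  df <- data.frame(row.names = seq_along(lhs))
  df$lhs <- lhs
  df$rhs <- rhs
  if (is.null(metrics))
    metrics <- data.frame(sup_seq = rep(5L, length(lhs)),
                          sup_lhs = 5L, sup_rhs = 6L,
                          seq_sup = 0.5, seq_conf = 1.0, lift = 1.5,
                          cf = 1.0, conviction = Inf)
  df <- cbind(df, metrics)
  labf <- function(codes) paste(item_label(codes, codebook), collapse = "&")
  df$lhs_label <- vapply(df$lhs, labf, character(1))
  df$rhs_label <- vapply(df$rhs, labf, character(1))
  df$group <- group
  attr(df, "n_sequences") <- n_sequences
  attr(df, "codebook") <- codebook
  attr(df, "group") <- group
  class(df) <- c("RuleSet", "data.frame")
  df
}

# Small expression fixture written to disk for the reader tests
write_expression_fixture <- function(dir, drop_subject = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  probes <- paste0("pr", 1:4)
  samples <- c("s1.t1", "s1.t2", "s2.t1", "s2.t2")
  set.seed(42)
  mat <- matrix(round(stats::rnorm(16, 7, 1), 3), nrow = 4,
                dimnames = list(probes, samples))
  df <- data.frame(probe_id = probes, mat, check.names = FALSE)
  utils::write.table(df, file.path(dir, "matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sheet <- data.frame(sample_id = samples,
                      subject = rep(c("s1", "s2"), each = 2),
                      timepoint = rep(c("t1", "t2"), 2),
                      group = rep(c("A", "B"), each = 2))
  if (!is.null(drop_subject))
    sheet <- sheet[!(sheet$subject == drop_subject &
                       sheet$timepoint == "t2"), ]
  utils::write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dir
}
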