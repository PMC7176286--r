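test_that("frequent itemsets match exhaustive enumeration on the toy DB", {
  db <- toy_db_plus()
  A <- encode_item(2, 0, 3); B <- encode_item(1, 1, 3)
  f <- mine_frequent_itemsets(db, 0.5)
  keys <- vapply(f$items, paste, character(1), collapse = " ")
  expect_setequal(keys, c(paste(A), paste(B), paste(B, A)))  # sorted codes
  expect_identical(f$count, rep(3L, 3))
  expect_identical(nrow(mine_frequent_itemsets(db, 1.0)), 0L)
  expect_error(mine_frequent_itemsets(sequence_database(list()), 0.5),
               "empty")
})

test_that("candidate rules respect association confidence", {
  db <- toy_db_plus()
  f <- mine_frequent_itemsets(db, 0.5)
  cand <- generate_candidate_rules(f, 0.5)
  expect_identical(nrow(cand), 2L)  # A->B and B->A, both conf 1
  expect_true(all(cand$assoc_conf == 1))
  expect_identical(nrow(generate_candidate_rules(f, 1.01)), 0L)
})

test_that("sequence containment requires a cut point", {
  expect_true(sequence_contains(list(1L, 2L), 1L, 2L))
  expect_false(sequence_contains(list(c(1L, 2L)), 1L, 2L))  # no cut
  # LHS items may straddle itemsets before the cut
  expect_true(sequence_contains(list(1L, 3L, 2L), c(1L, 3L), 2L))
  expect_false(sequence_contains(list(2L, 1L), 1L, 2L))
})

test_that("rule metrics reproduce the hand-computed toy values", {
  m <- compute_rule_metrics(3L, 3L, 3L, 4L)
  expect_equal(m$seq_sup, 0.75)
  expect_equal(m$seq_conf, 1)
  expect_equal(m$lift, 4 / 3)
  expect_equal(m$cf, 1)
  expect_identical(m$conviction, Inf)

  m2 <- compute_rule_metrics(2L, 3L, 4L, 4L)
  expect_equal(m2$seq_sup, 0.5)
  expect_equal(m2$seq_conf, 2 / 3)
  expect_equal(m2$lift, 2 / 3)
  expect_equal(m2$cf, -1 / 3)
  expect_equal(m2$conviction, 0)

  # statistical independence: lift 1, cf 0
  m3 <- compute_rule_metrics(2L, 4L, 4L, 8L)
  expect_equal(m3$lift, 1)
  expect_equal(m3$cf, 0)

  expect_error(compute_rule_metrics(2L, 0L, 4L, 8L), "positive")
  expect_error(compute_rule_metrics(5L, 3L, 4L, 8L), "inconsistent")
})

test_that("the miner recovers the toy rules with exact counts", {
  rs <- mine_sequential_rules(toy_db_plus(), 0.5, 0.5)
  expect_identical(nrow(rs), 1L)
  expect_identical(rs$lhs_label, "pA/GA=2")
  expect_identical(rs$rhs_label, "pB/GB=1")
  expect_identical(rs$sup_seq, 3L)
  expect_equal(rs$seq_sup, 0.75)
  rsm <- mine_sequential_rules(toy_db_minus(), 0.5, 0.5)
  key <- paste(rsm$lhs_label, rsm$rhs_label)
  i <- match("pA/GA=2 pB/GB=1", key)
  expect_equal(rsm$seq_sup[i], 0.5)
  expect_equal(rsm$cf[i], -1 / 3)

  single <- sequence_database(list(list(7L, 8L)))
  one <- mine_sequential_rules(single, 1.0, 1.0)
  expect_identical(nrow(one), 1L)
  expect_equal(one$seq_sup, 1)
  expect_equal(one$seq_conf, 1)
})

test_that("miner output equals the brute-force oracle on random databases", {
  for (seed in 1:40) {
    db <- random_seqdb(seed)
    thr <- list(c(0.3, 0.3), c(0.5, 0.6))[[1L + seed %% 2L]]
    mined <- mine_sequential_rules(db, thr[1], thr[2], max_itemset = Inf)
    got <- ruleset_keys(mined)
    got <- got[order(got$lhs_key, got$rhs_key), , drop = FALSE]
    want <- oracle_mine(db, thr[1], thr[2])
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("sequential measures never exceed their flattened bounds", {
  for (seed in 41:55) {
    db <- random_seqdb(seed)
    rs <- mine_sequential_rules(db, 0.3, 0.3, max_itemset = Inf)
    if (!nrow(rs)) next
    tx <- lapply(db$sequences, function(s) unique(unlist(s)))
    n <- length(tx)
    for (i in seq_len(nrow(rs))) {
      both <- sum(vapply(tx, function(t)
        all(c(rs$lhs[[i]], rs$rhs[[i]]) %in% t), logical(1)))
      expect_lte(rs$sup_seq[i], both)                   # assoc support bound
      expect_lte(rs$seq_conf[i], both / rs$sup_lhs[i])  # assoc conf bound
    }
  }
})

test_that("raising either threshold never adds rules", {
  for (seed in 56:65) {
    db <- random_seqdb(seed)
    lo <- ruleset_keys(mine_sequential_rules(db, 0.3, 0.3,
                                             max_itemset = Inf))
    hi <- ruleset_keys(mine_sequential_rules(db, 0.5, 0.6,
                                             max_itemset = Inf))
    expect_true(all(paste(hi$lhs_key, hi$rhs_key) %in%
                      paste(lo$lhs_key, lo$rhs_key)))
  }
})

test_that("very strong filtering keeps positive-dependence rules only", {
  rs <- mine_sequential_rules(toy_db_plus(), 0.5, 0.5)
  kept <- filter_very_strong(rs, 0.45)
  expect_identical(nrow(kept), 1L)   # seq_sup 0.75 > 0.45, cf 1 > 0
  # literal variant: notsup 1/4 = 0.25 is not > 1 - 0.45
  expect_identical(nrow(filter_very_strong(rs, 0.45, variant = "literal")),
                   0L)
  expect_identical(
    nrow(filter_very_strong(rs, 0.45, variant = "counter_reciprocal",
                            not_sup_threshold = 0.2)), 1L)
  expect_error(filter_very_strong(rs, 0.45, variant = "counter_reciprocal"),
               "not_sup_threshold")
  # negative-dependence rules are dropped under every variant
  rsm <- mine_sequential_rules(toy_db_minus(), 0.4, 0.4)
  neg <- rsm[rsm$cf <= 0, , drop = FALSE]
  expect_gt(nrow(neg), 0L)
  for (v in c("cf_only", "literal")) {
    kept <- filter_very_strong(rsm, 0.4, v)
    expect_false(any(paste(kept$lhs_label, kept$rhs_label) %in%
                       paste(neg$lhs_label, neg$rhs_label)))
  }
})

test_that("certainty factor sign always agrees with lift", {
  for (seed in 66:80) {
    rs <- mine_sequential_rules(random_seqdb(seed), 0.3, 0.3,
                                max_itemset = Inf)
    if (!nrow(rs)) next
    expect_true(all(abs(sign(rs$cf) - sign(rs$lift - 1)) < 1e-12 |
                      (abs(rs$cf) < 1e-12 & abs(rs$lift - 1) < 1e-12)))
  }
})

test_that("contrast mining returns group-exclusive, disjoint rule sets", {
  cb <- toy_codebook()
  A <- encode_item(2, 0, 3); B <- encode_item(1, 1, 3)
  C <- encode_item(2, 2, 3)
  db_a <- sequence_database(rep(list(list(A, B)), 4), group = "a",
                            codebook = cb)
  # in b the A->B pattern is rare but C->B passes in both
  db_b <- sequence_database(c(list(list(A, B)), rep(list(list(C, B)), 3)),
                            group = "b", codebook = cb)
  ct <- mine_contrast(db_a, db_b, 0.5, 0.6)
  a_keys <- paste(ct$only_a$lhs_label, ct$only_a$rhs_label)
  b_keys <- paste(ct$only_b$lhs_label, ct$only_b$rhs_label)
  expect_true("pA/GA=2 pB/GB=1" %in% a_keys)
  expect_false("pA/GA=2 pB/GB=1" %in% b_keys)
  expect_length(intersect(a_keys, b_keys), 0L)
  cb2 <- toy_codebook(3)
  db_c <- sequence_database(list(list(A)), group = "c", codebook = cb2)
  expect_error(mine_contrast(db_a, db_c, 0.5, 0.5), "incompatible")
})

test_that("replication matching compares gene(+state) sets across cohorts", {
  cb1 <- make_codebook(data.frame(probe_id = c("p101", "p202"),
                                  gene_symbol = c("G1", "G2")), width = 3)
  cb2 <- make_codebook(data.frame(probe_id = c("p555", "p999"),
                                  gene_symbol = c("G2", "G1")), width = 3)
  r1 <- make_test_ruleset(list(encode_item(2, 0, 3)),
                          list(encode_item(1, 1, 3)), cb1, group = "d1")
  # different probes, same genes and states
  r2 <- make_test_ruleset(list(encode_item(2, 1, 3)),
                          list(encode_item(1, 0, 3)), cb2, group = "d2")
  groups <- match_rules(list(d1 = r1, d2 = r2))
  expect_length(groups, 1L)
  expect_setequal(groups[[1]]$dataset, c("d1", "d2"))

  # same genes but opposite states only match with ignore_state
  r3 <- make_test_ruleset(list(encode_item(1, 1, 3)),
                          list(encode_item(2, 0, 3)), cb2, group = "d2")
  expect_length(match_rules(list(d1 = r1, d2 = r3)), 0L)
  expect_length(match_rules(list(d1 = r1, d2 = r3), ignore_state = TRUE), 1L)

  expect_error(match_rules(list(d1 = r1)), ">= 2 rule sets")
})
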