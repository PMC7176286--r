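ann_fixture <- function() {
  annotation_table("BP", list(
    G1 = c("T1", "T2"), G2 = "T1", G3 = "T3",
    G5 = c("T1", "T5"), G6 = c("T1", "T5", "T6")))
}

test_that("cross matches need annotated genes on both sides", {
  ann <- ann_fixture()
  ms <- find_matches("G1", "G2", ann)
  expect_identical(ms$term, "T1")
  expect_setequal(ms$covered[[1]], c("G1", "G2"))
  expect_equal(attr(ms, "f_best"), 1)

  ms2 <- find_matches(c("G1", "G3"), "G2", ann)
  expect_identical(ms2$term, "T1")
  expect_equal(attr(ms2, "f_best"), 2 / 3)

  ms3 <- find_matches("G3", "G4", ann)
  expect_identical(nrow(ms3), 0L)
  expect_true(is.na(attr(ms3, "f_best")))

  # duplicated probes of one gene count once
  ms4 <- find_matches(c("G1", "g1"), "G2", ann)
  expect_equal(attr(ms4, "f_best"), 1)
})

test_that("categories follow the coverage-fraction bands", {
  ann <- ann_fixture()
  expect_identical(assign_category(find_matches("G1", "G2", ann)), 1L)
  expect_identical(assign_category(find_matches(c("G1", "G3"), "G2", ann)),
                   3L)
  expect_identical(assign_category(find_matches("G3", "G4", ann)), 5L)
  # 3 of 4 genes covered -> 0.75 -> category 2
  ms <- find_matches(c("G1", "G5", "G3"), "G2", ann)
  expect_equal(attr(ms, "f_best"), 3 / 4)
  expect_identical(assign_category(ms), 2L)
})

test_that("points sum covered genes over cross terms", {
  ann <- ann_fixture()
  expect_identical(compute_points(find_matches("G1", "G2", ann)), 2L)
  # T1 covers {G1,G5,G6}, T5 covers {G5,G6}: 3 + 2 points
  ms <- find_matches(c("G1", "G5"), "G6", ann)
  expect_identical(compute_points(ms), 5L)
  expect_identical(compute_points(find_matches("G3", "G4", ann)), 0L)
})

test_that("ranking scores are corpus-relative within category", {
  cb <- make_codebook(data.frame(
    probe_id = paste0("p", 1:4),
    gene_symbol = c("G1", "G2", "G3", "G4")), width = 3)
  it <- function(gene_idx, state = 2L) encode_item(state, gene_idx - 1L, 3)
  rs <- make_test_ruleset(
    lhs = list(it(1), c(it(1), it(3)), it(3)),
    rhs = list(it(2), it(2), it(4)), cb)
  scored <- score_ruleset(rs, ann_fixture())
  det <- attr(scored, "score_detail")
  expect_identical(det$category, c(1L, 3L, 5L))
  expect_identical(det$np, c(2L, 2L, 0L))
  expect_equal(scored$bp, c(1 + (1 - 2 / 3), 3 + (1 - 2 / 3), 6.0))

  # single rule: maxNP is its own NP -> score = cat + 1/(np+1)
  one <- make_test_ruleset(list(it(1)), list(it(2)), cb)
  s1 <- score_ruleset(one, ann_fixture())
  expect_equal(s1$bp, 1 + 1 / 3)

  # all-category-5 sets score exactly 6
  none <- make_test_ruleset(list(it(3)), list(it(4)), cb)
  s5 <- score_ruleset(none, ann_fixture())
  expect_equal(s5$bp, 6.0)
  expect_error(score_ruleset(none[0, ], ann_fixture()), "empty")
})

test_that("scores stay in (1,6], improve with points, ignore rule order", {
  set.seed(9)
  cb <- make_codebook(data.frame(probe_id = sprintf("p%02d", 1:12),
                                 gene_symbol = sprintf("G%02d", 1:12)),
                      width = 3)
  genes <- sprintf("G%02d", 1:12)
  terms <- split(sample(paste0("T", 1:6), 30, replace = TRUE),
                 sample(genes, 30, replace = TRUE))
  ann <- annotation_table("MF", terms)
  it <- function(i) encode_item(2L, i - 1L, 3)
  lhs <- lapply(1:10, function(i) it(sample(12, 1)))
  rhs <- lapply(1:10, function(i) it(sample(12, 1)))
  rs <- make_test_ruleset(lhs, rhs, cb)
  scored <- score_ruleset(rs, ann)
  det <- attr(scored, "score_detail")
  expect_true(all(scored$mf > 1 & scored$mf <= 6))
  for (ct in unique(det$category)) {
    d <- det[det$category == ct, ]
    if (nrow(d) > 1)
      expect_true(all(diff(d$score[order(d$np)]) <= 1e-12))
  }
  # permutation invariance
  perm <- sample(nrow(rs))
  rs2 <- rs[perm, ]
  attr(rs2, "codebook") <- cb
  class(rs2) <- class(rs)
  scored2 <- score_ruleset(rs2, ann)
  expect_equal(scored2$mf, scored$mf[perm])
})

test_that("a term shared by all rule genes never worsens the category", {
  cb <- make_codebook(data.frame(probe_id = c("p1", "p2"),
                                 gene_symbol = c("G1", "G3")), width = 3)
  rs <- make_test_ruleset(list(encode_item(2, 0, 3)),
                          list(encode_item(2, 1, 3)), cb)
  before <- attr(score_ruleset(rs, ann_fixture()), "score_detail")$category
  ann2 <- annotation_table("BP", list(G1 = c("T1", "T2", "TX"),
                                      G3 = c("T3", "TX")))
  after <- attr(score_ruleset(rs, ann2), "score_detail")$category
  expect_lte(after, before)
})

test_that("TF measure climbs the milestone ladder", {
  dn <- function(g) data.frame(gene = g, state = 1L)
  up <- function(g) data.frame(gene = g, state = 2L)
  # down TF with repression: target up direction-matches -> 3
  tab <- tf_table("TF1", "G2", "Repression")
  expect_identical(rule_tf_score(dn("TF1"), up("G2"), tab), 3L)
  # repression with same direction does not match -> 2
  expect_identical(rule_tf_score(dn("TF1"), dn("G2"), tab), 2L)
  # Unknown mode can never direction-match
  tab2 <- tf_table("TF4", "G5", "Unknown")
  expect_identical(rule_tf_score(dn("TF4"), dn("G5"), tab2), 2L)
  # LHS TF without its target on the RHS
  tab3 <- tf_table("TFX", "GY", "Activation")
  expect_identical(rule_tf_score(up("TFX"), up("GZ"), tab3), 1L)
  # no LHS TF at all
  expect_identical(rule_tf_score(up("GA"), up("G2"), tab), 0L)
  # activation matches equal states
  tab4 <- tf_table("TF9", "G9", "Activation")
  expect_identical(rule_tf_score(up("TF9"), up("G9"), tab4), 3L)

  # monotone in table content: adding rows never lowers the score
  set.seed(4)
  for (i in 1:10) {
    lhs <- data.frame(gene = sample(c("TF1", "TFX", "GA"), 2),
                      state = sample(1:2, 2, replace = TRUE))
    rhs <- data.frame(gene = sample(c("G2", "GY", "GZ"), 2),
                      state = sample(1:2, 2, replace = TRUE))
    small <- tf_table("TF1", "G2", "Repression")
    big <- tf_table(c("TF1", "TFX", "TFX"), c("G2", "GY", "GZ"),
                    c("Repression", "Activation", "Unknown"))
    expect_gte(rule_tf_score(lhs, rhs, big),
               rule_tf_score(lhs, rhs, small))
  }
})

test_that("the XML match report round-trips terms and covered genes", {
  cb <- make_codebook(data.frame(probe_id = c("p1", "p2"),
                                 gene_symbol = c("G1", "G2")), width = 3)
  rs <- make_test_ruleset(list(encode_item(2, 0, 3)),
                          list(encode_item(1, 1, 3)), cb)
  ann <- ann_fixture()
  rs <- score_ruleset(rs, ann)
  path <- withr::local_tempfile(fileext = ".xml")
  write_match_report(rs, list(ann), path)
  doc <- xml2::read_xml(path)
  rules <- xml2::xml_find_all(doc, "//rule")
  expect_length(rules, 1L)
  matches <- xml2::xml_find_all(rules[[1]], "match")
  expect_identical(xml2::xml_attr(matches, "term"), "T1")
  expect_identical(xml2::xml_attr(matches, "genes"), "G1,G2")
  expect_identical(xml2::xml_attr(matches, "namespace"), "BP")

  # a rule without matches keeps its node with zero children
  cb2 <- make_codebook(data.frame(probe_id = c("p1", "p2"),
                                  gene_symbol = c("G3", "G4")), width = 3)
  rs2 <- make_test_ruleset(list(encode_item(2, 0, 3)),
                           list(encode_item(1, 1, 3)), cb2)
  write_match_report(rs2, list(ann), path)
  doc2 <- xml2::read_xml(path)
  expect_length(xml2::xml_find_all(doc2, "//rule"), 1L)
  expect_length(xml2::xml_find_all(doc2, "//match"), 0L)
})
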