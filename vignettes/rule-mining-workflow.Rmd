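---
title: "Mining time-lagged gene-gene rules from longitudinal expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining time-lagged gene-gene rules from longitudinal expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqruleged)
```

## The problem and the model

Long-term human interventions (dietary programs, clinical trials) profile
each subject's transcriptome at a handful of timepoints. Gene regulation
in such designs is often time-lagged: a change in a regulator during one
period is followed by changes in its targets during the next. seqruleged
mines such relations as *sequential rules* `LHS -> RHS`, where every LHS
item (a discrete up/down event of one probe in one time interval) occurs
before every RHS item within a subject's event sequence.

The pipeline has three stages.

**1. Preprocessing.** Expression is assumed normalized on the log2 scale
(e.g. RMA upstream). For each time interval the *signal log ratio* (SLR)
of a probe is the log2 value at the interval end minus at the start, so
+1 is a doubling and -1 a halving of transcript abundance. Feature
selection keeps, per interval and group, the probes whose mean SLR passes
a paired t-test against zero (Bonferroni-adjusted p below `alpha`) with
`|mean SLR| >= lfc`; a probe enters downstream analysis when it is
selected in *any* interval or group. Each subject's SLR is then
discretized per selected probe and interval into three states — 2
(increase), 1 (decrease), 0 (no change) — by strict comparison against
the group-mean SLR: for a positively selected probe a subject is an
"increase" only when its SLR strictly exceeds the group mean. Using the
group mean as the threshold focuses the discretization on the cohort-wide
intervention response rather than individual idiosyncrasy; the strict
inequality means equality with the mean is always "no change", and when
every subject moves identically no event is emitted at all (the change
carries no between-subject signal).

**2. Knowledge extraction.** Nonzero states become integer-coded items
(leading digit = state, remaining digits = a stable, lexicographically
assigned probe index), one itemset per consecutive "mining" interval, one
sequence per subject. The overall first-to-last interval participates in
feature selection only: it overlaps the consecutive intervals and would
duplicate their events in the sequences. Rules are mined in two phases:
an Apriori pass over sequences flattened to transactions, followed by
sequential counting with a cut point — a sequence supports `LHS -> RHS`
if some position splits it so that all LHS items occur at or before the
split and all RHS items after it. The flattened pass is a sound pruning
bound, because ordered containment implies unordered containment: a
rule's sequential support never exceeds its flattened association
support, and likewise for confidence. Each surviving rule carries five
frequentist metrics:

* `seqSup = sup(LHS -> RHS) / |SD|`, the fraction of sequences
  containing the rule in order;
* `seqConf = sup(LHS -> RHS) / sup(LHS)`;
* `lift = seqSup / (sup(LHS)/|SD| * sup(RHS)/|SD|)`;
* certainty factor `CF`, the normalized change in RHS probability given
  the LHS, in [-1, 1];
* `conviction = (1 - sup(RHS)/|SD|) / (1 - seqConf)`.

The sequential analogues substitute sequence-containment fractions for
transaction supports; metrics keep their usual reading (lift > 1,
CF > 0, conviction > 1: positive dependence). `conviction` is defined as
`+Inf` whenever `seqConf = 1` — including the degenerate 0/0 case where
the RHS also occurs in every sequence — because a perfectly confident
rule is a perfect implication.

**3. Functional validation.** Each rule is scored against external
biological knowledge: four annotation measures (BP/MF/CC for GO-style
namespaces, SP for pathways) and a TF measure from a TF-target
regulation table (TRRUST-style). For the annotation measures, only
*cross* terms count — terms annotating at least one gene on each side of
the rule — so a rule is rewarded for coherence across the temporal
divide, not for a big LHS that shares terms internally. The rule's
category (1 best .. 5 worst) comes from the best term's coverage
fraction `f_best` = covered genes / distinct rule genes, with bands
1 / >= 0.75 / >= 0.5 / any cross match / none; its points `NP` are the
total genes covered over all cross terms; and the score is
`CAT + (1 - NP / (maxNP in category + 1))`, where the maximum is taken
within the same category of the *same rule set*. Scores therefore live
in (1, 6], lower is better, and a category-5 rule with no matches scores
exactly 6. The TF measure climbs milestones 1 (an LHS gene is a listed
TF), 2 (an RHS gene is one of its targets), 3 (the regulation mode
matches the discrete states: Activation means equal states, Repression
opposite states, Unknown never matches); the rule keeps the highest
milestone over all TF-target pairs.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `alpha` | 0.05 | adjusted p | conventional family-wise error after Bonferroni |
| `lfc` | 1.0 | log2 units | two-fold change; inclusive (`>=`) |
| `min_seq_sup` | 0.45 | fraction of subjects | discovery-scale default for ~24-subject arms (support count 11/24) |
| `min_seq_conf` | 0.4 | fraction | permissive phase-2 floor; confidence of kept rules is typically far higher |
| `max_itemset` | 4 | items | caps the candidate lattice; truncation is logged |
| `very_strong` | `cf_only` | — | see below |
| `prior_df` | 4 | df | moderated-t prior weight, a weakly informative choice for n ~ 10-25 |
| `bands` | 1/0.75/0.5 | coverage fraction | category boundaries of the annotation score |

Bonferroni uses the number of probes as the family size, separately per
interval and group: each interval/group combination is tested as its own
family, matching a per-interval differential-expression analysis. The
"moderated" selection variant shrinks per-probe variances toward the
family mean variance with `prior_df` prior degrees of freedom; the plain
paired t is the default because it is assumption-light and exactly
reproducible with `stats::t.test`.

**Very-strong filtering.** A rule is worth keeping when both it and its
counter-reciprocal (not-RHS implies not-LHS) have support. The default
`cf_only` variant requires `seqSup > min_seq_sup` and `CF > 0`; CF is
precisely the sign test of positive dependence, and the counter-reciprocal
of a rule has the same CF sign. The `literal` variant additionally
requires the fraction of sequences containing *neither* side to exceed
`1 - min_seq_sup`; note that at the default thresholds this condition is
very restrictive (with support above 0.45 at most 0.55 of sequences can
contain neither side, and the inequality is strict), so `cf_only` is the
default and a free threshold is exposed as `counter_reciprocal`.

## What the generator simulates — and what it does not

`simulate_dataset()` emulates a two-arm intervention cohort: by default
24 + 22 subjects (the discovery design this package targets), three
timepoints, 200 probes with one gene each, baseline log2 intensities
Normal(7, 1) per subject-probe, and i.i.d. Normal(0, 0.2) measurement
noise. A planted rule adds a signed effect (default 2.0 log2 units) to
the LHS probe from timepoint 2 onward and to the RHS probe from
timepoint 3 onward in a deterministic, seed-driven subset of
`round(penetrance * n)` carriers. The default effect of 2.0 is chosen so
that at the reference penetrance of 0.6 the group-mean SLR (0.6 x 2.0 =
1.2) clears the selection threshold of 1 by construction — an effect of
1.5 at that penetrance would be filtered out before mining ever sees it,
which is a property of the selection rule, not of the miner.

The generator deliberately omits probe-specific affinities, batch
effects, subject-level random effects, correlated noise and
multiple-probes-per-gene designs. Passing tests on this generator
therefore demonstrate the *algorithmic* contract (recovery of planted
temporal structure at known penetrance, exact support accounting,
determinism), not robustness to microarray artifacts; on real data the
preprocessing quality (normalization, batch correction) remains the
user's responsibility.

The test suite and the workflow examples run at desk scale: random
mining databases of up to 8 items and 6 sequences checked against a
brute-force enumerator, and synthetic cohorts of 2 x 24 subjects x 200
probes, which keeps the whole suite near ten seconds while still
exercising every stage at the reference design's subject counts.

## Numerical and representational choices

* **Ties at the discretization threshold** go to "no change" (strict
  inequalities), so a subject exactly at the group mean never becomes an
  event.
* **Zero-variance SLRs** with nonzero mean give `t = +/-Inf`, `p = 0`,
  and are flagged (`zero_var`); all-equal-and-zero gives `t = 0`.
* **Threshold comparisons** in the miner use a 1e-12 slack so that
  fractions like 0.45 computed as 10.8/24 are not lost to floating-point
  representation.
* **Output order** of rules is fixed: decreasing (seqConf, seqSup), then
  lexicographic labels — mining is fully deterministic and rerunning a
  pipeline reproduces its rule tables byte for byte.
* **Item codes** are `state * 10^width + probe_index` with width 4 by
  default (10,000 probes after selection; auto-widened with a warning);
  indices are assigned by a stable sort of probe ids and persisted in a
  sidecar codebook so codes are comparable across stages and runs.
* **Empty itemsets are kept** in sequences (and written as a bare `-1`
  in the SPMF dialect): they preserve ordinal positions and keep |SD|
  honest in every support denominator — a subject with no events still
  counts against support.
* **LHS and RHS must be disjoint item sets**, but the same gene may
  appear on both sides through different items (state or interval),
  which is exactly how feedback-loop rules (a gene predicting its own
  later rebound) are expressed.
* **Rule persistence** uses a documented TSV / JSON-lines schema with
  items serialized as `probe/GENE=state`; infinite conviction is written
  as the literal `Inf` and read back as such.

## Design choices that were genuinely open

* The annotation score's category bands and per-match weights (covered
  genes per term) implement the stated intent — rules whose genes all
  share a term rank best, and the score must not reward side size — with
  the simplest monotone choices; both are configurable arguments.
* The TF measure is read as the *highest milestone attained* rather than
  an all-or-nothing score, since observed scores of 1 (TF present,
  target absent) are meaningful and reported.
* Phase 1 of the miner prunes with `min_conf = min_seq_conf` rather
  than 0; the association bound proves either choice sound, and the
  tighter one is faster.
* Cross-cohort replication matches rules at the gene(+state) level,
  dropping probe ids (different array platforms name probes
  differently); `ignore_state = TRUE` additionally matches opposite
  regulation directions across cohorts.
* Subjects with incomplete timepoint series are a hard error by default
  (`drop_incomplete = TRUE` excludes them with a warning): silent
  complete-case analysis hides cohort attrition.

## Worked example

```{r example, eval = FALSE}
rules <- list(
  planted_rule("G0001", "up", "G0002", "down", penetrance = 0.75,
               group = "VLCD"))
cfg <- sim_config(groups = c(VLCD = 12L, LCD = 12L), n_probes = 60L,
                  rules = rules, seed = 5L)
sim <- simulate_dataset(cfg)
ann <- simulate_annotations(sim$truth, seed = 5L)
write_simulation(sim, ann, "fixture")

run_pipeline(list(
  matrix = "fixture/matrix.tsv", samples = "fixture/samples.tsv",
  probe_map = "fixture/probe_map.tsv",
  annotations = list(BP = "fixture/bp.gmt"),
  tf_table = "fixture/tf_table.tsv",
  min_seq_sup = 0.45, min_seq_conf = 0.4, seed = 5L), "out")

read_rules("out/rules_VLCD.tsv")
```

The planted rule comes back with `sup_count = 9` (the 9 of 12 carriers),
`seq_conf = 1`, `conviction = Inf`, `tf = 3` (its planted up->down pair
is a Repression row in the simulated TF table) and a BP score of 1.33
(category 1: the planted shared term covers both genes; 2 points against
a category maximum of 2).

## Known limitations

* The Apriori phase is exponential in the number of frequent co-occurring
  items; `max_itemset` (default 4) bounds it, at the cost of silence
  about longer rules. Post-selection probe panels in the hundreds are
  the intended regime.
* Sequences are ordinal: the miner knows event order, not calendar time,
  so unequal interval lengths are invisible to it.
* Annotation scores use identical-term matches only; semantic similarity
  over an ontology graph (partial term relatedness) is out of scope.
* The moderated selection variant is a simple shrinkage, not a full
  empirical-Bayes fit; users wanting exact parity with established
  differential-expression tools should select probes externally and pass
  the reduced matrix in.
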