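---
title: "Methods: network pharmacology of multi-herb medicines with tcmnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network pharmacology of multi-herb medicines with tcmnp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmnp)
```

## Scope and data model

`tcmnp` implements the standard network-pharmacology workflow for
multi-herb traditional medicines as a chain of small, independently
testable stages:

1. literature-based herb–disease association,
2. ADME screening of herbal ingredients (oral bioavailability +
   Tanimoto drug-likeness, with an explicit rescue list),
3. consensus acceptance of compound–target interaction scores,
4. bipartite compound–target and target–pathway network construction
   with herb-role (Jun–Chen–Zuo–Shi) classification,
5. gene-set over-representation analysis of the accepted targets,
6. physicochemical descriptor comparison against a reference drug
   collection.

All tabular inputs are plain delimited text (tab-separated with a
header by default, comma-separated via the `sep` argument), gene sets
are standard GMT, and networks export to SIF and GraphML so they load
directly into Cytoscape-style tools. The package ships transcribed
study tables for a 20-herb breast-cancer formula (150 screened
ingredients, per-herb literature counts, 33 curated protein targets)
plus seeded generators, so every stage runs and is tested entirely
offline.

Compound OB values and RF/SVM interaction scores are *inputs*, never
computed: the upstream predictors that produce them are proprietary
pretrained models and are out of scope. The screening and consensus
stages are therefore pure, reproducible decision rules over supplied
scores.

## Herb–disease association

With a corpus of $N$ articles of which $K$ are disease-relevant, a herb
appearing in $n$ articles, $k$ of them disease-relevant, is scored by
the upper tail of the hypergeometric distribution,
$P(X \ge k)$ for $X \sim \mathrm{Hyper}(N, K, n)$.
The printed form of this statistic in the source literature writes the
summation bounds inconsistently (both $i = 1$ and $i = 0$ as the lower
index of the subtracted sum); we implement the standard one-sided
enrichment reading, the survival function $P(X \ge k)$.

Numerics: the corpus here has $N \approx 1.05\times 10^8$, so binomial
coefficients are never formed. The implementation delegates to
`stats::phyper(..., lower.tail = FALSE)`, which works on log
probabilities internally, and the package exposes `log.p = TRUE`
directly. Herb selection compares log-p against `log(alpha)`: this
keeps the rule correct even when a p-value underflows double precision
(a common event at corpus scale — several packaged herbs have p-values
below `1e-308`), and makes `alpha = 0` select nothing, as it should.

Defaults: `alpha = 0.01`, per-herb with no multiplicity correction,
matching the study convention the package reproduces; a
Benjamini–Hochberg option (`adjust = "BH"`) is available for users who
prefer family-wise control over a herb panel.

Tests verify the implementation against a brute-force enumeration
oracle (direct summation of $\binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}$)
for every corpus size up to 60, plus the monotonicity
($p(k{+}1) \le p(k)$) and complement ($P(X \ge k) + P(X \le k{-}1) = 1$)
identities at random parameter draws.

## ADME screening

**Drug-likeness.** DL is the Tanimoto coefficient
$F(A,B) = A\cdot B / (|A|^2 + |B|^2 - A\cdot B)$ between a compound's
property vector and the average vector of a reference drug collection.
The vector space of the original screen (raw descriptors, scaled
descriptors, or fingerprints) is not published; `tcmnp` defaults to the
eight-descriptor vector with each component divided by the reference
set's per-component standard deviation before the Tanimoto product.
Without this scaling, molecular weight (hundreds of Da) dominates the
dot product and the other seven descriptors are numerically irrelevant;
with it, the statistic is deterministic, dependency-light and unit-free.
`compute_dl()` itself is the bare coefficient, so users can supply any
vectorization they prefer.

**Thresholds.** `ob_min = 30` (percent, on the printed scale: `36.91`
means 36.91%) and `dl_min = 0.18` (a fraction). Both comparisons are
*inclusive* (`>=`), following the stated selection rules; the packaged
compound table contains threshold-boundary cases that the tests pin.

**Rescue list.** Real studies retain a few compounds that fail the
thresholds on pharmacological grounds. This is modelled as an explicit
set of compound ids in `screen_config()` — auditable configuration, not
an algorithm — and every screened compound receives a reason code
(`passed_both`, `rescued`, `failed_ob`, `failed_dl`, `failed_both`).
The packaged table reproduces the known example: 32 Radix Salviae
ingredients of which 28 pass and 4 (`DS15`, `DS19`, `DS21`, `DS32`) are
rescued. Rows of the packaged table outside Radix Salviae that sit
below the thresholds carry `rescued = TRUE` in the fixture so that the
150-record table is self-consistent; the source text prints no
per-compound justification for those, which is a transcription caveat,
not a property of the method.

**Deglycosylation.** Oral administration exposes glycosides to
intestinal glycosidases, so screens conventionally add the aglycone
(`_qt`) product as its own record. `deglycosylate()` is a record-level,
best-effort implementation: O-linked sugar units are detected and
cleaved textually against a small library of pyranose SMILES fragments
(glucosyl and rhamnosyl patterns), every sugar is cleaved, the parent
record is retained, and the derivative gets the `_qt` suffix with OB,
DL and descriptors cleared for recomputation. Records flagged as
glycosides without a structure produce a cleared `_qt` record directly.
This is deliberately not a chemistry engine: unparsable or exotic
structures pass through untouched with a warning, and realistic
glycoside chemistry is a declared non-goal.

## Target consensus

A pair is accepted when `rf_score > 0.8` **and** `svm_score > 0.7` —
strict inequalities, following the stated "greater than" rule, which
the tests pin at the boundary (a score of exactly 0.8 is rejected). An
optional whitelist (defaulting in the packaged study to the 33 curated
targets) restricts acceptance to a disease-relevant panel; the curation
of that panel is not an algorithm and is represented only as the list
itself. The filter is idempotent and monotone in both thresholds
(property tests).

For synthetic work, `surrogate_scores()` replaces the pretrained
models: each herb has a tier mean, each compound draws
Poisson(tier-mean) planted links that score above both thresholds with
probability `edge_strength`, and a configurable number of sub-threshold
decoy pairs is appended. It is deterministic per seed.

## Networks and herb roles

`build_ct_network()` connects candidates to accepted targets,
de-duplicates pairs (with a warning), drops compounds with no accepted
target into a reported `dropped` list, and includes target nodes only
when incident to an edge. Graphs are stored as igraph objects with
`kind` and `herb_id` vertex attributes; bipartiteness and the
degree-sum identity ($\sum$ left degrees $= \sum$ right degrees
$= |E|$) are enforced by construction and re-checked property-style.

Herb roles formalize the traditional Jun–Chen–Zuo–Shi reading of such
networks, which in the source literature is narrative (read off a
figure). The implemented rule: rank herbs by
(`n_active_compounds`, `total_degree`) descending; rank 1 is Jun
(monarch); the next `floor(chen_fraction * H)` are Chen (ministers);
the remainder are Zuo–Shi (assistants/guides, merged because the two
roles are never separated computationally). Remaining ties break
lexicographically on `herb_id` and are flagged. Two notes on this
design:

* `floor` rather than `ceiling`: with the default
  `chen_fraction = 0.35`, floor gives the expected 1/7/12 split at 20
  herbs *and* keeps a 3-herb toy example at 1 Chen; a ceiling rule
  would promote a second herb to Chen in small panels, which
  contradicts how the tiering is used.
* This is an explicit, configurable interpretation of a qualitative
  rule, not a published algorithm; `chen_fraction` is a parameter
  precisely because the minister tier's size is a narrative choice.

`build_tp_network()` links targets to the gene sets containing them and
reports how many targets participate in two or more pathways.

## Enrichment

`ora()` performs hypergeometric over-representation of a selected
target set against a GMT collection over an explicit universe (each set
is intersected with the universe before testing; the same survival
function as the association stage is reused, and the tests compare it
against enumeration for universes up to size 40). Retention uses the
*raw* p-value at `alpha = 0.05`, matching the reproduced workflow;
Benjamini–Hochberg adjusted values are always reported alongside, and
retention can be switched to them. The `"ease"` variant (testing
$k - 1$ overlaps) is provided because service-based workflows often
report that conservative score; which variant underlay the original
p ≤ 0.05 rule is not stated anywhere, so `"standard"` is the default.
`top_terms()` truncates the ranked list (default 20) with ties broken
by term id.

## Descriptor comparison

`compare_groups()` compares each of the eight descriptors between two
groups. The original analysis does not name its test; the default here
is Welch's unequal-variance t-test, because the published group
standard deviations are strongly unequal (e.g. MW SD 113.89 vs 208.89),
and a two-sided permutation test on the mean difference (10,000
resamples by default) serves as both a config option and the validation
oracle — the tests require |p_Welch − p_perm| ≤ 0.02 on n = 50 draws.
Significance tiers are mutually exclusive (`p<0.01`, `p<0.05`, `ns`)
with no correction across the eight descriptors, mirroring the starred
two-tier table convention. Identical constant groups are reported as
`ns` (no evidence of a difference) rather than erroring on a zero
variance.

## Synthetic data: what it does and does not emulate

`sim_config()` defaults encode the packaged study's scale, chosen once
as the study conditions:

* 20 herbs in 1/7/12 role tiers; tier mean accepted-targets-per-compound
  12 / 7.24 / 6.74; nominal per-herb candidate counts 32 / 6 / 4
  (approximating the published tier totals 32/41/57);
* a 1618-compound pool with expected pass fraction 150/1618 through the
  OB/DL filter, allocated so the monarch tier carries proportionally
  more passing compounds;
* descriptors drawn independently per column from Gaussians at the
  published group means/SDs (MW and TPSA truncated at 0, count
  descriptors rounded and clipped at 0);
* 33 targets; 20 gene sets (19 decoys plus `term_planted`) over a
  universe of 3× the target roster, so a selected target set can show
  genuine over-representation;
* corpus N = 104,544,921, K = 791,592 with per-herb literature
  enrichment factor 3 (factor 1 is a null herb).

One root seed drives everything; per-generator streams are derived by
fixed offsets, so each stage is independently reproducible, and all
generators restore the caller's RNG state.

What the generator does **not** emulate: correlated descriptors (no
copula; real MW/TPSA/acceptor counts are strongly correlated), valid
chemistry (SMILES exist only for the small deglycosylation test pool),
target promiscuity structure (links are uniform over targets rather
than hub-biased, so degree distributions of real target panels —
e.g. an estrogen-receptor hub — are not reproduced), and literature
count over-dispersion (k is binomial given n). Passing the synthetic
recovery tests therefore demonstrates that the pipeline's inference
recovers planted structure under its own assumptions, not that those
assumptions hold for any particular real dataset.

Under the default screening-based scenario the Chen and Zuo–Shi tiers
overlap in realized candidate counts (7.4 vs 4.9 expected per herb with
Poisson-scale noise), so exact recovery of the *middle* tiers is not
expected and not asserted; the exact-tier recovery test instead uses
`gen_candidate_table()`, which plants the candidate counts exactly.
The monarch herb is recovered in both regimes.

## Problem sizes used in the test suite

The suite exercises: enumeration-oracle sweeps over all corpus sizes
N ≤ 60 and ORA universes ≤ 40; 10,000-replicate type-I calibration of
the association test at n = 50,000 articles (rejection rate 0.01 ±
0.004); tier-mean recovery at ~1000 compounds per tier (tolerance
±0.5); role-tier recovery over 40 seeded replicates; and 10,000-draw
descriptor cohorts for CLT-bound checks. These sizes were chosen to
make Monte-Carlo error comfortably smaller than each tolerance while
keeping the default test run fast on a single CPU.

## Known limitations

* OB and interaction scores must be supplied (or simulated); the
  package deliberately contains no bioavailability or chemogenomic
  predictor.
* The DL vector space is a documented choice, not a reconstruction —
  published per-compound DL values cannot disambiguate it, so packaged
  DL values are used as printed rather than recomputed.
* Deglycosylation is textual pattern matching over common pyranose
  fragments; it will miss unusual sugar encodings and does not
  canonicalize products beyond string identity.
* The Jun–Chen–Zuo–Shi tiering is an explicit formalization of a
  narrative rule; different `chen_fraction` choices give different
  minister tiers, and ties at tier boundaries are resolved
  lexicographically (and flagged) rather than scientifically.
* Enrichment results depend entirely on the supplied GMT collection
  and universe; no ontology traversal or term de-redundancy is done.
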