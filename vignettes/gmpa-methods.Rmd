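---
title: "Predicting metalloproteins from fractionation data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting metalloproteins from fractionation data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Native (non-denaturing) chromatographic fractionation of a biomass extract,
with every fraction profiled both by ICP-MS (elemental metal concentrations)
and by tandem MS (protein identifications via peptide spectra), makes it
possible to ask proteome-wide which proteins travel with which metals —
without purifying anything to homogeneity. The two data types are
heterogeneous: ICP-MS is quantitative, MS/MS here is effectively
presence/absence (peptide counts are only locally semi-quantitative). The
methods in this package therefore avoid comparing peak shapes or intensities
and work from co-occurrence in fraction space alone.

The pipeline is: inclusion filter → Boolean presence matrix → metal-peak
regions → per-pair association score → per-metal significance curve →
co-occurrence clustering (the metalloprotein count estimate) → greedy peak
set cover (a lower-bound sanity check) → optionally, keyword-based metal
classification of protein domain annotations.

## Data model

Experiments are three TSV tables (`fractions`, `metals`, `observations`)
validated on load; fractions carry an explicit 0-based `order_index` within
their separation, so elution order never leans on identifier spelling.
Proteins enter the analysis only if they reach two or more peptides in at
least one fraction (`filter_proteins()`, `min_peptides = 2`). The rule is
applied dataset-wide — one confident identification makes every sighting of
that protein trustworthy — rather than per fraction; per-fraction
application would silently delete all single-peptide sightings of otherwise
well-supported proteins, discarding exactly the low-abundance tail this
approach exists to recover. The alternative is available by filtering the
observation table directly before loading.

## Metal peaks

A metal peak is a contiguous run of at least two fractions, within one
separation, whose concentrations stand substantially above the surrounding
baseline in *every* technical replicate. Manually curated region tables are
the primary path (`load_peak_regions()`); `detect_peaks()` formalizes the
visual rule for automated use:

* per replicate, the local background of a candidate fraction is the
  **median** concentration over the `window` (default 5) nearest
  non-flagged fractions on each side, taking the **minimum of the two side
  medians**. At a peak edge one side always looks into clean baseline, so a
  peak cannot hide inside its own background window; a plain centred
  window stalls on peaks wider than half the window, and a nearest-`k`
  window is asymmetric at right-hand peak edges where distance ties fall
  back into the peak.
* a fraction is flagged when every replicate exceeds `fold` (default 3)
  times its background. Sweeps are synchronous and iterate to a fixpoint,
  with flagged fractions removed from all background windows, so wide
  peaks are climbed from their edges inwards and the result does not
  depend on scan order.
* maximal contiguous flagged runs of at least `min_len = 2` fractions
  become regions.

Raising `fold` never adds a flagged fraction. Peaks wider than about twice
the window cannot be fully flagged; choose `window` at least as large as
the widest peak you expect. The defaults are calibrated for sharp
enrichment peaks (several-fold over baseline) and make no claim to
reproduce any particular manual curation.

## The association score

For protein $p$ and metal $m$, with $f$ fractions in the analysis universe,
$f_m$ of them inside peaks of $m$, $f_p$ containing $p$, and $f_{pm}$ the
overlap, the score is the hypergeometric upper tail

$$G(p, m) = \sum_{n = f_{pm}}^{\min(f_p, f_m)}
\frac{\binom{f_m}{n}\binom{f - f_m}{f_p - n}}{\binom{f}{f_p}}
= P(X \ge f_{pm}),$$

the probability of at least the observed overlap if the protein's fractions
were scattered uniformly at random. It is computed through the
hypergeometric survival function (`phyper`), never factorials. Strong
associations underflow double precision, so the linear-scale score is
floored at $10^{-300}$ and a log-scale companion (`gmpa_ln_score()`,
computed with `log.p = TRUE`) is carried through all downstream fitting and
filtering; every comparison against a curve happens in log space, where the
floor is consistent and no precision is lost.

The analysis universe is the set of fractions in the presence matrix — the
level actually analysed — not every fraction ever collected; restrict the
fraction table before building the matrix to change it.

## Significance curves

Occurrence frequency dominates the raw score, so each metal gets an
exponential curve through (occurrences, score) space:
$\mathrm{curve}(k) = \exp(a + c\,b\,k)$, where $(a, b)$ is the
least-squares regression of log-score on occurrences over **all** proteins
of the metal and $c > 0$ rescales only the exponent. Proteins at or below
the curve (boundary inclusive) with at least `min_occurrences = 10`
occurrences are significant; rarer proteins cannot support any conclusion
and are removed regardless of score.

* **Anchored curves** (`set_reference_curve()`): for metals with known
  metalloproteins, $c$ is the minimum over qualifying references of
  $(\ln s_r - a) / (b\,k_r)$, which guarantees every qualifying reference
  ends up significant. References seen in fewer than `min_occurrences`
  fractions do not qualify and are not guaranteed.
* **Ratio cap** (`c_max = 2`): the curve may fall at most twice as fast as
  the regression. Without the cap, a single reference with an
  astronomically small score drives $c$ arbitrarily high; the anchored
  curve then over-fits that reference and its ratio is useless for
  extrapolation. Capping can only *raise* the curve, so the
  reference-capture guarantee is unaffected.
* **Extrapolated curves**: metals without usable references borrow the
  arithmetic mean of the anchored metals' ratios, applied to their own
  regression. Averaging per-metal ratios (not pooling reference proteins)
  keeps metals with many references from dominating.
* **Fallback**: with no references anywhere, the regression curve itself
  ($c = 1$) is used, and `manual_curve()` lets users hand-set all three
  parameters.

The occurrence cutoff is applied together with the curve (logical AND), so
its ordering relative to curve filtering cannot change the result.

## Clustering and the metalloprotein count

Significant proteins are clustered by co-occurrence: Euclidean distance on
raw 0/1 presence vectors over all fractions, Ward linkage
(`hclust(method = "ward.D2")`, the variance-minimizing criterion for
Euclidean input), and a hybrid tree cut. Rows are put in lexicographic
order before distances are computed, so input order never matters.

The cut (`cut_tree_hybrid()`) works in three steps: a static cut at
`cut_height_fraction = 0.99` of the maximum merge height; then recursive
splitting of each branch whenever its top merge height reaches
$3 - \texttt{deep\_split}/2$ times the median merge height inside the
branch (default `deep_split = 2`, i.e. ratio 2). Merge heights in
co-elution data are strongly bimodal — tight within-group merges versus
tall between-group merges — but chained between-group merges have small
*local* height gaps, so the criterion compares each merge to its branch's
internal cohesion rather than to its immediate children. Finally, branches
smaller than `min_cluster_size = 3` are left unassigned (label 0); if no
branch at all is admissible, the whole tree is one cluster, since a static
cut always severs the root and a small homogeneous set would otherwise
dissolve into fragments.

A cluster's **core** is the set of fractions where at least half (boundary
inclusive) of its proteins are observed; core overlap between clusters is
their Jaccard index. Low overlap supports the reading that each cluster
accounts for at least one distinct metalloprotein, which is why
`predict_metalloprotein_count()` simply returns the cluster count.

As an independent check, `greedy_cover()` computes how few proteins suffice
to touch every peak of the metal (a protein covers a peak region — the unit
of coverage — if observed in any of its fractions), with the classical
greedy approximation and deterministic tie-breaking (lower score, then
lexicographic identifier). The cluster count and the cover size are
reported side by side; neither bounds the other formally.

## Domain-annotation classification

`classify_entries()` matches case-insensitive regular expressions against
InterPro-style entry names and abstracts; the shipped pattern table
(`inst/extdata/ipm_patterns.tsv`) covers the ten default metals with
element names, ion adjectives and cofactor vocabulary (heme and Fe–S for
Fe; molybdopterin for Mo and W, since tungstoenzymes bind W through the
same cofactor; cobalamin/corrin for Co; zinc fingers for Zn; a guarded
pattern for Pb to avoid the verb "lead"). It is plain data, versioned with
the package, and meant to be replaced or extended by the user. Keyword
hits are inherently noisy — entries describing enzyme families may mention
several alternative metals — so curation scores, not cleverer patterns,
handle ambiguity: score 0 vetoes an entry/metal pair, any positive score
keeps it, absence of curation keeps it by default.

## The synthetic generator

`synth_generate()` produces complete experiments with known truth: ordered
fractions in several separations; per-metal replicate traces with a
lognormal baseline (lognormal rather than Gaussian so concentrations stay
positive; `baseline_cv = 0.2`) and planted rectangular regions raised
`peak_fold = 8`; planted metalloproteins present in their metal's peak
fractions with `p_hit = 0.8` and elsewhere at `p_bg = 0.02`; background
proteins present uniformly at `bg_presence = 0.03`; peptide counts
$1 + \mathrm{Poisson}(2)$, with 5% of background proteins restricted to
single-peptide evidence so the inclusion filter is exercised. Same-metal
regions are placed with at least a two-fraction gap so that detector
recovery is well-defined region by region. All planted proteins of a metal
share that metal's full peak support, so the planted co-elution structure
is one group per metal; `make`-style fixtures with many disjoint-support
groups are used to stress the tree cut separately.

What the generator does **not** emulate matters for interpreting green
tests: real background proteins co-elute in complexes and smear across
contiguous fractions, giving score/occurrence clouds with a pronounced
negative trend; the uniform synthetic background has no such trend, so
regression slopes are shallow and curve filtering is an easier problem
here than on real data. Multi-level purification enrichment, isotope
interference and peak-shape variation are likewise out of scope. Passing
tests demonstrate correctness of the machinery and recoverability of
planted signal, not field performance on any particular organism.

## Problem sizes and numerical choices

Validation runs at desk scale by choice: default experiments are 8
separations × 60 fractions with 350 proteins; the survey-scale preset (43 ×
60 = 2,580 fractions, 870 proteins, ten metals) exercises the full pipeline
end to end in seconds. Score/oracle agreement is checked exhaustively for
universes up to 15 fractions and against exact rational arithmetic on
randomized instances up to 60. Ties in greedy covering and cluster
labelling are broken lexicographically; all stages are deterministic given
inputs and parameters, and the generator restores the caller's RNG state.

## Known limitations

* The peak detector assumes locally flat baselines; drifting baselines
  need a larger `window` or manual regions, and peaks wider than about
  twice the window are not called.
* Significance curves inherit the quality of the regression: a metal whose
  score cloud shows no occurrence trend (slope ≥ 0) cannot be anchored and
  falls back to extrapolation or the regression curve.
* The cluster count is an estimate of *distinct co-elution behaviours*
  among significant proteins; complexes containing several true
  metalloproteins deflate it, and diffuse background co-passers can
  inflate it by one.
* Euclidean distance on sparse Boolean vectors weighs joint absence;
  this matches the established practice the pipeline follows, but for very
  sparse matrices a Jaccard-based variant would discriminate better.
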