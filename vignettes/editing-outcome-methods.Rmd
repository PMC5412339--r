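---
title: "Methods: profiling CRISPR-Cas9 editing outcomes from clone sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling CRISPR-Cas9 editing outcomes from clone sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhejscope)
```

# The problem

A CRISPR-Cas9 editing experiment of the colony-sequencing kind produces a
small cohort of Sanger-sequenced clones, each carrying whatever indel the
non-homologous end joining (NHEJ) machinery left at the double-strand break
(DSB). nhejscope turns that cohort — plus the guide cloning oligos, a
reference amplicon and, downstream, qPCR Ct and Western-blot densitometry
tables — into quantitative editing-outcome reports: per-clone indel calls, a
per-position percent-deletion profile around the cut, functional-disruption
classifications, and expression-knockdown estimates.

The motivating application is silencing of the mutant Huntingtin transgene
in bone-marrow mesenchymal stem cells from a Huntington's-disease mouse
model, with one guide in the 5' UTR upstream of the open reading frame and a
second at the exon1–intron boundary; the package itself is generic over any
SpCas9-style experiment of this shape.

# Coordinates and conventions

All intervals are **0-based, half-open** `[start, end)` on the plus strand,
and cut sites are **inter-base indices**: a cut at `interbase = k` falls
between bases `k-1` and `k`. This makes the cut-site and footprint
arithmetic exact and free of off-by-one ambiguity; the 1-based closed
convention common in R appears nowhere internally.

Profile offsets follow the convention of editing-pattern figures in the
colony-sequencing literature: `+k` labels the k-th base 5' (upstream) of the
DSB, `-k` the k-th base 3' (downstream); there is no offset 0. A reference
position `i` maps to `+(cut - i)` when `i < cut` and `-(i - cut + 1)`
otherwise. Users who prefer the usual genomic orientation can pass
`convention = "genomic"`, which flips the signs of the labels only.

# Guide model and cut-site rule

Guides enter either as raw 20-mers or as BsmBI cloning-oligo pairs
(`CACC`+spacer top, `AAAC`+revcomp bottom). Published oligo tables sometimes
print the bottom oligo 3'→5', so that its plain character reversal equals
the conventional form; `parse_cloning_oligo()` accepts both orientations,
reports which one matched, and a `strict` mode accepts only the
conventional design. When the synthesized spacer is a 21-mer starting with
a scaffold-appended G, the default is to strip it and report the 20-nt
protospacer; because the cut rule is PAM-anchored this choice never moves
the predicted cut.

`locate_protospacer()` is an exact-match search for protospacer+NGG on the
plus strand and CCN+revcomp(protospacer) on the minus strand, and demands a
unique PAM-adjacent hit. Mismatch-tolerant scanning is deliberately absent:
the analysis targets an amplicon containing a perfect site, and mismatch
scanning is off-target analysis, out of scope here. The PAM pattern is
configurable (`N` is a wildcard); the default NGG is SpCas9's.

SpCas9 cuts bluntly 3 nt from the PAM. With a plus-strand target `[s, e)`
and PAM `[e, e+3)` the inter-base cut is `e - 3` (between positions 17 and
18 of a 20-mer protospacer); the minus-strand mirror is `s + 3`. A property
test embeds 1000 random guides on both strands and checks that exactly 3 nt
always lie between cut and PAM.

`virtual_pcr()` extracts the reference amplicon from a larger template by
unique exact primer matches (forward on the plus strand, reverse as its
reverse complement downstream), product inclusive of both primers.

# Indel calling

Clones are aligned to the reference by optimal global (Needleman–Wunsch)
alignment with affine gap penalties, computed by
`Biostrings::pairwiseAlignment()` over a custom ACGTN matrix in which `N`
never matches. Default scoring: match +2, mismatch −3, gap open −5, gap
extend −1. The rationale for the strong opening penalty is that one repair
event should surface as one contiguous call, the way colony-figure
tabulations book-keep single deletion blocks.

Each maximal gap run becomes one call, then every call is **left-aligned**:
shifted to the smallest reference start that leaves the implied clone
sequence unchanged (the usual VCF-style normalization), with the constraint
that a call never shifts past the end of the preceding call. Combined with
the aligner's deterministic tie-breaking this makes output placements
canonical and bit-reproducible. Tests verify optimality against an
independent pure-R affine-gap dynamic program and placement against a
brute-force enumerator of the repeat-ambiguity equivalence class.

**Combined events are reported in parsimony-canonical form.** Under the
default scoring, an insertion of length M directly adjacent to a deletion
of length L > M is absorbed into the deletion as M substitutions whenever
M ≤ 5 (two gap openings cost more than one opening plus M mismatches).
The two representations imply the *identical* clone sequence, so no caller
could distinguish them from sequence alone; nhejscope reports the canonical
one, preserves the net length change exactly, and counts the substitution
columns. The `both` (deletion + insertion) class therefore appears for
spatially separated events or insertions longer than 5 nt. Substitutions
are counted but never interpreted — Sanger-verified clones are assumed
error-free, and the analysis concerns indels.

Clones whose length deviates from the reference by more than 90% (default)
are flagged as truncated reads but still called, never dropped.

# Profile, windows, skew

`positional_profile()` reports, for every offset within a flank (default
15 nt), the percentage of clones whose deletion footprint covers that
offset. Insertions never contribute (the quantity is deletion frequency); a
separate insertion-point histogram is available. Deletions extending beyond
the flank still count at every in-flank offset they cover. Window
fractions (`window_fraction()`) give the percent of clones deleting at
least one base within an inclusive offset window, e.g. `-1..-3` or
`+1..+3`.

`skew_statistic()` compares mean percent-deletion over `+1..+flank` against
`-1..-flank`, overall and restricted to clones whose total deletion reaches
`large_threshold` (default 20 nt — a stated package default; the underlying
experiments never defined "large"). When no clone reaches the threshold the
subset is reported as absent, not as zero. `estimate_alpha()` reports the
fraction of all deleted bases lying 3' of the cut, the empirical
counterpart of the generator's asymmetry parameter.

# Consequence classification

Disruption is purely positional: a feature is disrupted when a deletion
overlaps it (half-open overlap, so a deletion ending exactly at the feature
start leaves it intact) or an insertion point lies strictly inside it.
Reading-frame status sums whole-call signed length changes of calls
overlapping the annotated ORF and asks whether the sum is divisible by 3;
clones with no ORF-overlapping call are `not_applicable`. The splice-donor
check requires the donor feature to be exactly the first two intron bases
(canonically GT) and flags deletion of either base or an insertion at or
inside the dinucleotide. The Kozak window is user-annotated — the package
never scans for the motif — with `kozak_window()` offering the common
`[ATG-6, ATG+4)` default. No strength scores, no transcription-mechanism
modeling: those are biological inferences the knockdown module measures
instead.

# Knockdown quantification

`ddct_fold()` implements the comparative-threshold (2^−ΔΔCt) method: per
group, ΔCt = mean target Ct − mean reference-gene Ct; ΔΔCt subtracts the
control group's ΔCt; fold = 2^−ΔΔCt; percent reduction = (1 − fold) × 100.
The housekeeping gene is carried as a *role*, not an identity, since table
schemas rarely agree on naming. Per-replicate folds (each target replicate
against the group's reference mean, or replicate-paired behind
`paired = TRUE`, since run pairing is usually unstated) feed dispersion
estimates — both SEM of folds and SEM of ΔCt are emitted, as figure error
bars are commonly one or the other — and downstream group statistics.
One-way ANOVA and Tukey HSD come from `stats::aov()`/`stats::TukeyHSD()`;
the bespoke content is the pipeline, not the distribution quadrature, and a
hand-computed sums-of-squares oracle checks the wiring. Densitometry tables
(target-band OD / loading-control OD per replicate, normalized to the
control mean) go through the same group statistics.

# The synthetic-data generator

`simulate_cohort()` draws, per clone, an outcome class
(unmodified / insertion-only / deletion+insertion / deletion-only as the
remainder), a deletion size from a two-component mixture, and an
upstream/downstream split; insertions are uniform-random bases at the cut
with geometric lengths. Defaults, chosen once to emulate the motivating
colony cohorts and stated here rather than fitted to any figure:

* class probabilities 0.05 / 0.05 / 0.15 (most colonies edited; roughly one
  in six carrying both an insertion and a deletion, as in a 4-of-24 cohort);
* deletion sizes: weight 0.7 on a geometric component with mean 3 nt, the
  rest uniform on [20, 72] nt — spanning the printed extremes of the
  motivating cohorts (3–72 nt for the UTR guide, 1–61 nt for the
  exon1–intron guide) without being fitted to them;
* `alpha = 0.5` (symmetric split), `ins_len_mean = 2` nt.

Deletions always include or abut the cut (`u + d = L` anchored at the cut);
detached deletions are not modeled. The downstream extent uses **stochastic
rounding**, `d = floor(alpha * L + U)` with `U ~ Uniform(0,1)`, so that
`E[d] = alpha * L` exactly; deterministic rounding would make `alpha = 0.5`
asymmetric (size-1 deletions would always land upstream) and bias the
recovery of `alpha`. Every generator records truth rows that reconstruct
the emitted clone exactly and is bit-reproducible under a seed.

`simulate_ct_table()` gives the control target Ct a Normal(base, sd) draw
and shifts treated groups by −log2(fold) (knockdown raises Ct);
`simulate_densitometry()` uses multiplicative log-normal noise on optical
densities. Noise-free settings round-trip analytically through the
pipelines.

**What the generator does and does not emulate.** It reproduces cut-anchored
NHEJ indel structure, class mixes, size mixtures and directional skew, plus
the measurement models of qPCR and densitometry. It does not model
sequencing error, chromatograms, microhomology-directed deletion biases, or
amplification-efficiency deviations from 2.0 — so passing tests demonstrate
correctness of the analysis pipeline under the stated generative model, not
robustness to those real-data artifacts.

# Numerical and design notes

* **Repeat ambiguity.** A deletion inside a repeat tract has several
  score-equivalent placements; left-alignment picks the smallest start.
  Tests that need a *specific* placement (e.g. "every clone deletes the
  −2 base") therefore use junctions designed to be shift-free: the base 5'
  of the cut occurs nowhere downstream of it, so cut-anchored deletions
  cannot move. This mirrors real practice, where profile positions are
  only meaningful up to alignment convention.
* **Sub-cohort sizes in tests.** Property suites use 300–1000 simulated
  clones and 100–500 simulation replicates; these sizes give binomial/SE
  margins comfortably tighter than the asserted tolerances while keeping
  the default test run fast.
* **Degenerate inputs.** Zero overall variance makes the ANOVA F undefined
  and is an error; a missing reference-gene row errors naming the sample;
  empty cohorts, malformed oligos, ambiguous or absent protospacers,
  multiple priming sites and out-of-bounds features all raise early,
  specific errors.
* **Determinism.** `run_pipeline()` writes every parameter with a default
  into the run log together with a hash of the analysis-relevant
  configuration (output location excluded) and the seed; identical
  configurations give byte-identical bundles.
* **Open conventions decided here.** The distance between a guide and a
  nearby landmark (e.g. a Kozak window) depends on which guide end and
  which landmark base anchor the measurement; rather than guess, the
  package exposes interval coordinates for both and leaves the subtraction
  to the user. Whether colony panels across figures are nested subsets is
  unknowable from the inputs; every summary reports its own n.

# A worked run

```{r worked}
g1 <- parse_cloning_oligo("CACCGGCCTCCGGGGACTGCCGTGC",
                          "CCGGAGGCCCCTGACGGCACGCAAA", name = "gRNA1")
g1

mk <- make_reference(60, g1, flank3 = 60, seed = 11,
                     features = kozak_window(88))
sim <- simulate_cohort(mk$ref, mk$cut, nhej_model(), n = 24, seed = 12)
fit <- nhej_cohort(mk$ref, sim$clones, guide = g1)
summary(fit)

ct <- simulate_ct_table(folds = c(gRNA1 = 0.21, gRNA2 = 0.42),
                        noise_sd = 0.1, seed = 13)
ddct_fold(ct$table, "control")
```

```{r plot, fig.width = 7, fig.height = 3.5}
plot(fit, main = "percent deletion by offset from the DSB")
```
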