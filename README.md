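# nhejscope

Quantitative profiling of CRISPR-Cas9 editing outcomes from Sanger-sequenced
clone cohorts, in R.

When an editing experiment is read out by cloning the amplicon around the
double-strand break (DSB) and sequencing colonies, the raw result is a
handful of clone sequences carrying whatever indels non-homologous end
joining (NHEJ) produced. nhejscope takes those sequences — together with the
guide cloning oligos, a reference amplicon, optional feature annotations,
and downstream qPCR / Western-blot tables — and produces the standard
editing-outcome report:

* **Guide model** — parse and validate `CACC`/`AAAC` cloning-oligo pairs
  (both printed orientations), locate the protospacer next to its NGG PAM,
  and predict the blunt SpCas9 cut 3 nt upstream of the PAM as an inter-base
  index. Virtual PCR extracts reference amplicons from larger templates.
* **Indel calling** — optimal global alignment with affine gaps
  (match +2, mismatch −3, gap open −5, gap extend −1 by default), one call
  per maximal gap run, VCF-style left-alignment into repeat tracts,
  per-clone edit class (`unmodified`/`deletion`/`insertion`/`both`), net
  length change, and cohort summaries (min/max deletion, class counts).
* **Positional profile** — percent of clones deleting each base at signed
  offsets around the cut (`+k` = k-th base 5′ of the DSB, `-k` = 3′, the
  convention of editing-pattern figures), window fractions such as
  "deleted within −1..−3", and an upstream/downstream skew statistic with a
  large-deletion subset.
* **Consequences** — positional disruption of the Kozak window, upstream
  ORF and splice donor, plus reading-frame status (net ORF length change
  mod 3).
* **Knockdown** — the comparative-threshold 2^−ΔΔCt method on replicate Ct
  tables (fold change, percent reduction, SEMs) and normalized densitometry
  ratios, each with one-way ANOVA and Tukey HSD across groups.
* **Synthetic data** — ground-truthed generators for edited-clone cohorts
  (class mixture, geometric+uniform deletion-size mixture, downstream
  fraction `alpha`, insertions at the cut), Ct tables and densitometry
  tables, so the whole pipeline is testable without external data.

The model at the core is simple and explicit. For a plus-strand protospacer
match `[s, e)` with PAM `[e, e+3)`, the cut sits at inter-base `e − 3`.
A deletion of size L in the generator removes `d` bases 3′ and `L − d`
bases 5′ of the cut with `E[d] = αL`. For qPCR,
ΔCt = mean Ct(target) − mean Ct(reference), ΔΔCt = ΔCt(group) − ΔCt(control),
fold = 2^−ΔΔCt, and percent reduction = (1 − fold) × 100.

All coordinates are 0-based half-open; cut sites are inter-base indices.

## Worked example

```r
library(nhejscope)

# guide from its published cloning-oligo pair (bottom printed 3'->5')
g1 <- parse_cloning_oligo("CACCGGCCTCCGGGGACTGCCGTGC",
                          "CCGGAGGCCCCTGACGGCACGCAAA", name = "gRNA1")
g1
#> <guide_rna> gRNA1: 5'-GCCTCCGGGGACTGCCGTGC-3' (20 nt, oligo_pair)

# synthetic reference around the target, 24-clone simulated cohort, analysis
mk  <- make_reference(60, g1, flank3 = 60, seed = 11,
                      features = kozak_window(88))
sim <- simulate_cohort(mk$ref, mk$cut, nhej_model(), n = 24, seed = 12)
fit <- nhej_cohort(mk$ref, sim$clones, guide = g1)
summary(fit)
#> NHEJ editing-outcome analysis
#>   reference: synthetic (143 bp), cut at inter-base 77
#>   clones: 24  classes: unmodified=1, deletion=20, insertion=3, both=0
#>   total deletion per clone: 1-70 nt
#>   deletion in -1..-3 window: 62.5% of clones
#>   deletion in +1..+3 window: 75.0% of clones
#>   mean % deleted, upstream +1..+15: 23.6 ; downstream -1..-15: 23.3
#>   large-deletion subset (n=5): upstream 93.3 ; downstream 94.7
#>   downstream deleted-base fraction (alpha-hat): 0.496
#>   consequences: kozak_disrupted=20.8%

# knockdown from a simulated Ct table with true folds 0.21 and 0.42
ct <- simulate_ct_table(folds = c(gRNA1 = 0.21, gRNA2 = 0.42),
                        noise_sd = 0.1, seed = 13)
ddct_fold(ct$table, "control")
#> <ddct_fit> 2^-ddCt relative quantification (control: control)
#>    group delta_ct delta_delta_ct  fold percent_reduction sem_fold sem_ddct n_reps
#>  control    6.010          0.000 1.000             0.000    0.041    0.060      3
#>    gRNA1    8.272          2.262 0.208            79.156    0.007    0.046      3
#>    gRNA2    7.086          1.076 0.474            52.568    0.014    0.041      3
```

Reading the output: 23 of 24 simulated colonies carry an edit; per-clone
total deletions span 1–70 nt; the percent-deletion profile is roughly
symmetric around the cut (`alpha-hat` ≈ 0.5, matching the generator), and
the five clones with ≥ 20 nt deleted have lost nearly every base within
±15 nt. The ΔΔCt fit recovers the simulated knockdowns: ≈ 79% reduction for
gRNA1 (fold 0.208 vs a true 0.21) and ≈ 53% for gRNA2 at three replicates
of Ct noise 0.1 cycles.

`run_pipeline(run_config(...))` chains the stages over files (FASTA
reference and clones, BED-like features, Ct/densitometry CSVs) and writes a
report bundle — per-clone TSV with consequence columns, profile TSV, cohort
summary JSON, knockdown JSON, and a run log carrying the seed and a
configuration hash; identical configurations produce byte-identical
bundles. See the methods vignette
(`vignettes/editing-outcome-methods.Rmd`) for the model, parameter
defaults, and the design decisions behind the caller's canonical
(left-aligned, parsimony) representation of indels.

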