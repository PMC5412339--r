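Package: nhejscope
Title: CRISPR-Cas9 Editing-Outcome Profiling from Edited-Clone Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles non-homologous end joining (NHEJ) outcomes of CRISPR-Cas9
    editing experiments from Sanger-sequenced clone sequences. Parses guide-RNA
    cloning oligos, locates protospacers and predicts SpCas9 blunt cut sites
    3 nt upstream of the NGG PAM, extracts amplicons by virtual PCR, calls and
    left-normalizes indels from global alignments of clone sequences against a
    reference amplicon, builds per-position percent-deletion profiles around
    the double-strand break, classifies functional consequences (Kozak window,
    upstream ORF, reading frame, splice donor), and quantifies expression
    knockdown from qPCR Ct tables (2^-ddCt) and Western-blot densitometry with
    one-way ANOVA and Tukey HSD. Includes a ground-truthed synthetic-data
    generator for edited-clone cohorts, Ct tables and densitometry tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
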