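# -- guide RNAs and cloning-oligo parsing ---------------------------------

#' Construct a guide RNA
#'
#' A guide is represented by its protospacer: the 20-nt genomic target matched
#' by the spacer (21 nt when a scaffold-appended leading G is retained).
#'
#' @param name Guide name.
#' @param protospacer 20- or 21-nt DNA string over ACGT.
#' @param source Provenance: `"raw"` or `"oligo_pair"`.
#' @return An object of class `guide_rna`.
#' @export
#' @examples
#' guide_rna("gRNA1", "GCCTCCGGGGACTGCCGTGC")
guide_rna <- function(name, protospacer, source = c("raw", "oligo_pair")) {
  source <- match.arg(source)
  protospacer <- unname(toupper(protospacer))
  assert_dna(protospacer, "protospacer")
  if (!nchar(protospacer) %in% c(20L, 21L))
    stop("protospacer must be 20 nt (or 21 nt with retained scaffold G), got ",
         nchar(protospacer), " nt", call. = FALSE)
  structure(list(name = name, protospacer = protospacer, source = source),
            class = "guide_rna")
}

#' @export
print.guide_rna <- function(x, ...) {
  cat("<guide_rna> ", x$name, ": 5'-", x$protospacer, "-3' (",
      nchar(x$protospacer), " nt, ", x$source, ")\n", sep = "")
  invisible(x)
}

#' Parse a BsmBI cloning-oligo pair into a guide RNA
#'
#' Guide spacers are cloned into lentiCRISPRv2-style vectors as annealed oligo
#' duplexes with 4-nt overhangs: the top oligo is `CACC` + spacer, the bottom
#' oligo is `AAAC` + reverse complement of the spacer (written 5'->3').
#' Published oligo tables sometimes print the bottom oligo 3'->5' instead, so
#' that its plain character reversal equals the conventional form; both
#' orientations are accepted unless `strict = TRUE`.
#'
#' @param top Top-strand oligo, must begin with the `CACC` overhang.
#' @param bottom Bottom-strand oligo.
#' @param keep_scaffold_g If the spacer after overhang removal is 21 nt and
#'   starts with `G` (a scaffold-appended G), keep it (`TRUE`) or strip it to
#'   the 20-nt protospacer (`FALSE`, default). The cut-site rule is
#'   PAM-anchored, so this choice never moves the predicted cut.
#' @param strict Only accept the conventional 5'->3' bottom-oligo orientation.
#' @param name Guide name attached to the result.
#' @return A `guide_rna` with attribute `"validation"`: a list with `valid`,
#'   `orientation` (`"conventional"` or `"written_3to5"`), and `diagnostics`.
#' @export
#' @examples
#' g <- parse_cloning_oligo("CACCGGCCTCCGGGGACTGCCGTGC",
#'                          "CCGGAGGCCCCTGACGGCACGCAAA")
#' g$protospacer            # 20-nt protospacer, scaffold G stripped
#' attr(g, "validation")$orientation
parse_cloning_oligo <- function(top, bottom, keep_scaffold_g = FALSE,
                                strict = FALSE, name = "guide") {
  top <- unname(toupper(top)); bottom <- unname(toupper(bottom))
  assert_dna(top, "top oligo"); assert_dna(bottom, "bottom oligo")
  if (!startsWith(top, "CACC"))
    stop("malformed oligo: top oligo lacks the CACC overhang (starts ",
         substr(top, 1L, 4L), ")", call. = FALSE)
  spacer <- substring(top, 5L)      # spacer as synthesized (may keep scaffold G)
  if (!nchar(spacer) %in% c(20L, 21L))
    stop("malformed oligo: spacer after CACC removal is ", nchar(spacer),
         " nt; expected 20 or 21", call. = FALSE)

  # bottom validated against the full synthesized spacer (what anneals)
  conventional <- paste0("AAAC", revcomp(spacer))
  written_3to5 <- paste(rev(strsplit(conventional, "", fixed = TRUE)[[1L]]),
                        collapse = "")
  orientation <- if (bottom == conventional) "conventional"
                 else if (!strict && bottom == written_3to5) "written_3to5"
                 else NA_character_
  diagnostics <- c(expected_conventional = conventional,
                   expected_written_3to5 = written_3to5,
                   observed = bottom)
  if (is.na(orientation))
    stop("bottom oligo inconsistent with protospacer under ",
         if (strict) "the conventional orientation" else "every accepted orientation",
         ":\n  expected 5'->3': ", conventional,
         if (!strict) paste0("\n  or written 3'->5': ", written_3to5),
         "\n  observed:        ", bottom, call. = FALSE)

  protospacer <- spacer
  if (!keep_scaffold_g && nchar(spacer) == 21L && startsWith(spacer, "G"))
    protospacer <- substring(spacer, 2L)

  g <- guide_rna(name, protospacer, source = "oligo_pair")
  attr(g, "validation") <- list(valid = TRUE, orientation = orientation,
                                diagnostics = diagnostics)
  g
}
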