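#' @import Biostrings
#' @importFrom stats aov TukeyHSD sd rgeom rnorm runif setNames var
#' @importFrom utils read.delim write.table read.csv
NULL

# -- low-level sequence helpers -------------------------------------------
# All coordinates in this package are 0-based, half-open [start, end) on the
# plus strand; cut sites are inter-base indices (the cut falls between bases
# interbase-1 and interbase). See ?nhejscope.

DNA_BASES4 <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGGT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @keywords internal
assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a single non-empty string", call. = FALSE)
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  if (!grepl(pat, x))
    stop(what, " contains characters outside ",
         if (allow_n) "ACGTN" else "ACGT",
         " (got: ", substr(x, 1L, 40L), ")", call. = FALSE)
  invisible(x)
}

# locate every occurrence of a pattern, 0-based starts
str_find_all <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits) - 1L
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a (multi-)FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
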