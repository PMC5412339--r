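# -- reference amplicons, features, protospacer search, cut prediction ----

FEATURE_LABELS <- c("kozak", "start_codon", "uORF", "splice_donor", "exon",
                    "intron", "primer_fwd", "primer_rev", "other")

#' Build a feature table
#'
#' Features are intervals on the reference amplicon, 0-based half-open on the
#' plus strand.
#'
#' @param label Character vector of feature labels (one of
#'   `"kozak"`, `"start_codon"`, `"uORF"`, `"splice_donor"`, `"exon"`,
#'   `"intron"`, `"primer_fwd"`, `"primer_rev"`, `"other"`).
#' @param start,end Integer vectors, 0-based half-open.
#' @param strand `"+"` or `"-"` per feature.
#' @return A `data.frame` with columns label/start/end/strand.
#' @export
feature_table <- function(label, start, end, strand = "+") {
  label <- as.character(label)
  bad <- setdiff(label, FEATURE_LABELS)
  if (length(bad))
    stop("unknown feature label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end))
    stop("feature intervals must satisfy start < end", call. = FALSE)
  data.frame(label = label, start = start, end = end,
             strand = rep_len(strand, length(label)),
             stringsAsFactors = FALSE)
}

#' Read a BED-like feature table
#'
#' Four tab-separated columns without header: amplicon id, start, end, label
#' (0-based half-open), optionally a fifth strand column.
#'
#' @param path Path to the TSV file.
#' @param id If given, keep only rows whose first column equals `id`.
#' @return A feature `data.frame` as from [feature_table()].
#' @export
read_features <- function(path, id = NULL) {
  if (!file.exists(path)) stop("feature file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("feature table needs >= 4 columns", call. = FALSE)
  if (!is.null(id)) tab <- tab[tab[[1L]] == id, , drop = FALSE]
  feature_table(tab[[4L]], tab[[2L]], tab[[3L]],
                strand = if (ncol(tab) >= 5L) tab[[5L]] else "+")
}

#' Construct a reference amplicon
#'
#' @param seq DNA sequence (ACGTN) of the amplicon.
#' @param id Amplicon identifier.
#' @param features Optional feature `data.frame` (see [feature_table()]);
#'   all intervals must lie within `[0, nchar(seq)]`.
#' @return An object of class `ref_amplicon` with fields `id`, `seq`,
#'   `features`.
#' @export
ref_amplicon <- function(seq, id = "amplicon", features = NULL) {
  seq <- toupper(seq)
  assert_dna(seq, "reference sequence", allow_n = TRUE)
  if (!is.null(features)) {
    features <- feature_table(features$label, features$start, features$end,
                              strand = if (is.null(features$strand)) "+"
                                       else features$strand)
    if (any(features$start < 0L) || any(features$end > nchar(seq)))
      stop("feature interval outside [0, ", nchar(seq), ")", call. = FALSE)
  }
  structure(list(id = id, seq = seq, features = features),
            class = "ref_amplicon")
}

#' @export
print.ref_amplicon <- function(x, ...) {
  cat("<ref_amplicon> ", x$id, ": ", nchar(x$seq), " bp, ",
      if (is.null(x$features)) "no features" else
        paste(nrow(x$features), "feature(s)"), "\n", sep = "")
  invisible(x)
}

# coerce plain strings for convenience
as_ref <- function(ref) {
  if (inherits(ref, "ref_amplicon")) ref else ref_amplicon(ref)
}

# PAM pattern ("NGG") -> regex-free candidate test at a 0-based position
pam_matches <- function(seq, pos, pam = "NGG") {
  n <- nchar(pam)
  if (pos < 0L || pos + n > nchar(seq)) return(FALSE)
  s <- substr(seq, pos + 1L, pos + n)
  p <- strsplit(pam, "", fixed = TRUE)[[1L]]
  all(mapply(function(a, b) b == "N" || a == b,
             strsplit(s, "", fixed = TRUE)[[1L]], p))
}

#' Locate a protospacer in a reference amplicon
#'
#' Exact-match search for the protospacer immediately followed by an NGG PAM
#' on the plus strand, and for its reverse complement preceded by CCN (i.e.
#' protospacer+NGG on the minus strand). Exactly one PAM-adjacent hit must
#' exist.
#'
#' @param guide A [guide_rna()] (or a raw protospacer string).
#' @param ref A [ref_amplicon()] (or a raw sequence string).
#' @param pam PAM pattern, default `"NGG"` (SpCas9); `N` is a wildcard.
#' @return An object of class `protospacer_match`: `guide_name`, `start`,
#'   `end` (0-based half-open target interval on the + strand), `strand`,
#'   `pam_start`, `pam_end`, `pam_seq` (+-strand bases at the PAM interval).
#' @export
locate_protospacer <- function(guide, ref, pam = "NGG") {
  if (is.character(guide)) guide <- guide_rna("guide", guide)
  ref <- as_ref(ref)
  glen <- nchar(guide$protospacer)
  if (nchar(ref$seq) < glen + nchar(pam))
    stop("reference shorter than protospacer + PAM", call. = FALSE)

  hits <- list()
  for (s in str_find_all(guide$protospacer, ref$seq)) {   # + strand: spacer then NGG
    if (pam_matches(ref$seq, s + glen, pam))
      hits[[length(hits) + 1L]] <- list(start = s, end = s + glen, strand = "+",
                                        pam_start = s + glen,
                                        pam_end = s + glen + nchar(pam))
  }
  rc <- revcomp(guide$protospacer)                         # - strand: CCN then revcomp(spacer)
  rc_pam <- revcomp(pam)                                   # NGG -> CCN
  for (s in str_find_all(rc, ref$seq)) {
    if (pam_matches(ref$seq, s - nchar(pam), rc_pam))
      hits[[length(hits) + 1L]] <- list(start = s, end = s + glen, strand = "-",
                                        pam_start = s - nchar(pam),
                                        pam_end = s)
  }
  if (length(hits) == 0L)
    stop("protospacer '", guide$name, "' not found (with PAM ", pam,
         ") in reference '", ref$id, "'", call. = FALSE)
  if (length(hits) > 1L)
    stop("ambiguous protospacer '", guide$name, "': ", length(hits),
         " PAM-adjacent matches at + strand starts ",
         paste(vapply(hits, function(h) sprintf("%d(%s)", h$start, h$strand),
                      ""), collapse = ", "), call. = FALSE)
  h <- hits[[1L]]
  structure(list(guide_name = guide$name, start = h$start, end = h$end,
                 strand = h$strand, pam_start = h$pam_start,
                 pam_end = h$pam_end,
                 pam_seq = substr(ref$seq, h$pam_start + 1L, h$pam_end)),
            class = "protospacer_match")
}

#' @export
print.protospacer_match <- function(x, ...) {
  cat("<protospacer_match> ", x$guide_name, " at [", x$start, ",", x$end,
      ") strand ", x$strand, ", PAM ", x$pam_seq, " at [", x$pam_start, ",",
      x$pam_end, ")\n", sep = "")
  invisible(x)
}

#' Predict the SpCas9 cut site from a protospacer match
#'
#' Cas9 cuts bluntly 3 nt from the PAM: with a plus-strand target `[s, e)` and
#' PAM at `[e, e+3)` the inter-base cut index is `e - 3` (between protospacer
#' positions 17 and 18 of a 20-mer); on the minus strand with CCN at
#' `[s-3, s)` it is `s + 3`. Exactly 3 protospacer bases always lie between
#' the cut and the PAM.
#'
#' @param match A `protospacer_match`.
#' @return An object of class `cut_site`: `interbase` (cut falls between
#'   + strand bases `interbase - 1` and `interbase`) and `strand_of_guide`.
#' @export
predict_cut_site <- function(match) {
  stopifnot(inherits(match, "protospacer_match"))
  interbase <- if (match$strand == "+") match$end - 3L else match$start + 3L
  structure(list(interbase = as.integer(interbase),
                 strand_of_guide = match$strand),
            class = "cut_site")
}

#' @export
print.cut_site <- function(x, ...) {
  cat("<cut_site> inter-base ", x$interbase, " (guide on ",
      x$strand_of_guide, " strand)\n", sep = "")
  invisible(x)
}

#' Extract an amplicon by virtual PCR
#'
#' Finds the unique exact match of the forward primer on the plus strand and
#' the unique exact match of the reverse complement of the reverse primer
#' downstream of it; the product spans both primers inclusively.
#'
#' @param template Template DNA (string or `ref_amplicon`).
#' @param fwd_primer,rev_primer Primer sequences (>= 15 nt), written 5'->3'
#'   as ordered for synthesis.
#' @param id Identifier for the product amplicon.
#' @return A [ref_amplicon()] for the product, with attribute `"coords"`
#'   giving the 0-based product interval on the template.
#' @export
virtual_pcr <- function(template, fwd_primer, rev_primer, id = "product") {
  tmpl <- if (inherits(template, "ref_amplicon")) template$seq
          else toupper(template)
  assert_dna(tmpl, "template", allow_n = TRUE)
  fwd_primer <- toupper(fwd_primer); rev_primer <- toupper(rev_primer)
  for (p in c(fwd_primer, rev_primer))
    if (nchar(p) < 15L) stop("primers must be >= 15 nt", call. = FALSE)

  f_hits <- str_find_all(fwd_primer, tmpl)
  r_hits <- str_find_all(revcomp(rev_primer), tmpl)
  if (length(f_hits) == 0L)
    stop("forward primer not found in template", call. = FALSE)
  if (length(r_hits) == 0L)
    stop("reverse primer (as reverse complement) not found in template",
         call. = FALSE)
  if (length(f_hits) > 1L || length(r_hits) > 1L)
    stop("ambiguous priming: ", length(f_hits), " forward / ",
         length(r_hits), " reverse site(s); multiple products possible",
         call. = FALSE)
  f <- f_hits[1L]; r_end <- r_hits[1L] + nchar(rev_primer)
  if (r_hits[1L] < f + nchar(fwd_primer))
    stop("primer orientation error: reverse-primer site upstream of the ",
         "forward-primer site", call. = FALSE)
  out <- ref_amplicon(substr(tmpl, f + 1L, r_end), id = id)
  attr(out, "coords") <- c(start = f, end = r_end)
  out
}
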