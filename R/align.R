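# -- global alignment and indel normalization -----------------------------

#' Alignment scoring scheme
#'
#' Affine-gap scoring for the global alignment of a clone against the
#' reference. The defaults (match +2, mismatch -3, gap open -5, gap extend
#' -1) favor one contiguous gap per repair event, so a single NHEJ deletion
#' appears as a single call rather than scattered gaps.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_open Gap-opening score (<= 0), charged once per gap.
#' @param gap_extend Gap-extension score (<= 0), charged per gapped base.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = -5,
                           gap_extend = -1) {
  if (match <= 0) stop("match score must be positive", call. = FALSE)
  if (mismatch >= 0) stop("mismatch score must be negative", call. = FALSE)
  if (gap_open > 0 || gap_extend > 0)
    stop("gap scores must be <= 0", call. = FALSE)
  if (abs(gap_open) < abs(gap_extend))
    stop("|gap_open| must be >= |gap_extend|", call. = FALSE)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

# ACGTN substitution matrix; N never matches anything (including N)
substitution_matrix <- function(scoring) {
  b <- c(DNA_BASES4, "N")
  m <- matrix(scoring$mismatch, 5L, 5L, dimnames = list(b, b))
  diag(m)[1:4] <- scoring$match
  m
}

#' Global alignment of a clone against a reference
#'
#' Optimal Needleman-Wunsch global alignment with affine gap penalties,
#' computed with [Biostrings::pairwiseAlignment()]. Tie-breaking among
#' co-optimal alignments is deterministic; gap placement is made canonical
#' downstream by [normalize_indels()] left-alignment.
#'
#' @param ref Reference sequence (string or `ref_amplicon`).
#' @param query Clone sequence (ACGTN).
#' @param scoring A [scoring_scheme()].
#' @return An object of class `nhej_alignment`: `ref_aln` and `query_aln`
#'   (gapped strings of equal length), `score`, and the ungapped `ref`.
#' @export
global_align <- function(ref, query, scoring = scoring_scheme()) {
  ref <- as_ref(ref)$seq
  query <- toupper(query)
  assert_dna(query, "query", allow_n = TRUE)
  global_align_many(ref, query, scoring)[[1L]]
}

# vectorized core: one reference, many queries (single C call)
global_align_many <- function(ref, queries, scoring = scoring_scheme()) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(queries),
    subject = Biostrings::DNAString(ref),
    type = "global",
    substitutionMatrix = substitution_matrix(scoring),
    gapOpening = -scoring$gap_open,
    gapExtension = -scoring$gap_extend)
  ra <- as.character(Biostrings::alignedSubject(pa))
  qa <- as.character(Biostrings::alignedPattern(pa))
  sc <- Biostrings::score(pa)
  lapply(seq_along(queries), function(i)
    structure(list(ref_aln = ra[i], query_aln = qa[i], score = sc[i],
                   ref = ref),
              class = "nhej_alignment"))
}

#' @export
print.nhej_alignment <- function(x, ...) {
  cat("<nhej_alignment> score ", x$score, "\n  ref:   ", x$ref_aln,
      "\n  query: ", x$query_aln, "\n", sep = "")
  invisible(x)
}

#' Extract and left-normalize indel calls from an alignment
#'
#' Each maximal gap run in the alignment becomes one call, then every call is
#' left-aligned: shifted to the smallest reference start that leaves the
#' implied clone sequence unchanged, so placements inside repeat tracts are
#' canonical (the usual VCF/CRISPR-pipeline normalization).
#'
#' @param aln An `nhej_alignment` from [global_align()].
#' @return A `data.frame` of calls sorted by reference position with columns
#'   `kind` (`"deletion"`/`"insertion"`), `start`, `end` (0-based half-open
#'   reference interval; `start == end` marks an insertion point),
#'   `inserted_seq` (empty for deletions) and `length`. Substitution count is
#'   attached as attribute `"substitutions"`.
#' @export
normalize_indels <- function(aln) {
  stopifnot(inherits(aln, "nhej_alignment"))
  rs <- strsplit(aln$ref_aln, "", fixed = TRUE)[[1L]]
  qs <- strsplit(aln$query_aln, "", fixed = TRUE)[[1L]]
  stopifnot(length(rs) == length(qs))
  refc <- strsplit(aln$ref, "", fixed = TRUE)[[1L]]

  kind <- character(0); start <- integer(0); end <- integer(0)
  ins <- character(0)
  subs <- 0L
  rpos <- 0L          # 0-based count of reference bases consumed
  i <- 1L
  n <- length(rs)
  while (i <= n) {
    if (qs[i] == "-") {                       # deletion run
      j <- i
      while (j < n && qs[j + 1L] == "-") j <- j + 1L
      len <- j - i + 1L
      kind <- c(kind, "deletion")
      start <- c(start, rpos); end <- c(end, rpos + len)
      ins <- c(ins, "")
      rpos <- rpos + len
      i <- j + 1L
    } else if (rs[i] == "-") {                # insertion run
      j <- i
      while (j < n && rs[j + 1L] == "-") j <- j + 1L
      kind <- c(kind, "insertion")
      start <- c(start, rpos); end <- c(end, rpos)
      ins <- c(ins, paste(qs[i:j], collapse = ""))
      i <- j + 1L
    } else {
      if (rs[i] != qs[i]) subs <- subs + 1L
      rpos <- rpos + 1L
      i <- i + 1L
    }
  }

  # left-align each call against the ungapped reference; a call never shifts
  # past the end of the previous call (calls are produced in column order)
  floor <- 0L
  for (k in seq_along(kind)) {
    if (!length(kind)) break
    if (kind[k] == "deletion") {
      s <- start[k]; e <- end[k]
      while (s > floor && refc[s] == refc[e]) { s <- s - 1L; e <- e - 1L }
      start[k] <- s; end[k] <- e
      floor <- e
    } else {
      p <- start[k]
      b <- strsplit(ins[k], "", fixed = TRUE)[[1L]]
      while (p > floor && b[length(b)] == refc[p]) {
        b <- c(refc[p], b[-length(b)])
        p <- p - 1L
      }
      start[k] <- p; end[k] <- p
      ins[k] <- paste(b, collapse = "")
      floor <- p
    }
  }
  calls <- data.frame(kind = kind, start = start, end = end,
                      inserted_seq = ins,
                      length = ifelse(kind == "deletion",
                                      end - start, nchar(ins)),
                      stringsAsFactors = FALSE)
  # insertions sort before deletions at the same point (apply order)
  calls <- calls[order(calls$start, calls$kind == "deletion"), , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "substitutions") <- subs
  calls
}

#' Apply indel calls to a reference sequence
#'
#' Reconstructs the clone sequence implied by a set of calls; the inverse of
#' indel calling (up to substitutions, which calls do not carry).
#'
#' @param ref Reference sequence (string or `ref_amplicon`).
#' @param calls Call `data.frame` as from [normalize_indels()].
#' @return The edited sequence.
#' @export
apply_calls <- function(ref, calls) {
  seq <- as_ref(ref)$seq
  if (nrow(calls) == 0L) return(seq)
  calls <- calls[order(calls$start, calls$kind == "deletion"), , drop = FALSE]
  out <- character(0)
  pos <- 0L                                   # 0-based consumed prefix
  for (k in seq_len(nrow(calls))) {
    s <- calls$start[k]
    if (s < pos) stop("overlapping calls at reference position ", s,
                      call. = FALSE)
    out <- c(out, substr(seq, pos + 1L, s))
    if (calls$kind[k] == "deletion") pos <- calls$end[k]
    else { out <- c(out, calls$inserted_seq[k]); pos <- s }
  }
  paste0(paste(out, collapse = ""), substring(seq, pos + 1L))
}
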