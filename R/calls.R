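# -- per-clone edit calling and cohort summaries --------------------------

EDIT_CLASSES <- c("unmodified", "deletion", "insertion", "both")

classify_calls <- function(calls) {
  has_del <- any(calls$kind == "deletion")
  has_ins <- any(calls$kind == "insertion")
  if (has_del && has_ins) "both"
  else if (has_del) "deletion"
  else if (has_ins) "insertion"
  else "unmodified"
}

new_clone_edit <- function(clone_id, calls, flagged = FALSE) {
  net <- sum(calls$length[calls$kind == "insertion"]) -
         sum(calls$length[calls$kind == "deletion"])
  structure(list(clone_id = clone_id,
                 calls = calls,
                 net_change = as.integer(net),
                 edit_class = classify_calls(calls),
                 substitutions = attr(calls, "substitutions") %||% 0L,
                 flagged = flagged),
            class = "clone_edit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call edits in one clone sequence
#'
#' Globally aligns the clone against the reference, extracts left-normalized
#' indel calls and classifies the clone. An insertion directly adjacent to a
#' longer deletion is reported in alignment-canonical form (the shorter net
#' indel plus substitutions), since the two representations are
#' indistinguishable at the sequence level under parsimony.
#'
#' @param ref Reference (string or [ref_amplicon()]).
#' @param clone Clone sequence (string; ACGTN), or a named length-1 vector.
#' @param scoring A [scoring_scheme()].
#' @param clone_id Clone identifier (defaults to the name of `clone`).
#' @param max_length_dev Flag clones whose length deviates from the reference
#'   by more than this fraction (default 0.9) as truncated reads; they are
#'   still called, not dropped.
#' @return An object of class `clone_edit`: `clone_id`, `calls` (see
#'   [normalize_indels()]), `net_change` (inserted minus deleted nt),
#'   `edit_class` (`unmodified`/`deletion`/`insertion`/`both`),
#'   `substitutions`, `flagged`.
#' @export
call_edits <- function(ref, clone, scoring = scoring_scheme(),
                       clone_id = NULL, max_length_dev = 0.9) {
  if (is.null(clone_id))
    clone_id <- if (!is.null(names(clone))) names(clone)[1L] else "clone"
  call_edits_many(ref, stats::setNames(clone, clone_id), scoring,
                  max_length_dev = max_length_dev)[[1L]]
}

#' Call edits in a cohort of clone sequences
#'
#' Vectorized form of [call_edits()]: all clones are aligned against the
#' reference in one pass.
#'
#' @inheritParams call_edits
#' @param clones Named character vector of clone sequences (or a path read
#'   with [read_fasta()] beforehand).
#' @return A list of `clone_edit` records.
#' @export
call_edits_many <- function(ref, clones, scoring = scoring_scheme(),
                            max_length_dev = 0.9) {
  ref <- as_ref(ref)
  clones <- toupper(clones)
  if (length(clones) == 0L) stop("no clone sequences given", call. = FALSE)
  for (i in seq_along(clones)) assert_dna(clones[i], "clone", allow_n = TRUE)
  ids <- names(clones) %||% paste0("clone", seq_along(clones))
  rl <- nchar(ref$seq)
  flagged <- abs(nchar(clones) - rl) > max_length_dev * rl
  if (any(flagged))
    warning("truncated read(s) flagged (length deviates > ",
            max_length_dev * 100, "% from reference): ",
            paste(ids[flagged], collapse = ", "), call. = FALSE)
  alns <- global_align_many(ref$seq, unname(clones), scoring)
  lapply(seq_along(alns), function(i)
    new_clone_edit(ids[i], normalize_indels(alns[[i]]), flagged[i]))
}

#' @export
print.clone_edit <- function(x, ...) {
  cat("<clone_edit> ", x$clone_id, ": ", x$edit_class,
      ", net ", sprintf("%+d", x$net_change), " nt, ",
      nrow(x$calls), " call(s), ", x$substitutions, " substitution(s)",
      if (x$flagged) " [flagged: truncated]", "\n", sep = "")
  if (nrow(x$calls)) print(format_calls(x$calls))
  invisible(x)
}

# compact call string, e.g. "del:41-44" / "ins:47:GG"
format_calls <- function(calls) {
  if (nrow(calls) == 0L) return("")
  paste(ifelse(calls$kind == "deletion",
               sprintf("del:%d-%d", calls$start, calls$end),
               sprintf("ins:%d:%s", calls$start, calls$inserted_seq)),
        collapse = ";")
}

#' Total deleted nucleotides of a clone record
#' @param record A `clone_edit`.
#' @return Integer, summed deletion lengths.
#' @export
total_deleted <- function(record) {
  as.integer(sum(record$calls$length[record$calls$kind == "deletion"]))
}

#' Summarize an edited-clone cohort
#'
#' @param records List of `clone_edit` records.
#' @return An object of class `edit_summary`: `n_clones`, `min_deletion` /
#'   `max_deletion` (over per-clone total deleted nt, clones without
#'   deletions excluded; `NA` if none), and `class_counts`.
#' @export
summarize_cohort <- function(records) {
  if (length(records) == 0L) stop("empty cohort", call. = FALSE)
  stopifnot(all(vapply(records, inherits, TRUE, "clone_edit")))
  del <- vapply(records, total_deleted, 0L)
  cls <- vapply(records, function(r) r$edit_class, "")
  counts <- table(factor(cls, levels = EDIT_CLASSES))
  with_del <- del[del > 0L]
  structure(list(n_clones = length(records),
                 min_deletion = if (length(with_del)) min(with_del) else NA_integer_,
                 max_deletion = if (length(with_del)) max(with_del) else NA_integer_,
                 class_counts = counts),
            class = "edit_summary")
}

#' @export
print.edit_summary <- function(x, ...) {
  cat("<edit_summary> n = ", x$n_clones, " clones\n", sep = "")
  if (!is.na(x$min_deletion))
    cat("  total deletion per clone: min ", x$min_deletion, " nt, max ",
        x$max_deletion, " nt\n", sep = "")
  cat("  classes: ",
      paste(names(x$class_counts), as.integer(x$class_counts),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-clone calls as a data frame
#'
#' @param records List of `clone_edit` records.
#' @return A `data.frame` with one row per clone: `clone_id`, `edit_class`,
#'   `net_change`, `substitutions`, `total_deleted`, `total_inserted`,
#'   `calls` (compact string), `flagged`.
#' @export
records_table <- function(records) {
  data.frame(
    clone_id = vapply(records, function(r) r$clone_id, ""),
    edit_class = vapply(records, function(r) r$edit_class, ""),
    net_change = vapply(records, function(r) r$net_change, 0L),
    substitutions = vapply(records, function(r) r$substitutions, 0L),
    total_deleted = vapply(records, total_deleted, 0L),
    total_inserted = vapply(records, function(r)
      as.integer(sum(r$calls$length[r$calls$kind == "insertion"])), 0L),
    calls = vapply(records, function(r) format_calls(r$calls), ""),
    flagged = vapply(records, function(r) r$flagged, TRUE),
    stringsAsFactors = FALSE)
}
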