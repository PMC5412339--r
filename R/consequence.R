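# -- functional-consequence classification --------------------------------

as_feature <- function(feature) {
  f <- as.list(feature)
  if (is.null(f$start) || is.null(f$end))
    stop("feature needs start and end", call. = FALSE)
  f$start <- as.integer(f$start); f$end <- as.integer(f$end)
  if (f$start >= f$end) stop("feature must satisfy start < end", call. = FALSE)
  f
}

# half-open interval overlap
overlaps <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2

#' Positional disruption of a feature by a clone's edits
#'
#' A feature is disrupted when any deletion interval overlaps it (half-open
#' overlap; a deletion ending exactly at the feature start leaves it intact)
#' or any insertion point lies strictly inside it. Disruption is purely
#' positional — no strength score is implied.
#'
#' @param record A `clone_edit`.
#' @param feature A one-row feature `data.frame` or list with `start`, `end`
#'   (0-based half-open).
#' @return `"intact"` or `"disrupted"`.
#' @export
feature_disruption <- function(record, feature) {
  f <- as_feature(feature)
  calls <- record$calls
  if (nrow(calls) == 0L) return("intact")
  del <- calls[calls$kind == "deletion", , drop = FALSE]
  ins <- calls[calls$kind == "insertion", , drop = FALSE]
  hit <- any(overlaps(del$start, del$end, f$start, f$end)) ||
         any(ins$start > f$start & ins$start < f$end)
  if (hit) "disrupted" else "intact"
}

#' Reading-frame status of a clone over an ORF
#'
#' Sums the signed length changes of all calls overlapping the ORF interval
#' (whole-call lengths; a partially overlapping deletion contributes its full
#' length): frameshift when the sum is not a multiple of 3.
#'
#' @param record A `clone_edit`.
#' @param orf_interval Feature (list/row) with `start`, `end` delimiting the
#'   annotated ORF (or its first exon) on the reference.
#' @return `"in_frame"`, `"frameshift"`, or `"not_applicable"` when no call
#'   overlaps the ORF.
#' @export
frameshift_status <- function(record, orf_interval) {
  f <- as_feature(orf_interval)
  calls <- record$calls
  if (nrow(calls) == 0L) return("not_applicable")
  in_orf <- ifelse(calls$kind == "deletion",
                   overlaps(calls$start, calls$end, f$start, f$end),
                   calls$start > f$start & calls$start < f$end)
  if (!any(in_orf)) return("not_applicable")
  signed <- ifelse(calls$kind == "deletion", -calls$length, calls$length)
  if (sum(signed[in_orf]) %% 3L != 0L) "frameshift" else "in_frame"
}

#' Splice-donor disruption check
#'
#' The donor feature must be the first two intron bases (canonically GT on
#' the plus strand). Disrupted when either donor base is deleted, or when an
#' insertion falls between the two bases or immediately 5' of them.
#'
#' @param record A `clone_edit`.
#' @param boundary Donor feature with `start`, `end` (`end - start` must be 2).
#' @return `"intact"` or `"disrupted"`.
#' @export
splice_donor_check <- function(record, boundary) {
  f <- as_feature(boundary)
  if (f$end - f$start != 2L)
    stop("splice-donor feature must span exactly the 2 donor bases",
         call. = FALSE)
  calls <- record$calls
  if (nrow(calls) == 0L) return("intact")
  del <- calls[calls$kind == "deletion", , drop = FALSE]
  ins <- calls[calls$kind == "insertion", , drop = FALSE]
  hit <- any(overlaps(del$start, del$end, f$start, f$end)) ||
         any(ins$start %in% c(f$start, f$start + 1L))
  if (hit) "disrupted" else "intact"
}

#' Cohort-level consequence classification
#'
#' Classifies every clone against the annotated features of the reference:
#' Kozak-window and uORF disruption (positional overlap), reading-frame
#' status over the feature labeled `"exon"` (the ORF-bearing exon), and
#' splice-donor integrity. Categories whose feature is absent are reported
#' `not_annotated` / `not_applicable`.
#'
#' @param records List of `clone_edit` records.
#' @param features Feature `data.frame` (see [feature_table()]); labels used:
#'   `kozak`, `uORF`, `exon`, `splice_donor`.
#' @return List with `table` (one row per clone: columns `clone_id`, `kozak`,
#'   `uorf`, `frame`, `splice_donor`) and `fractions` (percent of clones
#'   disrupted/frameshifted per annotated category).
#' @export
cohort_consequences <- function(records, features) {
  if (length(records) == 0L) stop("empty cohort", call. = FALSE)
  feat <- function(lab) {
    i <- which(features$label == lab)
    if (length(i)) as_feature(features[i[1L], ]) else NULL
  }
  kz <- feat("kozak"); uo <- feat("uORF"); ex <- feat("exon")
  sd_ <- feat("splice_donor")

  one <- function(r) c(
    clone_id = r$clone_id,
    kozak = if (is.null(kz)) "not_annotated" else feature_disruption(r, kz),
    uorf = if (is.null(uo)) "not_annotated" else feature_disruption(r, uo),
    frame = if (is.null(ex)) "not_applicable" else frameshift_status(r, ex),
    splice_donor = if (is.null(sd_)) "not_annotated"
                   else splice_donor_check(r, sd_))
  tab <- as.data.frame(do.call(rbind, lapply(records, one)),
                       stringsAsFactors = FALSE)
  frac <- c(
    kozak_disrupted = if (is.null(kz)) NA_real_ else
      100 * mean(tab$kozak == "disrupted"),
    uorf_disrupted = if (is.null(uo)) NA_real_ else
      100 * mean(tab$uorf == "disrupted"),
    frameshift = if (is.null(ex)) NA_real_ else
      100 * mean(tab$frame == "frameshift"),
    splice_donor_disrupted = if (is.null(sd_)) NA_real_ else
      100 * mean(tab$splice_donor == "disrupted"))
  list(table = tab, fractions = frac)
}

#' Default Kozak window around a start codon
#'
#' Annotates the translation-initiation context as the 10-base window
#' `[atg_start - 6, atg_start + 4)`: six bases of 5' context plus the ATG
#' and the following base. A convenience only — the window can always be
#' annotated explicitly.
#'
#' @param atg_start 0-based position of the A of the start codon.
#' @return One-row feature `data.frame` labeled `"kozak"`.
#' @export
kozak_window <- function(atg_start) {
  atg_start <- as.integer(atg_start)
  feature_table("kozak", atg_start - 6L, atg_start + 4L)
}
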