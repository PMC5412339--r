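# -- positional deletion profile around the cut ---------------------------
#
# Offset convention ("figure" convention): +k is the k-th base 5' (upstream)
# of the cut, -k the k-th base 3' (downstream); there is no offset 0.
# Reference position i (0-based) maps to +(cut - i) when i < cut and to
# -(i - cut + 1) otherwise. "genomic" flips the signs.

#' Signed deletion footprint of a clone
#'
#' Maps every deleted reference base of a clone to its signed offset from the
#' cut site.
#'
#' @param record A `clone_edit`.
#' @param cut A `cut_site` (or bare inter-base integer).
#' @return Sorted integer vector of signed offsets (possibly empty);
#'   insertions do not contribute.
#' @export
#' @examples
#' # a deletion of [cut-3, cut) has footprint {+1,+2,+3}
deletion_footprint <- function(record, cut) {
  cut <- cut_index(cut)
  dels <- record$calls[record$calls$kind == "deletion", , drop = FALSE]
  if (nrow(dels) == 0L) return(integer(0))
  pos <- unlist(lapply(seq_len(nrow(dels)), function(k)
    seq.int(dels$start[k], dels$end[k] - 1L)))
  off <- ifelse(pos < cut, cut - pos, -(pos - cut + 1L))
  sort(unique(as.integer(off)))
}

cut_index <- function(cut) {
  if (inherits(cut, "cut_site")) cut$interbase else as.integer(cut)
}

offset_labels <- function(flank, convention = c("figure", "genomic")) {
  convention <- match.arg(convention)
  lab <- c(seq.int(flank, 1L), seq.int(-1L, -flank))
  if (convention == "genomic") -lab else lab
}

#' Per-position percent-deletion profile
#'
#' For every signed offset within `flank` of the cut, the percentage of
#' clones whose deletion footprint covers that offset. Deletions extending
#' beyond the flank still count at every in-flank offset they cover.
#'
#' @param records List of `clone_edit` records.
#' @param cut A `cut_site` (or inter-base integer).
#' @param flank Maximum |offset| reported (> 0).
#' @param convention `"figure"` (default; + = upstream/5' of the cut, as
#'   editing-pattern figures are commonly labeled) or `"genomic"`
#'   (signs flipped).
#' @return An object of class `positional_profile`: a `data.frame` `profile`
#'   with columns `offset` and `percent_deleted` (ordered upstream to
#'   downstream), plus `n_clones`, `flank`, `convention`.
#' @export
positional_profile <- function(records, cut, flank = 15L,
                               convention = c("figure", "genomic")) {
  convention <- match.arg(convention)
  if (length(records) == 0L) stop("empty cohort", call. = FALSE)
  flank <- as.integer(flank)
  if (flank <= 0L) stop("flank must be positive", call. = FALSE)
  cut <- cut_index(cut)
  # counts in figure convention, then relabel
  fig_lab <- c(seq.int(flank, 1L), seq.int(-1L, -flank))
  counts <- integer(length(fig_lab))
  for (r in records) {
    fp <- deletion_footprint(r, cut)
    counts <- counts + as.integer(fig_lab %in% fp)
  }
  structure(list(
    profile = data.frame(offset = offset_labels(flank, convention),
                         percent_deleted = 100 * counts / length(records)),
    n_clones = length(records), flank = flank, convention = convention),
    class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat("<positional_profile> n = ", x$n_clones, " clones, flank ", x$flank,
      " (", x$convention, " convention)\n", sep = "")
  print(utils::head(x$profile, 2L * x$flank))
  invisible(x)
}

#' Fraction of clones deleting within an offset window
#'
#' @param records List of `clone_edit` records.
#' @param cut A `cut_site` (or inter-base integer).
#' @param window Length-2 integer vector, inclusive signed-offset range in
#'   the figure convention (e.g. `c(-3, -1)` for the first three bases
#'   downstream of the cut); offset 0 does not exist and is ignored in
#'   spanning windows.
#' @return List with `window`, `fraction` (percent of clones with >= 1
#'   deleted base in the window) and `n_clones`.
#' @export
window_fraction <- function(records, cut, window) {
  if (length(window) != 2L) stop("window must be length 2", call. = FALSE)
  offs <- setdiff(seq.int(min(window), max(window)), 0L)
  cut <- cut_index(cut)
  hit <- vapply(records, function(r)
    any(deletion_footprint(r, cut) %in% offs), TRUE)
  list(window = sort(as.integer(window)),
       fraction = 100 * mean(hit),
       n_clones = length(records))
}

#' Upstream/downstream deletion skew
#'
#' Mean percent-deletion over the upstream (+1..+flank) and downstream
#' (-1..-flank) offsets, for the whole cohort and for the subset of clones
#' with a large total deletion.
#'
#' @param records List of `clone_edit` records.
#' @param cut A `cut_site` (or inter-base integer).
#' @param flank Offsets considered on each side (>= 1).
#' @param large_threshold Total deleted nt at or above which a clone counts
#'   as a large-deletion clone (default 20 nt; a stated default, the
#'   underlying experiments never defined "large").
#' @return List with `upstream_mean`, `downstream_mean` (percent), `n_clones`,
#'   and `large` — the same pair restricted to large-deletion clones plus
#'   `n_large`, or `NULL` when no clone reaches the threshold (reported as
#'   absent, not zero).
#' @export
skew_statistic <- function(records, cut, flank = 15L, large_threshold = 20L) {
  if (flank < 1L) stop("flank must be >= 1", call. = FALSE)
  side_means <- function(recs) {
    pp <- positional_profile(recs, cut, flank)$profile
    c(upstream = mean(pp$percent_deleted[pp$offset > 0L]),
      downstream = mean(pp$percent_deleted[pp$offset < 0L]))
  }
  all_m <- side_means(records)
  large <- Filter(function(r) total_deleted(r) >= large_threshold, records)
  out <- list(upstream_mean = unname(all_m["upstream"]),
              downstream_mean = unname(all_m["downstream"]),
              n_clones = length(records), large = NULL)
  if (length(large)) {
    lm <- side_means(large)
    out$large <- list(upstream_mean = unname(lm["upstream"]),
                      downstream_mean = unname(lm["downstream"]),
                      n_large = length(large))
  }
  out
}

#' Estimate the downstream deletion fraction (alpha)
#'
#' The fraction of all deleted bases that lie 3' (downstream) of the cut —
#' the empirical counterpart of the generator's `alpha`.
#'
#' @param records List of `clone_edit` records.
#' @param cut A `cut_site` (or inter-base integer).
#' @return Proportion in `[0, 1]`, `NaN` when the cohort has no deletions.
#' @export
estimate_alpha <- function(records, cut) {
  cut <- cut_index(cut)
  down <- 0L; tot <- 0L
  for (r in records) {
    dels <- r$calls[r$calls$kind == "deletion", , drop = FALSE]
    if (nrow(dels) == 0L) next
    for (k in seq_len(nrow(dels))) {
      s <- dels$start[k]; e <- dels$end[k]
      tot <- tot + (e - s)
      down <- down + max(0L, e - max(s, cut))
    }
  }
  down / tot
}

#' Insertion-point histogram
#'
#' Companion to the deletion profile: counts clones inserting at each signed
#' inter-base offset from the cut (an insertion at reference point p lies
#' between offsets +(cut-p) and -(cut-p+1); it is labeled by the inter-base
#' index `p - cut`, 0 = at the cut).
#'
#' @param records List of `clone_edit` records.
#' @param cut A `cut_site` (or inter-base integer).
#' @return A `data.frame` with columns `rel_point` and `n_clones`.
#' @export
insertion_points <- function(records, cut) {
  cut <- cut_index(cut)
  pts <- unlist(lapply(records, function(r) {
    p <- unique(r$calls$start[r$calls$kind == "insertion"])
    p - cut
  }))
  if (is.null(pts) || length(pts) == 0L)
    return(data.frame(rel_point = integer(0), n_clones = integer(0)))
  tab <- table(pts)
  data.frame(rel_point = as.integer(names(tab)),
             n_clones = as.integer(tab))
}
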