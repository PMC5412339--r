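# -- ground-truthed synthetic data for every pipeline stage ---------------

rand_dna <- function(n) paste(sample(DNA_BASES4, n, replace = TRUE),
                              collapse = "")

#' NHEJ repair-outcome model
#'
#' Parameters of the generative model for edited-clone cohorts. Per clone, an
#' outcome class is drawn (unmodified / insertion-only / deletion+insertion /
#' deletion-only as the remainder); deletion sizes come from a mixture of a
#' geometric "small" component and a uniform "large" component; a deletion of
#' size L removes `round(alpha * L)` bases downstream (3') of the cut and the
#' rest upstream, so deletions always include or abut the cut; insertions are
#' uniform-random bases placed at the cut, with geometric lengths.
#'
#' @param p_unmodified,p_insertion_only,p_both Class probabilities (deletion
#'   -only is the remainder; the three must sum to <= 1). Defaults 0.05 /
#'   0.05 / 0.15 emulate colony cohorts in which nearly every clone is edited
#'   and roughly one in six carries both an insertion and a deletion.
#' @param w_small Weight of the small (geometric) deletion-size component.
#' @param small_mean Mean of the geometric small-deletion size (nt, >= 1).
#' @param large_range Inclusive `[lo, hi]` of the uniform large-deletion
#'   component; the default 20-72 nt spans deletion sizes reported for
#'   Cas9 colony cohorts.
#' @param alpha Downstream fraction in `[0, 1]`: share of deleted bases taken
#'   3' of the cut (0.5 = symmetric).
#' @param ins_len_mean Mean of the geometric insertion length (nt, >= 1).
#' @return An object of class `nhej_model`.
#' @export
nhej_model <- function(p_unmodified = 0.05, p_insertion_only = 0.05,
                       p_both = 0.15, w_small = 0.7, small_mean = 3,
                       large_range = c(20L, 72L), alpha = 0.5,
                       ins_len_mean = 2) {
  p <- c(p_unmodified, p_insertion_only, p_both)
  if (any(p < 0) || sum(p) > 1)
    stop("class probabilities must be >= 0 and sum to <= 1", call. = FALSE)
  if (w_small < 0 || w_small > 1) stop("w_small must be in [0,1]", call. = FALSE)
  if (small_mean < 1 || ins_len_mean < 1)
    stop("geometric means must be >= 1", call. = FALSE)
  large_range <- as.integer(large_range)
  if (length(large_range) != 2L || large_range[1L] > large_range[2L])
    stop("large_range must be [lo, hi] with lo <= hi", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0,1]", call. = FALSE)
  structure(list(p_unmodified = p_unmodified,
                 p_insertion_only = p_insertion_only,
                 p_both = p_both,
                 w_small = w_small, small_mean = small_mean,
                 large_range = large_range, alpha = alpha,
                 ins_len_mean = ins_len_mean),
            class = "nhej_model")
}

# geometric on {1, 2, ...} with the given mean
rgeom1 <- function(n, mean) stats::rgeom(n, prob = 1 / mean) + 1L

draw_del_size <- function(model) {
  if (stats::runif(1L) < model$w_small) rgeom1(1L, model$small_mean)
  else sample(seq.int(model$large_range[1L], model$large_range[2L]), 1L)
}

#' Build a random reference amplicon around a guide target
#'
#' Random flanks are drawn around protospacer + PAM; the construct is redrawn
#' until the protospacer occurs exactly once with its PAM (so downstream
#' coordinate arithmetic is unambiguous). Requested features are stamped onto
#' the sequence: a `start_codon` feature writes ATG at its interval, a
#' `splice_donor` writes GT.
#'
#' @param flank5,flank3 Flank lengths (>= 10 nt).
#' @param guide A [guide_rna()] or protospacer string.
#' @param pam Concrete 3-nt PAM to embed (default `"TGG"`).
#' @param features Optional feature `data.frame` ([feature_table()]) in final
#'   amplicon coordinates; must fit within the sequence.
#' @param seed Optional integer seed for reproducibility.
#' @param id Amplicon id.
#' @return List with `ref` (a `ref_amplicon`), `match` (the located
#'   protospacer) and `cut` (the predicted `cut_site`).
#' @export
#' @examples
#' mk <- make_reference(30, "GCCTCCGGGGACTGCCGTGC", flank3 = 30, seed = 1)
#' nchar(mk$ref$seq)   # 30 + 20 + 3 + 30
#' mk$cut$interbase    # 30 + 20 - 3
make_reference <- function(flank5, guide, pam = "TGG", flank3 = flank5,
                           features = NULL, seed = NULL, id = "synthetic") {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(guide)) guide <- guide_rna("guide", guide)
  if (flank5 < 10L || flank3 < 10L) stop("flanks must be >= 10 nt", call. = FALSE)
  assert_dna(pam, "PAM")
  core <- paste0(guide$protospacer, pam)
  for (try in 1:100) {
    seq <- paste0(rand_dna(flank5), core, rand_dna(flank3))
    ok <- tryCatch({
      m <- locate_protospacer(guide, seq)
      m$start == flank5 && m$strand == "+"
    }, error = function(e) FALSE)
    if (ok) break
    if (try == 100L) stop("could not draw flanks with a unique target site",
                          call. = FALSE)
  }
  if (!is.null(features)) {
    if (any(features$start < 0L) || any(features$end > nchar(seq)))
      stop("feature specification exceeds sequence bounds", call. = FALSE)
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    for (k in seq_len(nrow(features))) {
      lab <- features$label[k]; s <- features$start[k]
      if (lab == "start_codon")
        chars[(s + 1L):(s + 3L)] <- c("A", "T", "G")
      if (lab == "splice_donor")
        chars[(s + 1L):(s + 2L)] <- c("G", "T")
    }
    seq <- paste(chars, collapse = "")
  }
  ref <- ref_amplicon(seq, id = id, features = features)
  match <- locate_protospacer(guide, ref)
  list(ref = ref, match = match, cut = predict_cut_site(match))
}

#' Simulate an NHEJ-edited clone cohort with ground truth
#'
#' @param ref A `ref_amplicon` (or sequence string).
#' @param cut A `cut_site` (or inter-base integer) to center edits on.
#' @param model An [nhej_model()].
#' @param n Number of clones (>= 1).
#' @param seed Optional integer seed.
#' @return List with `clones` (named character vector of clone sequences) and
#'   `truth` — a `data.frame` per clone: `clone_id`, `class` (intended edit
#'   class), `del_start`, `del_end`, `del_len` (0-based half-open, NA when no
#'   deletion), `ins_point`, `ins_seq` (NA/"" when no insertion),
#'   `net_change`. Applying the truth row to the reference reproduces the
#'   emitted clone exactly.
#' @export
simulate_cohort <- function(ref, cut, model = nhej_model(), n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- as_ref(ref)
  cut <- cut_index(cut)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  L <- nchar(ref$seq)

  draw_deletion <- function() {
    for (try in 1:50) {
      dl <- draw_del_size(model)
      # stochastic rounding keeps E[downstream] = alpha * size exactly, so
      # alpha = 0.5 is symmetric in expectation even for odd sizes
      d <- as.integer(floor(model$alpha * dl + stats::runif(1L)))
      u <- dl - d
      if (cut - u >= 0L && cut + d <= L) return(c(cut - u, cut + d))
      if (try == 50L) stop("deletion repeatedly exceeds the reference; ",
                           "enlarge the flanks or shrink the size mixture",
                           call. = FALSE)
    }
  }

  ids <- sprintf("sim%03d", seq_len(n))
  classes <- character(n)
  del_start <- del_end <- rep(NA_integer_, n)
  ins_point <- rep(NA_integer_, n); ins_seq <- rep("", n)
  clones <- character(n)

  for (i in seq_len(n)) {
    u01 <- stats::runif(1L)
    cls <- if (u01 < model$p_unmodified) "unmodified"
           else if (u01 < model$p_unmodified + model$p_insertion_only) "insertion"
           else if (u01 < model$p_unmodified + model$p_insertion_only +
                      model$p_both) "both"
           else "deletion"
    classes[i] <- cls
    seq <- ref$seq
    ipoint <- cut
    if (cls %in% c("deletion", "both")) {
      de <- draw_deletion()
      del_start[i] <- de[1L]; del_end[i] <- de[2L]
      ipoint <- de[1L]                    # insertion sits at the junction
    }
    if (cls %in% c("insertion", "both")) {
      ins_point[i] <- ipoint
      ins_seq[i] <- rand_dna(rgeom1(1L, model$ins_len_mean))
    }
    pre <- if (is.na(del_start[i])) cut else del_start[i]
    post <- if (is.na(del_end[i])) cut else del_end[i]
    clones[i] <- paste0(substr(seq, 1L, pre),
                        if (cls %in% c("insertion", "both")) ins_seq[i] else "",
                        substring(seq, post + 1L))
    if (cls == "unmodified") clones[i] <- seq
  }
  names(clones) <- ids
  truth <- data.frame(
    clone_id = ids, class = classes,
    del_start = del_start, del_end = del_end,
    del_len = ifelse(is.na(del_start), 0L, del_end - del_start),
    ins_point = ins_point, ins_seq = ins_seq,
    net_change = nchar(clones) - L,
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(clones = clones, truth = truth)
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Control target Ct ~ Normal(base_ct_target, noise_sd); a group with true
#' fold f has target Ct ~ Normal(base_ct_target - log2(f), noise_sd)
#' (knockdown, f < 1, raises the Ct); the reference gene is
#' Normal(base_ct_reference, noise_sd) in every group.
#'
#' @param folds Named numeric vector of true fold changes per treated group
#'   (names become group names), all > 0.
#' @param base_ct_target,base_ct_reference Mean Ct of the target / reference
#'   gene in the control condition (cycles).
#' @param noise_sd Replicate noise standard deviation (cycles).
#' @param n_reps Replicates per group and gene (>= 2).
#' @param control Name of the control group.
#' @param seed Optional integer seed.
#' @return List with `table` (a valid Ct `data.frame`) and `truth` (named
#'   fold vector including the control at 1).
#' @export
simulate_ct_table <- function(folds = c(gRNA1 = 0.21, gRNA2 = 0.42),
                              base_ct_target = 24, base_ct_reference = 18,
                              noise_sd = 0.1, n_reps = 3L,
                              control = "control", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(folds <= 0)) stop("folds must be > 0", call. = FALSE)
  if (n_reps < 2L) stop("n_reps must be >= 2", call. = FALSE)
  if (is.null(names(folds))) names(folds) <- paste0("group", seq_along(folds))
  all_folds <- c(stats::setNames(1, control), folds)
  rows <- lapply(names(all_folds), function(g) {
    mu_t <- base_ct_target - log2(all_folds[[g]])
    data.frame(group = g, sample = g,
               gene_role = rep(c("target", "reference"), each = n_reps),
               replicate = rep(seq_len(n_reps), 2L),
               ct = c(stats::rnorm(n_reps, mu_t, noise_sd),
                      stats::rnorm(n_reps, base_ct_reference, noise_sd)),
               stringsAsFactors = FALSE)
  })
  list(table = validate_ct_table(do.call(rbind, rows)), truth = all_folds)
}

#' Simulate a densitometry table with known expression ratios
#'
#' Optical densities carry multiplicative log-normal noise: the target band
#' OD is `base_od * ratio * exp(N(0, noise_sd))`, the loading-control band
#' `base_od * exp(N(0, noise_sd))`.
#'
#' @param ratios Named true target/loading expression ratios per treated
#'   group relative to control.
#' @param base_od Control-condition mean OD (arbitrary units).
#' @param noise_sd Log-scale noise standard deviation.
#' @param n_reps Replicates per group (>= 2).
#' @param control Name of the control group.
#' @param seed Optional integer seed.
#' @return List with `table` (`group`, `replicate`, `od_target`,
#'   `od_loading`) and `truth`.
#' @export
simulate_densitometry <- function(ratios = c(gRNA1 = 0.21, gRNA2 = 0.42),
                                  base_od = 1, noise_sd = 0.1, n_reps = 3L,
                                  control = "control", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(ratios <= 0)) stop("ratios must be > 0", call. = FALSE)
  if (n_reps < 2L) stop("n_reps must be >= 2", call. = FALSE)
  if (is.null(names(ratios))) names(ratios) <- paste0("group", seq_along(ratios))
  all_r <- c(stats::setNames(1, control), ratios)
  rows <- lapply(names(all_r), function(g)
    data.frame(group = g, replicate = seq_len(n_reps),
               od_target = base_od * all_r[[g]] *
                 exp(stats::rnorm(n_reps, 0, noise_sd)),
               od_loading = base_od * exp(stats::rnorm(n_reps, 0, noise_sd)),
               stringsAsFactors = FALSE))
  list(table = do.call(rbind, rows), truth = all_r)
}
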