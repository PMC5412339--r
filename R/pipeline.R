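# -- central cohort analysis ("fit" object) and report pipeline -----------

#' Analyze an edited-clone cohort
#'
#' The package's central analysis: given a reference amplicon and clone
#' sequences, locates the guide target (unless a cut site is supplied),
#' predicts the Cas9 cut, calls and normalizes indels in every clone, and
#' derives the cohort summary, the per-position percent-deletion profile,
#' window fractions, the upstream/downstream skew and — when the reference
#' carries feature annotations — per-clone functional consequences.
#'
#' @param ref Reference amplicon ([ref_amplicon()], string, or FASTA path).
#' @param clones Named character vector of clone sequences, or a FASTA path.
#' @param guide A [guide_rna()] or protospacer string (ignored when `cut`
#'   is given).
#' @param cut Optional `cut_site` or inter-base integer; when `NULL` it is
#'   predicted from `guide`.
#' @param scoring A [scoring_scheme()].
#' @param flank Profile half-width in nt.
#' @param large_threshold Total-deletion size (nt) defining the
#'   large-deletion subset of the skew statistic.
#' @param convention Offset-label convention for the profile (see
#'   [positional_profile()]).
#' @param pam PAM pattern for protospacer location.
#' @return An object of class `nhej_fit` with components `ref`, `match`,
#'   `cut`, `records`, `summary`, `profile`, `windows` (fractions for the
#'   -1..-3 and +1..+3 windows), `skew`, `alpha_hat`, `consequences` (or
#'   `NULL`), `scoring`. Methods: `print`, `summary`, `plot`,
#'   `as.data.frame`, `simulate`.
#' @export
#' @examples
#' mk <- make_reference(40, "GCCTCCGGGGACTGCCGTGC", flank3 = 40, seed = 3)
#' sim <- simulate_cohort(mk$ref, mk$cut, nhej_model(), n = 24, seed = 4)
#' fit <- nhej_cohort(mk$ref, sim$clones, cut = mk$cut)
#' fit
#' summary(fit)
nhej_cohort <- function(ref, clones, guide = NULL, cut = NULL,
                        scoring = scoring_scheme(), flank = 15L,
                        large_threshold = 20L,
                        convention = c("figure", "genomic"), pam = "NGG") {
  convention <- match.arg(convention)
  if (is.character(ref) && length(ref) == 1L && file.exists(ref))
    ref <- { fa <- read_fasta(ref); ref_amplicon(fa[[1L]], id = names(fa)[1L]) }
  ref <- as_ref(ref)
  if (is.character(clones) && length(clones) == 1L && file.exists(clones))
    clones <- read_fasta(clones)

  match <- NULL
  if (is.null(cut)) {
    if (is.null(guide))
      stop("supply either a guide or a cut site", call. = FALSE)
    match <- locate_protospacer(guide, ref, pam = pam)
    cut <- predict_cut_site(match)
  } else if (!inherits(cut, "cut_site")) {
    cut <- structure(list(interbase = as.integer(cut), strand_of_guide = "+"),
                     class = "cut_site")
  }

  records <- call_edits_many(ref, clones, scoring)
  fit <- structure(list(
    ref = ref, match = match, cut = cut, records = records,
    summary = summarize_cohort(records),
    profile = positional_profile(records, cut, flank, convention),
    windows = list(
      downstream_1_3 = window_fraction(records, cut, c(-3L, -1L)),
      upstream_1_3 = window_fraction(records, cut, c(1L, 3L))),
    skew = skew_statistic(records, cut, flank, large_threshold),
    alpha_hat = estimate_alpha(records, cut),
    consequences = if (!is.null(ref$features))
      cohort_consequences(records, ref$features),
    scoring = scoring), class = "nhej_fit")
  fit
}

#' @export
print.nhej_fit <- function(x, ...) {
  s <- x$summary
  cat("NHEJ editing-outcome analysis\n")
  cat("  reference: ", x$ref$id, " (", nchar(x$ref$seq), " bp), cut at ",
      "inter-base ", x$cut$interbase, "\n", sep = "")
  cat("  clones: ", s$n_clones, "  classes: ",
      paste(names(s$class_counts), as.integer(s$class_counts),
            sep = "=", collapse = ", "), "\n", sep = "")
  if (!is.na(s$min_deletion))
    cat("  total deletion per clone: ", s$min_deletion, "-", s$max_deletion,
        " nt\n", sep = "")
  invisible(x)
}

#' @export
#' @method summary nhej_fit
summary.nhej_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.nhej_fit")
}

#' @export
print.summary.nhej_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  w <- f$windows
  cat(sprintf("  deletion in -1..-3 window: %.1f%% of clones\n",
              w$downstream_1_3$fraction))
  cat(sprintf("  deletion in +1..+3 window: %.1f%% of clones\n",
              w$upstream_1_3$fraction))
  cat(sprintf("  mean %% deleted, upstream +1..+%d: %.1f ; downstream -1..-%d: %.1f\n",
              f$profile$flank, f$skew$upstream_mean,
              f$profile$flank, f$skew$downstream_mean))
  if (!is.null(f$skew$large))
    cat(sprintf("  large-deletion subset (n=%d): upstream %.1f ; downstream %.1f\n",
                f$skew$large$n_large, f$skew$large$upstream_mean,
                f$skew$large$downstream_mean))
  cat(sprintf("  downstream deleted-base fraction (alpha-hat): %.3f\n",
              f$alpha_hat))
  if (!is.null(f$consequences)) {
    fr <- f$consequences$fractions
    fr <- fr[!is.na(fr)]
    cat("  consequences: ",
        paste(names(fr), sprintf("%.1f%%", fr), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.nhej_fit <- function(x, ...) {
  pp <- x$profile$profile
  graphics::barplot(pp$percent_deleted, names.arg = pp$offset,
                    xlab = "offset from cut", ylab = "% clones with deletion",
                    las = 2, ...)
  invisible(x)
}

#' @export
#' @method as.data.frame nhej_fit
as.data.frame.nhej_fit <- function(x, ...) {
  tab <- records_table(x$records)
  if (!is.null(x$consequences))
    tab <- cbind(tab, x$consequences$table[, -1L, drop = FALSE])
  tab
}

#' Simulate cohorts from a fitted editing profile
#'
#' Parametric-bootstrap style: draws new cohorts from an [nhej_model()] whose
#' class probabilities and downstream fraction are the fitted empirical
#' values (deletion sizes keep the model's default mixture).
#'
#' @param object An `nhej_fit`.
#' @param nsim Number of cohorts.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `simulate_cohort()` results of the fitted cohort size.
#' @export
simulate.nhej_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cc <- object$summary$class_counts / object$summary$n_clones
  mod <- nhej_model(p_unmodified = cc[["unmodified"]],
                    p_insertion_only = cc[["insertion"]],
                    p_both = cc[["both"]],
                    alpha = if (is.nan(object$alpha_hat)) 0.5
                            else object$alpha_hat)
  lapply(seq_len(nsim), function(i)
    simulate_cohort(object$ref, object$cut, mod,
                    n = object$summary$n_clones))
}

# -- report pipeline ------------------------------------------------------

#' Assemble a pipeline run configuration
#'
#' @param ref Path to the reference FASTA (or a `ref_amplicon`).
#' @param clones Path to the clone multi-FASTA (or named sequences).
#' @param guide_oligos Optional top/bottom oligo pair (character length 2)
#'   parsed with [parse_cloning_oligo()].
#' @param guide Optional raw protospacer (used when `guide_oligos` is NULL).
#' @param features Optional BED-like feature TSV path (see [read_features()])
#'   or feature `data.frame`.
#' @param ct Optional Ct CSV path or `data.frame`.
#' @param densitometry Optional densitometry CSV path or `data.frame`.
#' @param control_group Control group name for the knockdown stages.
#' @param out_dir Output directory (created if missing).
#' @param scoring A [scoring_scheme()].
#' @param pam PAM pattern.
#' @param flank Profile half-width.
#' @param large_threshold Large-deletion threshold (nt).
#' @param convention Offset convention.
#' @param seed Integer seed recorded in (and used throughout) the run.
#' @return A `run_config` list.
#' @export
run_config <- function(ref, clones, guide_oligos = NULL, guide = NULL,
                       features = NULL, ct = NULL, densitometry = NULL,
                       control_group = "control", out_dir = "nhejscope_out",
                       scoring = scoring_scheme(), pam = "NGG", flank = 15L,
                       large_threshold = 20L, convention = "figure",
                       seed = 1L) {
  structure(list(ref = ref, clones = clones, guide_oligos = guide_oligos,
                 guide = guide, features = features, ct = ct,
                 densitometry = densitometry, control_group = control_group,
                 out_dir = out_dir, scoring = scoring, pam = pam,
                 flank = as.integer(flank),
                 large_threshold = as.integer(large_threshold),
                 convention = convention, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  cfg <- config[setdiff(names(config), "out_dir")]   # output location is not an input
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full editing-outcome pipeline
#'
#' Executes locate -> cut -> call -> profile -> consequence -> knockdown and
#' writes a report bundle: per-clone calls TSV (with consequence columns),
#' profile TSV, cohort summary JSON, knockdown JSON (when Ct/densitometry
#' inputs are given) and a run log recording every parameter, the config
#' hash and the seed. Reruns with identical inputs are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `nhej_fit`, knockdown results and
#'   output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c("ref", "clones", "features", "ct", "densitometry")) {
    v <- config[[p]]
    if (is.character(v) && length(v) == 1L && !file.exists(v))
      stop("config error: ", p, " file not found: ", v, call. = FALSE)
  }
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  ref <- stage("reference", {
    r <- config$ref
    if (is.character(r)) {
      fa <- read_fasta(r)
      r <- ref_amplicon(fa[[1L]], id = names(fa)[1L])
    }
    feats <- config$features
    if (is.character(feats)) feats <- read_features(feats, id = r$id)
    if (!is.null(feats)) r <- ref_amplicon(r$seq, r$id, feats)
    r
  })
  guide <- stage("guide", {
    if (!is.null(config$guide_oligos))
      parse_cloning_oligo(config$guide_oligos[1L], config$guide_oligos[2L])
    else if (!is.null(config$guide)) {
      if (is.character(config$guide)) guide_rna("guide", config$guide)
      else config$guide
    } else stop("no guide given (guide or guide_oligos)", call. = FALSE)
  })
  clones <- stage("clones", {
    cl <- config$clones
    if (is.character(cl) && length(cl) == 1L) read_fasta(cl) else cl
  })
  fit <- stage("cohort", nhej_cohort(
    ref, clones, guide = guide, scoring = config$scoring,
    flank = config$flank, large_threshold = config$large_threshold,
    convention = config$convention, pam = config$pam))

  knock <- NULL; dens <- NULL
  if (!is.null(config$ct)) knock <- stage("knockdown", {
    tab <- if (is.character(config$ct)) read_ct_table(config$ct) else config$ct
    ddct_fold(tab, config$control_group)
  })
  if (!is.null(config$densitometry)) dens <- stage("densitometry", {
    tab <- if (is.character(config$densitometry))
      utils::read.csv(config$densitometry, stringsAsFactors = FALSE)
    else config$densitometry
    densitometry_ratio(tab, config$control_group)
  })

  # -- write the bundle
  hash <- config_hash(config)
  paths <- list(
    calls = file.path(config$out_dir, "calls.tsv"),
    profile = file.path(config$out_dir, "profile.tsv"),
    summary = file.path(config$out_dir, "summary.json"),
    knockdown = file.path(config$out_dir, "knockdown.json"),
    log = file.path(config$out_dir, "run_log.txt"))

  utils::write.table(as.data.frame(fit), paths$calls, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pp <- fit$profile$profile
  pp$n <- fit$profile$n_clones
  utils::write.table(pp, paths$profile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- fit$summary
  jsonlite::write_json(list(
    config_hash = hash, seed = config$seed,
    n_clones = s$n_clones, min_deletion = s$min_deletion,
    max_deletion = s$max_deletion, class_counts = as.list(s$class_counts),
    windows = fit$windows, skew = fit$skew, alpha_hat = fit$alpha_hat,
    consequence_fractions = if (!is.null(fit$consequences))
      as.list(fit$consequences$fractions)),
    paths$summary, auto_unbox = TRUE, digits = NA, pretty = TRUE,
    na = "null")
  if (!is.null(knock) || !is.null(dens))
    jsonlite::write_json(list(
      config_hash = hash, seed = config$seed,
      qpcr = if (!is.null(knock)) c(
        list(control = knock$control_group),
        list(by_group = knock$by_group),
        group_stats(knock$replicate_folds)),
      densitometry = dens[c("by_group", "anova", "tukey")]),
      paths$knockdown, auto_unbox = TRUE, digits = NA, pretty = TRUE,
      na = "null")

  log <- c("nhejscope run log",
           paste0("config_hash: ", hash),
           paste0("seed: ", config$seed),
           paste0("pam: ", config$pam),
           paste0("flank: ", config$flank),
           paste0("large_threshold: ", config$large_threshold),
           paste0("convention: ", config$convention),
           paste0("control_group: ", config$control_group),
           paste0("scoring: match=", config$scoring$match,
                  " mismatch=", config$scoring$mismatch,
                  " gap_open=", config$scoring$gap_open,
                  " gap_extend=", config$scoring$gap_extend),
           paste0("reference: ", fit$ref$id, " (", nchar(fit$ref$seq), " bp)"),
           paste0("cut_interbase: ", fit$cut$interbase),
           paste0("n_clones: ", s$n_clones))
  writeLines(log, paths$log)

  invisible(list(fit = fit, knockdown = knock, densitometry = dens,
                 paths = paths, config_hash = hash))
}
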