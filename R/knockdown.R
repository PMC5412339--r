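# -- expression knockdown: 2^-ddCt, densitometry, group statistics --------

#' Validate a qPCR Ct table
#'
#' @param table `data.frame` with columns `group`, `sample`, `gene_role`
#'   (`"target"`/`"reference"`), `replicate`, `ct`.
#' @return The validated table (invisibly usable), with `gene_role`
#'   normalized to lower case.
#' @export
validate_ct_table <- function(table) {
  need <- c("group", "sample", "gene_role", "replicate", "ct")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  table$gene_role <- tolower(table$gene_role)
  if (!all(table$gene_role %in% c("target", "reference")))
    stop("gene_role must be 'target' or 'reference'", call. = FALSE)
  if (any(!is.finite(table$ct)) || any(table$ct <= 0) || any(table$ct > 45))
    stop("Ct values must lie in (0, 45]", call. = FALSE)
  for (key in unique(paste(table$group, table$sample, sep = "\r"))) {
    gs <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sub <- table[table$group == gs[1L] & table$sample == gs[2L], ]
    if (!any(sub$gene_role == "target"))
      stop("no target-gene rows for sample '", gs[2L], "' (group '",
           gs[1L], "')", call. = FALSE)
    if (!any(sub$gene_role == "reference"))
      stop("no reference-gene rows for sample '", gs[2L], "' (group '",
           gs[1L], "')", call. = FALSE)
  }
  table
}

#' Read a Ct table from CSV
#'
#' Expects a header `group,sample,gene_role,replicate,ct`.
#'
#' @param path Path to the CSV file.
#' @return Validated Ct `data.frame`.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("Ct table not found: ", path, call. = FALSE)
  validate_ct_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Relative quantification by the comparative-Ct (2^-ddCt) method
#'
#' Per group, dCt = mean target Ct - mean reference Ct; ddCt = dCt -
#' dCt(control); fold change = 2^-ddCt; percent reduction = (1 - fold) x 100.
#' Per-replicate folds (target replicate Ct against the group's reference
#' mean, or replicate-paired with `paired = TRUE`) are retained for
#' dispersion estimates and downstream ANOVA.
#'
#' @param table Ct table (see [validate_ct_table()]).
#' @param control_group Name of the calibrator group.
#' @param paired Pair target and reference Ct by replicate index instead of
#'   using the group-mean reference Ct for per-replicate folds.
#' @return An object of class `ddct_fit`: `by_group` data frame (`group`,
#'   `delta_ct`, `delta_delta_ct`, `fold`, `percent_reduction`, `sem_fold`,
#'   `sem_ddct`, `n_reps`), `replicate_folds` (named list), `control_group`.
#' @export
#' @examples
#' tab <- simulate_ct_table(folds = c(gRNA1 = 0.25), noise_sd = 0, seed = 1)
#' ddct_fold(tab$table, "control")
ddct_fold <- function(table, control_group, paired = FALSE) {
  table <- validate_ct_table(table)
  if (!control_group %in% table$group)
    stop("control group '", control_group, "' absent from table",
         call. = FALSE)
  groups <- unique(table$group)
  groups <- c(control_group, setdiff(groups, control_group))

  per_group <- lapply(groups, function(g) {
    sub <- table[table$group == g, ]
    tg <- sub[sub$gene_role == "target", ]
    rf <- sub[sub$gene_role == "reference", ]
    dct <- mean(tg$ct) - mean(rf$ct)
    if (paired) {
      m <- merge(tg[, c("sample", "replicate", "ct")],
                 rf[, c("sample", "replicate", "ct")],
                 by = c("sample", "replicate"), suffixes = c("_t", "_r"))
      if (nrow(m) == 0L)
        stop("no replicate-paired target/reference rows in group '", g, "'",
             call. = FALSE)
      rep_dct <- m$ct_t - m$ct_r
    } else {
      rep_dct <- tg$ct - mean(rf$ct)
    }
    list(group = g, dct = dct, rep_dct = rep_dct)
  })
  ctrl_dct <- per_group[[1L]]$dct

  rows <- lapply(per_group, function(p) {
    ddct <- p$dct - ctrl_dct
    rep_folds <- 2^-(p$rep_dct - ctrl_dct)
    n <- length(rep_folds)
    data.frame(group = p$group,
               delta_ct = p$dct,
               delta_delta_ct = ddct,
               fold = 2^-ddct,
               percent_reduction = (1 - 2^-ddct) * 100,
               sem_fold = stats::sd(rep_folds) / sqrt(n),
               sem_ddct = stats::sd(p$rep_dct) / sqrt(n),
               n_reps = n,
               stringsAsFactors = FALSE)
  })
  structure(list(by_group = do.call(rbind, rows),
                 replicate_folds = stats::setNames(
                   lapply(per_group, function(p) 2^-(p$rep_dct - ctrl_dct)),
                   groups),
                 control_group = control_group),
            class = "ddct_fit")
}

#' @export
print.ddct_fit <- function(x, digits = 3, ...) {
  cat("<ddct_fit> 2^-ddCt relative quantification (control: ",
      x$control_group, ")\n", sep = "")
  tab <- x$by_group
  tab[-1L] <- lapply(tab[-1L], function(v) round(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
#' @method summary ddct_fit
summary.ddct_fit <- function(object, ...) {
  gs <- group_stats(object$replicate_folds)
  out <- list(fit = object, anova = gs$anova, tukey = gs$tukey)
  class(out) <- "summary.ddct_fit"
  out
}

#' @export
print.summary.ddct_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nOne-way ANOVA on replicate folds: F(%d, %d) = %.2f, p = %.3g\n",
              x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p))
  cat("Tukey HSD:\n")
  print(x$tukey, row.names = FALSE)
  invisible(x)
}

#' @export
plot.ddct_fit <- function(x, ...) {
  tab <- x$by_group
  bp <- graphics::barplot(tab$fold, names.arg = tab$group,
                          ylab = "fold change (2^-ddCt)",
                          ylim = c(0, max(1, tab$fold) * 1.2), ...)
  graphics::arrows(bp, tab$fold - tab$sem_fold, bp, tab$fold + tab$sem_fold,
                   angle = 90, code = 3, length = 0.05)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' One-way ANOVA across groups
#'
#' Standard fixed-effects one-way analysis of variance on a named list of
#' replicate values (fitted with [stats::aov()]).
#'
#' @param groups Named list of numeric vectors, one per group (>= 2 groups,
#'   each >= 2 values).
#' @return List with `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  check_groups(groups)
  dat <- groups_df(groups)
  if (stats::var(dat$value) == 0)
    stop("undefined F: zero within-group and between-group variance",
         call. = FALSE)
  fit <- stats::aov(value ~ group, data = dat)
  s <- summary(fit)[[1L]]
  list(F = s[["F value"]][1L],
       df_between = as.integer(s[["Df"]][1L]),
       df_within = as.integer(s[["Df"]][2L]),
       p = s[["Pr(>F)"]][1L])
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range-based pairwise comparisons after one-way ANOVA
#' (via [stats::TukeyHSD()]).
#'
#' @param groups Named list of numeric vectors (as [one_way_anova()]).
#' @return `data.frame` with columns `group_i`, `group_j`, `diff`, `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  check_groups(groups)
  dat <- groups_df(groups)
  tk <- stats::TukeyHSD(stats::aov(value ~ group, data = dat))$group
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group_i = vapply(pair, `[`, "", 2L),
             group_j = vapply(pair, `[`, "", 1L),
             diff = unname(tk[, "diff"]),
             p_adj = unname(tk[, "p adj"]),
             stringsAsFactors = FALSE)
}

check_groups <- function(groups) {
  if (is.null(names(groups)) || length(groups) < 2L)
    stop("need a named list of >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 0L) < 2L))
    stop("every group needs >= 2 values", call. = FALSE)
}

groups_df <- function(groups) {
  data.frame(group = factor(rep(names(groups), lengths(groups)),
                            levels = names(groups)),
             value = unlist(groups, use.names = FALSE))
}

group_stats <- function(groups) {
  list(anova = one_way_anova(groups), tukey = tukey_hsd(groups))
}

#' Densitometry ratios with group statistics
#'
#' Per replicate, ratio = target-band optical density / loading-control
#' optical density; ratios are normalized to the control-group mean and
#' compared across groups by one-way ANOVA and Tukey HSD.
#'
#' @param table `data.frame` with columns `group`, `replicate`, `od_target`,
#'   `od_loading` (loading OD must be > 0).
#' @param control_group Name of the untreated/control group.
#' @return List with `by_group` (`group`, `mean_ratio`, `sem`, `n_reps`;
#'   ratios normalized to control), `replicates` (named list of normalized
#'   ratios), `anova`, `tukey`.
#' @export
densitometry_ratio <- function(table, control_group) {
  need <- c("group", "replicate", "od_target", "od_loading")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("densitometry table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(table$od_loading <= 0))
    stop("od_loading must be > 0", call. = FALSE)
  if (!control_group %in% table$group)
    stop("control group '", control_group, "' absent", call. = FALSE)
  table$ratio <- table$od_target / table$od_loading
  ctrl_mean <- mean(table$ratio[table$group == control_group])
  table$norm <- table$ratio / ctrl_mean
  groups <- c(control_group, setdiff(unique(table$group), control_group))
  reps <- lapply(stats::setNames(groups, groups),
                 function(g) table$norm[table$group == g])
  by_group <- data.frame(
    group = groups,
    mean_ratio = vapply(reps, mean, 0),
    sem = vapply(reps, function(v) stats::sd(v) / sqrt(length(v)), 0),
    n_reps = vapply(reps, length, 0L),
    stringsAsFactors = FALSE)
  c(list(by_group = by_group, replicates = reps), group_stats(reps))
}
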