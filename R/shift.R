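#' Per-protein log2 fold changes between two conditions
#'
#' FC = mean(test) - mean(reference) on the log2 scale. For ratio data
#' (SILAC against a common reference) the averaged log2 ratio itself is the
#' fold change, and only the test condition is consulted.
#'
#' @param means A `"condition_means"` object.
#' @param conditions Character vector `c(reference, test)`. For ratio data
#'   a single condition label is accepted.
#' @return Named numeric vector of log2 fold changes; proteins missing a
#'   required condition mean are excluded and their count attached as
#'   attribute `"n_excluded"`.
#' @export
protein_fold_changes <- function(means, conditions) {
  stopifnot(inherits(means, "condition_means"))
  conditions <- as.character(conditions)
  if (means$is_ratio && length(conditions) == 1L) {
    fc <- means$means[, conditions]
  } else {
    if (length(conditions) != 2L)
      stop("'conditions' must be c(reference, test)", call. = FALSE)
    fc <- means$means[, conditions[2L]] - means$means[, conditions[1L]]
  }
  names(fc) <- rownames(means$means)
  keep <- is.finite(fc)
  out <- fc[keep]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' U is computed from rank sums with midrank ties. The p-value is exact
#' (by enumeration of the permutation distribution) when the combined
#' sample size is at most 20 and there are no ties; otherwise the normal
#' approximation with tie-corrected variance and continuity correction is
#' used. When every value in both samples is identical, p = 1.
#'
#' @param a,b Numeric vectors (non-empty; `NA` dropped).
#' @param mode `"auto"` (default, as described), `"exact"` or
#'   `"normal-approx"`.
#' @return List with `U` (statistic for sample `a`), `p` (two-sided) and
#'   `exact` (logical).
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal-approx")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n <- length(a); m <- length(b)
  if (n < 1L || m < 1L) stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (length(unique(c(a, b))) == 1L)
    return(list(U = U, p = 1, exact = FALSE))
  use_exact <- switch(mode,
    auto = (n + m) <= 20L && !ties,
    exact = TRUE,
    `normal-approx` = FALSE)
  if (use_exact && ties)
    stop("exact mode is undefined with ties", call. = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1
  list(U = U, p = min(p, 1), exact = use_exact)
}

#' Test a compartment for a fold-change distribution shift
#'
#' Mann-Whitney test of the compartment's protein fold changes against a
#' background distribution: by default the whole proteome (including the
#' compartment itself, the literal reading of a "compared to the whole
#' proteome" contrast), optionally its complement.
#'
#' @param fc Named numeric vector of log2 fold changes (whole proteome).
#' @param ann A `"compartment_annotation"`.
#' @param compartment Compartment name.
#' @param background `"whole-proteome"` (default) or `"complement"`.
#' @param alpha Significance level for the `significant` flag (default
#'   0.01).
#' @return One-row data frame (class keeps plain): `compartment`,
#'   `n_proteins`, `mean_log2fc`, `median_log2fc`, `U`, `p`, `significant`.
#' @export
compartment_shift_test <- function(fc, ann, compartment,
                                   background = c("whole-proteome", "complement"),
                                   alpha = 0.01) {
  background <- match.arg(background)
  members <- intersect(compartment_members(ann, compartment), names(fc))
  if (length(members) < 2L)
    stop("compartment '", compartment, "' has fewer than 2 quantified proteins",
         call. = FALSE)
  comp_fc <- fc[members]
  bg_fc <- if (background == "whole-proteome") fc else fc[setdiff(names(fc), members)]
  if (!length(bg_fc)) stop("empty background", call. = FALSE)
  mw <- mann_whitney(comp_fc, bg_fc, mode = "auto")
  data.frame(compartment = compartment, n_proteins = length(comp_fc),
             mean_log2fc = mean(comp_fc), median_log2fc = stats::median(comp_fc),
             U = mw$U, p = mw$p, significant = mw$p < alpha,
             stringsAsFactors = FALSE)
}

#' Compartment shift report
#'
#' One row per analyzed compartment: mean and median log2 fold change and
#' the Mann-Whitney test against the whole proteome. Compartments with
#' fewer than `min_size` quantified proteins are skipped with a note.
#'
#' @param means A `"condition_means"` object.
#' @param ann A `"compartment_annotation"`.
#' @param conditions `c(reference, test)` (or one label for ratio data).
#' @param compartments Compartment names; default the four major
#'   compartments.
#' @param background,alpha Passed to [compartment_shift_test()].
#' @param min_size Minimum quantified proteins per compartment (default 2).
#' @return List with `results` (data frame) and `skipped` (data frame).
#' @export
shift_report <- function(means, ann, conditions,
                         compartments = names(compartment_definitions("four")),
                         background = "whole-proteome", alpha = 0.01,
                         min_size = 2L) {
  fc <- protein_fold_changes(means, conditions)
  rows <- list(); skipped <- list()
  for (comp in compartments) {
    n <- length(intersect(compartment_members(ann, comp), names(fc)))
    if (n < min_size) {
      skipped[[comp]] <- data.frame(compartment = comp, n = n,
                                    reason = sprintf("fewer than %d quantified proteins", min_size),
                                    stringsAsFactors = FALSE)
      next
    }
    rows[[comp]] <- compartment_shift_test(fc, ann, comp,
                                           background = background, alpha = alpha)
  }
  list(
    results = if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
      else data.frame(),
    skipped = if (length(skipped)) do.call(rbind, c(skipped, list(make.row.names = FALSE)))
      else data.frame(compartment = character(), n = integer(),
                      reason = character(), stringsAsFactors = FALSE)
  )
}

#' Cross-run correlation of compartment mean shifts
#'
#' Given several shift reports (one per dataset/contrast), correlates the
#' per-compartment mean log2 fold changes between every pair of
#' compartments across runs. Compartments whose shifts track each other
#' across datasets (e.g. two organelles co-regulated in number) show
#' correlations near 1.
#'
#' @param reports List of `results` data frames from [shift_report()].
#' @return Matrix of Pearson correlations (compartment x compartment).
#' @export
shift_correlation <- function(reports) {
  if (length(reports) < 2L)
    stop("need at least 2 shift reports", call. = FALSE)
  comps <- sort(unique(unlist(lapply(reports, function(r) r$compartment))))
  mat <- sapply(reports, function(r) r$mean_log2fc[match(comps, r$compartment)])
  rownames(mat) <- comps
  stats::cor(t(mat), use = "pairwise.complete.obs")
}
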