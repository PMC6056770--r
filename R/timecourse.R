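#' Construct a ratio time series
#'
#' A proteins x timepoints matrix of log2 ratios against a common
#' reference (SILAC-style), with the first timepoint as baseline.
#'
#' @param values Numeric matrix, rownames = protein ids (unique), colnames
#'   = ordered timepoint labels.
#' @param timepoints Optional explicit ordering of timepoint labels;
#'   default the column order.
#' @return Object of class `"ratio_series"`: list with `values`,
#'   `timepoints`, `baseline`.
#' @export
ratio_series <- function(values, timepoints = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("protein ids (rownames) must be present and unique", call. = FALSE)
  timepoints <- as.character(timepoints)
  if (anyDuplicated(timepoints))
    stop("duplicate timepoint label(s)", call. = FALSE)
  if (!setequal(timepoints, colnames(values)) || length(timepoints) < 2L)
    stop("'timepoints' must order the >= 2 column labels", call. = FALSE)
  values <- values[, timepoints, drop = FALSE]
  structure(list(values = values, timepoints = timepoints,
                 baseline = timepoints[[1L]]),
            class = "ratio_series")
}

#' Read a wide ratio table (protein x timepoints)
#'
#' First column protein id, remaining columns are ordered timepoints of
#' log2 ratios against a common reference.
#'
#' @param path TSV/CSV path (optionally gzipped).
#' @return A [ratio_series()].
#' @export
read_ratio_table <- function(path) {
  tab <- read_delim_auto(path)
  if (nrow(tab) == 0L) stop("empty ratio table: ", path, call. = FALSE)
  if (ncol(tab) < 3L)
    stop("time-course mode needs >= 2 timepoint columns", call. = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate protein id(s) in ", path, call. = FALSE)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  ratio_series(vals)
}

#' Delta ratios relative to the baseline timepoint
#'
#' For each protein, the difference between its log2 ratio at every
#' timepoint and its ratio at baseline (day 1 by convention). Proteins
#' with a missing baseline value are excluded and counted.
#'
#' @param s A [ratio_series()].
#' @return List of class `"delta_series"`: `values` (proteins x
#'   timepoints, baseline column identically 0), `baseline`,
#'   `n_excluded`.
#' @export
delta_ratios <- function(s) {
  stopifnot(inherits(s, "ratio_series"))
  base <- s$values[, s$baseline]
  keep <- is.finite(base)
  delta <- s$values[keep, , drop = FALSE] - base[keep]
  structure(list(values = delta, timepoints = s$timepoints,
                 baseline = s$baseline, n_excluded = sum(!keep)),
            class = "delta_series")
}

#' Per-timepoint CNV records against baseline
#'
#' Fits compartment models with x = baseline ratios and y = ratios at
#' timepoint `t`, and computes CNV values exactly as in the pairwise
#' analysis.
#'
#' @param s A [ratio_series()].
#' @param ann A `"compartment_annotation"`.
#' @param t Timepoint label (not the baseline).
#' @param ... Passed to [run_cnv()] (e.g. `min_fit_size`, `compartments`).
#' @return A `"cnv_result"` for that timepoint.
#' @export
timepoint_cnv <- function(s, ann, t, ...) {
  stopifnot(inherits(s, "ratio_series"))
  t <- as.character(t)
  if (identical(t, s$baseline))
    stop("timepoint equals the baseline", call. = FALSE)
  if (!t %in% s$timepoints) stop("unknown timepoint: ", t, call. = FALSE)
  cm <- structure(list(
    means = s$values[, c(s$baseline, t), drop = FALSE],
    n_observed = matrix(1L, nrow(s$values), 2L,
                        dimnames = list(rownames(s$values), c(s$baseline, t))),
    is_ratio = TRUE), class = "condition_means")
  run_cnv(cm, ann, conditions = c(s$baseline, t), ...)
}

#' Compartment ratio-distribution trajectory
#'
#' For each non-baseline timepoint, Mann-Whitney test of the compartment's
#' ratio distribution at that timepoint against its distribution at
#' baseline, plus per-timepoint mean/median.
#'
#' @param s A [ratio_series()].
#' @param ann A `"compartment_annotation"`.
#' @param compartment Compartment name.
#' @param alpha Significance level (default 0.01).
#' @return Data frame: timepoint, n, mean_ratio, median_ratio, U, p,
#'   significant.
#' @export
compartment_trajectory_test <- function(s, ann, compartment, alpha = 0.01) {
  stopifnot(inherits(s, "ratio_series"))
  members <- intersect(compartment_members(ann, compartment), rownames(s$values))
  if (length(members) < 2L)
    stop("compartment '", compartment, "' has fewer than 2 proteins with data",
         call. = FALSE)
  base_vals <- s$values[members, s$baseline]
  base_vals <- base_vals[is.finite(base_vals)]
  rows <- lapply(setdiff(s$timepoints, s$baseline), function(t) {
    v <- s$values[members, t]
    v <- v[is.finite(v)]
    mw <- mann_whitney(v, base_vals, mode = "auto")
    data.frame(timepoint = t, n = length(v), mean_ratio = mean(v),
               median_ratio = stats::median(v), U = mw$U, p = mw$p,
               significant = mw$p < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Protein-group (complex) trajectory tests
#'
#' Tracks a protein group (e.g. a complex) across timepoints in two
#' complementary readouts, each compared by unpaired Mann-Whitney against
#' the group's values at the first non-baseline timepoint:
#' * `delta` mode: the members' delta ratios (change vs baseline). A
#'   compartment-wide drift moves the whole group and turns this test
#'   significant.
#' * `cnv` mode: the members' CNV values from the per-timepoint
#'   compartment models. A group that merely follows its compartment's
#'   trend stays null here; only composition changes register.
#' The per-timepoint variance across members (`spread`) supports a
#' stoichiometry-loss readout.
#'
#' @param s A [ratio_series()].
#' @param ann A `"compartment_annotation"`.
#' @param group Character vector of member protein ids (>= 2 with data).
#' @param mode `"delta"` or `"cnv"`.
#' @param cnv_by_timepoint For `mode = "cnv"`, an optional pre-computed
#'   named list of `"cnv_result"` objects per non-baseline timepoint (from
#'   [timepoint_cnv()]); computed on the fly when `NULL`.
#' @param alpha Significance level (default 0.05).
#' @param paired Use the paired (signed-rank) variant instead of the
#'   unpaired Mann-Whitney (default `FALSE`).
#' @param ... Passed to [timepoint_cnv()] when computing CNV records.
#' @return Data frame: timepoint, mode, n, mean_value, spread, U, p,
#'   significant. The reference timepoint row carries `NA` statistics.
#' @export
group_trajectory_test <- function(s, ann, group, mode = c("delta", "cnv"),
                                  cnv_by_timepoint = NULL, alpha = 0.05,
                                  paired = FALSE, ...) {
  stopifnot(inherits(s, "ratio_series"))
  mode <- match.arg(mode)
  missing_members <- setdiff(group, rownames(s$values))
  if (length(missing_members))
    stop("group member(s) absent from data: ",
         paste(missing_members, collapse = ", "), call. = FALSE)
  tps <- setdiff(s$timepoints, s$baseline)
  ref_t <- tps[[1L]]
  if (mode == "delta") {
    d <- delta_ratios(s)
    member_values <- lapply(tps, function(t) {
      v <- d$values[intersect(group, rownames(d$values)), t]
      v[is.finite(v)]
    })
  } else {
    if (is.null(cnv_by_timepoint)) {
      cnv_by_timepoint <- lapply(tps, function(t) timepoint_cnv(s, ann, t, ...))
      names(cnv_by_timepoint) <- tps
    }
    member_values <- lapply(tps, function(t) {
      rec <- cnv_by_timepoint[[t]]$records
      v <- rec$cnv[rec$protein %in% group]
      v[is.finite(v)]
    })
  }
  names(member_values) <- tps
  if (length(member_values[[ref_t]]) < 2L)
    stop("group has fewer than 2 members with data at timepoint ", ref_t,
         call. = FALSE)
  rows <- lapply(tps, function(t) {
    v <- member_values[[t]]
    if (t == ref_t) {
      return(data.frame(timepoint = t, mode = mode, n = length(v),
                        mean_value = mean(v), spread = stats::var(v),
                        U = NA_real_, p = NA_real_, significant = NA,
                        stringsAsFactors = FALSE))
    }
    ref <- member_values[[ref_t]]
    if (paired) {
      shared_n <- min(length(v), length(ref))
      wt <- suppressWarnings(
        stats::wilcox.test(v[seq_len(shared_n)], ref[seq_len(shared_n)],
                           paired = TRUE))
      mw <- list(U = unname(wt$statistic), p = wt$p.value)
      if (is.nan(mw$p)) mw$p <- 1
    } else {
      mw <- mann_whitney(v, ref, mode = "auto")
    }
    data.frame(timepoint = t, mode = mode, n = length(v),
               mean_value = mean(v), spread = stats::var(v),
               U = mw$U, p = mw$p, significant = mw$p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
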