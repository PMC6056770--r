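#' Construct an abundance matrix
#'
#' Bundles a proteins x samples matrix of log2 abundances with the sample
#' design (condition label and replicate index per sample). Missing values
#' are `NA` and are distinct from zero throughout the package; they are
#' never imputed.
#'
#' @param values Numeric matrix, rows = proteins (rownames are protein
#'   identifiers, unique), columns = samples (colnames are sample
#'   identifiers). Values are log2 abundances, or log2 ratios against a
#'   common reference when `is_ratio = TRUE`.
#' @param design Data frame with columns `sample`, `condition`,
#'   `replicate`; one row per sample column of `values`.
#' @param is_ratio Logical; `TRUE` marks values as log2 ratios against a
#'   common reference (SILAC-style) rather than absolute log2 abundances.
#'
#' @return An object of class `"abundance_matrix"`: a list with elements
#'   `values`, `design` and `is_ratio`.
#' @export
abundance_matrix <- function(values, design, is_ratio = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0L)
    dimnames(values) <- list(character(), colnames(values))
  if (nrow(values) > 0L &&
      (is.null(rownames(values)) || anyDuplicated(rownames(values))))
    stop("protein identifiers (rownames) must be present and unique", call. = FALSE)
  if (is.null(colnames(values)))
    stop("sample identifiers (colnames) must be present", call. = FALSE)
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  req <- c("sample", "condition", "replicate")
  if (!all(req %in% names(design)))
    stop("design must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  design$sample <- as.character(design$sample)
  design$condition <- as.character(design$condition)
  if (anyDuplicated(design$sample))
    stop("duplicate sample in design: ",
         paste(unique(design$sample[duplicated(design$sample)]), collapse = ", "),
         call. = FALSE)
  unmapped <- setdiff(colnames(values), design$sample)
  if (length(unmapped))
    stop("sample column(s) not mapped in design: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  design <- design[match(colnames(values), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(values = values, design = design, is_ratio = isTRUE(is_ratio)),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d proteins x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_ratio) "log2 ratios" else "log2 abundances"))
  tab <- table(x$design$condition)
  cat("conditions:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("missing values: %.1f%%\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Condition labels of an abundance matrix
#' @param m An `abundance_matrix`.
#' @return Character vector of distinct condition labels, in design order.
#' @export
conditions <- function(m) unique(m$design$condition)

#' Read a protein abundance table and its sample design
#'
#' The abundance table is a delimited file whose first column holds protein
#' identifiers and whose remaining columns are samples. The design file has
#' columns `sample`, `condition`, `replicate` and must map every sample
#' column. Both files may be gzip-compressed. Linear-scale input is
#' log2-transformed; non-positive linear values become missing.
#'
#' @param path Path to the abundance table (TSV or CSV, optionally .gz).
#' @param design_path Path to the design table.
#' @param value_scale Either `"log2"` (values stored as-is) or `"linear"`
#'   (values log2-transformed; values <= 0 set to `NA`).
#' @param is_ratio Logical, passed to [abundance_matrix()].
#' @param sep Field separator; `""` (default) autodetects tab vs comma from
#'   the first line.
#'
#' @return An [abundance_matrix()].
#' @export
read_abundance_table <- function(path, design_path, value_scale = c("log2", "linear"),
                                 is_ratio = FALSE, sep = "") {
  value_scale <- match.arg(value_scale)
  tab <- read_delim_auto(path, sep)
  if (nrow(tab) == 0L) stop("empty abundance table: ", path, call. = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate protein id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (ncol(tab) < 2L) stop("no sample columns in ", path, call. = FALSE)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  if (value_scale == "linear") {
    vals[!is.na(vals) & vals <= 0] <- NA_real_
    vals <- log2(vals)
  }
  design <- read_delim_auto(design_path, sep)
  abundance_matrix(vals, design, is_ratio = is_ratio)
}

read_delim_auto <- function(path, sep = "") {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path, call. = FALSE)
  if (!nzchar(sep))
    sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(gzfile(path), header = TRUE, sep = sep, quote = "\"",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

#' Filter proteins by replicate coverage
#'
#' Keeps a protein only if, in each of the two conditions compared, it is
#' quantified (non-missing) in strictly more than half of that condition's
#' replicates. The number of dropped proteins is attached as attribute
#' `"n_dropped"` and reported via `message()`.
#'
#' @param m An [abundance_matrix()].
#' @param condition_pair Character vector of the two condition labels.
#' @param min_fraction Required fraction of replicates (strict inequality);
#'   default `0.5`.
#'
#' @return The filtered `abundance_matrix`, restricted to the samples of the
#'   two conditions.
#' @export
filter_by_replicate_coverage <- function(m, condition_pair, min_fraction = 0.5) {
  stopifnot(inherits(m, "abundance_matrix"))
  condition_pair <- as.character(condition_pair)
  if (length(condition_pair) != 2L)
    stop("'condition_pair' must name exactly two conditions", call. = FALSE)
  missing_cond <- setdiff(condition_pair, m$design$condition)
  if (length(missing_cond))
    stop("condition(s) absent from design: ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  keep_samp <- m$design$condition %in% condition_pair
  vals <- m$values[, keep_samp, drop = FALSE]
  design <- m$design[keep_samp, , drop = FALSE]
  keep <- rep(TRUE, nrow(vals))
  for (cond in condition_pair) {
    cols <- design$condition == cond
    n_rep <- sum(cols)
    if (n_rep == 0L) stop("condition has zero replicates: ", cond, call. = FALSE)
    n_obs <- rowSums(!is.na(vals[, cols, drop = FALSE]))
    keep <- keep & (n_obs > min_fraction * n_rep)
  }
  out <- abundance_matrix(vals[keep, , drop = FALSE], design, is_ratio = m$is_ratio)
  attr(out, "n_dropped") <- sum(!keep)
  message(sprintf("replicate-coverage filter: kept %d of %d proteins (%d dropped)",
                  sum(keep), length(keep), sum(!keep)))
  out
}

#' Quantile-normalize an abundance matrix across samples
#'
#' Forces every sample to share one common value distribution: each
#' sample's sorted observed values are replaced by the rank-wise means
#' across samples. Ties receive the mean of the rank-wise means over their
#' tied ranks, and samples with fewer observed values are mapped through
#' interpolation of the reference distribution at their quantile positions.
#' Missing entries stay missing.
#'
#' @param m An [abundance_matrix()] with at least two samples.
#' @return A quantile-normalized `abundance_matrix`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (ncol(m$values) < 2L)
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  all_na <- colSums(!is.na(m$values)) == 0L
  if (any(all_na))
    stop("sample(s) with all values missing: ",
         paste(colnames(m$values)[all_na], collapse = ", "), call. = FALSE)
  norm <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(norm) <- dimnames(m$values)
  out <- m
  out$values <- norm
  out
}

#' Average replicates per condition
#'
#' Arithmetic mean of the observed (non-missing) log2 values per
#' (protein, condition), with the number of observations recorded.
#'
#' @param m An [abundance_matrix()].
#' @return An object of class `"condition_means"`: list with `means`
#'   (proteins x conditions matrix), `n_observed` (same shape, integer) and
#'   `is_ratio`.
#' @export
average_replicates <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  conds <- unique(m$design$condition)
  means <- matrix(NA_real_, nrow(m$values), length(conds),
                  dimnames = list(rownames(m$values), conds))
  n_obs <- matrix(0L, nrow(m$values), length(conds),
                  dimnames = dimnames(means))
  for (cond in conds) {
    cols <- m$design$condition == cond
    sub <- m$values[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    s <- rowSums(sub, na.rm = TRUE)
    means[, cond] <- ifelse(n > 0L, s / n, NA_real_)
    n_obs[, cond] <- n
  }
  structure(list(means = means, n_observed = n_obs, is_ratio = m$is_ratio),
            class = "condition_means")
}

#' @export
print.condition_means <- function(x, ...) {
  cat(sprintf("condition_means: %d proteins x %d conditions\n",
              nrow(x$means), ncol(x$means)))
  invisible(x)
}
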