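#' Fit a per-compartment linear model
#'
#' Ordinary least squares of the test condition's mean log2 abundance (y)
#' on the reference condition's (x), over the proteins of one compartment.
#' The model p-value is the two-sided t-test of the slope (equivalently the
#' F-test of the simple regression) and determines whether the model is
#' retained (default threshold 0.05). Non-retained models still yield CNV
#' records downstream, flagged as non-retained.
#'
#' @param x,y Numeric vectors of mean log2 abundances (reference, test).
#' @param compartment Compartment name (for reporting).
#' @param min_fit_size Minimum number of proteins to fit (default 10; hard
#'   floor 3).
#' @param retention_p Retention threshold on the model p-value (default 0.05).
#' @return An object of class `"compartment_model"`: list with
#'   `compartment`, `n_proteins`, `slope`, `intercept`, `r_squared`,
#'   `model_p`, `retained`, `residual_sd` and the `fit` (an `lm` object).
#' @export
fit_compartment_model <- function(x, y, compartment = NA_character_,
                                  min_fit_size = 10L, retention_p = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    stop("compartment model not fittable: ", n, " point(s), hard floor is 3",
         call. = FALSE)
  if (n < min_fit_size)
    stop("compartment below min_fit_size (", min_fit_size, "): n = ", n,
         call. = FALSE)
  if (length(unique(x)) == 1L)
    stop("degenerate fit: x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # perfect fits are handled downstream
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- sm$r.squared
  model_p <- unname(sm$coefficients[2L, 4L])
  res <- stats::residuals(fit)
  structure(list(
    compartment = compartment,
    n_proteins = n,
    slope = slope,
    intercept = intercept,
    r_squared = r2,
    model_p = model_p,
    retained = model_p < retention_p,
    residual_sd = stats::sd(res),
    fit = fit
  ), class = "compartment_model")
}

#' @export
print.compartment_model <- function(x, ...) {
  cat(sprintf(
    "compartment_model [%s]: n=%d, y = %.4f + %.4f x, R2=%.3f, p=%.3g, %s\n",
    x$compartment, x$n_proteins, x$intercept, x$slope, x$r_squared, x$model_p,
    if (x$retained) "retained" else "NOT retained"))
  invisible(x)
}

#' Compute CNV values (standardized residuals) for one compartment
#'
#' The CNV value of a protein is its residual from the compartment model,
#' centered by the residual mean and scaled by the residual standard
#' deviation (n-1 denominator). When every residual is identical (e.g. a
#' perfect fit) the CNV value is not computable and is returned as `NA`
#' with a warning.
#'
#' @param model A `"compartment_model"` fitted on these points.
#' @param protein_ids Character vector of protein ids, aligned with `x`/`y`.
#' @param x,y The points the model was fitted on (reference, test means).
#' @param studentized Logical; use internally studentized residuals
#'   (leverage-corrected) instead of plain z-scored residuals. Default
#'   `FALSE`.
#' @return Data frame with columns `protein`, `compartment`, `x`, `y`,
#'   `residual`, `cnv`, `retained`.
#' @export
compute_cnv <- function(model, protein_ids, x, y, studentized = FALSE) {
  stopifnot(inherits(model, "compartment_model"))
  ok <- is.finite(x) & is.finite(y)
  protein_ids <- protein_ids[ok]; x <- x[ok]; y <- y[ok]
  e <- y - (model$intercept + model$slope * x)
  if (studentized) {
    h <- 1 / length(x) + (x - mean(x))^2 / sum((x - mean(x))^2)
    sigma <- sqrt(sum(e^2) / (length(e) - 2L))
    cnv <- e / (sigma * sqrt(1 - h))
  } else {
    s <- stats::sd(e)
    # a perfect fit leaves residuals at rounding-error scale; treat any
    # residual spread negligible relative to the data as degenerate
    degenerate_tol <- 1e-10 * max(1, stats::sd(y))
    if (!is.finite(s) || s < degenerate_tol) {
      warning("all residuals identical in compartment '", model$compartment,
              "': CNV values not computable", call. = FALSE)
      cnv <- rep(NA_real_, length(e))
    } else {
      cnv <- (e - mean(e)) / s
    }
  }
  data.frame(protein = protein_ids, compartment = model$compartment,
             x = x, y = y, residual = e, cnv = cnv,
             retained = model$retained,
             stringsAsFactors = FALSE)
}

#' Two-sided normal-null p-values for CNV values
#'
#' CNV values are standardized residuals; under the null of a protein
#' following its compartment trend they are treated as standard-normal
#' z-scores: p = 2 * (1 - Phi(|z|)).
#'
#' @param cnv Numeric vector of CNV values (may contain `NA`).
#' @return Numeric vector of p-values (`NA` where `cnv` is not finite).
#' @export
cnv_pvalues <- function(cnv) {
  p <- 2 * stats::pnorm(-abs(cnv))
  p[!is.finite(cnv)] <- NA_real_
  p
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment, clipped to 1. An optional empirical-null mode
#' first rescales the z-scores by a robust (MAD-based) null standard
#' deviation before converting to p-values, approximating an
#' empirical-null FDR estimate when the bulk of the z distribution is
#' wider or narrower than standard normal.
#'
#' @param p Numeric vector of p-values in [0, 1] (`NA` allowed).
#' @return Numeric vector of BH-adjusted q-values.
#' @export
qvalues <- function(p) {
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Empirical-null rescaled p-values for z-scores
#'
#' Estimates the null standard deviation of a z-score vector by the median
#' absolute deviation (consistent for the normal) and returns two-sided
#' p-values of the rescaled scores. Useful when outliers inflate the plain
#' residual SD.
#'
#' @param z Numeric vector of z-scores.
#' @return Numeric vector of p-values.
#' @export
empirical_null_pvalues <- function(z) {
  s0 <- stats::mad(z, na.rm = TRUE)
  if (!is.finite(s0) || s0 == 0) s0 <- 1
  cnv_pvalues(z / s0)
}

#' Run the CNV analysis across compartments
#'
#' For each compartment with at least `min_fit_size` annotated and
#' quantified proteins: fit the compartment linear model between the two
#' conditions' averaged log2 abundances, compute CNV values, p-values and
#' q-values. Proteins annotated to several compartments yield one record
#' per compartment. q-values are computed within each compartment by
#' default (each compartment has its own residual distribution); a pooled
#' mode adjusts across all records jointly.
#'
#' @param means A `"condition_means"` object (see [average_replicates()]).
#' @param ann A `"compartment_annotation"`.
#' @param conditions Character vector of two condition labels
#'   `c(reference, test)`; x is the reference, y the test condition, so a
#'   positive CNV value means relatively more abundant in the test
#'   condition than the compartment trend predicts.
#' @param compartments Compartment names to analyze; default all names
#'   appearing in the annotation.
#' @param min_fit_size Minimum proteins per compartment model (default 10).
#' @param retention_p Model retention threshold (default 0.05).
#' @param q_scope `"per-compartment"` (default) or `"pooled"`.
#' @param p_mode `"normal"` (default; plain standard-normal null) or
#'   `"empirical-null"` (MAD-rescaled, see [empirical_null_pvalues()]).
#' @param studentized Passed to [compute_cnv()].
#' @return An object of class `"cnv_result"`: list with `models` (data
#'   frame: compartment, n, slope, intercept, R2, model_p, retained),
#'   `records` (data frame: protein, compartment, x, y, residual, cnv, p,
#'   q, retained) and `skipped` (data frame of compartments below the size
#'   floor).
#' @export
run_cnv <- function(means, ann, conditions, compartments = NULL,
                    min_fit_size = 10L, retention_p = 0.05,
                    q_scope = c("per-compartment", "pooled"),
                    p_mode = c("normal", "empirical-null"),
                    studentized = FALSE) {
  stopifnot(inherits(means, "condition_means"),
            inherits(ann, "compartment_annotation"))
  q_scope <- match.arg(q_scope)
  p_mode <- match.arg(p_mode)
  conditions <- as.character(conditions)
  if (length(conditions) != 2L)
    stop("'conditions' must be c(reference, test)", call. = FALSE)
  absent <- setdiff(conditions, colnames(means$means))
  if (length(absent))
    stop("condition(s) absent from means: ", paste(absent, collapse = ", "),
         call. = FALSE)
  if (is.null(compartments))
    compartments <- sort(unique(unlist(ann$compartments, use.names = FALSE)))

  xs <- means$means[, conditions[1L]]
  ys <- means$means[, conditions[2L]]
  prot_all <- rownames(means$means)

  models <- list(); records <- list(); skipped <- list()
  for (comp in compartments) {
    members <- intersect(compartment_members(ann, comp), prot_all)
    idx <- match(members, prot_all)
    ok <- is.finite(xs[idx]) & is.finite(ys[idx])
    members <- members[ok]; idx <- idx[ok]
    if (length(members) < min_fit_size) {
      skipped[[comp]] <- data.frame(compartment = comp, n = length(members),
                                    reason = sprintf("below min_fit_size (%d)", min_fit_size),
                                    stringsAsFactors = FALSE)
      next
    }
    model <- fit_compartment_model(xs[idx], ys[idx], compartment = comp,
                                   min_fit_size = min_fit_size,
                                   retention_p = retention_p)
    rec <- compute_cnv(model, members, xs[idx], ys[idx], studentized = studentized)
    rec$p <- if (p_mode == "normal") cnv_pvalues(rec$cnv) else
      empirical_null_pvalues(rec$cnv)
    if (q_scope == "per-compartment") rec$q <- qvalues(rec$p)
    models[[comp]] <- data.frame(
      compartment = comp, n = model$n_proteins, slope = model$slope,
      intercept = model$intercept, R2 = model$r_squared,
      model_p = model$model_p, retained = model$retained,
      stringsAsFactors = FALSE)
    records[[comp]] <- rec
  }
  if (!length(models))
    stop("no compartment had enough quantified proteins to fit a model",
         call. = FALSE)
  records <- do.call(rbind, c(records, list(make.row.names = FALSE)))
  if (q_scope == "pooled") records$q <- qvalues(records$p)
  structure(list(
    models = do.call(rbind, c(models, list(make.row.names = FALSE))),
    records = records,
    skipped = if (length(skipped))
      do.call(rbind, c(skipped, list(make.row.names = FALSE)))
    else data.frame(compartment = character(), n = integer(),
                    reason = character(), stringsAsFactors = FALSE)
  ), class = "cnv_result")
}

#' @export
print.cnv_result <- function(x, ...) {
  cat(sprintf("cnv_result: %d compartment model(s), %d record(s), %d skipped\n",
              nrow(x$models), nrow(x$records), nrow(x$skipped)))
  print(x$models, row.names = FALSE)
  invisible(x)
}

#' Per-protein CNV summary (minimum q across compartments)
#'
#' Collapses multi-compartment CNV records to one row per protein: the
#' minimum q-value across the protein's compartments and the compartment
#' achieving it. Used for overlap classification against the standard
#' differential expression comparator.
#'
#' @param records The `records` data frame of a [run_cnv()] result.
#' @param compartments Optional subset of compartments to consider (e.g.
#'   the four major ones).
#' @return Data frame with columns `protein`, `q_cnv`, `cnv`,
#'   `compartment`.
#' @export
cnv_protein_summary <- function(records, compartments = NULL) {
  if (!is.null(compartments))
    records <- records[records$compartment %in% compartments, , drop = FALSE]
  records <- records[is.finite(records$q), , drop = FALSE]
  if (!nrow(records))
    return(data.frame(protein = character(), q_cnv = numeric(),
                      cnv = numeric(), compartment = character(),
                      stringsAsFactors = FALSE))
  ord <- order(records$protein, records$q)
  records <- records[ord, , drop = FALSE]
  first <- !duplicated(records$protein)
  data.frame(protein = records$protein[first], q_cnv = records$q[first],
             cnv = records$cnv[first], compartment = records$compartment[first],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlate CNV values between two model variants
#'
#' Per-compartment Pearson correlation of CNV values for proteins shared
#' between two runs (e.g. all-protein models vs compartment-exclusive
#' models), plus the average across compartments. Supports the robustness
#' check that multi-compartment membership does not distort the models.
#'
#' @param records_all,records_exclusive `records` data frames from two
#'   [run_cnv()] calls.
#' @return List with `per_compartment` (data frame: compartment,
#'   n_shared, pearson_r) and `average_r`.
#' @export
compare_model_variants <- function(records_all, records_exclusive) {
  comps <- intersect(unique(records_all$compartment),
                     unique(records_exclusive$compartment))
  rows <- lapply(comps, function(comp) {
    a <- records_all[records_all$compartment == comp, ]
    b <- records_exclusive[records_exclusive$compartment == comp, ]
    shared <- intersect(a$protein, b$protein)
    va <- a$cnv[match(shared, a$protein)]
    vb <- b$cnv[match(shared, b$protein)]
    ok <- is.finite(va) & is.finite(vb)
    r <- if (sum(ok) >= 3L) stats::cor(va[ok], vb[ok]) else NA_real_
    data.frame(compartment = comp, n_shared = sum(ok), pearson_r = r,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(per_compartment = per, average_r = mean(per$pearson_r, na.rm = TRUE))
}
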