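#' Specify a synthetic two-condition proteomics experiment
#'
#' Emulates the generative picture behind compartment normalization: each
#' protein has a baseline log2 abundance; between the reference and the
#' test condition its compartment may shift wholesale by delta_c log2
#' units (a morphological change, e.g. more organelles), each protein
#' carries an independent within-compartment residual (sigma_res), a small
#' fraction of proteins are true composition outliers displaced by
#' +/- gamma * sigma_res, and every replicate measurement adds noise
#' (sigma_rep). Missing values are missing-completely-at-random by
#' default; an intensity-dependent left-censoring mode is available.
#'
#' @param compartments Named integer vector: proteins per compartment.
#' @param delta Named numeric vector of per-compartment shifts (log2
#'   units); unnamed compartments default to 0.
#' @param n_background Number of unannotated background proteins.
#' @param baseline_mean,baseline_sd Baseline log2 abundance distribution
#'   (default N(25, 2), an iBAQ-like scale).
#' @param sigma_rep Replicate noise SD (log2 units, default 0.2).
#' @param sigma_res Within-compartment residual SD (log2 units, default
#'   0.3).
#' @param f_out Outlier fraction per compartment (default 0).
#' @param gamma Outlier effect size in units of `sigma_res` (default 4).
#' @param missing_rate Missing-value rate in [0, 1) (default 0).
#' @param missing_mode `"mcar"` (default) or `"censor"` (left-censoring:
#'   the lowest `missing_rate` fraction of replicate values is removed).
#' @param n_reps Replicates per condition (default 3).
#' @param seed Integer RNG seed.
#' @return A validated list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(compartments = c(mitochondrion = 200),
                            delta = c(mitochondrion = 0),
                            n_background = 2000,
                            baseline_mean = 25, baseline_sd = 2,
                            sigma_rep = 0.2, sigma_res = 0.3,
                            f_out = 0, gamma = 4,
                            missing_rate = 0,
                            missing_mode = c("mcar", "censor"),
                            n_reps = 3L, seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  if (is.null(names(compartments)) || any(!nzchar(names(compartments))))
    stop("invalid spec field 'compartments': must be a named vector", call. = FALSE)
  if (any(compartments < 0)) stop("invalid spec field 'compartments': negative size", call. = FALSE)
  for (fld in c("sigma_rep", "sigma_res", "baseline_sd"))
    if (get(fld) < 0) stop("invalid spec field '", fld, "': must be >= 0", call. = FALSE)
  if (f_out < 0 || f_out > 1) stop("invalid spec field 'f_out': must be in [0,1]", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("invalid spec field 'missing_rate': must be in [0,1)", call. = FALSE)
  if (n_reps < 1L) stop("invalid spec field 'n_reps': must be >= 1", call. = FALSE)
  d <- stats::setNames(rep(0, length(compartments)), names(compartments))
  unknown <- setdiff(names(delta), names(compartments))
  if (length(unknown))
    stop("invalid spec field 'delta': unknown compartment(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  d[names(delta)] <- delta
  structure(list(compartments = compartments, delta = d,
                 n_background = as.integer(n_background),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 sigma_rep = sigma_rep, sigma_res = sigma_res,
                 f_out = f_out, gamma = gamma,
                 missing_rate = missing_rate, missing_mode = missing_mode,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate a synthetic two-condition dataset with ground truth
#'
#' Condition A abundance: a_i ~ N(baseline_mean, baseline_sd^2).
#' Condition B abundance: b_i = a_i + delta_c(i) + eps_i + o_i with
#' eps_i ~ N(0, sigma_res^2) and o_i = +/- gamma * sigma_res for the
#' round(f_out * n) outliers of each compartment (signs alternating so the
#' compartment model slope stays unbiased), 0 otherwise. Background
#' proteins get delta = 0 and no annotation. Replicates add
#' N(0, sigma_rep^2); missingness is applied last. The same seed
#' reproduces the output exactly.
#'
#' @param spec A [simulation_spec()].
#' @return List with `matrix` (an [abundance_matrix()], conditions "A" and
#'   "B" with `n_reps` replicates each), `annotation` (a
#'   `"compartment_annotation"`), and `truth` (data frame: protein,
#'   compartment, delta, is_outlier, residual_effect — the latter the true
#'   eps_i + o_i).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  comp_names <- names(spec$compartments)
  comp_of <- c(rep(comp_names, spec$compartments),
               rep(NA_character_, spec$n_background))
  n <- length(comp_of)
  prot <- sprintf("P%05d", seq_len(n))

  a <- stats::rnorm(n, spec$baseline_mean, spec$baseline_sd)
  eps <- stats::rnorm(n, 0, spec$sigma_res)
  delta <- ifelse(is.na(comp_of), 0, spec$delta[comp_of])
  o <- numeric(n)
  is_out <- logical(n)
  for (comp in comp_names) {
    idx <- which(comp_of == comp)
    k <- round(spec$f_out * length(idx))
    if (k > 0L) {
      pick <- sample(idx, k)
      signs <- rep(c(1, -1), length.out = k)
      o[pick] <- signs * spec$gamma * spec$sigma_res
      is_out[pick] <- TRUE
    }
  }
  b <- a + delta + eps + o

  reps <- function(mu, cond) {
    m <- matrix(stats::rnorm(n * spec$n_reps, 0, spec$sigma_rep), n, spec$n_reps) + mu
    colnames(m) <- sprintf("%s_r%d", cond, seq_len(spec$n_reps))
    m
  }
  vals <- cbind(reps(a, "A"), reps(b, "B"))
  rownames(vals) <- prot
  if (spec$missing_rate > 0) {
    if (spec$missing_mode == "mcar") {
      drop <- matrix(stats::runif(length(vals)) < spec$missing_rate,
                     nrow(vals), ncol(vals))
    } else {
      thr <- stats::quantile(vals, spec$missing_rate)
      drop <- vals < thr
    }
    vals[drop] <- NA_real_
  }
  design <- data.frame(
    sample = colnames(vals),
    condition = rep(c("A", "B"), each = spec$n_reps),
    replicate = rep(seq_len(spec$n_reps), 2L),
    stringsAsFactors = FALSE)
  ann <- as_compartment_annotation(
    stats::setNames(as.list(comp_of[!is.na(comp_of)]), prot[!is.na(comp_of)]))
  truth <- data.frame(protein = prot, compartment = comp_of, delta = delta,
                      is_outlier = is_out, residual_effect = eps + o,
                      stringsAsFactors = FALSE)
  list(matrix = abundance_matrix(vals, design), annotation = ann, truth = truth)
}

#' Generate a synthetic SILAC ratio time course with ground truth
#'
#' Baseline log2 ratios r_1 ~ N(ratio_mean, ratio_sd^2); at later
#' timepoints r_t = r_1 + drift_c(t) + trajectory effect + residual noise.
#' Compartment drifts emulate organelle-level remodeling with age;
#' per-protein trajectory effects emulate proteins deviating from their
#' compartment's trajectory.
#'
#' @param spec A [simulation_spec()] (`compartments`, `sigma_res`,
#'   `n_background`, `seed` are used; ratios have no replicates).
#' @param timepoints Character vector of ordered timepoint labels
#'   (default `c("d1","d6","d12","d17","d22")`).
#' @param drift Named list: compartment -> numeric vector of per-timepoint
#'   drifts (log2 units, first entry must be 0); missing compartments
#'   drift 0.
#' @param trajectory_effects Optional data frame (protein, timepoint,
#'   effect) of extra per-protein offsets.
#' @param ratio_mean,ratio_sd Baseline ratio distribution (default
#'   N(0, 1)).
#' @return List with `series` (a [ratio_series()]), `annotation`, and
#'   `truth` (data frame: protein, compartment, timepoint, drift, effect).
#' @export
generate_timecourse <- function(spec,
                                timepoints = c("d1", "d6", "d12", "d17", "d22"),
                                drift = list(),
                                trajectory_effects = NULL,
                                ratio_mean = 0, ratio_sd = 1) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (length(timepoints) < 2L) stop("need >= 2 timepoints", call. = FALSE)
  set.seed(spec$seed)
  comp_names <- names(spec$compartments)
  comp_of <- c(rep(comp_names, spec$compartments),
               rep(NA_character_, spec$n_background))
  n <- length(comp_of)
  prot <- sprintf("P%05d", seq_len(n))
  tn <- length(timepoints)

  dr <- matrix(0, n, tn, dimnames = list(prot, timepoints))
  for (comp in names(drift)) {
    v <- drift[[comp]]
    if (length(v) != tn || v[[1L]] != 0)
      stop("drift for '", comp, "' must have one entry per timepoint, first 0",
           call. = FALSE)
    dr[comp_of %in% comp, ] <- matrix(v, sum(comp_of %in% comp), tn, byrow = TRUE)
  }
  eff <- matrix(0, n, tn, dimnames = list(prot, timepoints))
  if (!is.null(trajectory_effects)) {
    for (i in seq_len(nrow(trajectory_effects))) {
      eff[trajectory_effects$protein[i], trajectory_effects$timepoint[i]] <-
        trajectory_effects$effect[i]
    }
  }
  r1 <- stats::rnorm(n, ratio_mean, ratio_sd)
  noise <- cbind(0, matrix(stats::rnorm(n * (tn - 1L), 0, spec$sigma_res),
                           n, tn - 1L))
  vals <- r1 + dr + eff + noise
  dimnames(vals) <- list(prot, timepoints)
  ann <- as_compartment_annotation(
    stats::setNames(as.list(comp_of[!is.na(comp_of)]), prot[!is.na(comp_of)]))
  truth <- data.frame(
    protein = rep(prot, tn),
    compartment = rep(comp_of, tn),
    timepoint = rep(timepoints, each = n),
    drift = as.vector(dr), effect = as.vector(eff),
    stringsAsFactors = FALSE)
  list(series = ratio_series(vals), annotation = ann, truth = truth)
}

#' Write a simulated dataset to pipeline-readable files
#'
#' Emits the same TSV formats the pipeline reads (abundance table, design
#' table, grouping table) plus the ground-truth table.
#'
#' @param sim Result of [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "abundance.tsv"),
             design = file.path(dir, "design.tsv"),
             groups = file.path(dir, "groups.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_tsv(data.frame(protein = rownames(sim$matrix$values),
                       sim$matrix$values, check.names = FALSE),
            paths[["matrix"]])
  write_tsv(sim$matrix$design, paths[["design"]])
  ann <- sim$annotation$compartments
  write_tsv(data.frame(protein = rep(names(ann), lengths(ann)),
                       group = unlist(ann, use.names = FALSE)),
            paths[["groups"]])
  write_tsv(sim$truth, paths[["truth"]])
  invisible(paths)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
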