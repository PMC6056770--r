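#' Build a run configuration
#'
#' @param ... Configuration fields overriding the defaults (see
#'   [run_compare()] / [run_timecourse()] for their meaning). A YAML file
#'   can be loaded with [read_run_config()].
#' @return List of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(
    mode = "compare",
    matrix = NULL, design = NULL,
    obo = NULL, gaf = NULL, groups = NULL,
    compartments = "four",
    conditions = NULL, timepoints = NULL,
    value_scale = "log2", is_ratio = FALSE,
    normalization = "cnv-raw",          # or "comparison-quantile"
    min_fit_size = 10L, model_p = 0.05,
    q_thresholds = c(0.05, 0.1, 0.25),
    alpha = 0.01, group_alpha = 0.05,
    q_scope = "per-compartment", p_mode = "normal",
    seed = 1L, outdir = NULL)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(override)] <- override
  for (fld in c("model_p", "alpha", "group_alpha"))
    if (cfg[[fld]] <= 0 || cfg[[fld]] >= 1)
      stop("config field '", fld, "' must be in (0,1)", call. = FALSE)
  if (!cfg$normalization %in% c("cnv-raw", "comparison-quantile"))
    stop("unknown normalization mode: ", cfg$normalization, call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path Path to a flat key-value YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

resolve_annotation <- function(cfg) {
  has_go <- !is.null(cfg$obo) && !is.null(cfg$gaf)
  has_custom <- !is.null(cfg$groups)
  if (has_go == has_custom)
    stop("exactly one annotation source required: obo+gaf or groups",
         call. = FALSE)
  if (has_custom) return(load_custom_groups(cfg$groups))
  graph <- parse_ontology(cfg$obo)
  defs <- if (cfg$compartments %in% c("four", "ten"))
    compartment_definitions(cfg$compartments)
  else compartment_definitions(cfg$compartments)
  assign_compartments(read_gaf(cfg$gaf), expand_compartments(graph, defs))
}

resolve_compartments <- function(cfg, ann) {
  if (identical(cfg$compartments, "four")) return(names(compartment_definitions("four")))
  if (identical(cfg$compartments, "ten")) return(names(compartment_definitions("ten")))
  comps <- cfg$compartments
  known <- unique(unlist(ann$compartments, use.names = FALSE))
  unknown <- setdiff(comps, union(known, names(compartment_definitions("ten"))))
  if (length(unknown))
    stop("unknown compartment name(s) in config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  comps
}

config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outdir <- NULL  # the hash identifies the analysis, not its destination
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(cfg)), f)
  unname(tools::md5sum(f))
}

#' Run the pairwise compare pipeline
#'
#' Executes, in order: replicate-coverage filter; replicate averaging of
#' the raw (unnormalized) matrix for the CNV branch; annotation;
#' compartment shift tests; per-compartment CNV models; quantile
#' normalization and the moderated-t comparator; overlap classification.
#' In `normalization = "comparison-quantile"` mode (used when benchmarking
#' the two approaches on identical input) the CNV branch also runs on the
#' quantile-normalized matrix. All tables are written as TSV into
#' `cfg$outdir` (when set) along with a run log carrying the config hash;
#' re-running the same config reproduces identical files.
#'
#' @param cfg A [run_config()] with `mode = "compare"`. Instead of file
#'   paths, `matrix` may be an [abundance_matrix()] and `groups` /
#'   annotation may be supplied as a `"compartment_annotation"` via the
#'   `annotation` field of this function.
#' @param annotation Optional pre-built `"compartment_annotation"`
#'   (bypasses the config's annotation source).
#' @return List of class `"compare_result"`: `shift`, `cnv`, `de`,
#'   `overlap`, `correlation_r`, `counts` (protein counts after each
#'   stage), `stages` (ordered stage names), `config_hash`, `outdir`.
#' @export
run_compare <- function(cfg, annotation = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (!identical(cfg$mode, "compare"))
    stop("config mode is not 'compare'", call. = FALSE)
  if (is.null(cfg$conditions) || length(cfg$conditions) != 2L)
    stop("config must name two conditions c(reference, test)", call. = FALSE)
  stages <- character()
  counts <- list()
  log_line <- function(...) message(sprintf(...))

  m <- if (inherits(cfg$matrix, "abundance_matrix")) cfg$matrix else
    read_abundance_table(cfg$matrix, cfg$design, value_scale = cfg$value_scale,
                         is_ratio = cfg$is_ratio)
  counts$input <- nrow(m$values)

  ann <- if (!is.null(annotation)) annotation else resolve_annotation(cfg)
  comps <- resolve_compartments(cfg, ann)

  stages <- c(stages, "filter")
  m <- filter_by_replicate_coverage(m, cfg$conditions)
  counts$after_coverage_filter <- nrow(m$values)

  # CNV branch: averaged replicates, no prior normalization (unless the
  # benchmarking mode asks for a common quantile-normalized input)
  if (cfg$normalization == "comparison-quantile") {
    stages <- c(stages, "quantile_normalize_cnv_branch")
    m_cnv <- quantile_normalize(m)
  } else m_cnv <- m
  stages <- c(stages, "average")
  means <- average_replicates(m_cnv)

  stages <- c(stages, "annotate")
  counts$annotated <- sum(rownames(means$means) %in% names(ann$compartments))

  stages <- c(stages, "shift_tests")
  shift <- shift_report(means, ann, cfg$conditions, compartments = comps,
                        alpha = cfg$alpha)

  stages <- c(stages, "cnv")
  cnv <- run_cnv(means, ann, cfg$conditions, compartments = comps,
                 min_fit_size = cfg$min_fit_size, retention_p = cfg$model_p,
                 q_scope = cfg$q_scope, p_mode = cfg$p_mode)
  counts$cnv_records <- nrow(cnv$records)

  # comparator branch: quantile normalization precedes the moderated t
  stages <- c(stages, "quantile_normalize_comparator", "moderated_t")
  de <- moderated_ttest(quantile_normalize(m), cfg$conditions)
  counts$de_records <- nrow(de$records)

  stages <- c(stages, "overlap")
  cnv_sum <- cnv_protein_summary(cnv$records, compartments = comps)
  overlap <- classify_overlap(de$records, cnv_sum,
                              thresholds = cfg$q_thresholds)
  corr <- statistic_correlation(de$records, cnv_sum)

  res <- structure(list(shift = shift, cnv = cnv, de = de, overlap = overlap,
                        correlation_r = corr, counts = counts, stages = stages,
                        config_hash = config_hash(cfg), outdir = cfg$outdir),
                   class = "compare_result")
  if (!is.null(cfg$outdir)) write_compare_outputs(res, cfg)
  res
}

write_compare_outputs <- function(res, cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(cfg$outdir, name)
  write_tsv(res$cnv$models, out("models.tsv"))
  write_tsv(res$cnv$records, out("cnv_records.tsv"))
  write_tsv(res$shift$results, out("shift_report.tsv"))
  write_tsv(res$de$records, out("de_records.tsv"))
  write_tsv(res$overlap$classes, out("overlap_classes.tsv"))
  write_tsv(res$overlap$percentages, out("class_percentages.tsv"))
  writeLines(c(
    sprintf("config_hash: %s", res$config_hash),
    sprintf("stages: %s", paste(res$stages, collapse = " -> ")),
    sprintf("%s: %d", names(res$counts), unlist(res$counts)),
    sprintf("statistic_correlation_r: %s", format(res$correlation_r))
  ), out("run_log.txt"))
  invisible(res)
}

#' Run the time-course pipeline
#'
#' Reads a wide ratio table (protein x ordered timepoints of log2 SILAC
#' ratios against a common reference), computes delta ratios vs the
#' baseline (first) timepoint, per-timepoint CNV records against the
#' baseline, per-compartment trajectory tests, and, when a grouping file
#' is given, group trajectory tests in both delta and CNV readouts.
#'
#' @param cfg A [run_config()] with `mode = "timecourse"`; `matrix` is
#'   the ratio table path (or a `"ratio_series"`), `groups` the
#'   annotation, and the optional `complexes` field (via `groups_extra`
#'   argument) a second grouping of protein complexes to test.
#' @param annotation Optional pre-built annotation.
#' @param complex_groups Optional named list: group name -> member protein
#'   ids, tested with [group_trajectory_test()].
#' @return List of class `"timecourse_result"`: `delta`, `cnv_by_timepoint`,
#'   `trajectories`, `group_tests`, `stages`, `config_hash`, `outdir`.
#' @export
run_timecourse <- function(cfg, annotation = NULL, complex_groups = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (!identical(cfg$mode, "timecourse"))
    stop("config mode is not 'timecourse'", call. = FALSE)
  stages <- character()
  s <- if (inherits(cfg$matrix, "ratio_series")) cfg$matrix else
    read_ratio_table(cfg$matrix)
  if (!is.null(cfg$timepoints)) {
    if (anyDuplicated(cfg$timepoints))
      stop("duplicate timepoint labels in config", call. = FALSE)
    s <- ratio_series(s$values, as.character(cfg$timepoints))
  }
  ann <- if (!is.null(annotation)) annotation else resolve_annotation(cfg)
  comps <- resolve_compartments(cfg, ann)

  stages <- c(stages, "delta")
  delta <- delta_ratios(s)

  stages <- c(stages, "timepoint_cnv")
  tps <- setdiff(s$timepoints, s$baseline)
  cnv_by_tp <- lapply(tps, function(t)
    timepoint_cnv(s, ann, t, compartments = comps,
                  min_fit_size = cfg$min_fit_size, retention_p = cfg$model_p,
                  q_scope = cfg$q_scope, p_mode = cfg$p_mode))
  names(cnv_by_tp) <- tps

  stages <- c(stages, "trajectories")
  traj <- lapply(comps, function(comp)
    tryCatch(compartment_trajectory_test(s, ann, comp, alpha = cfg$alpha),
             error = function(e) NULL))
  names(traj) <- comps
  traj <- traj[!vapply(traj, is.null, logical(1L))]

  group_tests <- NULL
  if (!is.null(complex_groups)) {
    stages <- c(stages, "group_tests")
    group_tests <- lapply(complex_groups, function(members) {
      rbind(
        group_trajectory_test(s, ann, members, mode = "delta",
                              alpha = cfg$group_alpha),
        group_trajectory_test(s, ann, members, mode = "cnv",
                              cnv_by_timepoint = cnv_by_tp,
                              alpha = cfg$group_alpha))
    })
  }
  res <- structure(list(delta = delta, cnv_by_timepoint = cnv_by_tp,
                        trajectories = traj, group_tests = group_tests,
                        baseline = s$baseline, stages = stages,
                        config_hash = config_hash(cfg), outdir = cfg$outdir),
                   class = "timecourse_result")
  if (!is.null(cfg$outdir)) write_timecourse_outputs(res, cfg)
  res
}

write_timecourse_outputs <- function(res, cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(cfg$outdir, name)
  write_tsv(data.frame(protein = rownames(res$delta$values),
                       res$delta$values, check.names = FALSE),
            out("delta_ratios.tsv"))
  for (t in names(res$cnv_by_timepoint))
    write_tsv(res$cnv_by_timepoint[[t]]$records,
              out(sprintf("cnv_records_%s.tsv", t)))
  traj <- do.call(rbind, c(lapply(names(res$trajectories), function(comp)
    cbind(compartment = comp, res$trajectories[[comp]])),
    list(make.row.names = FALSE)))
  write_tsv(traj, out("trajectories.tsv"))
  if (!is.null(res$group_tests)) {
    gt <- do.call(rbind, c(lapply(names(res$group_tests), function(g)
      cbind(group = g, res$group_tests[[g]])), list(make.row.names = FALSE)))
    write_tsv(gt, out("group_tests.tsv"))
  }
  writeLines(c(
    sprintf("config_hash: %s", res$config_hash),
    sprintf("baseline: %s", res$baseline),
    sprintf("stages: %s", paste(res$stages, collapse = " -> "))
  ), out("run_log.txt"))
  invisible(res)
}
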