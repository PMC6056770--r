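#' Empirical-Bayes moderated two-sample t-test
#'
#' The standard differential expression comparator: per protein, the
#' pooled within-group variance s_g^2 (d_g residual degrees of freedom,
#' from the observed replicates of each condition) is shrunk toward a
#' prior s0^2 with d0 prior degrees of freedom,
#' \deqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g),}
#' and the moderated t statistic
#' \eqn{\tilde{t} = \Delta / (\tilde{s}_g \sqrt{1/n_A + 1/n_B})} is
#' referred to a t distribution with d0 + d_g degrees of freedom. The
#' hyperparameters (d0, s0^2) are estimated by closed-form moment matching
#' on log s_g^2 (digamma/trigamma inversion). Expects a
#' quantile-normalized matrix.
#'
#' @param m An [abundance_matrix()].
#' @param conditions `c(reference, test)`; the reported log2FC is
#'   test - reference.
#' @param d0_mode `"estimate"` (default) or `"fixed"`.
#' @param d0,s0_sq Prior degrees of freedom and prior variance when
#'   `d0_mode = "fixed"`. `d0 = 0` reduces to the ordinary pooled t-test;
#'   `d0 = Inf` fixes every variance at `s0_sq`.
#' @return List with `records` (data frame: protein, log2fc, s2, s2_post,
#'   t, df, p, q), `d0`, `s0_sq` and `n_excluded` (proteins with no
#'   residual degrees of freedom).
#' @export
moderated_ttest <- function(m, conditions, d0_mode = c("estimate", "fixed"),
                            d0 = NULL, s0_sq = NULL) {
  stopifnot(inherits(m, "abundance_matrix"))
  d0_mode <- match.arg(d0_mode)
  conditions <- as.character(conditions)
  if (length(conditions) != 2L)
    stop("'conditions' must be c(reference, test)", call. = FALSE)
  cols_a <- m$design$condition == conditions[1L]
  cols_b <- m$design$condition == conditions[2L]
  if (!any(cols_a) || !any(cols_b))
    stop("condition(s) absent from design", call. = FALSE)
  va <- m$values[, cols_a, drop = FALSE]
  vb <- m$values[, cols_b, drop = FALSE]
  na_ <- rowSums(!is.na(va)); nb <- rowSums(!is.na(vb))
  mean_a <- rowMeans(va, na.rm = TRUE); mean_b <- rowMeans(vb, na.rm = TRUE)
  ss_a <- rowSums((va - mean_a)^2, na.rm = TRUE)
  ss_b <- rowSums((vb - mean_b)^2, na.rm = TRUE)
  dg <- pmax(na_ - 1L, 0L) + pmax(nb - 1L, 0L)
  usable <- na_ >= 1L & nb >= 1L & dg >= 1L
  n_excluded <- sum(!usable)
  prot <- rownames(m$values)[usable]
  dg <- dg[usable]
  s2 <- (ss_a[usable] + ss_b[usable]) / dg
  lfc <- (mean_b - mean_a)[usable]
  scale_ <- sqrt(1 / na_[usable] + 1 / nb[usable])

  if (d0_mode == "estimate") {
    hp <- fit_variance_prior(s2, dg)
    d0 <- hp$d0; s0_sq <- hp$s0_sq
  } else {
    if (is.null(d0)) stop("d0_mode='fixed' requires d0", call. = FALSE)
    if (is.null(s0_sq)) s0_sq <- mean(s2)
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  tstat <- lfc / (sqrt(s2_post) * scale_)
  df_total <- dg + d0
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[!is.finite(tstat)] <- NA_real_
  records <- data.frame(protein = prot, log2fc = lfc, s2 = s2,
                        s2_post = s2_post, t = tstat, df = df_total,
                        p = p, q = qvalues(p), stringsAsFactors = FALSE)
  list(records = records, d0 = d0, s0_sq = s0_sq, n_excluded = n_excluded)
}

#' Moment-matching estimate of the variance prior
#'
#' Fits the scaled inverse-chi-square prior of the moderated t model:
#' given sample variances s2 with dg degrees of freedom each, matches the
#' mean and variance of log(s2) to the theoretical log-F moments,
#' inverting the trigamma function by Newton iteration.
#'
#' @param s2 Sample variances (> 0 entries are used).
#' @param dg Degrees of freedom per variance (recycled).
#' @return List with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, dg) {
  dg <- rep_len(dg, length(s2))
  ok <- is.finite(s2) & s2 > 0 & dg > 0
  s2 <- s2[ok]; dg <- dg[ok]
  if (length(s2) < 2L) stop("need >= 2 positive variances", call. = FALSE)
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(dg / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Inverse of the trigamma function
#'
#' Newton iteration on 1/trigamma, which is nearly linear; converges in a
#' handful of steps for any positive argument.
#'
#' @param x Positive numeric vector.
#' @return y such that trigamma(y) = x.
#' @export
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Classify proteins by standard-vs-CNV significance overlap
#'
#' At each q-value threshold tau, proteins split into: `both`
#' (significant by the standard comparator and the CNV approach),
#' `standard-only` (significant only proteome-wide, interpreted as
#' compartment-wide abundance change), `cnv-only` (significant only
#' relative to the compartment trend: changes newly revealed after
#' compartment normalization), and `neither`.
#'
#' @param de `records` data frame from [moderated_ttest()].
#' @param cnv_summary Per-protein CNV summary from [cnv_protein_summary()].
#' @param thresholds Numeric q-value thresholds (default
#'   `c(0.05, 0.1, 0.25)`).
#' @return List with `classes` (data frame: protein, threshold, q_de,
#'   q_cnv, class, partial) and `percentages` (data frame: threshold,
#'   class, n, percent). Proteins present in only one analysis are
#'   classified on the available side and flagged `partial`.
#' @export
classify_overlap <- function(de, cnv_summary, thresholds = c(0.05, 0.1, 0.25)) {
  prots <- union(de$protein, cnv_summary$protein)
  q_de <- de$q[match(prots, de$protein)]
  q_cnv <- cnv_summary$q_cnv[match(prots, cnv_summary$protein)]
  out <- list()
  for (tau in thresholds) {
    sig_de <- !is.na(q_de) & q_de < tau
    sig_cnv <- !is.na(q_cnv) & q_cnv < tau
    cls <- ifelse(sig_de & sig_cnv, "both",
           ifelse(sig_de, "standard-only",
           ifelse(sig_cnv, "cnv-only", "neither")))
    out[[as.character(tau)]] <- data.frame(
      protein = prots, threshold = tau, q_de = q_de, q_cnv = q_cnv,
      class = cls, partial = is.na(q_de) | is.na(q_cnv),
      stringsAsFactors = FALSE)
  }
  classes <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  lvl <- c("both", "standard-only", "cnv-only", "neither")
  pct <- do.call(rbind, lapply(thresholds, function(tau) {
    sub <- classes[classes$threshold == tau, ]
    n <- as.integer(table(factor(sub$class, levels = lvl)))
    data.frame(threshold = tau, class = lvl, n = n,
               percent = 100 * n / length(prots), stringsAsFactors = FALSE)
  }))
  list(classes = classes, percentages = pct)
}

#' Correlation between standard and CNV significance
#'
#' Pearson correlation of the -log10 q-values of the two approaches over
#' shared proteins. A low correlation indicates complementarity, expected
#' when compartment-wide shifts dominate the standard statistics.
#'
#' @param de `records` from [moderated_ttest()].
#' @param cnv_summary From [cnv_protein_summary()].
#' @return Pearson r, or `NA` when fewer than 3 shared proteins or one of
#'   the vectors has zero variance.
#' @export
statistic_correlation <- function(de, cnv_summary) {
  shared <- intersect(de$protein, cnv_summary$protein)
  a <- -log10(de$q[match(shared, de$protein)])
  b <- -log10(cnv_summary$q_cnv[match(shared, cnv_summary$protein)])
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
  stats::cor(a[ok], b[ok])
}
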