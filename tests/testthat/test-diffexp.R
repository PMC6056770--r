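make_two_group <- function(n_prot = 60, n_rep = 3, delta = 0, seed = 31) {
  set.seed(seed)
  sds <- sqrt(rchisq(n_prot, 4) / 4)
  v <- matrix(rnorm(n_prot * 2 * n_rep, sd = sds), n_prot, 2 * n_rep)
  v[, (n_rep + 1):(2 * n_rep)] <- v[, (n_rep + 1):(2 * n_rep)] + delta
  rownames(v) <- sprintf("P%03d", seq_len(n_prot))
  colnames(v) <- c(sprintf("A_r%d", 1:n_rep), sprintf("B_r%d", 1:n_rep))
  abundance_matrix(v, data.frame(sample = colnames(v),
                                 condition = rep(c("A", "B"), each = n_rep),
                                 replicate = rep(1:n_rep, 2)))
}

test_that("moderated t with d0 = 0 reduces to the ordinary pooled t-test", {
  m <- make_two_group()
  mt <- moderated_ttest(m, c("A", "B"), d0_mode = "fixed", d0 = 0)
  va <- m$values[, 1:3]; vb <- m$values[, 4:6]
  s2 <- (rowSums((va - rowMeans(va))^2) + rowSums((vb - rowMeans(vb))^2)) / 4
  t_ref <- (rowMeans(vb) - rowMeans(va)) / sqrt(s2 * (1 / 3 + 1 / 3))
  expect_equal(mt$records$t, unname(t_ref), tolerance = 1e-8)
  expect_equal(mt$records$p, unname(2 * pt(-abs(t_ref), df = 4)),
               tolerance = 1e-8)
})

test_that("variance shrinkage follows the closed formula and its limits", {
  # s2 = (1, 4), dg = 4, d0 = 4, s0^2 = 2  ->  s2_post = (1.5, 3.0)
  expect_equal((4 * 2 + 4 * c(1, 4)) / (4 + 4), c(1.5, 3.0))

  mm <- make_two_group()
  base <- moderated_ttest(mm, c("A", "B"), d0_mode = "fixed", d0 = 0)
  s0 <- mean(base$records$s2)
  lo <- moderated_ttest(mm, c("A", "B"), d0_mode = "fixed", d0 = 1e-8, s0_sq = s0)
  hi <- moderated_ttest(mm, c("A", "B"), d0_mode = "fixed", d0 = 1e8, s0_sq = s0)
  expect_equal(lo$records$s2_post, base$records$s2, tolerance = 1e-6)
  expect_equal(hi$records$s2_post, rep(s0, nrow(hi$records)), tolerance = 1e-6)
  inf <- moderated_ttest(mm, c("A", "B"), d0_mode = "fixed", d0 = Inf, s0_sq = s0)
  expect_equal(inf$records$s2_post, rep(s0, nrow(inf$records)))

  # shrinkage is strictly increasing in s2 for fixed hyperparameters
  est <- moderated_ttest(mm, c("A", "B"))
  ord <- order(est$records$s2)
  expect_true(all(diff(est$records$s2_post[ord]) > -1e-12))
  expect_true(all(
    est$records$s2_post >= pmin(est$records$s2, est$s0_sq) - 1e-12 &
    est$records$s2_post <= pmax(est$records$s2, est$s0_sq) + 1e-12))
})

test_that("estimated hyperparameters and statistics match the empirical-Bayes reference", {
  skip_if_not_installed("limma")
  m <- make_two_group(n_prot = 120, delta = 0.5)
  mt <- moderated_ttest(m, c("A", "B"))
  design <- cbind(Intercept = 1, B = rep(c(0, 1), each = 3))
  eb <- limma::eBayes(limma::lmFit(m$values, design))
  expect_equal(mt$d0, eb$df.prior, tolerance = 1e-8)
  expect_equal(mt$s0_sq, eb$s2.prior, tolerance = 1e-8)
  expect_equal(mt$records$t, unname(eb$t[, 2]), tolerance = 1e-8)
  expect_equal(mt$records$p, unname(eb$p.value[, 2]), tolerance = 1e-8)
})

test_that("identical group means give t = 0 and p = 1", {
  v <- matrix(rep(c(1, 2, 3, 1, 2, 3), each = 1), 1, 6,
              dimnames = list("p1", c(sprintf("A_r%d", 1:3), sprintf("B_r%d", 1:3))))
  m <- abundance_matrix(v, data.frame(sample = colnames(v),
                                      condition = rep(c("A", "B"), each = 3),
                                      replicate = rep(1:3, 2)))
  mt <- moderated_ttest(m, c("A", "B"), d0_mode = "fixed", d0 = 0)
  expect_equal(mt$records$t, 0)
  expect_equal(mt$records$p, 1)
})

test_that("proteins without residual degrees of freedom are excluded and counted", {
  v <- matrix(rnorm(12), 2, 6,
              dimnames = list(c("ok", "thin"),
                              c(sprintf("A_r%d", 1:3), sprintf("B_r%d", 1:3))))
  v["thin", c(2, 3, 5, 6)] <- NA  # one observation per condition: dg = 0
  m <- abundance_matrix(v, data.frame(sample = colnames(v),
                                      condition = rep(c("A", "B"), each = 3),
                                      replicate = rep(1:3, 2)))
  mt <- moderated_ttest(m, c("A", "B"), d0_mode = "fixed", d0 = 0)
  expect_equal(mt$records$protein, "ok")
  expect_equal(mt$n_excluded, 1L)
})

test_that("overlap classes partition proteins at each threshold", {
  de <- data.frame(protein = c("a", "b", "c", "d"),
                   q = c(0.05, 0.5, 0.01, 0.5))
  cnv <- data.frame(protein = c("a", "b", "c", "e"),
                    q_cnv = c(0.5, 0.05, 0.01, 0.02),
                    cnv = c(1, -2, 3, 2), compartment = "mitochondrion")
  ov <- classify_overlap(de, cnv, thresholds = c(0.05, 0.1, 0.25))
  cl <- ov$classes
  at <- function(p, tau) cl$class[cl$protein == p & cl$threshold == tau]
  expect_equal(at("a", 0.1), "standard-only")
  expect_equal(at("b", 0.1), "cnv-only")
  expect_equal(at("c", 0.05), "both")
  expect_equal(at("d", 0.1), "neither")
  expect_equal(at("e", 0.1), "cnv-only")
  expect_true(all(cl$partial[cl$protein == "e"]))
  # classes partition the union of proteins at each threshold
  for (tau in unique(cl$threshold)) {
    sub <- cl[cl$threshold == tau, ]
    expect_setequal(sub$protein, c("a", "b", "c", "d", "e"))
    expect_false(anyDuplicated(sub$protein) > 0)
  }
  pct <- ov$percentages
  expect_equal(sum(pct$percent[pct$threshold == 0.1]), 100)
})

test_that("statistic correlation handles identical, independent and degenerate inputs", {
  set.seed(33)
  q <- runif(200, 1e-6, 1)
  de <- data.frame(protein = sprintf("P%d", 1:200), q = q)
  cnv_same <- data.frame(protein = de$protein, q_cnv = q)
  expect_equal(statistic_correlation(de, cnv_same), 1)
  cnv_ind <- data.frame(protein = de$protein, q_cnv = runif(200, 1e-6, 1))
  expect_lt(abs(statistic_correlation(de, cnv_ind)), 0.2)
  cnv_const <- data.frame(protein = de$protein, q_cnv = 0.5)
  expect_true(is.na(statistic_correlation(de, cnv_const)))
  expect_true(is.na(statistic_correlation(de[1:2, ], cnv_same[1:2, ])))
})
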