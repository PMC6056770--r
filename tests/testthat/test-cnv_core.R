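test_that("compartment model matches closed-form normal equations", {
  # worked example: x = 1..5, y = (1,3,2,5,4)
  m <- fit_compartment_model(1:5, c(1, 3, 2, 5, 4), "toy", min_fit_size = 3)
  expect_equal(m$slope, 0.8)
  expect_equal(m$intercept, 0.6)
  expect_equal(m$r_squared, 0.64)
  # slope t-test with n-2 df, computed independently from the correlation
  r <- cor(1:5, c(1, 3, 2, 5, 4))
  t_stat <- r * sqrt(3) / sqrt(1 - r^2)
  expect_equal(m$model_p, 2 * pt(-abs(t_stat), df = 3), tolerance = 1e-12)
  expect_false(m$retained)
  expect_equal(m$residual_sd, sd(c(1, 3, 2, 5, 4) - (0.6 + 0.8 * 1:5)))

  # perfect fit and degenerate inputs
  perf <- fit_compartment_model(1:10, 1:10, min_fit_size = 3)
  expect_equal(perf$slope, 1); expect_equal(perf$intercept, 0)
  expect_equal(perf$r_squared, 1)
  expect_error(fit_compartment_model(1:2, 1:2, min_fit_size = 3), "floor")
  expect_error(fit_compartment_model(1:5, 1:5, min_fit_size = 10), "min_fit_size")
  expect_error(fit_compartment_model(rep(1, 5), rnorm(5), min_fit_size = 3),
               "constant")
})

test_that("OLS agrees with normal equations on random instances", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    x <- rnorm(n, 20, 3)
    y <- 0.5 + 0.9 * x + rnorm(n, 0, 0.5)
    m <- fit_compartment_model(x, y, min_fit_size = 3)
    sxx <- sum((x - mean(x))^2)
    b1 <- sum((x - mean(x)) * (y - mean(y))) / sxx
    b0 <- mean(y) - b1 * mean(x)
    expect_equal(m$slope, b1, tolerance = 1e-10)
    expect_equal(m$intercept, b0, tolerance = 1e-10)
  }
})

test_that("fitted coefficients minimize SSE on a brute-force grid", {
  set.seed(12)
  for (i in 1:3) {
    x <- rnorm(20, 10, 2); y <- 1 + x + rnorm(20, 0, 0.4)
    m <- fit_compartment_model(x, y, min_fit_size = 3)
    step <- 0.01
    b0g <- seq(m$intercept - 0.3, m$intercept + 0.3, by = step)
    b1g <- seq(m$slope - 0.3, m$slope + 0.3, by = step)
    sse <- outer(b0g, b1g, Vectorize(function(b0, b1) sum((y - b0 - b1 * x)^2)))
    best <- arrayInd(which.min(sse), dim(sse))
    expect_equal(b0g[best[1]], m$intercept, tolerance = step)
    expect_equal(b1g[best[2]], m$slope, tolerance = step)
  }
})

test_that("CNV values are centered, unit-scaled standardized residuals", {
  m <- fit_compartment_model(1:5, c(1, 3, 2, 5, 4), "toy", min_fit_size = 3)
  rec <- compute_cnv(m, sprintf("p%d", 1:5), 1:5, c(1, 3, 2, 5, 4))
  expect_equal(rec$residual, c(-0.4, 0.8, -1.0, 1.2, -0.6), tolerance = 1e-12)
  expect_equal(rec$cnv, c(-0.4216, 0.8433, -1.0541, 1.2649, -0.6325),
               tolerance = 1e-4)
  expect_equal(mean(rec$residual), 0, tolerance = 1e-9)
  expect_equal(sd(rec$cnv), 1, tolerance = 1e-9)

  # perfect fit: residuals identical -> not computable, flagged by NA
  perf <- fit_compartment_model(1:10, 2 * (1:10), min_fit_size = 3)
  expect_warning(rec0 <- compute_cnv(perf, sprintf("p%d", 1:10), 1:10, 2 * (1:10)),
                 "not computable")
  expect_true(all(is.na(rec0$cnv)))

  # adding a constant to every y is absorbed by the intercept
  set.seed(3)
  x <- rnorm(30, 20, 2); y <- x + rnorm(30, 0, 0.3)
  m1 <- fit_compartment_model(x, y, min_fit_size = 3)
  m2 <- fit_compartment_model(x, y + 5, min_fit_size = 3)
  r1 <- compute_cnv(m1, sprintf("p%d", 1:30), x, y)
  r2 <- compute_cnv(m2, sprintf("p%d", 1:30), x, y + 5)
  expect_equal(r2$cnv, r1$cnv, tolerance = 1e-10)
  expect_equal(m2$intercept, m1$intercept + 5, tolerance = 1e-10)
})

test_that("CNV values are invariant under compartment-wide affine maps of y", {
  set.seed(4)
  x <- rnorm(50, 22, 2); y <- 1 + 0.8 * x + rnorm(50, 0, 0.4)
  ids <- sprintf("p%d", 1:50)
  base <- compute_cnv(fit_compartment_model(x, y), ids, x, y)
  for (ab in list(c(2, 1), c(0.5, -3), c(3.7, 0))) {
    ya <- ab[1] * y + ab[2]
    rec <- compute_cnv(fit_compartment_model(x, ya), ids, x, ya)
    expect_equal(rec$cnv, base$cnv, tolerance = 1e-8)
  }
})

test_that("normal-null p-values and BH q-values behave as specified", {
  expect_equal(cnv_pvalues(0), 1)
  expect_equal(cnv_pvalues(1.959964), 0.05, tolerance = 1e-6)
  z <- c(-2.3, 0.7, 1.1)
  expect_equal(cnv_pvalues(z), cnv_pvalues(-z))
  expect_true(is.na(cnv_pvalues(NA_real_)))

  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(qvalues(1.0), 1.0)
  expect_equal(qvalues(numeric(0)), numeric(0))
  set.seed(5)
  p <- runif(200)
  q <- qvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q <= 1) && all(q >= p - 1e-15))
})

test_that("run_cnv emits one record per (protein, compartment) pair and skips small compartments", {
  set.seed(6)
  pts1 <- line_points(50); pts2 <- line_points(50)
  ids <- c(paste0("m", 1:50), paste0("n", 1:50), paste0("t", 1:5))
  x <- c(pts1$x, pts2$x, rnorm(5, 25, 2))
  y <- c(pts1$y, pts2$y, rnorm(5, 25, 2))
  sets <- c(rep("mitochondrion", 50), rep("nucleus", 50), rep("peroxisome", 5))
  ann_list <- setNames(as.list(sets), ids)
  ann_list[["m1"]] <- c("mitochondrion", "nucleus")   # dual membership
  ann <- as_compartment_annotation(ann_list)
  means <- means_from_xy(x, y, ids)
  res <- run_cnv(means, ann, c("A", "B"))
  expect_equal(nrow(res$models), 2L)
  expect_equal(nrow(res$records), 101L)   # 50 + 51 (m1 counted in both)
  expect_equal(res$skipped$compartment, "peroxisome")
  expect_equal(sum(res$records$protein == "m1"), 2L)
  # record count == sum of annotation-set sizes within analyzed compartments
  n_expected <- sum(vapply(ann$compartments[ids], function(s)
    sum(s %in% res$models$compartment), integer(1)))
  expect_equal(nrow(res$records), n_expected)
  # q-values are computed within compartments by default
  mito <- res$records[res$records$compartment == "mitochondrion", ]
  expect_equal(mito$q, qvalues(mito$p))
  expect_error(run_cnv(means, ann, c("A", "B"), compartments = "lysosome"),
               "no compartment")
})

test_that("model-variant comparison correlates shared CNV values per compartment", {
  set.seed(7)
  pts <- line_points(100)
  rec <- compute_cnv(fit_compartment_model(pts$x, pts$y, "mitochondrion"),
                     pts$ids, pts$x, pts$y)
  same <- compare_model_variants(rec, rec)
  expect_equal(same$per_compartment$pearson_r, 1)
  neg <- rec; neg$cnv <- -neg$cnv
  expect_equal(compare_model_variants(rec, neg)$per_compartment$pearson_r, -1)
  # independent values: |r| small, equal to the direct covariance formula
  other <- rec; other$cnv <- rnorm(100)
  r <- compare_model_variants(rec, other)$per_compartment$pearson_r
  a <- rec$cnv; b <- other$cnv
  r_direct <- mean((a - mean(a)) * (b - mean(b))) /
    sqrt(mean((a - mean(a))^2) * mean((b - mean(b))^2))
  expect_equal(r, r_direct, tolerance = 1e-12)
  expect_lt(abs(r), 0.3)
  # fewer than 3 shared proteins -> missing correlation
  tiny <- rec[1:2, ]
  expect_true(is.na(compare_model_variants(tiny, tiny)$per_compartment$pearson_r))
})

test_that("wholesale compartment shifts change the intercept, not the CNV values", {
  set.seed(8)
  pts <- line_points(200)
  ann <- annotation_one(pts$ids)
  means <- means_from_xy(pts$x, pts$y, pts$ids)
  base <- run_cnv(means, ann, c("A", "B"))
  shifted <- means
  shifted$means[, "B"] <- shifted$means[, "B"] + 1.5
  res <- run_cnv(shifted, ann, c("A", "B"))
  expect_equal(res$records$cnv, base$records$cnv, tolerance = 1e-8)
  expect_equal(res$models$intercept, base$models$intercept + 1.5,
               tolerance = 1e-8)
  expect_equal(res$models$slope, base$models$slope, tolerance = 1e-10)
})
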