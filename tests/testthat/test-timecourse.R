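toy_series <- function() {
  v <- rbind(
    nas34 = c(-3.2, -2.8, -2.4, -2.0, -1.5),
    upf   = c(-7.4, -5.0, -2.6, -0.1,  2.7),
    flat  = c( 0.5,  0.5,  0.5,  0.5,  0.5),
    gap   = c(  NA,  1.0,  1.1,  1.2,  1.3))
  colnames(v) <- c("d1", "d6", "d12", "d17", "d22")
  ratio_series(v)
}

test_that("delta ratios subtract the baseline and drop proteins missing it", {
  d <- delta_ratios(toy_series())
  expect_equal(unname(d$values["nas34", "d22"]), 1.7)
  expect_equal(unname(d$values["upf", "d22"]), 10.1)
  expect_true(all(d$values[, "d1"] == 0))          # exactly zero at baseline
  expect_false("gap" %in% rownames(d$values))
  expect_equal(d$n_excluded, 1L)
})

test_that("ratio series validate ordering and duplicates", {
  v <- matrix(rnorm(6), 3, 2, dimnames = list(c("a", "b", "c"), c("t1", "t2")))
  expect_equal(ratio_series(v)$baseline, "t1")
  expect_error(ratio_series(v[, 1, drop = FALSE]), ">= 2")
  vdup <- cbind(v, v[, 2, drop = FALSE])
  expect_error(ratio_series(vdup, c("t1", "t2", "t2")), "duplicate")
})

test_that("per-timepoint CNV models inherit shift invariance and flag degeneracy", {
  set.seed(41)
  n <- 60
  ids <- sprintf("P%03d", 1:n)
  r1 <- rnorm(n, 0, 1)
  r2 <- r1 + 0.4 + rnorm(n, 0, 0.2)
  v <- cbind(d1 = r1, d22 = r2); rownames(v) <- ids
  s <- ratio_series(v)
  ann <- annotation_one(ids, "extracellular")
  res <- timepoint_cnv(s, ann, "d22")
  expect_equal(nrow(res$records), n)
  # wholesale shift at the later timepoint leaves CNV values unchanged
  v2 <- v; v2[, "d22"] <- v2[, "d22"] + 2
  res2 <- timepoint_cnv(ratio_series(v2), ann, "d22")
  expect_equal(res2$records$cnv, res$records$cnv, tolerance = 1e-8)

  # identical timepoints: slope 1, zero residuals, CNV not computable
  v3 <- cbind(d1 = r1, d22 = r1); rownames(v3) <- ids
  expect_warning(res3 <- timepoint_cnv(ratio_series(v3), ann, "d22"),
                 "not computable")
  expect_equal(res3$models$slope, 1, tolerance = 1e-10)
  expect_true(all(is.na(res3$records$cnv)))
  expect_error(timepoint_cnv(s, ann, "d1"), "baseline")
})

test_that("a protein lagging a rising compartment gets a strongly negative CNV value", {
  set.seed(42)
  n <- 80
  ids <- sprintf("P%03d", 1:n)
  r1 <- rnorm(n, -1.4, 1)
  r2 <- r1 + 2.4 + rnorm(n, 0, 0.25)   # compartment-wide rise
  r2[1] <- r1[1]                        # the lagging protein stays put
  v <- cbind(d1 = r1, d22 = r2); rownames(v) <- ids
  res <- timepoint_cnv(ratio_series(v), annotation_one(ids, "extracellular"), "d22")
  rec <- res$records
  expect_equal(rec$protein[which.min(rec$cnv)], ids[1])
  expect_lt(rec$cnv[rec$protein == ids[1]], -3)
})

test_that("compartment trajectories flag drifted timepoints against baseline", {
  set.seed(43)
  n <- 100
  ids <- sprintf("P%03d", 1:n)
  ann <- annotation_one(ids)
  tps <- c("d1", "d6", "d12", "d17", "d22")
  r1 <- rnorm(n, 0, 0.5)
  # monotone drift: -0.25 per timepoint from d6 onwards
  drift <- c(0, -0.25, -0.5, -0.75, -1.0)
  v <- sapply(seq_along(tps), function(i) r1 + drift[i] + rnorm(n, 0, 0.2) * (i > 1))
  dimnames(v) <- list(ids, tps)
  traj <- compartment_trajectory_test(ratio_series(v), ann, "mitochondrion")
  expect_equal(traj$timepoint, tps[-1])
  expect_true(all(traj$significant))
  expect_lt(traj$mean_ratio[4], traj$mean_ratio[1])

  # identical timepoints: nothing significant
  v0 <- sapply(tps, function(t) r1); dimnames(v0) <- list(ids, tps)
  traj0 <- compartment_trajectory_test(ratio_series(v0), ann, "mitochondrion")
  expect_true(all(traj0$p == 1))
})

test_that("group tests dissociate delta-mode drift from cnv-mode composition change", {
  set.seed(44)
  n <- 120
  ids <- sprintf("P%03d", 1:n)
  ann <- annotation_one(ids)
  tps <- c("d1", "d6", "d12", "d17", "d22")
  drift <- c(0, -0.25, -0.5, -0.75, -1.0)
  r1 <- rnorm(n, 0, 0.8)
  v <- sapply(seq_along(tps), function(i)
    r1 + drift[i] + rnorm(n, 0, 0.2) * (i > 1))
  dimnames(v) <- list(ids, tps)
  s <- ratio_series(v)
  group <- ids[1:10]

  gt_d <- group_trajectory_test(s, ann, group, mode = "delta")
  gt_c <- group_trajectory_test(s, ann, group, mode = "cnv",
                                min_fit_size = 10)
  # whole compartment drifts: delta readout significant at the last
  # timepoint, CNV readout null (members follow their compartment trend)
  expect_true(gt_d$significant[gt_d$timepoint == "d22"])
  expect_false(gt_c$significant[gt_c$timepoint == "d22"])
  expect_true(is.na(gt_d$p[gt_d$timepoint == "d6"]))  # reference timepoint

  expect_error(group_trajectory_test(s, ann, c(group, "absent")),
               "absent")
})

test_that("one member drifting away from its complex shows an extreme CNV value", {
  set.seed(45)
  n <- 150
  ids <- sprintf("P%03d", 1:n)
  ann <- annotation_one(ids)
  r1 <- rnorm(n, 0, 0.8)
  r2 <- r1 + rnorm(n, 0, 0.2)
  r2[5] <- r1[5] - 3 * 0.2 * 5          # member 5 drops ~ -3 SD x scale
  v <- cbind(d1 = r1, d22 = r2); dimnames(v) <- list(ids, c("d1", "d22"))
  s <- ratio_series(v)
  group <- ids[1:10]
  cnv <- timepoint_cnv(s, ann, "d22")
  rec <- cnv$records
  member_z <- rec$cnv[match(group, rec$protein)]
  expect_lt(member_z[5], -3)
  gt <- group_trajectory_test(s, ann, group, mode = "cnv",
                              cnv_by_timepoint = list(d22 = cnv))
  expect_false(isTRUE(gt$significant[gt$timepoint == "d22"]))
})
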