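cube_pair <- function() {
  a <- array(0L, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- 1L
  b <- array(0L, c(4, 4, 4)); b[2:3, 1:2, 1:2] <- 1L
  list(a = a, b = b)
}

test_that("instance IoU is literal voxel counting", {
  p <- cube_pair()
  expect_equal(instance_iou(p$a, p$a, 1, 1), 1)
  far <- array(0L, c(4, 4, 4)); far[4, 4, 4] <- 1L
  expect_equal(instance_iou(p$a, far, 1, 1), 0)
  # 2x2x2 cube against itself shifted by one along z: 4 / 12
  expect_equal(instance_iou(p$a, p$b, 1, 1), 4 / 12)
  expect_equal(instance_iou(array(0L, c(2, 2, 2)), array(0L, c(2, 2, 2)), 1, 1), 0)
})

test_that("average precision counts TP, FP and FN under greedy matching", {
  ds <- assemble_dataset(phantom_spec("sphere", seed = 101), 3, c(60, 60, 60))
  expect_equal(average_precision(ds$truth, ds$truth, 0.95), 100)
  # one truth, one prediction at IoU 0.6: AP50 = 100, AP70 = 0
  p <- cube_pair()
  t1 <- array(0L, c(4, 4, 4)); t1[1:2, 1:2, 1:2] <- 1L
  pr <- array(0L, c(4, 4, 4)); pr[1:2, 1:2, 1:3] <- 1L   # IoU 8/12 = 0.667
  expect_equal(average_precision(t1, pr, 0.5), 100)
  expect_equal(average_precision(t1, pr, 0.7), 0)
  # 5 truth, 4 perfect predictions, none spurious: 4 / (4 + 0 + 1) = 80
  tr <- array(0L, c(3, 3, 10)); for (k in 1:5) tr[2, 2, 2 * k - 1] <- k
  pd <- tr; pd[pd == 5] <- 0L
  expect_equal(average_precision(tr, pd, 0.5), 80)
  expect_equal(average_precision(tr, array(0L, dim(tr)), 0.5), 0)
})

test_that("mAP averages ten thresholds and matches an independent recomputation", {
  ds <- assemble_dataset(phantom_spec("sphere", seed = 102), 3, c(60, 60, 60))
  ev <- mean_ap(ds$truth, ds$truth)
  expect_length(ev$ap_by_threshold, 10)
  expect_equal(ev$map, 100)
  # one prediction covering everything vs 5 equal instances: all IoU = 1/5 -> 0
  tr <- array(0L, c(3, 3, 20)); for (k in 1:5) tr[, , (4 * k - 3):(4 * k)] <- k
  blob <- array(1L, dim(tr))
  expect_equal(mean_ap(tr, blob)$map, 0)
  # random label grids: every threshold equals the oracle
  set.seed(103)
  for (i in 1:3) {
    t_m <- array(sample(0:3, 6^3, TRUE), c(6, 6, 6))
    p_m <- array(sample(0:4, 6^3, TRUE), c(6, 6, 6))
    ev2 <- mean_ap(t_m, p_m)
    for (thr in c(0.5, 0.7, 0.9)) {
      expect_equal(ev2$ap_by_threshold[[sprintf("AP%02.0f", 100 * thr)]],
                   oracle_ap(t_m, p_m, thr))
    }
  }
})

test_that("AP is monotone in the threshold and invariant to relabeling", {
  ds <- assemble_dataset(phantom_spec("column", seed = 104), 3, c(60, 60, 60))
  fit <- segment_instances(ds$tomogram, ds$semantic, "columnar")
  ev <- mean_ap(ds$truth, fit$mask)
  expect_true(all(diff(ev$ap_by_threshold) <= 1e-9))
  # permute prediction labels: identical report
  perm <- sample(max(fit$mask))
  relab <- array(0L, dim(fit$mask))
  relab[fit$mask > 0] <- perm[as.integer(fit$mask[fit$mask > 0])]
  ev2 <- mean_ap(ds$truth, relab)
  expect_equal(ev2$ap_by_threshold, ev$ap_by_threshold)
  # greedy matching is one-to-one
  expect_identical(anyDuplicated(ev$matching$truth), 0L)
  expect_identical(anyDuplicated(ev$matching$pred), 0L)
})

test_that("per-instance statistics report voxel volumes and mean raw intensity", {
  inst <- array(0L, c(6, 6, 10))
  inst[2:3, 2:3, 1:3] <- 1L
  inst[5, 5, 1:4] <- 2L
  st <- instance_statistics(tomogram(array(0.4, dim(inst))), instance_mask(inst),
                            condition = "0mM")
  expect_equal(st$mean_intensity, c(0.4, 0.4))
  expect_identical(st$volume, c(12L, 4L))
  expect_identical(st$condition, c("0mM", "0mM"))
  # volumes sum to the semantic support
  ds <- assemble_dataset(phantom_spec("sphere", seed = 105), 3, c(60, 60, 60))
  st2 <- instance_statistics(ds$tomogram, ds$truth)
  expect_identical(sum(st2$volume), sum(ds$semantic > 0))
  # a 170-voxel instance reports volume 170 (the reference vesicle volume)
  i170 <- array(0L, c(10, 10, 10)); i170[seq_len(170)] <- 1L
  st3 <- instance_statistics(tomogram(array(0.4, c(10, 10, 10))),
                             instance_mask(i170))
  expect_identical(st3$volume, 170L)
})

test_that("rank-sum comparison is calibrated and matches exact enumeration", {
  same <- tibble::tibble(instance_id = 1:6, volume = c(5L, 9L, 12L, 15L, 20L, 31L),
                         mean_intensity = 0.4, condition = "a")
  p_same <- compare_conditions(same, same, "volume")$p_value
  expect_gt(p_same, 0.9)
  # 3-SD shift with n = 200 per group is overwhelmingly significant
  set.seed(106)
  a <- tibble::tibble(instance_id = 1:200, volume = 1L,
                      mean_intensity = rnorm(200, 0.40, 0.01), condition = "a")
  b <- tibble::tibble(instance_id = 1:200, volume = 1L,
                      mean_intensity = rnorm(200, 0.43, 0.01), condition = "b")
  expect_lte(compare_conditions(a, b, "intensity")$p_value, 1e-4)
  # two 4-element samples: p equals exhaustive rank-arrangement enumeration
  x <- c(1.2, 3.4, 2.2, 5.0); y <- c(4.1, 6.3, 7.7, 2.8)
  sx <- tibble::tibble(instance_id = 1:4, volume = 1L, mean_intensity = x,
                       condition = "a")
  sy <- tibble::tibble(instance_id = 1:4, volume = 1L, mean_intensity = y,
                       condition = "b")
  got <- compare_conditions(sx, sy, "intensity")
  expect_equal(got$p_value, oracle_mw_p(x, y))
  expect_equal(got$statistic, sum(outer(x, y, ">")))
  expect_error(compare_conditions(sx[0, ], sy, "volume"), "non-empty")
})
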