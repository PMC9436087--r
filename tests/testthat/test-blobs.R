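test_that("truncated Gaussian kernel preserves constants and matches direct evaluation", {
  for (s in c(1, 4, 10)) {
    out <- build_scale_bank(array(0.4, c(6, 6, 6)), s, s)$volumes[[1]]
    expect_equal(unique(round(as.vector(out), 12)), 0.4)
  }
  # impulse response at sigma = 1 equals the renormalised kernel values
  a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 1
  got <- build_scale_bank(a, 1, 1)$volumes[[1]][2:4, 2:4, 2:4]
  o <- -1:1
  want <- exp(-outer(outer(o^2, o^2, "+"), o^2, "+") / 2)
  want <- want / sum(want)
  expect_equal(got, want, tolerance = 1e-12)
  # widening sigma flattens the peak monotonically
  bank <- build_scale_bank(a, 1, 10)
  peaks <- vapply(bank$volumes, function(v) v[3, 3, 3], numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("local maxima match the exhaustive 26-neighbourhood definition", {
  # one isotropic bump -> a single candidate at the apex
  d2 <- as.matrix(expand.grid(z = 1:9, y = 1:9, x = 1:9))
  bump <- array(exp(-rowSums((d2 - 5)^2) / 18), c(9, 9, 9))
  bank <- list(sigmas = 1, volumes = list(bump))
  cand <- find_local_maxima(bank)
  expect_identical(nrow(cand), 1L)
  expect_identical(c(cand$z, cand$y, cand$x), c(5L, 5L, 5L))
  # constant field: no strict maxima anywhere
  flat <- list(sigmas = 1, volumes = list(array(0.3, c(6, 6, 6))))
  expect_identical(nrow(find_local_maxima(flat)), 0L)
  # two bumps 8 voxels apart -> both apexes
  two <- array(0, c(9, 9, 17))
  for (cx in c(5, 13)) {
    two <- pmax(two, array(exp(-rowSums(sweep(as.matrix(
      expand.grid(z = 1:9, y = 1:9, x = 1:17)), 2, c(5, 5, cx))^2) / 8),
      c(9, 9, 17)))
  }
  cand2 <- find_local_maxima(list(sigmas = 1, volumes = list(two)))
  expect_identical(nrow(cand2), 2L)
  expect_setequal(cand2$x, c(5L, 13L))
  # random fields agree with the oracle
  set.seed(41)
  for (i in 1:3) {
    f <- array(rnorm(8^3), c(8, 8, 8))
    got <- find_local_maxima(list(sigmas = 1, volumes = list(f)))
    want <- which(oracle_local_maxima(f))
    expect_identical(sort(got$z + (got$y - 1L) * 8L + (got$x - 1L) * 64L),
                     sort(want))
  }
})

test_that("candidates off the mask are screened out, survivors are the set intersection", {
  set.seed(42)
  m <- array(as.integer(runif(6^3) < 0.4), c(6, 6, 6))
  cand <- tibble::tibble(z = sample(6, 30, TRUE), y = sample(6, 30, TRUE),
                         x = sample(6, 30, TRUE), sigma = 1)
  keep <- screen_by_mask(cand, m)
  expect_true(all(m[cbind(keep$z, keep$y, keep$x)] > 0))
  on_mask <- m[cbind(cand$z, cand$y, cand$x)] > 0
  expect_identical(nrow(keep), sum(on_mask))
  expect_identical(screen_by_mask(cand[on_mask, ], m), cand[on_mask, ])
})

test_that("overlap ratio equals brute-force voxel counting", {
  filled <- array(1L, c(21, 21, 21))
  expect_equal(overlap_ratio(c(11, 11, 11), 2, filled), 1.0)
  # half-space through the center
  half <- array(0L, c(21, 21, 21)); half[, , 1:11] <- 1L
  got <- overlap_ratio(c(11, 11, 11), 5, half)
  want <- oracle_overlap_ratio(c(11, 11, 11), 5, half)
  expect_equal(got, want)
  expect_gt(got, 0.5)        # half the ball plus the included center plane
  expect_lt(got, 0.62)
  # single-voxel mask: exactly one of the discrete sphere voxels is inside
  single <- array(0L, c(9, 9, 9)); single[5, 5, 5] <- 1L
  vs3 <- sum(rowSums(as.matrix(expand.grid(-3:3, -3:3, -3:3))^2) < 9)
  expect_equal(overlap_ratio(c(5, 5, 5), 3, single), 1 / vs3)
  # random centers and radii against the oracle
  set.seed(43)
  m <- array(as.integer(runif(11^3) < 0.5), c(11, 11, 11))
  for (i in 1:5) {
    cen <- sample(3:9, 3, TRUE)
    r <- sample(c(1.5, 2, 2.5, 3.5), 1)
    expect_equal(overlap_ratio(cen, r, m), oracle_overlap_ratio(cen, r, m))
  }
})

test_that("radius estimation recovers sphere radii and obeys its stopping rule", {
  ball <- make_ball_mask(6, 19)
  est <- estimate_radius(c(10, 10, 10), ball)
  expect_lt(abs(est$radius - 6), 1)
  # single-voxel mask floors at r_min
  single <- array(0L, c(7, 7, 7)); single[4, 4, 4] <- 1L
  expect_equal(estimate_radius(c(4, 4, 4), single)$radius, 1.5)
  # stopping rule: a_r >= 0.8 at the returned radius, < 0.8 at the next scan
  set.seed(44)
  for (i in 1:5) {
    m <- array(as.integer(runif(13^3) < 0.6), c(13, 13, 13))
    cen <- c(7, 7, 7); m[7, 7, 7] <- 1L
    est <- estimate_radius(cen, m)
    prof <- est$profile
    if (prof$a_r[1] < 0.8) {
      expect_equal(est$radius, 1.5)          # even r_min fails: floor case
    } else {
      at <- prof$a_r[prof$r == est$radius]
      expect_gte(at, 0.8)
      nxt <- prof$a_r[prof$r == est$radius + 0.5]
      if (length(nxt)) expect_lt(nxt, 0.8)
    }
  }
})

test_that("greedy blob selection matches a literal re-execution of the rule", {
  near <- tibble::tibble(z = c(5, 5), y = c(5, 5), x = c(5, 15),
                         radius = c(3, 3), intensity = c(0.5, 0.4))
  expect_identical(nrow(rank_and_select_blobs(near)), 2L)   # separated: both
  close <- tibble::tibble(z = c(5, 5), y = c(5, 5), x = c(5, 7),
                          radius = c(3, 3), intensity = c(0.5, 0.4))
  sel <- rank_and_select_blobs(close)                        # 2 <= radius 3
  expect_identical(nrow(sel), 1L)
  expect_identical(sel$x, 5)
  set.seed(45)
  for (i in 1:4) {
    cand <- tibble::tibble(z = sample(30, 50, TRUE), y = sample(30, 50, TRUE),
                           x = sample(30, 50, TRUE),
                           radius = runif(50, 1.5, 6),
                           intensity = runif(50))
    cand <- cand[!duplicated(cand[, c("z", "y", "x")]), ]
    got <- rank_and_select_blobs(cand)
    want <- oracle_greedy_select(as.data.frame(cand))
    expect_equal(got[, c("z", "y", "x", "radius", "intensity")],
                 tibble::as_tibble(want[, c("z", "y", "x", "radius", "intensity")]))
  }
})

test_that("well-separated sphere phantoms are recovered with their radii", {
  # k solid spheres with radially decaying intensity, centers far apart
  spec <- phantom_spec("sphere", noise_sd = 0)
  for (k in c(1, 3)) {
    vol <- array(0.1, c(30, 30, 30 * k))
    msk <- array(0L, dim(vol))
    centers <- cbind(15, 15, 30 * seq_len(k) - 15)
    withr::with_seed(50 + k, {
      for (i in seq_len(k)) {
        ph <- make_phantom(spec, radius = 5)
        d <- dim(ph$mask)
        lo <- centers[i, ] - (d - 1) %/% 2
        zz <- lo[1]:(lo[1] + d[1] - 1); yy <- lo[2]:(lo[2] + d[2] - 1)
        xx <- lo[3]:(lo[3] + d[3] - 1)
        msk[zz, yy, xx] <- pmax(msk[zz, yy, xx], ph$mask)
        vol[zz, yy, xx] <- pmax(vol[zz, yy, xx], ph$intensity)
      }
    })
    fit <- segment_instances(tomogram(vol), semantic_mask(msk), "sphere")
    expect_identical(nrow(fit$blobs), as.integer(k))
    expect_true(all(abs(fit$blobs$radius - 5) <= 1))
  }
})
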