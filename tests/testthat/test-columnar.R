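blob_tbl <- function(coords, radius = 2) {
  tibble::tibble(blob_id = seq_len(nrow(coords)), z = coords[, 1],
                 y = coords[, 2], x = coords[, 3], radius = radius)
}

test_that("candidate reference vectors follow the piecewise sum/difference rule", {
  # perfect collinearity seen from the middle blob: difference branch
  b <- blob_tbl(rbind(c(0, 0, 0), c(0, 0, 4), c(0, 0, -4)))
  cand <- candidate_reference_vector(1, b)
  expect_equal(cand$cos_adj, 1)
  expect_equal(abs(cand$vector / sqrt(sum(cand$vector^2))), c(0, 0, 1))
  # right angle: |cos| = 0 < cos(30 deg), no candidate
  b2 <- blob_tbl(rbind(c(0, 0, 0), c(0, 0, 3), c(0, 3, 0)))
  expect_null(candidate_reference_vector(1, b2))
  # same-side neighbours within 30 deg: sum branch points along the chain
  b3 <- blob_tbl(rbind(c(0, 0, 0), c(0, 0, 3), c(0, 1, 6)))
  cand3 <- candidate_reference_vector(1, b3)
  v1 <- c(0, 0, 3); v2 <- c(0, 1, 6)
  expect_equal(cand3$vector, v1 + v2)
  expect_equal(cand3$cos_adj,
               abs(sum(v1 * v2)) / sqrt(sum(v1^2) * sum(v2^2)))
  # random triplets agree with direct vector algebra
  set.seed(61)
  for (i in 1:10) {
    co <- matrix(runif(9, 0, 20), 3, 3)
    b <- blob_tbl(co)
    got <- candidate_reference_vector(1, b)
    v1 <- co[2, ] - co[1, ]; v2 <- co[3, ] - co[1, ]
    d1 <- sqrt(sum((co[2, ] - co[1, ])^2)); d2 <- sqrt(sum((co[3, ] - co[1, ])^2))
    if (d2 < d1) { tmp <- v1; v1 <- v2; v2 <- tmp }
    cth <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    if (abs(cth) <= cos(pi / 6)) {
      expect_null(got)
    } else {
      expect_equal(got$cos_adj, abs(cth))
      expect_equal(got$vector, if (cth >= 0) v1 + v2 else v1 - v2)
    }
  }
})

test_that("reference-vector location picks the most collinear triplet or signals none", {
  line <- blob_tbl(cbind(0, 0, seq(0, 16, by = 4)))
  loc <- locate_reference_vector(line)
  expect_length(loc$seed_ids, 3)
  dir <- loc$vector / sqrt(sum(loc$vector^2))
  expect_equal(abs(dir), c(0, 0, 1))
  expect_null(locate_reference_vector(line[1:2, ]))   # fewer than three blobs
  # winner equals exhaustive enumeration over all nucleating blobs
  set.seed(62)
  for (i in 1:5) {
    b <- blob_tbl(matrix(runif(18, 0, 30), 6, 3))
    got <- locate_reference_vector(b)
    cands <- lapply(b$blob_id, candidate_reference_vector, blobs = b)
    cands <- Filter(Negate(is.null), cands)
    if (!length(cands)) {
      expect_null(got)
    } else {
      best <- cands[[which.max(vapply(cands, `[[`, numeric(1), "cos_adj"))]]
      expect_equal(got$cos_adj, best$cos_adj)
    }
  }
})

test_that("instance growth honours the angular and distance conditions", {
  # seed triplet along x; 4th collinear blob one diameter beyond joins
  b <- blob_tbl(rbind(c(0, 0, 0), c(0, 0, 4), c(0, 0, 8), c(0, 0, 14)), radius = 2)
  got <- grow_instance(1:3, c(0, 0, 1), b)
  expect_setequal(got, 1:4)
  # a nearby blob perpendicular to the reference vector is excluded
  bp <- blob_tbl(rbind(c(0, 0, 0), c(0, 0, 4), c(0, 0, 8), c(0, 5, 4)), radius = 2)
  expect_setequal(grow_instance(1:3, c(0, 0, 1), bp), 1:3)
  # a jittered 6-chain (<= 5 deg off axis, gaps below the diameter sum) joins fully
  set.seed(63)
  step <- 5
  co <- matrix(0, 6, 3)
  for (k in 2:6) {
    ang <- runif(1, -5, 5) * pi / 180
    co[k, ] <- co[k - 1, ] + step * c(sin(ang), 0, cos(ang))
  }
  chain <- blob_tbl(co, radius = 2)
  loc <- locate_reference_vector(chain)
  got <- grow_instance(loc$seed_ids, loc$vector, chain)
  expect_setequal(got, 1:6)
})

test_that("K-means fallback clusters leftovers and finds the elbow", {
  one <- blob_tbl(matrix(c(3, 4, 5), 1))
  expect_identical(kmeans_residual(one), list(1L))
  # two tight clouds 50 voxels apart -> K = 2, groups equal the clouds
  set.seed(64)
  cloud <- rbind(matrix(rnorm(9, 10, 0.5), 3, 3),
                 matrix(rnorm(9, 60, 0.5), 3, 3))
  b <- blob_tbl(cloud)
  got <- kmeans_residual(b)
  expect_length(got, 2)
  expect_setequal(got[[1]], 1:3)
  expect_setequal(got[[2]], 4:6)
  # all blobs coincident -> a single group
  co <- blob_tbl(matrix(5, 4, 3))
  expect_identical(kmeans_residual(co), list(1:4))
})

test_that("columnar grouping partitions the blobs and recovers two straight columns", {
  set.seed(65)
  # random blob clouds: every blob in exactly one group
  for (i in 1:3) {
    b <- blob_tbl(matrix(runif(3 * 8, 0, 40), 8, 3), radius = 2)
    g <- group_columnar(b)
    expect_setequal(g$blob_id, b$blob_id)
    expect_identical(anyDuplicated(g$blob_id), 0L)
  }
  # two separated straight columns of 5 touching blobs each
  c1 <- cbind(10, 10, seq(5, 25, by = 5))
  c2 <- cbind(40, 40, seq(5, 25, by = 5))
  b2 <- blob_tbl(rbind(c1, c2), radius = 3)
  g2 <- group_columnar(b2)
  expect_identical(length(unique(g2$instance_id)), 2L)
  expect_length(unique(g2$instance_id[g2$blob_id %in% 1:5]), 1L)
  expect_length(unique(g2$instance_id[g2$blob_id %in% 6:10]), 1L)
  refs <- attr(g2, "references")
  expect_identical(nrow(refs), 2L)
  expect_true(all(refs$cos_adj > cos(pi / 6)))
})
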