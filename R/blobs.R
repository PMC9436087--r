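#' Candidate blob centers from local intensity maxima
#'
#' A voxel is a local maximum when its value is `>=` all of its 26 neighbours
#' and strictly `>` at least one of them, in at least one of the denoised
#' volumes of the scale bank. Neighbours outside the volume are ignored (so a
#' perfectly constant crop yields no candidates, and plateaus wider than one
#' voxel yield none either). Candidates found at several scales collapse to
#' one per voxel position, keeping the smallest sigma at which they peaked.
#'
#' @param bank a scale bank from [build_scale_bank()].
#' @return tibble with columns `z, y, x` (1-based crop coordinates) and
#'   `sigma`, ordered by position.
#' @export
find_local_maxima <- function(bank) {
  found <- list()
  for (i in seq_along(bank$sigmas)) {
    v <- bank$volumes[[i]]
    cand <- which(local_maxima3(v))
    if (length(cand)) {
      found[[length(found) + 1L]] <-
        data.frame(lin = cand, sigma = bank$sigmas[i])
    }
  }
  d <- dim(bank$volumes[[1]])
  if (!length(found)) {
    return(tibble::tibble(z = integer(), y = integer(), x = integer(),
                          sigma = numeric()))
  }
  all <- do.call(rbind, found)
  all <- all[order(all$sigma), , drop = FALSE]
  all <- all[!duplicated(all$lin), , drop = FALSE]
  all <- all[order(all$lin), , drop = FALSE]
  co <- arrayInd(all$lin, d)
  tibble::tibble(z = co[, 1], y = co[, 2], x = co[, 3], sigma = all$sigma)
}

# strict-ish local maxima of one 3D array (26-neighbourhood)
local_maxima3 <- function(a) {
  d <- dim(a)
  lo <- pad3(a, -Inf)   # out-of-volume neighbours never beat the center
  hi <- pad3(a, Inf)    # ... and never count as a strictly smaller neighbour
  iz <- seq_len(d[1]) + 1L; iy <- seq_len(d[2]) + 1L; ix <- seq_len(d[3]) + 1L
  nb_max <- array(-Inf, d)
  nb_min <- array(Inf, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    nb_max <- pmax(nb_max, lo[iz + dz, iy + dy, ix + dx, drop = FALSE])
    nb_min <- pmin(nb_min, hi[iz + dz, iy + dy, ix + dx, drop = FALSE])
  }
  a >= nb_max & a > nb_min
}

pad3 <- function(a, fill) {
  d <- dim(a)
  p <- array(fill, d + 2L)
  p[seq_len(d[1]) + 1L, seq_len(d[2]) + 1L, seq_len(d[3]) + 1L] <- a
  p
}

#' Keep only candidate centers that lie on the semantic mask
#'
#' @param candidates tibble with `z, y, x` columns (crop coordinates).
#' @param mask_crop 0/1 array.
#' @return the subset of `candidates` whose voxel is foreground.
#' @export
screen_by_mask <- function(candidates, mask_crop) {
  if (!nrow(candidates)) return(candidates)
  keep <- mask_crop[cbind(candidates$z, candidates$y, candidates$x)] > 0
  candidates[keep, , drop = FALSE]
}

#' Sphere/mask overlapping ratio a_r
#'
#' For a candidate sphere of radius `r` centered on `center`, the overlapping
#' ratio is `a_r = V_m(r) / V_s(r)`: `V_s(r)` counts all voxels whose
#' center-to-center Euclidean distance to the blob center is `< r` (the
#' discrete sphere volume, independent of the mask and of the volume border),
#' and `V_m(r)` counts the subset of those that fall on mask foreground.
#'
#' @param center integer `(z, y, x)` voxel coordinate.
#' @param r radius in voxels (`>= 1`, so the center voxel is always counted).
#' @param mask_crop 0/1 array.
#' @return scalar in `[0, 1]`.
#' @export
overlap_ratio <- function(center, r, mask_crop) {
  off <- sphere_offsets(r)
  v_s <- nrow(off)
  pos <- off + matrix(as.integer(center), v_s, 3, byrow = TRUE)
  d <- dim(mask_crop)
  inb <- pos[, 1] >= 1 & pos[, 1] <= d[1] & pos[, 2] >= 1 & pos[, 2] <= d[2] &
         pos[, 3] >= 1 & pos[, 3] <= d[3]
  v_m <- if (any(inb)) sum(mask_crop[pos[inb, , drop = FALSE]] > 0) else 0
  v_m / v_s
}

# integer offsets with Euclidean norm < r, cached per radius
sphere_offsets <- local({
  cache <- new.env(parent = emptyenv())
  function(r) {
    key <- format(r, digits = 12)
    if (!is.null(cache[[key]])) return(cache[[key]])
    m <- ceiling(r)
    o <- -m:m
    g <- as.matrix(expand.grid(dz = o, dy = o, dx = o))
    g <- g[g[, 1]^2 + g[, 2]^2 + g[, 3]^2 < r^2, , drop = FALSE]
    storage.mode(g) <- "integer"
    cache[[key]] <- g
    g
  }
})

#' Estimate a blob radius from the overlapping-ratio profile
#'
#' Scans radii from `r_min` (default 1.5 voxels, the minimal blob size) up to
#' half the diagonal length of the cluster bounding box in steps of `r_step`,
#' computing [overlap_ratio()] at each. The scan stops at the first radius
#' whose ratio drops below `threshold` (default 0.8) and the previous radius
#' is kept; if even `r_min` fails the threshold, `r_min` is returned.
#'
#' @param center `(z, y, x)` voxel coordinate inside the mask.
#' @param mask_crop 0/1 array.
#' @param r_min,r_step,threshold scan floor, step and stopping threshold.
#' @param r_max scan ceiling; defaults to half the crop-box diagonal.
#' @return list with `radius` and `profile` (tibble of sampled `(r, a_r)`).
#' @export
estimate_radius <- function(center, mask_crop, r_min = 1.5, r_step = 0.5,
                            threshold = 0.8, r_max = NULL) {
  if (is.null(r_max)) r_max <- sqrt(sum(dim(mask_crop)^2)) / 2
  rs <- seq(r_min, max(r_min, r_max), by = r_step)
  a <- numeric(0)
  radius <- r_min
  for (i in seq_along(rs)) {
    a[i] <- overlap_ratio(center, rs[i], mask_crop)
    if (a[i] < threshold) break
    radius <- rs[i]
  }
  list(radius = radius,
       profile = tibble::tibble(r = rs[seq_along(a)], a_r = a))
}

#' Greedy selection of non-overlapping blobs
#'
#' Candidates are ranked by their center intensity in the raw tomogram,
#' descending (ties broken by `(z, y, x)` lexicographic order, then these are
#' already unique positions). The top candidate is always selected; each
#' later candidate is selected iff its center's Euclidean distance to every
#' previously selected blob is strictly larger than that blob's radius.
#'
#' @param candidates tibble with `z, y, x, radius, intensity` (and optionally
#'   `sigma`); coordinates may be in any single common frame.
#' @return the selected subset, in rank order, with a `blob_id` column
#'   numbering them 1..n.
#' @export
rank_and_select_blobs <- function(candidates) {
  if (!nrow(candidates)) {
    return(tibble::add_column(candidates[0, ], blob_id = integer(), .before = 1))
  }
  ord <- order(-candidates$intensity, candidates$z, candidates$y, candidates$x)
  cand <- candidates[ord, , drop = FALSE]
  cz <- cand$z; cy <- cand$y; cx <- cand$x; cr <- cand$radius
  sel <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(sel)) {
      dd <- sqrt((cz[sel] - cz[i])^2 + (cy[sel] - cy[i])^2 + (cx[sel] - cx[i])^2)
      if (any(dd <= cr[sel])) next
    }
    sel <- c(sel, i)
  }
  out <- cand[sel, , drop = FALSE]
  tibble::add_column(out, blob_id = seq_len(nrow(out)), .before = 1)
}

#' Detect blobs in one organelle cluster
#'
#' Runs the per-cluster detection chain: ten-scale Gaussian denoising,
#' 26-neighbourhood local maxima, screening by the semantic mask, radius
#' estimation from the overlapping ratio, and greedy non-overlapping
#' selection ranked by raw center intensity.
#'
#' @param cluster a cluster from [label_connected_clusters()] (must carry
#'   `tomo_crop`).
#' @param config a [pipeline_config()].
#' @return tibble of blobs with columns `blob_id, z, y, x, radius, intensity,
#'   sigma`; coordinates are in the parent-volume frame.
#' @export
detect_blobs <- function(cluster, config = pipeline_config()) {
  stopifnot(!is.null(cluster$tomo_crop))
  bank <- build_scale_bank(cluster$tomo_crop, config$sigma_min, config$sigma_max)
  cand <- find_local_maxima(bank)
  cand <- screen_by_mask(cand, cluster$mask_crop)
  if (!nrow(cand)) {
    return(tibble::tibble(blob_id = integer(), z = integer(), y = integer(),
                          x = integer(), radius = numeric(),
                          intensity = numeric(), sigma = numeric()))
  }
  r_max <- sqrt(sum(dim(cluster$mask_crop)^2)) / 2
  cand$radius <- vapply(seq_len(nrow(cand)), function(i) {
    estimate_radius(c(cand$z[i], cand$y[i], cand$x[i]), cluster$mask_crop,
                    r_min = config$r_min, r_step = config$r_step,
                    threshold = config$overlap_threshold, r_max = r_max)$radius
  }, numeric(1))
  cand$intensity <- cluster$tomo_crop[cbind(cand$z, cand$y, cand$x)]
  sel <- rank_and_select_blobs(cand)
  lo <- cluster$box["lo", ]
  sel$z <- sel$z + lo[1] - 1L
  sel$y <- sel$y + lo[2] - 1L
  sel$x <- sel$x + lo[3] - 1L
  sel[, c("blob_id", "z", "y", "x", "radius", "intensity", "sigma")]
}

#' Pipeline configuration
#'
#' All tunables of the instance-splitting pipeline with their default values:
#' Gaussian scale range `sigma_min..sigma_max` (voxels), minimal blob radius
#' `r_min` (voxels), overlapping-ratio threshold, radius scan step,
#' collinearity angle threshold (degrees) for columnar grouping, and the
#' K-means settings of the residual clustering step.
#'
#' @param sigma_min,sigma_max Gaussian denoising scale range (voxels).
#' @param r_min minimal blob radius (voxels).
#' @param overlap_threshold overlapping-ratio stopping threshold.
#' @param r_step radius scan step (voxels).
#' @param angle_threshold_deg collinearity tolerance for reference vectors and
#'   blob growth (degrees from the axis).
#' @param kmeans_max_k largest K tried by the elbow rule.
#' @param kmeans_seed,kmeans_restarts K-means reproducibility settings.
#' @return named list of class `"sxt_config"`.
#' @export
pipeline_config <- function(sigma_min = 1, sigma_max = 10, r_min = 1.5,
                            overlap_threshold = 0.8, r_step = 0.5,
                            angle_threshold_deg = 30, kmeans_max_k = 8,
                            kmeans_seed = 1L, kmeans_restarts = 10L) {
  structure(list(sigma_min = sigma_min, sigma_max = sigma_max, r_min = r_min,
                 overlap_threshold = overlap_threshold, r_step = r_step,
                 angle_threshold_deg = angle_threshold_deg,
                 kmeans_max_k = kmeans_max_k, kmeans_seed = as.integer(kmeans_seed),
                 kmeans_restarts = as.integer(kmeans_restarts)),
            class = "sxt_config")
}
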