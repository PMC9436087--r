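#' Candidate reference vector for one blob
#'
#' For blob `B_i`, takes its two nearest blobs `B_i1`, `B_i2` among the given
#' (unassigned) blobs and forms the vectors from `B_i`'s center to theirs. If
#' the adjacent angle `theta` between the two vectors is within 30 degrees of
#' collinearity (`|cos(theta)| > cos(30 deg)`), the candidate direction is
#' their sum when `theta <= 90 deg` or their difference when `theta > 90 deg`
#' (so a blob flanked by chain neighbours on opposite sides yields the chain
#' axis). Otherwise there is no candidate.
#'
#' @param blob_id the blob to evaluate.
#' @param blobs tibble of available blobs (`blob_id, z, y, x, radius`), the
#'   evaluated blob included; at least 3 rows.
#' @param angle_threshold_deg collinearity tolerance (degrees).
#' @return `NULL`, or a list with `vector` (length-3, `(z, y, x)` frame),
#'   `cos_adj` (`|cos(theta)|`) and `seed_ids` (the three blob ids).
#' @export
candidate_reference_vector <- function(blob_id, blobs, angle_threshold_deg = 30) {
  if (nrow(blobs) < 3) return(NULL)
  i <- match(blob_id, blobs$blob_id)
  stopifnot(!is.na(i))
  ci <- c(blobs$z[i], blobs$y[i], blobs$x[i])
  others <- blobs[-i, , drop = FALSE]
  dd <- sqrt((others$z - ci[1])^2 + (others$y - ci[2])^2 + (others$x - ci[3])^2)
  ord <- order(dd, others$blob_id)
  n1 <- others[ord[1], ]; n2 <- others[ord[2], ]
  v1 <- c(n1$z, n1$y, n1$x) - ci
  v2 <- c(n2$z, n2$y, n2$x) - ci
  l1 <- sqrt(sum(v1^2)); l2 <- sqrt(sum(v2^2))
  if (l1 == 0 || l2 == 0) return(NULL)  # coincident centers: no direction
  cth <- sum(v1 * v2) / (l1 * l2)
  if (abs(cth) <= cos(angle_threshold_deg * pi / 180)) return(NULL)
  vec <- if (cth >= 0) v1 + v2 else v1 - v2
  list(vector = vec, cos_adj = abs(cth),
       seed_ids = c(blob_id, n1$blob_id, n2$blob_id))
}

#' Locate the best reference vector among unassigned blobs
#'
#' Evaluates [candidate_reference_vector()] for every unassigned blob and
#' returns the winner with the maximum `|cos(theta_adj)|` (ties broken by the
#' lowest nucleating blob id). The winner's three blobs seed a new columnar
#' instance. Returns `NULL` when fewer than three blobs remain or no blob has
#' a near-collinear pair of neighbours — the signal to fall back to K-means.
#'
#' @param unassigned tibble of unassigned blobs.
#' @param angle_threshold_deg collinearity tolerance (degrees).
#' @return `NULL` or a list as in [candidate_reference_vector()].
#' @export
locate_reference_vector <- function(unassigned, angle_threshold_deg = 30) {
  if (nrow(unassigned) < 3) return(NULL)
  best <- NULL
  for (id in sort(unassigned$blob_id)) {
    cand <- candidate_reference_vector(id, unassigned, angle_threshold_deg)
    if (is.null(cand)) next
    if (is.null(best) || cand$cos_adj > best$cos_adj) best <- cand
  }
  best
}

#' Grow a columnar instance by adding proximal, axis-aligned blobs
#'
#' Repeatedly scans the unassigned blobs; a blob joins the instance when ANY
#' testing vector from its center to a current member satisfies both
#' conditions: (i) the vector is within 30 degrees of the instance's
#' reference vector in absolute cosine, and (ii) its length is shorter than
#' the sum of the two blobs' diameters (`2 r_blob + 2 r_member`). The member
#' set updates immediately after each addition; growth stops when a full
#' pass adds nothing. The reference vector itself is never re-estimated.
#'
#' @param member_ids blob ids currently in the instance (the seed triplet).
#' @param reference length-3 reference vector (`(z, y, x)` frame).
#' @param blobs tibble of blobs still unassigned (members excluded or
#'   included; members are ignored as candidates).
#' @param angle_threshold_deg collinearity tolerance (degrees).
#' @return integer vector of member blob ids, seeds first, in join order.
#' @export
grow_instance <- function(member_ids, reference, blobs, angle_threshold_deg = 30) {
  cth_min <- cos(angle_threshold_deg * pi / 180)
  lref <- sqrt(sum(reference^2))
  stopifnot(lref > 0)
  pool <- blobs[!(blobs$blob_id %in% member_ids), , drop = FALSE]
  members <- blobs_index(blobs, member_ids)
  repeat {
    added <- FALSE
    for (j in seq_len(nrow(pool))) {
      b <- pool[j, ]
      if (b$blob_id %in% members$blob_id) next
      tv_z <- members$z - b$z; tv_y <- members$y - b$y; tv_x <- members$x - b$x
      len <- sqrt(tv_z^2 + tv_y^2 + tv_x^2)
      dot <- tv_z * reference[1] + tv_y * reference[2] + tv_x * reference[3]
      ok_angle <- len > 0 & abs(dot) / (len * lref) > cth_min
      ok_len <- len < 2 * b$radius + 2 * members$radius
      if (any(ok_angle & ok_len)) {
        members <- rbind(members, b[, names(members)])
        added <- TRUE
      }
    }
    if (!added) break
    pool <- pool[!(pool$blob_id %in% members$blob_id), , drop = FALSE]
  }
  members$blob_id
}

blobs_index <- function(blobs, ids) {
  blobs[match(ids, blobs$blob_id), c("blob_id", "z", "y", "x", "radius"),
        drop = FALSE]
}

#' Cluster leftover blobs with elbow-selected K-means
#'
#' Blobs that never joined a reference-vector instance (short, near-ellipsoid
#' organelles are represented by only one or two blobs, or by triplets too
#' bent to pass the collinearity test) are clustered on their center
#' coordinates. K runs over `1..min(max_k, n)`; the within-cluster sum of
#' squares curve is computed for each K (10 restarts, fixed seed) and the K
#' maximising its second difference — the elbow — is kept. With two or fewer
#' blobs, or zero coordinate variance, K = 1.
#'
#' @param unassigned tibble of blobs (`blob_id, z, y, x`).
#' @param max_k largest K considered.
#' @param seed,restarts K-means reproducibility settings.
#' @return list of integer vectors of blob ids, one per cluster, ordered by
#'   first blob id.
#' @export
kmeans_residual <- function(unassigned, max_k = 8, seed = 1L, restarts = 10L) {
  n <- nrow(unassigned)
  if (n == 0) return(list())
  if (n <= 2) return(list(sort(unassigned$blob_id)))
  xyz <- cbind(unassigned$z, unassigned$y, unassigned$x)
  wss1 <- sum(scale(xyz, scale = FALSE)^2)
  if (wss1 < 1e-9) return(list(sort(unassigned$blob_id)))
  n_distinct <- nrow(unique(xyz))
  k_max <- min(max_k, n_distinct)
  wss <- numeric(k_max)
  wss[1] <- wss1
  fits <- vector("list", k_max)
  withr::with_seed(seed, {
    for (k in seq_len(k_max)[-1]) {
      if (k == n_distinct) {
        # every distinct point is its own cluster: WSS is exactly 0 and
        # stats::kmeans declines centers == nrow(x)
        key <- apply(xyz, 1, paste, collapse = ",")
        fits[[k]] <- list(cluster = match(key, unique(key)))
        wss[k] <- 0
      } else {
        fits[[k]] <- kmeans(xyz, centers = k, nstart = restarts, iter.max = 50)
        wss[k] <- fits[[k]]$tot.withinss
      }
    }
  })
  ks <- seq_len(k_max)
  interior <- ks[ks >= 2 & ks <= k_max - 1]
  k_best <- if (!length(interior)) 1L else {
    d2 <- wss[interior - 1] - 2 * wss[interior] + wss[interior + 1]
    interior[which.max(d2)]
  }
  if (k_best == 1L) return(list(sort(unassigned$blob_id)))
  memb <- fits[[k_best]]$cluster
  grp <- split(unassigned$blob_id, memb)
  grp <- lapply(grp, sort)
  grp[order(vapply(grp, min, numeric(1)))]
}

#' Group blobs into columnar organelle instances
#'
#' The full columnar grouping loop: locate the best reference vector among
#' unassigned blobs (a near-collinear triplet), grow that instance by
#' angular/distance tests, repeat until no reference vector can be located,
#' then cluster whatever remains with elbow-selected K-means. Every blob ends
#' up in exactly one instance.
#'
#' @param blobs tibble of blobs (`blob_id, z, y, x, radius`).
#' @param config a [pipeline_config()].
#' @return tibble `(blob_id, instance_id)` with a `references` attribute: a
#'   tibble of per-instance reference vectors (`NA` for K-means instances).
#' @export
group_columnar <- function(blobs, config = pipeline_config()) {
  th <- config$angle_threshold_deg
  unassigned <- blobs
  assignments <- list()
  refs <- list()
  inst <- 0L
  while (nrow(unassigned) >= 3) {
    loc <- locate_reference_vector(unassigned, th)
    if (is.null(loc)) break
    members <- grow_instance(loc$seed_ids, loc$vector, unassigned, th)
    inst <- inst + 1L
    assignments[[inst]] <- members
    refs[[inst]] <- c(loc$vector, loc$cos_adj)
    unassigned <- unassigned[!(unassigned$blob_id %in% members), , drop = FALSE]
  }
  for (grp in kmeans_residual(unassigned, config$kmeans_max_k,
                              config$kmeans_seed, config$kmeans_restarts)) {
    inst <- inst + 1L
    assignments[[inst]] <- grp
    refs[[inst]] <- rep(NA_real_, 4)
  }
  out <- tibble::tibble(
    blob_id = unlist(assignments, use.names = FALSE),
    instance_id = rep(seq_along(assignments),
                      vapply(assignments, length, integer(1))))
  ref_m <- do.call(rbind, refs)
  attr(out, "references") <- if (is.null(ref_m)) {
    tibble::tibble(instance_id = integer(), ref_z = numeric(),
                   ref_y = numeric(), ref_x = numeric(), cos_adj = numeric())
  } else {
    tibble::tibble(instance_id = seq_along(assignments),
                   ref_z = ref_m[, 1], ref_y = ref_m[, 2], ref_x = ref_m[, 3],
                   cos_adj = ref_m[, 4])
  }
  out
}
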