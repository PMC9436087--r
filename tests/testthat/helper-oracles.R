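# Independent brute-force oracles used to freeze expected values. These stay
# deliberately naive (queue-based flood fill, exhaustive neighbourhood scans,
# literal rule re-execution) and share no code with the implementation.

# BFS flood fill over 26-connectivity; returns an integer label array
oracle_flood_fill <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nextlab <- 0L
  for (start in which(mask > 0)) {
    if (lab[start] > 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      p <- arrayInd(v, d)
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        q <- p + c(dz, dy, dx)
        if (any(q < 1) || any(q > d)) next
        ql <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
        if (mask[ql] > 0 && lab[ql] == 0L) {
          lab[ql] <- nextlab
          queue <- c(queue, ql)
        }
      }
    }
  }
  lab
}

# exhaustive 26-neighbourhood local-maximum test for every voxel
oracle_local_maxima <- function(a) {
  d <- dim(a)
  res <- array(FALSE, d)
  for (v in seq_along(a)) {
    p <- arrayInd(v, d)
    ge_all <- TRUE; gt_one <- FALSE
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      q <- p + c(dz, dy, dx)
      if (any(q < 1) || any(q > d)) next
      nv <- a[q[1], q[2], q[3]]
      if (a[v] < nv) ge_all <- FALSE
      if (a[v] > nv) gt_one <- TRUE
    }
    res[v] <- ge_all && gt_one
  }
  res
}

# literal voxel-counting overlap ratio: voxels at Euclidean distance < r
oracle_overlap_ratio <- function(center, r, mask) {
  d <- dim(mask)
  m <- ceiling(r)
  v_s <- 0L; v_m <- 0L
  for (dz in -m:m) for (dy in -m:m) for (dx in -m:m) {
    if (dz^2 + dy^2 + dx^2 >= r^2) next
    v_s <- v_s + 1L
    q <- center + c(dz, dy, dx)
    if (any(q < 1) || any(q > d)) next
    if (mask[q[1], q[2], q[3]] > 0) v_m <- v_m + 1L
  }
  v_m / v_s
}

# literal re-execution of the greedy selection rule
oracle_greedy_select <- function(cand) {
  ord <- order(-cand$intensity, cand$z, cand$y, cand$x)
  cand <- cand[ord, ]
  picked <- list()
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (p in picked) {
      dd <- sqrt(sum((c(cand$z[i], cand$y[i], cand$x[i]) -
                      c(p$z, p$y, p$x))^2))
      if (dd <= p$radius) { ok <- FALSE; break }
    }
    if (ok) picked[[length(picked) + 1L]] <- cand[i, ]
  }
  do.call(rbind, picked)
}

# exhaustive per-voxel argmin of distance/radius, restricted to the voxel's
# own connected component (lower blob_id wins ties)
oracle_assign <- function(mask, blobs, groups = NULL) {
  if (is.null(groups)) {
    groups <- data.frame(blob_id = blobs$blob_id,
                         instance_id = seq_len(nrow(blobs)))
  }
  comp <- oracle_flood_fill(mask)
  d <- dim(mask)
  out <- array(0L, d)
  bc <- comp[cbind(blobs$z, blobs$y, blobs$x)]
  for (v in which(mask > 0)) {
    p <- arrayInd(v, d)
    best <- Inf; best_id <- NA
    for (j in order(blobs$blob_id)) {
      if (bc[j] != comp[v]) next
      s <- sqrt(sum((p - c(blobs$z[j], blobs$y[j], blobs$x[j]))^2)) /
        blobs$radius[j]
      if (s < best) { best <- s; best_id <- blobs$blob_id[j] }
    }
    out[v] <- if (is.na(best_id)) 0L else
      groups$instance_id[groups$blob_id == best_id]
  }
  # components without any blob are one whole-cluster instance each
  extra <- max(groups$instance_id, 0L)
  for (ci in setdiff(seq_len(max(comp)), unique(bc))) {
    extra <- extra + 1L
    out[comp == ci] <- extra
  }
  out
}

# independent AP recomputation: greedy matching rebuilt from per-pair IoUs
oracle_ap <- function(truth, pred, thr) {
  tl <- setdiff(sort(unique(as.vector(truth))), 0)
  pl <- setdiff(sort(unique(as.vector(pred))), 0)
  pairs <- expand.grid(t = tl, p = pl)
  if (nrow(pairs)) {
    pairs$iou <- mapply(function(t, p) {
      a <- truth == t; b <- pred == p
      sum(a & b) / sum(a | b)
    }, pairs$t, pairs$p)
    pairs <- pairs[order(-pairs$iou, pairs$t, pairs$p), ]
  }
  used_t <- used_p <- c(); tp <- 0L
  for (i in seq_len(nrow(pairs))) {
    if (pairs$iou[i] <= 0) break
    if (pairs$t[i] %in% used_t || pairs$p[i] %in% used_p) next
    used_t <- c(used_t, pairs$t[i]); used_p <- c(used_p, pairs$p[i])
    if (pairs$iou[i] >= thr) tp <- tp + 1L
  }
  100 * tp / (tp + (length(pl) - tp) + (length(tl) - tp))
}

# Mann-Whitney U by exhaustive enumeration of group assignments: the exact
# two-sided p-value is the fraction of equally-likely rank arrangements with
# a U at least as extreme as observed
oracle_mw_p <- function(a, b) {
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- u_stat(a, b)
  pool <- c(a, b)
  n_a <- length(a)
  combs <- utils::combn(length(pool), n_a)
  mu <- n_a * length(b) / 2
  hits <- 0L
  for (j in seq_len(ncol(combs))) {
    u <- u_stat(pool[combs[, j]], pool[-combs[, j]])
    if (abs(u - mu) >= abs(obs - mu) - 1e-12) hits <- hits + 1L
  }
  hits / ncol(combs)
}

# small solid-ball semantic mask centered in a cube
make_ball_mask <- function(radius, dim_len = 2 * ceiling(radius) + 5) {
  d <- rep(dim_len, 3)
  cen <- rep((dim_len + 1) / 2, 3)
  g <- expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3])
  inside <- (g$z - cen[1])^2 + (g$y - cen[2])^2 + (g$x - cen[3])^2 <= radius^2
  array(as.integer(inside), d)
}
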