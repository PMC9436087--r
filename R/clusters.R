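#' Label 26-connected components of a binary mask
#'
#' Voxels are neighbours when their `(z, y, x)` indices differ by at most 1 on
#' every axis (26-connectivity). Components are numbered 1..K in order of
#' their first voxel (smallest linear index, i.e. fastest-varying z).
#'
#' @param mask a [semantic_mask()] or bare 0/1 3D array.
#' @return integer array of the same shape; 0 = background.
#' @export
label_components <- function(mask) {
  a <- if (inherits(mask, "sxt_volume")) as_bare_array(mask) else as.array(mask)
  d <- dim(a)
  idx <- which(a > 0)
  lab <- array(0L, d)
  if (!length(idx)) return(lab)
  pos <- array(0L, d)
  pos[idx] <- seq_along(idx)
  co <- arrayInd(idx, d)
  # 13 positive half-offsets of the 26-neighbourhood
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
             (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0), , drop = FALSE]
  edges <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    nb <- co + matrix(off[k, ], nrow(co), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_id <- pos[nb[ok, , drop = FALSE]]
    hit <- nb_id > 0L
    if (any(hit)) {
      edges[[k]] <- cbind(which(ok)[hit], nb_id[hit])
    }
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # renumber components by first (smallest linear index) voxel
  first <- vapply(split(seq_along(idx), memb), min, numeric(1))
  remap <- integer(length(first))
  remap[order(first)] <- seq_along(first)
  lab[idx] <- remap[memb]
  lab
}

#' Split a semantic mask into organelle clusters
#'
#' Step one of the pipeline: each 26-connected component of the mask becomes
#' an independent cluster carrying a cropped copy of the mask and (optionally)
#' of the tomogram. The crop box is the component's tight bounding box padded
#' by two voxels per edge and clipped at the volume border; the padding gives
#' the Gaussian filters and radius scan room beyond the organelle surface.
#'
#' @param mask a [semantic_mask()].
#' @param tomo the paired [tomogram()], or `NULL` for mask-only clusters.
#' @return list of cluster objects, each a list with elements `cluster_id`,
#'   `box` (2x3 matrix, inclusive `(z, y, x)` extents in the parent volume),
#'   `mask_crop` (0/1 array) and `tomo_crop` (array or `NULL`).
#' @export
label_connected_clusters <- function(mask, tomo = NULL) {
  if (!is.null(tomo)) stopifnot(all(dim(tomo) == dim(mask)))
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0L) return(list())
  d <- dim(lab)
  co_all <- arrayInd(which(lab > 0), d)
  memb <- lab[lab > 0]
  lapply(seq_len(k), function(i) {
    co <- co_all[memb == i, , drop = FALSE]
    lo <- pmax(apply(co, 2, min) - 2L, 1L)
    hi <- pmin(apply(co, 2, max) + 2L, d)
    box <- rbind(lo = lo, hi = hi)
    colnames(box) <- c("z", "y", "x")
    mask_crop <- array(0L, hi - lo + 1L)
    mask_crop[co - matrix(lo - 1L, nrow(co), 3, byrow = TRUE)] <- 1L
    tomo_crop <- if (is.null(tomo)) NULL else {
      as_bare_array(tomo)[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    }
    list(cluster_id = i, box = box, mask_crop = mask_crop, tomo_crop = tomo_crop)
  })
}
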