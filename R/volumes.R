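#' Volumetric grid containers
#'
#' A volume is a plain 3D numeric array in `(z, y, x)` axis order (first index
#' is the slowest physical axis, matching common tomography conventions) with
#' two attributes: `voxel_size`, the physical edge length of a voxel per axis
#' in nanometres, and `origin`, the 1-based integer voxel offset of the grid
#' inside a parent volume. All voxel coordinates in this package are 1-based
#' `(z, y, x)` indices into the array.
#'
#' Three kinds are distinguished by class:
#' * `tomogram()` — real-valued intensities; in soft X-ray tomography a
#'   voxel's intensity numerically equals its linear absorption coefficient
#'   (LAC), so values are typically in the 0.1–0.5 range.
#' * `semantic_mask()` — one organelle class, values in \{0, 1\}.
#' * `instance_mask()` — non-negative integer labels, 0 = background and
#'   `k >= 1` = organelle instance `k`.
#'
#' @param data 3D array (or something coercible to one) in `(z, y, x)` order.
#' @param voxel_size numeric length 1 or 3; nm per voxel edge (default 35,
#'   the sampling of the beta-cell tomograms this tool targets).
#' @param origin integer length 3; 1-based offset of this grid in a parent
#'   volume (default `c(1, 1, 1)`).
#' @return An object of class `"tomogram"`, `"semantic_mask"` or
#'   `"instance_mask"` (all also `"sxt_volume"`).
#' @examples
#' t <- tomogram(array(0.3, c(4, 4, 4)))
#' m <- semantic_mask(array(0L, c(4, 4, 4)))
#' @name volumes
NULL

new_volume <- function(data, voxel_size, origin, kind) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    stop("volume data must be a 3D array, got ", length(dim(data)), " dims",
         call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all grid dimensions must be >= 1", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("voxel_size components must be finite and > 0", call. = FALSE)
  }
  origin <- as.integer(origin)
  stopifnot(length(origin) == 3L)
  structure(data,
            voxel_size = voxel_size, origin = origin,
            class = c(kind, "sxt_volume", class(data)))
}

#' @rdname volumes
#' @export
tomogram <- function(data, voxel_size = c(35, 35, 35), origin = c(1L, 1L, 1L)) {
  v <- new_volume(data, voxel_size, origin, "tomogram")
  if (any(!is.finite(v))) stop("tomogram intensities must be finite", call. = FALSE)
  v
}

#' @rdname volumes
#' @export
semantic_mask <- function(data, voxel_size = c(35, 35, 35), origin = c(1L, 1L, 1L)) {
  v <- new_volume(data, voxel_size, origin, "semantic_mask")
  vals <- unique(as.vector(v))
  if (!all(vals %in% c(0, 1))) {
    stop("semantic mask values must be 0 or 1", call. = FALSE)
  }
  v
}

#' @rdname volumes
#' @export
instance_mask <- function(data, voxel_size = c(35, 35, 35), origin = c(1L, 1L, 1L)) {
  v <- new_volume(data, voxel_size, origin, "instance_mask")
  x <- as.vector(v)
  if (any(x < 0) || any(x != round(x))) {
    stop("instance mask values must be non-negative integers", call. = FALSE)
  }
  v
}

#' @export
print.sxt_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<%s> %d x %d x %d voxels (z, y, x), voxel size %s nm\n",
              class(x)[1L], d[1L], d[2L], d[3L],
              paste(format(attr(x, "voxel_size")), collapse = " x ")))
  if (inherits(x, "instance_mask")) {
    cat(sprintf("  %d labels, %d foreground voxels\n",
                length(setdiff(unique(as.vector(x)), 0)), sum(x > 0)))
  } else if (inherits(x, "semantic_mask")) {
    cat(sprintf("  %d foreground voxels\n", sum(x > 0)))
  } else {
    cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  }
  invisible(x)
}

#' Voxel size of a volume, in nanometres per axis
#' @param vol an `sxt_volume`.
#' @return numeric length 3 `(z, y, x)`.
#' @export
voxel_size <- function(vol) attr(vol, "voxel_size")

# strip volume attributes down to a bare array (internal)
as_bare_array <- function(vol) {
  a <- unclass(vol)
  attr(a, "voxel_size") <- NULL
  attr(a, "origin") <- NULL
  a
}

# relabel a non-negative integer label array so labels are contiguous 1..K,
# ordered by first (smallest linear index) occurrence
relabel_contiguous <- function(lab) {
  v <- as.vector(lab)
  pos <- which(v > 0)
  if (!length(pos)) return(lab)
  old <- v[pos]
  first <- vapply(split(pos, old), min, numeric(1))
  ord <- names(sort(first))
  map <- setNames(seq_along(ord), ord)
  v[pos] <- map[as.character(old)]
  array(as.integer(v), dim(lab))
}
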