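#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-unit table of a result
#' (per-instance rows for a segmentation, per-threshold AP rows for an
#' evaluation, per-method-and-dataset rows for a benchmark) and `glance()` a
#' one-row summary.
#'
#' @param x an `sxt_instances`, `sxt_eval` or `sxt_benchmark` object.
#' @param ... unused.
#' @name sxtseg-tidiers
NULL

#' @rdname sxtseg-tidiers
#' @export
tidy.sxt_instances <- function(x, ...) {
  vol <- tibble::tibble(instance_id = as.vector(x$mask)[x$mask > 0])
  vol <- dplyr::count(vol, .data$instance_id, name = "volume")
  blobs <- dplyr::summarise(dplyr::group_by(x$blobs, .data$instance_id),
                            n_blobs = dplyr::n(),
                            mean_radius = mean(.data$radius), .groups = "drop")
  dplyr::left_join(vol, blobs, by = "instance_id")
}

#' @rdname sxtseg-tidiers
#' @export
glance.sxt_instances <- function(x, ...) {
  tibble::tibble(n_instances = length(setdiff(unique(as.vector(x$mask)), 0)),
                 n_blobs = nrow(x$blobs),
                 n_clusters = length(unique(x$blobs$cluster_id)),
                 morphology = x$morphology)
}

#' @rdname sxtseg-tidiers
#' @export
tidy.sxt_eval <- function(x, ...) {
  tibble::tibble(iou_threshold = seq(0.50, 0.95, by = 0.05),
                 ap = unname(x$ap_by_threshold))
}

#' @rdname sxtseg-tidiers
#' @export
glance.sxt_eval <- function(x, ...) {
  tibble::tibble(map = x$map, ap50 = x$ap_by_threshold[["AP50"]],
                 ap70 = x$ap_by_threshold[["AP70"]],
                 ap90 = x$ap_by_threshold[["AP90"]],
                 n_truth = x$n_truth, n_pred = x$n_pred)
}

#' @rdname sxtseg-tidiers
#' @export
tidy.sxt_benchmark <- function(x, ...) attr(x, "per_dataset")

#' @rdname sxtseg-tidiers
#' @export
glance.sxt_benchmark <- function(x, ...) {
  tibble::as_tibble(x)
}
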