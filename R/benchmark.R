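#' Run the instance-splitting pipeline on volume files
#'
#' File-level wrapper: reads a tomogram and a semantic mask (MRC or TIFF),
#' runs [segment_instances()] with the given morphology, writes the instance
#' mask next to `output` and a JSON provenance file (`<output>.json`) with
#' the configuration, blob table and per-cluster instance counts. All
#' coordinates in the JSON are 1-based `(z, y, x)` voxel indices.
#'
#' @param tomogram_path,mask_path input volume files (same grid).
#' @param morphology `"sphere"` or `"columnar"`.
#' @param output path of the instance-mask volume to write (`.mrc` or
#'   `.tif`).
#' @param config a [pipeline_config()].
#' @return the `sxt_instances` object, invisibly.
#' @export
run_pipeline <- function(tomogram_path, mask_path,
                         morphology = c("sphere", "columnar"),
                         output, config = pipeline_config()) {
  morphology <- match.arg(morphology)
  tomo <- read_volume(tomogram_path, kind = "tomogram")
  mask <- read_volume(mask_path, kind = "semantic_mask")
  if (!all(dim(tomo) == dim(mask))) {
    stop("tomogram and mask grids differ: ", paste(dim(tomo), collapse = "x"),
         " vs ", paste(dim(mask), collapse = "x"), call. = FALSE)
  }
  fit <- segment_instances(tomo, mask, morphology, config)
  write_volume(fit$mask, output)
  prov <- list(
    morphology = morphology,
    config = unclass(config),
    coordinate_convention = "1-based (z, y, x) voxel indices",
    n_instances = length(setdiff(unique(as.vector(fit$mask)), 0)),
    blobs = fit$blobs,
    clusters = dplyr::count(fit$blobs, .data$cluster_id,
                            wt = NULL, name = "n_blobs")
  )
  jsonlite::write_json(prov, paste0(output, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(fit)
}

#' Benchmark the tool and the three baselines on synthetic datasets
#'
#' Generates `n_datasets` seeded synthetic datasets (dataset `i` uses seed
#' `master_seed + 7919 * i`), runs the post-processing tool and the three
#' comparison methods (connected-regions labeling, watershed, watershed with
#' a sigma = 1 Gaussian prefilter) on each, evaluates every result against
#' the generator ground truth with [mean_ap()], and averages the AP metrics
#' across datasets.
#'
#' @param morphology `"sphere"` or `"column"` (the tool runs its sphere or
#'   columnar route accordingly).
#' @param n_datasets number of datasets (default 10).
#' @param spec a [phantom_spec()]; its seed is overridden per dataset.
#' @param n_instances instances per dataset (default 5).
#' @param volume_shape dataset volume dimensions.
#' @param master_seed integer master seed.
#' @param config a [pipeline_config()].
#' @param methods subset of `c("tool", "connected", "watershed",
#'   "watershed_gaussian")` to run.
#' @return tibble of class `"sxt_benchmark"` with one row per method:
#'   `method, map, ap50, ap70, ap90` (percent, averaged over datasets) and a
#'   `per_dataset` attribute holding the unaveraged tibble.
#' @export
run_benchmark <- function(morphology = c("sphere", "column"),
                          n_datasets = 10L,
                          spec = NULL,
                          n_instances = 5L,
                          volume_shape = c(100L, 100L, 100L),
                          master_seed = 1L,
                          config = pipeline_config(),
                          methods = c("tool", "connected", "watershed",
                                      "watershed_gaussian")) {
  morphology <- match.arg(morphology)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(spec)) spec <- phantom_spec(morphology)
  route <- if (morphology == "sphere") "sphere" else "columnar"
  rows <- list()
  for (i in seq_len(n_datasets)) {
    spec$seed <- as.integer(master_seed + 7919 * i)
    ds <- assemble_dataset(spec, n_instances, volume_shape)
    preds <- list()
    if ("tool" %in% methods) {
      preds$tool <- segment_instances(ds$tomogram, ds$semantic, route, config)$mask
    }
    if ("connected" %in% methods) {
      preds$connected <- baseline_connected(ds$semantic)
    }
    if ("watershed" %in% methods) {
      preds$watershed <- baseline_watershed(ds$tomogram, ds$semantic)
    }
    if ("watershed_gaussian" %in% methods) {
      preds$watershed_gaussian <- baseline_watershed(ds$tomogram, ds$semantic,
                                                     presmooth_sigma = 1)
    }
    for (m in names(preds)) {
      ev <- mean_ap(ds$truth, preds[[m]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        dataset = i, method = m, map = ev$map,
        ap50 = ev$ap_by_threshold[["AP50"]],
        ap70 = ev$ap_by_threshold[["AP70"]],
        ap90 = ev$ap_by_threshold[["AP90"]],
        n_pred = ev$n_pred)
    }
  }
  per_dataset <- dplyr::bind_rows(rows)
  avg <- dplyr::summarise(dplyr::group_by(per_dataset, .data$method),
                          map = mean(.data$map), ap50 = mean(.data$ap50),
                          ap70 = mean(.data$ap70), ap90 = mean(.data$ap90),
                          .groups = "drop")
  avg <- avg[order(match(avg$method, c("tool", "connected", "watershed",
                                       "watershed_gaussian"))), ]
  attr(avg, "per_dataset") <- per_dataset
  attr(avg, "morphology") <- morphology
  class(avg) <- c("sxt_benchmark", class(avg))
  avg
}
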