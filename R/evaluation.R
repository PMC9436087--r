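#' Intersection-over-union of two instance labels
#'
#' @param truth,pred [instance_mask()]s (or integer arrays) on the same grid.
#' @param truth_label,pred_label the labels to compare.
#' @return `|A intersect B| / |A union B|`; an empty union gives 0.
#' @export
instance_iou <- function(truth, pred, truth_label, pred_label) {
  a <- truth == truth_label
  b <- pred == pred_label
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

# full IoU table between truth and prediction labels (rows = truth)
iou_table <- function(truth, pred) {
  t_v <- as.vector(truth); p_v <- as.vector(pred)
  fg <- t_v > 0 | p_v > 0
  t_lab <- sort(setdiff(unique(t_v[fg]), 0))
  p_lab <- sort(setdiff(unique(p_v[fg]), 0))
  if (!length(t_lab) || !length(p_lab)) {
    return(matrix(0, length(t_lab), length(p_lab),
                  dimnames = list(t_lab, p_lab)))
  }
  joint <- table(factor(t_v[fg], levels = t_lab),
                 factor(p_v[fg], levels = p_lab))
  n_t <- tabulate(match(t_v[fg], t_lab), length(t_lab))
  n_p <- tabulate(match(p_v[fg], p_lab), length(p_lab))
  inter <- unclass(joint)
  union <- outer(n_t, n_p, "+") - inter
  iou <- inter / pmax(union, 1)
  dimnames(iou) <- list(t_lab, p_lab)
  iou
}

#' Greedy one-to-one matching of predicted to ground-truth instances
#'
#' Pairs are taken in order of descending IoU (ties broken by the lower truth
#' then prediction label); each truth and each prediction instance is used at
#' most once; zero-IoU pairs never match. The matching is computed once from
#' the full IoU table and reused for every threshold.
#'
#' @param truth,pred [instance_mask()]s on the same grid.
#' @return tibble `(truth, pred, iou)`, one row per matched pair.
#' @export
match_instances <- function(truth, pred) {
  iou <- iou_table(truth, pred)
  out <- list()
  while (length(iou) && max(iou) > 0) {
    best <- which(iou == max(iou), arr.ind = TRUE)
    best <- best[order(as.integer(rownames(iou)[best[, 1]]),
                       as.integer(colnames(iou)[best[, 2]])), , drop = FALSE][1, ]
    out[[length(out) + 1L]] <- tibble::tibble(
      truth = as.integer(rownames(iou)[best[1]]),
      pred = as.integer(colnames(iou)[best[2]]),
      iou = iou[best[1], best[2]])
    iou <- iou[-best[1], -best[2], drop = FALSE]
  }
  if (!length(out)) {
    return(tibble::tibble(truth = integer(), pred = integer(), iou = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$truth)
}

#' Average precision at one IoU threshold
#'
#' Score-free AP for unscored instance masks: with a one-to-one greedy IoU
#' matching, a prediction is a true positive iff matched with IoU at or above
#' the threshold, and `AP = TP / (TP + FP + FN) * 100`. This convention is
#' standard for segmentation methods that emit no confidence scores and
#' coincides with ranked AP at the perfect and empty endpoints.
#'
#' @param truth,pred [instance_mask()]s on the same grid.
#' @param iou_threshold scalar in (0, 1).
#' @param matching optional precomputed [match_instances()] result.
#' @return AP in percent.
#' @export
average_precision <- function(truth, pred, iou_threshold, matching = NULL) {
  if (is.null(matching)) matching <- match_instances(truth, pred)
  n_truth <- length(setdiff(unique(as.vector(truth)), 0))
  n_pred <- length(setdiff(unique(as.vector(pred)), 0))
  if (n_truth == 0 && n_pred == 0) return(100)
  tp <- sum(matching$iou >= iou_threshold)
  100 * tp / (tp + (n_pred - tp) + (n_truth - tp))
}

#' AP across IoU thresholds 0.50–0.95 and their mean
#'
#' Computes [average_precision()] at the ten IoU thresholds 0.50, 0.55, ...,
#' 0.95 and their arithmetic mean (mAP, AP@\[.5:.95\]), reusing one greedy
#' matching.
#'
#' @param truth,pred [instance_mask()]s on the same grid.
#' @return object of class `"sxt_eval"`: list with `ap_by_threshold` (named
#'   numeric, percent), `map` (percent), `matching` (tibble), `n_truth`,
#'   `n_pred`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
mean_ap <- function(truth, pred) {
  stopifnot(all(dim(truth) == dim(pred)))
  matching <- match_instances(truth, pred)
  thr <- seq(0.50, 0.95, by = 0.05)
  ap <- vapply(thr, function(t) average_precision(truth, pred, t, matching),
               numeric(1))
  names(ap) <- sprintf("AP%02.0f", 100 * thr)
  structure(list(ap_by_threshold = ap, map = mean(ap), matching = matching,
                 n_truth = length(setdiff(unique(as.vector(truth)), 0)),
                 n_pred = length(setdiff(unique(as.vector(pred)), 0))),
            class = "sxt_eval")
}

#' @export
print.sxt_eval <- function(x, ...) {
  cat(sprintf("<sxt_eval> mAP %.1f%% (%d truth vs %d predicted instances)\n",
              x$map, x$n_truth, x$n_pred))
  cat("  ", paste(sprintf("%s=%.1f", names(x$ap_by_threshold),
                          x$ap_by_threshold), collapse = " "), "\n")
  invisible(x)
}

#' Per-instance volume and intensity statistics
#'
#' @param tomo a [tomogram()].
#' @param inst an aligned [instance_mask()].
#' @param condition optional condition tag (e.g. a treatment label) attached
#'   to every row.
#' @return tibble with `instance_id`, `volume` (voxels), `mean_intensity`
#'   (raw tomogram units) and `condition`.
#' @export
instance_statistics <- function(tomo, inst, condition = NA_character_) {
  stopifnot(all(dim(tomo) == dim(inst)))
  lin <- which(inst > 0)
  if (!length(lin)) {
    return(tibble::tibble(instance_id = integer(), volume = integer(),
                          mean_intensity = numeric(),
                          condition = character()))
  }
  lab <- as.vector(inst)[lin]
  val <- as.vector(tomo)[lin]
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(instance_id = lab, v = val),
                    .data$instance_id),
    volume = dplyr::n(), mean_intensity = mean(.data$v), .groups = "drop")
  tibble::add_column(agg, condition = as.character(condition))
}

#' Rank-sum comparison of per-instance statistics between two conditions
#'
#' Two-sided two-sample Mann-Whitney U (Wilcoxon rank-sum) test on instance
#' volume or mean intensity, with tie correction; the exact distribution is
#' used for small untied samples, the normal approximation otherwise.
#' P-values are reported raw, without multiplicity correction.
#'
#' @param stats_a,stats_b [instance_statistics()] tibbles for two conditions.
#' @param metric `"volume"` or `"intensity"`.
#' @return one-row tibble with `metric`, `n_a`, `n_b`, the U `statistic` and
#'   `p_value`.
#' @export
compare_conditions <- function(stats_a, stats_b,
                               metric = c("volume", "intensity")) {
  metric <- match.arg(metric)
  col <- if (metric == "volume") "volume" else "mean_intensity"
  a <- stats_a[[col]]; b <- stats_b[[col]]
  if (!length(a) || !length(b)) {
    stop("both condition groups must be non-empty", call. = FALSE)
  }
  ht <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  tibble::tibble(metric = metric, n_a = length(a), n_b = length(b),
                 statistic = unname(ht$statistic), p_value = ht$p.value)
}
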