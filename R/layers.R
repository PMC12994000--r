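# Network order of the hidden layers considered for winner assignment.
WINNER_LAYERS <- c("conv1", "conv2", "conv3", "lstm", "layer4")

#' Assign each voxel to the layer that predicts it best
#'
#' Per eligible voxel, the winner is the layer with the highest layer-wise
#' mean prediction accuracy. Exact ties are broken toward the earlier layer
#' in network order (deterministic and conservative for hierarchy claims);
#' the number of ties is recorded in attribute `"n_ties"`.
#'
#' @param layerwise_r `V x L` matrix (or data frame) of layer-wise mean
#'   correlations with layer names as columns, or a tibble with a `voxel`
#'   column plus one column per layer.
#' @param eligibility Logical length-`V` mask of voxels passing the
#'   significance gate (e.g. `significant` from [one_sample_fwe()]).
#' @param layers Layer order used for tie-breaking.
#' @return A `venc_assignment` tibble: `voxel`, `eligible`, `winner`
#'   (`NA` outside the mask), `winner_r`.
#' @export
assign_winner_layer <- function(layerwise_r, eligibility = NULL,
                                layers = WINNER_LAYERS) {
  df <- as.data.frame(layerwise_r)
  voxel <- if ("voxel" %in% names(df)) df$voxel else seq_len(nrow(df))
  missing <- setdiff(layers, names(df))
  if (length(missing)) stop_venc("missing layer column(s): %s", paste(missing, collapse = ", "))
  m <- as.matrix(df[layers])
  v <- nrow(m)
  eligibility <- eligibility %||% rep(TRUE, v)
  best <- apply(m, 1, max)
  first_hit <- apply(m == best, 1, which.max) # earliest layer wins ties
  n_ties <- sum(rowSums(m == best) > 1 & eligibility)
  winner <- layers[first_hit]
  winner[!eligibility] <- NA_character_
  wr <- best
  wr[!eligibility] <- NA_real_
  out <- tibble::tibble(voxel = voxel, eligible = eligibility,
                        winner = factor(winner, levels = layers),
                        winner_r = wr)
  attr(out, "n_ties") <- n_ties
  class(out) <- c("venc_assignment", class(out))
  out
}

#' Layer composition of each region of interest
#'
#' For each ROI, the fraction of eligible voxels assigned to each layer;
#' fractions sum to one per ROI. ROIs with no eligible voxels are excluded
#' and listed in attribute `"empty_rois"`.
#'
#' @param assignment A `venc_assignment`.
#' @param roi Length-`V` ROI labels aligned with `assignment$voxel`, or a
#'   data frame with `voxel` and `roi` columns.
#' @param layers Layer set over which proportions are computed.
#' @return A `venc_composition` tibble: `roi`, `layer`, `n`, `proportion`,
#'   with per-ROI eligible counts in `n_eligible`.
#' @export
roi_layer_proportions <- function(assignment, roi, layers = WINNER_LAYERS) {
  stopifnot(inherits(assignment, "venc_assignment"))
  if (is.data.frame(roi)) {
    roi <- roi$roi[match(assignment$voxel, roi$voxel)]
  }
  if (length(roi) != nrow(assignment)) stop_venc("`roi` not aligned with assignment")
  keep <- assignment$eligible & !is.na(roi)
  roi_f <- factor(roi)
  tab <- table(roi = roi_f[keep], layer = factor(assignment$winner[keep], levels = layers))
  totals <- rowSums(tab)
  empty <- names(totals)[totals == 0]
  ok <- totals > 0
  out <- as.data.frame(tab[ok, , drop = FALSE], responseName = "n")
  out$n_eligible <- totals[ok][as.character(out$roi)]
  out$proportion <- out$n / out$n_eligible
  out <- tibble::as_tibble(out)
  attr(out, "empty_rois") <- empty
  class(out) <- c("venc_composition", class(out))
  out
}

#' Early-vs-late layer log-ratio
#'
#' `log((p_early + eps) / (p_late + eps))` where `p_early` is the summed
#' proportion of the convolutional layers and `p_late` that of the LSTM and
#' layer 4. The symmetric pseudo-count keeps the ratio finite for degenerate
#' compositions and makes the statistic exactly antisymmetric under swapping
#' the early and late masses.
#'
#' @param proportions Numeric vector of layer proportions named by layer, or
#'   a `venc_composition` (one log-ratio per ROI).
#' @param pseudo_count Additive pseudo-count `eps`. For a composition the
#'   default is `1 / (2 * n_eligible)` per ROI; for a plain vector it is 0.
#' @param early,late Layer labels counted as early / late.
#' @return Scalar, or a tibble (`roi`, `logratio`) for compositions.
#' @export
early_late_logratio <- function(proportions, pseudo_count = NULL,
                                early = c("conv1", "conv2", "conv3"),
                                late = c("lstm", "layer4")) {
  lr <- function(pe, pl, eps) log((pe + eps) / (pl + eps))
  if (inherits(proportions, "venc_composition") || is.data.frame(proportions)) {
    df <- as.data.frame(proportions)
    sp <- split(df, df$roi, drop = TRUE)
    out <- purrr::map_dfr(sp, function(x) {
      eps <- pseudo_count %||% (1 / (2 * x$n_eligible[1]))
      tibble::tibble(roi = x$roi[1],
                     logratio = lr(sum(x$proportion[x$layer %in% early]),
                                   sum(x$proportion[x$layer %in% late]), eps))
    })
    return(out)
  }
  p <- proportions
  eps <- pseudo_count %||% 0
  lr(sum(p[early], na.rm = TRUE), sum(p[late], na.rm = TRUE), eps)
}

#' Pairwise ROI comparisons of early/late log-ratios
#'
#' Paired t-tests across subjects for every ROI pair on the per-subject
#' log-ratios, Bonferroni-corrected over the number of pairs.
#'
#' @param data Tidy tibble with `subject`, `roi`, `logratio` columns (one
#'   value per subject and ROI).
#' @param correction [stats::p.adjust()] method (default `"bonferroni"`).
#' @return Tibble: `roi1`, `roi2`, `estimate` (mean difference roi1 - roi2),
#'   `t`, `df`, `p`, `p_adjusted`.
#' @export
compare_roi_ratios <- function(data, correction = "bonferroni") {
  df <- as.data.frame(data)
  stopifnot(all(c("subject", "roi", "logratio") %in% names(df)))
  wide <- tapply(df$logratio, list(factor(df$subject), factor(df$roi)), mean)
  if (any(is.na(wide))) stop_venc("unpaired data: every subject needs every ROI")
  rois <- colnames(wide)
  pairs <- utils::combn(rois, 2)
  rows <- apply(pairs, 2, function(pr) {
    d <- wide[, pr[1]] - wide[, pr[2]]
    ht <- paired_t_safe(d)
    tibble::tibble(roi1 = pr[1], roi2 = pr[2], estimate = mean(d),
                   t = ht$t, df = ht$df, p = ht$p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = correction)
  out
}
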