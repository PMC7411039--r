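# Validation harness: link-level precision/recall and per-cell track
# purity of a track set against simulator ground truth.

#' Tracking accuracy against ground truth
#'
#' Each track point is matched to the nearest ground-truth tumor cell
#' position in the same frame within `match_radius_px`. A link (pair of
#' consecutive points in a track) is correct iff both endpoints match the
#' same ground-truth cell. Recall is computed over ground-truth links
#' (consecutive live frames of each cell); purity of a track is the
#' fraction of its matched points carrying its modal cell label, averaged
#' over tracks weighted by length.
#'
#' @param ground_truth a `ground_truth` data frame
#' @param trackset a `track_set`
#' @param match_radius_px matching radius in pixels
#' @return list with `link_precision`, `link_recall`, `purity`,
#'   `n_gt_links`, `n_track_links`
#' @export
tracking_accuracy <- function(ground_truth, trackset, match_radius_px = 3) {
  gt <- ground_truth[ground_truth$kind == "TUMOR" &
                       !(ground_truth$compartment %in% c("DEAD", "ENGULFED")), ]
  gt_links <- 0L
  if (nrow(gt) > 1) {
    o <- order(gt$cell_id, gt$frame)
    same <- gt$cell_id[o][-1] == gt$cell_id[o][-nrow(gt)]
    consec <- diff(gt$frame[o]) == 1L
    gt_links <- sum(same & consec)
  }
  ts <- as.data.frame(trackset)
  if (nrow(ts) == 0L)
    return(list(link_precision = NA_real_, link_recall = 0,
                purity = NA_real_, n_gt_links = gt_links, n_track_links = 0L))

  gt_by_frame <- split(gt, gt$frame)
  label <- rep(NA_integer_, nrow(ts))
  for (f in unique(ts$frame)) {
    gf <- gt_by_frame[[as.character(f)]]
    rows <- which(ts$frame == f)
    if (is.null(gf) || !nrow(gf)) next
    d2 <- outer(ts$x_px[rows], gf$x_px, "-")^2 +
      outer(ts$y_px[rows], gf$y_px, "-")^2
    j <- max.col(-d2, ties.method = "first")
    ok <- d2[cbind(seq_along(rows), j)] <= match_radius_px^2
    label[rows[ok]] <- gf$cell_id[j[ok]]
  }

  o <- order(ts$track_id, ts$frame)
  same <- ts$track_id[o][-1] == ts$track_id[o][-nrow(ts)]
  l1 <- label[o][-nrow(ts)]; l2 <- label[o][-1]
  n_links <- sum(same)
  correct <- sum(same & !is.na(l1) & !is.na(l2) & l1 == l2)

  pur <- vapply(split(label[o], ts$track_id[o]), function(ls) {
    ls <- ls[!is.na(ls)]
    if (!length(ls)) return(c(0, 0))
    c(max(table(ls)), length(ls))
  }, numeric(2))
  purity <- if (sum(pur[2, ]) > 0) sum(pur[1, ]) / sum(pur[2, ]) else NA_real_

  list(link_precision = if (n_links) correct / n_links else NA_real_,
       link_recall = if (gt_links) correct / gt_links else NA_real_,
       purity = purity, n_gt_links = gt_links, n_track_links = n_links)
}
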