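#' Nuclei-seeded cell segmentation
#'
#' Built-in segmenter for the phagocytosis assay: nuclei are thresholded
#' and labelled (4-connected) to give one seed per cell, then labels are
#' propagated over the thresholded cell-body (Iba1) area with a
#' Voronoi-style watershed (EBImage `propagate`). Deterministic given
#' its inputs. Label images from an external segmenter can be passed to
#' [quantify_phagocytosis()] directly instead.
#'
#' @param iba1 2D cell-body intensity matrix.
#' @param nuclei 2D nuclei intensity matrix.
#' @param pixel_size_um calibration.
#' @param iba1_threshold,nuclei_threshold `"otsu"` or numeric.
#' @param min_nucleus_area_um2 nuclei components below this are ignored.
#' @return `CellSegmentation`: list with `labels` (integer matrix,
#'   0 background), `n_cells`, `pixel_size_um`, `table` (per-cell
#'   centroid and area).
#' @export
segment_cells <- function(iba1, nuclei, pixel_size_um,
                          iba1_threshold = "otsu",
                          nuclei_threshold = "otsu",
                          min_nucleus_area_um2 = 3) {
  nuc_mask <- nuclei >= resolve_threshold(nuclei, nuclei_threshold)
  if (!any(nuc_mask)) stop("no nuclei detected")
  seeds <- label_components(nuc_mask)
  # drop tiny nuclei fragments, relabel contiguously
  min_px <- min_nucleus_area_um2 / pixel_size_um^2
  sizes <- tabulate(seeds[seeds > 0])
  keep <- which(sizes >= min_px)
  if (length(keep) == 0) stop("no nuclei detected")
  relab <- integer(length(sizes)); relab[keep] <- seq_along(keep)
  seeds[seeds > 0] <- relab[seeds[seeds > 0]]
  cell_mask <- (iba1 >= resolve_threshold(iba1, iba1_threshold)) | seeds > 0
  lab <- EBImage::propagate(EBImage::as.Image(iba1),
                            seeds = EBImage::as.Image(seeds),
                            mask = EBImage::as.Image(cell_mask * 1))
  labels <- matrix(as.integer(EBImage::imageData(lab)), nrow = nrow(iba1))
  cell_segmentation(labels, pixel_size_um)
}

#' Wrap a label image as a `CellSegmentation`
#'
#' @param labels integer matrix, 0 = background, k = cell k; labels are
#'   compacted to contiguous positive integers.
#' @param pixel_size_um calibration.
#' @return `CellSegmentation` (see [segment_cells()]).
#' @export
cell_segmentation <- function(labels, pixel_size_um) {
  stopifnot(is.matrix(labels), all(labels >= 0))
  ids <- sort(unique(labels[labels > 0]))
  relab <- integer(max(c(0L, ids))); relab[ids] <- seq_along(ids)
  labels[labels > 0] <- relab[labels[labels > 0]]
  pc <- pixel_centers(nrow(labels), ncol(labels), pixel_size_um)
  tab <- do.call(rbind, lapply(seq_along(ids), function(k) {
    idx <- which(labels == k, arr.ind = TRUE)
    data.frame(cell_id = k, x_um = mean(pc$x[idx[, 2]]),
               y_um = mean(pc$y[idx[, 1]]),
               area_um2 = nrow(idx) * pixel_size_um^2)
  }))
  if (is.null(tab))
    tab <- data.frame(cell_id = integer(), x_um = numeric(),
                      y_um = numeric(), area_um2 = numeric())
  structure(list(labels = labels, n_cells = length(ids),
                 pixel_size_um = pixel_size_um, table = tab),
            class = "CellSegmentation")
}

#' Score amyloid phagocytosis per cell
#'
#' A cell is scored positive when its FITC-positive pixel area (pixels
#' at or above `positive_threshold`) reaches `min_punctum_area_um2`.
#' Two intensity summaries are reported per cell: the mean FITC
#' intensity over the whole cell mask (`mean_fitc_cell`) and the mean
#' over the cell's FITC-positive pixels only (`mean_fitc_puncta`). The
#' summary `mean_fitc_positive` averages `mean_fitc_puncta` over
#' positive cells (so it recovers the punctum plateau intensity), and is
#' `NA` (flagged) when no cell is positive.
#'
#' @param seg `CellSegmentation`.
#' @param fitc 2D FITC intensity matrix, same shape as `seg$labels`.
#' @param positive_threshold `"otsu"` (computed on FITC restricted to
#'   cell pixels) or numeric.
#' @param min_punctum_area_um2 minimum FITC-positive area for a positive
#'   call.
#' @return `PhagoSummary`: list with `n_cells`, `n_positive`,
#'   `proportion_positive`, `mean_fitc_positive`, `per_cell` data.frame.
#' @export
quantify_phagocytosis <- function(seg, fitc, positive_threshold = "otsu",
                                  min_punctum_area_um2 = 1) {
  stopifnot(inherits(seg, "CellSegmentation"),
            all(dim(fitc) == dim(seg$labels)))
  if (seg$n_cells == 0) stop("segmentation contains zero cells")
  in_cells <- seg$labels > 0
  thr <- if (is.numeric(positive_threshold)) positive_threshold else
    resolve_threshold(matrix(fitc[in_cells], ncol = 1), positive_threshold)
  px_area <- seg$pixel_size_um^2
  per <- lapply(seq_len(seg$n_cells), function(k) {
    sel <- seg$labels == k
    v <- fitc[sel]
    pos_px <- v >= thr
    pos_area <- sum(pos_px) * px_area
    data.frame(cell_id = k,
               area_um2 = sum(sel) * px_area,
               mean_fitc_cell = mean(v),
               fitc_pos_area_um2 = pos_area,
               mean_fitc_puncta = if (any(pos_px)) mean(v[pos_px]) else
                 NA_real_,
               positive = pos_area >= min_punctum_area_um2)
  })
  per <- do.call(rbind, per)
  n_pos <- sum(per$positive)
  structure(list(
    n_cells = seg$n_cells, n_positive = n_pos,
    proportion_positive = n_pos / seg$n_cells,
    mean_fitc_positive = if (n_pos > 0)
      mean(per$mean_fitc_puncta[per$positive]) else NA_real_,
    threshold = thr, per_cell = per),
    class = "PhagoSummary")
}

#' @export
print.PhagoSummary <- function(x, ...) {
  cat(sprintf("PhagoSummary: %d/%d cells positive (%.1f%%), mean FITC %s\n",
              x$n_positive, x$n_cells, 100 * x$proportion_positive,
              ifelse(is.na(x$mean_fitc_positive), "NA",
                     format(x$mean_fitc_positive, digits = 4))))
  invisible(x)
}
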