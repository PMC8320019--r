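#' Per-glomerulus nuclear-YAP ratio
#'
#' Among the podocytes (TLE4-positive nuclei) of each ROI, the fraction
#' that is nuclear-YAP positive:
#' `ratio = n(podocyte & nuclear-YAP+) / n(podocyte)`.
#' Glomeruli without podocytes get an `NA` ratio (flagged missing).
#'
#' @param nuclei nucleus records carrying both `is_podocyte` and
#'   `is_nuclear_yap_positive` flags (see [classify_podocytes()],
#'   [classify_nuclear_yap()]).
#' @return Data frame: `roi_id`, `n_tle4_pos`, `n_tle4_pos_nuclear_yap`,
#'   `nuclear_yap_ratio`.
#' @export
glomerular_yap_ratio <- function(nuclei) {
  if (any(is.na(nuclei$is_podocyte)) ||
      any(is.na(nuclei$is_nuclear_yap_positive)))
    stop("podoquant_unclassified: classify podocytes and nuclear YAP first")
  rois <- sort(unique(nuclei$roi_id))
  out <- do.call(rbind, lapply(rois, function(r) {
    sub <- nuclei[nuclei$roi_id == r, , drop = FALSE]
    n_pod <- sum(sub$is_podocyte)
    n_both <- sum(sub$is_podocyte & sub$is_nuclear_yap_positive)
    data.frame(roi_id = r, n_tle4_pos = n_pod,
               n_tle4_pos_nuclear_yap = n_both,
               nuclear_yap_ratio = if (n_pod > 0) n_both / n_pod else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Measure nuclear and cytoplasmic YAP per cultured cell
#'
#' Cell-culture mode: nuclei are segmented from the DNA channel over the
#' whole image and the cytoplasmic compartment of each cell is taken as a
#' fixed-width ring around its nuclear mask (excluding all nuclei). The
#' ring stands in for a full cell segmentation, which plated podocytes at
#' subconfluent density do not require.
#'
#' @param image a `CalibratedImage` with `DNA` and `YAP` roles.
#' @param dna_threshold DNA intensity threshold for nuclear segmentation.
#' @param min_nucleus_area minimum nuclear profile area, um^2.
#' @param ring_width_um width of the perinuclear cytoplasmic ring, um.
#' @return Data frame of cell records: `cell_id`, `centroid_x_um`,
#'   `centroid_y_um`, `nuclear_mean_yap`, `cytoplasmic_mean_yap`,
#'   `nc_ratio`, `is_nuclear_localized` (NA until classified).
#' @export
measure_cell_yap <- function(image, dna_threshold = 100,
                             min_nucleus_area = 10, ring_width_um = 3) {
  stopifnot(inherits(image, "CalibratedImage"))
  dna <- channel(image, "DNA")
  yap <- channel(image, "YAP")
  ps <- image$pixel_size
  mask <- dna >= dna_threshold
  empty <- data.frame(cell_id = integer(), centroid_x_um = numeric(),
                      centroid_y_um = numeric(), nuclear_mean_yap = numeric(),
                      cytoplasmic_mean_yap = numeric(), nc_ratio = numeric(),
                      is_nuclear_localized = logical())
  if (!any(mask)) return(empty)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  storage.mode(lab) <- "integer"
  r_px <- max(1L, round(ring_width_um / ps))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  nr <- nrow(lab); nc <- ncol(lab)
  pix <- which(lab > 0L)
  groups <- split(pix, lab[pix])
  recs <- list(); kept <- 0L
  for (k in seq_along(groups)) {
    p <- groups[[k]]
    idx <- cbind((p - 1L) %% nr + 1L, (p - 1L) %/% nr + 1L)
    area <- nrow(idx) * ps^2
    if (area < min_nucleus_area) next
    # dilate this nucleus within a padded bounding window
    r0 <- max(1L, min(idx[, 1]) - r_px); r1 <- min(nr, max(idx[, 1]) + r_px)
    c0 <- max(1L, min(idx[, 2]) - r_px); c1 <- min(nc, max(idx[, 2]) + r_px)
    win <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
    win[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)] <- 1
    dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(win), brush))
    ring_local <- which(dil > 0 & win == 0, arr.ind = TRUE)
    ring <- cbind(ring_local[, 1] + r0 - 1L, ring_local[, 2] + c0 - 1L)
    ring <- ring[!mask[ring], , drop = FALSE]  # exclude every nucleus
    cyto <- if (nrow(ring)) mean(yap[ring]) else NA_real_
    nucl <- mean(yap[idx])
    if (!is.na(cyto) && cyto <= 0)
      stop("podoquant_zero_cytoplasm: cytoplasmic mean is zero for cell ", k)
    kept <- kept + 1L
    recs[[kept]] <- data.frame(
      cell_id = kept,
      centroid_x_um = mean(idx[, 2] - 0.5) * ps,
      centroid_y_um = mean(idx[, 1] - 0.5) * ps,
      nuclear_mean_yap = nucl, cytoplasmic_mean_yap = cyto,
      nc_ratio = nucl / cyto, is_nuclear_localized = NA)
  }
  if (kept == 0L) return(empty)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Classify YAP localization of cultured cells
#'
#' A cell is called nuclear-localized when its nuclear/cytoplasmic mean
#' YAP ratio is at or above `nc_ratio_threshold`. The threshold (default
#' 1.2) is a calibration knob replacing the visual scoring used at the
#' bench; with the nuclear:cytoplasmic contrasts typical of clear
#' translocation states the call is insensitive to its exact value.
#'
#' @param cells data frame from [measure_cell_yap()].
#' @param nc_ratio_threshold N/C ratio at or above which a cell counts as
#'   nuclear-localized.
#' @return `cells` with `is_nuclear_localized` set.
#' @export
classify_cell_localization <- function(cells, nc_ratio_threshold = 1.2) {
  if (!all(c("nuclear_mean_yap", "cytoplasmic_mean_yap") %in% names(cells)))
    stop("podoquant_missing_intensity: compartment means required")
  if (any(cells$cytoplasmic_mean_yap <= 0, na.rm = TRUE))
    stop("podoquant_zero_cytoplasm: cytoplasmic mean must be positive")
  cells$is_nuclear_localized <-
    cells$nuclear_mean_yap / cells$cytoplasmic_mean_yap >= nc_ratio_threshold
  cells
}

#' Percent nuclear-YAP-positive cells across replicates
#'
#' For each replicate, the percentage of nuclear-localized cells among
#' the first `n_sampled` records (deterministic order, so repeated calls
#' agree); then the mean and SD across replicates — the usual "% nuclear
#' YAP, N experiments x n cells" summary.
#'
#' @param replicates a single classified cell data frame or a list of
#'   them (one per experimental replicate).
#' @param n_sampled number of cells scored per replicate.
#' @return List with `percent_mean`, `percent_sd`, `per_replicate`
#'   (numeric vector of percentages), `n_sampled`.
#' @export
percent_nuclear_yap <- function(replicates, n_sampled = 100) {
  if (is.data.frame(replicates)) replicates <- list(replicates)
  if (length(replicates) == 0L)
    stop("podoquant_empty_input: no replicates")
  per <- vapply(replicates, function(cells) {
    if (nrow(cells) == 0L)
      stop("podoquant_empty_input: replicate without cells")
    if (any(is.na(cells$is_nuclear_localized)))
      stop("podoquant_unclassified: run classify_cell_localization() first")
    if (n_sampled > nrow(cells))
      stop("podoquant_bad_sample: n_sampled exceeds available cells")
    sub <- cells[order(cells$cell_id), , drop = FALSE][seq_len(n_sampled), ]
    100 * mean(sub$is_nuclear_localized)
  }, numeric(1))
  list(percent_mean = mean(per),
       percent_sd = if (length(per) > 1L) sd(per) else NA_real_,
       per_replicate = per, n_sampled = n_sampled)
}
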