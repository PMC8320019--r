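#' Segment glomerular tuft ROIs from the GLEPP1 channel
#'
#' Classical threshold-and-morphology segmentation: pixels at or above
#' `glepp1_threshold` are taken as tuft candidate, gaps are closed with a
#' disc structuring element, interior holes (nuclei, capillary lumina) are
#' filled, and connected components smaller than `min_area` are dropped.
#' Intensity ties count as positive (`>=` comparison throughout).
#'
#' @param image a [calibrated_image()] with a `GLEPP1` role.
#' @param glepp1_threshold intensity threshold on the native scale.
#' @param min_area minimum tuft cross-section area in um^2. Glomerular
#'   tuft profiles are large objects; the default (2000 um^2) rejects
#'   stray capsular or tubular staining.
#' @param closing_radius radius of the morphological closing element in
#'   um (default 5, about the scale of intra-tuft capillary gaps).
#' @return An object of class `GlomerulusSet`: list with `labels` (integer
#'   matrix, 0 = background, k = ROI k), `rois` (data frame: `roi_id`,
#'   `tuft_area_um2`, `centroid_x_um`, `centroid_y_um`,
#'   `glepp1_positive_fraction`), and `pixel_size`.
#' @export
segment_glomeruli <- function(image, glepp1_threshold = 100,
                              min_area = 2000, closing_radius = 5) {
  stopifnot(inherits(image, "CalibratedImage"))
  if (!is.numeric(min_area) || min_area <= 0)
    stop("podoquant_bad_min_area: min_area must be positive")
  gl <- channel(image, "GLEPP1")
  ps <- image$pixel_size
  mask <- gl >= glepp1_threshold
  if (!any(mask)) {
    return(empty_glomerulus_set(dim(gl), ps))
  }
  img <- EBImage::Image(mask * 1)
  r_px <- max(0L, round(closing_radius / ps))
  if (r_px > 0) {
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    img <- EBImage::closing(img, brush)
  }
  img <- EBImage::fillHull(img)
  lab <- EBImage::imageData(EBImage::bwlabel(img))
  storage.mode(lab) <- "integer"
  areas_px <- tabulate(lab[lab > 0L])
  keep <- which(areas_px * ps^2 >= min_area)
  if (length(keep) == 0L) return(empty_glomerulus_set(dim(gl), ps))
  relab <- integer(length(areas_px))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  nr <- nrow(lab)
  pix <- which(lab > 0L)
  groups <- split(pix, lab[pix])
  rois <- do.call(rbind, lapply(seq_along(keep), function(k) {
    p <- groups[[as.character(k)]]
    rows <- (p - 1L) %% nr + 1L
    cols <- (p - 1L) %/% nr + 1L
    data.frame(
      roi_id = k,
      tuft_area_um2 = length(p) * ps^2,
      centroid_x_um = mean(cols - 0.5) * ps,
      centroid_y_um = mean(rows - 0.5) * ps,
      glepp1_positive_fraction = mean(gl[p] >= glepp1_threshold)
    )
  }))
  structure(list(labels = lab, rois = rois, pixel_size = ps),
            class = "GlomerulusSet")
}

empty_glomerulus_set <- function(dims, ps) {
  structure(list(
    labels = matrix(0L, dims[1], dims[2]),
    rois = data.frame(roi_id = integer(), tuft_area_um2 = numeric(),
                      centroid_x_um = numeric(), centroid_y_um = numeric(),
                      glepp1_positive_fraction = numeric()),
    pixel_size = ps), class = "GlomerulusSet")
}

#' @export
print.GlomerulusSet <- function(x, ...) {
  cat(sprintf("GlomerulusSet: %d ROI(s) in a %d x %d px image\n",
              nrow(x$rois), nrow(x$labels), ncol(x$labels)))
  if (nrow(x$rois)) print(x$rois)
  invisible(x)
}

#' GLEPP1-positive fraction of one tuft ROI
#'
#' Fraction of ROI pixels whose GLEPP1 intensity is at or above the
#' threshold — the image-analysis analogue of "GLEPP1 positive percentage
#' tuft area". After morphological closing and hole filling the ROI mask
#' contains sub-threshold pixels (nuclei, lumina), so this is generally
#' below 1.
#'
#' @param image a `CalibratedImage`.
#' @param glomeruli a `GlomerulusSet` from [segment_glomeruli()].
#' @param roi_id which ROI.
#' @param glepp1_threshold intensity threshold.
#' @return Fraction in `[0, 1]`.
#' @export
glepp1_positive_fraction <- function(image, glomeruli, roi_id,
                                     glepp1_threshold = 100) {
  stopifnot(inherits(glomeruli, "GlomerulusSet"))
  sel <- glomeruli$labels == roi_id
  if (!any(sel)) stop("podoquant_empty_mask: ROI ", roi_id, " has no pixels")
  gl <- channel(image, "GLEPP1")
  mean(gl[sel] >= glepp1_threshold)
}

#' Segment nuclear profiles within glomerular ROIs
#'
#' Thresholds the DNA channel, optionally splits touching nuclei by a
#' distance-transform watershed, removes objects below `min_nucleus_area`,
#' and assigns each nucleus to the ROI containing its centroid. Nuclei
#' whose centroid falls outside every ROI are discarded; nuclei that
#' merely touch an ROI boundary are kept in full, so per-marker mean
#' intensities are always computed over the complete nuclear mask.
#'
#' @param image a `CalibratedImage` with a `DNA` role.
#' @param glomeruli a `GlomerulusSet`; pass `NULL` to segment nuclei over
#'   the whole image (cell-culture mode), in which case `roi_id` is 0 for
#'   every record.
#' @param dna_threshold intensity threshold on the DNA channel.
#' @param min_nucleus_area minimum profile area in um^2; sub-threshold
#'   fragments and optical debris are removed.
#' @param split_touching if `TRUE`, apply a watershed on the distance
#'   transform to separate touching nuclei.
#' @return Data frame of nucleus records: `nucleus_id`, `roi_id`,
#'   `centroid_x_um`, `centroid_y_um`, `profile_area_um2`,
#'   `apparent_profile_diameter_um` (equivalent-circle diameter
#'   `2*sqrt(area/pi)`), one `mean_<ROLE>` column per channel role, and
#'   logical flags `is_podocyte`, `is_nuclear_yap_positive` (NA until set
#'   by the classification step).
#' @export
segment_nuclei <- function(image, glomeruli = NULL, dna_threshold = 100,
                           min_nucleus_area = 10, split_touching = FALSE) {
  stopifnot(inherits(image, "CalibratedImage"))
  dna <- channel(image, "DNA")
  ps <- image$pixel_size
  mask <- dna >= dna_threshold
  roles <- names(image$channel_roles)
  empty <- nucleus_record_frame(roles)
  if (!any(mask)) return(empty)
  if (split_touching) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1))
  } else {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  }
  storage.mode(lab) <- "integer"
  n_obj <- max(lab)
  if (n_obj == 0L) return(empty)
  chans <- lapply(roles, function(r) channel(image, r))
  names(chans) <- roles
  nr <- nrow(lab)
  pix <- which(lab > 0L)
  groups <- split(pix, lab[pix])
  recs <- vector("list", n_obj)
  kept <- 0L
  for (p in groups) {
    area <- length(p) * ps^2
    if (area < min_nucleus_area) next
    rows <- (p - 1L) %% nr + 1L
    cols <- (p - 1L) %/% nr + 1L
    cy_px <- mean(rows - 0.5)
    cx_px <- mean(cols - 0.5)
    if (is.null(glomeruli)) {
      roi <- 0L
    } else {
      roi <- glomeruli$labels[pmin(pmax(round(cy_px + 0.5), 1), nr),
                              pmin(pmax(round(cx_px + 0.5), 1), ncol(lab))]
      if (roi == 0L) next
    }
    kept <- kept + 1L
    means <- vapply(chans, function(m) mean(m[p]), numeric(1))
    rec <- data.frame(nucleus_id = kept, roi_id = as.integer(roi),
                      centroid_x_um = cx_px * ps, centroid_y_um = cy_px * ps,
                      profile_area_um2 = area,
                      apparent_profile_diameter_um = 2 * sqrt(area / pi))
    for (r in roles) rec[[paste0("mean_", r)]] <- means[[r]]
    rec$is_podocyte <- NA
    rec$is_nuclear_yap_positive <- NA
    recs[[kept]] <- rec
  }
  if (kept == 0L) return(empty)
  out <- do.call(rbind, recs[seq_len(kept)])
  rownames(out) <- NULL
  out
}

nucleus_record_frame <- function(roles) {
  out <- data.frame(nucleus_id = integer(), roi_id = integer(),
                    centroid_x_um = numeric(), centroid_y_um = numeric(),
                    profile_area_um2 = numeric(),
                    apparent_profile_diameter_um = numeric())
  for (r in roles) out[[paste0("mean_", r)]] <- numeric()
  out$is_podocyte <- logical()
  out$is_nuclear_yap_positive <- logical()
  out
}
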