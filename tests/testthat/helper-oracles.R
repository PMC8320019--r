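# Independent Monte-Carlo oracle for the slab-projection forward model:
# uniform centre offsets across the padded slab, full-diameter projection
# when the equator lies inside the slab, cap circle otherwise.
mc_profile_diameter <- function(D, T, n = 1e6, seed = 42,
                                min_detectable = 0) {
  set.seed(seed)
  u <- runif(n, -D / 2, T + D / 2)
  delta <- pmax(0, pmax(-u, u - T))
  d <- 2 * sqrt(pmax(0, (D / 2)^2 - delta^2))
  mean(d[d >= min_detectable])
}

# GlomerulusSet covering a whole image with a single ROI (fixture builder)
full_image_roi <- function(dims, ps, glepp1 = NULL, threshold = 100) {
  lab <- matrix(1L, dims[1], dims[2])
  frac <- if (is.null(glepp1)) 1 else mean(glepp1 >= threshold)
  structure(list(
    labels = lab,
    rois = data.frame(roi_id = 1L, tuft_area_um2 = prod(dims) * ps^2,
                      centroid_x_um = dims[2] / 2 * ps,
                      centroid_y_um = dims[1] / 2 * ps,
                      glepp1_positive_fraction = frac),
    pixel_size = ps), class = "GlomerulusSet")
}

# nucleus-record fixture with given marker means
nuclei_df <- function(tle4 = numeric(), yap = numeric(),
                      diameter = rep(7, length(tle4)),
                      roi_id = rep(1L, length(tle4))) {
  n <- length(tle4)
  data.frame(nucleus_id = seq_len(n), roi_id = roi_id,
             centroid_x_um = runif(n, 0, 100),
             centroid_y_um = runif(n, 0, 100),
             profile_area_um2 = pi * (diameter / 2)^2,
             apparent_profile_diameter_um = diameter,
             mean_TLE4 = tle4,
             mean_YAP = if (length(yap)) yap else rep(0, n),
             is_podocyte = NA, is_nuclear_yap_positive = NA)
}

# draw a hard-edged disk into a matrix (test-local twin of the renderer)
test_disk <- function(mat, cx_px, cy_px, r_px, value) {
  ii <- row(mat) - 0.5; jj <- col(mat) - 0.5
  mat[(ii - cy_px)^2 + (jj - cx_px)^2 <= r_px^2] <- value
  mat
}
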