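test_that("disjoint bright tufts are recovered with accurate areas", {
  g <- data.frame(center_x_um = c(50, 150, 250), center_y_um = rep(50, 3),
                  radius_um = c(40, 35, 30))
  ph <- generate_tissue_phantom(phantom_spec(
    glomeruli = g, nv_true = 50, noise_sd = 0, blur_sigma = 0, seed = 5))
  rois <- segment_glomeruli(ph$image)$rois
  expect_identical(nrow(rois), 3L)
  # area within one pixel-perimeter band of pi r^2
  ord <- order(rois$centroid_x_um)
  for (i in 1:3) {
    r <- g$radius_um[i]
    expect_lt(abs(rois$tuft_area_um2[ord[i]] - pi * r^2),
              2 * pi * r * ph$image$pixel_size + 1)
  }
})

test_that("no signal or sub-minimum tufts give an empty ROI set", {
  px <- array(0, dim = c(64, 64, 4))
  img <- calibrated_image(px, c(GLEPP1 = 1, TLE4 = 2, YAP = 3, DNA = 4), 0.5)
  expect_identical(nrow(segment_glomeruli(img)$rois), 0L)

  small <- generate_tissue_phantom(phantom_spec(
    n_tufts = 1, tuft_radius_um = 20, nv_true = 50, noise_sd = 0, seed = 2))
  expect_identical(nrow(segment_glomeruli(small$image,
                                          min_area = 2000)$rois), 0L)
  expect_gt(nrow(segment_glomeruli(small$image, min_area = 500)$rois), 0L)
  expect_error(segment_glomeruli(small$image, min_area = -1), "bad_min_area")
})

test_that("GLEPP1-positive fraction matches brute-force pixel counts", {
  # half-bright gradient fixture over a whole-image ROI
  gl <- matrix(0, 40, 40); gl[, 1:20] <- 200
  px <- array(0, dim = c(40, 40, 2)); px[, , 1] <- gl
  img <- calibrated_image(px, c(GLEPP1 = 1, DNA = 2), 0.5)
  roi <- full_image_roi(c(40, 40), 0.5)
  expect_equal(glepp1_positive_fraction(img, roi, 1, 100),
               sum(gl >= 100) / length(gl))
  expect_equal(glepp1_positive_fraction(img, roi, 1, 0), 1.0)
  expect_equal(glepp1_positive_fraction(img, roi, 1, 201), 0.0)
  expect_error(glepp1_positive_fraction(img, roi, 7, 100), "empty_mask")
})

test_that("nuclei are counted exactly and measured consistently", {
  ph <- generate_tissue_phantom(phantom_spec(
    n_tufts = 1, nv_true = 150, frac_tle4 = 1, noise_sd = 0, seed = 9))
  glom <- segment_glomeruli(ph$image)
  nuc <- segment_nuclei(ph$image, glom, min_nucleus_area = 2)
  expect_identical(nrow(nuc), nrow(ph$truth$nuclei))
  # postconditions: diameter is the equivalent-circle diameter; centroids
  # fall inside the parent ROI
  expect_equal(nuc$apparent_profile_diameter_um,
               2 * sqrt(nuc$profile_area_um2 / pi))
  ps <- ph$image$pixel_size
  at <- cbind(round(nuc$centroid_y_um / ps + 0.5),
              round(nuc$centroid_x_um / ps + 0.5))
  expect_true(all(glom$labels[at] == nuc$roi_id))
  # an ROI devoid of nuclei yields an empty record set
  bare <- generate_tissue_phantom(phantom_spec(
    n_tufts = 1, nv_true = 0, noise_sd = 0, seed = 1))
  expect_identical(nrow(segment_nuclei(bare$image,
                                       segment_glomeruli(bare$image))), 0L)
})

test_that("touching nuclei split under the watershed option only", {
  dna <- matrix(0, 64, 64)
  dna <- test_disk(dna, 26, 32, 6, 200)
  dna <- test_disk(dna, 38, 32, 6, 200)   # centres 12 px apart, r = 6
  gl <- matrix(200, 64, 64)
  px <- array(0, dim = c(64, 64, 2)); px[, , 1] <- gl; px[, , 2] <- dna
  img <- calibrated_image(px, c(GLEPP1 = 1, DNA = 2), 0.5)
  roi <- segment_glomeruli(img, min_area = 100)
  merged <- segment_nuclei(img, roi, min_nucleus_area = 2,
                           split_touching = FALSE)
  split <- segment_nuclei(img, roi, min_nucleus_area = 2,
                          split_touching = TRUE)
  expect_identical(nrow(merged), 1L)
  expect_identical(nrow(split), 2L)
})

test_that("segmentation is invariant under whole-pixel translation", {
  ph <- generate_tissue_phantom(phantom_spec(
    n_tufts = 1, tuft_radius_um = 30, nv_true = 150, frac_tle4 = 1,
    noise_sd = 0, seed = 4))
  px <- ph$image$pixels
  d <- dim(px)
  shifted <- array(ph$truth$spec$intensities$background, dim = d + c(8, 6, 0))
  shifted[8 + seq_len(d[1]), 6 + seq_len(d[2]), ] <- px
  img2 <- calibrated_image(shifted, ph$image$channel_roles,
                           ph$image$pixel_size)
  g1 <- segment_glomeruli(ph$image); g2 <- segment_glomeruli(img2)
  expect_equal(g1$rois$tuft_area_um2, g2$rois$tuft_area_um2)
  n1 <- segment_nuclei(ph$image, g1, min_nucleus_area = 2)
  n2 <- segment_nuclei(img2, g2, min_nucleus_area = 2)
  expect_identical(nrow(n1), nrow(n2))
  expect_equal(sort(n1$profile_area_um2), sort(n2$profile_area_um2))
})
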