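test_that("glomerular YAP ratio is a direct count quotient", {
  n <- nuclei_df(tle4 = c(rep(200, 10), rep(0, 5)),
                 yap = c(rep(100, 7), rep(0, 8)))
  n <- classify_nuclear_yap(classify_podocytes(n))
  r <- glomerular_yap_ratio(n)
  expect_identical(r$n_tle4_pos, 10L)
  expect_identical(r$n_tle4_pos_nuclear_yap, 7L)
  expect_equal(r$nuclear_yap_ratio, 0.7)
  # zero podocytes: flagged missing, not zero or infinite
  none <- classify_nuclear_yap(classify_podocytes(nuclei_df(tle4 = c(0, 0),
                                                            yap = c(0, 0))))
  expect_true(is.na(glomerular_yap_ratio(none)$nuclear_yap_ratio))
  expect_error(glomerular_yap_ratio(nuclei_df(tle4 = 1)), "unclassified")
})

test_that("ratio bounds and relabeling invariance", {
  set.seed(11)
  n <- nuclei_df(tle4 = runif(120, 0, 255), yap = runif(120, 0, 255),
                 roi_id = sample(1:4, 120, replace = TRUE))
  n <- classify_nuclear_yap(classify_podocytes(n))
  r <- glomerular_yap_ratio(n)
  ok <- !is.na(r$nuclear_yap_ratio)
  expect_true(all(r$nuclear_yap_ratio[ok] >= 0 & r$nuclear_yap_ratio[ok] <= 1))
  expect_true(all(r$n_tle4_pos_nuclear_yap <= r$n_tle4_pos))
  perm <- sample(nrow(n))
  expect_equal(glomerular_yap_ratio(n[perm, ]), r)
})

test_that("cell localization calls follow the N/C ratio threshold", {
  cells <- data.frame(cell_id = 1:3, nuclear_mean_yap = c(200, 100, 119),
                      cytoplasmic_mean_yap = c(100, 100, 100),
                      is_nuclear_localized = NA)
  out <- classify_cell_localization(cells, nc_ratio_threshold = 1.2)
  expect_identical(out$is_nuclear_localized, c(TRUE, FALSE, FALSE))
  cells$cytoplasmic_mean_yap[1] <- 0
  expect_error(classify_cell_localization(cells), "zero_cytoplasm")
  # raising the threshold never increases the positive count
  set.seed(3)
  cc <- data.frame(cell_id = 1:50, nuclear_mean_yap = runif(50, 20, 220),
                   cytoplasmic_mean_yap = runif(50, 20, 220))
  counts <- vapply(seq(0.5, 3, by = 0.25), function(th)
    sum(classify_cell_localization(cc, th)$is_nuclear_localized), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cell phantom classification is perfect at 3x contrast", {
  ph <- generate_cell_culture_phantom(n_cells = 25, fraction_nuclear = 0.6,
                                      contrast_ratio = 3, noise_sd = 2,
                                      seed = 21)
  cells <- measure_cell_yap(ph$image)
  expect_identical(nrow(cells), 25L)
  cells <- classify_cell_localization(cells)
  # match measured cells to the manifest by position
  got <- cells
  truth_idx <- vapply(seq_len(nrow(got)), function(i) {
    which.min((ph$truth$cells$x_um - got$centroid_x_um[i])^2 +
              (ph$truth$cells$y_um - got$centroid_y_um[i])^2)
  }, integer(1))
  truth <- ph$truth$cells[truth_idx, ]
  expect_identical(got$is_nuclear_localized, truth$is_nuclear)
  # measured N/C ratio reflects the rendered contrast on both sides
  expect_gt(min(got$nc_ratio[truth$is_nuclear]), 2)
  expect_lt(max(got$nc_ratio[!truth$is_nuclear]), 0.6)
})

test_that("percent nuclear YAP summarises replicates", {
  loc <- data.frame(cell_id = 1:100, nuclear_mean_yap = 200,
                    cytoplasmic_mean_yap = 100)
  loc <- classify_cell_localization(loc)
  expect_equal(percent_nuclear_yap(loc, 100)$percent_mean, 100)
  unloc <- data.frame(cell_id = 1:100, nuclear_mean_yap = 50,
                      cytoplasmic_mean_yap = 100)
  unloc <- classify_cell_localization(unloc)
  expect_equal(percent_nuclear_yap(unloc, 100)$percent_mean, 0)
  mix <- rbind(loc[1:60, ], unloc[1:40, ]); mix$cell_id <- 1:100
  res <- percent_nuclear_yap(list(mix, mix, mix), 100)
  expect_equal(res$percent_mean, 60)
  expect_equal(res$percent_sd, 0)
  expect_error(percent_nuclear_yap(loc, 200), "bad_sample")
})
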