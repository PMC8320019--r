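#' Phantom specification for synthetic tissue images
#'
#' Collects every parameter of the synthetic biopsy-section generator.
#' Defaults describe the imaging regime the pipeline targets: 8-bit
#' channels at 0.5 um/px (a 20x whole-slide scan), 3 um sections,
#' podocyte nuclei of 8 um caliper diameter, a true podocyte density of
#' 226 per 10^6 um^3 (an early-grade value), podocytes making up 40% of
#' glomerular nuclei, and half of them nuclear-YAP positive.
#'
#' @param n_tufts number of glomerular tuft cross-sections (laid out on a
#'   grid; alternatively supply `glomeruli` directly).
#' @param glomeruli optional data frame `center_x_um`, `center_y_um`,
#'   `radius_um` placing tufts explicitly; tufts must not overlap.
#' @param tuft_radius_um tuft cross-section radius for the grid layout.
#' @param pixel_size um per pixel.
#' @param bit_depth intensity maximum (255 = 8-bit).
#' @param nv_true true podocyte density, per 10^6 um^3.
#' @param nuclear_diameter_um caliper diameter `D` of nuclei, um.
#' @param section_thickness slab thickness `T`, um.
#' @param frac_tle4 fraction of glomerular nuclei that are TLE4+
#'   (podocytes); total nuclear density is `nv_true / frac_tle4`.
#' @param frac_nuclear_yap fraction of TLE4+ nuclei that are
#'   nuclear-YAP positive.
#' @param intensities named list of rendered plateau intensities:
#'   `background`, `glepp1_tuft`, `dna_nucleus`, `tle4_pos`, `tle4_neg`,
#'   `yap_pos`, `yap_neg`.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param blur_sigma Gaussian blur SD in pixels applied to each channel
#'   (hard-edged disks otherwise).
#' @param min_profile_diameter_um profiles smaller than this are treated
#'   as below the detection limit: not rendered and absent from the
#'   manifest.
#' @param fixed_count if `TRUE` use the rounded expected profile count
#'   per tuft instead of a Poisson draw.
#' @param seed RNG seed; a fixed seed makes the phantom bit-identical.
#' @return Object of class `PhantomSpec` (a validated list).
#' @export
phantom_spec <- function(n_tufts = 1, glomeruli = NULL, tuft_radius_um = 60,
                         pixel_size = 0.5, bit_depth = 255,
                         nv_true = 226, nuclear_diameter_um = 8,
                         section_thickness = 3,
                         frac_tle4 = 0.4, frac_nuclear_yap = 0.5,
                         intensities = list(), noise_sd = 2, blur_sigma = 1,
                         min_profile_diameter_um = 2, fixed_count = FALSE,
                         seed = 1) {
  if (frac_tle4 < 0 || frac_tle4 > 1 || frac_nuclear_yap < 0 ||
      frac_nuclear_yap > 1)
    stop("podoquant_bad_spec: fractions must lie in [0,1]")
  if (nuclear_diameter_um >= 2 * tuft_radius_um)
    stop("podoquant_bad_spec: nuclear diameter must be below tuft diameter")
  if (nv_true < 0 || pixel_size <= 0 || section_thickness < 0)
    stop("podoquant_bad_spec: non-positive geometry parameter")
  defaults <- list(background = 5, glepp1_tuft = 180, dna_nucleus = 200,
                   tle4_pos = 200, tle4_neg = 40, yap_pos = 150,
                   yap_neg = 30)
  intensities <- utils::modifyList(defaults, intensities)
  if (is.null(glomeruli)) {
    # grid layout with a margin wide enough for closing + blur artefacts
    margin <- 15
    cell <- 2 * (tuft_radius_um + margin)
    ncol_g <- ceiling(sqrt(n_tufts))
    nrow_g <- ceiling(n_tufts / ncol_g)
    k <- seq_len(n_tufts) - 1L
    glomeruli <- data.frame(
      center_x_um = (k %% ncol_g) * cell + cell / 2,
      center_y_um = (k %/% ncol_g) * cell + cell / 2,
      radius_um = tuft_radius_um)
  }
  # reject overlapping tufts: ground truth must stay unambiguous
  if (nrow(glomeruli) > 1L) {
    for (i in seq_len(nrow(glomeruli) - 1L)) {
      for (j in seq(i + 1L, nrow(glomeruli))) {
        dd <- sqrt((glomeruli$center_x_um[i] - glomeruli$center_x_um[j])^2 +
                   (glomeruli$center_y_um[i] - glomeruli$center_y_um[j])^2)
        if (dd < glomeruli$radius_um[i] + glomeruli$radius_um[j])
          stop("podoquant_overlapping_tufts: tufts ", i, " and ", j,
               " overlap")
      }
    }
  }
  structure(list(glomeruli = glomeruli, pixel_size = pixel_size,
                 bit_depth = bit_depth, nv_true = nv_true,
                 nuclear_diameter_um = nuclear_diameter_um,
                 section_thickness = section_thickness,
                 frac_tle4 = frac_tle4, frac_nuclear_yap = frac_nuclear_yap,
                 intensities = intensities, noise_sd = noise_sd,
                 blur_sigma = blur_sigma,
                 min_profile_diameter_um = min_profile_diameter_um,
                 fixed_count = fixed_count, seed = seed),
            class = "PhantomSpec")
}

#' Simulate apparent profile diameters of slab-sectioned spheres
#'
#' Monte-Carlo twin of the analytic forward model: sphere centres are
#' placed at volumetric density `nv` (Poisson by default), the slab cuts
#' the tuft sphere at its equator, and every sphere intersecting the slab
#' contributes a full-thickness projection profile — diameter `D` when
#' the equator lies inside the slab, a cap circle otherwise. The mean of
#' many simulated diameters converges to
#' [expected_profile_diameter()]`(D, T)`.
#'
#' @param nv volumetric density, per 10^6 um^3.
#' @param D sphere caliper diameter, um.
#' @param T slab thickness, um.
#' @param tuft_radius_um radius of the sampled tuft cross-section, um.
#' @param seed optional RNG seed.
#' @param fixed_count use the rounded expectation instead of Poisson.
#' @param min_profile_diameter_um drop profiles below this diameter
#'   (detection limit); 0 keeps all.
#' @return List: `diameters` (um), `expected_count` (before the
#'   detection limit), `n_visible`.
#' @export
generate_section_profiles <- function(nv, D, T, tuft_radius_um = 60,
                                      seed = NULL, fixed_count = FALSE,
                                      min_profile_diameter_um = 0) {
  if (nv < 0 || D <= 0 || T < 0 || tuft_radius_um <= 0)
    stop("podoquant_bad_spec: all geometry parameters must be positive")
  if (D >= 2 * tuft_radius_um)
    stop("podoquant_bad_spec: degenerate geometry, D >= tuft diameter")
  A <- pi * tuft_radius_um^2
  lambda <- nv / 1e6 * (D + T) * A
  with_seed(seed, {
    n <- if (fixed_count) round(lambda) else rpois(1, lambda)
    if (n == 0L)
      return(list(diameters = numeric(), expected_count = lambda,
                  n_visible = 0L))
    # centre offset along the section axis, uniform over the slab padded
    # by one radius on each side
    u <- runif(n, -D / 2, T + D / 2)
    delta <- pmax(0, pmax(-u, u - T))     # distance beyond nearest face
    d <- 2 * sqrt(pmax(0, (D / 2)^2 - delta^2))
    d <- d[d >= max(min_profile_diameter_um, .Machine$double.eps)]
    list(diameters = d, expected_count = lambda, n_visible = length(d))
  })
}

# draw a disk (max-combine) into a matrix; centre/diameter in um
draw_disk <- function(mat, cx_um, cy_um, d_um, value, ps) {
  r <- d_um / 2 / ps
  cx <- cx_um / ps; cy <- cy_um / ps
  j0 <- max(1L, floor(cx - r)); j1 <- min(ncol(mat), ceiling(cx + r) + 1L)
  i0 <- max(1L, floor(cy - r)); i1 <- min(nrow(mat), ceiling(cy + r) + 1L)
  ii <- seq(i0, i1); jj <- seq(j0, j1)
  dy2 <- ((ii - 0.5) - cy)^2
  dx2 <- ((jj - 0.5) - cx)^2
  inside <- outer(dy2, dx2, "+") <= r^2
  sub <- mat[ii, jj, drop = FALSE]
  sub[inside] <- pmax(sub[inside], value)
  mat[ii, jj] <- sub
  mat
}

#' Generate a synthetic tissue phantom with ground truth
#'
#' Renders a 4-channel calibrated image (GLEPP1, TLE4, YAP, DNA) of
#' circular glomerular tuft cross-sections containing nuclear profiles
#' whose diameters follow the slab-section forward model, with marker
#' assignments drawn at the specified fractions, then applies Gaussian
#' blur and additive noise. Every rendered object is listed in the
#' returned manifest and vice versa.
#'
#' Nuclear profiles are placed without overlap (minimum edge gap 1.5 um)
#' and fully inside their tuft, so noise-free phantoms are exactly
#' countable by the segmentation stage.
#'
#' @param spec a [phantom_spec()].
#' @return List with `image` (a `CalibratedImage`, roles GLEPP1=1,
#'   TLE4=2, YAP=3, DNA=4) and `truth`: `tufts` (per-tuft geometry and
#'   counts), `nuclei` (per-profile position, diameter, marker flags),
#'   and the echoed `spec`.
#' @export
generate_tissue_phantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  ps <- spec$pixel_size
  ints <- spec$intensities
  g <- spec$glomeruli
  W_um <- max(g$center_x_um + g$radius_um) + 15
  H_um <- max(g$center_y_um + g$radius_um) + 15
  H <- ceiling(H_um / ps); W <- ceiling(W_um / ps)
  ch <- list(GLEPP1 = matrix(ints$background, H, W),
             TLE4 = matrix(ints$background, H, W),
             YAP = matrix(ints$background, H, W),
             DNA = matrix(ints$background, H, W))
  D <- spec$nuclear_diameter_um
  T <- spec$section_thickness
  nv_total <- if (spec$frac_tle4 > 0) spec$nv_true / spec$frac_tle4
              else spec$nv_true
  with_seed(spec$seed, {
    tufts <- list(); nuclei <- list(); nid <- 0L
    for (t in seq_len(nrow(g))) {
      cx <- g$center_x_um[t]; cy <- g$center_y_um[t]; R <- g$radius_um[t]
      prof <- generate_section_profiles(
        nv_total, D, T, R, seed = NULL, fixed_count = spec$fixed_count,
        min_profile_diameter_um = spec$min_profile_diameter_um)
      ds <- prof$diameters
      n <- length(ds)
      placed <- matrix(numeric(), 0, 3)  # x, y, radius (um)
      tle4 <- logical(n); yap <- logical(n)
      for (i in seq_len(n)) {
        r_i <- ds[i] / 2
        ok <- FALSE
        for (try in seq_len(5000L)) {
          # uniform position within the tuft keeping the profile inside
          rho <- (R - r_i - 0.5) * sqrt(runif(1))
          th <- runif(1, 0, 2 * pi)
          x <- cx + rho * cos(th); y <- cy + rho * sin(th)
          if (nrow(placed) == 0L ||
              all(sqrt((placed[, 1] - x)^2 + (placed[, 2] - y)^2) >=
                  placed[, 3] + r_i + 1.5)) { ok <- TRUE; break }
        }
        if (!ok)
          stop("podoquant_phantom_too_dense: could not place profile ",
               "without overlap; reduce nv_true or enlarge the tuft")
        placed <- rbind(placed, c(x, y, r_i))
        tle4[i] <- runif(1) < spec$frac_tle4
        yap[i] <- tle4[i] && (runif(1) < spec$frac_nuclear_yap)
        nid <- nid + 1L
        nuclei[[nid]] <- data.frame(
          nucleus_id = nid, tuft_id = t, x_um = x, y_um = y,
          profile_diameter_um = ds[i], is_tle4 = tle4[i],
          is_nuclear_yap = yap[i])
      }
      # render this tuft on a local tile, then blit once into each channel
      pad <- 12
      x0_um <- cx - R - pad; y0_um <- cy - R - pad
      j0 <- max(1L, floor(x0_um / ps) + 1L)
      i0 <- max(1L, floor(y0_um / ps) + 1L)
      j1 <- min(W, ceiling((cx + R + pad) / ps))
      i1 <- min(H, ceiling((cy + R + pad) / ps))
      ox_um <- (j0 - 1L) * ps; oy_um <- (i0 - 1L) * ps
      th_ <- i1 - i0 + 1L; tw_ <- j1 - j0 + 1L
      tile <- list(GLEPP1 = matrix(ints$background, th_, tw_),
                   TLE4 = matrix(ints$background, th_, tw_),
                   YAP = matrix(ints$background, th_, tw_),
                   DNA = matrix(ints$background, th_, tw_))
      tile$GLEPP1 <- draw_disk(tile$GLEPP1, cx - ox_um, cy - oy_um, 2 * R,
                               ints$glepp1_tuft, ps)
      for (i in seq_len(n)) {
        x <- placed[i, 1] - ox_um; y <- placed[i, 2] - oy_um
        tile$DNA <- draw_disk(tile$DNA, x, y, ds[i], ints$dna_nucleus, ps)
        tile$TLE4 <- draw_disk(tile$TLE4, x, y, ds[i],
                               if (tle4[i]) ints$tle4_pos else ints$tle4_neg,
                               ps)
        tile$YAP <- draw_disk(tile$YAP, x, y, ds[i],
                              if (yap[i]) ints$yap_pos else ints$yap_neg, ps)
      }
      for (nm in names(ch))
        ch[[nm]][i0:i1, j0:j1] <- pmax(ch[[nm]][i0:i1, j0:j1], tile[[nm]])
      tufts[[t]] <- data.frame(
        tuft_id = t, center_x_um = cx, center_y_um = cy, radius_um = R,
        area_um2 = pi * R^2, n_profiles = n, n_tle4 = sum(tle4),
        n_tle4_yap = sum(yap))
    }
    for (nm in names(ch)) {
      m <- ch[[nm]]
      if (spec$blur_sigma > 0)
        m <- EBImage::imageData(EBImage::gblur(EBImage::Image(m),
                                               sigma = spec$blur_sigma))
      if (spec$noise_sd > 0)
        m <- m + rnorm(length(m), 0, spec$noise_sd)
      ch[[nm]] <- round(pmin(pmax(m, 0), spec$bit_depth))
    }
    image <- calibrated_image(ch, c(GLEPP1 = 1, TLE4 = 2, YAP = 3, DNA = 4),
                              ps, T, spec$bit_depth)
    truth <- list(
      tufts = do.call(rbind, tufts),
      nuclei = if (nid > 0L) do.call(rbind, nuclei) else
        data.frame(nucleus_id = integer(), tuft_id = integer(),
                   x_um = numeric(), y_um = numeric(),
                   profile_diameter_um = numeric(), is_tle4 = logical(),
                   is_nuclear_yap = logical()),
      spec = spec)
    list(image = image, truth = truth)
  })
}

#' Generate a synthetic cell-culture phantom with ground truth
#'
#' Renders plated cells on a grid, each a cytoplasmic disk with a
#' concentric nuclear disk, in two channels (YAP, DNA). Nuclear-localized
#' cells carry a nuclear:cytoplasmic YAP intensity ratio of
#' `contrast_ratio`; the remaining cells the reciprocal. The localization
#' label of every cell is recorded in the manifest.
#'
#' @param n_cells number of cells (> 0).
#' @param fraction_nuclear probability that a cell is nuclear-localized.
#' @param contrast_ratio nuclear:cytoplasmic plateau intensity ratio for
#'   localized cells (> 0).
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed (fixed seed gives a bit-identical image).
#' @param pixel_size um per pixel.
#' @param nucleus_radius_um,cell_radius_um cell geometry, um.
#' @param base_intensity plateau intensity of the dim compartment.
#' @param blur_sigma Gaussian blur SD in pixels.
#' @param bit_depth intensity maximum.
#' @return List with `image` (roles YAP=1, DNA=2) and `truth`: per-cell
#'   data frame (`cell_id`, position, `is_nuclear`, plateau means).
#' @export
generate_cell_culture_phantom <- function(n_cells, fraction_nuclear,
                                          contrast_ratio = 3, noise_sd = 2,
                                          seed = 1, pixel_size = 0.5,
                                          nucleus_radius_um = 5,
                                          cell_radius_um = 12,
                                          base_intensity = 60,
                                          blur_sigma = 1, bit_depth = 255) {
  if (n_cells <= 0) stop("podoquant_bad_spec: n_cells must be positive")
  if (fraction_nuclear < 0 || fraction_nuclear > 1)
    stop("podoquant_bad_spec: fraction_nuclear must lie in [0,1]")
  if (contrast_ratio <= 0)
    stop("podoquant_bad_spec: contrast_ratio must be positive")
  if (base_intensity * contrast_ratio > bit_depth)
    stop("podoquant_bad_spec: bright compartment exceeds bit_depth")
  ps <- pixel_size
  cell_box <- 2 * cell_radius_um + 6
  ncol_g <- ceiling(sqrt(n_cells))
  nrow_g <- ceiling(n_cells / ncol_g)
  H <- ceiling(nrow_g * cell_box / ps); W <- ceiling(ncol_g * cell_box / ps)
  yap <- matrix(2, H, W); dna <- matrix(2, H, W)
  with_seed(seed, {
    cells <- vector("list", n_cells)
    for (k in seq_len(n_cells)) {
      i <- (k - 1L) %/% ncol_g; j <- (k - 1L) %% ncol_g
      x <- j * cell_box + cell_box / 2
      y <- i * cell_box + cell_box / 2
      loc <- runif(1) < fraction_nuclear
      nuc_val <- if (loc) base_intensity * contrast_ratio else base_intensity
      cyt_val <- if (loc) base_intensity else base_intensity * contrast_ratio
      yap <- draw_disk(yap, x, y, 2 * cell_radius_um, cyt_val, ps)
      # nucleus overwrites the cytoplasmic plateau
      r <- nucleus_radius_um / ps
      jj <- which(((col(yap) - 0.5) - x / ps)^2 +
                  ((row(yap) - 0.5) - y / ps)^2 <= r^2)
      yap[jj] <- nuc_val
      dna <- draw_disk(dna, x, y, 2 * nucleus_radius_um, 200, ps)
      cells[[k]] <- data.frame(cell_id = k, x_um = x, y_um = y,
                               is_nuclear = loc, nuclear_plateau = nuc_val,
                               cytoplasmic_plateau = cyt_val)
    }
    blur_noise <- function(m) {
      if (blur_sigma > 0)
        m <- EBImage::imageData(EBImage::gblur(EBImage::Image(m),
                                               sigma = blur_sigma))
      if (noise_sd > 0) m <- m + rnorm(length(m), 0, noise_sd)
      round(pmin(pmax(m, 0), bit_depth))
    }
    image <- calibrated_image(list(blur_noise(yap), blur_noise(dna)),
                              c(YAP = 1, DNA = 2), ps,
                              section_thickness = 0, bit_depth = bit_depth)
    list(image = image, truth = list(cells = do.call(rbind, cells)))
  })
}
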