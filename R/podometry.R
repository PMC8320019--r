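#' Expected apparent profile diameter of a sectioned sphere
#'
#' Forward model for spherical nuclei of caliper diameter `D` sampled by a
#' slab of thickness `T` with full-thickness projection: a nucleus is seen
#' whenever any part of it intersects the slab, and its apparent profile
#' is the projection through the slab. Spheres whose equator lies inside
#' the slab project at their full diameter `D`; spheres centred a distance
#' `delta` beyond a slab face show a cap circle of diameter
#' `2*sqrt((D/2)^2 - delta^2)`. Averaging over a uniform centre position
#' gives the closed form
#' \deqn{\bar d = \frac{D\,(T + \pi D/4)}{D + T}.}
#' The thin-section limit (`T = 0`) is `pi*D/4`; as `T` grows, `\bar d`
#' tends to `D`.
#'
#' With a detection limit `min_detectable = h > 0`, profiles smaller than
#' `h` are never observed; the expectation is then taken over visible
#' profiles only, which raises it above the `h = 0` value.
#'
#' @param D true (caliper) sphere diameter, um. Must be positive.
#' @param T section thickness, um. Must be non-negative.
#' @param min_detectable minimum detectable profile diameter `h`, um
#'   (`0 <= h < D`); 0 means every profile is seen.
#' @return Expected apparent profile diameter, um.
#' @seealso [estimate_caliper_diameter()] for the inverse.
#' @export
expected_profile_diameter <- function(D, T, min_detectable = 0) {
  if (any(!is.finite(D)) || any(D <= 0))
    stop("podoquant_bad_diameter: D must be positive")
  if (any(!is.finite(T)) || any(T < 0))
    stop("podoquant_bad_thickness: T must be non-negative")
  h <- min_detectable
  if (any(h < 0) || any(h >= D))
    stop("podoquant_bad_detection_limit: need 0 <= min_detectable < D")
  if (all(h == 0)) return(D * (T + pi * D / 4) / (D + T))
  # visible-profile mean: caps truncated at offset delta_c on both faces
  R <- D / 2
  delta_c <- sqrt(R^2 - (h / 2)^2)
  cap_int <- delta_c * h / 2 + R^2 * asin(delta_c / R)  # int 2*sqrt(R^2-d^2)
  (T * D + 2 * cap_int) / (T + 2 * delta_c)
}

#' Estimate the caliper diameter from a mean apparent profile diameter
#'
#' Inverts the forward model of [expected_profile_diameter()]: `D` is the
#' positive root of `(pi/4) D^2 + (T - dbar) D - dbar*T = 0`, computed
#' with a numerically stable quadratic solver. The round trip
#' `estimate_caliper_diameter(expected_profile_diameter(D, T), T)`
#' reproduces `D` to near machine precision.
#'
#' With a detection limit `min_detectable = h > 0` the truncated forward
#' model has no closed-form inverse and is solved numerically.
#'
#' @param dbar mean apparent profile diameter, um. Must be positive.
#' @param T section thickness, um.
#' @param min_detectable minimum detectable profile diameter `h`, um;
#'   must be below `dbar`.
#' @return Caliper diameter `D`, um.
#' @export
estimate_caliper_diameter <- function(dbar, T, min_detectable = 0) {
  if (any(!is.finite(dbar)) || any(dbar <= 0))
    stop("podoquant_bad_diameter: dbar must be positive")
  if (any(!is.finite(T)) || any(T < 0))
    stop("podoquant_bad_thickness: T must be non-negative")
  h <- min_detectable
  if (any(h < 0) || any(h >= dbar))
    stop("podoquant_bad_detection_limit: need 0 <= min_detectable < dbar")
  if (any(h > 0)) {
    solve1 <- function(db, TT, hh) {
      f <- function(D) expected_profile_diameter(D, TT, hh) - db
      stats::uniroot(f, lower = db * (1 + 1e-12), upper = 4 * db,
                     tol = 1e-12)$root
    }
    return(mapply(solve1, dbar, T, h))
  }
  a <- pi / 4
  b <- T - dbar
  cc <- -dbar * T
  disc <- b^2 - 4 * a * cc
  if (any(disc < 0))
    stop("podoquant_numerical_domain: no real root for given dbar, T")
  # stable root pair: q/a and cc/q
  q <- -0.5 * (b + sign(b + (b == 0)) * sqrt(disc))
  r1 <- q / a
  r2 <- ifelse(q != 0, cc / q, 0)
  D <- pmax(r1, r2)
  if (any(D <= 0))
    stop("podoquant_numerical_domain: no positive root for given dbar, T")
  D
}

#' Volumetric nuclear density from a per-area profile count
#'
#' Abercrombie-type thickness correction: profiles counted per unit
#' section area over-count objects by the factor `D + T` (an object is
#' seen whenever its centre lies within a slab of effective thickness
#' `D + T`), so
#' \deqn{N_V = \frac{n_{app}/A}{D + T} \times 10^6}
#' reported per `10^6` um^3 of tuft volume.
#'
#' With a detection limit `h > 0`, an object is counted only when its
#' centre lies within `sqrt((D/2)^2 - (h/2)^2)` of a slab face, so the
#' effective counting depth shrinks from `D + T` to
#' `T + 2*sqrt((D/2)^2 - (h/2)^2)`.
#'
#' @param n_app apparent (counted) number of profiles.
#' @param A tuft cross-section area, um^2. Must be positive.
#' @param D caliper diameter of the counted nuclei, um.
#' @param T section thickness, um.
#' @param min_detectable minimum detectable profile diameter `h`, um.
#' @return Density in objects per `10^6` um^3.
#' @export
nuclear_density <- function(n_app, A, D, T, min_detectable = 0) {
  if (any(!is.finite(A)) || any(A <= 0))
    stop("podoquant_zero_area: A must be positive")
  if (any(n_app < 0)) stop("podoquant_bad_count: n_app must be non-negative")
  h <- min_detectable
  if (any(h < 0) || any(h >= D))
    stop("podoquant_bad_detection_limit: need 0 <= min_detectable < D")
  depth <- T + 2 * sqrt((D / 2)^2 - (h / 2)^2)
  if (any(depth <= 0))
    stop("podoquant_bad_thickness: counting depth must be positive")
  (n_app / A) / depth * 1e6
}

#' Glomerular tuft volume from its cross-section area
#'
#' Weibel-Gomez estimator under the assumption that tufts are spheres:
#' `V = (beta / k) * A^(3/2)` with shape coefficient `beta = 1.38`
#' (sphere) and size-distribution coefficient `k = 1.01`.
#'
#' @param A tuft cross-section area, um^2 (non-negative).
#' @param beta shape coefficient (1.38 for spheres).
#' @param k size-distribution coefficient.
#' @return Estimated tuft volume, um^3.
#' @export
tuft_volume <- function(A, beta = 1.38, k = 1.01) {
  if (any(!is.finite(A)) || any(A < 0))
    stop("podoquant_bad_area: A must be non-negative")
  (beta / k) * A^1.5
}

#' Per-glomerulus podometric metrics
#'
#' Assembles the full estimator chain for every ROI: the apparent podocyte
#' count and mean profile diameter from classified nuclei, the caliper
#' diameter via [estimate_caliper_diameter()], volumetric density via
#' [nuclear_density()], tuft volume via [tuft_volume()], and the derived
#' podocytes-per-tuft and volume-per-podocyte figures.
#'
#' For a tuft with zero podocytes the density is 0 and the
#' diameter/volume-per-podocyte fields are `NA` (flagged missing, never
#' infinite).
#'
#' @param glomeruli a `GlomerulusSet` from [segment_glomeruli()].
#' @param nuclei classified nucleus records (after
#'   [classify_podocytes()]).
#' @param section_thickness slab thickness `T`, um.
#' @param beta,k Weibel-Gomez coefficients, see [tuft_volume()].
#' @param caliper_diameter optional fixed caliper diameter `D` (um) used
#'   for every tuft, e.g. a per-case pooled estimate; by default `D` is
#'   estimated per tuft from that tuft's podocyte profiles.
#' @param min_detectable minimum detectable profile diameter `h`, um
#'   (default 0: no truncation correction); see [nuclear_density()].
#' @return Data frame with one row per ROI: `roi_id`, `tuft_area_um2`,
#'   `glepp1_positive_fraction`, `n_podocytes`,
#'   `mean_profile_diameter_um`, `areal_density_per_um2`,
#'   `caliper_diameter_um`, `nuclear_density_per_1e6um3`,
#'   `tuft_volume_um3`, `podocytes_per_tuft`, `volume_per_podocyte_um3`.
#' @export
derive_metrics <- function(glomeruli, nuclei, section_thickness = 3,
                           beta = 1.38, k = 1.01, caliper_diameter = NULL,
                           min_detectable = 0) {
  stopifnot(inherits(glomeruli, "GlomerulusSet"))
  if (nrow(glomeruli$rois) == 0L)
    stop("podoquant_empty_roi: no glomeruli to derive metrics for")
  if (any(is.na(nuclei$is_podocyte)))
    stop("podoquant_unclassified: run classify_podocytes() first")
  T <- section_thickness
  out <- lapply(seq_len(nrow(glomeruli$rois)), function(i) {
    roi <- glomeruli$rois[i, ]
    pod <- nuclei[nuclei$roi_id == roi$roi_id & nuclei$is_podocyte, ,
                  drop = FALSE]
    n_app <- nrow(pod)
    A <- roi$tuft_area_um2
    V <- tuft_volume(A, beta, k)
    if (n_app == 0L) {
      dbar <- NA_real_; D <- NA_real_; nv <- 0
      vpp <- NA_real_; ppt <- 0
    } else {
      dbar <- mean(pod$apparent_profile_diameter_um)
      D <- if (is.null(caliper_diameter))
        estimate_caliper_diameter(dbar, T, min_detectable)
      else caliper_diameter
      nv <- nuclear_density(n_app, A, D, T, min_detectable)
      vpp <- 1e6 / nv
      ppt <- nv * V / 1e6
    }
    data.frame(roi_id = roi$roi_id, tuft_area_um2 = A,
               glepp1_positive_fraction = roi$glepp1_positive_fraction,
               n_podocytes = n_app, mean_profile_diameter_um = dbar,
               areal_density_per_um2 = n_app / A,
               caliper_diameter_um = D,
               nuclear_density_per_1e6um3 = nv,
               tuft_volume_um3 = V,
               podocytes_per_tuft = ppt,
               volume_per_podocyte_um3 = vpp)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Aggregate per-glomerulus metrics into a case summary
#'
#' Unweighted per-glomerulus means of every metric, plus a QC flag:
#' `qc_pass` is `TRUE` only when at least `min_glomeruli` tufts were
#' evaluated (default 6, the usual minimum for a podometric case).
#' A summary is produced even for failing cases, flagged not dropped.
#'
#' @param metrics data frame from [derive_metrics()].
#' @param min_glomeruli minimum tuft count for QC.
#' @param case_id identifier copied into the summary.
#' @return One-row data frame: `case_id`, `n_glomeruli`, `qc_pass`, and a
#'   `mean_*` column for each metric (missing values excluded from means).
#' @export
aggregate_case <- function(metrics, min_glomeruli = 6, case_id = NA) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0L)
    stop("podoquant_empty_metrics: no glomerulus metrics to aggregate")
  fields <- c("tuft_area_um2", "glepp1_positive_fraction", "n_podocytes",
              "mean_profile_diameter_um", "areal_density_per_um2",
              "caliper_diameter_um", "nuclear_density_per_1e6um3",
              "tuft_volume_um3", "podocytes_per_tuft",
              "volume_per_podocyte_um3")
  out <- data.frame(case_id = case_id, n_glomeruli = nrow(metrics),
                    qc_pass = nrow(metrics) >= min_glomeruli)
  for (f in fields) out[[paste0("mean_", f)]] <- mean(metrics[[f]], na.rm = TRUE)
  out
}
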