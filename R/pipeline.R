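#' Assemble a run configuration
#'
#' Gathers every knob of the quantification pipeline with its default.
#' Values loaded from a YAML file override these defaults (see
#' [load_run_config()]); explicit arguments override both.
#'
#' @param input a directory containing multi-channel TIFFs (one per
#'   case) or a character vector of TIFF paths.
#' @param output_dir directory for all outputs of the run.
#' @param channel_roles named vector mapping roles to 1-based pages.
#' @param pixel_size um per pixel.
#' @param section_thickness slab thickness `T`, um.
#' @param bit_depth intensity maximum.
#' @param glepp1_threshold,dna_threshold segmentation thresholds.
#' @param min_area,closing_radius glomerulus segmentation parameters
#'   (um^2, um); see [segment_glomeruli()].
#' @param min_nucleus_area,split_touching nucleus segmentation
#'   parameters; see [segment_nuclei()].
#' @param yap_threshold,tle4_threshold classification thresholds; see
#'   [threshold_config()].
#' @param beta,k Weibel-Gomez coefficients.
#' @param min_detectable minimum detectable profile diameter, um; see
#'   [nuclear_density()].
#' @param min_glomeruli QC minimum tufts per case.
#' @param seed recorded in outputs; the quantification itself is
#'   deterministic.
#' @return Object of class `RunConfig` (a list).
#' @export
run_config <- function(input, output_dir,
                       channel_roles = c(GLEPP1 = 1, TLE4 = 2, YAP = 3, DNA = 4),
                       pixel_size = 0.5, section_thickness = 3,
                       bit_depth = 255,
                       glepp1_threshold = 100, dna_threshold = 100,
                       min_area = 2000, closing_radius = 5,
                       min_nucleus_area = 10, split_touching = FALSE,
                       yap_threshold = 75, tle4_threshold = 115,
                       beta = 1.38, k = 1.01, min_detectable = 0,
                       min_glomeruli = 6, seed = 1) {
  structure(as.list(environment()), class = "RunConfig")
}

#' Load a run configuration from a YAML file
#'
#' Flat key-value YAML; keys are the arguments of [run_config()].
#' `channel_roles` is given as a mapping of role name to page index.
#'
#' @param path YAML file.
#' @param ... overrides applied after the file.
#' @return A `RunConfig`.
#' @export
load_run_config <- function(path, ...) {
  if (!file.exists(path))
    stop("podoquant_missing_file: no such config: ", path)
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$channel_roles))
    vals$channel_roles <- unlist(vals$channel_roles)
  vals <- utils::modifyList(vals, list(...))
  do.call(run_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("podoquant_stage_failure [", name, "]: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full tissue quantification pipeline
#'
#' Fixed stage order per image: segment glomeruli from GLEPP1, segment
#' nuclei within ROIs, classify podocytes and nuclear YAP, derive
#' podometric metrics, compute per-glomerulus YAP ratios, aggregate each
#' case, and write all tables plus a run log to the output directory.
#' Identical inputs and configuration give byte-identical CSVs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list of the output tables: `glomeruli`, `nuclei`,
#'   `yap`, `cases`.
#' @export
run_quantify <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  paths <- config$input
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
  paths <- sort(paths)
  if (length(paths) == 0L)
    stop("podoquant_empty_input: no TIFF images to process")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  # hash covers the analysis parameters only, not run-local paths
  params <- unclass(config)
  params$input <- NULL; params$output_dir <- NULL
  param_json <- jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA)
  thr <- threshold_config(config$yap_threshold, config$tle4_threshold,
                          bit_depth = config$bit_depth)
  all_glom <- list(); all_nuc <- list(); all_yap <- list(); all_case <- list()
  log_lines <- c(sprintf("podoquant %s", as.character(packageVersion("podoquant"))),
                 sprintf("seed: %s", config$seed),
                 sprintf("config_hash: %s",
                         substr(digest_string(as.character(param_json)), 1, 16)))
  for (p in paths) {
    case_id <- sub("\\.tiff?$", "", basename(p), ignore.case = TRUE)
    img <- stage(paste0("load:", case_id),
                 load_multichannel_image(p, config$channel_roles,
                                         config$pixel_size,
                                         config$section_thickness,
                                         config$bit_depth))
    glom <- stage(paste0("segment_glomeruli:", case_id),
                  segment_glomeruli(img, config$glepp1_threshold,
                                    config$min_area, config$closing_radius))
    if (nrow(glom$rois) == 0L) {
      log_lines <- c(log_lines, sprintf("%s: 0 glomeruli, skipped", case_id))
      next
    }
    nuc <- stage(paste0("segment_nuclei:", case_id),
                 segment_nuclei(img, glom, config$dna_threshold,
                                config$min_nucleus_area,
                                config$split_touching))
    nuc <- stage(paste0("classify:", case_id), {
      n <- classify_podocytes(nuc, thr)
      if ("YAP" %in% names(img$channel_roles)) classify_nuclear_yap(n, thr)
      else n
    })
    met <- stage(paste0("podometry:", case_id),
                 derive_metrics(glom, nuc, config$section_thickness,
                                config$beta, config$k,
                                min_detectable = config$min_detectable))
    yap <- if ("YAP" %in% names(img$channel_roles))
      stage(paste0("yap:", case_id), glomerular_yap_ratio(nuc)) else NULL
    summ <- stage(paste0("aggregate:", case_id),
                  aggregate_case(met, config$min_glomeruli, case_id))
    if (!is.null(yap))
      summ$mean_nuclear_yap_ratio <- mean(yap$nuclear_yap_ratio, na.rm = TRUE)
    met$case_id <- case_id; nuc$case_id <- case_id
    if (!is.null(yap)) yap$case_id <- case_id
    all_glom[[case_id]] <- met; all_nuc[[case_id]] <- nuc
    all_yap[[case_id]] <- yap; all_case[[case_id]] <- summ
    log_lines <- c(log_lines,
                   sprintf("%s: %d glomeruli, %d nuclei", case_id,
                           nrow(met), nrow(nuc)))
  }
  if (length(all_case) == 0L)
    stop("podoquant_empty_input: no case produced any glomerulus")
  out <- list(glomeruli = do.call(rbind, unname(all_glom)),
              nuclei = do.call(rbind, unname(all_nuc)),
              yap = if (length(Filter(Negate(is.null), all_yap)))
                do.call(rbind, unname(Filter(Negate(is.null), all_yap)))
                else NULL,
              cases = do.call(rbind, unname(all_case)))
  od <- config$output_dir
  write_metrics_table(out$glomeruli, file.path(od, "glomeruli.csv"))
  write_metrics_table(out$nuclei, file.path(od, "nuclei.csv"))
  if (!is.null(out$yap))
    write_metrics_table(out$yap, file.path(od, "yap_ratios.csv"))
  write_metrics_table(out$cases, file.path(od, "case_summaries.csv"))
  writeLines(as.character(cfg_json), file.path(od, "config.json"))
  writeLines(log_lines, file.path(od, "run_log.txt"))
  invisible(out)
}

# md5 of a string via a temp file (tools ships with base R)
digest_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

#' Run the grade-stratified cohort report
#'
#' Joins per-case summaries with clinical metadata and emits the
#' stratified report of [grade_stratified_report()]. Cases missing from
#' the metadata (or without a grade) are listed in a warning and
#' excluded; the run continues with the matched cases.
#'
#' @param cases per-case summary data frame (e.g. from [run_quantify()]).
#' @param metadata clinical metadata from [read_case_metadata()].
#' @param output_dir optional directory: writes `report.csv` and a
#'   plain-text rendering `report.txt`.
#' @param variables see [grade_stratified_report()].
#' @return The report data frame, invisibly when written to disk.
#' @export
run_report <- function(cases, metadata, output_dir = NULL,
                       variables = NULL) {
  unmatched <- setdiff(cases$case_id, metadata$case_id)
  nograde <- metadata$case_id[is.na(metadata$grade_group)]
  bad <- union(unmatched, intersect(cases$case_id, nograde))
  if (length(bad))
    warning("podoquant_unmatched_cases: excluded ",
            paste(bad, collapse = ", "))
  keep <- setdiff(cases$case_id, bad)
  rep <- grade_stratified_report(cases[cases$case_id %in% keep, , drop = FALSE],
                                 metadata, variables)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_metrics_table(rep, file.path(output_dir, "report.csv"))
    txt <- c(sprintf("%-32s %18s %18s %8s", "variable", "grade I/II",
                     "grade III/IV", "p"),
             sprintf("%-32s %8.3f +/- %6.3f %8.3f +/- %6.3f %8.3g",
                     rep$variable, rep$mean_early, rep$sd_early,
                     rep$mean_late, rep$sd_late, rep$p_value))
    writeLines(txt, file.path(output_dir, "report.txt"))
    return(invisible(rep))
  }
  rep
}
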