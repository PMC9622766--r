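#' Pipeline run configuration
#'
#' Validated bag of every parameter an end-to-end quantification run needs.
#' Unknown keys are rejected so a mistyped option can never be silently
#' ignored; [run_pipeline()] writes the full configuration into the run
#' manifest, from which the run can be re-executed exactly.
#'
#' @param input_dir directory holding section images (`.png`/`.tif`) with
#'   sibling `.json` annotations, and optionally `sections.csv`
#'   (`section_id`, `group`, `condition`) describing the cohort design.
#' @param output_dir directory for all outputs (created if missing).
#' @param channel RGB channel whose excess is thresholded (default `"R"`).
#' @param marker stain label recorded on the masks.
#' @param threshold_method automatic thresholding method (only `"otsu"`).
#' @param bin_width_um depth bin width for profiles, micrometers.
#' @param junction_depth_um papillary/reticular junction depth; `NULL` takes
#'   it from each section's annotation.
#' @param stat_adjust multiplicity handling for the binwise comparison:
#'   `"none"` or `"BH"`.
#' @param seed integer seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed namespaces any downstream resampling).
#' @param verbose print per-file progress?
#' @return A validated `run_config` list.
#' @export
run_config <- function(input_dir, output_dir,
                       channel = "R", marker = "generic",
                       threshold_method = "otsu",
                       bin_width_um = 10, junction_depth_um = NULL,
                       stat_adjust = "none", seed = 1L, verbose = FALSE,
                       ...) {
  extra <- names(list(...))
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  cfg <- list(input_dir = input_dir, output_dir = output_dir,
              channel = match.arg(channel, c("R", "G", "B")),
              marker = marker,
              threshold_method = match.arg(threshold_method, "otsu"),
              bin_width_um = bin_width_um,
              junction_depth_um = junction_depth_um,
              stat_adjust = match.arg(stat_adjust, c("none", "BH")),
              seed = as.integer(seed), verbose = isTRUE(verbose))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  known <- c("input_dir", "output_dir", "channel", "marker",
             "threshold_method", "bin_width_um", "junction_depth_um",
             "stat_adjust", "seed", "verbose")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(cfg$bin_width_um) || cfg$bin_width_um <= 0)
    stop("`bin_width_um` must be a positive number", call. = FALSE)
  if (!is.null(cfg$junction_depth_um) && cfg$junction_depth_um <= 0)
    stop("`junction_depth_um` must be positive", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a JSON or key=value file
#'
#' @param path JSON file (keys as in [run_config()]) or a plain text file of
#'   `key=value` lines.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  cfg <- if (grepl("^\\s*\\{", paste(txt, collapse = ""))) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    kv <- strsplit(txt[nzchar(trimws(txt)) & !startsWith(trimws(txt), "#")],
                   "=", fixed = TRUE)
    vals <- lapply(kv, function(p) {
      v <- trimws(paste(p[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    })
    stats::setNames(vals, vapply(kv, function(p) trimws(p[1]), ""))
  }
  do.call(run_config, cfg)
}

#' Simulate a four-group synthetic cohort to disk
#'
#' Writes a complete synthetic dataset mirroring the four-group hind-limb
#' lymphedema design: for every animal, one control-limb and one
#' lymphedematous-limb section (PNG image + JSON annotation), where the LD
#' section's stain content is the group's fold multiple of the control's.
#' Also writes `sections.csv` (the cohort design), `ground_truth.csv` (exact
#' generator truth per section) and `paw_cohort.csv` (a caliper table from
#' [generate_paw_cohort()]).  Identical arguments always reproduce identical
#' files.
#'
#' @param out_dir output directory (created if missing).
#' @param group_sizes animals per group, default `c(8, 7, 11, 13)`.
#' @param area_folds per-group LD/control stain-area fold, default
#'   `c(2, 2, 2, 3)` (lymphatic-marker magnitudes).
#' @param control_blobs stain blobs per control section (default 120).
#' @param noise_sd pixel noise (default 5).
#' @param seed integer seed; per-section seeds are derived from it.
#' @param scene_height_px,scene_width_px,pixel_size_um scene geometry.
#' @return Invisibly, the ground-truth tibble.
#' @export
simulate_cohort <- function(out_dir,
                            group_sizes = c(8L, 7L, 11L, 13L),
                            area_folds = c(2, 2, 2, 3),
                            control_blobs = 120L,
                            noise_sd = 5,
                            seed = 1L,
                            scene_height_px = 340L,
                            scene_width_px = 400L,
                            pixel_size_um = 2) {
  stopifnot(length(group_sizes) == 4L, length(area_folds) == 4L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed) %% 100000L
  rows <- list(); design <- list()
  i <- 0L
  for (g in 1:4) for (a in seq_len(group_sizes[g])) {
    for (cond in c("control", "LD")) {
      i <- i + 1L
      is_ld <- cond == "LD"
      spec <- scene_spec(
        image_height_px = scene_height_px, image_width_px = scene_width_px,
        pixel_size_um = pixel_size_um,
        epidermis_thickness_um = 20, junction_depth_um = 350,
        blob_count = if (is_ld) round(control_blobs * area_folds[g])
                     else control_blobs,
        blob_radius_px = 1.5,
        depth_distribution = if (is_ld) depth_uniform(40, 600)
                             else depth_uniform(40, 320),
        noise_sd = noise_sd, follicle_count = 3,
        seed = seed + 7L * i)
      sec <- generate_skin_section(spec)
      id <- sprintf("g%d-m%02d-%s", g, a, cond)
      write_section_image(sec$image, file.path(out_dir, paste0(id, ".png")))
      rows[[i]] <- tibble::tibble(
        section_id = id, group = g, condition = cond,
        blob_count = spec$blob_count,
        total_stain_area_um2 = sec$truth$total_stain_area_um2,
        true_p90_um = sec$truth$true_p90_um)
      design[[i]] <- tibble::tibble(section_id = id, group = g,
                                    condition = cond)
    }
  }
  truth <- dplyr::bind_rows(rows)
  readr::write_csv(dplyr::bind_rows(design),
                   file.path(out_dir, "sections.csv"))
  readr::write_csv(truth, file.path(out_dir, "ground_truth.csv"))
  folds <- tibble::tibble(group = 1:4,
                          day = 40L,
                          fold = c(1.1, 1.1, 2.5, 3))
  readr::write_csv(generate_paw_cohort(group_sizes, folds, noise_sd = 0.05,
                                       seed = seed + 1L),
                   file.path(out_dir, "paw_cohort.csv"))
  invisible(truth)
}

#' Run the full quantification pipeline over a directory of sections
#'
#' For every annotated section image under `config$input_dir`: segment the
#' stain (excess color + automatic threshold), build the depth map and depth
#' profile, and write the stain mask (PNG) and per-bin profile rows.  When a
#' `sections.csv` cohort design is present, LD and control profiles are
#' compared per group (binwise Mann-Whitney) and the median integrated-area
#' fold change per group is reported.  All tables are CSV; a JSON manifest
#' records every parameter, the seed and every file processed, so re-running
#' the same configuration over the same inputs reproduces identical CSV
#' content.  A section whose annotation is missing or unreadable is recorded
#' as an error and skipped; the run continues and finishes with non-zero
#' `status`.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list: `status` (0 = clean), `summary` tibble,
#'   `errors` tibble, and the paths written.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  out <- config$output_dir
  dir.create(file.path(out, "masks"), recursive = TRUE, showWarnings = FALSE)
  imgs <- sort(list.files(config$input_dir, "\\.(png|tif|tiff)$",
                          full.names = TRUE))
  if (length(imgs) == 0L)
    stop("no section images found in ", config$input_dir, call. = FALSE)
  say <- function(...) if (config$verbose) message(sprintf(...))

  profiles <- list(); summaries <- list(); errors <- list()
  profile_objs <- list()
  for (path in imgs) {
    id <- sub("\\.[^.]+$", "", basename(path))
    res <- tryCatch({
      img <- read_section_image(path)
      stain <- segment_stain(img, channel = config$channel,
                             marker = config$marker,
                             threshold_method = config$threshold_method)
      dmap <- depth_map(img)
      prof <- depth_profile(stain, dmap, config$bin_width_um)
      junction <- config$junction_depth_um %||% img$junction_depth_um
      png::writePNG(matrix(as.numeric(stain$mask), nrow(stain$mask)),
                    file.path(out, "masks", paste0(id, "_mask.png")))
      list(stain = stain, prof = prof, junction = junction)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      say("ERROR %s: %s", id, conditionMessage(res))
      errors[[id]] <- tibble::tibble(section_id = id,
                                     error = conditionMessage(res))
      next
    }
    say("processed %s (%d stained px)", id, sum(res$stain$mask))
    profile_objs[[id]] <- res$prof
    profiles[[id]] <- dplyr::mutate(tidy(res$prof), section_id = id,
                                    .before = 1)
    comp <- if (!is.null(res$junction))
      split_compartments(res$prof, res$junction) else NULL
    summaries[[id]] <- tibble::tibble(
      section_id = id,
      threshold = res$stain$threshold_used,
      stained_px = sum(res$stain$mask),
      integrated_area_um2 = res$prof$integrated_area_um2,
      p90_um = res$prof$p90_um,
      papillary_area_um2 = if (is.null(comp)) NA_real_ else
        comp$papillary$integrated_area_um2,
      reticular_area_um2 = if (is.null(comp)) NA_real_ else
        comp$reticular$integrated_area_um2)
  }
  summary_tbl <- dplyr::bind_rows(summaries)
  readr::write_csv(dplyr::bind_rows(profiles),
                   file.path(out, "profiles.csv"))
  readr::write_csv(summary_tbl, file.path(out, "summary.csv"))

  design_path <- file.path(config$input_dir, "sections.csv")
  if (file.exists(design_path) && nrow(summary_tbl) > 0) {
    design <- readr::read_csv(design_path, show_col_types = FALSE)
    joined <- dplyr::inner_join(summary_tbl, design, by = "section_id")
    folds <- joined |>
      dplyr::group_by(.data$group, .data$condition) |>
      dplyr::summarise(median_area = stats::median(.data$integrated_area_um2),
                       .groups = "drop") |>
      tidyr::pivot_wider(names_from = "condition",
                         values_from = "median_area") |>
      dplyr::mutate(fold_change = .data$LD / .data$control)
    readr::write_csv(folds, file.path(out, "stats_folds.csv"))
    binwise <- list()
    for (g in sort(unique(joined$group))) {
      ids_ld <- joined$section_id[joined$group == g &
                                    joined$condition == "LD"]
      ids_ct <- joined$section_id[joined$group == g &
                                    joined$condition == "control"]
      if (length(ids_ld) >= 3 && length(ids_ct) >= 3) {
        cmpr <- compare_profiles_pointwise(
          profile_objs[ids_ld], profile_objs[ids_ct],
          adjust = config$stat_adjust)
        binwise[[as.character(g)]] <-
          dplyr::mutate(tidy(cmpr), group = g, .before = 1)
      }
    }
    if (length(binwise))
      readr::write_csv(dplyr::bind_rows(binwise),
                       file.path(out, "stats_binwise.csv"))
  }

  errors_tbl <- dplyr::bind_rows(errors)
  if (nrow(errors_tbl))
    readr::write_csv(errors_tbl, file.path(out, "errors.csv"))
  manifest <- list(
    package = "dermquant",
    version = as.character(utils::packageVersion("dermquant")),
    config = unclass(config),
    n_sections = length(imgs),
    processed = setdiff(sub("\\.[^.]+$", "", basename(imgs)),
                        if (nrow(errors_tbl)) errors_tbl$section_id
                        else character(0)),
    errors = if (nrow(errors_tbl)) errors_tbl$section_id else character(0))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(status = as.integer(nrow(errors_tbl) > 0),
                 summary = summary_tbl, errors = errors_tbl,
                 output_dir = out))
}
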