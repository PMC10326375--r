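#' Batch-process a directory of fields of view
#'
#' Applies one analysis mode to every matched input file independently,
#' aggregates per-FOV tables, and writes a machine-readable run manifest
#' (parameters, seed, and per-file status). A failing FOV is logged and
#' skipped, not fatal. Reruns with the same configuration and seed give
#' identical outputs.
#'
#' @param config A named list (or path to a YAML file) with fields:
#'   `mode` (`"count"`, `"influx"`, or `"cluster"`), `input` (glob pattern of
#'   input files), `output_dir`, `seed`, and an optional per-mode parameter
#'   block `params`. For `influx`, `input` matches the ionomycin stacks and
#'   `suffixes` (default `c(blank = "_blank", sample = "_sample", iono =
#'   "_iono")`) derive the sibling files.
#' @return A tibble summary, one row per input FOV (with `status`); per-mode
#'   result tables and `manifest.json` are written to `output_dir`.
#' @export
run_batch <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  mode <- match.arg(config$mode, c("count", "influx", "cluster"))
  if (is.null(config$input)) abort("`config$input` (glob) is required.")
  files <- Sys.glob(config$input)
  if (mode == "influx") {
    sfx <- config$suffixes %||% c(blank = "_blank", sample = "_sample", iono = "_iono")
    files <- files[grepl(sfx[["iono"]], basename(files), fixed = TRUE)]
  }
  if (!length(files)) {
    abort(sprintf("No inputs matched glob: %s", config$input))
  }
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prm <- config$params %||% list()

  per_file <- vector("list", length(files))
  detail <- vector("list", length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    res <- tryCatch({
      if (mode == "count") {
        dp <- do.call(detection_params, prm)
        parts <- detect_spots(read_image_stack(f), dp)
        detail[[i]] <- dplyr::mutate(as_tibble(parts), file = basename(f))
        tibble(file = basename(f), status = "ok",
               count = attr(parts, "n_particles"),
               median_intensity = glance(parts)$median_intensity)
      } else if (mode == "influx") {
        sfx <- config$suffixes %||% c(blank = "_blank", sample = "_sample", iono = "_iono")
        fb <- sub(sfx[["iono"]], sfx[["blank"]], f, fixed = TRUE)
        fs <- sub(sfx[["iono"]], sfx[["sample"]], f, fixed = TRUE)
        rec <- influx_fov(read_image_stack(fb), read_image_stack(fs),
                          read_image_stack(f),
                          threshold = prm$threshold %||% 100)
        detail[[i]] <- dplyr::mutate(as_tibble(rec), file = basename(f))
        g <- glance(rec)
        tibble(file = basename(f), status = "ok",
               n_liposomes = g$n_liposomes,
               median_influx_percent = g$median_influx_percent)
      } else {
        locs <- read_localizations(f, dialect = prm$dialect %||% "auto",
                                   pixel_nm = prm$pixel_nm %||% 100)
        cl <- cluster_localizations(
          locs, eps = prm$eps %||% 60, min_pts = prm$min_pts %||% 5L,
          render_pixel_nm = prm$render_pixel_nm %||% 20
        )
        detail[[i]] <- dplyr::mutate(as_tibble(cl), file = basename(f))
        g <- glance(cl)
        tibble(file = basename(f), status = "ok",
               n_clusters = g$n_clusters, median_length_nm = g$median_length_nm)
      }
    }, error = function(e) {
      tibble(file = basename(f), status = paste0("failed: ", conditionMessage(e)))
    })
    per_file[[i]] <- res
  }
  summary <- dplyr::bind_rows(per_file)
  details <- dplyr::bind_rows(detail)
  readr::write_csv(summary, file.path(out_dir, paste0(mode, "_summary.csv")))
  if (nrow(details)) {
    readr::write_csv(details, file.path(out_dir, paste0(mode, "_results.csv")))
  }
  manifest <- list(
    mode = mode, input = config$input, seed = config$seed,
    params = prm,
    files = stats::setNames(as.list(summary$status), summary$file),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  summary
}

#' Validate spot counting on simulated ground truth
#'
#' For every combination of `snr` and `n_dots`, simulates `n_fov` fields of
#' view, detects spots, and reports the mean counting accuracy against the
#' prominence-based ground-truth count — the desk-scale machine behind the
#' counting-accuracy validation curves.
#'
#' @param snr Vector of signal-to-noise ratios (dot peak mean over baseline
#'   mean).
#' @param n_dots Vector of dot counts per FOV.
#' @param n_fov Fields of view per condition (default 9).
#' @param params Detection parameters ([detection_params()]).
#' @param sim Base simulation parameters ([dl_sim_params()]); `snr`/`n_dots`
#'   and per-FOV seeds override its fields.
#' @param seed Global seed; per-FOV seeds are derived from it.
#' @return Tibble with one row per condition: `snr`, `n_dots`,
#'   `mean_accuracy`, `sd_accuracy`.
#' @export
validate_counting <- function(snr = c(1, 1.5, 2, 4), n_dots = 300L,
                              n_fov = 9L, params = detection_params(),
                              sim = dl_sim_params(), seed = 1L) {
  grid <- tidyr::expand_grid(snr = snr, n_dots = as.integer(n_dots))
  purrr::pmap_dfr(grid, function(snr, n_dots) {
    acc <- purrr::map_dbl(seq_len(n_fov), function(i) {
      p <- dl_sim_params(
        image_size = sim$image_size, n_dots = n_dots,
        dot_diameter_range = sim$dot_diameter_range,
        peak_sd = sim$peak_sd,
        baseline_mean = sim$baseline_mean, baseline_sd = sim$baseline_sd,
        illumination = sim$illumination,
        gaussian_mask = sim$gaussian_mask,
        snr = snr,
        seed = derive_seed(seed, i + round(1000 * snr) * 17L + n_dots * 131L)
      )
      fov <- simulate_dl(p)
      truth <- attr(fov$truth, "true_count")
      measured <- attr(detect_spots(fov$noisy, params), "n_particles")
      counting_accuracy(measured, truth)
    })
    tibble(
      snr = snr, n_dots = n_dots,
      mean_accuracy = mean(acc), sd_accuracy = sd(acc)
    )
  })
}
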