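#' Run configuration for the simulate / quantify / analyze pipeline
#'
#' A single serializable record drives all three stages; a run is fully
#' reproduced by its configuration (which embeds the master seed). The
#' master seed fans out to per-stage child seeds by a fixed affine rule
#' (`seed * 101 + stage offset`, reduced modulo 2^31 - 1) so each stage is
#' independently reproducible.
#'
#' @param seed master integer seed.
#' @param out_dir output directory.
#' @param n_eyes cohort size.
#' @param n_images how many eyes additionally receive a synthetic
#'   angiogram + ROI + ground-truth sidecar (0 = cohort table only).
#' @param paired if `TRUE`, image-derived metrics replace the sampled
#'   metrics for imaged eyes (full image-to-statistics integration).
#' @param pixel_scale mm per pixel of synthetic images.
#' @param vessel_width_px rasterized vessel width.
#' @param binarize_method,fd_substrate,area_source,bridge_px,enhance
#'   forwarded to [quantify()].
#' @param alpha,weights,va_outcome,count_model,holm forwarded to
#'   [analysis_config()].
#' @param cohort_params `mnv_cohort_params`; defaults to the calibrated set.
#' @param growth `mnv_growth_params` for synthetic trees.
#' @param noise `mnv_noise_params` for synthetic angiograms.
#' @return list of class `mnv_run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("mnvrun"),
                       n_eyes = NULL, n_images = 0L, paired = FALSE,
                       pixel_scale = 0.012, vessel_width_px = 3L,
                       binarize_method = "otsu", fd_substrate = "skeleton",
                       area_source = "roi", bridge_px = 0L, enhance = FALSE,
                       alpha = 0.05, weights = "fence",
                       va_outcome = "change", count_model = "linear",
                       holm = FALSE,
                       cohort_params = default_cohort_params(),
                       growth = growth_params(),
                       noise = noise_params()) {
  if (!is.null(n_eyes)) {
    cohort_params$n_eyes <- as.integer(n_eyes)
  }
  structure(
    list(
      seed = as.integer(seed), out_dir = out_dir,
      n_images = as.integer(n_images), paired = isTRUE(paired),
      pixel_scale = pixel_scale, vessel_width_px = vessel_width_px,
      binarize_method = binarize_method, fd_substrate = fd_substrate,
      area_source = area_source, bridge_px = bridge_px, enhance = enhance,
      alpha = alpha, weights = weights, va_outcome = va_outcome,
      count_model = count_model, holm = holm,
      cohort_params = cohort_params, growth = growth, noise = noise
    ),
    class = "mnv_run_config"
  )
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; the nested
#' `cohort_params`, `growth`, and `noise` blocks mirror
#' [cohort_params()], [growth_params()], and [noise_params()]. Keys given
#' in `overrides` (e.g. parsed command-line flags) take precedence over
#' file values.
#'
#' @param path YAML file.
#' @param overrides named list of scalar overrides.
#' @return `mnv_run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  nested <- list(
    cohort_params = cohort_params, growth = growth_params,
    noise = noise_params
  )
  args <- raw
  for (nm in names(nested)) {
    if (!is.null(raw[[nm]])) args[[nm]] <- do.call(nested[[nm]], raw[[nm]])
  }
  do.call(run_config, args)
}

child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 101 + offset) %% (2^31 - 1))
}

#' Simulate stage: cohort table, images, and ground truth
#'
#' Writes `cohort.csv`, the resolved configuration (`config.yaml`), a run
#' log, and -- for the first `n_images` eyes -- a 16-bit TIFF angiogram, an
#' 8-bit PNG ROI mask, and a JSON ground-truth sidecar each. In paired
#' mode the imaged eyes' table metrics are replaced by the metrics
#' measured from their own synthetic image, so the cohort and the images
#' are mutually consistent.
#'
#' @param config `mnv_run_config`.
#' @return invisible manifest: list with `cohort_path`, `image_paths`,
#'   `roi_paths`, `truth_paths`, `cohort`.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "mnv_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir)) {
    stop("cannot create output directory: ", config$out_dir, call. = FALSE)
  }
  t0 <- Sys.time()
  cohort <- generate_cohort(config$cohort_params,
                            seed = child_seed(config$seed, 1L))
  n_img <- min(config$n_images, nrow(cohort))
  image_paths <- roi_paths <- truth_paths <- character(0)
  if (n_img > 0L) {
    for (i in seq_len(n_img)) {
      s <- child_seed(config$seed, 100L + i)
      tree <- generate_vessel_tree(s, config$growth)
      tree <- scale_tree_to_length(tree, cohort$suml_mm[i])
      mask <- rasterize_network(tree, pixel_scale = config$pixel_scale,
                                vessel_width_px = config$vessel_width_px)
      img <- synthesize_angiogram(mask, config$noise, seed = s + 1L,
                                  pixel_scale = config$pixel_scale)
      roi <- make_roi_from_mask(mask, dilate_px = 6L)
      eye <- cohort$eye_id[i]
      ip <- file.path(config$out_dir, paste0(eye, ".tiff"))
      rp <- file.path(config$out_dir, paste0(eye, "_roi.png"))
      tp <- file.path(config$out_dir, paste0(eye, "_truth.json"))
      write_angiogram(img, ip)
      png::writePNG(roi * 1, rp)
      write_tree_json(tree, tp)
      image_paths <- c(image_paths, ip)
      roi_paths <- c(roi_paths, rp)
      truth_paths <- c(truth_paths, tp)
      if (config$paired) {
        met <- quantify(
          img, roi, pixel_scale = config$pixel_scale,
          binarize_method = config$binarize_method,
          enhance = config$enhance, fd_substrate = config$fd_substrate,
          area_source = config$area_source, bridge_px = config$bridge_px
        )
        cohort$area_mm2[i] <- met$area_mm2
        cohort$suml_mm[i] <- met$suml_mm
        cohort$fd[i] <- met$fd
        cohort$flow_density_pct[i] <- met$flow_density_pct
      }
    }
  }
  cohort_path <- file.path(config$out_dir, "cohort.csv")
  write_cohort(cohort, cohort_path)
  write_resolved_config(config)
  log_run(config, "simulate", t0,
          sprintf("%d eyes, %d images", nrow(cohort), n_img))
  invisible(list(
    cohort_path = cohort_path, image_paths = image_paths,
    roi_paths = roi_paths, truth_paths = truth_paths, cohort = cohort
  ))
}

# Delineated-membrane ROI surrogate: dilate the vessel mask and fill holes,
# giving a compact region around the network like a manual outline would.
make_roi_from_mask <- function(mask, dilate_px = 6L) {
  brush <- EBImage::makeBrush(2L * dilate_px + 1L, "disc")
  roi <- EBImage::dilate(mask_matrix(mask) * 1, brush)
  roi <- EBImage::fillHull(roi)
  roi > 0.5
}

#' Quantify stage: per-eye metrics from images
#'
#' Reads every `<eye>.tiff` / `<eye>_roi.png` pair in `config$out_dir`,
#' runs [quantify()], and writes `metrics.csv` keyed by `eye_id`.
#' Per-eye failures (missing ROI, unreadable file, degenerate region) are
#' recorded in the `error` column and the run continues.
#'
#' @param config `mnv_run_config`.
#' @return invisible data.frame of metrics (one row per image, `error`
#'   column `NA` on success).
#' @export
cmd_quantify <- function(config) {
  stopifnot(inherits(config, "mnv_run_config"))
  t0 <- Sys.time()
  imgs <- list.files(config$out_dir, pattern = "\\.tiff?$",
                     full.names = TRUE)
  if (length(imgs) == 0L) {
    stop("no images found in ", config$out_dir, call. = FALSE)
  }
  rows <- lapply(imgs, function(ip) {
    eye <- sub("\\.tiff?$", "", basename(ip))
    out <- data.frame(
      eye_id = eye, area_mm2 = NA_real_, suml_mm = NA_real_,
      fd = NA_real_, flow_density_pct = NA_real_,
      error = NA_character_, stringsAsFactors = FALSE
    )
    res <- tryCatch({
      img <- read_angiogram(ip, pixel_scale = config$pixel_scale)
      rp <- file.path(config$out_dir, paste0(eye, "_roi.png"))
      if (!file.exists(rp)) stop("missing ROI for ", eye)
      roi <- read_roi(rp, dim(img$intensity))
      quantify(
        img, roi,
        binarize_method = config$binarize_method,
        enhance = config$enhance, fd_substrate = config$fd_substrate,
        area_source = config$area_source, bridge_px = config$bridge_px
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error <- conditionMessage(res)
    } else {
      out$area_mm2 <- res$area_mm2
      out$suml_mm <- res$suml_mm
      out$fd <- res$fd
      out$flow_density_pct <- res$flow_density_pct
    }
    out
  })
  metrics <- do.call(rbind, rows)
  utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  log_run(config, "quantify", t0,
          sprintf("%d images, %d failures", nrow(metrics),
                  sum(!is.na(metrics$error))))
  invisible(metrics)
}

#' Analyze stage: weighted regression report from a cohort CSV
#'
#' @param config `mnv_run_config`.
#' @param cohort_path cohort CSV; defaults to the one written by
#'   [cmd_simulate()] in `config$out_dir`.
#' @return invisible `mnv_analysis_report` (also written as `report.json`
#'   and `report.csv`).
#' @export
cmd_analyze <- function(config,
                        cohort_path = file.path(config$out_dir,
                                                "cohort.csv")) {
  stopifnot(inherits(config, "mnv_run_config"))
  t0 <- Sys.time()
  cohort <- read_cohort(cohort_path)
  report <- analyze_cohort(cohort, analysis_config(
    alpha = config$alpha, weights = config$weights,
    va_outcome = config$va_outcome, count_model = config$count_model,
    holm = config$holm
  ))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results(report, file.path(config$out_dir, "report.json"),
                csv_path = file.path(config$out_dir, "report.csv"))
  log_run(config, "analyze", t0,
          sprintf("%d models, %d failed", length(report$models),
                  sum(vapply(report$models, function(m) m$failed,
                             logical(1L)))))
  invisible(report)
}

#' Run simulate, quantify (if images were produced), and analyze
#'
#' @param config `mnv_run_config`.
#' @return invisible list with the simulate manifest, the metrics table
#'   (or `NULL`), and the analysis report.
#' @export
run_pipeline <- function(config = run_config()) {
  sim <- cmd_simulate(config)
  metrics <- if (length(sim$image_paths)) cmd_quantify(config) else NULL
  report <- cmd_analyze(config, sim$cohort_path)
  invisible(list(simulate = sim, metrics = metrics, report = report))
}

write_resolved_config <- function(config) {
  plain <- lapply(unclass(config), function(x) {
    if (inherits(x, "mnv_cohort_params")) {
      # store the user-facing knobs, not the derived calibration values
      unclass(x)[c("n_eyes", "area_mean", "area_sd", "suml_mean", "suml_sd",
                   "fd_mean", "fd_sd", "flow_mean", "flow_sd", "type_probs",
                   "ivi_mean", "ivi_sd", "beta_area", "beta_suml",
                   "beta_fd", "beta_flow", "log_cor", "bcva_mean",
                   "bcva_sd", "bcva3_sd", "va_change_mean")]
    } else if (inherits(x, c("mnv_growth_params", "mnv_noise_params"))) {
      unclass(x)
    } else x
  })
  yaml::write_yaml(plain, file.path(config$out_dir, "config.yaml"))
}

log_run <- function(config, stage, t0, detail) {
  line <- sprintf(
    "%s | stage=%s | seed=%d | R=%s | mnvmorph=%s | %.2fs | %s",
    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, config$seed,
    getRversion(),
    as.character(utils::packageVersion("mnvmorph")),
    as.numeric(difftime(Sys.time(), t0, units = "secs")), detail
  )
  cat(line, "\n", file = file.path(config$out_dir, "run.log"),
      append = TRUE, sep = "")
}
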