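#' En-face angiogram container
#'
#' A 2-D grid of non-negative 16-bit intensities plus an isotropic physical
#' pixel scale. The physical field width is `cols * pixel_scale`; the
#' default acquisition geometry resolves a 6 x 6 mm field into 500 x 500
#' samples (0.012 mm/pixel). The scale is always supplied by the caller --
#' it is never inferred from file metadata, because exported device images
#' do not carry a trustworthy grid spacing.
#'
#' @param intensity numeric matrix of intensities in 0..65535.
#' @param pixel_scale mm per pixel, > 0.
#' @param quality optional scalar image-quality score (acquisitions below 6
#'   are conventionally excluded from analysis).
#' @return object of class `mnv_angiogram`: list with `intensity`
#'   (integer matrix), `pixel_scale`, `field_mm`, `quality`.
#' @export
as_angiogram <- function(intensity, pixel_scale, quality = NA_real_) {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    stop("intensity must be a numeric matrix", call. = FALSE)
  }
  stopifnot(nrow(intensity) > 0, ncol(intensity) > 0, pixel_scale > 0)
  if (any(intensity < 0 | intensity > 65535)) {
    stop("intensities must lie in 0..65535", call. = FALSE)
  }
  storage.mode(intensity) <- "integer"
  structure(
    list(
      intensity = intensity, pixel_scale = pixel_scale,
      field_mm = ncol(intensity) * pixel_scale, quality = quality
    ),
    class = "mnv_angiogram"
  )
}

#' @export
print.mnv_angiogram <- function(x, ...) {
  cat(sprintf(
    "en-face angiogram: %d x %d px @ %.4g mm/px (field %.2f mm)\n",
    nrow(x$intensity), ncol(x$intensity), x$pixel_scale, x$field_mm
  ))
  invisible(x)
}

angiogram_matrix <- function(img) {
  if (inherits(img, "mnv_angiogram")) return(img$intensity + 0)
  if (is.matrix(img) && is.numeric(img)) return(img)
  stop("expected an mnv_angiogram or numeric matrix", call. = FALSE)
}

#' Read a grayscale angiogram from TIFF or PNG
#'
#' Integer intensities are preserved losslessly (16-bit TIFF/PNG map to
#' 0..65535, 8-bit to 0..255 scaled up to the 16-bit range). Multi-channel
#' (RGB) images are rejected: en-face angiograms are single-channel by
#' definition and silently collapsing channels would hide an acquisition
#' export mistake.
#'
#' @param path file path (`.tif`, `.tiff`, `.png`).
#' @param pixel_scale mm per pixel (required; see [as_angiogram()]).
#' @param quality optional quality score to attach.
#' @return `mnv_angiogram`.
#' @export
read_angiogram <- function(path, pixel_scale, quality = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 2L) round(a * 65535) else a
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(arr)) != 2L) {
    stop("expected a single-channel 2-D image, got ",
         paste(dim(arr), collapse = " x "), call. = FALSE)
  }
  as_angiogram(arr, pixel_scale = pixel_scale, quality = quality)
}

#' Write an angiogram as 16-bit grayscale TIFF (or 8-bit PNG)
#'
#' TIFF output preserves the full 16-bit intensity range losslessly and is
#' the pipeline's image format of record; PNG output quantizes to 8 bits
#' (the PNG writer available here is 8-bit) and is intended for masks and
#' quick previews.
#'
#' @param img `mnv_angiogram`.
#' @param path destination (`.tif`, `.tiff`, `.png`).
#' @return `path`, invisibly.
#' @export
write_angiogram <- function(img, path) {
  stopifnot(inherits(img, "mnv_angiogram"))
  ext <- tolower(tools::file_ext(path))
  grid01 <- img$intensity / 65535
  switch(ext,
    tif = , tiff = tiff::writeTIFF(grid01, path, bits.per.sample = 16L),
    png = png::writePNG(grid01, path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Read an MNV region of interest
#'
#' Accepts either a binary mask image (PNG, foreground > 0) or a polygon
#' stored as JSON: a list of `[row, col]` vertices in 0-based pixel
#' coordinates, rasterized on load by even-odd pixel-center containment
#' (see [rasterize_polygon()]). An empty ROI is returned with a warning and
#' flagged via the `empty` attribute rather than raising, so batch runs can
#' record the eye as failed downstream.
#'
#' @param path `.png` mask or `.json` polygon.
#' @param shape `c(rows, cols)` of the target image (required for
#'   polygons; checked against mask files).
#' @return logical matrix of class `mnv_roi` with attribute `empty`.
#' @export
read_roi <- function(path, shape) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) != 2L) {
        stop("ROI mask must be single-channel", call. = FALSE)
      }
      a > 0.5
    },
    json = {
      poly <- jsonlite::fromJSON(path)
      if (is.list(poly)) poly <- do.call(rbind, poly)
      rasterize_polygon(poly, shape)
    },
    stop("unsupported ROI format: .", ext, call. = FALSE)
  )
  if (!identical(dim(m), as.integer(shape))) {
    stop(sprintf(
      "ROI shape (%s) does not match image shape (%s)",
      paste(dim(m), collapse = " x "), paste(shape, collapse = " x ")
    ), call. = FALSE)
  }
  if (!any(m)) warning("ROI is empty")
  structure(m, class = c("mnv_roi", class(m)), empty = !any(m))
}

roi_matrix <- function(roi) {
  m <- unclass(roi)
  attr(m, "empty") <- NULL
  mask_matrix(m)
}

#' Rasterize a polygon by even-odd pixel-center containment
#'
#' A pixel belongs to the ROI when its center -- the integer lattice point
#' `(row, col)`, 0-based -- lies inside the polygon under the even-odd
#' (crossing-number) rule. Horizontal-edge and on-vertex degeneracies
#' follow the half-open convention of the crossing test; a degenerate
#' polygon with zero area yields an empty mask.
#'
#' @param vertices numeric matrix, one `[row, col]` vertex per row, 0-based
#'   pixel coordinates; the polygon closes implicitly.
#' @param shape `c(rows, cols)` of the target grid.
#' @return logical matrix.
#' @export
rasterize_polygon <- function(vertices, shape) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2L, length(shape) == 2L)
  nrp <- nrow(vertices)
  out <- matrix(FALSE, shape[1L], shape[2L])
  if (nrp < 3L) return(out)
  pr <- vertices[, 1L]; pc <- vertices[, 2L]
  # pixel centers at integer coordinates (0-based)
  ctr_r <- rep(0:(shape[1L] - 1L), times = shape[2L])
  ctr_c <- rep(0:(shape[2L] - 1L), each = shape[1L])
  inside <- logical(length(ctr_r))
  j <- nrp
  for (i in seq_len(nrp)) {
    crosses <- ((pr[i] > ctr_r) != (pr[j] > ctr_r))
    if (any(crosses)) {
      xint <- pc[j] + (ctr_r - pr[j]) * (pc[i] - pc[j]) / (pr[i] - pr[j])
      flip <- crosses & (ctr_c < xint)
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  out[] <- inside
  out
}

# ---- cohort tables ----------------------------------------------------------

cohort_schema <- c(
  eye_id = "character", mnv_type = "integer", area_mm2 = "numeric",
  suml_mm = "numeric", fd = "numeric", flow_density_pct = "numeric",
  bcva_baseline_logmar = "numeric", bcva_3y_logmar = "numeric",
  ivi_count_3y = "integer"
)

#' Validate a cohort table
#'
#' Checks the per-eye schema: all columns present, MNV type in {1, 2, 3},
#' non-negative metrics, finite logMAR values, and non-negative integer
#' injection counts. Errors name the offending column and rows.
#'
#' @param cohort data.frame.
#' @return the validated data.frame (typed), invisibly usable downstream.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(names(cohort_schema), names(cohort))
  if (length(missing_cols)) {
    stop("cohort table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_rows <- function(cond, what) {
    if (any(cond)) {
      stop(sprintf("invalid %s in row(s): %s", what,
                   paste(utils::head(which(cond), 10L), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad_rows(!cohort$mnv_type %in% c(1L, 2L, 3L), "mnv_type (must be 1, 2, or 3)")
  for (col in c("area_mm2", "suml_mm", "fd", "flow_density_pct")) {
    bad_rows(!is.finite(cohort[[col]]) | cohort[[col]] < 0,
             paste0(col, " (must be finite and >= 0)"))
  }
  bad_rows(!is.finite(cohort$bcva_baseline_logmar), "bcva_baseline_logmar")
  bad_rows(!is.finite(cohort$bcva_3y_logmar), "bcva_3y_logmar")
  ivi <- cohort$ivi_count_3y
  bad_rows(!is.finite(ivi) | ivi < 0 | ivi != round(ivi),
           "ivi_count_3y (must be a non-negative integer)")
  cohort$mnv_type <- as.integer(cohort$mnv_type)
  cohort$ivi_count_3y <- as.integer(cohort$ivi_count_3y)
  cohort
}

#' Read / write the per-eye cohort CSV
#'
#' Plain CSV with the columns of the cohort schema (`eye_id`, `mnv_type`,
#' `area_mm2`, `suml_mm`, `fd`, `flow_density_pct`,
#' `bcva_baseline_logmar`, `bcva_3y_logmar`, `ivi_count_3y`); validated on
#' read.
#'
#' @param path CSV file path.
#' @return `read_cohort`: validated data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' @rdname read_cohort
#' @param cohort data.frame to write.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- ground-truth sidecars --------------------------------------------------

#' Write / read the ground-truth sidecar of a synthetic tree
#'
#' JSON record with the segment polylines in mm, per-segment lengths, root
#' locations, total length, growth parameters, and seed; the machine-
#' readable ground truth accompanying each synthetic angiogram.
#'
#' @param tree `mnv_vessel_tree`.
#' @param path destination `.json`.
#' @return `write_tree_json`: `path` invisibly; `read_tree_json`: the
#'   reconstructed `mnv_vessel_tree`.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "mnv_vessel_tree"))
  payload <- list(
    segments = tree$segments,
    roots = tree$roots,
    total_length_mm = tree$total_length_mm,
    params = unclass(tree$params),
    seed = tree$seed
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(
    list(
      segments = as.data.frame(x$segments),
      roots = as.data.frame(x$roots),
      total_length_mm = x$total_length_mm,
      params = do.call(growth_params, x$params),
      seed = x$seed
    ),
    class = "mnv_vessel_tree"
  )
}

#' Write an analysis report to JSON (and optionally CSV)
#'
#' Serializes the per-model term table together with the fences and weight
#' summaries of each model.
#'
#' @param report `mnv_analysis_report` from [analyze_cohort()].
#' @param path destination `.json`.
#' @param csv_path optional destination for the flat term table.
#' @return `path`, invisibly.
#' @export
write_results <- function(report, path, csv_path = NULL) {
  stopifnot(inherits(report, "mnv_analysis_report"))
  payload <- list(
    alpha = report$alpha,
    config = report$config,
    table = report$table,
    models = lapply(report$models, function(m) {
      list(
        outcome = m$outcome, terms = m$terms,
        joint_p = m$joint_p, failed = m$failed, error = m$error,
        fences = lapply(m$fences, unclass),
        weight_summary = if (is.null(m$weights)) NULL else
          list(min = min(m$weights), mean = mean(m$weights),
               n_downweighted = sum(m$weights < 1))
      )
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  if (!is.null(csv_path)) {
    utils::write.csv(report$table, csv_path, row.names = FALSE)
  }
  invisible(path)
}
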