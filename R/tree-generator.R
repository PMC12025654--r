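#' Growth parameters for the stochastic vascular tree generator
#'
#' The synthetic MNV network grows by stochastic recursive branching: each
#' root emits one seed segment; in every later generation each active tip
#' either bifurcates (probability `branch_prob`) into two daughters
#' deflected by roughly +/- `branch_angle_deg`, or continues as a single
#' segment; every new segment direction receives Gaussian angular jitter
#' (`angle_sd_deg`) and a log-normal length with mean `length_mean_mm` and
#' coefficient of variation `length_cv`. This model was chosen over
#' L-system rewriting because segment lengths are explicit, which makes
#' ground-truth total length an exact bookkeeping identity. A higher
#' `branch_prob` produces denser, more space-filling networks and hence a
#' higher measured fractal dimension after rasterization -- the generator's
#' documented monotone knob.
#'
#' @param n_roots number of root locations.
#' @param generations number of growth generations (>= 1).
#' @param branch_prob per-tip bifurcation probability per generation, in
#'   \[0, 1\].
#' @param length_mean_mm mean segment length, mm.
#' @param length_cv coefficient of variation of segment lengths.
#' @param angle_sd_deg SD of the angular jitter, degrees.
#' @param branch_angle_deg mean half-angle between daughter branches.
#' @param field_mm physical field width (segments are clipped to the field
#'   at rasterization, not at growth).
#' @return validated list of class `mnv_growth_params`.
#' @export
growth_params <- function(n_roots = 1L, generations = 6L,
                          branch_prob = 0.85, length_mean_mm = 0.18,
                          length_cv = 0.35, angle_sd_deg = 12,
                          branch_angle_deg = 35, field_mm = 6) {
  stopifnot(
    n_roots >= 1, generations >= 1,
    branch_prob >= 0, branch_prob <= 1,
    length_mean_mm > 0, length_cv > 0,
    angle_sd_deg >= 0, branch_angle_deg >= 0, field_mm > 0
  )
  structure(
    list(
      n_roots = as.integer(n_roots), generations = as.integer(generations),
      branch_prob = branch_prob, length_mean_mm = length_mean_mm,
      length_cv = length_cv, angle_sd_deg = angle_sd_deg,
      branch_angle_deg = branch_angle_deg, field_mm = field_mm
    ),
    class = "mnv_growth_params"
  )
}

#' Grow a ground-truthed synthetic vascular network
#'
#' Runs the branching growth model of [growth_params()] from `n_roots`
#' roots placed near the field center. The returned object records every
#' segment in physical coordinates together with its exact length, so the
#' network's total length is the sum of its segment lengths by
#' construction; this is the ground truth against which rasterization and
#' skeleton-based measurement are validated. Identical `(seed, params)`
#' reproduce identical networks.
#'
#' @param seed integer RNG seed.
#' @param params `mnv_growth_params`.
#' @return object of class `mnv_vessel_tree`: list with `segments`
#'   (data.frame: `x0`, `y0`, `x1`, `y1`, `length_mm`, `generation`,
#'   `root`), `roots` (data.frame: `x`, `y`), `total_length_mm`, `params`,
#'   `seed`.
#' @export
generate_vessel_tree <- function(seed, params = growth_params()) {
  stopifnot(inherits(params, "mnv_growth_params"))
  set.seed(seed)
  deg2rad <- pi / 180
  sdlog2 <- log(1 + params$length_cv^2)
  meanlog <- log(params$length_mean_mm) - sdlog2 / 2
  sdlog <- sqrt(sdlog2)
  centre <- params$field_mm / 2
  # roots scattered in a small disc around the field centre
  r_r <- 0.1 * params$field_mm * sqrt(stats::runif(params$n_roots))
  r_t <- stats::runif(params$n_roots, 0, 2 * pi)
  roots <- data.frame(x = centre + r_r * cos(r_t), y = centre + r_r * sin(r_t))

  segs <- vector("list", 256L)
  n_seg <- 0L
  push_seg <- function(x0, y0, ang, gen, root_id) {
    len <- stats::rlnorm(1L, meanlog, sdlog)
    x1 <- x0 + len * cos(ang); y1 <- y0 + len * sin(ang)
    n_seg <<- n_seg + 1L
    if (n_seg > length(segs)) length(segs) <<- 2L * n_seg
    segs[[n_seg]] <<- c(x0, y0, x1, y1, len, gen, root_id)
    c(x1, y1, ang)
  }

  tips <- list()  # each: c(x, y, angle, root_id)
  for (k in seq_len(params$n_roots)) {
    ang0 <- stats::runif(1L, 0, 2 * pi)
    tip <- push_seg(roots$x[k], roots$y[k], ang0, 1L, k)
    tips[[length(tips) + 1L]] <- c(tip, k)
  }
  if (params$generations > 1L) {
    for (gen in 2:params$generations) {
      new_tips <- list()
      for (tp in tips) {
        x <- tp[1L]; y <- tp[2L]; ang <- tp[3L]; rt <- tp[4L]
        if (stats::runif(1L) < params$branch_prob) {
          for (sgn in c(-1, 1)) {
            a <- ang + sgn * params$branch_angle_deg * deg2rad +
              stats::rnorm(1L, 0, params$angle_sd_deg * deg2rad)
            nt <- push_seg(x, y, a, gen, rt)
            new_tips[[length(new_tips) + 1L]] <- c(nt, rt)
          }
        } else {
          a <- ang + stats::rnorm(1L, 0, params$angle_sd_deg * deg2rad)
          nt <- push_seg(x, y, a, gen, rt)
          new_tips[[length(new_tips) + 1L]] <- c(nt, rt)
        }
      }
      tips <- new_tips
    }
  }

  seg_mat <- do.call(rbind, segs[seq_len(n_seg)])
  segments <- data.frame(
    x0 = seg_mat[, 1L], y0 = seg_mat[, 2L],
    x1 = seg_mat[, 3L], y1 = seg_mat[, 4L],
    length_mm = seg_mat[, 5L],
    generation = as.integer(seg_mat[, 6L]),
    root = as.integer(seg_mat[, 7L])
  )
  structure(
    list(
      segments = segments, roots = roots,
      total_length_mm = sum(segments$length_mm),
      params = params, seed = seed
    ),
    class = "mnv_vessel_tree"
  )
}

#' @export
print.mnv_vessel_tree <- function(x, ...) {
  cat(sprintf(
    "synthetic vessel tree: %d segments from %d root(s), total length %.3f mm (seed %d)\n",
    nrow(x$segments), nrow(x$roots), x$total_length_mm, x$seed
  ))
  invisible(x)
}

#' Rescale a vessel tree to a target total length
#'
#' Scales all coordinates about the tree's root centroid so the total
#' ground-truth length equals `target_mm`. Used by the paired simulation
#' mode to tie image-derived metrics to sampled cohort values.
#'
#' @param tree `mnv_vessel_tree`.
#' @param target_mm desired total length, mm.
#' @return rescaled `mnv_vessel_tree`.
#' @export
scale_tree_to_length <- function(tree, target_mm) {
  stopifnot(inherits(tree, "mnv_vessel_tree"), target_mm > 0)
  f <- target_mm / tree$total_length_mm
  cx <- mean(tree$roots$x); cy <- mean(tree$roots$y)
  s <- tree$segments
  for (col in c("x0", "x1")) s[[col]] <- cx + (s[[col]] - cx) * f
  for (col in c("y0", "y1")) s[[col]] <- cy + (s[[col]] - cy) * f
  s$length_mm <- s$length_mm * f
  tree$segments <- s
  tree$total_length_mm <- sum(s$length_mm)
  tree
}

#' Rasterize a vessel network onto a pixel grid
#'
#' Draws every segment onto a binary grid at the given pixel scale by
#' dense sampling along the segment (step = `pixel_scale / 3`, endpoints
#' included), then optionally dilates to the requested vessel width with a
#' disc brush. Pixels are indexed 0-based, row-major, with pixel `(i, j)`
#' covering the physical square `[j, j+1) x [i, i+1)` in units of
#' `pixel_scale` (x maps to columns, y to rows). Segments falling outside
#' the field are clipped; an empty network yields an all-`FALSE` mask.
#'
#' @param tree `mnv_vessel_tree`.
#' @param pixel_scale mm per pixel; the default resolves a 6 mm field into
#'   500 samples.
#' @param vessel_width_px drawn vessel width in pixels (odd widths render
#'   symmetrically; width 1 marks the centerline only).
#' @param dims grid size `c(rows, cols)`; default derived from the field.
#' @return logical matrix of vessel pixels.
#' @export
rasterize_network <- function(tree, pixel_scale = 0.012,
                              vessel_width_px = 3L, dims = NULL) {
  stopifnot(inherits(tree, "mnv_vessel_tree"), pixel_scale > 0,
            vessel_width_px >= 1)
  if (is.null(dims)) {
    n <- round(tree$params$field_mm / pixel_scale)
    dims <- c(n, n)
  }
  mask <- matrix(FALSE, dims[1L], dims[2L])
  segs <- tree$segments
  if (nrow(segs) == 0L) return(mask)
  step <- pixel_scale / 3
  for (i in seq_len(nrow(segs))) {
    len <- segs$length_mm[i]
    nstep <- max(1L, ceiling(len / step))
    t <- seq(0, 1, length.out = nstep + 1L)
    xs <- segs$x0[i] + t * (segs$x1[i] - segs$x0[i])
    ys <- segs$y0[i] + t * (segs$y1[i] - segs$y0[i])
    cc <- floor(xs / pixel_scale) + 1L
    rr <- floor(ys / pixel_scale) + 1L
    ok <- rr >= 1L & rr <= dims[1L] & cc >= 1L & cc <= dims[2L]
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  w <- as.integer(vessel_width_px)
  if (w > 1L) {
    b <- if (w %% 2L == 0L) w + 1L else w
    brush <- EBImage::makeBrush(b, if (b >= 5L) "disc" else "box")
    mask <- EBImage::dilate(mask * 1, brush) > 0.5
  }
  mask
}
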