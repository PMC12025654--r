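test_that("binarization recovers a noiseless two-level image exactly", {
  truth <- matrix(FALSE, 64, 64); truth[20:44, 30:33] <- TRUE
  img <- synthesize_angiogram(truth, noise_params(speckle_cv = 0,
                                                  granularity_amp = 0))
  roi <- matrix(TRUE, 64, 64)
  mask <- binarize(img, roi)
  expect_equal(unclass(mask)[, ], truth, ignore_attr = TRUE)
})

test_that("binarization guards its degenerate inputs", {
  img <- as_angiogram(matrix(1000L, 32, 32), pixel_scale = 0.012)
  roi <- matrix(TRUE, 32, 32)
  expect_error(binarize(img, roi), "constant intensity")
  expect_error(binarize(img, matrix(FALSE, 32, 32)), "ROI is empty")
  # all-background ROI region (vessel outside the ROI): the speckle
  # histogram has no flow-class separation -> empty mask + warning
  truth <- matrix(FALSE, 64, 64); truth[5, 5:20] <- TRUE
  img2 <- synthesize_angiogram(truth, noise_params(), seed = 3)
  roi2 <- matrix(FALSE, 64, 64); roi2[40:60, 40:60] <- TRUE
  expect_warning(m2 <- binarize(img2, roi2), "flow signal")
  expect_equal(sum(m2), 0L)
})

test_that("binarization of a noisy synthetic eye overlaps ground truth (Dice >= 0.8)", {
  dice <- vapply(1:3, function(s) {
    tree <- generate_vessel_tree(s, growth_params())
    truth <- rasterize_network(tree, 0.012, 3)
    img <- synthesize_angiogram(truth, noise_params(), seed = s + 50)
    roi <- mnvmorph:::make_roi_from_mask(truth, 6L)
    mask <- binarize(img, roi, despeckle_px = 25, fill_holes_px = 30)
    2 * sum(mask & truth) / (sum(mask) + sum(truth))
  }, numeric(1))
  expect_true(all(dice >= 0.8))
})

test_that("thinning produces one-pixel midlines, preserves topology, is idempotent", {
  # wide bar reduces to a single straight midline (end erosion bounded by
  # the half-width at each end)
  bar <- matrix(FALSE, 40, 120); bar[18:22, 11:110] <- TRUE
  sk <- thin_mask(bar)
  px <- which(sk, arr.ind = TRUE)
  expect_equal(length(unique(px[, 1])), 1L)   # single row: straight midline
  expect_equal(unique(px[, 1]), 20)
  expect_gte(sum(sk), 100 - 2 * 3)
  expect_lte(sum(sk), 100)

  # idempotence on thin input
  expect_identical(thin_mask(sk), sk)
  line <- matrix(FALSE, 21, 21); line[11, 3:18] <- TRUE
  expect_identical(thin_mask(line), line)

  # topology: component count preserved on random blobs
  for (s in 1:3) {
    set.seed(s)
    blob <- matrix(runif(3600) < 0.55, 60, 60)
    skb <- thin_mask(blob)
    expect_equal(count_components_8(skb), count_components_8(blob))
  }

  expect_equal(sum(thin_mask(matrix(FALSE, 10, 10))), 0L)
})

test_that("the vessel graph matches analytic topologies and lengths", {
  # straight 101-pixel line: 2 endpoints, 1 edge, 100 axial steps = 1.2 mm
  line <- matrix(FALSE, 20, 120); line[10, 10:110] <- TRUE
  net <- build_network(line, pixel_scale = 0.012)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(sum(net$nodes$kind == "endpoint"), 2L)
  expect_equal(compute_suml(net), 1.2)

  # 101-pixel diagonal: 100 sqrt(2) steps
  dg <- matrix(FALSE, 120, 120)
  dg[cbind(6:106, 6:106)] <- TRUE
  expect_equal(compute_suml(build_network(dg, 0.012)), 100 * sqrt(2) * 0.012)

  # plus shape: one junction, four endpoints, four edges
  pl <- matrix(FALSE, 101, 101)
  pl[51, 1:101] <- TRUE; pl[1:101, 51] <- TRUE
  netp <- build_network(pl, 0.012)
  expect_equal(sum(netp$nodes$kind == "junction"), 1L)
  expect_equal(sum(netp$nodes$kind == "endpoint"), 4L)
  expect_equal(nrow(netp$edges), 4L)

  # thick plus thinned: same topology via junction clustering
  plt <- matrix(FALSE, 101, 101)
  plt[48:54, 11:91] <- TRUE; plt[11:91, 48:54] <- TRUE
  nett <- build_network(thin_mask(plt), 1)
  expect_equal(length(unique(nett$nodes$id[nett$nodes$kind == "junction"])), 1L)
  expect_equal(sum(nett$nodes$kind == "endpoint"), 4L)
  expect_equal(nrow(nett$edges), 4L)

  # empty skeleton -> empty network; sumL 0
  net0 <- build_network(matrix(FALSE, 10, 10), 0.012)
  expect_equal(nrow(net0$edges), 0L)
  expect_equal(compute_suml(net0), 0)

  # isolated cycle becomes a single self-edge
  ring <- matrix(FALSE, 20, 20)
  ring[5, 5:15] <- TRUE; ring[15, 5:15] <- TRUE
  ring[5:15, 5] <- TRUE; ring[5:15, 15] <- TRUE
  netr <- build_network(ring, 1)
  expect_equal(nrow(netr$edges), 1L)
  expect_equal(netr$edges$from, netr$edges$to)
  # geodesic with corner cutting: each interior right angle contributes
  # sqrt(2) instead of 2 steps
  expect_gt(netr$edges$n_steps, 37)
  expect_lte(netr$edges$n_steps, 40)
})

test_that("non-thin input is rejected by the network builder", {
  bar <- matrix(FALSE, 40, 120); bar[18:22, 11:110] <- TRUE
  expect_error(build_network(bar, 0.012), "not thin")
})

test_that("area and flow density follow their closed-form definitions", {
  expect_equal(compute_area(matrix(FALSE, 10, 10), 0.012), 0)
  m <- matrix(FALSE, 100, 100); m[1:10, 1:100] <- TRUE
  expect_equal(compute_area(m, 0.012), 1000 * 0.012^2)
  expect_equal(compute_area(matrix(TRUE, 500, 500), 0.012), 36)

  roi <- matrix(FALSE, 50, 50); roi[1:40, 1:25] <- TRUE  # 1000 px
  mask <- matrix(FALSE, 50, 50); mask[1:40, 1:25][seq_len(412)] <- TRUE
  expect_equal(compute_flow_density(mask, roi), 41.2)
  expect_equal(compute_flow_density(roi, roi), 100)
  expect_equal(compute_flow_density(matrix(FALSE, 50, 50), roi), 0)
  expect_error(compute_flow_density(mask, matrix(FALSE, 50, 50)), "empty ROI")
})

test_that("box-counting dimension matches closed-form sets", {
  line <- matrix(FALSE, 512, 512); line[256, ] <- TRUE
  expect_equal(as.numeric(compute_fd(line)), 1.0, tolerance = 0.05)
  square <- matrix(TRUE, 512, 512)
  expect_equal(as.numeric(compute_fd(square)), 2.0, tolerance = 0.05)
  carpet <- make_sierpinski(5L)
  expect_equal(as.numeric(compute_fd(carpet)), log(8) / log(3),
               tolerance = 0.05)
  # ladder is retained for inspection
  bc <- attr(compute_fd(carpet), "box_counts")
  expect_true(all(diff(bc$n_boxes) < 0))
  expect_equal(bc$s, 2^(1:5))
})

test_that("box counts equal the exhaustive count on small grids", {
  set.seed(33)
  for (i in 1:5) {
    m <- matrix(runif(144) < 0.4, 12, 12)
    if (!any(m)) m[5, 5] <- TRUE
    idx <- which(m, arr.ind = TRUE)
    rows <- idx[, 1] - min(idx[, 1])
    cols <- idx[, 2] - min(idx[, 2])
    for (s in c(1L, 2L, 3L, 4L, 5L)) {
      fast <- length(unique((cols %/% s) * (max(rows) %/% s + 1L) +
                              (rows %/% s)))
      expect_equal(fast, brute_force_box_count(m, s))
    }
  }
})

test_that("structures spanning too few scales raise an informative error", {
  tiny <- matrix(FALSE, 16, 16); tiny[8, 4:12] <- TRUE
  expect_error(compute_fd(tiny), "scales")
  expect_error(compute_fd(matrix(FALSE, 64, 64)), "empty")
})

test_that("quantify composes the stages deterministically with provenance", {
  tree <- generate_vessel_tree(5, growth_params())
  truth <- rasterize_network(tree, 0.012, 3)
  img <- synthesize_angiogram(truth, noise_params(), seed = 55)
  roi <- mnvmorph:::make_roi_from_mask(truth, 6L)

  m1 <- quantify(img, roi)
  m2 <- quantify(img, roi)
  expect_identical(m1[c("area_mm2", "suml_mm", "fd", "flow_density_pct")],
                   m2[c("area_mm2", "suml_mm", "fd", "flow_density_pct")])
  expect_equal(m1$area_mm2, compute_area(roi, 0.012))
  expect_gt(m1$fd, 1); expect_lt(m1$fd, 2)
  expect_true(is.list(m1$provenance$binarize))
  expect_s3_class(m1$provenance$box_counts, "data.frame")
  expect_equal(m1$suml_mm, tree$total_length_mm, tolerance = 0.15)

  # noiseless input: sumL within the raster budget, flow density exact
  img0 <- synthesize_angiogram(truth, noise_params(speckle_cv = 0,
                                                   granularity_amp = 0))
  m0 <- quantify(img0, roi, despeckle_px = 0, fill_holes_px = 0)
  expect_equal(m0$suml_mm, tree$total_length_mm, tolerance = 0.10)
  expect_equal(m0$flow_density_pct, 100 * sum(truth) / sum(roi))
})

test_that("metrics obey scale equivariance and rotation robustness", {
  tree <- generate_vessel_tree(8, growth_params())
  mask <- rasterize_network(tree, 0.012, 3)
  sk <- thin_mask(mask)
  s1 <- compute_suml(build_network(sk, 0.012))
  s2 <- compute_suml(build_network(sk, 0.024))
  expect_equal(s2, 2 * s1)
  expect_equal(compute_area(mask, 0.024), 4 * compute_area(mask, 0.012))
  # FD and flow density carry no pixel scale at all

  # rasterized straight segments at 0, 45, 90 degrees agree within 5%
  mk_seg <- function(x0, y0, x1, y1) {
    tr <- generate_vessel_tree(1, growth_params(branch_prob = 0,
                                                generations = 1))
    len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
    tr$segments <- data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                              length_mm = len, generation = 1L, root = 1L)
    tr$total_length_mm <- len
    compute_suml(build_network(
      thin_mask(rasterize_network(tr, 0.012, 1)), 0.012)) / len
  }
  r0 <- mk_seg(1, 3, 2.5, 3)
  r90 <- mk_seg(3, 1, 3, 2.5)
  r45 <- mk_seg(1, 1, 1 + 1.5 / sqrt(2), 1 + 1.5 / sqrt(2))
  expect_lt(max(abs(c(r0, r45, r90) - 1)), 0.05)
  expect_lt(max(c(r0, r45, r90)) / min(c(r0, r45, r90)) - 1, 0.05)
})

test_that("fd stays in [1, 2] for connected skeletons across generator settings", {
  for (s in 1:4) {
    tree <- generate_vessel_tree(s, growth_params(branch_prob = 0.6))
    sk <- thin_mask(rasterize_network(tree, 0.012, 3))
    fd <- as.numeric(compute_fd(sk))
    expect_gte(fd, 0.95)
    expect_lte(fd, 2)
  }
})

test_that("multiscale ridge enhancement highlights vessel centerlines", {
  truth <- matrix(FALSE, 80, 80); truth[40, 10:70] <- TRUE
  img <- synthesize_angiogram(truth, noise_params(speckle_cv = 0.1))
  v <- enhance_vessels(img$intensity + 0)
  on_v <- mean(v[truth]); off_v <- mean(v[!truth])
  expect_gt(on_v, 5 * off_v)
})
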