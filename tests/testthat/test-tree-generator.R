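test_that("degenerate growth yields exactly one segment with exact bookkeeping", {
  p <- growth_params(branch_prob = 0, n_roots = 1, generations = 1)
  tree <- generate_vessel_tree(1, p)
  expect_equal(nrow(tree$segments), 1L)
  expect_equal(tree$total_length_mm, tree$segments$length_mm[1])
})

test_that("tree generation is deterministic per (seed, params)", {
  p <- growth_params()
  a <- generate_vessel_tree(42, p)
  b <- generate_vessel_tree(42, p)
  expect_identical(a$segments, b$segments)
  expect_false(identical(a$segments, generate_vessel_tree(43, p)$segments))
})

test_that("total length equals the sum of segment lengths and all lengths are positive", {
  for (s in 1:5) {
    tree <- generate_vessel_tree(s, growth_params())
    expect_true(all(tree$segments$length_mm > 0))
    expect_equal(tree$total_length_mm, sum(tree$segments$length_mm))
    # every segment chains to its root: each non-root segment starts where
    # some earlier segment ends
    segs <- tree$segments
    if (nrow(segs) > 1) {
      for (i in 2:nrow(segs)) {
        d <- sqrt((segs$x0[i] - segs$x1[1:(i - 1)])^2 +
                  (segs$y0[i] - segs$y1[1:(i - 1)])^2)
        expect_lt(min(d), 1e-12)
      }
    }
  }
})

test_that("growth parameters are validated", {
  expect_error(growth_params(branch_prob = 1.2))
  expect_error(growth_params(length_mean_mm = -1))
  expect_error(growth_params(generations = 0))
})

test_that("higher branching probability raises the measured fractal dimension", {
  fd_at <- function(bp, seeds) {
    mean(vapply(seeds, function(s) {
      tree <- generate_vessel_tree(s, growth_params(branch_prob = bp))
      as.numeric(compute_fd(thin_mask(rasterize_network(tree))))
    }, numeric(1)))
  }
  seeds <- 1:12
  expect_gt(fd_at(0.95, seeds), fd_at(0.3, seeds))
})

test_that("rasterization covers segments, clips the field, and handles empties", {
  # single horizontal 1.2 mm segment at 0.012 mm/px, width 1 -> 101-pixel run
  p <- growth_params(branch_prob = 0, generations = 1)
  tree <- generate_vessel_tree(1, p)
  tree$segments <- data.frame(
    x0 = 1.0, y0 = 3.0, x1 = 2.2, y1 = 3.0, length_mm = 1.2,
    generation = 1L, root = 1L
  )
  tree$total_length_mm <- 1.2
  m <- rasterize_network(tree, pixel_scale = 0.012, vessel_width_px = 1)
  expect_equal(dim(m), c(500L, 500L))
  expect_equal(sum(m), 101L)
  expect_equal(length(unique(which(m, arr.ind = TRUE)[, 1])), 1L)

  # out-of-field segment is clipped, not an error
  tree$segments$x1 <- 9.0
  expect_silent(m2 <- rasterize_network(tree, 0.012, 1))
  expect_true(all(which(m2, arr.ind = TRUE)[, 2] <= 500))

  # empty network -> all-FALSE mask
  tree$segments <- tree$segments[0, ]
  expect_equal(sum(rasterize_network(tree, 0.012, 1)), 0L)
})

test_that("skeleton length of the rasterized tree recovers ground truth within 10%", {
  errs <- vapply(1:6, function(s) {
    tree <- generate_vessel_tree(s, growth_params())
    mask <- rasterize_network(tree, pixel_scale = 0.012, vessel_width_px = 3)
    net <- build_network(thin_mask(mask), pixel_scale = 0.012)
    compute_suml(net) / tree$total_length_mm - 1
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.10)
  expect_true(all(abs(errs) < 0.15))
})

test_that("tree rescaling hits the target length exactly", {
  tree <- generate_vessel_tree(3, growth_params())
  scaled <- scale_tree_to_length(tree, 12.95)
  expect_equal(scaled$total_length_mm, 12.95, tolerance = 1e-12)
  expect_equal(nrow(scaled$segments), nrow(tree$segments))
})
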