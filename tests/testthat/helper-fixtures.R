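# Shared fixture builders for the morphometry and simulation tests.

# Sierpinski carpet of the given depth on a 3^depth grid; pixel (i, j) is
# foreground unless some base-3 digit pair is (1, 1).
make_sierpinski <- function(depth) {
  n <- 3L^depth
  in_carpet <- function(i, j) {
    for (k in seq_len(depth)) {
      if (i %% 3L == 1L && j %% 3L == 1L) return(FALSE)
      i <- i %/% 3L; j <- j %/% 3L
    }
    TRUE
  }
  m <- matrix(FALSE, n, n)
  for (i in 0:(n - 1L)) {
    for (j in 0:(n - 1L)) m[i + 1L, j + 1L] <- in_carpet(i, j)
  }
  m
}

# Exhaustive box occupancy count: scan every s x s box over the bounding
# box of the structure and test each pixel. Deliberately naive.
brute_force_box_count <- function(m, s) {
  idx <- which(m, arr.ind = TRUE)
  r0 <- min(idx[, 1L]); c0 <- min(idx[, 2L])
  r1 <- max(idx[, 1L]); c1 <- max(idx[, 2L])
  count <- 0L
  for (br in seq(r0, r1, by = s)) {
    for (bc in seq(c0, c1, by = s)) {
      rows <- br:min(br + s - 1L, r1)
      cols <- bc:min(bc + s - 1L, c1)
      if (any(m[rows, cols, drop = FALSE])) count <- count + 1L
    }
  }
  count
}

# 8-connected component count by flood fill (independent of any package
# labelling routine).
count_components_8 <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  k <- 0L
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  for (s in seq_len(nrow(idx))) {
    if (lab[idx[s, 1L], idx[s, 2L]] > 0L) next
    k <- k + 1L
    stack <- list(idx[s, ])
    while (length(stack)) {
      pc <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      r <- pc[1L]; c <- pc[2L]
      if (r < 1L || c < 1L || r > nrow(m) || c > ncol(m)) next
      if (!m[r, c] || lab[r, c] > 0L) next
      lab[r, c] <- k
      for (dr in -1:1) for (dc in -1:1) {
        if (dr || dc) stack[[length(stack) + 1L]] <- c(r + dr, c + dc)
      }
    }
  }
  k
}

# p-value of one term of one model in an analysis report
report_p <- function(report, model, term) {
  t <- report$table
  t$p_value[t$model == model & t$term == term]
}
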