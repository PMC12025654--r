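#' Topology-preserving thinning to 1-pixel centerlines
#'
#' Reduces a binary vessel mask to 8-connected one-pixel-wide midlines by
#' iterative Zhang-Suen thinning: in two alternating subiterations, border
#' pixels are deleted when their 8-neighborhood shows 2..6 foreground
#' neighbors, exactly one 0-to-1 transition around the pixel, and the
#' directional conditions of the subiteration hold; deletions within one
#' subiteration are simultaneous. The procedure preserves the connectivity
#' of the mask (each connected component of the mask yields one connected
#' skeleton component), is idempotent on already-thin input, and retains
#' free line ends (an endpoint has one neighbor, which blocks deletion).
#'
#' @param mask logical (or 0/1) matrix.
#' @return logical matrix of the same shape; the skeleton.
#' @seealso [extract_centerlines()], [build_network()]
#' @export
thin_mask <- function(mask) {
  m <- mask_matrix(mask)
  if (!any(m)) return(m)
  # pad with a background frame so neighborhood shifts need no edge cases
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  sh <- function(x, dr, dc) {
    rr <- seq_len(nr) + 1L + dr
    cc <- seq_len(nc) + 1L + dc
    x[rr, cc, drop = FALSE]
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      core <- p[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
      # neighbors in Zhang-Suen order P2..P9 = N, NE, E, SE, S, SW, W, NW
      n2 <- sh(p, -1L, 0L); n3 <- sh(p, -1L, 1L); n4 <- sh(p, 0L, 1L)
      n5 <- sh(p, 1L, 1L);  n6 <- sh(p, 1L, 0L);  n7 <- sh(p, 1L, -1L)
      n8 <- sh(p, 0L, -1L); n9 <- sh(p, -1L, -1L)
      b <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
      a <- (!n2 & n3) + (!n3 & n4) + (!n4 & n5) + (!n5 & n6) +
           (!n6 & n7) + (!n7 & n8) + (!n8 & n9) + (!n9 & n2)
      cond <- core & b >= 2 & b <= 6 & a == 1
      if (sub == 1L) {
        cond <- cond & !(n2 & n4 & n6) & !(n4 & n6 & n8)
      } else {
        cond <- cond & !(n2 & n4 & n8) & !(n2 & n6 & n8)
      }
      if (any(cond)) {
        core[cond] <- FALSE
        p[2:(nr + 1L), 2:(nc + 1L)] <- core
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # Zhang-Suen can leave residual 2x2 blocks on blob-like regions; remove
  # them by sequential deletion of simple points (neighbor count >= 2 and
  # exactly one foreground run in the 8-ring), which preserves both
  # connectivity and endpoints.
  repeat {
    core <- p[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
    blocks <- core[-nrow(core), -ncol(core), drop = FALSE] &
      core[-1L, -ncol(core), drop = FALSE] &
      core[-nrow(core), -1L, drop = FALSE] &
      core[-1L, -1L, drop = FALSE]
    if (!any(blocks)) break
    bidx <- which(blocks, arr.ind = TRUE)
    cand <- rbind(bidx, bidx + rep(c(1L, 0L), each = nrow(bidx)),
                  bidx + rep(c(0L, 1L), each = nrow(bidx)),
                  bidx + 1L)
    cand <- unique(cand)
    progress <- FALSE
    ring <- cbind(
      dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
      dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
    )
    for (ci in seq_len(nrow(cand))) {
      r <- cand[ci, 1L] + 1L; c <- cand[ci, 2L] + 1L  # padded coords
      if (!p[r, c]) next
      nb <- p[cbind(r + ring[, 1L], c + ring[, 2L])]
      b <- sum(nb)
      a <- sum(!nb & nb[c(2:8, 1L)])
      if (b >= 2L && a == 1L) {
        p[r, c] <- FALSE
        progress <- TRUE
      }
    }
    if (!progress) break
  }
  p[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
}

#' Extract vessel centerlines from a binary mask
#'
#' The skeletonization front end of the morphometry pipeline: optionally
#' bridges small gaps in the flow mask by a morphological closing (radius
#' `bridge_px`), then thins to one-pixel centerlines with [thin_mask()].
#' With `bridge_px = 0` (the default) the connectivity of the input mask is
#' preserved exactly; closing trades that guarantee for robustness to
#' speckle dropouts along a vessel.
#'
#' @param mask logical vessel mask (e.g. from [binarize()]).
#' @param bridge_px radius in pixels of the optional closing; 0 disables.
#' @return logical skeleton matrix.
#' @export
extract_centerlines <- function(mask, bridge_px = 0L) {
  m <- mask_matrix(mask)
  if (!any(m)) return(m)
  if (bridge_px > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(bridge_px) + 1L, "disc")
    m <- EBImage::closing(m * 1, brush) > 0.5
  }
  thin_mask(m)
}

# Coerce the various mask representations to a logical matrix.
mask_matrix <- function(mask) {
  if (is.logical(mask) && is.matrix(mask)) {
    m <- mask
  } else if (is.numeric(mask) && is.matrix(mask)) {
    m <- mask > 0.5
  } else {
    stop("expected a logical or 0/1 numeric matrix", call. = FALSE)
  }
  attributes(m) <- list(dim = dim(m))
  m
}
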