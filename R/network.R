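#' Build a centerline graph from a skeleton
#'
#' Decomposes a one-pixel-wide skeleton into a graph whose nodes are
#' endpoints (pixels with exactly one 8-neighbor) and junctions (pixels
#' with three or more), and whose edges are the maximal node-free pixel
#' paths between them. Junction pixels that touch within an 8-neighborhood
#' are merged into a single node, which prevents spurious micro-edges at
#' thick crossings. Edge length is the geodesic pixel-path length: each
#' axial step contributes `pixel_scale` mm and each diagonal step
#' `sqrt(2) * pixel_scale` mm. A connected component consisting purely of
#' degree-2 pixels (an isolated loop) becomes a single self-edge carrying
#' the full cycle length; an isolated single pixel becomes a node with no
#' edges.
#'
#' @param skeleton logical matrix of centerline pixels, as produced by
#'   [thin_mask()]. Thinness is enforced: a 2x2 foreground block is only
#'   accepted when all four pixels are junction pixels (a thick crossing
#'   with no one-pixel representation); any other 2x2 block raises a
#'   contract-violation error.
#' @param pixel_scale mm per pixel (isotropic).
#' @return object of class `mnv_vessel_network`: list with `nodes`
#'   (data.frame: `id`, `row`, `col`, `kind`), `edges` (data.frame:
#'   `from`, `to`, `n_steps`, `length_mm`), `pixel_scale`, `skeleton`.
#' @export
build_network <- function(skeleton, pixel_scale) {
  stopifnot(is.numeric(pixel_scale), pixel_scale > 0)
  sk <- mask_matrix(skeleton)
  empty <- list(
    nodes = data.frame(id = integer(), row = integer(), col = integer(),
                       kind = character(), stringsAsFactors = FALSE),
    edges = data.frame(from = integer(), to = integer(),
                       n_steps = numeric(), length_mm = numeric()),
    pixel_scale = pixel_scale, skeleton = sk
  )
  if (!any(sk)) return(structure(empty, class = "mnv_vessel_network"))

  nr <- nrow(sk)
  idx <- which(sk)                       # column-major linear indices
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  key <- function(r, c) (c - 1L) * nr + r
  pix_pos <- new.env(hash = TRUE, size = length(idx))
  for (i in seq_along(idx)) assign(as.character(idx[i]), i, envir = pix_pos)
  pos_of <- function(k) get(as.character(k), envir = pix_pos)

  offs <- cbind(
    dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
    dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  )
  nc_ <- ncol(sk)
  at <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc_ && sk[r, c]
  # Diagonal adjacency is pruned when the two pixels share a foreground
  # 4-neighbor: the chain then routes through that pixel instead of
  # short-cutting across the triangle. Without this, staircase patterns
  # left by thinning read as spurious junctions.
  neighbors_of <- function(i) {
    r <- rows[i]; c <- cols[i]
    ks <- integer(8L)
    n_k <- 0L
    for (o in seq_len(8L)) {
      dr <- offs[o, 1L]; dc <- offs[o, 2L]
      rr <- r + dr; cc <- c + dc
      if (!at(rr, cc)) next
      if (dr != 0L && dc != 0L && (at(r, cc) || at(rr, c))) next
      n_k <- n_k + 1L
      ks[n_k] <- key(rr, cc)
    }
    ks[seq_len(n_k)]
  }
  nbr <- lapply(seq_along(idx), neighbors_of)   # linear keys
  deg <- lengths(nbr)

  # Thinness contract: 2x2 foreground blocks are tolerated only when all
  # four pixels are junction pixels (a thick crossing point that has no
  # one-pixel 8-connected representation); any other 2x2 block means the
  # input was not thinned.
  if (any_2x2_block(sk)) {
    degm <- matrix(0L, nrow(sk), ncol(sk))
    degm[idx] <- deg
    j <- degm >= 3L
    jall <- j[-nrow(j), -ncol(j)] & j[-1L, -ncol(j)] &
      j[-nrow(j), -1L] & j[-1L, -1L]
    bl <- sk[-nrow(sk), -ncol(sk)] & sk[-1L, -ncol(sk)] &
      sk[-nrow(sk), -1L] & sk[-1L, -1L]
    if (any(bl & !jall)) {
      stop("skeleton is not thin (2x2 foreground block outside a ",
           "junction); run thin_mask() first", call. = FALSE)
    }
  }

  is_node <- deg != 2L                    # endpoints, junctions, isolated
  node_pos <- which(is_node)
  # merge 8-adjacent junction pixels (deg >= 3) into one node id
  cluster <- integer(length(idx))
  next_id <- 0L
  for (i in node_pos) {
    if (cluster[i] > 0L) next
    next_id <- next_id + 1L
    if (deg[i] < 3L) { cluster[i] <- next_id; next }
    stack <- i
    while (length(stack)) {
      j <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (cluster[j] > 0L) next
      cluster[j] <- next_id
      for (k in nbr[[j]]) {
        kp <- pos_of(k)
        if (deg[kp] >= 3L && cluster[kp] == 0L) stack <- c(stack, kp)
      }
    }
  }

  step_len <- function(a, b) {
    sqrt((rows[a] - rows[b])^2 + (cols[a] - cols[b])^2)
  }
  # Geodesic path length with corner cutting: triangle pruning routes
  # oblique chains around right-angle doglegs whose endpoints are diagonal
  # neighbors; measuring such a pair of unit steps as one sqrt(2) step
  # restores the length of the underlying 8-connected curve.
  walk_steps <- function(path_prev2, prev, cur, acc, last_axial) {
    s <- step_len(prev, cur)
    if (last_axial && s == 1 &&
        !is.na(path_prev2) &&
        abs(rows[cur] - rows[path_prev2]) == 1L &&
        abs(cols[cur] - cols[path_prev2]) == 1L) {
      list(acc = acc - 1 + sqrt(2), last_axial = FALSE)
    } else {
      list(acc = acc + s, last_axial = (s == 1))
    }
  }
  edges_from <- integer(); edges_to <- integer(); edges_steps <- numeric()
  used <- new.env(hash = TRUE)            # directed half-steps consumed
  mark <- function(a, b) assign(paste(a, b), TRUE, envir = used)
  seen <- function(a, b) exists(paste(a, b), envir = used)

  add_edge <- function(from, to, steps) {
    edges_from <<- c(edges_from, from)
    edges_to <<- c(edges_to, to)
    edges_steps <<- c(edges_steps, steps)
  }

  for (i in node_pos) {
    for (k in nbr[[i]]) {
      j <- pos_of(k)
      if (seen(i, j)) next
      if (is_node[j]) {
        # direct node-node adjacency; skip intra-cluster contacts
        if (cluster[i] == cluster[j]) { mark(i, j); mark(j, i); next }
        mark(i, j); mark(j, i)
        add_edge(cluster[i], cluster[j], step_len(i, j))
        next
      }
      # walk along degree-2 pixels until the next node pixel
      steps <- 0
      prev <- i; cur <- j
      prev2 <- NA_integer_; last_axial <- FALSE
      mark(i, j)
      repeat {
        st <- walk_steps(prev2, prev, cur, steps, last_axial)
        steps <- st$acc; last_axial <- st$last_axial
        if (is_node[cur]) { mark(cur, prev); break }
        nxt_keys <- nbr[[cur]]
        nxt <- vapply(nxt_keys, pos_of, integer(1L))
        nxt <- nxt[nxt != prev]
        if (length(nxt) == 0L) break      # dangling (cannot happen on thin input)
        prev2 <- prev
        prev <- cur; cur <- nxt[[1L]]
        mark(prev, cur)
      }
      if (cluster[cur] > 0L) add_edge(cluster[i], cluster[cur], steps)
    }
  }

  # isolated cycles: all pixels degree 2, none visited
  visited_any <- vapply(seq_along(idx), function(i) {
    any(vapply(nbr[[i]], function(k) seen(i, pos_of(k)), logical(1L)))
  }, logical(1L))
  todo <- which(deg == 2L & !visited_any)
  while (length(todo)) {
    start <- todo[[1L]]
    next_id <- next_id + 1L
    cluster[start] <- next_id
    steps <- 0
    prev <- start; cur <- pos_of(nbr[[start]][[1L]])
    prev2 <- NA_integer_; last_axial <- FALSE
    mark(start, cur)
    repeat {
      st <- walk_steps(prev2, prev, cur, steps, last_axial)
      steps <- st$acc; last_axial <- st$last_axial
      mark(prev, cur); mark(cur, prev)
      if (cur == start) break
      nxt <- vapply(nbr[[cur]], pos_of, integer(1L))
      nxt <- nxt[nxt != prev]
      prev2 <- prev
      prev <- cur; cur <- nxt[[1L]]
    }
    add_edge(next_id, next_id, steps)
    visited_any <- vapply(seq_along(idx), function(i) {
      any(vapply(nbr[[i]], function(k) seen(i, pos_of(k)), logical(1L)))
    }, logical(1L))
    todo <- which(deg == 2L & !visited_any)
  }

  kind <- ifelse(deg == 0L, "isolated",
                 ifelse(deg == 1L, "endpoint", "junction"))
  has_pix <- cluster > 0L
  nodes <- data.frame(
    id = cluster[has_pix], row = rows[has_pix], col = cols[has_pix],
    kind = kind[has_pix], stringsAsFactors = FALSE
  )
  # one representative row per node id (cluster centroid pixel is the first)
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- data.frame(
    from = edges_from, to = edges_to, n_steps = edges_steps,
    length_mm = edges_steps * pixel_scale
  )
  structure(
    list(nodes = nodes, edges = edges, pixel_scale = pixel_scale,
         skeleton = sk),
    class = "mnv_vessel_network"
  )
}

#' @export
print.mnv_vessel_network <- function(x, ...) {
  cat(sprintf(
    "vessel network: %d nodes (%d endpoints, %d junctions), %d edges, sumL = %.3f mm\n",
    nrow(x$nodes), sum(x$nodes$kind == "endpoint"),
    sum(x$nodes$kind == "junction"), nrow(x$edges), compute_suml(x)
  ))
  invisible(x)
}

#' Total vascular length (sumL)
#'
#' Sum of the geodesic lengths of every centerline segment of the network,
#' in mm.
#'
#' @param net `mnv_vessel_network` from [build_network()].
#' @return numeric scalar, mm.
#' @export
compute_suml <- function(net) {
  stopifnot(inherits(net, "mnv_vessel_network"))
  sum(net$edges$length_mm)
}

any_2x2_block <- function(m) {
  if (nrow(m) < 2L || ncol(m) < 2L) return(FALSE)
  a <- m[-nrow(m), -ncol(m)] & m[-1L, -ncol(m)] &
       m[-nrow(m), -1L] & m[-1L, -1L]
  any(a)
}
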