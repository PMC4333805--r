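# Independent oracles used by the unit and acceptance tests. Both are
# deliberately brute-force: connected components + component maximum,
# computed with plain BFS, nothing shared with the implementations under
# test.

# Per-supported-component maximum of a max_network: supported nodes take
# the maximum feedforward over their connected component in the subgraph
# induced by supported nodes; unsupported nodes keep their own drive.
oracle_component_max <- function(ff, edges, support) {
  n <- length(ff)
  adj <- vector("list", n)
  if (!is.null(edges) && nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  out <- ff
  seen <- rep(FALSE, n)
  for (s in seq_len(n)) {
    if (seen[s] || !support[s]) next
    comp <- integer(0); queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) {
        if (!seen[w] && support[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    out[comp] <- max(ff[comp])
  }
  out
}

# Geodesic region-max oracle for the filling-in layer: flood-fill the
# support-and-boundary-connected components of the lattice and assign each
# supported cell its component's maximum feature; unsupported cells keep
# their own value. Edges between vertical neighbours are cut where the H
# mask is set at either endpoint, horizontal neighbours likewise for V.
oracle_region_max <- function(feature, mask_h, mask_v, thr_frac) {
  n <- nrow(feature); m <- ncol(feature)
  support <- feature >= thr_frac * max(feature)
  h <- mask_h > 0; v <- mask_v > 0
  out <- feature
  seen <- matrix(FALSE, n, m)
  for (sr in seq_len(n)) for (sc in seq_len(m)) {
    if (seen[sr, sc] || !support[sr, sc]) next
    comp <- matrix(integer(0), ncol = 2)
    queue <- list(c(sr, sc)); seen[sr, sc] <- TRUE
    while (length(queue)) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      comp <- rbind(comp, p)
      r <- p[1]; c <- p[2]
      for (q in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))) {
        r2 <- q[1]; c2 <- q[2]
        if (r2 < 1 || r2 > n || c2 < 1 || c2 > m) next
        if (seen[r2, c2] || !support[r2, c2]) next
        blocked <- if (r2 != r) h[r, c] || h[r2, c2] else v[r, c] || v[r2, c2]
        if (blocked) next
        seen[r2, c2] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
    out[comp] <- max(feature[comp])
  }
  out
}

# plain matrix shift used by the mask-rim checks
shift_mat_test <- function(m, dr, dc, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# random small max_network for property tests
random_net <- function(n_max = 50, p_edge = 0.1, p_support = 0.85) {
  n <- sample(2:n_max, 1)
  ff <- round(stats::runif(n), 3)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- pairs[keep, , drop = FALSE]
  support <- stats::runif(n) < p_support
  max_network(ff, edges, support)
}

# random feature/mask instance for the filling oracle tests
random_fill_instance <- function(n = 32) {
  feature <- matrix(stats::runif(n * n), n, n)
  mask_h <- matrix(stats::runif(n * n) < 0.08, n, n)
  mask_v <- matrix(stats::runif(n * n) < 0.08, n, n)
  list(feature = feature,
       mask = structure(list(H = mask_h, V = mask_v),
                        class = "boundary_mask"))
}
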