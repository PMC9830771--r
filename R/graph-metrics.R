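# Global and nodal graph measures for binary undirected networks:
# clustering coefficient, characteristic path length, small-world index
# against degree-preserving random references, betweenness, hubs.

# All-pairs hop distances by vectorized frontier expansion; Inf marks
# unreachable pairs. Faster than an igraph round-trip at the network
# sizes used here (tens to ~120 nodes).
.hop_distances <- function(A) {
  n <- nrow(A)
  A <- (A > 0) * 1
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  frontier <- A
  D[A == 1] <- 1
  visited <- A == 1 | diag(n) == 1
  k <- 1L
  while (any(frontier == 1) && k < n) {
    k <- k + 1L
    nxt <- (frontier %*% A > 0) & !visited
    if (!any(nxt)) break
    D[nxt] <- k
    visited <- visited | nxt
    frontier <- nxt * 1
  }
  D
}

# igraph object from a binary adjacency matrix, via the upper-triangle
# edge list (cheaper than graph_from_adjacency_matrix in tight loops).
.ig_from_adj <- function(A) {
  n <- nrow(A)
  e <- which(A > 0 & upper.tri(A), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, t(e))
  g
}

#' Clustering coefficient
#'
#' Per-node value: the fraction of realized edges among the node's
#' neighbours; nodes with fewer than two neighbours contribute 0. The
#' network value `C` is the arithmetic mean over all nodes — a measure of
#' network segregation.
#'
#' @param A binary symmetric adjacency matrix.
#' @return list with `C` (mean) and `node` (per-node values).
#' @export
clustering_coefficient <- function(A) {
  n <- nrow(A)
  if (n == 0L) return(list(C = 0, node = numeric(0)))
  A <- (A > 0) * 1
  deg <- rowSums(A)
  # closed triples through node i = diag(A^3)_i = sum_j (A^2)_ij A_ij
  # (A symmetric); possible triples = k(k-1)
  tri2 <- rowSums((A %*% A) * A)
  denom <- deg * (deg - 1)
  node <- ifelse(denom > 0, tri2 / denom, 0)
  names(node) <- rownames(A)
  list(C = mean(node), node = node)
}

# Lean mean clustering coefficient for the permutation hot loop.
.cc_mean <- function(A) {
  deg <- rowSums(A)
  tri2 <- rowSums((A %*% A) * A)
  denom <- deg * (deg - 1)
  ok <- denom > 0
  sum(tri2[ok] / denom[ok]) / nrow(A)
}

#' Characteristic path length
#'
#' Mean shortest-path hop distance over all unordered node pairs — a
#' measure of network integration. On a disconnected graph the mean is
#' taken over the largest connected component and `disconnected = TRUE`
#' is flagged (this arises only inside permutation replicates, since
#' observed density grids start at the full-connectivity minimum).
#'
#' @param A binary symmetric adjacency matrix.
#' @return list with `L`, `disconnected` flag, and `component_size`.
#' @export
characteristic_path_length <- function(A) {
  n <- nrow(A)
  if (n < 2L) return(list(L = NA_real_, disconnected = FALSE,
                          component_size = n))
  D <- .hop_distances(A)
  finite <- is.finite(D)
  if (all(finite)) {
    return(list(L = sum(D) / (n * (n - 1)), disconnected = FALSE,
                component_size = n))
  }
  # components from the reachability pattern of the distance matrix
  comp_of <- integer(n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (comp_of[v] == 0L) {
      cid <- cid + 1L
      comp_of[finite[v, ]] <- cid
    }
  }
  big <- which(comp_of == which.max(tabulate(comp_of)))
  m <- length(big)
  L <- if (m < 2L) NA_real_ else sum(D[big, big]) / (m * (m - 1))
  list(L = L, disconnected = TRUE, component_size = m)
}

#' Nodal betweenness centrality
#'
#' For each node, the fraction of all-pairs shortest paths that pass
#' through it, normalized by `(N-1)(N-2)/2` so values lie in `[0, 1]`.
#' High-betweenness regions act as relay stations of the covariance
#' network; the hub rule ([identify_hubs()]) is scale-invariant, so the
#' normalization is presentational.
#'
#' @param A binary symmetric adjacency matrix.
#' @param normalized if `FALSE`, return raw pair counts.
#' @return named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(A, normalized = TRUE) {
  n <- nrow(A)
  b <- igraph::betweenness(.ig_from_adj(A), directed = FALSE)
  if (normalized && n > 2L) b <- b / ((n - 1) * (n - 2) / 2)
  names(b) <- rownames(A)
  b
}

#' Degree-preserving random reference graphs
#'
#' Generates `n_random` rewired versions of the input graph by repeated
#' double-edge swaps (the Maslov-Sneppen null model): two edges (a,b),
#' (c,d) are replaced by (a,d), (c,b), which preserves every node's
#' degree. Swaps are connectivity-preserving — batches of swaps that
#' disconnect the graph are rolled back, so every reference graph is
#' connected whenever the input is. Returns the mean clustering
#' coefficient and characteristic path length over the ensemble, the
#' denominators of the small-world index.
#'
#' @param A binary symmetric adjacency matrix of a connected graph.
#' @param n_random number of reference graphs (default 20).
#' @param n_swaps_per_edge attempted swaps per edge in each reference
#'   (default 10).
#' @param seed RNG seed; the same seed reproduces the ensemble exactly.
#' @param return_graphs also return the rewired adjacency matrices.
#' @return list with `C_rand`, `L_rand`, per-graph vectors `C_values`,
#'   `L_values`, and (if requested) `graphs`.
#' @export
random_reference <- function(A, n_random = 20L, n_swaps_per_edge = 10L,
                             seed = 1L, return_graphs = FALSE) {
  A <- (A > 0) * 1
  edges <- which(A > 0 & upper.tri(A), arr.ind = TRUE)
  if (nrow(edges) < 2L) stop("graph too small to rewire")
  # a disconnected input (permutation replicates under a fixed d_min)
  # cannot be held to connectivity preservation: only degrees are kept
  keep_connected <- .is_connected_adj(A)
  .with_seed(seed, {
    Cs <- Ls <- numeric(n_random)
    graphs <- if (return_graphs) vector("list", n_random) else NULL
    any_accepted <- FALSE
    for (r in seq_len(n_random)) {
      rw <- .rewire_connected(A, edges, n_attempts = n_swaps_per_edge *
                                nrow(edges),
                              keep_connected = keep_connected)
      if (rw$accepted > 0L) any_accepted <- TRUE
      Cs[r] <- clustering_coefficient(rw$A)$C
      Ls[r] <- characteristic_path_length(rw$A)$L
      if (return_graphs) graphs[[r]] <- rw$A
    }
    if (!any_accepted) {
      stop("graph too constrained to rewire: no swap was accepted")
    }
    out <- list(C_rand = mean(Cs), L_rand = mean(Ls),
                C_values = Cs, L_values = Ls)
    if (return_graphs) out$graphs <- graphs
    out
  })
}

# One connectivity-preserving degree-preserving rewire of A.
# Swaps are applied in windows; after each window the graph's
# connectivity is checked and the whole window rolled back if it broke,
# with the window size adapting (double on success, halve on failure).
.rewire_connected <- function(A, edges, n_attempts, keep_connected = TRUE) {
  n <- nrow(A)
  E <- nrow(edges)
  accepted <- 0L
  window <- 1L
  pending <- list()   # swaps since last verified-connected state
  attempt <- 0L
  while (attempt < n_attempts) {
    attempt <- attempt + 1L
    idx <- sample.int(E, 2L)
    e1 <- edges[idx[1], ]
    e2 <- edges[idx[2], ]
    a <- e1[1]; b <- e1[2]; c <- e2[1]; d <- e2[2]
    if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
    if (length(unique(c(a, b, c, d))) < 4L) next
    if (A[a, d] == 1 || A[c, b] == 1) next
    # apply swap: (a,b),(c,d) -> (a,d),(c,b)
    A[a, b] <- A[b, a] <- 0
    A[c, d] <- A[d, c] <- 0
    A[a, d] <- A[d, a] <- 1
    A[c, b] <- A[b, c] <- 1
    edges[idx[1], ] <- c(min(a, d), max(a, d))
    edges[idx[2], ] <- c(min(c, b), max(c, b))
    pending[[length(pending) + 1L]] <- list(idx = idx, old1 = c(a, b),
                                            old2 = c(c, d))
    if (length(pending) >= window) {
      if (!keep_connected || .is_connected_adj(A)) {
        accepted <- accepted + length(pending)
        pending <- list()
        window <- min(window * 2L, 256L)
      } else {
        for (sw in rev(pending)) {
          o1 <- sw$old1; o2 <- sw$old2
          A[o1[1], o2[2]] <- A[o2[2], o1[1]] <- 0
          A[o2[1], o1[2]] <- A[o1[2], o2[1]] <- 0
          A[o1[1], o1[2]] <- A[o1[2], o1[1]] <- 1
          A[o2[1], o2[2]] <- A[o2[2], o2[1]] <- 1
          edges[sw$idx[1], ] <- sort(o1)
          edges[sw$idx[2], ] <- sort(o2)
        }
        pending <- list()
        window <- max(window %/% 2L, 1L)
      }
    }
  }
  if (length(pending)) {
    if (!keep_connected || .is_connected_adj(A)) {
      accepted <- accepted + length(pending)
    } else {
      for (sw in rev(pending)) {
        o1 <- sw$old1; o2 <- sw$old2
        A[o1[1], o2[2]] <- A[o2[2], o1[1]] <- 0
        A[o2[1], o1[2]] <- A[o1[2], o2[1]] <- 0
        A[o1[1], o1[2]] <- A[o1[2], o1[1]] <- 1
        A[o2[1], o2[2]] <- A[o2[2], o2[1]] <- 1
      }
    }
  }
  list(A = A, accepted = accepted)
}

#' Small-world index
#'
#' `sigma = (C / C_rand) / (L / L_rand)`: the clustering coefficient and
#' characteristic path length of the network, each normalized by the
#' corresponding mean over degree-preserving random reference graphs.
#' `sigma > 1` indicates small-world organization — clustering well above
#' random with near-random path length.
#'
#' @param C,L observed clustering coefficient and path length.
#' @param C_rand,L_rand reference-ensemble means.
#' @return the small-world index.
#' @export
small_world_index <- function(C, L, C_rand, L_rand) {
  if (C < 0) stop("C must be nonnegative")
  if (any(c(L, C_rand, L_rand) <= 0)) {
    stop("L, C_rand and L_rand must be positive")
  }
  (C / C_rand) / (L / L_rand)
}

#' Global network metrics at one density
#'
#' @param A binary symmetric adjacency matrix.
#' @param density the density at which `A` was thresholded (stored in the
#'   output).
#' @param n_random,n_swaps_per_edge,seed passed to [random_reference()].
#' @return one-row data.frame: `density`, `C`, `L`, `C_rand`, `L_rand`,
#'   `sigma`, `n_random`, `disconnected`.
#' @export
global_metrics <- function(A, density = NA_real_, n_random = 20L,
                           n_swaps_per_edge = 10L, seed = 1L) {
  cc <- clustering_coefficient(A)
  pl <- characteristic_path_length(A)
  rr <- random_reference(A, n_random = n_random,
                         n_swaps_per_edge = n_swaps_per_edge, seed = seed)
  data.frame(density = density, C = cc$C, L = pl$L,
             C_rand = rr$C_rand, L_rand = rr$L_rand,
             sigma = small_world_index(cc$C, pl$L, rr$C_rand, rr$L_rand),
             n_random = n_random, disconnected = pl$disconnected)
}

#' Identify network hubs
#'
#' A region is a hub if its betweenness is at least two standard
#' deviations above the mean betweenness over all regions. The SD is the
#' population (n-denominator) SD by default; the sample SD is available
#' via `sd_type`.
#'
#' @param betweenness named numeric vector of nodal betweenness.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return data.frame of hubs (`region`, `betweenness`) with attributes
#'   `mean`, `sd`, `threshold`.
#' @export
identify_hubs <- function(betweenness, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(length(betweenness) >= 2L)
  if (is.null(names(betweenness))) {
    names(betweenness) <- as.character(seq_along(betweenness))
  }
  m <- mean(betweenness)
  s <- stats::sd(betweenness)
  if (sd_type == "population") {
    s <- s * sqrt((length(betweenness) - 1) / length(betweenness))
  }
  if (is.na(s) || s == 0) {
    hubs <- data.frame(region = character(0), betweenness = numeric(0))
  } else {
    thr <- m + 2 * s
    sel <- betweenness >= thr
    hubs <- data.frame(region = names(betweenness)[sel],
                       betweenness = unname(betweenness[sel]))
    hubs <- hubs[order(-hubs$betweenness), , drop = FALSE]
    rownames(hubs) <- NULL
  }
  attr(hubs, "mean") <- m
  attr(hubs, "sd") <- s
  attr(hubs, "threshold") <- if (is.na(s) || s == 0) Inf else m + 2 * s
  hubs
}
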