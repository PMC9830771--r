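# Brute-force graph oracles, deliberately independent of the package's
# implementations (and of igraph): neighbour-pair enumeration for
# clustering, Floyd-Warshall for distances, shortest-path counting by
# dynamic programming over BFS layers for betweenness.

bf_clustering <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (A[nb[i], nb[j]] > 0) links <- links + 1
      }
    }
    vals[v] <- links / (k * (k - 1) / 2)
  }
  list(C = mean(vals), node = vals)
}

bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

bf_path_length <- function(A) {
  D <- bf_distances(A)
  n <- nrow(A)
  mean(D[upper.tri(D)])
}

# Count shortest paths sigma[s, t] layer by layer, then accumulate each
# interior node's fractional membership.
bf_betweenness <- function(A, normalized = TRUE) {
  n <- nrow(A)
  D <- bf_distances(A)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    dmax <- max(D[s, is.finite(D[s, ])])
    if (dmax < 1) next
    for (d in seq_len(dmax)) {
      for (t in which(D[s, ] == d)) {
        preds <- which(A[, t] > 0 & D[s, ] == d - 1)
        sigma[s, t] <- sum(sigma[s, preds])
      }
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(D[s, t])) next
        if (D[s, v] + D[v, t] == D[s, t]) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  if (normalized && n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
  btw
}

bf_connected <- function(A) {
  n <- nrow(A)
  reached <- c(TRUE, rep(FALSE, n - 1))
  repeat {
    new <- (colSums(A[reached, , drop = FALSE]) > 0) & !reached
    if (!any(new)) break
    reached <- reached | new
  }
  all(reached)
}

# Random connected simple graph on n nodes (edge probability p),
# regenerated until connected.
random_connected_graph <- function(n, p = 0.35) {
  repeat {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    on <- up[stats::runif(length(up)) < p]
    A[on] <- 1
    A <- A + t(A)
    if (sum(A) > 0 && bf_connected(A)) return(A)
  }
}

# Small volume table built from an explicit matrix.
table_from_matrix <- function(Y, age = NULL, sex = NULL,
                              group = "g1", timepoint = NULL,
                              ids = NULL) {
  n <- nrow(Y)
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("R%02d", seq_len(ncol(Y)))
  if (is.null(age)) age <- seq(20, 40, length.out = n)
  if (is.null(sex)) sex <- rep_len(c(0, 1), n)
  if (is.null(ids)) ids <- sprintf("T%03d", seq_len(n))
  tab <- data.frame(subject_id = ids, group = group,
                    age = age, sex = sex, stringsAsFactors = FALSE)
  if (!is.null(timepoint)) tab$timepoint <- timepoint
  cbind(tab, as.data.frame(Y))
}
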