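#' Residualize region volumes on nuisance covariates
#'
#' Replaces every region column by the residuals of an ordinary
#' least-squares fit on the named covariates plus an intercept — the
#' standard way age and sex are "entered as covariates" before computing
#' across-subject structural covariance. With an empty covariate list the
#' volumes are simply mean-centred. Constant covariates are dropped with
#' a warning. Residual means are zero to numerical precision, and
#' residualizing twice equals residualizing once.
#'
#' @param table a volume table.
#' @param covariates character vector of covariate column names
#'   (default `c("age", "sex")`).
#' @return the volume table with residualized region columns.
#' @export
residualize <- function(table, covariates = c("age", "sex")) {
  Y <- .region_matrix(table)
  n <- nrow(Y)
  keep <- character(0)
  for (cv in covariates) {
    if (!cv %in% colnames(table)) stop("covariate not found: ", cv)
    x <- as.numeric(table[[cv]])
    if (anyNA(x)) stop("missing values in covariate ", cv)
    if (stats::var(x) == 0) {
      warning("dropping constant covariate ", cv)
    } else keep <- c(keep, cv)
  }
  if (length(keep) + 1L > n) {
    stop("more covariates (plus intercept) than subjects")
  }
  X <- cbind(`(Intercept)` = rep(1, n))
  for (cv in keep) X <- cbind(X, as.numeric(table[[cv]]))
  res <- stats::lm.fit(X, Y)$residuals
  out <- table
  out[, region_names(table)] <- res
  out
}

#' Build a group's structural covariance network
#'
#' Computes the Pearson correlation between every pair of regions across
#' the subjects of one group; the regions are the nodes and the
#' correlations are the candidate edges of the group-level network.
#'
#' @param table a volume table for one group (typically residualized with
#'   [residualize()] first).
#' @param group_label optional label stored in the result.
#' @return an object of class `cov_network` with fields `region_names`,
#'   `corr` (symmetric, unit diagonal), `group_label`, `n_subjects`.
#' @export
correlation_network <- function(table, group_label = NULL) {
  Y <- .region_matrix(table)
  if (nrow(Y) < 3L) stop("need at least 3 subjects to correlate regions")
  v <- apply(Y, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance region(s): ",
         paste(colnames(Y)[v == 0], collapse = ", "))
  }
  C <- stats::cor(Y)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  if (is.null(group_label) && "group" %in% colnames(table)) {
    group_label <- paste(unique(table$group), collapse = "+")
  }
  structure(list(region_names = colnames(Y), corr = C,
                 group_label = group_label, n_subjects = nrow(Y)),
            class = "cov_network")
}

#' @export
print.cov_network <- function(x, ...) {
  cat("Structural covariance network (", length(x$region_names),
      " regions, n = ", x$n_subjects,
      if (!is.null(x$group_label)) paste0(", group ", x$group_label),
      ")\n", sep = "")
  invisible(x)
}

# Rank candidate edges: positive correlations only, decreasing r, ties
# broken by lexicographic (row, col) of the upper triangle for
# bit-reproducibility (order() is stable). Implemented on the raw
# correlation matrix in .rank_from_cor (group-comparison.R).
.edge_ranking <- function(net) .rank_from_cor(net$corr)

# Number of edges implied by density d for a network with n nodes.
.k_at_density <- function(d, n) as.integer(round(d * n * (n - 1) / 2))

#' Threshold a covariance network at a target density
#'
#' Keeps the `k = round(d * N(N-1)/2)` most strongly positively correlated
#' region pairs as edges of a binary undirected graph. Negative
#' correlations are never edges; ties at the cutoff are broken by
#' lexicographic (row, col) order so results are identical across runs.
#'
#' @param net a [correlation_network()].
#' @param d target density in (0, 1].
#' @return binary symmetric adjacency matrix with zero diagonal and
#'   region names as dimnames.
#' @export
binarize_at_density <- function(net, d) {
  stopifnot(inherits(net, "cov_network"), d > 0, d <= 1)
  n <- length(net$region_names)
  rk <- .edge_ranking(net)
  k <- .k_at_density(d, n)
  if (k == 0L) stop("density ", d, " implies zero edges")
  if (k > nrow(rk$pairs)) {
    stop("density ", d, " requires ", k, " edges but only ",
         nrow(rk$pairs), " positive correlations exist ",
         "(maximum achievable density ",
         signif(nrow(rk$pairs) / rk$n_possible, 4), ")")
  }
  A <- matrix(0, n, n, dimnames = list(net$region_names, net$region_names))
  sel <- rk$pairs[seq_len(k), , drop = FALSE]
  A[sel] <- 1
  A[sel[, 2:1, drop = FALSE]] <- 1
  A
}

# Connectivity of a binary adjacency matrix via vectorized frontier
# expansion (all nodes reachable from node 1).
.is_connected_adj <- function(A) {
  n <- nrow(A)
  if (n == 1L) return(TRUE)
  reached <- logical(n)
  reached[1L] <- TRUE
  frontier <- reached
  while (any(frontier)) {
    nxt <- (colSums(A[frontier, , drop = FALSE]) > 0) & !reached
    reached <- reached | nxt
    frontier <- nxt
  }
  all(reached)
}

#' Minimum density with full connectivity
#'
#' The smallest density on the grid at which the binarized graph of
#' *every* supplied network forms a single connected component spanning
#' all regions. Comparisons across groups are run from this density
#' upwards so that path-based measures are defined everywhere.
#'
#' @param nets a `cov_network` or list of them.
#' @param grid_step density grid step (default 0.01).
#' @param d_max upper density bound searched (default 0.5).
#' @return the minimum full-connectivity density d_min.
#' @export
min_connectivity_density <- function(nets, grid_step = 0.01, d_max = 0.5) {
  if (inherits(nets, "cov_network")) nets <- list(nets)
  stopifnot(length(nets) >= 1L)
  .d_min_from_cors(lapply(nets, function(x) x$corr), grid_step, d_max)
}

.d_min_from_cors <- function(cors, grid_step, d_max) {
  grid <- .round_grid(seq(grid_step, d_max, by = grid_step))
  rks <- lapply(cors, .rank_from_cor)
  n <- nrow(cors[[1]])
  for (d in grid) {
    k <- .k_at_density(d, n)
    if (k == 0L) next
    ok <- TRUE
    for (rk in rks) {
      if (k > nrow(rk$pairs)) { ok <- FALSE; break }
      A <- matrix(0, n, n)
      sel <- rk$pairs[seq_len(k), , drop = FALSE]
      A[sel] <- 1
      A[sel[, 2:1, drop = FALSE]] <- 1
      if (!.is_connected_adj(A)) { ok <- FALSE; break }
    }
    if (ok) return(d)
  }
  stop("no grid density <= ", d_max,
       " yields full connectivity for all supplied networks")
}

#' Binarize a network over a density grid
#'
#' Evaluates [binarize_at_density()] at every grid density from `d_min`
#' to `d_max`. Because edges are ranked once, the edge sets are nested:
#' every edge present at a density is present at all higher densities.
#'
#' @param net a [correlation_network()].
#' @param d_min lower density bound (see [min_connectivity_density()]).
#' @param d_max upper density bound (default 0.5).
#' @param grid_step grid step (default 0.01).
#' @return an object of class `density_profile`: list with `density_grid`,
#'   `adjacency` (list of binary matrices), `d_min`, `region_names`.
#' @export
build_profile <- function(net, d_min, d_max = 0.5, grid_step = 0.01) {
  stopifnot(inherits(net, "cov_network"), d_min <= d_max)
  grid <- .round_grid(seq(d_min, d_max, by = grid_step))
  adj <- lapply(grid, function(d) binarize_at_density(net, d))
  structure(list(density_grid = grid, adjacency = adj, d_min = d_min,
                 region_names = net$region_names),
            class = "density_profile")
}

#' Write a correlation matrix as square TSV
#'
#' @param net a [correlation_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_tsv <- function(net, path) {
  df <- data.frame(region = net$region_names, net$corr,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a density profile as an edge list
#'
#' Three columns: `region_a`, `region_b`, `density_first_present` — the
#' smallest grid density at which the edge appears (edge sets are nested).
#'
#' @param profile a [build_profile()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list_tsv <- function(profile, path) {
  grid <- profile$density_grid
  first <- NULL
  seen <- matrix(FALSE, nrow(profile$adjacency[[1]]),
                 ncol(profile$adjacency[[1]]))
  rows <- list()
  for (i in seq_along(grid)) {
    A <- profile$adjacency[[i]] > 0
    new <- which(A & upper.tri(A) & !seen, arr.ind = TRUE)
    if (nrow(new)) {
      new <- new[order(new[, 1], new[, 2]), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        region_a = profile$region_names[new[, 1]],
        region_b = profile$region_names[new[, 2]],
        density_first_present = grid[i])
    }
    seen <- seen | A
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
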