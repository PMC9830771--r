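# Permutation inference on network measures: cross-sectional
# (group A vs group B) and longitudinal paired (baseline vs follow-up),
# with AUC-over-density summarization and FDR correction over regions.

#' Area under a metric curve across densities
#'
#' Trapezoidal integral of a per-density metric (or metric difference)
#' over the density grid — the threshold-robust summary used for
#' permutation inference. A single-density grid integrates to 0.
#'
#' @param values numeric vector, one value per grid density.
#' @param grid strictly increasing density grid of the same length.
#' @return the trapezoidal integral.
#' @export
auc_over_densities <- function(values, grid) {
  if (length(values) != length(grid)) {
    stop("values and grid must have the same length")
  }
  if (length(grid) > 1L && any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing")
  }
  if (length(grid) < 2L) return(0)
  pracma::trapz(grid, values)
}

#' Randomly relabel subjects across two groups
#'
#' Pools the subjects of both tables and reassigns them uniformly at
#' random to two pseudo-groups of the original sizes. Deterministic given
#' `(seed, i)`, so permutation `i` of a run is always reproducible.
#'
#' @param table_a,table_b volume tables with disjoint subject sets.
#' @param seed master seed of the permutation run.
#' @param i permutation index.
#' @return list with elements `a` and `b`, the relabeled tables.
#' @export
permute_groups <- function(table_a, table_b, seed, i) {
  if (length(intersect(table_a$subject_id, table_b$subject_id)) > 0) {
    stop("subject sets must be disjoint for unpaired permutation")
  }
  pooled <- rbind(table_a, table_b)
  n_a <- nrow(table_a)
  .with_seed(.derive_seed(seed, i), {
    idx <- sample.int(nrow(pooled))
    list(a = pooled[idx[seq_len(n_a)], , drop = FALSE],
         b = pooled[idx[-seq_len(n_a)], , drop = FALSE])
  })
}

#' Randomly swap baseline/follow-up labels within subjects
#'
#' For a paired design the exchangeable unit is the subject's pair of
#' timepoints: independently per subject, the baseline and follow-up
#' labels are swapped with probability 1/2. Deterministic given
#' `(seed, i)`.
#'
#' @param paired_table volume table in which every subject has exactly
#'   one `baseline` and one `followup` row.
#' @param seed master seed of the permutation run.
#' @param i permutation index.
#' @return the table with permuted timepoint labels.
#' @export
permute_timepoints <- function(paired_table, seed, i) {
  subj <- unique(paired_table$subject_id)
  for (s in subj) {
    tps <- sort(paired_table$timepoint[paired_table$subject_id == s])
    if (!identical(tps, c("baseline", "followup"))) {
      stop("subject ", s, " does not have exactly one baseline and one ",
           "followup row")
    }
  }
  .with_seed(.derive_seed(seed, i), {
    flip <- stats::runif(length(subj)) < 0.5
    names(flip) <- subj
    out <- paired_table
    swap <- flip[out$subject_id]
    out$timepoint[swap] <- ifelse(
      paired_table$timepoint[swap] == "baseline", "followup", "baseline")
    out
  })
}

# --- fast matrix-level engine -------------------------------------------
# The permutation loop re-runs residualize -> correlate -> threshold ->
# metrics thousands of times, so it operates on plain matrices: Y is the
# subjects x regions volume matrix, X the covariate design (with
# intercept). Row permutation then replaces data.frame relabeling.

.design_matrix <- function(table, covariates) {
  n <- nrow(table)
  X <- matrix(1, n, 1)
  for (cv in covariates) {
    x <- as.numeric(table[[cv]])
    if (stats::var(x) > 0) X <- cbind(X, x)
  }
  X
}

# Residualize on covariates and correlate, matrix in / matrix out.
.res_cor <- function(Y, X) {
  stats::cor(stats::lm.fit(X, Y)$residuals)
}

# Edge ranking straight from a correlation matrix (see .edge_ranking).
.rank_from_cor <- function(C) {
  n <- nrow(C)
  ut <- which(upper.tri(C), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  r <- C[ut]
  pos <- r > 0
  ut <- ut[pos, , drop = FALSE]
  r <- r[pos]
  o <- order(-r)
  list(pairs = ut[o, , drop = FALSE], r = r[o],
       n_possible = n * (n - 1) / 2)
}

# Metric curves over a density grid from a correlation matrix:
# threshold incrementally (edge sets are nested, so edges are only ever
# added as the density grows) and evaluate the requested metrics at
# every density.
.curves_from_cor <- function(C, grid, metrics, region_names = NULL,
                             n_random = 20L, n_swaps_per_edge = 10L,
                             seed = 1L) {
  n <- nrow(C)
  if (is.null(region_names)) region_names <- colnames(C)
  rk <- .rank_from_cor(C)
  navail <- nrow(rk$pairs)
  ng <- length(grid)
  glob_names <- intersect(c("clustering", "path_length", "sigma"), metrics)
  global <- matrix(NA_real_, ng, length(glob_names),
                   dimnames = list(NULL, glob_names))
  btw <- if ("betweenness" %in% metrics) {
    matrix(NA_real_, n, ng, dimnames = list(region_names, NULL))
  } else NULL
  disconnected <- logical(ng)
  A <- matrix(0, n, n, dimnames = list(region_names, region_names))
  kprev <- 0L
  need_C <- any(c("clustering", "sigma") %in% metrics)
  need_L <- any(c("path_length", "sigma") %in% metrics)
  for (gi in seq_len(ng)) {
    k <- .k_at_density(grid[gi], n)
    if (k > navail) {
      # replicate cannot reach this density with positive correlations;
      # cap at all available edges and flag
      k <- navail
      disconnected[gi] <- TRUE
    }
    if (k > kprev) {
      sel <- rk$pairs[(kprev + 1L):k, , drop = FALSE]
      A[sel] <- 1
      A[sel[, 2:1, drop = FALSE]] <- 1
      kprev <- k
    }
    if (need_C) cc <- .cc_mean(A)
    if (need_L) {
      pl <- characteristic_path_length(A)
      if (pl$disconnected) disconnected[gi] <- TRUE
    }
    if ("clustering" %in% metrics) global[gi, "clustering"] <- cc
    if ("path_length" %in% metrics) global[gi, "path_length"] <- pl$L
    if ("sigma" %in% metrics) {
      rr <- random_reference(A, n_random = n_random,
                             n_swaps_per_edge = n_swaps_per_edge,
                             seed = .derive_seed(seed, gi))
      global[gi, "sigma"] <- small_world_index(cc, pl$L, rr$C_rand,
                                               rr$L_rand)
    }
    if (!is.null(btw)) btw[, gi] <- betweenness_centrality(A)
  }
  list(global = global, betweenness = btw, disconnected = disconnected)
}

# AUC differences (a minus b) for all requested metrics.
.auc_diffs <- function(curves_a, curves_b, grid) {
  glob <- NULL
  gn <- colnames(curves_a$global)
  if (length(gn)) {
    glob <- vapply(gn, function(m) {
      auc_over_densities(curves_a$global[, m] - curves_b$global[, m], grid)
    }, numeric(1))
  }
  btw <- NULL
  if (!is.null(curves_a$betweenness)) {
    d <- curves_a$betweenness - curves_b$betweenness
    btw <- apply(d, 1, auc_over_densities, grid = grid)
  }
  list(global = glob, betweenness = btw,
       disconnected = any(curves_a$disconnected) ||
         any(curves_b$disconnected))
}

#' Permutation comparison of network metrics between two groups
#'
#' The group-level network is a property of the whole group, so the
#' permutation unit is the subject: in every permutation the subjects are
#' relabeled and the *entire* pipeline (residualize on covariates,
#' correlate, threshold over the density grid, compute metrics, integrate
#' differences over densities) is recomputed. Two-tailed p-values use the
#' add-one convention `p = (#{|perm AUC diff| >= |observed|} + 1) /
#' (n_perm + 1)`, and per-region betweenness p-values are
#' Benjamini-Hochberg adjusted across regions (global metrics are not
#' pooled with the regional tests).
#'
#' For the paired (longitudinal) design, `table_a` and `table_b` must
#' hold the same subjects at baseline and follow-up, and permutation
#' swaps the two timepoint labels independently per subject.
#'
#' The minimum full-connectivity density `d_min` is determined from the
#' observed pair of networks and reused in every replicate; a replicate
#' whose graph disconnects is flagged and its path length taken on the
#' largest component. Set `recompute_d_min = TRUE` to instead determine
#' `d_min` within each replicate.
#'
#' @param table_a,table_b volume tables for the two conditions.
#' @param covariates nuisance covariates to residualize out.
#' @param metrics any of `"clustering"`, `"path_length"`, `"sigma"`,
#'   `"betweenness"`.
#' @param n_perm number of permutations (default 1000).
#' @param paired if `TRUE`, within-subject timepoint-swapping permutation.
#' @param seed master seed; fixes the whole comparison bit-for-bit.
#' @param grid_step,d_max density grid parameters.
#' @param d_min lower density bound; determined from the observed
#'   networks when `NULL`.
#' @param n_random,n_swaps_per_edge random-reference settings (only used
#'   when `"sigma"` is requested).
#' @param recompute_d_min recompute d_min inside each replicate.
#' @param alpha significance level recorded in the output (default 0.05).
#' @return an object of class `scnet_comparison`; see Details.
#' @export
compare_metrics <- function(table_a, table_b,
                            covariates = c("age", "sex"),
                            metrics = c("clustering", "path_length",
                                        "betweenness"),
                            n_perm = 1000L, paired = FALSE, seed = 1L,
                            grid_step = 0.01, d_max = 0.5, d_min = NULL,
                            n_random = 20L, n_swaps_per_edge = 10L,
                            recompute_d_min = FALSE, alpha = 0.05) {
  metrics <- match.arg(metrics, c("clustering", "path_length", "sigma",
                                  "betweenness"), several.ok = TRUE)
  regs_a <- region_names(table_a)
  if (!identical(regs_a, region_names(table_b))) {
    stop("the two tables must share the same region set (same order)")
  }
  if (paired) {
    if (!setequal(table_a$subject_id, table_b$subject_id)) {
      stop("paired comparison requires identical subject sets")
    }
    # align follow-up rows to baseline subject order
    table_b <- table_b[match(table_a$subject_id, table_b$subject_id), ,
                       drop = FALSE]
  } else if (length(intersect(table_a$subject_id, table_b$subject_id))) {
    stop("subject sets must be disjoint for an unpaired comparison")
  }
  net_a <- correlation_network(residualize(table_a, covariates))
  net_b <- correlation_network(residualize(table_b, covariates))
  if (is.null(d_min)) {
    d_min <- min_connectivity_density(list(net_a, net_b),
                                      grid_step = grid_step, d_max = d_max)
  }
  grid <- .round_grid(seq(d_min, d_max, by = grid_step))
  regs <- net_a$region_names
  curves_a <- .curves_from_cor(net_a$corr, grid, metrics, regs, n_random,
                               n_swaps_per_edge, .derive_seed(seed, 0L))
  curves_b <- .curves_from_cor(net_b$corr, grid, metrics, regs, n_random,
                               n_swaps_per_edge, .derive_seed(seed, 0L))
  obs <- .auc_diffs(curves_a, curves_b, grid)

  # matrix representation for the permutation loop
  Y_a <- .region_matrix(table_a)
  Y_b <- .region_matrix(table_b)
  X_a <- .design_matrix(table_a, covariates)
  X_b <- .design_matrix(table_b, covariates)
  n_a <- nrow(Y_a)
  if (!paired) {
    Y_pool <- rbind(Y_a, Y_b)
    X_pool <- rbind(X_a, X_b)
  }

  gn <- names(obs$global)
  perm_global <- matrix(NA_real_, n_perm, length(gn),
                        dimnames = list(NULL, gn))
  perm_btw <- if (!is.null(obs$betweenness)) {
    matrix(NA_real_, n_perm, length(obs$betweenness),
           dimnames = list(NULL, names(obs$betweenness)))
  } else NULL
  n_disc <- 0L
  for (i in seq_len(n_perm)) {
    if (paired) {
      # swap the two timepoint rows independently per subject
      flip <- .with_seed(.derive_seed(seed, i),
                         stats::runif(n_a) < 0.5)
      rep_Ya <- Y_a; rep_Yb <- Y_b
      rep_Ya[flip, ] <- Y_b[flip, , drop = FALSE]
      rep_Yb[flip, ] <- Y_a[flip, , drop = FALSE]
      C_a <- .res_cor(rep_Ya, X_a)
      C_b <- .res_cor(rep_Yb, X_b)
    } else {
      idx <- .with_seed(.derive_seed(seed, i),
                        sample.int(nrow(Y_pool)))
      ia <- idx[seq_len(n_a)]
      ib <- idx[-seq_len(n_a)]
      C_a <- .res_cor(Y_pool[ia, , drop = FALSE],
                      X_pool[ia, , drop = FALSE])
      C_b <- .res_cor(Y_pool[ib, , drop = FALSE],
                      X_pool[ib, , drop = FALSE])
    }
    g_i <- grid
    if (recompute_d_min) {
      dm <- .d_min_from_cors(list(C_a, C_b), grid_step, d_max)
      g_i <- .round_grid(seq(dm, d_max, by = grid_step))
    }
    ca <- .curves_from_cor(C_a, g_i, metrics, regs, n_random,
                           n_swaps_per_edge, .derive_seed(seed, i))
    cb <- .curves_from_cor(C_b, g_i, metrics, regs, n_random,
                           n_swaps_per_edge, .derive_seed(seed, i))
    di <- .auc_diffs(ca, cb, g_i)
    if (di$disconnected) n_disc <- n_disc + 1L
    if (length(gn)) perm_global[i, ] <- di$global
    if (!is.null(perm_btw)) perm_btw[i, ] <- di$betweenness
  }

  perm_p <- function(observed, perms) {
    (sum(abs(perms) >= abs(observed)) + 1) / (n_perm + 1)
  }
  global_df <- NULL
  if (length(gn)) {
    global_df <- data.frame(
      metric = gn,
      observed_auc_diff = unname(obs$global),
      p = vapply(gn, function(m) perm_p(obs$global[[m]], perm_global[, m]),
                 numeric(1)),
      row.names = NULL)
  }
  btw_df <- NULL
  if (!is.null(obs$betweenness)) {
    p <- vapply(seq_along(obs$betweenness), function(j) {
      perm_p(obs$betweenness[[j]], perm_btw[, j])
    }, numeric(1))
    q <- fdr_adjust(p)
    btw_df <- data.frame(region = names(obs$betweenness),
                         observed_auc_diff = unname(obs$betweenness),
                         p = p, q = q,
                         significant = q < alpha,
                         row.names = NULL)
  }
  structure(list(global = global_df, betweenness = btw_df,
                 perm_global = perm_global, perm_betweenness = perm_btw,
                 d_min = d_min, grid = grid, grid_step = grid_step,
                 d_max = d_max, n_perm = n_perm, seed = seed,
                 paired = paired, covariates = covariates,
                 metrics = metrics, alpha = alpha,
                 n_disconnected_replicates = n_disc,
                 observed_disconnected = obs$disconnected),
            class = "scnet_comparison")
}

#' @export
print.scnet_comparison <- function(x, ...) {
  cat("Permutation network comparison (",
      if (x$paired) "paired" else "unpaired",
      ", n_perm = ", x$n_perm, ", densities [", x$d_min, ", ", x$d_max,
      "] step ", x$grid_step, ")\n", sep = "")
  if (!is.null(x$global)) {
    cat("\nGlobal metrics (AUC differences):\n")
    print(x$global, row.names = FALSE)
  }
  if (!is.null(x$betweenness)) {
    sig <- x$betweenness[x$betweenness$significant, , drop = FALSE]
    cat("\nRegional betweenness: ", nrow(sig), " of ",
        nrow(x$betweenness), " regions with q < ", x$alpha, "\n", sep = "")
    if (nrow(sig)) print(sig, row.names = FALSE)
  }
  if (x$n_disconnected_replicates > 0) {
    cat("\n", x$n_disconnected_replicates,
        " replicate(s) disconnected at some density",
        " (largest-component convention applied)\n", sep = "")
  }
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, capped at 1 with monotonicity enforced.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
fdr_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
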