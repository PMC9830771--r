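test_that("residualize matches the closed-form normal-equation solution", {
  set.seed(1)
  Y <- matrix(rnorm(15), 5, 3)
  age <- c(21, 34, 28, 45, 39)
  sex <- c(0, 1, 0, 1, 1)
  tab <- table_from_matrix(Y, age = age, sex = sex)
  out <- residualize(tab, c("age", "sex"))
  X <- cbind(1, age, sex)
  beta <- solve(t(X) %*% X, t(X) %*% Y)   # explicit normal equations
  expect_equal(as.matrix(out[, region_names(out)]), Y - X %*% beta,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(as.matrix(out[, region_names(out)])))), 1e-10)
})

test_that("residualization is idempotent and orthogonal to covariates", {
  set.seed(2)
  n <- 30
  age <- rnorm(n, 30, 5)
  Y <- cbind(2 * age + rnorm(n), rnorm(n), rnorm(n, 10))
  tab <- table_from_matrix(Y, age = age)
  r1 <- residualize(tab, c("age", "sex"))
  r2 <- residualize(r1, c("age", "sex"))
  expect_equal(as.matrix(r1[, region_names(r1)]),
               as.matrix(r2[, region_names(r2)]), tolerance = 1e-10)
  expect_lt(abs(cor(r1[[region_names(r1)[1]]], age)), 1e-10)
})

test_that("residualize handles empty, constant and excess covariates", {
  set.seed(3)
  Y <- matrix(rnorm(20), 5, 4)
  tab <- table_from_matrix(Y)
  out <- residualize(tab, character(0))
  expect_equal(as.matrix(out[, region_names(out)]),
               scale(Y, scale = FALSE), tolerance = 1e-12,
               ignore_attr = TRUE)
  tab$sex <- 1  # constant
  expect_warning(residualize(tab, c("age", "sex")), "constant covariate")
  tab3 <- table_from_matrix(matrix(rnorm(6), 2, 3))
  expect_error(residualize(tab3, c("age", "sex")), "more covariates")
})

test_that("correlation network matches the product-moment formula by hand", {
  Y <- cbind(a = c(1, 2, 4, 7), b = c(2, 1, 5, 6), c = c(9, 6, 4, 1))
  tab <- table_from_matrix(Y)
  net <- correlation_network(tab)
  hand <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(net$corr["a", "b"], hand(Y[, "a"], Y[, "b"]), tolerance = 1e-12)
  expect_equal(net$corr["a", "c"], hand(Y[, "a"], Y[, "c"]), tolerance = 1e-12)
  expect_equal(net$corr["b", "c"], hand(Y[, "b"], Y[, "c"]), tolerance = 1e-12)
  expect_identical(diag(net$corr), setNames(rep(1, 3), c("a", "b", "c")))
  expect_equal(net$corr, t(net$corr))
  expect_equal(net$n_subjects, 4L)
})

test_that("duplicated and negated regions give correlations +1 and -1", {
  set.seed(4)
  x <- rnorm(10)
  Y <- cbind(r1 = x, r2 = x, r3 = -x + 0, r4 = rnorm(10))
  net <- correlation_network(table_from_matrix(Y))
  expect_equal(net$corr["r1", "r2"], 1)
  expect_equal(net$corr["r1", "r3"], -1)
})

test_that("correlation network rejects degenerate inputs", {
  Y <- cbind(a = c(1, 1, 1, 1), b = rnorm(4))
  expect_error(correlation_network(table_from_matrix(Y)),
               "zero-variance region.*a")
  expect_error(correlation_network(table_from_matrix(matrix(rnorm(4), 2, 2))),
               "at least 3 subjects")
})

test_that("binarize_at_density keeps exactly the top-k positive pairs", {
  # N = 4: rank the 6 pairs by hand
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 0.9
  C[1, 3] <- C[3, 1] <- 0.7
  C[2, 3] <- C[3, 2] <- 0.5
  C[1, 4] <- C[4, 1] <- 0.3
  C[2, 4] <- C[4, 2] <- -0.2
  C[3, 4] <- C[4, 3] <- 0.1
  rn <- c("w", "x", "y", "z")
  dimnames(C) <- list(rn, rn)
  net <- structure(list(region_names = rn, corr = C, group_label = NULL,
                        n_subjects = 10L), class = "cov_network")
  A <- binarize_at_density(net, 0.5)  # k = 3: pairs (1,2), (1,3), (2,3)
  expect_equal(sum(A) / 2, 3)
  expect_equal(A["w", "x"], 1)
  expect_equal(A["w", "y"], 1)
  expect_equal(A["x", "y"], 1)
  expect_equal(A["w", "z"], 0)
  # full density on all-positive correlations: complete graph
  Cp <- abs(C); diag(Cp) <- 1
  netp <- structure(list(region_names = rn, corr = Cp, group_label = NULL,
                         n_subjects = 10L), class = "cov_network")
  Ap <- binarize_at_density(netp, 1)
  expect_true(all(Ap[upper.tri(Ap)] == 1))
  expect_true(all(diag(Ap) == 0))
})

test_that("ties at the cutoff break lexicographically and reproducibly", {
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 0.8
  C[1, 3] <- C[3, 1] <- 0.5   # tied
  C[2, 4] <- C[4, 2] <- 0.5   # tied
  C[3, 4] <- C[4, 3] <- 0.2
  C[1, 4] <- C[4, 1] <- 0.1
  C[2, 3] <- C[3, 2] <- 0.05
  dimnames(C) <- list(letters[1:4], letters[1:4])
  net <- structure(list(region_names = letters[1:4], corr = C,
                        group_label = NULL, n_subjects = 10L),
                   class = "cov_network")
  A1 <- binarize_at_density(net, 2 / 6)  # k = 2: (1,2) then tie -> (1,3)
  expect_equal(A1["a", "c"], 1)
  expect_equal(A1["b", "d"], 0)
  expect_identical(A1, binarize_at_density(net, 2 / 6))
})

test_that("binarize_at_density reports impossible densities", {
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- 0.5
  C[1, 3] <- C[3, 1] <- -0.4
  C[2, 3] <- C[3, 2] <- -0.6
  dimnames(C) <- list(letters[1:3], letters[1:3])
  net <- structure(list(region_names = letters[1:3], corr = C,
                        group_label = NULL, n_subjects = 10L),
                   class = "cov_network")
  expect_error(binarize_at_density(net, 0.05), "zero edges")
  expect_error(binarize_at_density(net, 1), "maximum achievable density")
})

test_that("correlation network is invariant to positive affine rescaling", {
  set.seed(6)
  Y <- matrix(rnorm(60), 12, 5)
  tab1 <- table_from_matrix(Y)
  Y2 <- sweep(sweep(Y, 2, c(2, 0.5, 3, 10, 1.3), "*"), 2,
              c(1, -4, 0, 2, 7), "+")
  tab2 <- table_from_matrix(Y2)
  n1 <- correlation_network(tab1)
  n2 <- correlation_network(tab2)
  expect_equal(n1$corr, n2$corr, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("min_connectivity_density agrees with a brute-force scan", {
  set.seed(7)
  spec <- synthetic_spec(n_regions = 15, n_subjects_per_group = 25,
                         seed = 77)
  tab <- generate_cohort(spec)
  net <- correlation_network(residualize(tab[tab$group == "control", ]))
  d_min <- min_connectivity_density(net, grid_step = 0.01)
  # oracle: scan the same grid, binarize independently, BFS connectivity
  grid <- round(seq(0.01, 0.5, by = 0.01), 10)
  oracle <- NA
  for (d in grid) {
    k <- round(d * 15 * 14 / 2)
    if (k == 0) next
    A <- try(binarize_at_density(net, d), silent = TRUE)
    if (inherits(A, "try-error")) next
    if (bf_connected(A)) { oracle <- d; break }
  }
  expect_equal(d_min, oracle)
})

test_that("a star-structured network connects exactly at k = N - 1", {
  n <- 10
  C <- matrix(0.01, n, n)
  C[1, ] <- C[, 1] <- seq(0.9, 0.82, length.out = n)[seq_len(n)]
  diag(C) <- 1
  rn <- sprintf("s%02d", 1:n)
  dimnames(C) <- list(rn, rn)
  net <- structure(list(region_names = rn, corr = C, group_label = NULL,
                        n_subjects = 20L), class = "cov_network")
  d_min <- min_connectivity_density(net, grid_step = 0.01)
  k_min <- round(d_min * n * (n - 1) / 2)
  expect_equal(k_min, n - 1)
  # one grid step below must be disconnected
  prev <- round(d_min - 0.01, 10)
  if (round(prev * n * (n - 1) / 2) >= 1) {
    expect_false(bf_connected(binarize_at_density(net, prev)))
  }
})

test_that("joint d_min over two groups is the max of the individual minima", {
  set.seed(8)
  spec <- synthetic_spec(n_regions = 12, n_subjects_per_group = 20, seed = 5)
  tab <- generate_cohort(spec)
  na <- correlation_network(residualize(tab[tab$group == "control", ]))
  nb <- correlation_network(residualize(tab[tab$group == "patient", ]))
  expect_equal(min_connectivity_density(list(na, nb)),
               max(min_connectivity_density(na),
                   min_connectivity_density(nb)))
})

test_that("density profiles have the right grid and nested edge sets", {
  set.seed(9)
  spec <- synthetic_spec(n_regions = 14, n_subjects_per_group = 30, seed = 3)
  tab <- generate_cohort(spec)
  net <- correlation_network(residualize(tab[tab$group == "patient", ]))
  prof <- build_profile(net, d_min = 0.1, d_max = 0.5, grid_step = 0.01)
  expect_length(prof$density_grid, 41)
  for (i in seq_along(prof$density_grid)) {
    A <- prof$adjacency[[i]]
    k <- round(prof$density_grid[i] * 14 * 13 / 2)
    expect_equal(sum(A) / 2, k)
    if (i > 1) {
      expect_true(all(A[prof$adjacency[[i - 1]] == 1] == 1))
    }
  }
  single <- build_profile(net, d_min = 0.3, d_max = 0.3)
  expect_length(single$density_grid, 1)
})
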