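test_that("AUC over densities: constants, ramps, and a refinement oracle", {
  grid <- round(seq(0.1, 0.5, by = 0.01), 10)
  expect_equal(auc_over_densities(rep(3, length(grid)), grid), 3 * 0.4,
               tolerance = 1e-12)
  ramp_grid <- round(seq(0, 1, by = 0.01), 10)
  expect_equal(auc_over_densities(ramp_grid, ramp_grid), 0.5,
               tolerance = 1e-12)
  # trapezoid on a smooth curve matches a fine Riemann sum within step^2
  set.seed(31)
  f <- function(x) sin(7 * x) + 0.5 * x^2
  step <- 0.01
  coarse <- seq(0.1, 0.5, by = step)
  got <- auc_over_densities(f(coarse), coarse)
  fine <- seq(0.1, 0.5, by = 1e-5)
  riemann <- sum(f(fine[-1]) + f(fine[-length(fine)])) / 2 * 1e-5
  expect_lt(abs(got - riemann), step^2)
  expect_error(auc_over_densities(1:3, c(0.1, 0.2)), "same length")
  expect_error(auc_over_densities(1:3, c(0.1, 0.3, 0.2)), "increasing")
  expect_equal(auc_over_densities(5, 0.3), 0)
})

test_that("group permutation preserves sizes, is seeded, and is uniform", {
  spec <- synthetic_spec(n_regions = 6, n_subjects_per_group = 12, seed = 8)
  tab <- generate_cohort(spec)
  a <- tab[tab$group == "control", ]
  b <- tab[tab$group == "patient", ]
  b2 <- b[1:8, ]  # unequal sizes
  counts <- setNames(numeric(12 + 8), c(a$subject_id, b2$subject_id))
  for (i in 1:400) {
    p <- permute_groups(a, b2, seed = 5, i = i)
    expect_equal(nrow(p$a), 12)
    expect_equal(nrow(p$b), 8)
    expect_length(intersect(p$a$subject_id, p$b$subject_id), 0)
    counts[p$a$subject_id] <- counts[p$a$subject_id] + 1
  }
  # each subject lands in pseudo-group A with frequency ~ 12/20
  expect_true(all(abs(counts / 400 - 12 / 20) < 0.1))
  expect_identical(permute_groups(a, b2, seed = 5, i = 7),
                   permute_groups(a, b2, seed = 5, i = 7))
  expect_false(identical(permute_groups(a, b2, seed = 5, i = 7),
                         permute_groups(a, b2, seed = 5, i = 8)))
  expect_error(permute_groups(a, a, seed = 1, i = 1), "disjoint")
})

test_that("timepoint permutation swaps within subjects only", {
  spec <- synthetic_spec(n_regions = 5, n_subjects_per_group = 4,
                         longitudinal = TRUE, seed = 3)
  tab <- generate_cohort(spec)
  tab <- tab[tab$group == "control", ]
  n_sub <- length(unique(tab$subject_id))
  seen_all_swap <- seen_no_swap <- FALSE
  for (i in 1:200) {
    pt <- permute_timepoints(tab, seed = 2, i = i)
    tp <- table(pt$subject_id, pt$timepoint)
    expect_true(all(tp == 1))  # each subject keeps one row per label
    n_flipped <- sum(pt$timepoint != tab$timepoint) / 2
    if (n_flipped == n_sub) seen_all_swap <- TRUE
    if (n_flipped == 0) seen_no_swap <- TRUE
  }
  expect_true(seen_all_swap)  # with 4 subjects both extremes are reachable
  expect_true(seen_no_swap)
  expect_error(permute_timepoints(tab[-1, ], seed = 1, i = 1),
               "does not have exactly one baseline")
})

test_that("identical paired tables give zero differences and p = 1", {
  spec <- synthetic_spec(n_regions = 12, n_subjects_per_group = 15, seed = 4)
  tab <- generate_cohort(spec)
  a <- tab[tab$group == "control", ]
  cmp <- compare_metrics(a, a, metrics = c("clustering", "path_length",
                                           "betweenness"),
                         n_perm = 30, paired = TRUE, seed = 6)
  expect_equal(cmp$global$observed_auc_diff, c(0, 0), tolerance = 1e-14)
  expect_equal(cmp$global$p, c(1, 1))
  expect_equal(cmp$betweenness$observed_auc_diff,
               rep(0, nrow(cmp$betweenness)), tolerance = 1e-14)
  expect_equal(cmp$betweenness$p, rep(1, nrow(cmp$betweenness)))
})

test_that("p-values live on the permutation grid and are seed-reproducible", {
  spec <- synthetic_spec(n_regions = 10, n_subjects_per_group = 12, seed = 13)
  tab <- generate_cohort(spec)
  a <- tab[tab$group == "control", ]
  b <- tab[tab$group == "patient", ]
  n_perm <- 40
  cmp1 <- compare_metrics(a, b, metrics = "clustering", n_perm = n_perm,
                          seed = 11)
  cmp2 <- compare_metrics(a, b, metrics = "clustering", n_perm = n_perm,
                          seed = 11)
  expect_identical(cmp1, cmp2)
  expect_gte(cmp1$global$p, 1 / (n_perm + 1))
  expect_lte(cmp1$global$p, 1)
  # p equals its defining formula applied to the stored permutation draws
  expect_equal(cmp1$global$p,
               (sum(abs(cmp1$perm_global[, "clustering"]) >=
                      abs(cmp1$global$observed_auc_diff)) + 1) / (n_perm + 1))
})

test_that("paired p-values are invariant to which condition is called A", {
  spec <- synthetic_spec(n_regions = 10, n_subjects_per_group = 14,
                         longitudinal = TRUE, followup_change = -0.01,
                         seed = 19)
  tab <- generate_cohort(spec)
  g <- tab[tab$group == "patient", ]
  base <- g[g$timepoint == "baseline", ]
  fup <- g[g$timepoint == "followup", ]
  c_ab <- compare_metrics(base, fup, metrics = c("clustering",
                                                 "betweenness"),
                          n_perm = 60, paired = TRUE, seed = 23)
  c_ba <- compare_metrics(fup, base, metrics = c("clustering",
                                                 "betweenness"),
                          n_perm = 60, paired = TRUE, seed = 23)
  expect_equal(c_ab$global$observed_auc_diff,
               -c_ba$global$observed_auc_diff, tolerance = 1e-12)
  expect_equal(c_ab$global$p, c_ba$global$p)
  expect_equal(c_ab$betweenness$p, c_ba$betweenness$p)
})

test_that("betweenness q-values are BH-consistent with the raw p-values", {
  spec <- synthetic_spec(n_regions = 12, n_subjects_per_group = 12, seed = 29)
  tab <- generate_cohort(spec)
  cmp <- compare_metrics(tab[tab$group == "control", ],
                         tab[tab$group == "patient", ],
                         metrics = "betweenness", n_perm = 25, seed = 31)
  expect_equal(cmp$betweenness$q, p.adjust(cmp$betweenness$p, "BH"))
  expect_true(all(cmp$betweenness$q >= cmp$betweenness$p))
  o <- order(cmp$betweenness$p)
  expect_true(all(diff(cmp$betweenness$q[o]) >= -1e-15))
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(0.03, 5)), rep(0.03, 5))
  # step-up by hand: q_i = min over k >= i of m * p_(k) / k
  p <- c(0.01, 0.02, 0.03, 0.5)
  hand <- rev(cummin(rev(4 * p / 1:4)))
  expect_equal(hand, c(0.04, 0.04, 0.04, 0.5), tolerance = 1e-12)
  expect_equal(fdr_adjust(p), hand, tolerance = 1e-12)
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_adjust(c(0.1, -0.2)), "\\[0, 1\\]")
})
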