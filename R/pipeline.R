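# Orchestration: run configuration, NSS subgroup assignment, the
# cross-sectional and longitudinal experiments, and TSV/JSON reporting.

#' Run configuration
#'
#' Collects every tunable of an analysis run. The defaults reproduce the
#' standard settings of grey-matter covariance studies: density upper
#' bound 0.5, 1000 permutations, 20 random reference graphs.
#'
#' @param covariates nuisance covariates residualized out of the volumes.
#' @param grid_step density grid step.
#' @param d_max upper density bound.
#' @param n_perm number of permutations.
#' @param n_random random reference graphs per density (sigma only).
#' @param n_swaps_per_edge attempted swaps per edge when rewiring.
#' @param metrics metrics to compare; see [compare_metrics()].
#' @param alpha significance level for FDR-corrected maps.
#' @param seed master seed; every source of randomness in the run flows
#'   from it.
#' @param output_dir optional directory for TSV/JSON reports.
#' @return a `run_config` list.
#' @export
run_config <- function(covariates = c("age", "sex"), grid_step = 0.01,
                       d_max = 0.5, n_perm = 1000L, n_random = 20L,
                       n_swaps_per_edge = 10L,
                       metrics = c("clustering", "path_length",
                                   "betweenness"),
                       alpha = 0.05, seed = 1L, output_dir = NULL) {
  stopifnot(grid_step > 0, d_max > 0, d_max <= 1, n_perm >= 1,
            n_random >= 1, alpha > 0, alpha < 1)
  structure(list(covariates = covariates, grid_step = grid_step,
                 d_max = d_max, n_perm = as.integer(n_perm),
                 n_random = as.integer(n_random),
                 n_swaps_per_edge = as.integer(n_swaps_per_edge),
                 metrics = metrics, alpha = alpha,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Split patients into NSS-persisting and NSS-decreasing subgroups
#'
#' Dichotomizes subjects by the change of their total neurological
#' soft-sign (NSS) score: change = baseline - follow-up; subjects whose
#' change exceeds the sample mean change form the `decreasing` subgroup,
#' the rest the `persisting` subgroup.
#'
#' @param nss data.frame with columns `subject_id`, `nss_baseline`,
#'   `nss_followup`.
#' @return data.frame with `subject_id`, `change`, `subgroup`.
#' @export
assign_nss_subgroups <- function(nss) {
  req <- c("subject_id", "nss_baseline", "nss_followup")
  if (!all(req %in% colnames(nss))) {
    stop("nss table needs columns: ", paste(req, collapse = ", "))
  }
  miss <- nss$subject_id[is.na(nss$nss_baseline) | is.na(nss$nss_followup)]
  if (length(miss)) {
    stop("missing NSS scores for subject(s): ", paste(miss, collapse = ", "))
  }
  change <- nss$nss_baseline - nss$nss_followup
  if (stats::var(change) == 0) {
    stop("all subjects have identical NSS change; the mean-change split ",
         "is degenerate. Choose a different split rule or inspect the ",
         "scores.")
  }
  subgroup <- ifelse(change > mean(change), "decreasing", "persisting")
  if (length(unique(subgroup)) < 2L) {
    stop("mean-change split produced an empty subgroup")
  }
  data.frame(subject_id = nss$subject_id, change = change,
             subgroup = subgroup, stringsAsFactors = FALSE)
}

# Metadata record stored next to every numeric output so a run can be
# replayed exactly. Deliberately free of timestamps.
.run_metadata <- function(config, d_min, extra = list()) {
  c(list(seed = config$seed, n_perm = config$n_perm,
         grid_step = config$grid_step, d_max = config$d_max,
         d_min = d_min, n_random = config$n_random,
         n_swaps_per_edge = config$n_swaps_per_edge,
         covariates = config$covariates, metrics = config$metrics,
         alpha = config$alpha,
         conventions = list(
           edge_sign = "positive correlations only",
           tie_break = "lexicographic (row, col)",
           p_value = "(exceedances + 1) / (n_perm + 1), two-tailed",
           disconnected = "largest-component path length with flag",
           hub_sd = "population SD, threshold mean + 2 SD",
           fdr = "Benjamini-Hochberg across regions")),
    extra)
}

.write_outputs <- function(dir, prefix, cmp, hubs_list, global_tables,
                           config, meta) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(name) file.path(dir, paste0(prefix, "_", name))
  if (!is.null(cmp$betweenness)) {
    utils::write.table(cmp$betweenness, f("betweenness_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cmp$global)) {
    utils::write.table(cmp$global, f("global_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in names(hubs_list)) {
    h <- hubs_list[[nm]]
    utils::write.table(h, f(paste0("hubs_", nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (nm in names(global_tables)) {
    utils::write.table(global_tables[[nm]],
                       f(paste0("nodal_", nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(meta, f("run_metadata.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}

# Nodal betweenness report for one group at d_min, with hub flags.
.nodal_report <- function(table, covariates, d_min) {
  net <- correlation_network(residualize(table, covariates))
  A <- binarize_at_density(net, d_min)
  b <- betweenness_centrality(A)
  hubs <- identify_hubs(b)
  data.frame(region = names(b), density = d_min, betweenness = unname(b),
             is_hub = names(b) %in% hubs$region)
}

#' Cross-sectional experiment: group A vs group B at one timepoint
#'
#' Runs the full comparison between the two groups of a volume table
#' (residualization, per-group covariance networks, density
#' thresholding from the joint minimum full-connectivity density to
#' `d_max`, metric AUC permutation tests, FDR over regions), and reports
#' each group's nodal betweenness and hub set at the minimum density.
#'
#' @param table volume table holding both groups (one timepoint; if a
#'   `timepoint` column is present only `baseline` rows are used).
#' @param config a [run_config()].
#' @param groups optional length-2 character: which group labels to
#'   compare (default: the two labels present, in sorted order).
#' @return list with `comparison` ([compare_metrics()] result), `nodal`
#'   (per-group betweenness/hub tables), `d_min`, `metadata`.
#' @export
run_cross_sectional <- function(table, config = run_config(),
                                groups = NULL) {
  if ("timepoint" %in% colnames(table)) {
    table <- table[table$timepoint == "baseline" | is.na(table$timepoint), ,
                   drop = FALSE]
  }
  if (is.null(groups)) groups <- sort(unique(table$group))
  stopifnot(length(groups) == 2L)
  tab_a <- table[table$group == groups[1], , drop = FALSE]
  tab_b <- table[table$group == groups[2], , drop = FALSE]
  cmp <- compare_metrics(tab_a, tab_b, covariates = config$covariates,
                         metrics = config$metrics, n_perm = config$n_perm,
                         paired = FALSE, seed = config$seed,
                         grid_step = config$grid_step, d_max = config$d_max,
                         n_random = config$n_random,
                         n_swaps_per_edge = config$n_swaps_per_edge,
                         alpha = config$alpha)
  nodal <- list()
  nodal[[groups[1]]] <- .nodal_report(tab_a, config$covariates, cmp$d_min)
  nodal[[groups[2]]] <- .nodal_report(tab_b, config$covariates, cmp$d_min)
  meta <- .run_metadata(config, cmp$d_min,
                        list(design = "cross-sectional", groups = groups))
  if (!is.null(config$output_dir)) {
    hubs <- lapply(nodal, function(x) x[x$is_hub, c("region", "betweenness")])
    .write_outputs(config$output_dir, "cross_sectional", cmp, hubs, nodal,
                   config, meta)
  }
  list(comparison = cmp, nodal = nodal, d_min = cmp$d_min, metadata = meta)
}

#' Longitudinal experiment: baseline vs follow-up within subgroups
#'
#' For each subgroup of a [assign_nss_subgroups()] assignment (or each
#' group label if no assignment is given), compares baseline against
#' follow-up networks with the paired within-subject permutation scheme
#' and reports hub sets at both timepoints side by side.
#'
#' @param table longitudinal volume table (both timepoints per subject).
#' @param config a [run_config()].
#' @param assignment optional data.frame `subject_id`, `subgroup`
#'   restricting and partitioning the subjects.
#' @return named list per subgroup: `comparison`, `nodal` (baseline and
#'   follow-up), `d_min`, `metadata`.
#' @export
run_longitudinal <- function(table, config = run_config(),
                             assignment = NULL) {
  stopifnot("timepoint" %in% colnames(table))
  if (is.null(assignment)) {
    assignment <- data.frame(subject_id = unique(table$subject_id),
                             subgroup = "all")
  }
  out <- list()
  for (sg in unique(assignment$subgroup)) {
    ids <- assignment$subject_id[assignment$subgroup == sg]
    sub <- table[table$subject_id %in% ids, , drop = FALSE]
    base <- sub[sub$timepoint == "baseline", , drop = FALSE]
    fup <- sub[sub$timepoint == "followup", , drop = FALSE]
    cmp <- compare_metrics(base, fup, covariates = config$covariates,
                           metrics = config$metrics, n_perm = config$n_perm,
                           paired = TRUE, seed = config$seed,
                           grid_step = config$grid_step,
                           d_max = config$d_max,
                           n_random = config$n_random,
                           n_swaps_per_edge = config$n_swaps_per_edge,
                           alpha = config$alpha)
    nodal <- list(
      baseline = .nodal_report(base, config$covariates, cmp$d_min),
      followup = .nodal_report(fup, config$covariates, cmp$d_min))
    meta <- .run_metadata(config, cmp$d_min,
                          list(design = "longitudinal paired",
                               subgroup = sg))
    if (!is.null(config$output_dir)) {
      hubs <- lapply(nodal, function(x)
        x[x$is_hub, c("region", "betweenness")])
      .write_outputs(config$output_dir, paste0("longitudinal_", sg), cmp,
                     hubs, nodal, config, meta)
    }
    out[[sg]] <- list(comparison = cmp, nodal = nodal, d_min = cmp$d_min,
                      metadata = meta)
  }
  out
}
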