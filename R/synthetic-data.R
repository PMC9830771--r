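#' Specify a synthetic grey-matter volume cohort
#'
#' Defines the population model from which [generate_cohort()] draws
#' subjects x regions volume tables. Regional volumes are multivariate
#' normal around a mean of 1.0 (arbitrary units) with a block-structured
#' correlation matrix: regions within a block correlate at `rho_in`,
#' regions in different blocks at `rho_out`, and an optional hub region
#' correlates at `rho_hub` with every other region. Linear age and sex
#' effects are added on top, so that downstream covariate residualization
#' can be exercised. A second group can receive a correlation perturbation
#' on one region (see [implant_group_difference()]), and a paired
#' follow-up timepoint with within-subject correlation `rho_t` can be
#' generated for longitudinal designs.
#'
#' The implied population correlation matrix of every group is validated
#' to be positive semi-definite at construction; a non-PSD
#' parameterization is an error (no silent nearest-PSD repair).
#'
#' @param n_regions number of regions (nodes). Defaults to the 116-region
#'   AAL parcellation.
#' @param n_subjects_per_group subjects per group.
#' @param block_sizes integer vector partitioning the regions into
#'   covariance blocks; must sum to `n_regions`. Default: blocks of 10
#'   (last block takes the remainder).
#' @param rho_in correlation between regions within a block.
#' @param rho_out correlation between regions in different blocks.
#' @param hub_region optional region index whose correlation with every
#'   other region is raised to `rho_hub`.
#' @param rho_hub correlation of the hub region with all others.
#' @param age_slope per-region volume change per year of age (recycled).
#' @param sex_offset per-region volume offset for sex == 1 (recycled).
#' @param group_effect optional `list(region =, delta_rho =)`: additive
#'   perturbation of group 2's population correlations involving `region`.
#' @param longitudinal if `TRUE`, generate paired baseline and follow-up
#'   rows per subject.
#' @param rho_t within-subject (test-retest) correlation of the residual
#'   volume component between timepoints.
#' @param followup_change per-region mean volume change at follow-up
#'   (recycled; only used when `longitudinal = TRUE`).
#' @param noise_sd residual volume standard deviation.
#' @param age_mean,age_sd mean and SD of the simulated age distribution.
#' @param group_labels labels of the two groups.
#' @param region_names optional region names; default AAL labels (first
#'   `n_regions`) when `n_regions <= 116`, otherwise `ROI_###`.
#' @param seed RNG seed; the same spec with the same seed generates a
#'   bit-identical table.
#' @return an object of class `synthetic_spec`.
#' @seealso [generate_cohort()], [implant_group_difference()]
#' @export
synthetic_spec <- function(n_regions = 116L,
                           n_subjects_per_group = 20L,
                           block_sizes = NULL,
                           rho_in = 0.3,
                           rho_out = 0.05,
                           hub_region = NULL,
                           rho_hub = 0.5,
                           age_slope = 0.002,
                           sex_offset = 0.01,
                           group_effect = NULL,
                           longitudinal = FALSE,
                           rho_t = 0.8,
                           followup_change = 0,
                           noise_sd = 0.1,
                           age_mean = 25,
                           age_sd = 4,
                           group_labels = c("control", "patient"),
                           region_names = NULL,
                           seed = 1L) {
  n_regions <- as.integer(n_regions)
  stopifnot(n_regions >= 2L, n_subjects_per_group >= 2L, noise_sd > 0)
  if (is.null(block_sizes)) {
    nb <- n_regions %/% 10L
    if (nb == 0L) block_sizes <- n_regions
    else {
      block_sizes <- rep(10L, nb)
      rem <- n_regions - sum(block_sizes)
      if (rem > 0L) block_sizes <- c(block_sizes, rem)
    }
  }
  if (sum(block_sizes) != n_regions) {
    stop("block_sizes must sum to n_regions")
  }
  for (r in c(rho_in, rho_out, rho_hub, rho_t)) {
    if (r <= -1 || r >= 1) stop("correlation parameters must lie in (-1, 1)")
  }
  if (!is.null(hub_region)) {
    hub_region <- as.integer(hub_region)
    if (hub_region < 1L || hub_region > n_regions) stop("hub_region out of range")
  }
  if (is.null(region_names)) {
    region_names <- if (n_regions <= 116L) aal_region_names(n_regions)
                    else sprintf("ROI_%03d", seq_len(n_regions))
  }
  stopifnot(length(region_names) == n_regions, !anyDuplicated(region_names))
  spec <- structure(list(
    n_regions = n_regions,
    n_subjects_per_group = as.integer(n_subjects_per_group),
    block_sizes = as.integer(block_sizes),
    rho_in = rho_in, rho_out = rho_out,
    hub_region = hub_region, rho_hub = rho_hub,
    age_slope = rep_len(age_slope, n_regions),
    sex_offset = rep_len(sex_offset, n_regions),
    group_effect = group_effect,
    longitudinal = isTRUE(longitudinal),
    rho_t = rho_t,
    followup_change = rep_len(followup_change, n_regions),
    noise_sd = noise_sd,
    age_mean = age_mean, age_sd = age_sd,
    group_labels = group_labels,
    region_names = region_names,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
  # Validate both groups' population correlation matrices eagerly.
  population_correlation(spec, group = 1L)
  population_correlation(spec, group = 2L)
  spec
}

#' Population correlation matrix implied by a synthetic spec
#'
#' @param spec a [synthetic_spec()].
#' @param group 1 or 2; group 2 includes the `group_effect` perturbation.
#' @return the n_regions x n_regions population correlation matrix.
#' @export
population_correlation <- function(spec, group = 1L) {
  n <- spec$n_regions
  block_id <- rep(seq_along(spec$block_sizes), spec$block_sizes)
  same_block <- outer(block_id, block_id, "==")
  R <- ifelse(same_block, spec$rho_in, spec$rho_out)
  if (!is.null(spec$hub_region)) {
    h <- spec$hub_region
    R[h, ] <- spec$rho_hub
    R[, h] <- spec$rho_hub
  }
  diag(R) <- 1
  if (group == 2L && !is.null(spec$group_effect)) {
    ge <- spec$group_effect
    r <- as.integer(ge$region)
    if (r < 1L || r > n) stop("group_effect region out of range")
    R[r, -r] <- R[r, -r] + ge$delta_rho
    R[-r, r] <- R[-r, r] + ge$delta_rho
    if (any(abs(R[r, -r]) >= 1)) {
      stop("group_effect on region ", spec$region_names[r],
           " pushes a correlation outside (-1, 1)")
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    offender <- if (group == 2L && !is.null(spec$group_effect)) {
      paste0("group-2 perturbation on region ",
             spec$region_names[spec$group_effect$region])
    } else {
      paste0("block structure (rho_in = ", spec$rho_in,
             ", rho_out = ", spec$rho_out,
             if (!is.null(spec$hub_region))
               paste0(", rho_hub = ", spec$rho_hub, " on region ",
                      spec$region_names[spec$hub_region]) else "", ")")
    }
    stop("population correlation matrix is not positive semi-definite; ",
         "offending parameterization: ", offender,
         " (min eigenvalue ", signif(min(ev), 4), ")")
  }
  dimnames(R) <- list(spec$region_names, spec$region_names)
  R
}

#' Perturb group 2's correlations involving one region
#'
#' Returns a copy of `spec` in which every population correlation of
#' `target_region` with the other regions is shifted by `delta_rho` in
#' group 2 only, creating a localized between-group covariance difference
#' that downstream betweenness comparisons should recover. The perturbed
#' matrix must remain positive semi-definite, otherwise an error is raised.
#'
#' @param spec a [synthetic_spec()].
#' @param target_region region index (or name) to perturb.
#' @param delta_rho additive correlation shift.
#' @return the modified `synthetic_spec`.
#' @export
implant_group_difference <- function(spec, target_region, delta_rho) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.character(target_region)) {
    target_region <- match(target_region, spec$region_names)
    if (is.na(target_region)) stop("unknown target region")
  }
  if (delta_rho == 0) return(spec)
  spec$group_effect <- list(region = as.integer(target_region),
                            delta_rho = delta_rho)
  population_correlation(spec, group = 2L)  # PSD check, errors if violated
  spec
}

#' Generate a synthetic volume table
#'
#' Draws the cohort defined by a [synthetic_spec()]: for each group,
#' `n_subjects_per_group` subjects with age ~ Normal(age_mean, age_sd),
#' sex balanced 0/1, and regional volumes
#' `1.0 + age_slope * (age - age_mean) + sex_offset * sex + e`, where `e`
#' is multivariate normal with covariance `noise_sd^2 * R_group`. For
#' longitudinal specs each subject additionally receives a follow-up row
#' whose residual component correlates at `rho_t` with baseline and whose
#' mean is shifted by `followup_change`.
#'
#' Volumes are truncated at zero with a warning if a draw ever goes
#' negative (it should not at default noise levels, since grey-matter
#' volumes are positive).
#'
#' @param spec a [synthetic_spec()].
#' @return a data.frame with columns `subject_id`, `group`, `timepoint`,
#'   `age`, `sex`, then one column per region.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_subjects_per_group
    p <- spec$n_regions
    rows <- list()
    sid0 <- 0L
    for (g in 1:2) {
      R <- population_correlation(spec, group = g)
      Sigma <- spec$noise_sd^2 * R
      age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
      sex <- rep_len(c(0L, 1L), n)[sample.int(n)]
      eps <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = Sigma)
      mean_part <- 1.0 +
        outer(age - spec$age_mean, spec$age_slope) +
        outer(sex, spec$sex_offset)
      ids <- sprintf("S%04d", sid0 + seq_len(n))
      sid0 <- sid0 + n
      base <- data.frame(subject_id = ids,
                         group = spec$group_labels[g],
                         timepoint = "baseline",
                         age = age, sex = sex,
                         stringsAsFactors = FALSE)
      vols <- mean_part + eps
      colnames(vols) <- spec$region_names
      rows[[length(rows) + 1L]] <- cbind(base, as.data.frame(vols))
      if (spec$longitudinal) {
        eps2 <- spec$rho_t * eps +
          sqrt(1 - spec$rho_t^2) * MASS::mvrnorm(n, mu = rep(0, p),
                                                 Sigma = Sigma)
        vols2 <- mean_part +
          matrix(spec$followup_change, n, p, byrow = TRUE) + eps2
        colnames(vols2) <- spec$region_names
        fu <- base
        fu$timepoint <- "followup"
        rows[[length(rows) + 1L]] <- cbind(fu, as.data.frame(vols2))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    reg <- region_names(out)
    m <- as.matrix(out[, reg])
    if (any(m < 0)) {
      warning("truncated ", sum(m < 0), " negative volume draw(s) at 0")
      m[m < 0] <- 0
      out[, reg] <- m
    }
    out
  })
}

#' Write a volume table as TSV
#'
#' Fixed column order: `subject_id`, `group`, `timepoint`, `age`, `sex`,
#' then the region columns.
#'
#' @param table a volume table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume_table <- function(table, path) {
  cols <- c(intersect(.meta_cols, colnames(table)), region_names(table))
  utils::write.table(table[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a volume table from delimited text
#'
#' The delimiter (tab or comma) is detected from the header line; a header
#' is required.
#'
#' @param path TSV or CSV file with metadata columns and one column per
#'   region.
#' @return a volume table data.frame.
#' @export
read_volume_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  regs <- setdiff(colnames(tab), .meta_cols)
  if (length(regs) == 0L) stop("no region columns found in ", path)
  if (anyNA(tab[, regs])) stop("missing volumes in ", path)
  if (all(c("subject_id", "timepoint") %in% colnames(tab))) {
    key <- paste(tab$subject_id, tab$timepoint)
    if (anyDuplicated(key)) stop("duplicate (subject_id, timepoint) rows")
  }
  tab
}
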