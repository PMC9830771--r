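# Internal helpers shared across modules.

# Metadata columns of a volume table; everything else is a region column.
.meta_cols <- c("subject_id", "group", "timepoint", "age", "sex")

#' Names of the region columns of a volume table
#'
#' @param table a volume table (see [generate_cohort()]).
#' @return character vector of region column names, in table order.
#' @export
region_names <- function(table) {
  setdiff(colnames(table), .meta_cols)
}

# Extract the subjects x regions numeric matrix from a volume table.
.region_matrix <- function(table) {
  regs <- region_names(table)
  if (length(regs) == 0L) stop("volume table has no region columns")
  m <- as.matrix(table[, regs, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$subject_id
  m
}

#' Standard AAL parcellation labels
#'
#' Returns the first `n` labels of the 116-region Automated Anatomical
#' Labeling (AAL) atlas, the parcellation conventionally used to define
#' nodes of grey-matter structural covariance networks.
#'
#' @param n number of labels (1 to 116).
#' @return character vector of length `n`.
#' @export
aal_region_names <- function(n = 116L) {
  path <- system.file("extdata", "aal116_labels.txt", package = "scnet",
                      mustWork = TRUE)
  labels <- readLines(path)
  if (n < 1L || n > length(labels)) {
    stop("n must be between 1 and ", length(labels))
  }
  labels[seq_len(n)]
}

# Derive a reproducible sub-seed from a master seed and an iteration index.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
.derive_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) %% 48611 * 44111 + as.numeric(i)) %%
               2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Round a density grid to suppress floating-point drift from seq().
.round_grid <- function(x) round(x, 10)
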