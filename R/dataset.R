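#' Build a labelled synthetic expression dataset
#'
#' Full generator pipeline: for each condition, draw `n_per_timepoint`
#' independently perturbed copies of the network ([perturb_coefficients()]),
#' integrate each ([simulate_trajectory()]) and sample the five standard time
#' points, then add expression-proportional Gaussian noise and zero-inflated
#' dropout with the scale calibrated on the noisy matrix
#' ([calibrate_dropout_scale()]). The default build yields 100 samples per
#' condition, 20 per (condition, time). Row order and all draws are
#' deterministic given `seed`.
#'
#' @param network a `grn_network`; defaults to [default_network()] of the
#'   given preset.
#' @param conditions character vector of condition labels (default control +
#'   inflammatory) or a list of [condition()] objects.
#' @param n_per_timepoint trajectories per condition (each contributes one
#'   sample at each of the five time points; default 20).
#' @param preset parameter preset used when `network` is NULL.
#' @param seed integer seed.
#' @param perturb_fraction per-sample coefficient perturbation half-width.
#' @param noise_c Gaussian noise variance coefficient.
#' @param dropout_target target zeroed fraction (set `dropout = FALSE` to
#'   skip dropout entirely).
#' @param dropout logical; apply dropout?
#' @param config a [sim_config()].
#' @return An object of class `grn_dataset`: `matrix` (samples x genes, after
#'   noise and dropout), `predropout` (after noise, before dropout), `mask`
#'   (logical, TRUE where zeroed by dropout), `records` (sample metadata:
#'   sample_id, condition, time_h, trajectory_id), `genes`, `dropout_scale`.
#' @examples
#' ds <- build_dataset(n_per_timepoint = 2, seed = 1)
#' ds
#' @export
build_dataset <- function(network = NULL,
                          conditions = c("control", "inflammatory"),
                          n_per_timepoint = 20,
                          preset = c("moderate", "severe"),
                          seed = 42, perturb_fraction = 0.25,
                          noise_c = 0.05, dropout_target = 0.175,
                          dropout = TRUE, config = sim_config()) {
  preset <- match.arg(preset)
  if (is.null(network)) network <- default_network(preset)
  if (n_per_timepoint < 1) stop("n_per_timepoint must be >= 1")
  if (is.character(conditions)) conditions <- lapply(conditions, condition)
  set.seed(seed)
  genes <- network$genes$symbol
  rows <- list(); recs <- list()
  for (cond in conditions) {
    for (j in seq_len(n_per_timepoint)) {
      traj_id <- sprintf("%s_%02d", cond$label, j)
      pert <- perturb_coefficients(network, perturb_fraction)
      traj <- tryCatch(simulate_trajectory(pert, cond, config),
                       error = function(e)
                         stop("simulation failed for trajectory ", traj_id,
                              ": ", conditionMessage(e)))
      rows[[traj_id]] <- traj$values
      recs[[traj_id]] <- data.frame(
        sample_id = sprintf("%s_t%02d", traj_id, traj$times),
        condition = cond$label, time_h = traj$times,
        trajectory_id = traj_id, stringsAsFactors = FALSE)
    }
  }
  clean <- do.call(rbind, rows)
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  noisy <- add_gaussian_noise(clean, noise_c)
  if (dropout) {
    scale <- calibrate_dropout_scale(noisy, dropout_target)
    dd <- apply_dropout(noisy, scale)
    mat <- dd$values; mask <- dd$mask
  } else {
    scale <- 0
    mat <- noisy
    mask <- matrix(FALSE, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  }
  rownames(mat) <- rownames(mask) <- records$sample_id
  rownames(noisy) <- records$sample_id
  structure(list(matrix = mat, predropout = noisy, mask = mask,
                 records = records, genes = genes, dropout_scale = scale,
                 preset = preset),
            class = "grn_dataset")
}

#' @export
print.grn_dataset <- function(x, ...) {
  cat("Synthetic expression dataset:", nrow(x$matrix), "samples x",
      length(x$genes), "genes\n")
  print(table(condition = x$records$condition, time_h = x$records$time_h))
  cat(sprintf("dropout: %.1f%% of entries zeroed (scale %.4g)\n",
              100 * mean(x$mask), x$dropout_scale))
  invisible(x)
}

.subset_dataset <- function(ds, keep) {
  out <- ds
  out$matrix <- ds$matrix[keep, , drop = FALSE]
  out$mask <- ds$mask[keep, , drop = FALSE]
  if (!is.null(ds$predropout))
    out$predropout <- ds$predropout[keep, , drop = FALSE]
  out$records <- ds$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Trajectory-exclusive train/test split
#'
#' Partitions trajectory ids, stratified by condition, so that every row of a
#' trajectory lands on exactly one side — no time point of a test trajectory
#' is ever seen in training. The test side receives
#' `round(test_fraction * n_trajectories)` trajectories per condition.
#'
#' @param ds a `grn_dataset`.
#' @param test_fraction in (0, 1) (default 0.2).
#' @param seed integer seed for the trajectory draw.
#' @return List with `train` and `test` (`grn_dataset`s) and
#'   `test_trajectories` (the held-out ids).
#' @export
trajectory_split <- function(ds, test_fraction = 0.2, seed = 7) {
  stopifnot(inherits(ds, "grn_dataset"))
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  set.seed(seed)
  test_ids <- character()
  for (cond in unique(ds$records$condition)) {
    ids <- unique(ds$records$trajectory_id[ds$records$condition == cond])
    k <- round(test_fraction * length(ids))
    if (k < 1 || k >= length(ids))
      stop("too few trajectories in condition ", cond,
           " for a nonempty split")
    test_ids <- c(test_ids, sample(ids, k))
  }
  is_test <- ds$records$trajectory_id %in% test_ids
  list(train = .subset_dataset(ds, !is_test),
       test = .subset_dataset(ds, is_test),
       test_trajectories = sort(test_ids))
}

# condition/gene/time means; masked dropout entries are excluded (they are
# missing-completely-at-random within a gene column, so exclusion is an
# unbiased estimate of the pre-dropout mean) unless on_masked = TRUE.
.cond_means <- function(ds, cond, time, on_masked = FALSE) {
  sel <- ds$records$condition == cond & ds$records$time_h == time
  if (!any(sel)) stop("no samples for condition ", cond, " at ", time, " h")
  if (!on_masked && !is.null(ds$predropout))
    return(colMeans(ds$predropout[sel, , drop = FALSE]))
  m <- ds$matrix[sel, , drop = FALSE]
  if (on_masked || is.null(ds$mask)) return(colMeans(m))
  msk <- ds$mask[sel, , drop = FALSE]
  vapply(seq_len(ncol(m)), function(j) {
    ok <- !msk[, j]
    if (!any(ok)) 0 else mean(m[ok, j])
  }, numeric(1))
}

#' Per-gene fold change between inflamed and control
#'
#' Epsilon-stabilised ratio of condition means at one sampled time point:
#' `(mean_inflamed + eps) / (mean_control + eps)`. Means are computed on
#' pre-dropout values when available (dropout zeros would bias condition
#' means); `fc_on_masked = TRUE` restores the naive zero-inclusive means.
#'
#' @param ds a `grn_dataset` containing both conditions.
#' @param time sampled hour.
#' @param eps ratio stabiliser keeping log2 finite when means approach 0.
#' @param fc_on_masked include dropout zeros in the means?
#' @param inflamed,control condition labels compared.
#' @return data.frame with gene, mean_control, mean_inflamed, ratio and
#'   log2_ratio, one row per gene.
#' @export
fold_change <- function(ds, time, eps = 1e-6, fc_on_masked = FALSE,
                        inflamed = "inflammatory", control = "control") {
  stopifnot(inherits(ds, "grn_dataset"))
  if (!time %in% ds$records$time_h)
    stop(time, " h is not one of the sampled time points")
  mc <- .cond_means(ds, control, time, fc_on_masked)
  mi <- .cond_means(ds, inflamed, time, fc_on_masked)
  ratio <- (mi + eps) / (mc + eps)
  data.frame(gene = ds$genes, time_h = time, mean_control = mc,
             mean_inflamed = mi, ratio = ratio, log2_ratio = log2(ratio),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summary-table statistics over per-time-point condition means
#'
#' For each gene: the mean expression at each sampled time point (across that
#' condition's samples, excluding dropout-masked entries), then count, mean,
#' std, min, quartiles (linear interpolation) and max of those per-time-point
#' means. With the default five sample times, count = 5.
#'
#' @param ds a `grn_dataset`.
#' @param cond condition label.
#' @return data.frame, one row per gene, columns count/mean/std/min/q25/
#'   median/q75/max.
#' @export
condition_summary <- function(ds, cond = "inflammatory") {
  stopifnot(inherits(ds, "grn_dataset"))
  if (!cond %in% ds$records$condition) stop("condition ", cond, " not present")
  times <- sort(unique(ds$records$time_h[ds$records$condition == cond]))
  tm <- vapply(times, function(t)
    vapply(seq_along(ds$genes), function(j) {
      sel <- ds$records$condition == cond & ds$records$time_h == t
      ok <- sel & !ds$mask[, j]
      if (!any(ok)) 0 else mean(ds$matrix[ok, j])
    }, numeric(1)), numeric(length(ds$genes)))
  # tm: genes x times matrix of per-time-point means
  qs <- t(apply(tm, 1, stats::quantile, probs = c(0.25, 0.5, 0.75),
                type = 7))
  data.frame(gene = ds$genes, count = length(times), mean = rowMeans(tm),
             std = apply(tm, 1, stats::sd), min = apply(tm, 1, min),
             q25 = qs[, 1], median = qs[, 2], q75 = qs[, 3],
             max = apply(tm, 1, max), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Call differentially expressed genes from a fold-change report
#'
#' @param report output of [fold_change()].
#' @param log2fc_threshold absolute log2 fold-change cut-off (default 0.5, so
#'   the 0.6-0.7 suppression factors qualify as down-regulated).
#' @return List with `up` and `down`: gene vectors sorted by |log2 ratio|
#'   descending.
#' @export
identify_degs <- function(report, log2fc_threshold = 0.5) {
  if (nrow(report) == 0) stop("report must be nonempty")
  o <- order(abs(report$log2_ratio), decreasing = TRUE)
  r <- report[o, ]
  list(up = r$gene[r$log2_ratio >= log2fc_threshold],
       down = r$gene[r$log2_ratio <= -log2fc_threshold])
}

#' Write / read a dataset as CSV
#'
#' `expression.csv` has columns `sample_id, condition, time_h, trajectory_id`
#' followed by one column per gene (12 significant digits); `mask.csv` has
#' the same layout with 0/1 entries marking dropout. A read-back reproduces
#' matrix values to 12 significant digits and all metadata exactly (the
#' pre-dropout matrix is not serialised; after a round-trip, mean-based
#' reports fall back to mask-excluded means).
#'
#' @param ds a `grn_dataset`.
#' @param dir output directory (created if missing).
#' @return `write_dataset` returns the directory invisibly; `read_dataset`
#'   returns a `grn_dataset`.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "grn_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- ds$records[, c("sample_id", "condition", "time_h", "trajectory_id")]
  vals <- as.data.frame(apply(ds$matrix, 2, formatC, digits = 12,
                              format = "g"))
  utils::write.csv(cbind(meta, vals), file.path(dir, "expression.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cbind(meta, as.data.frame(ds$mask * 1L)),
                   file.path(dir, "mask.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  path <- file.path(dir, "expression.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_cols <- c("sample_id", "condition", "time_h", "trajectory_id")
  if (!identical(names(df)[1:4], meta_cols))
    stop("malformed header in ", path, ": expected leading columns ",
         paste(meta_cols, collapse = ", "))
  if (nrow(df) == 0 || ncol(df) <= 4) stop("empty expression matrix in ", path)
  genes <- names(df)[-(1:4)]
  mat <- as.matrix(df[, genes, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric expression values in ", path)
  neg <- which(apply(mat < 0, 1, any))
  if (length(neg) > 0)
    stop("negative expression value at row ", neg[1], " of ", path)
  mask_path <- file.path(dir, "mask.csv")
  if (file.exists(mask_path)) {
    mdf <- utils::read.csv(mask_path, stringsAsFactors = FALSE)
    mask <- as.matrix(mdf[, genes, drop = FALSE]) == 1
  } else {
    mask <- matrix(FALSE, nrow(mat), ncol(mat))
  }
  rownames(mat) <- rownames(mask) <- df$sample_id
  colnames(mask) <- genes
  df$time_h <- as.numeric(df$time_h)
  structure(list(matrix = mat, predropout = NULL, mask = mask,
                 records = df[, meta_cols], genes = genes,
                 dropout_scale = NA_real_, preset = NA_character_),
            class = "grn_dataset")
}
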