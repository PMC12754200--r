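# random valid network for property-style tests
random_network <- function(n_genes = 5, n_edges = 6) {
  syms <- paste0("G", seq_len(n_genes))
  genes <- data.frame(
    symbol = syms,
    role = sample(c("cytokine", "mediator", "osteogenic"), n_genes,
                  replace = TRUE),
    basal_rate = runif(n_genes, 0.05, 0.5),
    decay_rate = runif(n_genes, 0.1, 0.8),
    initial_level = runif(n_genes, 0, 0.3),
    stringsAsFactors = FALSE
  )
  pairs <- expand.grid(source = syms, target = syms,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pick <- pairs[sample(nrow(pairs), min(n_edges, nrow(pairs))), ]
  edges <- data.frame(
    source = pick$source, target = pick$target,
    sign = sample(c(-1, 1), nrow(pick), replace = TRUE),
    weight = runif(nrow(pick), 0.1, 1),
    half_saturation = runif(nrow(pick), 0.5, 2),
    hill = sample(1:3, nrow(pick), replace = TRUE),
    stringsAsFactors = FALSE
  )
  regulatory_network(genes, edges)
}

# a hand-built tiny dataset with two cleanly separated classes, for
# classifier unit tests (2 genes, n trajectories per condition, 5 times)
toy_dataset <- function(n_traj = 5, gap = 3, seed = 1) {
  set.seed(seed)
  times <- c(0, 6, 12, 24, 48)
  recs <- list(); rows <- list()
  for (cond in c("control", "inflammatory")) {
    mu <- if (cond == "inflammatory") c(gap, 1) else c(0, 1 + gap)
    for (j in seq_len(n_traj)) {
      id <- sprintf("%s_%02d", cond, j)
      m <- cbind(rnorm(5, mu[1], 0.1), rnorm(5, mu[2], 0.1))
      m <- pmax(m, 0)
      colnames(m) <- c("GA", "GB")
      rows[[id]] <- m
      recs[[id]] <- data.frame(sample_id = paste0(id, "_t", times),
                               condition = cond, time_h = times,
                               trajectory_id = id,
                               stringsAsFactors = FALSE)
    }
  }
  mat <- do.call(rbind, rows)
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  rownames(mat) <- records$sample_id
  mask <- matrix(FALSE, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  structure(list(matrix = mat, predropout = mat, mask = mask,
                 records = records, genes = colnames(mat),
                 dropout_scale = 0, preset = "toy"),
            class = "grn_dataset")
}

# small (fast) default-pipeline dataset shared across tests
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_dataset(n_per_timepoint = 4,
                                                seed = 42)
    cache
  }
})
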