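#' Symmetric degree normalisation of an adjacency matrix
#'
#' Standard GCN propagation operator: `Ahat = D^(-1/2) A D^(-1/2)` with D the
#' diagonal of row sums. For a symmetric nonnegative A with positive
#' diagonal, Ahat is symmetric with spectral radius <= 1.
#'
#' @param A symmetric nonnegative matrix with strictly positive diagonal
#'   (e.g. [gae_adjacency()] output).
#' @return The normalised matrix.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (!isSymmetric(unname(A))) stop("A must be symmetric")
  if (any(A < 0)) stop("A must be nonnegative")
  if (any(diag(A) <= 0)) stop("A must have a strictly positive diagonal")
  ds <- rowSums(A)
  if (any(ds <= 0)) stop("zero row sum")  # cannot happen with unit diagonal
  inv <- 1 / sqrt(ds)
  A * tcrossprod(inv)
}

.relu <- function(x) pmax(x, 0)
.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Two-layer graph-convolutional encoder
#'
#' `Z = Ahat relu(Ahat X W1) W2`: node features are propagated over the
#' normalised graph twice, with a rectified hidden layer in between.
#' Deterministic given the weights; permutation-equivariant in the node
#' order.
#'
#' @param X node-feature matrix (genes x d), rows aligned to `Ahat`.
#' @param Ahat normalised adjacency ([normalize_adjacency()]).
#' @param model a trained `grn_gae` (or any list with `W1`, `W2`).
#' @return Latent matrix Z (genes x latent_dim).
#' @export
gae_encode <- function(X, Ahat, model) {
  X <- as.matrix(X)
  if (nrow(X) != nrow(Ahat)) stop("X rows must match Ahat")
  if (ncol(X) != nrow(model$W1)) stop("feature dimension mismatch")
  Ahat %*% .relu(Ahat %*% X %*% model$W1) %*% model$W2
}

#' Decode edge probabilities from a latent embedding
#'
#' `P = logistic(Z Z^T)`: symmetric, entries in (0, 1).
#'
#' @param Z latent matrix (genes x latent_dim).
#' @return Edge-probability matrix.
#' @export
decode_adjacency <- function(Z) .sigmoid(tcrossprod(as.matrix(Z)))

#' Decode (reconstruct) node features from a latent embedding
#'
#' `Xhat = Z W_dec`, the linear feature decoder whose mean squared error
#' against the input features is the reconstruction loss.
#'
#' @param Z latent matrix.
#' @param model a trained `grn_gae` (or any list with `W_dec`).
#' @return Reconstructed feature matrix, same shape as the input features.
#' @export
decode_features <- function(Z, model) {
  Z <- as.matrix(Z)
  if (ncol(Z) != nrow(model$W_dec)) stop("latent dimension mismatch")
  Z %*% model$W_dec
}

# Glorot-uniform initialisation
.glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

# one Adam update; state carries first/second moments and the step counter
.adam_step <- function(state, params, grads, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

.adam_init <- function(params)
  list(t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))

# gene-node features: per-(condition, time) mean expression, standardised
# per feature column (constant columns get unit scale)
.gae_features <- function(ds) {
  conds <- unique(ds$records$condition)
  times <- sort(unique(ds$records$time_h))
  cols <- list()
  for (cond in conds) for (t in times)
    cols[[paste(cond, t, sep = "_")]] <- .cond_means(ds, cond, t)
  X <- do.call(cbind, cols)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' Train the graph autoencoder
#'
#' Fits the two-layer GCN encoder, linear feature decoder and inner-product
#' adjacency decoder by full-batch Adam on the combined loss
#' `MSE(Xhat, X) + lambda * BCE(P, 1[A_gae offdiag > 0])`. Node features are
#' the dataset's per-(condition, time) mean expression per gene, standardised
#' per feature. Deterministic given `seed`.
#'
#' @param ds a `grn_dataset` (training portion).
#' @param network the `grn_network` supplying the known graph.
#' @param latent_dim latent dimensionality (default 16).
#' @param hidden_dim hidden GCN width (default 32).
#' @param epochs full-batch Adam steps (default 100).
#' @param learning_rate Adam step size (default 0.005).
#' @param lambda adjacency-loss weight (>= 0; 0 recovers a pure feature
#'   autoencoder).
#' @param seed integer seed for weight initialisation.
#' @return An object of class `grn_gae`: weights `W1`, `W2`, `W_dec`, gene
#'   embeddings `Z` (genes x latent_dim), `Ahat`, per-epoch post-update
#'   `history` (total/mse/bce) plus the pre-training `initial_loss`, the
#'   feature matrix and standardisation, and per-gene sample standardisation
#'   statistics.
#' @export
train_gae <- function(ds, network, latent_dim = 16, hidden_dim = 32,
                      epochs = 100, learning_rate = 0.005, lambda = 1.0,
                      seed = 1) {
  stopifnot(inherits(ds, "grn_dataset"), inherits(network, "grn_network"))
  if (latent_dim < 1 || hidden_dim < 1 || epochs < 1 || learning_rate <= 0 ||
      lambda < 0)
    stop("invalid GAE configuration")
  if (!identical(ds$genes, network$genes$symbol))
    stop("dataset gene panel must match the network")
  feats <- .gae_features(ds)
  X <- feats$X
  n <- nrow(X); d <- ncol(X)
  Ahat <- normalize_adjacency(gae_adjacency(network))
  Tadj <- (gae_adjacency(network) - diag(n)) > 0   # binarised known edges
  off <- !diag(n)
  M <- sum(off)

  set.seed(seed)
  params <- list(W1 = .glorot(d, hidden_dim),
                 W2 = .glorot(hidden_dim, latent_dim),
                 W_dec = .glorot(latent_dim, d))
  opt <- .adam_init(params)
  history <- data.frame(epoch = integer(epochs), total = numeric(epochs),
                        mse = numeric(epochs), bce = numeric(epochs))
  AX <- Ahat %*% X
  losses <- function(params) {
    H1 <- .relu(AX %*% params$W1)
    Z <- (Ahat %*% H1) %*% params$W2
    mse <- mean((Z %*% params$W_dec - X)^2)
    P <- pmin(pmax(.sigmoid(tcrossprod(Z)), 1e-12), 1 - 1e-12)
    bce <- -mean((Tadj * log(P) + (!Tadj) * log(1 - P))[off])
    c(total = mse + lambda * bce, mse = mse, bce = bce)
  }
  initial_loss <- losses(params)
  for (ep in seq_len(epochs)) {
    # forward
    H1pre <- AX %*% params$W1
    H1 <- .relu(H1pre)
    Zpre <- Ahat %*% H1
    Z <- Zpre %*% params$W2
    Xhat <- Z %*% params$W_dec
    P <- .sigmoid(tcrossprod(Z))
    R <- Xhat - X
    # backward
    dXhat <- 2 * R / (n * d)
    gW_dec <- crossprod(Z, dXhat)
    dZ <- dXhat %*% t(params$W_dec)
    G <- (lambda / M) * (P - Tadj)
    G[!off] <- 0
    dZ <- dZ + 2 * G %*% Z          # G symmetric; Z enters the Gram twice
    gW2 <- crossprod(Zpre, dZ)
    dH1 <- Ahat %*% dZ %*% t(params$W2)
    dH1[H1pre <= 0] <- 0
    gW1 <- crossprod(AX, dH1)
    upd <- .adam_step(opt, params,
                      list(W1 = gW1, W2 = gW2, W_dec = gW_dec),
                      learning_rate)
    opt <- upd$state; params <- upd$params
    l <- losses(params)
    if (!is.finite(l["total"])) stop("GAE training diverged at epoch ", ep)
    history[ep, ] <- list(ep, l[["total"]], l[["mse"]], l[["bce"]])
  }
  model <- c(params, list(Ahat = Ahat, X = X,
                          feat_center = feats$center,
                          feat_scale = feats$scale,
                          genes = ds$genes,
                          gene_center = colMeans(ds$matrix),
                          gene_scale = {
                            s <- apply(ds$matrix, 2, stats::sd)
                            s[s == 0] <- 1; s
                          },
                          history = history, initial_loss = initial_loss,
                          lambda = lambda,
                          latent_dim = latent_dim, seed = seed))
  model$Z <- gae_encode(X, Ahat, model)
  rownames(model$Z) <- ds$genes
  class(model) <- "grn_gae"
  model
}

#' @export
print.grn_gae <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat("Graph autoencoder:", nrow(x$Z), "genes ->", x$latent_dim,
      "latent dimensions\n")
  cat(sprintf("  final loss %.4f (feature MSE %.4f, adjacency BCE %.4f) after %d epochs\n",
              h$total, h$mse, h$bce, nrow(x$history)))
  invisible(x)
}

#' @export
plot.grn_gae <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$total, h$mse, h$bce), type = "l",
                    lty = 1, xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("total", "feature MSE", "adjacency BCE"),
                   col = 1:3, lty = 1, bty = "n")
  invisible(x)
}

#' Latent embeddings for individual samples
#'
#' Each sample's expression vector is standardised per gene with the
#' training-set statistics and projected onto the gene embeddings:
#' `s = Z^T x / n_genes`.
#'
#' @param model a trained `grn_gae`.
#' @param ds a `grn_dataset` over the model's gene panel.
#' @return samples x latent_dim matrix, rows aligned to `ds$records`.
#' @export
sample_embeddings <- function(model, ds) {
  stopifnot(inherits(model, "grn_gae"), inherits(ds, "grn_dataset"))
  missing <- setdiff(model$genes, ds$genes)
  if (length(missing) > 0)
    stop("dataset is missing panel genes: ", paste(missing, collapse = ", "))
  Xs <- sweep(sweep(ds$matrix[, model$genes, drop = FALSE], 2,
                    model$gene_center), 2, model$gene_scale, "/")
  Xs %*% model$Z / length(model$genes)
}

#' @export
predict.grn_gae <- function(object, newdata, ...) sample_embeddings(object,
                                                                    newdata)

#' Silhouette separation between two gene groups in latent space
#'
#' Mean silhouette width (Euclidean distance) over the genes of two disjoint
#' groups. By convention the score is 0 when all pairwise distances vanish.
#'
#' @param Z gene-embedding matrix with gene rownames.
#' @param group1,group2 disjoint gene sets, each with >= 2 members.
#' @return Mean silhouette in [-1, 1].
#' @export
latent_separation <- function(Z, group1, group2) {
  if (length(group1) < 2 || length(group2) < 2)
    stop("each group needs at least 2 genes")
  if (length(intersect(group1, group2)) > 0) stop("groups must be disjoint")
  sel <- c(group1, group2)
  if (!all(sel %in% rownames(Z)))
    stop("groups must be subsets of the embedded genes")
  zz <- Z[sel, , drop = FALSE]
  d <- stats::dist(zz)
  if (all(d == 0)) return(0)
  cl <- rep(1:2, c(length(group1), length(group2)))
  sil <- cluster::silhouette(cl, d)
  w <- sil[, "sil_width"]
  w[!is.finite(w)] <- 0
  mean(w)
}

#' Hub scores from the reconstructed graph
#'
#' Weighted degree in the decoded edge-probability matrix:
#' `score_g = sum_{h != g} P_gh`, sorted descending. Genes whose embeddings
#' align with many others (as the cytokine hubs do) score highest.
#'
#' @param model a trained `grn_gae`.
#' @return Named numeric vector, sorted descending.
#' @export
hub_scores <- function(model) {
  stopifnot(inherits(model, "grn_gae"))
  P <- decode_adjacency(model$Z)
  s <- rowSums(P) - diag(P)
  names(s) <- model$genes
  sort(s, decreasing = TRUE)
}

#' Hypergeometric enrichment of gene sets in latent dimensions
#'
#' For each latent dimension, genes are ranked by absolute loading and the
#' overlap of the top `top_k` genes with each gene set is scored with the
#' hypergeometric upper-tail probability P(X >= overlap).
#'
#' @param Z gene-embedding matrix with gene rownames.
#' @param gene_sets named list of gene vectors (subsets of the panel).
#' @param top_k number of top-loading genes per dimension (default 3).
#' @return Matrix of p-values, latent dimensions x gene sets.
#' @export
latent_dimension_enrichment <- function(Z, gene_sets, top_k = 3) {
  n <- nrow(Z)
  if (top_k >= n) stop("top_k must be smaller than the panel size")
  if (any(lengths(gene_sets) == 0)) stop("gene sets must be nonempty")
  if (!all(unlist(gene_sets) %in% rownames(Z)))
    stop("gene sets must be subsets of the embedded panel")
  out <- matrix(NA_real_, ncol(Z), length(gene_sets),
                dimnames = list(paste0("dim", seq_len(ncol(Z))),
                                names(gene_sets)))
  for (j in seq_len(ncol(Z))) {
    top <- rownames(Z)[order(abs(Z[, j]), decreasing = TRUE)][seq_len(top_k)]
    for (s in seq_along(gene_sets)) {
      set <- gene_sets[[s]]
      ov <- length(intersect(top, set))
      out[j, s] <- stats::phyper(ov - 1, length(set), n - length(set),
                                 top_k, lower.tail = FALSE)
    }
  }
  out
}
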