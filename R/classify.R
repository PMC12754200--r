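#' Train the feed-forward inflammatory-state classifier
#'
#' A fully connected network on the per-sample expression vector (the panel
#' genes; time is not an input feature): two rectified hidden layers (default
#' 32 and 16 units) and a single logistic output, trained with Adam on binary
#' cross-entropy in shuffled minibatches, so one epoch makes several updates
#' and 100 epochs saturate the decision scores. The inflammatory condition is
#' the positive class. Features are standardised with statistics of the
#' fitted rows.
#' A validation set is carved out of the training *trajectories* (no
#' time-point leakage into validation) and its accuracy is recorded per
#' epoch. Deterministic given `seed`.
#'
#' @param train a `grn_dataset` containing both classes.
#' @param hidden hidden layer sizes (default c(32, 16)).
#' @param epochs full-batch Adam steps (default 100).
#' @param learning_rate Adam step size (default 0.001).
#' @param batch_size minibatch size (default 32; rows are reshuffled every
#'   epoch with the training seed).
#' @param input_dropout denoising-augmentation rate (default 0.1): during
#'   training each input entry is independently reset to the standardised
#'   value of a raw zero with this probability, mirroring the generator's
#'   dropout mechanism so that predictions are robust to rare missingness
#'   patterns (and hence stable across training seeds).
#' @param val_fraction fraction of training trajectories held out for
#'   validation (default 0.2; 0 disables validation and the history records
#'   training accuracy instead).
#' @param val_seed seed for the validation carve-out, kept separate from the
#'   training seed so that retraining with a new `seed` varies only the
#'   stochastic optimisation, not the fitted rows.
#' @param positive label of the positive class (default "inflammatory").
#' @param seed integer seed (weight initialisation and minibatch shuffling).
#' @return An object of class `grn_classifier` with weights, standardisation
#'   statistics, the gene panel, per-epoch `history` (loss and accuracy) and
#'   the validation trajectory ids.
#' @export
train_classifier <- function(train, hidden = c(32, 16), epochs = 100,
                             learning_rate = 0.001, batch_size = 32,
                             input_dropout = 0.1,
                             val_fraction = 0.2, val_seed = 11,
                             positive = "inflammatory", seed = 1) {
  stopifnot(inherits(train, "grn_dataset"))
  if (epochs < 1 || any(hidden < 1) || learning_rate <= 0)
    stop("invalid classifier configuration")
  if (length(unique(train$records$condition)) < 2)
    stop("training set must contain both classes")
  if (!positive %in% train$records$condition)
    stop("positive class ", positive, " not present in the training set")

  if (val_fraction > 0) {
    carve <- trajectory_split(train, val_fraction, val_seed)
    fit_ds <- carve$train; val_ds <- carve$test
    val_ids <- carve$test_trajectories
  } else {
    fit_ds <- train; val_ds <- train; val_ids <- character()
  }
  X <- fit_ds$matrix
  y <- as.numeric(fit_ds$records$condition == positive)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  z0 <- -ctr / scl            # standardised value of a raw zero, per gene
  Xv <- sweep(sweep(val_ds$matrix, 2, ctr), 2, scl, "/")
  yv <- as.numeric(val_ds$records$condition == positive)

  set.seed(seed)
  sizes <- c(ncol(X), hidden, 1)
  L <- length(sizes) - 1
  params <- list()
  for (l in seq_len(L)) {
    params[[paste0("W", l)]] <- .glorot(sizes[l], sizes[l + 1])
    params[[paste0("b", l)]] <- matrix(0, 1, sizes[l + 1])
  }
  opt <- .adam_init(params)
  history <- data.frame(epoch = integer(epochs), loss = numeric(epochs),
                        accuracy = numeric(epochs))
  fwd <- function(X, params) {
    acts <- list(X)
    for (l in seq_len(L)) {
      pre <- sweep(acts[[l]] %*% params[[paste0("W", l)]], 2,
                   params[[paste0("b", l)]], "+")
      acts[[l + 1]] <- if (l < L) .relu(pre) else .sigmoid(pre)
    }
    acts
  }
  n <- nrow(Xs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      Xb <- Xs[idx, , drop = FALSE]; yb <- y[idx]
      if (input_dropout > 0) {
        m <- matrix(stats::runif(length(Xb)) < input_dropout, nrow(Xb))
        Xb[m] <- rep(z0, each = nrow(Xb))[m]
      }
      acts <- fwd(Xb, params)
      p <- pmin(pmax(acts[[L + 1]], 1e-12), 1 - 1e-12)
      loss <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
      if (!is.finite(loss))
        stop("classifier training diverged at epoch ", ep)
      ep_loss <- ep_loss + loss * length(idx) / n
      grads <- list()
      delta <- (acts[[L + 1]] - yb) / length(idx)  # dL/d(pre-act), output
      for (l in rev(seq_len(L))) {
        grads[[paste0("W", l)]] <- crossprod(acts[[l]], delta)
        grads[[paste0("b", l)]] <- matrix(colSums(delta), 1)
        if (l > 1) {
          delta <- delta %*% t(params[[paste0("W", l)]])
          delta[acts[[l]] <= 0] <- 0               # relu gate
        }
      }
      upd <- .adam_step(opt, params, grads[names(params)], learning_rate)
      opt <- upd$state; params <- upd$params
    }
    scores <- fwd(Xv, params)[[L + 1]]
    history[ep, ] <- list(ep, ep_loss, mean((scores >= 0.5) == yv))
  }
  structure(list(params = params, hidden = hidden, center = ctr, scale = scl,
                 genes = train$genes, positive = positive,
                 history = history, validation_trajectories = val_ids,
                 seed = seed),
            class = "grn_classifier")
}

#' @export
print.grn_classifier <- function(x, ...) {
  cat("Feed-forward classifier (", paste(x$hidden, collapse = "-"),
      " hidden units), positive class: ", x$positive, "\n", sep = "")
  cat(sprintf("  final %s accuracy %.3f after %d epochs\n",
              if (length(x$validation_trajectories)) "validation"
              else "training",
              x$history$accuracy[nrow(x$history)], nrow(x$history)))
  invisible(x)
}

.classifier_scores <- function(model, X) {
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  L <- length(model$hidden) + 1
  a <- Xs
  for (l in seq_len(L)) {
    a <- sweep(a %*% model$params[[paste0("W", l)]], 2,
               model$params[[paste0("b", l)]], "+")
    a <- if (l < L) .relu(a) else .sigmoid(a)
  }
  as.numeric(a)
}

#' Score new expression profiles
#'
#' Columns are aligned to the model's gene panel by name: missing panel genes
#' are an error, extra columns are ignored with a warning. The training
#' standardisation is applied before scoring.
#'
#' @param model a `grn_classifier`.
#' @param newdata numeric matrix or data.frame (samples x genes) with gene
#'   column names, or a `grn_dataset`.
#' @return data.frame with `score` in [0, 1] and hard `label` at
#'   threshold 0.5, aligned to input rows.
#' @export
predict_labels <- function(model, newdata) {
  stopifnot(inherits(model, "grn_classifier"))
  if (inherits(newdata, "grn_dataset")) newdata <- newdata$matrix
  X <- as.matrix(newdata)
  missing <- setdiff(model$genes, colnames(X))
  if (length(missing) > 0)
    stop("missing panel genes: ", paste(missing, collapse = ", "))
  extra <- setdiff(colnames(X), model$genes)
  if (length(extra) > 0)
    warning("ignoring columns outside the panel: ",
            paste(extra, collapse = ", "))
  score <- .classifier_scores(model, X[, model$genes, drop = FALSE])
  data.frame(score = score,
             label = ifelse(score >= 0.5, model$positive, "control"),
             stringsAsFactors = FALSE)
}

#' @export
predict.grn_classifier <- function(object, newdata, ...)
  predict_labels(object, newdata)

#' Rank-based AUROC
#'
#' The probability that a positive sample outscores a negative one, with ties
#' counted one half — the normalised Mann-Whitney U statistic, computed from
#' midranks.
#'
#' @param scores numeric scores.
#' @param labels logical/0-1 vector (TRUE/1 = positive); both classes must be
#'   present.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0)
    stop("both classes must be present to compute AUROC")
  r <- rank(scores)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Evaluate a classifier on a held-out dataset
#'
#' Hard labels at threshold 0.5 with the inflammatory condition as the
#' positive class; reports accuracy, precision, recall, F1, rank-based AUROC
#' and the confusion counts.
#'
#' @param model a `grn_classifier`.
#' @param test a nonempty `grn_dataset` over the model's gene panel.
#' @return An object of class `classifier_metrics`.
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(model, "grn_classifier"), inherits(test, "grn_dataset"))
  if (nrow(test$matrix) == 0) stop("test set is empty")
  scores <- predict_labels(model, test)$score
  truth <- test$records$condition == model$positive
  pred <- scores >= 0.5
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(accuracy = (tp + tn) / length(truth), precision = precision,
                 recall = recall, f1 = f1, auroc = auroc(scores, truth),
                 counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 n = length(truth)),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f | AUROC %.3f (n = %d)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$auroc, x$n))
  cat("confusion:", paste(names(x$counts), x$counts, sep = "=",
                          collapse = " "), "\n")
  invisible(x)
}

#' Accuracy stability across training seeds
#'
#' Retrains the classifier end-to-end with each seed on an identical
#' trajectory-exclusive split and returns the spread (max minus min) of the
#' test accuracies, in percentage points.
#'
#' @param ds a `grn_dataset`.
#' @param seeds at least two training seeds (default 1, 2, 3).
#' @param test_fraction,split_seed split parameters (fixed across seeds).
#' @param ... passed to [train_classifier()].
#' @return Accuracy range in percentage points, with the per-seed accuracies
#'   attached as the `accuracies` attribute.
#' @export
multi_seed_stability <- function(ds, seeds = c(1, 2, 3), test_fraction = 0.2,
                                 split_seed = 7, ...) {
  if (length(seeds) < 2) stop("need at least two seeds")
  sp <- trajectory_split(ds, test_fraction, split_seed)
  acc <- vapply(seeds, function(s) {
    m <- train_classifier(sp$train, seed = s, ...)
    evaluate(m, sp$test)$accuracy
  }, numeric(1))
  names(acc) <- seeds
  structure(100 * (max(acc) - min(acc)), accuracies = acc)
}
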