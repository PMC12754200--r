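test_that("adjacency normalisation is symmetric with spectrum in [-1, 1]", {
  expect_equal(normalize_adjacency(matrix(1)), matrix(1))
  A2 <- matrix(1, 2, 2)
  expect_equal(normalize_adjacency(A2), matrix(0.5, 2, 2))  # D = diag(2, 2)
  set.seed(1)
  for (i in 1:10) {
    A <- matrix(runif(25), 5, 5)
    A <- pmax(A, t(A)); diag(A) <- 1
    Ah <- normalize_adjacency(A)
    expect_true(isSymmetric(unname(Ah)))
    expect_lte(max(abs(eigen(Ah, symmetric = TRUE)$values)), 1 + 1e-12)
  }
  expect_error(normalize_adjacency(matrix(c(1, 2, 0, 1), 2)), "symmetric")
  expect_error(normalize_adjacency(matrix(c(1, -1, -1, 1), 2)), "nonnegative")
  expect_error(normalize_adjacency(diag(c(0, 1))), "diagonal")
})

test_that("encoder is zero-preserving, permutation-equivariant and deterministic", {
  set.seed(2)
  n <- 6; d <- 4
  A <- matrix(runif(n * n), n); A <- pmax(A, t(A)); diag(A) <- 1
  Ah <- normalize_adjacency(A)
  model <- list(W1 = matrix(rnorm(d * 8), d, 8),
                W2 = matrix(rnorm(8 * 3), 8, 3))
  expect_equal(gae_encode(matrix(0, n, d), Ah, model), matrix(0, n, 3))
  X <- matrix(rnorm(n * d), n, d)
  Z <- gae_encode(X, Ah, model)
  expect_identical(Z, gae_encode(X, Ah, model))
  perm <- sample(n)
  Zp <- gae_encode(X[perm, ], Ah[perm, perm], model)
  expect_equal(Zp, Z[perm, ], tolerance = 1e-12)
  expect_error(gae_encode(X[, 1:2], Ah, model), "dimension")
})

test_that("decoders behave per their closed forms", {
  expect_equal(decode_adjacency(matrix(0, 3, 2)), matrix(0.5, 3, 3))
  set.seed(3)
  Z <- matrix(rnorm(12), 4, 3)
  P <- decode_adjacency(Z)
  expect_true(isSymmetric(unname(P)))
  expect_true(all(P > 0 & P < 1))
  big <- rbind(c(10, 0, 0), c(10, 0, 0))
  expect_gt(decode_adjacency(big)[1, 2], 1 - 1e-12)
  model <- list(W_dec = matrix(rnorm(6), 3, 2))
  expect_equal(decode_features(matrix(0, 4, 3), model), matrix(0, 4, 2))
  expect_equal(dim(decode_features(Z, model)), c(4, 2))
  expect_error(decode_features(Z[, 1:2], model), "latent")
  # rank-limited features admit an exact linear autoencoding (no-graph limit)
  X <- matrix(rnorm(10 * 3), 10, 3) %*% matrix(rnorm(3 * 8), 3, 8)
  s <- svd(X)
  Zls <- s$u[, 1:3] %*% diag(s$d[1:3])
  Wd <- qr.solve(crossprod(Zls), crossprod(Zls, X))
  expect_lt(mean((Zls %*% Wd - X)^2), 1e-20)
})

test_that("GAE training descends, is seed-deterministic and keeps the graph term useful", {
  ds <- small_dataset()
  net <- default_network()
  g <- train_gae(ds, net, seed = 1)
  expect_equal(nrow(g$history), 100)
  expect_true(all(is.finite(as.matrix(g$history[, 2:4]))))
  expect_lt(g$history$total[100], g$initial_loss[["total"]])
  # overcomplete-latent guard: nonzero embeddings, BCE beats the all-0.5 rate
  expect_gt(sum(g$Z^2), 0)
  expect_lt(g$history$bce[100], log(2))
  g2 <- train_gae(ds, net, seed = 1)
  expect_identical(g$Z, g2$Z)
  g3 <- train_gae(ds, net, seed = 2)
  expect_false(identical(g$Z, g3$Z))
  expect_error(train_gae(ds, net, epochs = 0), "configuration")
})

test_that("sample embeddings are linear projections aligned to the panel", {
  ds <- small_dataset()
  g <- train_gae(ds, default_network(), seed = 1)
  se <- sample_embeddings(g, ds)
  expect_equal(dim(se), c(nrow(ds$matrix), 16))
  # a sample at the training gene means standardises to zero, so maps to zero
  at_mean <- ds
  at_mean$matrix <- matrix(g$gene_center, 2, 10, byrow = TRUE,
                           dimnames = list(NULL, ds$genes))
  expect_equal(unname(sample_embeddings(g, at_mean)), matrix(0, 2, 16),
               tolerance = 1e-12)
  # duplicated rows give identical embeddings
  dup <- ds
  dup$matrix[2, ] <- dup$matrix[1, ]
  se2 <- sample_embeddings(g, dup)
  expect_equal(se2[1, ], se2[2, ])
  bad <- ds; bad$genes <- bad$genes[-1]
  bad$matrix <- bad$matrix[, -1]
  expect_error(sample_embeddings(g, bad), "IL1B")
  # embeddings separate the conditions well above chance (2-means agreement)
  km <- stats::kmeans(se, 2, nstart = 10)
  agree <- mean((km$cluster == 1) ==
                  (ds$records$condition == "inflammatory"))
  expect_gt(max(agree, 1 - agree), 0.75)
})

test_that("latent separation scores constructed geometries correctly", {
  Z <- rbind(matrix(rnorm(6, 0, 0.01), 3, 2),
             matrix(rnorm(6, 10, 0.01), 3, 2))
  rownames(Z) <- paste0("g", 1:6)
  expect_gt(latent_separation(Z, paste0("g", 1:3), paste0("g", 4:6)), 0.9)
  Zc <- matrix(1, 4, 2, dimnames = list(paste0("g", 1:4), NULL))
  expect_equal(latent_separation(Zc, c("g1", "g2"), c("g3", "g4")), 0)
  expect_error(latent_separation(Z, "g1", c("g2", "g3")), "at least 2")
  expect_error(latent_separation(Z, c("g1", "g2"), c("g2", "g3")),
               "disjoint")
  # trained model separates cytokine and osteogenic modules
  g <- train_gae(small_dataset(), default_network(), seed = 1)
  expect_gt(latent_separation(g$Z, c("IL1B", "TNFA", "IL6"),
                              c("RUNX2", "ALPL")), 0)
})

test_that("hub scores equal reconstructed weighted degree", {
  ds <- small_dataset()
  g <- train_gae(ds, default_network(), seed = 1)
  hs <- hub_scores(g)
  expect_true(all(diff(unname(hs)) <= 0))
  expect_setequal(names(hs), ds$genes)
  flat <- g; flat$Z[] <- 0
  expect_equal(unname(hub_scores(flat)), rep(4.5, 10))   # (n - 1) * 0.5
  # an isolated far-away embedding scores lowest
  iso <- g
  iso$Z[] <- 0.5
  iso$Z[1, ] <- -50
  expect_equal(names(which.min(hub_scores(iso))), iso$genes[1])
})

test_that("latent-dimension enrichment matches hypergeometric point masses", {
  set.seed(9)
  Z <- matrix(rnorm(160), 10, 16, dimnames = list(LETTERS[1:10], NULL))
  top3 <- rownames(Z)[order(abs(Z[, 1]), decreasing = TRUE)][1:3]
  p <- latent_dimension_enrichment(Z, list(hit = top3, miss = setdiff(
    rownames(Z), top3)[1:3]), top_k = 3)
  expect_equal(p["dim1", "hit"], 1 / choose(10, 3))
  # zero overlap has upper-tail probability 1
  other <- setdiff(rownames(Z), top3)[1:3]
  expect_equal(unname(latent_dimension_enrichment(
    Z, list(s = other), top_k = 3)["dim1", "s"]), 1)
  expect_error(latent_dimension_enrichment(Z, list(s = character())), "nonempty")
  expect_error(latent_dimension_enrichment(Z, list(s = "A"), top_k = 10),
               "top_k")
  # trained model: cytokine and osteogenic sets peak on different dimensions
  g <- train_gae(small_dataset(), default_network(), seed = 1)
  pv <- latent_dimension_enrichment(g$Z, list(
    cytokine = c("IL1B", "TNFA", "IL6"),
    osteogenic = c("RUNX2", "ALPL", "SP7", "BMP2")))
  expect_false(which.min(pv[, "cytokine"]) == which.min(pv[, "osteogenic"]))
})
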