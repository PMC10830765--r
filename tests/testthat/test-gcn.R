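# GCN: parameter accounting, adjacency normalization, layer arithmetic
# against a brute-force oracle, permutation invariance, determinism and
# learnability on a separable toy problem.

test_that("parameter counts match the architecture accounting", {
  # (4*64+64) + 2*(64*64+64) + (64*3+3) = 320 + 8320 + 195
  expect_identical(count_parameters(gcn_model(3)), 8835L)
  expect_identical(count_parameters(gcn_model(2)), 8770L)
  # GCN stack alone: 8640
  m <- gcn_model(2)
  stack_only <- count_parameters(m) - length(m$params$Wh) - length(m$params$bh)
  expect_identical(stack_only, 8640L)
  expect_error(gcn_model(1), "2 classes")
})

test_that("normalized adjacency matches the self-loop degree formula", {
  # edgeless graph: A = 0 -> A_hat = I
  G0 <- toy_graph(matrix(0, 5, 4), edges = data.frame(i = integer(0),
                                                      j = integer(0),
                                                      weight = numeric(0)))
  expect_equal(normalize_adjacency(G0), diag(5))
  # two nodes, one unit edge: D = diag(2,2) -> all entries 0.5
  G2 <- toy_graph(matrix(0, 2, 4), edges = data.frame(i = 1, j = 2, weight = 1))
  expect_equal(normalize_adjacency(G2), matrix(0.5, 2, 2))
  # symmetry for arbitrary weighted graphs
  set.seed(10)
  X <- matrix(rnorm(8 * 4), 8, 4)
  A <- abs(matrix(rnorm(64), 8, 8)); A <- A + t(A); diag(A) <- 0
  Ah <- normalize_adjacency(A)
  expect_lt(max(abs(Ah - t(Ah))), 1e-12)
})

test_that("layer forward equals brute-force triple-loop computation", {
  set.seed(11)
  for (rep in 1:3) {
    N <- 5
    A <- abs(matrix(rnorm(N * N), N, N)); A <- A + t(A); diag(A) <- 0
    Ah <- normalize_adjacency(A)
    H <- matrix(rnorm(N * 3), N, 3)
    W <- matrix(rnorm(3 * 4), 3, 4)
    b <- rnorm(4)
    expect_equal(gcn_layer_forward(H, Ah, W, b), brute_gcn_layer(H, Ah, W, b),
                 tolerance = 1e-10)
  }
  # identity propagation: W = I, A_hat = I -> relu(H + b)
  H <- matrix(c(-1, 2, 0.5, -0.2, 1, 3), 3, 2)
  out <- gcn_layer_forward(H, diag(3), diag(2), c(0.1, -0.1))
  expect_equal(out, pmax(sweep(H, 2, c(0.1, -0.1), "+"), 0))
  # zero input with zero bias stays zero
  expect_equal(gcn_layer_forward(matrix(0, 3, 2), diag(3), diag(2), c(0, 0)),
               matrix(0, 3, 2))
  expect_error(gcn_layer_forward(H, diag(3), matrix(0, 3, 4), rep(0, 4)),
               "shape mismatch")
})

test_that("model forward is permutation invariant and deterministic in eval mode", {
  set.seed(12)
  N <- 9
  X <- matrix(rnorm(N * 4), N, 4, dimnames = list(1:N, c("mu", "sigma", "gamma", "k")))
  idx <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  keep <- sample(nrow(idx), 14)
  edges <- data.frame(i = idx[keep, 1], j = idx[keep, 2],
                      weight = runif(14, 0.5, 2))
  G <- toy_graph(X, edges)
  m <- gcn_model(3, seed = 1)
  l1 <- model_forward(G, m)
  expect_equal(model_forward(G, m), l1)  # eval-mode determinism

  perm <- sample(N)
  inv <- order(perm)
  Xp <- X[perm, , drop = FALSE]
  ep <- data.frame(i = pmin(inv[edges$i], inv[edges$j]),
                   j = pmax(inv[edges$i], inv[edges$j]),
                   weight = edges$weight)
  l2 <- model_forward(toy_graph(Xp, ep), m)
  expect_equal(l2, l1, tolerance = 1e-10)
})

test_that("zero features with zero biases yield head-bias logits", {
  G <- toy_graph(matrix(0, 6, 4))
  m <- gcn_model(3, seed = 2)
  m$params$bh <- c(0.3, -0.2, 0.1)
  expect_equal(model_forward(G, m), c(0.3, -0.2, 0.1))
})

test_that("feature-dimension mismatches are rejected", {
  G <- toy_graph(matrix(0, 6, 3))
  expect_error(model_forward(G, gcn_model(2)), "dimension")
  d <- separable_graphs(2)
  m <- gcn_model(2, seed = 1)
  G5 <- toy_graph(matrix(0, 5, 4))
  expect_silent(model_forward(G5, m))  # different N is fine, same features
})

test_that("softmax probabilities are normalized and consistent with labels", {
  d <- separable_graphs(5)
  m <- gcn_model(2, seed = 3)
  m$classes <- c("A", "B")
  pred <- predict_gcn(m, d$graphs)
  expect_equal(unname(rowSums(pred$probs)), rep(1, length(d$graphs)),
               tolerance = 1e-6)
  expect_equal(pred$labels,
               m$classes[max.col(pred$probs, ties.method = "first")])
})

test_that("batch prediction equals per-graph forward passes", {
  d <- separable_graphs(4)
  m <- gcn_model(2, seed = 4)
  m$classes <- c("A", "B")
  pred <- predict_gcn(m, d$graphs)
  for (i in c(1, 5, 8)) {
    logit <- model_forward(d$graphs[[i]], m)
    p <- exp(logit - max(logit)); p <- p / sum(p)
    expect_equal(unname(pred$probs[i, ]), unname(p), tolerance = 1e-10)
  }
})

test_that("training is deterministic given the seed", {
  d <- separable_graphs(4)
  cfg <- train_config(epochs = 5, batch_size = 4, seed = 9)
  m1 <- train_gcn(gcn_model(2, seed = 7), d$graphs, d$labels, cfg)
  m2 <- train_gcn(gcn_model(2, seed = 7), d$graphs, d$labels, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("a linearly separable toy reaches high training accuracy within 100 epochs", {
  d <- separable_graphs(10)
  m <- gcn_model(2, seed = 5)
  m <- train_gcn(m, d$graphs, d$labels,
                 train_config(epochs = 100, batch_size = 8, seed = 5))
  pred <- predict_gcn(m, d$graphs)
  expect_gte(mean(pred$labels == d$labels), 0.95)
})

test_that("single-class training sets are rejected", {
  d <- separable_graphs(3)
  expect_error(train_gcn(gcn_model(2), d$graphs[1:3], rep("A", 3),
                         train_config(epochs = 1)),
               "single class")
})

test_that("class weighting and the two-layer head variant run end to end", {
  d <- separable_graphs(5)
  m <- gcn_model(2, seed = 6, two_layer_head = TRUE)
  expect_gt(count_parameters(m), 8770)
  m <- train_gcn(m, d$graphs, d$labels,
                 train_config(epochs = 20, batch_size = 8, seed = 6,
                              class_weights = TRUE))
  expect_equal(nrow(m$history), 20)
})

test_that("checkpoints round-trip through JSON", {
  d <- separable_graphs(3)
  m <- train_gcn(gcn_model(2, seed = 8), d$graphs, d$labels,
                 train_config(epochs = 3, seed = 8))
  path <- withr::local_tempfile(fileext = ".json")
  write_gcn_checkpoint(m, path)
  m2 <- read_gcn_checkpoint(path)
  expect_equal(m2$params, m$params, tolerance = 1e-12)
  expect_identical(m2$classes, m$classes)
  p1 <- predict_gcn(m, d$graphs)
  p2 <- predict_gcn(m2, d$graphs)
  expect_equal(p1$probs, p2$probs, tolerance = 1e-12)
})
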