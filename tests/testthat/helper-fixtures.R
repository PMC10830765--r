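# Shared fixtures, generated in code: no data files.

# Small two-class cohort with a strong, localized atrophy effect.
tiny_cohort <- function(seed = 3, effect_mm = -0.3, n_regions = 20L,
                        vertices = 30L) {
  cfg <- sim_config(
    atlas_size = n_regions, vertices_per_region = vertices, seed = seed,
    n_patients_per_class = c(RR = 10L, PP = 10L),
    scans_per_class = c(RR = 20L, PP = 20L),
    class_effect = list(RR = list(regions = integer(0), effect_mm = 0),
                        PP = list(regions = 1:4, effect_mm = effect_mm)))
  simulate_cohort(cfg)
}

# Deterministic hand-built brain graph (no simulator involved).
toy_graph <- function(features, edges = NULL, tau = 0, metric = "taxicab") {
  N <- nrow(features)
  if (is.null(edges)) {
    idx <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
    edges <- data.table::data.table(i = idx[, 1], j = idx[, 2], weight = 1)
  }
  structure(list(features = features, edges = data.table::as.data.table(edges),
                 tau = tau, metric = metric, n_regions = N,
                 scan_id = "toy", threshold = NA_real_),
            class = "brain_graph")
}

# Linearly separable toy graph dataset: class B features are shifted by a
# large margin in every node.
separable_graphs <- function(n_per_class = 10, N = 12, seed = 42) {
  set.seed(seed)
  mk <- function(shift) {
    X <- matrix(rnorm(N * 4, 0, 0.1), N, 4,
                dimnames = list(1:N, c("mu", "sigma", "gamma", "k"))) + shift
    toy_graph(X)
  }
  graphs <- c(replicate(n_per_class, mk(0), simplify = FALSE),
              replicate(n_per_class, mk(2), simplify = FALSE))
  labels <- rep(c("A", "B"), each = n_per_class)
  list(graphs = graphs, labels = labels)
}

# Brute-force pairwise distance loops: the independent oracle.
brute_adjacency <- function(X, metric, S = NULL) {
  N <- nrow(X)
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i == j) next
      A[i, j] <- if (metric == "taxicab") {
        sum(abs(X[i, ] - X[j, ]))
      } else {
        sqrt(drop(t(X[i, ] - X[j, ]) %*% solve(S) %*% (X[i, ] - X[j, ])))
      }
    }
  }
  A
}

# Brute-force GCN layer: triple loop over nodes, inputs and outputs.
brute_gcn_layer <- function(H, A_hat, W, b) {
  N <- nrow(H); dout <- ncol(W)
  out <- matrix(0, N, dout)
  for (i in seq_len(N)) {
    for (j in seq_len(dout)) {
      acc <- 0
      for (k in seq_len(N)) {
        for (m in seq_len(ncol(H))) {
          acc <- acc + A_hat[i, k] * H[k, m] * W[m, j]
        }
      }
      out[i, j] <- max(0, acc + b[j])
    }
  }
  out
}
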