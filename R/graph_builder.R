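# Morphological connectivity graphs: pairwise dissimilarities between region
# feature vectors form a weighted adjacency; a fixed rejection quantile tau
# removes the lowest distances so every scan keeps the same graph density.

#' Mahalanobis distance between two 4-vectors
#'
#' \eqn{d_M(x_i, x_j) = ((x_i - x_j)^T S^{-1} (x_i - x_j))^{1/2}}.
#'
#' @param xi,xj Numeric vectors of equal length.
#' @param S Covariance matrix (symmetric positive definite after
#'   regularization; see [estimate_covariance()]).
#' @return Non-negative distance.
#' @export
mahalanobis_distance <- function(xi, xj, S) {
  d <- xi - xj
  Sinv <- tryCatch(solve(S), error = function(e) {
    stop("singular covariance (condition number ", format(kappa(S)), ")")
  })
  sqrt(max(0, drop(t(d) %*% Sinv %*% d)))
}

#' Taxicab (Manhattan, L1) distance between two feature vectors
#'
#' \eqn{d_T(x_i, x_j) = \sum_k |x_{ik} - x_{jk}|}.
#'
#' @param xi,xj Numeric vectors of equal length, finite.
#' @return Non-negative distance.
#' @export
taxicab_distance <- function(xi, xj) {
  if (!all(is.finite(xi), is.finite(xj))) stop("non-finite input vector")
  sum(abs(xi - xj))
}

#' Per-scan covariance of the region feature vectors
#'
#' Sample covariance of the N rows of a feature matrix — the covariance used
#' by the Mahalanobis dissimilarity, estimated once per scan from all its
#' region vectors. If the condition number exceeds `max_condition`, a ridge
#' `epsilon * I` with `epsilon = ridge_scale * trace(S)/4` (or
#' `ridge_scale` itself when the trace is zero) is added.
#'
#' @param X Feature matrix with at least 5 rows.
#' @param max_condition Condition-number threshold triggering the ridge
#'   (default 1e8).
#' @param ridge_scale Relative ridge magnitude (default 1e-6).
#' @return 4 x 4 covariance matrix, positive definite.
#' @export
estimate_covariance <- function(X, max_condition = 1e8, ridge_scale = 1e-6) {
  if (nrow(X) < 5) stop("need at least 5 region vectors to estimate covariance")
  S <- stats::cov(unclass(X))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  cond <- if (min(ev) <= 0) Inf else max(ev) / min(ev)
  if (cond > max_condition) {
    tr <- sum(diag(S))
    eps <- if (tr > 0) ridge_scale * tr / ncol(S) else ridge_scale
    S <- S + diag(eps, ncol(S))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 || max(ev) / min(ev) > 1 / .Machine$double.eps) {
      stop("covariance singular after regularization (condition number ",
           format(max(ev) / max(min(ev), .Machine$double.xmin)), ")")
    }
  }
  S
}

#' Pairwise dissimilarity (adjacency) matrix of a scan
#'
#' Computes all N(N-1)/2 pairwise distances between the scan's region feature
#' vectors. Symmetric with zero diagonal. For the Mahalanobis metric the
#' covariance is estimated from the scan's own region vectors
#' ([estimate_covariance()]).
#'
#' @param X A `feature_matrix` (N x 4).
#' @param metric `"mahalanobis"` or `"taxicab"`.
#' @return N x N matrix of class `adjacency_matrix` with attributes `metric`
#'   and `scan_id`.
#' @export
build_adjacency <- function(X, metric = c("mahalanobis", "taxicab")) {
  metric <- match.arg(metric)
  Xm <- unclass(X)
  if (!all(is.finite(Xm))) stop("non-finite feature values")
  if (metric == "taxicab") {
    A <- as.matrix(stats::dist(Xm, method = "manhattan"))
  } else {
    S <- estimate_covariance(X)
    R <- chol(S)
    # d_M(xi, xj) equals the Euclidean distance between rows of X %*% R^{-1}
    Y <- Xm %*% backsolve(R, diag(ncol(Xm)))
    A <- as.matrix(stats::dist(Y))
  }
  dimnames(A) <- list(rownames(Xm), rownames(Xm))
  structure(A, class = c("adjacency_matrix", "matrix", "array"),
            metric = metric, scan_id = attr(X, "scan_id"))
}

#' Threshold an adjacency matrix into a brain graph
#'
#' Computes the tau-quantile q (linear-interpolation sample quantile) of the
#' scan's N(N-1)/2 upper-triangular distances and retains edges with distance
#' >= q; the lowest distances (most similar region pairs) are rejected, and
#' the per-scan quantile keeps graph density identical across scans.
#' Retained edge weights are the raw distances. `tau = 0` keeps the complete
#' graph.
#'
#' @param A An `adjacency_matrix` (or plain symmetric matrix).
#' @param tau Rejection quantile in [0, 1).
#' @param X Node feature matrix to attach (optional if `A` was built by
#'   [build_adjacency()] and features are supplied separately).
#' @param prune_side `"lowest"` (default; remove the most similar pairs, as
#'   the pipeline default) or `"highest"` for the ablation variant that
#'   removes the largest distances instead.
#' @return Object of class `brain_graph`: list with `features` (N x 4 or
#'   `NULL`), `edges` (`data.table` i < j with `weight`), `tau`, `metric`,
#'   `n_regions`, `scan_id`, `threshold` (the quantile q used).
#' @export
threshold_graph <- function(A, tau, X = NULL, prune_side = c("lowest", "highest")) {
  prune_side <- match.arg(prune_side)
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0 || tau >= 1) {
    stop("tau must lie in [0, 1)")
  }
  N <- nrow(A)
  ut <- upper.tri(A)
  dvals <- A[ut]
  q <- stats::quantile(dvals, probs = tau, type = 7, names = FALSE)
  idx <- which(ut, arr.ind = TRUE)
  keep <- if (prune_side == "lowest") dvals >= q else {
    qh <- stats::quantile(dvals, probs = 1 - tau, type = 7, names = FALSE)
    dvals <= qh
  }
  if (tau == 0 && prune_side == "lowest") keep <- rep(TRUE, length(dvals))
  edges <- data.table::data.table(i = idx[keep, 1], j = idx[keep, 2],
                                  weight = dvals[keep])
  data.table::setorderv(edges, c("i", "j"))
  structure(list(features = X, edges = edges, tau = tau,
                 metric = attr(A, "metric"), n_regions = N,
                 scan_id = attr(A, "scan_id"),
                 threshold = if (prune_side == "lowest") q else NA_real_),
            class = "brain_graph")
}

#' Build the thresholded brain graph of one scan in a single call
#'
#' @param X A `feature_matrix`.
#' @inheritParams build_adjacency
#' @inheritParams threshold_graph
#' @return A `brain_graph` carrying `X` as node features.
#' @export
build_brain_graph <- function(X, metric = c("mahalanobis", "taxicab"), tau = 0,
                              prune_side = c("lowest", "highest")) {
  A <- build_adjacency(X, metric)
  threshold_graph(A, tau, X = X, prune_side = prune_side)
}

#' @export
print.brain_graph <- function(x, ...) {
  cat("brain_graph:", x$n_regions, "nodes,", nrow(x$edges), "edges",
      sprintf("(metric=%s, tau=%g)\n", x$metric %||% "?", x$tau))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reconstruct the dense weighted adjacency of a brain graph
#' @param G A `brain_graph`.
#' @return N x N symmetric matrix with zero diagonal.
#' @export
graph_adjacency <- function(G) {
  A <- matrix(0, G$n_regions, G$n_regions)
  if (nrow(G$edges)) {
    A[cbind(G$edges$i, G$edges$j)] <- G$edges$weight
    A[cbind(G$edges$j, G$edges$i)] <- G$edges$weight
  }
  A
}

#' Serialize a brain graph to text files
#'
#' Writes `<stem>.edges.tsv` (i, j, weight with 17 significant digits),
#' `<stem>.features.tsv` and a JSON sidecar `<stem>.json` (metric, tau, N,
#' scan_id, threshold). The round-trip through [deserialize_graph()] is
#' lossless.
#'
#' @param G A `brain_graph`.
#' @param stem Output path stem (no extension).
#' @return `stem`, invisibly.
#' @export
serialize_graph <- function(G, stem) {
  ed <- G$edges
  lines <- c("i\tj\tweight",
             if (nrow(ed)) sprintf("%d\t%d\t%.17g", ed$i, ed$j, ed$weight))
  writeLines(lines, paste0(stem, ".edges.tsv"))
  if (!is.null(G$features)) {
    X <- unclass(G$features)
    flines <- c(paste(c("region_id", colnames(X)), collapse = "\t"),
                sprintf("%s\t%.17g\t%.17g\t%.17g\t%.17g",
                        rownames(X) %||% seq_len(nrow(X)),
                        X[, 1], X[, 2], X[, 3], X[, 4]))
    writeLines(flines, paste0(stem, ".features.tsv"))
  }
  jsonlite::write_json(
    list(metric = G$metric, tau = G$tau, n_regions = G$n_regions,
         scan_id = G$scan_id, threshold = G$threshold,
         has_features = !is.null(G$features)),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(stem)
}

#' Read a brain graph written by [serialize_graph()]
#' @param stem Path stem used at write time.
#' @return A `brain_graph`.
#' @export
deserialize_graph <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  epath <- paste0(stem, ".edges.tsv")
  lines <- readLines(epath)
  if (!length(lines) || lines[1] != "i\tj\tweight") {
    stop("malformed edge file ", epath, " at line 1: expected header 'i\\tj\\tweight'")
  }
  if (length(lines) > 1) {
    parts <- strsplit(lines[-1], "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 3)
    if (length(bad)) stop("malformed edge file ", epath, " at line ", bad[1] + 1)
    edges <- data.table::data.table(
      i = as.integer(vapply(parts, `[[`, "", 1)),
      j = as.integer(vapply(parts, `[[`, "", 2)),
      weight = as.numeric(vapply(parts, `[[`, "", 3)))
    if (anyNA(edges)) stop("malformed edge file ", epath, " at line ",
                           which(rowSums(is.na(edges)) > 0)[1] + 1)
  } else {
    edges <- data.table::data.table(i = integer(0), j = integer(0),
                                    weight = numeric(0))
  }
  X <- NULL
  if (isTRUE(side$has_features)) {
    ft <- data.table::fread(paste0(stem, ".features.tsv"), sep = "\t")
    X <- as.matrix(ft[, -1, with = FALSE])
    dimnames(X) <- list(ft[[1]], stat_names)
    X <- structure(X, class = c("feature_matrix", "matrix", "array"),
                   scan_id = side$scan_id)
  }
  structure(list(features = X, edges = edges, tau = side$tau,
                 metric = side$metric, n_regions = side$n_regions,
                 scan_id = side$scan_id,
                 threshold = side$threshold %||% NA_real_),
            class = "brain_graph")
}

#' Export a brain graph to GraphML (requires the igraph package)
#' @param G A `brain_graph`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(G, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("GraphML export needs the igraph package")
  }
  g <- igraph::graph_from_data_frame(G$edges[, c("i", "j")], directed = FALSE,
                                     vertices = data.frame(name = seq_len(G$n_regions)))
  igraph::E(g)$weight <- G$edges$weight
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
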