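# Graph convolutional network for whole-graph classification.
#
# Propagation rule per layer: H^(l+1) = relu(D~^{-1/2} (A + I) D~^{-1/2} H^(l) W^(l) + b^(l))
# with D~ the diagonal degree matrix of A + I (self-loop weight 1). Three
# 64-channel layers, global mean pooling over nodes, dropout 0.3 on the
# pooled vector and a single affine head to C classes: 8835 trainable
# parameters at C = 3. Training is full explicit backpropagation with the
# Adam optimizer; no external deep-learning framework is involved, so the
# arithmetic is auditable end to end.

#' Construct a GCN classification model
#'
#' Three graph-convolution layers of `hidden` channels (ReLU, per-channel
#' biases), global mean pooling, dropout on the pooled vector and an affine
#' classification head. Weights are Glorot-uniform initialized, biases zero.
#'
#' @param n_classes Number of classes C.
#' @param in_dim Node feature dimension (4: mu, sigma, gamma, k).
#' @param hidden Channels per GCN layer (default 64).
#' @param dropout Dropout rate applied to the pooled vector during training
#'   (default 0.3).
#' @param two_layer_head Use a two-layer (hidden -> hidden -> C) head instead
#'   of the single affine map. Off by default; enabling it changes the
#'   parameter count away from 8835.
#' @param seed Optional seed for reproducible initialization.
#' @return Object of class `gcn_model`.
#' @examples
#' m <- gcn_model(3, seed = 1)
#' count_parameters(m)  # 8835
#' @export
gcn_model <- function(n_classes, in_dim = 4L, hidden = 64L, dropout = 0.3,
                      two_layer_head = FALSE, seed = NULL) {
  if (n_classes < 2) stop("need at least 2 classes")
  if (!is.null(seed)) set.seed(seed)
  glorot <- function(fin, fout) {
    lim <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
  }
  params <- list(
    W1 = glorot(in_dim, hidden), b1 = numeric(hidden),
    W2 = glorot(hidden, hidden), b2 = numeric(hidden),
    W3 = glorot(hidden, hidden), b3 = numeric(hidden)
  )
  if (two_layer_head) {
    params$Wh1 <- glorot(hidden, hidden); params$bh1 <- numeric(hidden)
    params$Wh <- glorot(hidden, n_classes); params$bh <- numeric(n_classes)
  } else {
    params$Wh <- glorot(hidden, n_classes); params$bh <- numeric(n_classes)
  }
  structure(list(params = params, n_classes = as.integer(n_classes),
                 in_dim = as.integer(in_dim), hidden = as.integer(hidden),
                 dropout = dropout, two_layer_head = two_layer_head,
                 classes = NULL),
            class = "gcn_model")
}

#' Count trainable parameters of a GCN model
#' @param model A `gcn_model`.
#' @return Integer number of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.gcn_model <- function(x, ...) {
  cat(sprintf("gcn_model: %d GCN channels x 3 layers, %s head, C=%d, %d parameters\n",
              x$hidden, if (x$two_layer_head) "2-layer" else "affine",
              x$n_classes, count_parameters(x)))
  invisible(x)
}

#' Symmetric degree-normalized adjacency with self-loops
#'
#' \eqn{\hat A = \tilde D^{-1/2} (A + I) \tilde D^{-1/2}} where
#' \eqn{\tilde D} is the diagonal of row sums of A + I. Self-loops carry
#' weight 1, so no degree can vanish. Edge weights are the raw retained
#' distances.
#'
#' @param G A `brain_graph`, or a dense symmetric weighted adjacency matrix
#'   with zero diagonal.
#' @return Dense symmetric N x N matrix.
#' @export
normalize_adjacency <- function(G) {
  A <- if (inherits(G, "brain_graph")) graph_adjacency(G) else as.matrix(G)
  if (any(A < 0)) stop("edge weights must be non-negative")
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * tcrossprod(dinv)
}

#' One graph-convolution layer forward pass
#'
#' `relu(A_hat %*% H %*% W + b)` with the bias broadcast per output channel.
#'
#' @param H N x d input node embedding.
#' @param A_hat Normalized adjacency ([normalize_adjacency()]).
#' @param W d x d' weight matrix.
#' @param b Length-d' bias.
#' @param activation Apply the ReLU (default `TRUE`).
#' @return N x d' matrix.
#' @export
gcn_layer_forward <- function(H, A_hat, W, b, activation = TRUE) {
  if (ncol(H) != nrow(W)) stop("shape mismatch: H has ", ncol(H),
                               " columns but W has ", nrow(W), " rows")
  if (length(b) != ncol(W)) stop("bias length must equal output channels")
  Z <- A_hat %*% H %*% W
  Z <- sweep(as.matrix(Z), 2, b, "+")
  if (activation) pmax(Z, 0) else Z
}

#' Forward pass of the full model on one graph
#'
#' Three GCN layers, global mean pooling over nodes, dropout (training mode
#' only) and the classification head.
#'
#' @param G A `brain_graph` with node features attached.
#' @param model A `gcn_model`.
#' @param training Apply dropout (default `FALSE`; evaluation is
#'   deterministic).
#' @return Numeric vector of C logits.
#' @export
model_forward <- function(G, model, training = FALSE) {
  X <- unclass(G$features)
  if (is.null(X)) stop("graph has no node features")
  if (ncol(X) != model$in_dim) {
    stop("feature dimension ", ncol(X), " does not match model (", model$in_dim, ")")
  }
  Ah <- normalize_adjacency(G)
  p <- model$params
  H <- gcn_layer_forward(X, Ah, p$W1, p$b1)
  H <- gcn_layer_forward(H, Ah, p$W2, p$b2)
  H <- gcn_layer_forward(H, Ah, p$W3, p$b3)
  pool <- colMeans(H)
  if (training && model$dropout > 0) {
    mask <- stats::runif(length(pool)) >= model$dropout
    pool <- pool * mask / (1 - model$dropout)
  }
  if (model$two_layer_head) {
    pool <- pmax(drop(pool %*% p$Wh1) + p$bh1, 0)
  }
  drop(pool %*% p$Wh) + p$bh
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

# --- stacked (mini-batch) machinery -----------------------------------------

# Precompute per-graph normalized adjacencies (sparse) and feature rows.
prepare_gcn_data <- function(graphs) {
  N <- graphs[[1]]$n_regions
  d <- ncol(graphs[[1]]$features)
  for (g in graphs) {
    if (g$n_regions != N) stop("all graphs must share the same node count")
    if (is.null(g$features) || ncol(g$features) != d) {
      stop("all graphs need node features of equal dimension")
    }
  }
  list(
    Ahat = lapply(graphs, function(g)
      methods::as(normalize_adjacency(g), "CsparseMatrix")),
    X = lapply(graphs, function(g) unclass(g$features)),
    N = N, d = d
  )
}

# Forward + optional backward on a batch of graph indices.
# Returns loss, probs and (if grad) parameter gradients.
gcn_batch_pass <- function(prep, model, idx, y = NULL, sample_w = NULL,
                           training = FALSE, grad = FALSE) {
  p <- model$params
  N <- prep$N
  B <- length(idx)
  A <- Matrix::bdiag(prep$Ahat[idx])
  Xb <- do.call(rbind, prep$X[idx])
  gid <- rep(seq_len(B), each = N)

  M1 <- Xb %*% p$W1
  Z1 <- sweep(as.matrix(A %*% M1), 2, p$b1, "+"); H1 <- pmax(Z1, 0)
  M2 <- H1 %*% p$W2
  Z2 <- sweep(as.matrix(A %*% M2), 2, p$b2, "+"); H2 <- pmax(Z2, 0)
  M3 <- H2 %*% p$W3
  Z3 <- sweep(as.matrix(A %*% M3), 2, p$b3, "+"); H3 <- pmax(Z3, 0)
  P <- rowsum(H3, gid) / N

  if (training && model$dropout > 0) {
    mask <- matrix(stats::runif(length(P)) >= model$dropout, nrow(P), ncol(P))
    Pd <- P * mask / (1 - model$dropout)
  } else {
    mask <- NULL
    Pd <- P
  }
  if (model$two_layer_head) {
    Zh1 <- sweep(Pd %*% p$Wh1, 2, p$bh1, "+"); Hh1 <- pmax(Zh1, 0)
  } else {
    Hh1 <- Pd
  }
  logits <- sweep(Hh1 %*% p$Wh, 2, p$bh, "+")
  probs <- softmax_rows(logits)

  loss <- NA_real_
  if (!is.null(y)) {
    if (is.null(sample_w)) sample_w <- rep(1, B)
    picked <- pmax(probs[cbind(seq_len(B), y)], 1e-12)
    loss <- sum(-log(picked) * sample_w) / sum(sample_w)
  }
  if (!grad) return(list(loss = loss, probs = probs))

  Gm <- probs
  Gm[cbind(seq_len(B), y)] <- Gm[cbind(seq_len(B), y)] - 1
  Gm <- Gm * (sample_w / sum(sample_w))

  grads <- list()
  grads$Wh <- crossprod(Hh1, Gm)
  grads$bh <- colSums(Gm)
  dHh1 <- Gm %*% t(p$Wh)
  if (model$two_layer_head) {
    dZh1 <- dHh1 * (Zh1 > 0)
    grads$Wh1 <- crossprod(Pd, dZh1)
    grads$bh1 <- colSums(dZh1)
    dPd <- dZh1 %*% t(p$Wh1)
  } else {
    dPd <- dHh1
  }
  dP <- if (!is.null(mask)) dPd * mask / (1 - model$dropout) else dPd
  dH3 <- dP[gid, , drop = FALSE] / N
  dZ3 <- dH3 * (Z3 > 0)
  dM3 <- as.matrix(A %*% dZ3)
  grads$W3 <- crossprod(H2, dM3)
  grads$b3 <- colSums(dZ3)
  dH2 <- dM3 %*% t(p$W3)
  dZ2 <- dH2 * (Z2 > 0)
  dM2 <- as.matrix(A %*% dZ2)
  grads$W2 <- crossprod(H1, dM2)
  grads$b2 <- colSums(dZ2)
  dH1 <- dM2 %*% t(p$W2)
  dZ1 <- dH1 * (Z1 > 0)
  dM1 <- as.matrix(A %*% dZ1)
  grads$W1 <- crossprod(Xb, dM1)
  grads$b1 <- colSums(dZ1)

  list(loss = loss, probs = probs, grads = grads)
}

#' Training configuration for the GCN
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Maximum epochs (default 200).
#' @param batch_size Mini-batch size in graphs (default 16; use `Inf` for
#'   full-batch steps).
#' @param seed Seed controlling initialization order, shuffling and dropout.
#' @param patience Early-stopping patience in epochs on validation loss
#'   (only active when a validation set is supplied; default 20).
#' @param class_weights Weight the cross-entropy inversely to class
#'   frequency (default `FALSE`).
#' @return List of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 200L, batch_size = 16L,
                         seed = 1L, patience = 20L, class_weights = FALSE) {
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = batch_size, seed = as.integer(seed),
                 patience = as.integer(patience), class_weights = class_weights),
            class = "train_config")
}

encode_labels <- function(labels, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(labels)))
  y <- match(as.character(labels), classes)
  if (anyNA(y)) stop("labels outside the model's class set: ",
                     paste(unique(labels[is.na(y)]), collapse = ", "))
  list(y = y, classes = classes)
}

#' Train a GCN on labeled brain graphs
#'
#' Minimizes the (optionally class-weighted) cross-entropy with Adam.
#' All randomness — shuffling and dropout — is governed by `config$seed`;
#' identical seeds give identical trained weights. When a validation set is
#' supplied, training stops after `patience` epochs without improvement in
#' validation loss and the best weights are restored.
#'
#' @param model A `gcn_model` (its initialization is kept as the starting
#'   point).
#' @param graphs List of `brain_graph`s with identical node counts.
#' @param labels Class labels (factor/character/integer), one per graph;
#'   at least two distinct classes.
#' @param config A [train_config()].
#' @param val_graphs,val_labels Optional validation set for early stopping.
#' @return The trained `gcn_model` with a `history` data.frame attached
#'   (`epoch`, `train_loss`, `train_acc`, `val_loss`, `val_acc`).
#' @export
train_gcn <- function(model, graphs, labels, config = train_config(),
                      val_graphs = NULL, val_labels = NULL) {
  stopifnot(inherits(model, "gcn_model"))
  if (length(graphs) != length(labels)) stop("one label per graph required")
  enc <- encode_labels(labels, model$classes)
  if (length(unique(enc$y)) < 2) stop("training set contains a single class")
  if (length(enc$classes) != model$n_classes) {
    stop("model built for ", model$n_classes, " classes but labels have ",
         length(enc$classes))
  }
  model$classes <- enc$classes
  y <- enc$y
  n <- length(graphs)
  prep <- prepare_gcn_data(graphs)
  if (ncol(prep$X[[1]]) != model$in_dim) {
    stop("feature dimension mismatch with model")
  }
  has_val <- !is.null(val_graphs)
  if (has_val) {
    venc <- encode_labels(val_labels, model$classes)
    vprep <- prepare_gcn_data(val_graphs)
  }
  w_class <- if (isTRUE(config$class_weights)) {
    tab <- tabulate(y, nbins = model$n_classes)
    n / (model$n_classes * pmax(tab, 1))
  } else rep(1, model$n_classes)

  set.seed(config$seed)
  opt <- adam_state(model$params)
  bs <- if (is.finite(config$batch_size)) min(config$batch_size, n) else n
  best_val <- Inf; best_params <- model$params; wait <- 0L
  hist <- vector("list", config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      out <- gcn_batch_pass(prep, model, idx, y = y[idx],
                            sample_w = w_class[y[idx]],
                            training = TRUE, grad = TRUE)
      upd <- adam_step(model$params, out$grads, opt, config$learning_rate)
      model$params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + out$loss * length(idx)
      ep_correct <- ep_correct + sum(max.col(out$probs) == y[idx])
    }
    val_loss <- NA_real_; val_acc <- NA_real_
    if (has_val) {
      vout <- gcn_batch_pass(vprep, model, seq_along(val_graphs),
                             y = venc$y, sample_w = w_class[venc$y])
      val_loss <- vout$loss
      val_acc <- mean(max.col(vout$probs) == venc$y)
      if (val_loss < best_val - 1e-8) {
        best_val <- val_loss; best_params <- model$params; wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / n,
                             train_acc = ep_correct / n,
                             val_loss = val_loss, val_acc = val_acc)
    if (has_val && wait >= config$patience) break
  }
  if (has_val) model$params <- best_params
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  model
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- state$beta1 * state$m[[k]] + (1 - state$beta1) * g
    state$v[[k]] <- state$beta2 * state$v[[k]] + (1 - state$beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + state$eps)
    if (!is.null(dim(params[[k]]))) dimnames(params[[k]]) <- NULL
    else names(params[[k]]) <- NULL
  }
  list(params = params, state = state)
}

#' Predict classes and probabilities for brain graphs
#'
#' Evaluation mode (no dropout); probabilities are softmax over logits and
#' sum to 1 per graph. Batch prediction equals per-graph prediction.
#'
#' @param model A trained `gcn_model`.
#' @param graphs List of `brain_graph`s with the model's node count.
#' @return List with `labels` (predicted class names, or indices when the
#'   model was never trained), `probs` (graphs x C matrix) and `logits`.
#' @export
predict_gcn <- function(model, graphs) {
  stopifnot(inherits(model, "gcn_model"))
  prep <- prepare_gcn_data(graphs)
  out <- gcn_batch_pass(prep, model, seq_along(graphs))
  # recompute logits for reporting
  pred_idx <- max.col(out$probs, ties.method = "first")
  labels <- if (!is.null(model$classes)) model$classes[pred_idx] else pred_idx
  colnames(out$probs) <- model$classes
  list(labels = labels, probs = out$probs)
}

#' Save / load a GCN checkpoint as JSON
#'
#' Stores weights, architecture and class labels in plain text.
#'
#' @param model A `gcn_model`.
#' @param path JSON output path.
#' @return `path` (write) or the restored `gcn_model` (read).
#' @export
write_gcn_checkpoint <- function(model, path) {
  obj <- list(
    n_classes = model$n_classes, in_dim = model$in_dim, hidden = model$hidden,
    dropout = model$dropout, two_layer_head = model$two_layer_head,
    classes = model$classes,
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
      else list(dim = NULL, data = as.vector(p))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_gcn_checkpoint
#' @export
read_gcn_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim)) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  structure(list(params = params, n_classes = obj$n_classes,
                 in_dim = obj$in_dim, hidden = obj$hidden,
                 dropout = obj$dropout, two_layer_head = isTRUE(obj$two_layer_head),
                 classes = obj$classes),
            class = "gcn_model")
}
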