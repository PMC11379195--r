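#' Sigmoid activation
#'
#' \eqn{S(x) = 1 / (1 + e^{-x})}: bounded output for every input, with a
#' gradient (\eqn{S(x)(1 - S(x))}) that is cheap to compute during
#' backpropagation. Computed in a branch that never overflows, and clamped
#' away from exactly 0 and 1 so downstream logs and ROC thresholds stay
#' finite.
#'
#' @param x numeric vector/matrix.
#' @return values strictly inside (0, 1).
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  pmin(pmax(out, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' Preset network architectures
#'
#' Three compact hidden-layer layouts: \code{"A"} = (7, 4), \code{"B"} =
#' (10, 10), \code{"C"} = (5, 4, 3). The input width is the panel size and
#' the output layer is a single sigmoid unit scoring the cancer class.
#'
#' @param arch \code{"A"}, \code{"B"}, \code{"C"} or a numeric vector of
#'   hidden layer sizes.
#' @return integer vector of hidden layer sizes.
#' @export
mlp_architecture <- function(arch = "A") {
  presets <- list(A = c(7, 4), B = c(10, 10), C = c(5, 4, 3))
  if (is.character(arch)) {
    if (!arch %in% names(presets)) {
      stop("unknown architecture '", arch, "'; use A, B, C or a numeric vector",
           call. = FALSE)
    }
    return(presets[[arch]])
  }
  arch <- as.integer(arch)
  if (!length(arch) || any(is.na(arch)) || any(arch < 1)) {
    stop("hidden layer sizes must be integers >= 1", call. = FALSE)
  }
  arch
}

#' Initialize a feed-forward sigmoid network
#'
#' Weights and biases are drawn i.i.d. uniform(-0.5, 0.5) under the seed, so
#' two initializations with the same arguments are identical.
#'
#' @param n_inputs input width (the panel size).
#' @param arch hidden layers; see [mlp_architecture()].
#' @param seed integer seed.
#' @return an object of class \code{"meth_mlp"} with weight matrices
#'   \code{W} (one per layer, incoming x outgoing) and bias vectors \code{b}.
#' @export
init_network <- function(n_inputs, arch = "A", seed = 1) {
  hidden <- mlp_architecture(arch)
  if (n_inputs < 1) stop("n_inputs must be >= 1", call. = FALSE)
  sizes <- c(n_inputs, hidden, 1L)
  with_seed(seed, {
    W <- vector("list", length(sizes) - 1L)
    b <- vector("list", length(sizes) - 1L)
    for (l in seq_along(W)) {
      W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -0.5, 0.5),
                       sizes[l], sizes[l + 1])
      b[[l]] <- stats::runif(sizes[l + 1], -0.5, 0.5)
    }
    structure(list(sizes = sizes, W = W, b = b, seed = seed,
                   panel_sites = NULL, trained = FALSE, history = NULL),
              class = "meth_mlp")
  })
}

#' @export
print.meth_mlp <- function(x, ...) {
  cat(sprintf("meth_mlp: layers %s%s\n",
              paste(x$sizes, collapse = " -> "),
              if (x$trained) sprintf(", trained (%d epochs, final loss %.4g)",
                                     length(x$history), x$history[length(x$history)])
              else " (untrained)"))
  invisible(x)
}

# Forward pass returning all layer activations (a[[1]] is the input).
mlp_forward <- function(model, X) {
  a <- vector("list", length(model$W) + 1L)
  a[[1]] <- X
  for (l in seq_along(model$W)) {
    z <- a[[l]] %*% model$W[[l]] +
      matrix(model$b[[l]], nrow(X), length(model$b[[l]]), byrow = TRUE)
    a[[l + 1]] <- sigmoid(z)
  }
  a
}

mlp_loss <- function(scores, y, loss) {
  if (loss == "mse") mean((scores - y)^2)
  else -mean(y * log(scores) + (1 - y) * log(1 - scores))
}

# Full-batch gradient of the loss w.r.t. every weight and bias.
mlp_gradient <- function(model, X, y, loss = "mse") {
  n <- nrow(X)
  a <- mlp_forward(model, X)
  out <- a[[length(a)]]
  delta <- if (loss == "mse") {
    2 * (out - y) / n * out * (1 - out)
  } else {
    (out - y) / n
  }
  L <- length(model$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- unname(crossprod(a[[l]], delta))
    gb[[l]] <- unname(colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(model$W[[l]])) * a[[l]] * (1 - a[[l]])
    }
  }
  list(W = gW, b = gb)
}

#' Train the network by full-batch backpropagation
#'
#' Gradient descent on the mean-squared error (default) or cross-entropy of
#' the single sigmoid output against 0/1 class labels (Cancer = 1). The
#' learning rate decreases slowly over time as
#' \code{lr0 / (1 + decay * epoch)}. Training stops at \code{max_epochs} or
#' when the loss improves by less than \code{tol}. Cohort sizes here are a
#' few hundred samples on a 10-odd-site panel, so full-batch updates are
#' cheap and deterministic.
#'
#' The test partition is quarantined: passing a matrix tagged
#' \code{partition == "test"} is an error.
#'
#' @param model an initialized [init_network()] model.
#' @param x training features: binarized [meth_matrix()] (restricted to the
#'   panel) or a plain numeric matrix.
#' @param labels class labels; defaults to those stored in \code{x}.
#' @param lr0 initial learning rate (default 1).
#' @param decay learning-rate decay constant.
#' @param max_epochs maximum number of epochs.
#' @param tol convergence tolerance on the loss improvement.
#' @param loss \code{"mse"} or \code{"cross_entropy"}.
#' @return the trained model; \code{$history} holds the per-epoch loss.
#' @export
train_network <- function(model, x, labels = NULL, lr0 = 1, decay = 0.001,
                          max_epochs = 3000, tol = 1e-9,
                          loss = c("mse", "cross_entropy")) {
  loss <- match.arg(loss)
  if (lr0 <= 0) stop("lr0 must be positive", call. = FALSE)
  if (inherits(x, "meth_matrix") && identical(x$partition, "test")) {
    stop("refusing to train on the quarantined test partition", call. = FALSE)
  }
  labels <- labels_or(x, labels)
  X <- values_of(x)
  if (anyNA(X)) stop("training features contain missing values", call. = FALSE)
  if (ncol(X) != model$sizes[1]) {
    stop(sprintf("feature width %d does not match network input width %d",
                 ncol(X), model$sizes[1]), call. = FALSE)
  }
  y <- as.numeric(labels == "Cancer")

  history <- numeric(max_epochs)
  prev <- Inf
  for (epoch in seq_len(max_epochs)) {
    g <- mlp_gradient(model, X, y, loss)
    lr <- lr0 / (1 + decay * (epoch - 1))
    for (l in seq_along(model$W)) {
      model$W[[l]] <- model$W[[l]] - lr * g$W[[l]]
      model$b[[l]] <- model$b[[l]] - lr * g$b[[l]]
    }
    cur <- mlp_loss(mlp_forward(model, X)[[length(model$W) + 1L]], y, loss)
    if (!is.finite(cur)) {
      stop(sprintf("non-finite loss at epoch %d", epoch), call. = FALSE)
    }
    history[epoch] <- cur
    if (abs(prev - cur) < tol) {
      history <- history[seq_len(epoch)]
      break
    }
    prev <- cur
  }
  model$trained <- TRUE
  model$history <- history
  if (inherits(x, "meth_matrix")) model$panel_sites <- colnames(X)
  model
}

#' Score samples with a trained network
#'
#' Forward pass producing one score in (0, 1) per sample. If the model
#' carries panel site names, the feature columns are checked and reordered
#' to the training panel order.
#'
#' @param model a \code{meth_mlp}.
#' @param x features ([meth_matrix()] or numeric matrix).
#' @return named numeric vector of scores.
#' @export
predict_scores <- function(model, x) {
  X <- values_of(x)
  if (nrow(X) == 0) return(stats::setNames(numeric(0), character(0)))
  if (!is.null(model$panel_sites)) {
    miss <- setdiff(model$panel_sites, colnames(X))
    if (length(miss)) {
      stop("features are missing panel site(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    X <- X[, model$panel_sites, drop = FALSE]
  } else if (ncol(X) != model$sizes[1]) {
    stop(sprintf("feature width %d does not match network input width %d",
                 ncol(X), model$sizes[1]), call. = FALSE)
  }
  a <- mlp_forward(model, X)
  stats::setNames(as.vector(a[[length(a)]]), rownames(X))
}

#' Threshold scores into class labels
#'
#' @param scores numeric scores in \[0, 1\].
#' @param threshold decision threshold; scores at or above it are Cancer.
#' @return factor of labels.
#' @export
classify <- function(scores, threshold = 0.5) {
  as_label_factor(ifelse(scores >= threshold, "Cancer", "Normal"))
}

#' Serialize a network to JSON / read it back
#'
#' Architecture, weights, biases, seed and panel sites as a portable JSON
#' document.
#'
#' @param model a \code{meth_mlp}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_network_json <- function(model, path) {
  obj <- list(sizes = model$sizes,
              W = lapply(model$W, function(w) unclass(w)),
              b = model$b, seed = model$seed,
              panel_sites = model$panel_sites, trained = model$trained)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(obj$sizes)
  W <- obj$W
  # jsonlite returns matrices for rectangular arrays; coerce defensively
  W <- lapply(seq_along(W), function(l) {
    matrix(as.numeric(W[[l]]), sizes[l], sizes[l + 1])
  })
  b <- lapply(obj$b, as.numeric)
  panel_sites <- if (length(obj$panel_sites)) as.character(obj$panel_sites) else NULL
  structure(list(sizes = sizes, W = W, b = b, seed = obj$seed,
                 panel_sites = panel_sites,
                 trained = isTRUE(obj$trained), history = NULL),
            class = "meth_mlp")
}
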