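# Shared fixtures and independent oracles for the test suite.

# A labeled beta matrix built by hand from a numeric matrix.
toy_matrix <- function(values, labels = NULL, positions = NULL, ...) {
  if (is.null(rownames(values))) rownames(values) <- sprintf("P%d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("S%d", seq_len(ncol(values)))
  meth_matrix(values, labels = labels, positions = positions, ...)
}

# Small strongly-separated cohort for fast end-to-end tests.
small_config <- function(seed = 7, ...) {
  cohort_config(n_cancer = 60, n_normal = 40, n_sites = 400,
                n_informative = 12, n_bad_sites = 4, n_bad_patients = 2,
                seed = seed, ...)
}

# Independent exhaustive information-gain oracle: plain-loop entropy scan,
# written from the definition (base-2 class entropy, weighted child average).
oracle_entropy <- function(y) {
  p <- mean(y)
  h <- 0
  for (q in c(p, 1 - p)) if (q > 0) h <- h - q * log2(q)
  h
}

oracle_gains <- function(X, y) {
  vapply(seq_len(ncol(X)), function(j) {
    on <- X[, j] == 1
    h <- oracle_entropy(y)
    for (side in list(y[on], y[!on])) {
      if (length(side) > 0) h <- h - length(side) / length(y) * oracle_entropy(side)
    }
    h
  }, numeric(1))
}

# Independent AUC oracle: pairwise concordance with half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "Cancer"]
  neg <- scores[labels == "Normal"]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Central finite-difference gradient of the training loss for one network.
numeric_gradient <- function(model, X, y, loss, eps = 1e-6) {
  loss_at <- function(m) {
    a <- methpanel:::mlp_forward(m, X)
    methpanel:::mlp_loss(a[[length(a)]], y, loss)
  }
  gW <- lapply(model$W, function(w) array(0, dim(w)))
  gb <- lapply(model$b, function(b) numeric(length(b)))
  for (l in seq_along(model$W)) {
    for (i in seq_along(model$W[[l]])) {
      m1 <- model; m1$W[[l]][i] <- m1$W[[l]][i] + eps
      m2 <- model; m2$W[[l]][i] <- m2$W[[l]][i] - eps
      gW[[l]][i] <- (loss_at(m1) - loss_at(m2)) / (2 * eps)
    }
    for (i in seq_along(model$b[[l]])) {
      m1 <- model; m1$b[[l]][i] <- m1$b[[l]][i] + eps
      m2 <- model; m2$b[[l]][i] <- m2$b[[l]][i] - eps
      gb[[l]][i] <- (loss_at(m1) - loss_at(m2)) / (2 * eps)
    }
  }
  list(W = gW, b = gb)
}

# Write a small GDC-style per-sample file from a data.frame of rows.
write_sample_fixture <- function(rows, path, header = TRUE) {
  lines <- apply(rows, 1, paste, collapse = "\t")
  if (header) lines <- c("probe_id\tchromosome\tposition\tbeta_value", lines)
  writeLines(lines, path)
  path
}
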