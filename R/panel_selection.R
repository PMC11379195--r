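#' Entropy of a two-class node (base 2)
#'
#' Shannon entropy of the class mix in a decision-tree node,
#' \eqn{-p_N \log_2 p_N - p_C \log_2 p_C}, with \eqn{0 \log 0 = 0}. Base-2
#' logarithms make the scale run from 0 (a pure node, fully divided data) to
#' 1 (an evenly mixed node).
#'
#' @param normal_fraction,cancer_fraction class fractions; must sum to 1.
#' @return entropy in \[0, 1\] bits.
#' @export
node_entropy <- function(normal_fraction, cancer_fraction) {
  if (any(normal_fraction < 0) || any(cancer_fraction < 0) ||
      any(abs(normal_fraction + cancer_fraction - 1) > 1e-8)) {
    stop("class fractions must be non-negative and sum to 1", call. = FALSE)
  }
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  -plogp(normal_fraction) - plogp(cancer_fraction)
}

# Entropy from a cancer-fraction vector (internal, vectorized).
entropy_p <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -p[ok] * log2(p[ok]) - (1 - p[ok]) * log2(1 - p[ok])
  h
}

# Information gain of every column of a binary matrix for binary labels y.
# Returns a vector of gains (NA for zero-variance columns is not needed:
# their gain is 0 by construction).
info_gain <- function(X, y) {
  n <- length(y)
  n1 <- colSums(X)
  n0 <- n - n1
  c1 <- as.vector(crossprod(X, y))
  c0 <- sum(y) - c1
  h_parent <- entropy_p(mean(y))
  p1 <- ifelse(n1 > 0, c1 / n1, 0)
  p0 <- ifelse(n0 > 0, c0 / n0, 0)
  h_children <- (n1 * entropy_p(p1) + n0 * entropy_p(p0)) / n
  h_parent - h_children
}

no_informative_split <- function(msg = "no site with positive information gain") {
  structure(class = c("methpanel_no_informative_split", "error", "condition"),
            list(message = msg, call = NULL))
}

node_stats <- function(y) {
  n <- length(y)
  p_c <- if (n > 0) mean(y) else 0
  list(n = n, n_cancer = sum(y), n_normal = n - sum(y),
       cancer_fraction = p_c, normal_fraction = 1 - p_c,
       entropy = entropy_p(p_c),
       # majority label; an exact tie goes to Cancer (the screening-safe side)
       pred = if (sum(y) >= n - sum(y)) "Cancer" else "Normal")
}

best_split <- function(X, y, excluded) {
  open <- setdiff(colnames(X), excluded)
  if (!length(open)) return(NULL)
  gains <- info_gain(X[, open, drop = FALSE], y)
  if (max(gains) <= 0) return(NULL)
  # ties broken by lowest column index in the original matrix order
  best <- open[which.max(gains)]
  list(site = best, gain = max(gains))
}

#' Fit a depth-2 entropy decision tree on binary methylation features
#'
#' The root split site is the one with maximal information gain (base-2 node
#' entropy) over all non-excluded sites; each impure child with an available
#' positive-gain split is split once more the same way, so the tree holds one
#' primary separating site and up to two secondary, mistake-correcting sites.
#' Pure or unsplittable children become leaves predicting their majority
#' class. If no site achieves positive gain at the root, a
#' \code{methpanel_no_informative_split} condition is signalled (the
#' selection loop catches it).
#'
#' @param x binarized [meth_matrix()] or a plain 0/1 matrix with column names.
#' @param labels class labels; defaults to those stored in \code{x}.
#' @param excluded character vector of site ids barred from splitting (the
#'   selection loop's exclusion mask).
#' @return an object of class \code{"depth2_tree"}.
#' @export
fit_depth2_tree <- function(x, labels = NULL, excluded = character(0)) {
  labels <- labels_or(x, labels)
  X <- values_of(x)
  if (!all(X %in% c(0, 1))) {
    stop("features must be binary; binarize() the matrix first", call. = FALSE)
  }
  if (is.null(colnames(X))) stop("feature matrix needs column names", call. = FALSE)
  y <- as.numeric(labels == "Cancer")

  root_split <- best_split(X, y, excluded)
  if (is.null(root_split)) stop(no_informative_split())

  grow_child <- function(rows) {
    yc <- y[rows]
    st <- node_stats(yc)
    if (st$entropy == 0) return(c(st, list(type = "leaf")))
    sp <- best_split(X[rows, , drop = FALSE], yc, excluded)
    if (is.null(sp)) return(c(st, list(type = "leaf")))
    on <- X[rows, sp$site] == 1
    c(st, list(type = "split", site = sp$site, gain = sp$gain,
               left = c(node_stats(yc[!on]), list(type = "leaf")),
               right = c(node_stats(yc[on]), list(type = "leaf"))))
  }

  on <- X[, root_split$site] == 1
  tree <- c(node_stats(y),
            list(type = "split", site = root_split$site, gain = root_split$gain,
                 left = grow_child(which(!on)),
                 right = grow_child(which(on))))
  structure(tree, class = "depth2_tree")
}

#' @export
print.depth2_tree <- function(x, ...) {
  fmt_leaf <- function(nd) sprintf("-> %s (n=%d, H=%.3f)", nd$pred, nd$n, nd$entropy)
  fmt_child <- function(nd, indent) {
    if (nd$type == "leaf") return(paste0(indent, fmt_leaf(nd)))
    paste(c(sprintf("%ssplit %s (gain %.3f)", indent, nd$site, nd$gain),
            paste0(indent, "  0 ", fmt_leaf(nd$left)),
            paste0(indent, "  1 ", fmt_leaf(nd$right))), collapse = "\n")
  }
  cat(sprintf("depth2_tree: root %s (gain %.3f, n=%d)\n", x$site, x$gain, x$n))
  cat("  0 ", sub("^\\s*", "", fmt_child(x$left, "  ")), "\n", sep = "")
  cat("  1 ", sub("^\\s*", "", fmt_child(x$right, "  ")), "\n", sep = "")
  invisible(x)
}

# Ordered distinct split sites: root first, then second-level left-to-right.
tree_sites <- function(tree) {
  out <- tree$site
  for (child in list(tree$left, tree$right)) {
    if (child$type == "split") out <- c(out, child$site)
  }
  unique(out)
}

#' Predict class labels from a fitted depth-2 tree
#'
#' @param object a \code{depth2_tree}.
#' @param newdata binarized [meth_matrix()] or 0/1 matrix containing the
#'   tree's split sites.
#' @param ... ignored.
#' @return factor of predicted labels.
#' @export
predict.depth2_tree <- function(object, newdata, ...) {
  X <- values_of(newdata)
  descend <- function(node, rows, out) {
    if (node$type == "leaf" || length(rows) == 0) {
      out[rows] <- node$pred
      return(out)
    }
    on <- X[rows, node$site] == 1
    out <- descend(node$left, rows[!on], out)
    descend(node$right, rows[on], out)
  }
  out <- character(nrow(X))
  out <- descend(object, seq_len(nrow(X)), out)
  as_label_factor(out)
}

#' Training-set classification accuracy of a depth-2 tree
#'
#' @param tree a \code{depth2_tree}.
#' @param x binarized matrix.
#' @param labels class labels; defaults to those stored in \code{x}.
#' @return fraction of samples whose leaf-majority label matches.
#' @export
tree_accuracy <- function(tree, x, labels = NULL) {
  labels <- labels_or(x, labels)
  mean(predict(tree, x) == labels)
}

#' Iterative masked CpG panel selection
#'
#' Repeatedly fits depth-2 entropy trees, masking every previously selected
#' site so that each run must discover new primary and secondary separating
#' locations. Each run contributes its 1–3 distinct split sites (root first,
#' then second-level children left to right); the loop stops at the end of
#' the first run that brings the panel to at least \code{min_panel} sites
#' (giving 10–12 sites with the defaults), or early — with a warning — when
#' no informative split remains or \code{max_runs} is reached.
#'
#' @param x binarized training data ([meth_matrix()] or 0/1 matrix).
#' @param labels class labels; defaults to those stored in \code{x}.
#' @param min_panel stop once the panel has at least this many sites.
#' @param max_runs hard cap on tree-fitting runs.
#' @return a \code{cpg_panel} data.frame with columns \code{site},
#'   \code{run} (which tree produced it) and \code{order} (selection order).
#' @export
iterative_select <- function(x, labels = NULL, min_panel = 10, max_runs = 50) {
  labels <- labels_or(x, labels)
  X <- values_of(x)
  if (nrow(X) == 0 || ncol(X) == 0) stop("empty matrix", call. = FALSE)
  sites <- character(0)
  runs <- integer(0)
  for (run in seq_len(max_runs)) {
    tree <- tryCatch(fit_depth2_tree(X, labels, excluded = sites),
                     methpanel_no_informative_split = function(e) NULL)
    if (is.null(tree)) {
      warning(sprintf("selection stopped after %d run(s): no informative split left (panel size %d)",
                      run - 1L, length(sites)), call. = FALSE)
      break
    }
    new_sites <- tree_sites(tree)
    sites <- c(sites, new_sites)
    runs <- c(runs, rep(run, length(new_sites)))
    if (length(sites) >= min_panel) break
    if (run == max_runs) {
      warning(sprintf("selection stopped at max_runs = %d with panel size %d",
                      max_runs, length(sites)), call. = FALSE)
    }
  }
  structure(data.frame(site = sites, run = runs, order = seq_along(sites),
                       stringsAsFactors = FALSE),
            class = c("cpg_panel", "data.frame"))
}

#' Separation score of a CpG site
#'
#' \eqn{-\frac{CancerMedian - cutoff}{CancerSD} \cdot
#'      \frac{NormalMedian - cutoff}{NormalSD}}: a rough, SD-standardized
#' measure of how far the two group medians sit on opposite sides of the
#' methylation cutoff. The score is positive exactly when the medians
#' straddle the cutoff, negative when both lie on the same side, and zero
#' when a median falls exactly on it. Undefined (\code{NA}) when either
#' group SD is zero.
#'
#' @param cancer_median,normal_median group medians of the continuous beta
#'   values.
#' @param cancer_sd,normal_sd group sample standard deviations.
#' @param cutoff methylation cutoff, default 0.3.
#' @return numeric score (vectorized).
#' @export
separation_score <- function(cancer_median, normal_median,
                             cancer_sd, normal_sd, cutoff = 0.3) {
  score <- -((cancer_median - cutoff) / cancer_sd) *
    ((normal_median - cutoff) / normal_sd)
  score[!is.na(cancer_sd) & cancer_sd == 0] <- NA_real_
  score[!is.na(normal_sd) & normal_sd == 0] <- NA_real_
  score
}

#' Per-site group medians and standard deviations
#'
#' Computed on continuous (pre-binarization) beta values; SDs use the sample
#' (n - 1) convention.
#'
#' @param x continuous [meth_matrix()] or numeric matrix.
#' @param sites site ids (default: all).
#' @param labels class labels; defaults to those stored in \code{x}.
#' @return data.frame with cancer/normal medians and SDs per site.
#' @export
site_group_stats <- function(x, sites = NULL, labels = NULL) {
  labels <- labels_or(x, labels)
  v <- values_of(x)
  sites <- sites %||% colnames(v)
  missing_sites <- setdiff(sites, colnames(v))
  if (length(missing_sites)) {
    stop("site(s) not in matrix: ", paste(missing_sites, collapse = ", "),
         call. = FALSE)
  }
  vc <- v[labels == "Cancer", sites, drop = FALSE]
  vn <- v[labels == "Normal", sites, drop = FALSE]
  data.frame(
    site = sites,
    cancer_median = apply(vc, 2, stats::median, na.rm = TRUE),
    normal_median = apply(vn, 2, stats::median, na.rm = TRUE),
    cancer_sd = apply(vc, 2, stats::sd, na.rm = TRUE),
    normal_sd = apply(vn, 2, stats::sd, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Refine a selected panel with the separation score
#'
#' Computes each panel site's group medians, SDs and separation score on the
#' continuous (pre-binarization) values — conventionally the pooled training
#' and validation samples — and retains only sites with strictly positive
#' scores, i.e. those whose cancer and normal medians fall on opposite sides
#' of the cutoff. Excluded sites stay in the table, flagged
#' \code{retained = FALSE}, with the score that disqualified them; sites with
#' a zero group SD are excluded with an \code{NA} score.
#'
#' @param panel a \code{cpg_panel} from [iterative_select()].
#' @param x continuous [meth_matrix()] holding the panel sites.
#' @param labels class labels; defaults to those stored in \code{x}.
#' @param cutoff methylation cutoff, default 0.3.
#' @return the panel with statistics, scores, position annotations (when
#'   available) and the \code{retained} flag.
#' @export
refine_panel <- function(panel, x, labels = NULL, cutoff = 0.3) {
  labels <- labels_or(x, labels)
  stats_df <- site_group_stats(x, panel$site, labels)
  score <- separation_score(stats_df$cancer_median, stats_df$normal_median,
                            stats_df$cancer_sd, stats_df$normal_sd, cutoff)
  out <- cbind(panel, stats_df[, -1, drop = FALSE],
               data.frame(separation_score = score,
                          retained = !is.na(score) & score > 0))
  if (inherits(x, "meth_matrix") && !is.null(x$positions)) {
    m <- match(out$site, x$positions$site)
    out$chromosome <- x$positions$chromosome[m]
    out$position <- x$positions$position[m]
  }
  n_excl <- sum(!out$retained)
  if (n_excl > 0) {
    reasons <- ifelse(is.na(out$separation_score[!out$retained]),
                      "zero group SD", "non-positive separation score")
    message(sprintf("refine_panel: excluded %d site(s): %s", n_excl,
                    paste(sprintf("%s (%s)", out$site[!out$retained], reasons),
                          collapse = ", ")))
  }
  class(out) <- c("cpg_panel", "data.frame")
  out
}
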