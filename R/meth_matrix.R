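#' Labeled beta-value matrix
#'
#' The central data container of the package: a samples x CpG-sites matrix of
#' methylation beta values in \[0, 1\] (possibly with missing entries),
#' together with per-sample class labels (\code{"Cancer"} / \code{"Normal"}),
#' per-site genomic positions, and a free-text tissue tag. Probes that do not
#' map to the genome carry the sentinel position \code{"*"}.
#'
#' @param values numeric matrix, samples as rows and CpG sites as columns;
#'   rownames are sample ids, colnames are probe ids. Non-missing entries must
#'   lie in \[0, 1\].
#' @param labels character or factor of length \code{nrow(values)} with values
#'   \code{"Cancer"} or \code{"Normal"}, or \code{NULL} for unlabeled data.
#' @param positions \code{data.frame} with columns \code{site},
#'   \code{chromosome}, \code{position} (character; \code{"*"} marks unmapped
#'   probes), one row per column of \code{values}, or \code{NULL}.
#' @param tissue free-text tissue tag.
#' @param binary logical; \code{TRUE} once the matrix has been binarized at
#'   the methylation cutoff.
#'
#' @return an object of class \code{"meth_matrix"}.
#' @export
meth_matrix <- function(values, labels = NULL, positions = NULL,
                        tissue = NA_character_, binary = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (samples x sites)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have sample ids as rownames and site ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("sample ids must be unique", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("site ids must be unique", call. = FALSE)
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    stop("non-missing beta values must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(values)) {
      stop("length(labels) must equal the number of samples", call. = FALSE)
    }
    labels <- as_label_factor(labels)
  }
  if (!is.null(positions)) {
    need <- c("site", "chromosome", "position")
    if (!all(need %in% names(positions))) {
      stop("'positions' needs columns site, chromosome, position", call. = FALSE)
    }
    positions <- positions[match(colnames(values), positions$site),
                           need, drop = FALSE]
    if (anyNA(positions$site)) {
      stop("'positions' must cover every site in 'values'", call. = FALSE)
    }
    positions$position <- as.character(positions$position)
    rownames(positions) <- NULL
  }
  structure(
    list(values = values, labels = labels, positions = positions,
         tissue = tissue, binary = isTRUE(binary), partition = NULL,
         drop_log = list()),
    class = "meth_matrix"
  )
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d samples x %d CpG sites%s\n",
              nrow(x$values), ncol(x$values),
              if (x$binary) " (binarized)" else ""))
  if (!is.na(x$tissue)) cat("  tissue:", x$tissue, "\n")
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat(sprintf("  labels: %d Cancer / %d Normal\n", tb[["Cancer"]], tb[["Normal"]]))
  }
  na_frac <- mean(is.na(x$values))
  cat(sprintf("  missing: %.2f%% of entries\n", 100 * na_frac))
  if (!is.null(x$partition)) cat("  partition:", x$partition, "\n")
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) dim(x$values)

#' Subset a meth_matrix by samples and/or sites
#'
#' Labels, positions and metadata are carried along.
#'
#' @param x a \code{meth_matrix}.
#' @param i sample index (integer, logical or sample ids).
#' @param j site index (integer, logical or site ids).
#' @param ... ignored.
#' @return a \code{meth_matrix}.
#' @export
`[.meth_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  out <- x
  out$values <- x$values[i, j, drop = FALSE]
  if (!is.null(x$labels)) out$labels <- x$labels[i]
  if (!is.null(x$positions)) {
    out$positions <- x$positions[match(colnames(out$values), x$positions$site), ,
                                 drop = FALSE]
    rownames(out$positions) <- NULL
  }
  out
}

sites_of <- function(x) colnames(x$values)
samples_of <- function(x) rownames(x$values)

# Extract the numeric matrix whether given a meth_matrix or a plain matrix.
values_of <- function(x) {
  if (inherits(x, "meth_matrix")) x$values else x
}

labels_or <- function(x, labels) {
  if (!is.null(labels)) return(as_label_factor(labels))
  if (inherits(x, "meth_matrix") && !is.null(x$labels)) return(x$labels)
  stop("sample labels are required (none stored in the matrix)", call. = FALSE)
}
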