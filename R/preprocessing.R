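#' Remove probes that do not map to the genome
#'
#' Drops every site whose position is the sentinel \code{"*"} (the bulk of
#' missing values in 450k exports comes from such non-existent probes). The
#' number of removed sites is logged via \code{message()}.
#'
#' @param x a [meth_matrix()] with position annotations.
#' @return the matrix without unmapped sites.
#' @export
drop_unmapped_sites <- function(x) {
  if (is.null(x$positions)) return(x)
  unmapped <- x$positions$position == "*"
  if (!any(unmapped)) return(x)
  if (all(unmapped)) stop("all sites are unmapped ('*'); nothing left", call. = FALSE)
  message(sprintf("drop_unmapped_sites: removed %d unmapped sites", sum(unmapped)))
  out <- x[, !unmapped]
  out$drop_log$unmapped_sites <- sum(unmapped)
  out
}

#' Filter high-missingness sites, then patients
#'
#' Two strictly sequential passes: first every CpG site whose NA fraction
#' exceeds \code{site_thresh} is discarded, then every patient whose NA
#' fraction over the *remaining* sites exceeds \code{patient_thresh}. Sites
#' go first because there are far more of them, so losing one costs less
#' information than losing a patient — and the order matters: removing a bad
#' site changes the patients' NA fractions. Both thresholds are strict
#' ("more than 15\%"): an entity at exactly the threshold is retained.
#'
#' @param x a [meth_matrix()].
#' @param site_thresh,patient_thresh NA-fraction thresholds in (0, 1).
#' @return the filtered matrix; counts of dropped sites/patients are stored
#'   in its \code{drop_log} and logged via \code{message()}.
#' @export
filter_missing <- function(x, site_thresh = 0.15, patient_thresh = 0.15) {
  for (th in c(site_thresh, patient_thresh)) {
    if (!is.numeric(th) || length(th) != 1 || th <= 0 || th >= 1) {
      stop("thresholds must lie in (0, 1)", call. = FALSE)
    }
  }
  na_mat <- is.na(x$values)
  site_frac <- colMeans(na_mat)
  keep_sites <- site_frac <= site_thresh
  if (!any(keep_sites)) stop("no sites survive the missingness filter", call. = FALSE)
  out <- x[, keep_sites]

  patient_frac <- rowMeans(is.na(out$values))
  keep_patients <- patient_frac <= patient_thresh
  if (!any(keep_patients)) stop("no patients survive the missingness filter", call. = FALSE)
  out <- out[keep_patients, ]

  n_sites_dropped <- sum(!keep_sites)
  n_patients_dropped <- sum(!keep_patients)
  if (n_sites_dropped || n_patients_dropped) {
    message(sprintf("filter_missing: dropped %d sites, then %d patients",
                    n_sites_dropped, n_patients_dropped))
  }
  out$drop_log$na_sites <- n_sites_dropped
  out$drop_log$na_patients <- n_patients_dropped
  out
}

#' Impute remaining missing values with the per-site mean
#'
#' Replaces every remaining NA with the arithmetic mean of that CpG site's
#' non-missing values across all retained samples of the cohort (the whole
#' tissue, pooled over classes). Note this is computed before the data split,
#' which leaks a little information between partitions; [split_dataset()]
#' users wanting strict hygiene can split first and impute per partition.
#'
#' @param x a [meth_matrix()].
#' @return the matrix with no missing values; non-missing entries untouched.
#' @export
impute_site_mean <- function(x) {
  v <- x$values
  if (!anyNA(v)) return(x)
  site_mean <- colMeans(v, na.rm = TRUE)
  if (anyNA(site_mean) || any(is.nan(site_mean))) {
    stop("site(s) with no observed values cannot be mean-imputed", call. = FALSE)
  }
  idx <- which(is.na(v), arr.ind = TRUE)
  v[idx] <- site_mean[idx[, 2]]
  x$values <- v
  x
}

#' Binarize beta values at the methylation cutoff
#'
#' Entries at or above the cutoff are methylated (1), entries below are
#' unmethylated (0). The matrix must be complete — impute first.
#'
#' @param x a [meth_matrix()].
#' @param cutoff methylation threshold, default 0.3.
#' @return a binary [meth_matrix()] (\code{binary = TRUE}).
#' @export
binarize <- function(x, cutoff = 0.3) {
  if (anyNA(x$values)) {
    stop("matrix contains missing values; impute before binarizing", call. = FALSE)
  }
  x$values[] <- as.numeric(x$values >= cutoff)
  x$binary <- TRUE
  x
}

#' Randomly split a cohort into train / validation / test partitions
#'
#' A uniform random permutation of the samples under the given seed,
#' partitioned as round(0.70 n) training, round(0.20 n) validation and the
#' remainder (about 10\%) testing. The test partition is quarantined: it is
#' tagged so that model fitting refuses it, and should only be touched by the
#' final evaluation.
#'
#' @param x a [meth_matrix()].
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed integer seed for the permutation.
#' @param stratify if \code{TRUE}, apply the same rule within each label
#'   class (off by default; the reference procedure is unstratified).
#' @return an object of class \code{"meth_split"}: list with \code{train},
#'   \code{validation}, \code{test} matrices (each tagged with its partition
#'   name), plus the fractions and seed.
#' @export
split_dataset <- function(x, fractions = c(0.7, 0.2, 0.1), seed = 1,
                          stratify = FALSE) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8) {
    stop("'fractions' must be three numbers summing to 1", call. = FALSE)
  }
  n <- nrow(x$values)
  if (n < 3) stop("need at least 3 samples to split", call. = FALSE)

  take <- function(idx) {
    m <- length(idx)
    n_train <- round(fractions[1] * m)
    n_val <- round(fractions[2] * m)
    list(train = idx[seq_len(n_train)],
         validation = idx[n_train + seq_len(n_val)],
         test = idx[setdiff(seq_len(m), seq_len(n_train + n_val))])
  }
  parts <- with_seed(seed, {
    if (stratify && !is.null(x$labels)) {
      per_class <- lapply(split(seq_len(n), x$labels), function(ix) take(sample(ix)))
      list(train = unlist(lapply(per_class, `[[`, "train"), use.names = FALSE),
           validation = unlist(lapply(per_class, `[[`, "validation"), use.names = FALSE),
           test = unlist(lapply(per_class, `[[`, "test"), use.names = FALSE))
    } else {
      take(sample.int(n))
    }
  })
  out <- lapply(names(parts), function(nm) {
    m <- x[parts[[nm]], ]
    m$partition <- nm
    m
  })
  names(out) <- names(parts)
  structure(c(out, list(fractions = fractions, seed = seed)),
            class = "meth_split")
}

#' @export
print.meth_split <- function(x, ...) {
  cat(sprintf("meth_split: %d train / %d validation / %d test samples (seed %d)\n",
              nrow(x$train$values), nrow(x$validation$values),
              nrow(x$test$values), x$seed))
  invisible(x)
}

#' Partition sizes under the splitting rule
#'
#' Train and validation sizes are rounded to the nearest integer; the test
#' partition takes the remainder.
#'
#' @param n number of samples.
#' @param fractions train/validation/test fractions.
#' @return named integer vector (train, validation, test).
#' @export
split_sizes <- function(n, fractions = c(0.7, 0.2, 0.1)) {
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  c(train = n_train, validation = n_val, test = n - n_train - n_val)
}

#' First four moments of the beta-value distribution per class
#'
#' Pools all non-missing values of each label group and reports mean,
#' population variance, standardized skewness and excess kurtosis — a quick
#' check that the cancer and normal distributions are comparably normalized.
#' For a constant group the variance is 0 and skewness/kurtosis are reported
#' as \code{NA} (undefined).
#'
#' @param x a [meth_matrix()].
#' @param labels class labels; defaults to those stored in \code{x}.
#' @return data.frame with one row per group: n, mean, variance, skewness,
#'   kurtosis.
#' @export
group_moments <- function(x, labels = NULL) {
  labels <- labels_or(x, labels)
  v <- values_of(x)
  out <- lapply(levels(labels), function(g) {
    vals <- v[labels == g, , drop = FALSE]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) stop("empty group: ", g, call. = FALSE)
    m <- mean(vals)
    m2 <- mean((vals - m)^2)
    if (m2 == 0) {
      data.frame(group = g, n = length(vals), mean = m, variance = 0,
                 skewness = NA_real_, kurtosis = NA_real_)
    } else {
      m3 <- mean((vals - m)^3)
      m4 <- mean((vals - m)^4)
      data.frame(group = g, n = length(vals), mean = m, variance = m2,
                 skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
    }
  })
  do.call(rbind, out)
}
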