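#' Fit the sequential CpG-panel diagnostic classifier
#'
#' The package's main modelling function. Starting from a labeled beta-value
#' matrix it runs the full sequential procedure:
#' \enumerate{
#'   \item drop unmapped (\code{"*"}) probes;
#'   \item discard CpG sites, then patients, with more than 15\% missing
#'     values (in that order);
#'   \item mean-impute the remaining missing values per site;
#'   \item split 70/20/10 into train/validation/test (test quarantined);
#'   \item binarize at the 0.3 methylation cutoff;
#'   \item select a CpG panel by iterative masked depth-2 entropy trees on
#'     the binarized training data, until at least \code{min_panel} sites;
#'   \item refine the panel by the separation score on the continuous
#'     training + validation values, keeping positive-score sites only;
#'   \item train a feed-forward sigmoid network on the binarized training
#'     panel features and score the validation partition.
#' }
#' The test partition is never touched here; see [evaluate_test()].
#'
#' @param x a labeled [meth_matrix()], e.g. from [simulate_cohort()] or
#'   [read_cohort()].
#' @param cutoff methylation cutoff for binarization and the separation
#'   score.
#' @param site_na_thresh,patient_na_thresh missingness thresholds of the two
#'   filter passes.
#' @param fractions train/validation/test split fractions.
#' @param min_panel,max_runs panel-selection stopping parameters.
#' @param arch network architecture (see [mlp_architecture()]).
#' @param lr0,decay,epochs,tol,loss training schedule (see
#'   [train_network()]).
#' @param select_with_validation also let the selection trees see the
#'   validation samples (off by default: trees fit on training data only).
#' @param stratify stratify the split by class label.
#' @param seed integer seed driving the split and the weight initialization.
#' @return an object of class \code{"methpanel_fit"} with the panel, the
#'   trained network, the split, the validation ROC and the preprocessing
#'   log.
#' @seealso [evaluate_test()], [run_pipeline()]
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_cancer = 60, n_normal = 40,
#'                                         n_sites = 300, n_informative = 12,
#'                                         seed = 11))
#' fit <- methpanel(cohort, epochs = 500, seed = 11)
#' fit
#' evaluate_test(fit)$auc
#' @export
methpanel <- function(x, cutoff = 0.3,
                      site_na_thresh = 0.15, patient_na_thresh = 0.15,
                      fractions = c(0.7, 0.2, 0.1),
                      min_panel = 10, max_runs = 50,
                      arch = "A", lr0 = 1, decay = 0.001, epochs = 3000,
                      tol = 1e-9, loss = "mse",
                      select_with_validation = FALSE, stratify = FALSE,
                      seed = 1) {
  cl <- match.call()
  if (!inherits(x, "meth_matrix")) stop("'x' must be a meth_matrix", call. = FALSE)
  if (is.null(x$labels)) stop("'x' must carry Cancer/Normal labels", call. = FALSE)

  n_input <- dim(x)
  x <- drop_unmapped_sites(x)
  x <- filter_missing(x, site_na_thresh, patient_na_thresh)
  x <- impute_site_mean(x)
  split <- split_dataset(x, fractions, seed = seed, stratify = stratify)

  select_data <- if (select_with_validation) {
    rbind_matrices(split$train, split$validation)
  } else {
    split$train
  }
  select_bin <- binarize(select_data, cutoff)
  panel0 <- iterative_select(select_bin, min_panel = min_panel,
                             max_runs = max_runs)

  trainval <- rbind_matrices(split$train, split$validation)
  panel <- refine_panel(panel0, trainval, cutoff = cutoff)
  kept <- panel$site[panel$retained]
  if (!length(kept)) {
    warning("no panel site survived the separation-score refinement; ",
            "keeping the unrefined panel (its sites are unreliable)",
            call. = FALSE)
    kept <- panel$site
  }

  train_bin <- binarize(split$train, cutoff)[, kept]
  net <- init_network(length(kept), arch = arch, seed = seed)
  net <- train_network(net, train_bin, lr0 = lr0, decay = decay,
                       max_epochs = epochs, tol = tol, loss = loss)

  val_bin <- binarize(split$validation, cutoff)[, kept]
  val_scores <- predict_scores(net, val_bin)
  val_roc <- roc_curve(val_scores, split$validation$labels)

  structure(
    list(call = cl, panel = panel, sites = kept, net = net, split = split,
         cutoff = cutoff, validation_roc = val_roc,
         validation_scores = val_scores,
         drop_log = x$drop_log, n_input = n_input,
         seed = seed, test_evaluations = 0L),
    class = "methpanel_fit"
  )
}

# Row-bind two meth_matrix objects sharing the same sites.
rbind_matrices <- function(a, b) {
  stopifnot(identical(colnames(a$values), colnames(b$values)))
  out <- a
  out$values <- rbind(a$values, b$values)
  out$labels <- factor(c(as.character(a$labels), as.character(b$labels)),
                       levels = c("Normal", "Cancer"))
  out$partition <- NULL
  out
}

#' Evaluate a fitted classifier on its quarantined test partition
#'
#' The one place where the test partition is read: binarizes it at the fit's
#' cutoff, restricts to the panel, scores the samples and computes the ROC.
#'
#' @param fit a [methpanel()] fit.
#' @return the test-partition \code{roc_result}, with the scores attached as
#'   attribute \code{"scores"}.
#' @export
evaluate_test <- function(fit) {
  test_bin <- binarize(fit$split$test, fit$cutoff)[, fit$sites]
  scores <- predict_scores(fit$net, test_bin)
  roc <- roc_curve(scores, fit$split$test$labels)
  attr(roc, "scores") <- scores
  roc
}

#' @export
print.methpanel_fit <- function(x, ...) {
  cat("Sequential CpG-panel methylation classifier\n")
  cat(sprintf("  panel: %d sites retained of %d selected\n",
              length(x$sites), nrow(x$panel)))
  cat(sprintf("  network: %s, %d training epochs\n",
              paste(x$net$sizes, collapse = " -> "), length(x$net$history)))
  cat(sprintf("  validation AUC: %.4f\n", x$validation_roc$auc))
  invisible(x)
}

#' @export
summary.methpanel_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.methpanel_fit")
}

#' @export
print.summary.methpanel_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  input: %d samples x %d sites; dropped %s unmapped, %s NA-sites, %s NA-patients\n",
              f$n_input[1], f$n_input[2],
              f$drop_log$unmapped_sites %||% 0,
              f$drop_log$na_sites %||% 0,
              f$drop_log$na_patients %||% 0))
  cat(sprintf("  split: %d / %d / %d (train/validation/test), seed %d\n",
              nrow(f$split$train$values), nrow(f$split$validation$values),
              nrow(f$split$test$values), f$seed))
  cat("\nPanel (selection order; retained sites have positive separation score):\n")
  cols <- intersect(c("site", "run", "cancer_median", "normal_median",
                      "separation_score", "retained"), names(f$panel))
  print(as.data.frame(f$panel)[, cols], digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
coef.methpanel_fit <- function(object, ...) {
  list(W = object$net$W, b = object$net$b)
}

#' Score or classify new samples with a fitted classifier
#'
#' @param object a [methpanel()] fit.
#' @param newdata a [meth_matrix()] (continuous values are binarized at the
#'   fit's cutoff) or a 0/1 matrix over the panel sites; defaults to the
#'   validation partition.
#' @param type \code{"score"} for the network's (0, 1) outputs,
#'   \code{"class"} for thresholded labels.
#' @param threshold decision threshold for \code{type = "class"}.
#' @param ... ignored.
#' @return numeric scores or a factor of labels.
#' @export
predict.methpanel_fit <- function(object, newdata = NULL,
                                  type = c("score", "class"),
                                  threshold = 0.5, ...) {
  type <- match.arg(type)
  newdata <- newdata %||% object$split$validation
  if (inherits(newdata, "meth_matrix") && !newdata$binary) {
    newdata <- binarize(newdata, object$cutoff)
  }
  scores <- predict_scores(object$net, newdata)
  if (type == "score") scores else classify(scores, threshold)
}

#' Plot the validation (and optionally test) ROC curve of a fit
#'
#' @param x a [methpanel()] fit.
#' @param which \code{"validation"} or \code{"test"}.
#' @param ... passed to [plot.roc_result()].
#' @return the plotted \code{roc_result}, invisibly.
#' @export
plot.methpanel_fit <- function(x, which = c("validation", "test"), ...) {
  which <- match.arg(which)
  roc <- if (which == "validation") x$validation_roc else evaluate_test(x)
  plot(roc, ...)
  invisible(roc)
}

#' Run the whole pipeline and write its report files
#'
#' End-to-end orchestration: obtain a cohort (simulate from a
#' [cohort_config()] or read a directory of GDC-style files), fit the
#' sequential classifier, evaluate the quarantined test partition exactly
#' once, and — when \code{out_dir} is given — write the panel table, the
#' network JSON, the test ROC points, a QC report (group moments and
#' 2-component PCA coordinates of the train+validation samples; the test
#' partition is excluded from all visual QC) and a JSON run manifest with
#' every seed and count. Reruns with identical inputs produce byte-identical
#' manifests.
#'
#' @param config a [cohort_config()] (simulated cohort) or a directory path
#'   of per-sample files with a manifest (see [read_cohort()]).
#' @param out_dir output directory, or \code{NULL} to skip writing.
#' @param seed seed for the split and network initialization.
#' @param ... further arguments to [methpanel()].
#' @return an object of class \code{"methpanel_report"}: list with the fit,
#'   the test ROC, QC tables and the manifest.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL, seed = 1, ...) {
  cohort <- if (inherits(config, "cohort_config")) {
    simulate_cohort(config)
  } else if (is.character(config)) {
    read_cohort(config)
  } else {
    stop("'config' must be a cohort_config or a cohort directory", call. = FALSE)
  }

  fit <- methpanel(cohort, seed = seed, ...)
  test_roc <- evaluate_test(fit)
  fit$test_evaluations <- 1L

  trainval <- rbind_matrices(fit$split$train, fit$split$validation)
  qc_moments <- group_moments(trainval)
  qc_pca <- pca_project(trainval, k = 2)

  manifest <- list(
    seed = seed,
    cohort = list(n_samples = fit$n_input[1], n_sites = fit$n_input[2],
                  simulated = inherits(config, "cohort_config"),
                  cohort_seed = if (inherits(config, "cohort_config")) config$seed else NULL),
    dropped = fit$drop_log,
    split = list(train = nrow(fit$split$train$values),
                 validation = nrow(fit$split$validation$values),
                 test = nrow(fit$split$test$values)),
    panel = list(selected = nrow(fit$panel), retained = length(fit$sites),
                 sites = fit$sites),
    network = list(layers = fit$net$sizes, epochs = length(fit$net$history)),
    validation_auc = fit$validation_roc$auc,
    test_auc = test_roc$auc,
    test_evaluations = fit$test_evaluations
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_panel(fit$panel, file.path(out_dir, "panel.tsv"),
                include_excluded = TRUE)
    write_network_json(fit$net, file.path(out_dir, "model.json"))
    utils::write.table(test_roc$points, file.path(out_dir, "roc_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(qc_moments, file.path(out_dir, "qc_moments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample_id = rownames(qc_pca),
                                  label = as.character(trainval$labels),
                                  PC1 = qc_pca[, 1], PC2 = qc_pca[, 2]),
                       file.path(out_dir, "qc_pca.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(fit = fit, test_roc = test_roc, qc_moments = qc_moments,
                 qc_pca = qc_pca, manifest = manifest),
            class = "methpanel_report")
}

#' @export
print.methpanel_report <- function(x, ...) {
  cat("methpanel pipeline report\n")
  cat(sprintf("  panel: %d retained sites; validation AUC %.4f; test AUC %.4f\n",
              length(x$fit$sites), x$fit$validation_roc$auc, x$test_roc$auc))
  invisible(x)
}
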