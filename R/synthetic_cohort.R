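#' Configuration for a synthetic tumor/normal methylation cohort
#'
#' Describes a simulated 450k-style cohort: class sizes (cancer samples
#' outnumber normals by default, as in public tumor repositories), a set of
#' planted informative CpG sites whose cancer and normal beta distributions
#' have medians on opposite sides of the 0.3 methylation cutoff, a bimodal
#' beta-mixture background of uninformative sites, and structured missingness
#' (a uniform base rate plus designated "bad" sites and patients whose NA
#' fraction exceeds the 15\% preprocessing threshold).
#'
#' @param n_cancer,n_normal number of cancer / normal samples.
#' @param n_sites total number of CpG sites.
#' @param n_informative number of planted discriminative sites.
#' @param informative_direction \code{"hyper_in_cancer"} or
#'   \code{"hypo_in_cancer"}, recycled to length \code{n_informative}. The
#'   default follows the tissue tag: bladder and kidney cohorts plant
#'   hypomethylated-in-cancer sites, prostate hypermethylated-in-cancer.
#' @param cancer_beta_params,normal_beta_params beta shape pairs (alpha, beta)
#'   for the cancer / normal group at a hypermethylated-in-cancer site; the
#'   pairs are swapped between groups at hypomethylated-in-cancer sites. The
#'   defaults Beta(8, 2) vs Beta(2, 8) put the group medians at about 0.82 and
#'   0.18, well on opposite sides of the cutoff.
#' @param background_mixture list with elements \code{shape1}, \code{shape2}
#'   (beta shape pairs) and \code{weight}: each background site is assigned to
#'   the first mixture component with probability \code{weight}, mimicking the
#'   bimodal methylome (most CpGs are stably unmethylated or methylated).
#' @param na_rate_base probability that any single entry is missing.
#' @param n_bad_sites,n_bad_patients number of sites / patients given an
#'   elevated missingness rate (drawn from background sites only, so the
#'   planted signal survives the NA filters).
#' @param na_rate_bad missingness fraction for bad entities; must exceed 0.15
#'   so that the 15\% filters have work to do. Applied as an exact count
#'   (\code{ceiling(na_rate_bad * m)} cells), guaranteeing a strict
#'   NA fraction > 0.15.
#' @param tissue free-text tissue tag.
#' @param seed integer seed; the whole cohort is reproducible given the
#'   configuration.
#'
#' @return an object of class \code{"cohort_config"}.
#' @seealso [generate_cohort()], [inject_missingness()]
#' @export
cohort_config <- function(n_cancer = 200, n_normal = 120, n_sites = 2000,
                          n_informative = 15,
                          informative_direction = NULL,
                          cancer_beta_params = c(8, 2),
                          normal_beta_params = c(2, 8),
                          background_mixture = list(shape1 = c(1.5, 8),
                                                    shape2 = c(8, 1.5),
                                                    weight = 0.5),
                          na_rate_base = 0.01,
                          n_bad_sites = 10, n_bad_patients = 3,
                          na_rate_bad = 0.30,
                          tissue = "bladder", seed = 1) {
  chk_count <- function(x, field, min = 0) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
      stop_cfg(field, sprintf("must be a single integer >= %d", min))
    }
  }
  chk_count(n_cancer, "n_cancer", 1)
  chk_count(n_normal, "n_normal", 1)
  chk_count(n_sites, "n_sites", 1)
  chk_count(n_informative, "n_informative", 0)
  chk_count(n_bad_sites, "n_bad_sites", 0)
  chk_count(n_bad_patients, "n_bad_patients", 0)
  if (n_informative > n_sites) stop_cfg("n_informative", "must be <= n_sites")

  chk_rate <- function(x, field) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
      stop_cfg(field, "must be a fraction in [0, 1]")
    }
  }
  chk_rate(na_rate_base, "na_rate_base")
  chk_rate(na_rate_bad, "na_rate_bad")
  if ((n_bad_sites > 0 || n_bad_patients > 0) && na_rate_bad <= 0.15) {
    stop_cfg("na_rate_bad", "must exceed 0.15 when bad sites/patients are requested")
  }

  chk_shape <- function(x, field) {
    if (length(x) != 2 || !is.numeric(x) || anyNA(x) || any(x <= 0)) {
      stop_cfg(field, "must be a pair of strictly positive beta shape parameters")
    }
  }
  chk_shape(cancer_beta_params, "cancer_beta_params")
  chk_shape(normal_beta_params, "normal_beta_params")
  chk_shape(background_mixture$shape1, "background_mixture$shape1")
  chk_shape(background_mixture$shape2, "background_mixture$shape2")
  chk_rate(background_mixture$weight, "background_mixture$weight")

  if (is.null(informative_direction)) {
    informative_direction <- if (tissue %in% c("bladder", "kidney")) {
      "hypo_in_cancer"
    } else {
      "hyper_in_cancer"
    }
  }
  if (!all(informative_direction %in% c("hyper_in_cancer", "hypo_in_cancer"))) {
    stop_cfg("informative_direction",
             "must be 'hyper_in_cancer' or 'hypo_in_cancer'")
  }
  informative_direction <- rep_len(informative_direction, n_informative)

  # Planted sites must have group medians on opposite sides of the cutoff;
  # checked exactly via the beta quantile function, no sampling involved.
  hi_med <- stats::qbeta(0.5, cancer_beta_params[1], cancer_beta_params[2])
  lo_med <- stats::qbeta(0.5, normal_beta_params[1], normal_beta_params[2])
  if (n_informative > 0 && !(hi_med > 0.3 && lo_med < 0.3) &&
      !(hi_med < 0.3 && lo_med > 0.3)) {
    stop_cfg("cancer_beta_params/normal_beta_params",
             "must give group medians on opposite sides of the 0.3 cutoff")
  }

  chk_count(seed, "seed")
  structure(
    list(n_cancer = n_cancer, n_normal = n_normal, n_sites = n_sites,
         n_informative = n_informative,
         informative_direction = informative_direction,
         cancer_beta_params = cancer_beta_params,
         normal_beta_params = normal_beta_params,
         background_mixture = background_mixture,
         na_rate_base = na_rate_base,
         n_bad_sites = n_bad_sites, n_bad_patients = n_bad_patients,
         na_rate_bad = na_rate_bad, tissue = tissue, seed = seed),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("cohort_config: %d cancer + %d normal samples, %d sites (%d informative), tissue '%s', seed %d\n",
              x$n_cancer, x$n_normal, x$n_sites, x$n_informative, x$tissue, x$seed))
  invisible(x)
}

#' Generate a complete (NA-free) synthetic cohort
#'
#' Draws a labeled beta-value matrix from the configuration: informative sites
#' from the class-specific beta distributions, background sites from the
#' shared bimodal mixture (each background site is committed to one mixture
#' component, so it is stably methylated or unmethylated across the cohort).
#' Site ids are synthetic 450k-style probe ids (\code{"cg"} + 8 digits) with
#' invented chromosome/position annotations. Byte-identical output for an
#' identical configuration.
#'
#' @param config a [cohort_config()].
#' @return a [meth_matrix()] with no missing values. The planted truth (which
#'   sites are informative, and their direction) is stored in the
#'   \code{$truth} field for downstream validation.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("'config' must be a cohort_config object", call. = FALSE)
  }
  n <- config$n_cancer + config$n_normal
  p <- config$n_sites
  with_seed(config$seed, {
    site_ids <- sort(sprintf("cg%08d", sample.int(99999999L, p)))
    sample_ids <- c(sprintf("%s-C%04d", config$tissue, seq_len(config$n_cancer)),
                    sprintf("%s-N%04d", config$tissue, seq_len(config$n_normal)))
    labels <- c(rep("Cancer", config$n_cancer), rep("Normal", config$n_normal))

    informative <- if (config$n_informative > 0) {
      sort(sample(site_ids, config$n_informative))
    } else {
      character(0)
    }
    is_inf <- site_ids %in% informative

    values <- matrix(NA_real_, n, p, dimnames = list(sample_ids, site_ids))
    is_cancer <- labels == "Cancer"

    # Background: per-site mixture component, then per-cell beta draws.
    bg_idx <- which(!is_inf)
    if (length(bg_idx)) {
      mix <- config$background_mixture
      comp1 <- stats::runif(length(bg_idx)) < mix$weight
      for (k in seq_along(bg_idx)) {
        ab <- if (comp1[k]) mix$shape1 else mix$shape2
        values[, bg_idx[k]] <- stats::rbeta(n, ab[1], ab[2])
      }
    }

    # Informative sites: class-specific distributions, direction per site.
    inf_idx <- which(is_inf)
    dir <- config$informative_direction
    for (k in seq_along(inf_idx)) {
      hi <- config$cancer_beta_params
      lo <- config$normal_beta_params
      if (dir[k] == "hypo_in_cancer") { tmp <- hi; hi <- lo; lo <- tmp }
      values[is_cancer, inf_idx[k]] <- stats::rbeta(sum(is_cancer), hi[1], hi[2])
      values[!is_cancer, inf_idx[k]] <- stats::rbeta(sum(!is_cancer), lo[1], lo[2])
    }

    positions <- data.frame(
      site = site_ids,
      chromosome = paste0("chr", sample(1:22, p, replace = TRUE)),
      position = as.character(sample.int(2.4e8, p)),
      stringsAsFactors = FALSE
    )

    out <- meth_matrix(values, labels = labels, positions = positions,
                       tissue = config$tissue)
    out$truth <- list(informative = informative,
                      direction = stats::setNames(dir, informative))
    out
  })
}

#' Inject structured missingness into a complete cohort
#'
#' Applies the configuration's missingness model: every cell is set to NA
#' independently with probability \code{na_rate_base}; then
#' \code{n_bad_sites} background sites and \code{n_bad_patients} patients
#' each receive an exact count of \code{ceiling(na_rate_bad * m)} missing
#' cells, guaranteeing an NA fraction strictly above the 15\% filter
#' threshold. Seeded by \code{config$seed} (offset, so it does not replay the
#' value-generation stream).
#'
#' @param x a complete [meth_matrix()] (no missing values).
#' @param config the [cohort_config()] used to generate it.
#' @return the matrix with missing entries.
#' @export
inject_missingness <- function(x, config) {
  if (!inherits(x, "meth_matrix")) stop("'x' must be a meth_matrix", call. = FALSE)
  if (anyNA(x$values)) stop("'x' must be complete (no missing values)", call. = FALSE)
  n <- nrow(x$values); p <- ncol(x$values)
  if (config$n_bad_sites > p) stop_cfg("n_bad_sites", "exceeds the number of sites")
  if (config$n_bad_patients > n) stop_cfg("n_bad_patients", "exceeds the number of patients")
  candidates <- setdiff(colnames(x$values), x$truth$informative %||% character(0))
  if (config$n_bad_sites > length(candidates)) {
    stop_cfg("n_bad_sites", "exceeds the number of background sites")
  }
  with_seed(config$seed + 1L, {
    v <- x$values
    if (config$na_rate_base > 0) {
      v[stats::runif(length(v)) < config$na_rate_base] <- NA_real_
    }
    if (config$n_bad_sites > 0) {
      bad_sites <- sample(candidates, config$n_bad_sites)
      k <- ceiling(config$na_rate_bad * n)
      for (s in bad_sites) v[sample.int(n, k), s] <- NA_real_
    }
    if (config$n_bad_patients > 0) {
      bad_patients <- sample(rownames(v), config$n_bad_patients)
      k <- ceiling(config$na_rate_bad * p)
      for (s in bad_patients) v[s, sample.int(p, k)] <- NA_real_
    }
    x$values <- v
    x
  })
}

#' Generate a cohort with missingness in one call
#'
#' Convenience wrapper: [generate_cohort()] followed by
#' [inject_missingness()].
#'
#' @param config a [cohort_config()].
#' @return a [meth_matrix()].
#' @export
simulate_cohort <- function(config = cohort_config()) {
  inject_missingness(generate_cohort(config), config)
}
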