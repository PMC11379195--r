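#' Read a GDC-style per-sample methylation file
#'
#' Parses a tab-separated file with one CpG probe per row and four columns:
#' probe id, chromosome, position, beta value. The beta value is \code{"NA"}
#' (or empty) when missing; probes that do not map to the genome carry the
#' position sentinel \code{"*"} and are flagged, not dropped — removing them
#' is the job of [drop_unmapped_sites()]. A single header line is detected
#' automatically (its fourth field is neither a number nor an NA literal).
#'
#' @param path path to the file.
#' @param sample_id sample identifier; defaults to the file name up to the
#'   first dot.
#' @return an object of class \code{"sample_record"}: a list with
#'   \code{sample_id} and a \code{rows} data.frame (probe_id, chromosome,
#'   position, beta, unmapped).
#' @export
read_sample_file <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sample_id <- sample_id %||% sub("\\..*$", "", basename(path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty methylation file: ", path, call. = FALSE)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  na_literals <- c("NA", "")

  is_na_literal <- function(s) s %in% na_literals
  first <- fields[[1]]
  has_header <- length(first) == 4 && !is_na_literal(first[4]) &&
    is.na(suppressWarnings(as.numeric(first[4])))
  if (has_header) {
    fields <- fields[-1]
    line_no <- line_no[-1]
  }
  if (!length(fields)) {
    return(structure(list(sample_id = sample_id,
                          rows = data.frame(probe_id = character(0),
                                            chromosome = character(0),
                                            position = character(0),
                                            beta = numeric(0),
                                            unmapped = logical(0))),
                     class = "sample_record"))
  }

  nf <- lengths(fields)
  if (any(nf != 4)) {
    bad <- which(nf != 4)[1]
    stop(sprintf("parse error in %s, line %d: expected 4 tab-separated fields, found %d",
                 path, line_no[bad], nf[bad]), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  beta_str <- m[, 4]
  beta <- suppressWarnings(as.numeric(beta_str))
  beta[is_na_literal(beta_str)] <- NA_real_
  bad_num <- which(is.na(beta) & !is_na_literal(beta_str))
  if (length(bad_num)) {
    stop(sprintf("parse error in %s, line %d: beta value '%s' is not numeric",
                 path, line_no[bad_num[1]], beta_str[bad_num[1]]), call. = FALSE)
  }
  oob <- which(!is.na(beta) & (beta < 0 | beta > 1))
  if (length(oob)) {
    stop(sprintf("parse error in %s, line %d: beta value %s outside [0, 1]",
                 path, line_no[oob[1]], beta_str[oob[1]]), call. = FALSE)
  }
  if (anyDuplicated(m[, 1])) {
    stop(sprintf("parse error in %s: duplicate probe id '%s'",
                 path, m[duplicated(m[, 1]), 1][1]), call. = FALSE)
  }
  rows <- data.frame(probe_id = m[, 1], chromosome = m[, 2], position = m[, 3],
                     beta = beta, unmapped = m[, 3] == "*",
                     stringsAsFactors = FALSE)
  structure(list(sample_id = sample_id, rows = rows), class = "sample_record")
}

#' @export
print.sample_record <- function(x, ...) {
  cat(sprintf("sample_record '%s': %d probes (%d unmapped, %d missing beta)\n",
              x$sample_id, nrow(x$rows), sum(x$rows$unmapped), sum(is.na(x$rows$beta))))
  invisible(x)
}

#' Assemble sample records into a labeled beta-value matrix
#'
#' Takes the intersection of the records' probe universes (logging how many
#' probes were dropped), orders sites lexicographically by probe id, and
#' joins class labels and tissue from the manifest.
#'
#' @param records list of [read_sample_file()] results.
#' @param manifest data.frame with columns \code{sample_id}, \code{tissue},
#'   \code{label}; every record's sample must appear in it.
#' @return a [meth_matrix()].
#' @export
assemble_matrix <- function(records, manifest) {
  if (!length(records)) stop("no sample records given", call. = FALSE)
  ids <- vapply(records, function(r) r$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample ids in records", call. = FALSE)
  missing_manifest <- setdiff(ids, manifest$sample_id)
  if (length(missing_manifest)) {
    stop("sample(s) absent from manifest: ", paste(missing_manifest, collapse = ", "),
         call. = FALSE)
  }
  universes <- lapply(records, function(r) r$rows$probe_id)
  common <- sort(Reduce(intersect, universes))
  dropped <- length(unique(unlist(universes))) - length(common)
  if (dropped > 0) {
    message(sprintf("assemble_matrix: dropped %d probes outside the common universe", dropped))
  }
  if (!length(common)) stop("records share no probes", call. = FALSE)

  values <- do.call(rbind, lapply(records, function(r) {
    r$rows$beta[match(common, r$rows$probe_id)]
  }))
  dimnames(values) <- list(ids, common)

  ref <- records[[1]]$rows
  positions <- data.frame(site = common,
                          chromosome = ref$chromosome[match(common, ref$probe_id)],
                          position = ref$position[match(common, ref$probe_id)],
                          stringsAsFactors = FALSE)
  mrow <- manifest[match(ids, manifest$sample_id), , drop = FALSE]
  tissue <- if ("tissue" %in% names(mrow)) unique(mrow$tissue)[1] else NA_character_
  meth_matrix(values, labels = mrow$label, positions = positions, tissue = tissue)
}

#' Write a cohort as GDC-style per-sample files plus a manifest
#'
#' One four-column tab-separated file per sample (probe id, chromosome,
#' position, beta; missing written as \code{"NA"}) and a \code{manifest.tsv}
#' mapping file to sample id, tissue and label.
#'
#' @param x a labeled [meth_matrix()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
write_cohort <- function(x, dir) {
  if (is.null(x$labels)) stop("cohort must be labeled", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pos <- x$positions %||% data.frame(site = sites_of(x), chromosome = "chrNA",
                                     position = "0", stringsAsFactors = FALSE)
  files <- character(nrow(x$values))
  for (i in seq_len(nrow(x$values))) {
    sid <- rownames(x$values)[i]
    files[i] <- paste0(sid, ".methylation.tsv")
    df <- data.frame(probe_id = colnames(x$values),
                     chromosome = pos$chromosome,
                     position = pos$position,
                     beta_value = x$values[i, ],
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, files[i]), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  manifest <- data.frame(file = files, sample_id = rownames(x$values),
                         tissue = x$tissue, label = as.character(x$labels),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing per-sample files and \code{manifest.tsv}.
#' @return a [meth_matrix()].
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) stop("manifest.tsv not found in ", dir, call. = FALSE)
  manifest <- utils::read.delim(mf, stringsAsFactors = FALSE)
  records <- Map(function(f, sid) read_sample_file(file.path(dir, f), sample_id = sid),
                 manifest$file, manifest$sample_id)
  assemble_matrix(unname(records), manifest)
}

panel_columns <- c("site", "chromosome", "position", "cancer_median",
                   "normal_median", "cancer_sd", "normal_sd",
                   "separation_score", "order", "run", "retained")

#' Write a CpG panel table
#'
#' A retained panel contains only sites with strictly positive separation
#' scores; by default the writer refuses a panel carrying excluded
#' (non-positive or undefined score) rows, unless \code{include_excluded}
#' records them alongside the retained sites.
#'
#' @param panel a \code{cpg_panel} (see [refine_panel()]).
#' @param path output TSV path.
#' @param include_excluded write excluded rows too.
#' @return invisibly, \code{path}.
#' @export
write_panel <- function(panel, path, include_excluded = FALSE) {
  df <- as.data.frame(panel)
  if (anyDuplicated(df$site)) stop("duplicate probe ids in panel", call. = FALSE)
  if (!"retained" %in% names(df)) df$retained <- TRUE
  score <- if ("separation_score" %in% names(df)) df$separation_score else rep(1, nrow(df))
  excluded <- !df$retained | is.na(score) | score <= 0
  if (any(excluded) && !include_excluded) {
    stop("panel contains excluded (non-positive score) rows; ",
         "write with include_excluded = TRUE or refine first", call. = FALSE)
  }
  if (!include_excluded) df <- df[!excluded, , drop = FALSE]
  utils::write.table(df[, intersect(panel_columns, names(df)), drop = FALSE],
                     path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a CpG panel table written by [write_panel()]
#'
#' @param path TSV path.
#' @return a \code{cpg_panel} data.frame.
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("position" %in% names(df)) df$position <- as.character(df$position)
  if (anyDuplicated(df$site)) {
    stop("duplicate probe ids in panel file: ",
         df$site[duplicated(df$site)][1], call. = FALSE)
  }
  if ("retained" %in% names(df)) df$retained <- as.logical(df$retained)
  class(df) <- c("cpg_panel", "data.frame")
  df
}
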