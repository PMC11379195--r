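# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

# Canonical label factor: Normal = 0, Cancer = 1.
as_label_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("Cancer", "Normal"))
  if (length(bad) > 0) {
    stop("labels must be 'Cancer' or 'Normal'; found: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(labels, levels = c("Normal", "Cancer"))
}

label_to_numeric <- function(labels) as.numeric(as_label_factor(labels) == "Cancer")
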