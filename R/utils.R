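# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are not disturbed.
#' A `NULL` seed evaluates `code` under the current RNG state.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Argument check with a readable message; all user-facing validation funnels
# through this so error classes are consistent.
check_arg <- function(ok, msg) {
  if (!isTRUE(ok)) {
    stop(errorCondition(msg, class = c("lfpevents_argument_error", "error")))
  }
  invisible(TRUE)
}

degenerate_error <- function(msg) {
  stop(errorCondition(msg, class = c("lfpevents_degenerate_error", "error")))
}

format_error <- function(msg) {
  stop(errorCondition(msg, class = c("lfpevents_format_error", "error")))
}

# Short md5 fingerprint of an R object (used for provenance columns).
hash_params <- function(x) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf), add = TRUE)
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(substr(tools::md5sum(tf), 1L, 12L))
}

# Map electrode depth (mm from cortical surface) to a region label:
# recording sites deeper than 2 mm are ventromedial PFC, shallower ones
# dorsomedial PFC. ACC sites are labelled explicitly, never inferred.
depth_to_region <- function(depth) {
  ifelse(is.na(depth), "unknown", ifelse(depth > 2, "vmPFC", "dmPFC"))
}
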