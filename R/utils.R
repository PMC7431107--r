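# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed` so that seeded components
#' never perturb the global random stream. All randomised operations in the
#' package route their seed through this helper, which is what makes whole
#' runs reproducible component-by-component.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Derive a bounded child seed from a parent seed and a component tag, so each
# pipeline component gets its own fixed stream. Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L)
}

# Minimal run log: a character vector accumulated by reference.
new_log <- function() {
  env <- new.env(parent = emptyenv())
  env$lines <- character(0)
  class(env) <- "radexplore_log"
  env
}

log_line <- function(log, ...) {
  if (is.null(log)) return(invisible(NULL))
  stopifnot(inherits(log, "radexplore_log"))
  log$lines <- c(log$lines, paste0(...))
  invisible(NULL)
}

#' @method print radexplore_log
#' @export
print.radexplore_log <- function(x, ...) {
  cat(x$lines, sep = "\n")
  invisible(x)
}

write_log <- function(log, path) {
  writeLines(if (length(log$lines)) log$lines else "(no events)", path)
  invisible(path)
}

stop_input <- function(...) {
  stop(structure(class = c("radexplore_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
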