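`%||%` <- function(a, b) if (is.null(a)) b else a

# condition helpers: configuration problems (bad ids, missing files, bad
# derivation rules) vs validation problems (data violating model invariants)
pram_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pram_error")))
}

config_error <- function(...) pram_stop(paste0(...), "pram_config_error")

validation_error <- function(...) pram_stop(paste0(...), "pram_validation_error")

usage_error <- function(...) pram_stop(paste0(...), "pram_usage_error")

# violations are data, not exceptions: a two-column data frame
violation <- function(where, problem) {
  data.frame(where = where, problem = problem, stringsAsFactors = FALSE)
}

no_violations <- function() violation(character(), character())

bind_violations <- function(...) {
  do.call(rbind, Filter(function(v) nrow(v) > 0L, list(...))) %||% no_violations()
}

is_num_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_on_violations <- function(v) {
  if (nrow(v) > 0L) {
    validation_error(
      nrow(v), " validation problem(s):\n",
      paste0("  - [", v$where, "] ", v$problem, collapse = "\n")
    )
  }
  invisible(v)
}
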