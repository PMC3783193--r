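# internal helpers shared across modules

#' @importFrom utils read.delim write.table head tail
NULL

# classed errors so callers/tests can dispatch on failure mode
tk_stop <- function(msg, type, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("tagkit_", type), "tagkit_error", "error", "condition")))
}

tk_warn <- function(msg, type) {
  warning(warningCondition(msg, class = c(paste0("tagkit_", type), "tagkit_warning", "warning", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a temporary RNG state; restores global .Random.seed afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# all start positions (1-based) of fixed pattern in subject string
str_find_all <- function(subject, pattern) {
  if (nchar(pattern) == 0 || nchar(pattern) > nchar(subject)) return(integer(0))
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}
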