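#' @keywords internal
"_PACKAGE"

#' @import EBImage
#' @importFrom stats rpois rnorm runif lm coef mad median quantile density
#'   pt setNames complete.cases sd
#' @importFrom utils read.csv write.csv head modifyList
NULL

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic entry points go through this
# so identical (inputs, seed) pairs reproduce identical output.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("betakin_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("betakin_data_error", "error")))
}

stop_undefined_fraction <- function(...) {
  stop(errorCondition(paste0(...),
    class = c("betakin_undefined_fraction", "betakin_data_error", "error")))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, allow_equal_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(name, " must be a single finite number")
  }
  lo_ok <- if (allow_equal_lower) x >= lower else x > lower
  hi_ok <- if (allow_equal_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    stop_config(name, " = ", x, " is outside its valid range")
  }
  invisible(x)
}

# md5 of a character scalar, via a temp file (base R only)
md5_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(x, f)
  unname(tools::md5sum(f))
}
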