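`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding used for crystalline-bond counts: `round_half_away(4.5)`
#' is 5, `round_half_away(-4.5)` is -5 (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Truncate toward zero to a number of decimals
#'
#' Reporting convention used for regime roots: the reference values for the
#' quadratic roots are printed with their decimals truncated toward zero
#' (2.5309 -> 2.53, -0.1976 -> -0.19).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places kept.
#' @return truncated numeric vector.
#' @export
trunc_toward_zero <- function(x, digits = 2) {
  m <- 10^digits
  trunc(x * m) / m
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL consumes the current stream (no save/restore).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_power_of_two <- function(n) {
  n <- as.numeric(n)
  n >= 1 && n == round(n) && bitwAnd(as.integer(n), as.integer(n - 1L)) == 0L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Write a saccharification time course to CSV
#'
#' Columns `time_h` and `conversion_pct`, the on-disk exchange format for
#' curves produced or consumed by the command-line workflow.
#'
#' @param tc a `time_course` (or any data.frame with the two columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_time_course <- function(tc, path) {
  utils::write.csv(data.frame(time_h = tc$time_h, conversion_pct = tc$conversion_pct),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a saccharification time course from CSV
#'
#' @param path CSV file with columns `time_h`, `conversion_pct`.
#' @return a `time_course` object.
#' @export
read_time_course <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_h", "conversion_pct") %in% names(d)))
    stopf("time-course CSV must have columns time_h, conversion_pct")
  new_time_course(d$time_h, d$conversion_pct)
}
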