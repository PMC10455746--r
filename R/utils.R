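# internal validation helpers -------------------------------------------

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (strict_lower && x <= lower)
    stop_field(field, sprintf("must be > %g", lower))
  if (!strict_lower && x < lower)
    stop_field(field, sprintf("must be >= %g", lower))
  if (strict_upper && x >= upper)
    stop_field(field, sprintf("must be < %g", upper))
  if (!strict_upper && x > upper)
    stop_field(field, sprintf("must be <= %g", upper))
  x
}

check_seed <- function(seed, field = "seed") {
  if (is.null(seed)) return(NULL)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed))
    stop_field(field, "must be a single integer")
  as.integer(seed)
}

check_file <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  path
}

# run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched so generators are pure functions of their model
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Summarize a group of measurements
#'
#' Mean and sample standard deviation (n - 1 denominator) of a numeric
#' vector, the summary used throughout for batch and cohort statistics.
#'
#' @param x numeric vector of measurements, length >= 2.
#' @param label optional label carried through to printing.
#' @return an object of class `group_summary`: a list with elements `n`,
#'   `mean`, `sd` and `label`.
#' @examples
#' group_summary(c(24.4, 24.8, 31.7, 18.0), label = "WAC PDL-02")
#' @export
group_summary <- function(x, label = NULL) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_field("x", "must be finite numeric values")
  if (length(x) < 2L)
    stop("sample SD undefined for fewer than 2 values", call. = FALSE)
  structure(
    list(n = length(x), mean = mean(x), sd = stats::sd(x), label = label),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, digits = 4, ...) {
  lab <- if (is.null(x$label)) "" else paste0(x$label, ": ")
  cat(sprintf("%s%s ± %s (n = %d)\n", lab,
              format(x$mean, digits = digits),
              format(x$sd, digits = digits), x$n))
  invisible(x)
}

#' @export
format.group_summary <- function(x, digits = 4, ...) {
  sprintf("%s ± %s (n = %d)", format(x$mean, digits = digits),
          format(x$sd, digits = digits), x$n)
}
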