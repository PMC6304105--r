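#' @importFrom methods new validObject is slot
#' @importFrom stats setNames
#' @importFrom utils read.table write.table
NULL

#' Round half away from zero
#'
#' The rounding convention used for every reported percentage and ratio
#' (unlike [round()], which rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Format a count ratio as a percentage
#'
#' Percentages in reports are rounded half away from zero to one decimal
#' place; raw numerator and denominator are always carried alongside so no
#' information is lost to rounding.
#'
#' @param num,den numerator and denominator counts.
#' @param digits decimal places to keep (default 1).
#' @return numeric percentage, rounded.
#' @examples
#' percentOf(267, 282)   # 94.7
#' percentOf(146, 47931) # 0.3
#' @export
percentOf <- function(num, den, digits = 1) {
  stopifnot(is.numeric(num), is.numeric(den), all(den > 0))
  roundHalfUp(100 * num / den, digits)
}

# deterministic 31-bit stream seed from (seed, stream name); keeps every
# output file on its own reproducible random stream
streamSeed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), nzchar(name))
  h <- as.double(seed %% 2147483647)
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 2147483647
  as.integer(h)
}

withStream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(streamSeed(seed, name))
  expr
}

.assertCount <- function(x, name, min = 0) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != as.integer(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

.assertFraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}
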