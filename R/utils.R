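#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used when rendering table percents (e.g. 30.35 -> 30.4).
#' Base `round()` rounds half to even, which renders 62.5 as 62.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

as_date_strict <- function(x) {
  if (inherits(x, "Date")) return(x)
  suppressWarnings(as.Date(as.character(x), format = "%Y-%m-%d"))
}

assert_scalar_date <- function(x, what) {
  d <- as_date_strict(x)
  if (length(d) != 1L || is.na(d)) {
    stop(sprintf("'%s' must be a single valid date (YYYY-MM-DD)", what), call. = FALSE)
  }
  d
}

# Stable order helper: base order() is stable for ties, which several ranking
# contracts here rely on.
stable_order <- function(...) order(..., method = "radix")

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

first_non_na <- function(x, default = NA) {
  x <- x[!is.na(x)]
  if (length(x)) x[[1L]] else default
}
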