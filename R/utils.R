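#' @keywords internal
"_PACKAGE"

#' @useDynLib flexfuse, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile rbinom rnorm runif rlnorm median sd plogis qlogis uniroot
#' @importFrom utils read.csv write.csv head modifyList
NULL

sigmoid <- function(x) plogis(x)
relu <- function(x) {
  x[x < 0] <- 0
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sentinel used on the common hash-mapped scale for missing cells
#'
#' Mapped bucket midpoints live in (0, 1); missing cells are carried as this
#' out-of-range code so that downstream encoders can route them to the
#' learned missing-bucket pathway instead of a numeric midpoint.
#'
#' @return A single numeric code.
#' @export
missing_code <- function() -1

stop_flex <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop_flex(fmt, ...)
  invisible(TRUE)
}

# seeded RNG scope helper: runs expr under a derived seed, restores RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# derive a child seed from a base seed and an index, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483629) + 1L
}
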