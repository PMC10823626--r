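#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rlnorm rmultinom rnorm runif plogis setNames
#' @importFrom utils head tail read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; accepts and returns plain uppercase character
#' strings (the package's internal sequence currency).
#'
#' @param x character vector of A/C/G/T strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  unname(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x))))
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for every printed percentage and
#' fold value so that, e.g., 89.85 reports as 89.9.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a total, one decimal
#'
#' @param count numerator count.
#' @param total denominator count (> 0).
#' @param digits decimal places (default 1, the reporting convention).
#' @return percentage rounded half-up.
#' @export
percent_of <- function(count, total, digits = 1) {
  stopifnot(total > 0)
  round_half_up(count / total * 100, digits)
}

# Named substream seeds derived from one master seed, so stages can be rerun
# independently.  Kept below 2^31 - 1.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n_bases) {
  paste(sample(DNA_BASES, n_bases, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
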