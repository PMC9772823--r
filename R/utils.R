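## small shared helpers (internal)

.BASES <- c("A", "C", "G", "T")

## random DNA as a single string, under the caller's RNG state
.randDNA <- function(n) {
  if (n <= 0L) return("")
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

## reverse complement for plain character strings (avoids S4 dispatch on
## the per-read hot path)
.revcomp <- function(x) {
  vapply(x, function(s) {
    v <- strsplit(chartr("ACGTacgtN", "TGCAtgcaN", s), "", fixed = TRUE)[[1L]]
    paste(rev(v), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.complementBase <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[[toupper(b)]]
}

## run code under a fixed seed, restoring the caller's RNG state afterwards
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Round half away from zero
#'
#' Decimal rounding in which a half always rounds up in magnitude
#' (`roundHalfUp(0.05, 1)` is `0.1`), matching how reported concentrations
#' and ratios are conventionally printed. `base::round()` instead rounds
#' halves to even.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Hamming distance between equal-length strings
.hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NA_integer_)
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}
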