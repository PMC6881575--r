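## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_domain(sprintf("'%s' must be a single non-missing number", name))
  if (integer && x != round(x))
    stop_domain(sprintf("'%s' must be an integer", name))
  if (x < lower || x > upper)
    stop_domain(sprintf("'%s' must be in [%s, %s]", name,
                        format(lower), format(upper)))
  x
}

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

## complement tables cover both alphabets
COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A", T = "A")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of an RNA character string
#' @noRd
revcomp_rna <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  paste(rev(unname(COMPLEMENT[chars])), collapse = "")
}

#' @noRd
revcomp_dna <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  paste(rev(unname(DNA_COMPLEMENT[chars])), collapse = "")
}

#' Random RNA sequence under an iid base model
#'
#' Draws a sequence of length `n` over the RNA alphabet \{A, C, G, U\}
#' with the given base frequencies. Used by the synthetic-data generator
#' for background transcript sequence and directly useful for estimating
#' chance seed-match rates.
#'
#' @param n sequence length (nt).
#' @param freq base frequencies in A, C, G, U order; must be positive and
#'   sum to 1. Default uniform.
#' @return a single character string.
#' @export
random_rna <- function(n, freq = rep(0.25, 4)) {
  check_number(n, "n", lower = 0, integer = TRUE)
  if (length(freq) != 4L || any(freq <= 0) || abs(sum(freq) - 1) > 1e-8)
    stop_domain("'freq' must be 4 positive frequencies summing to 1")
  paste(sample(RNA_BASES, n, replace = TRUE, prob = freq), collapse = "")
}

#' @noRd
random_dna <- function(n, freq = rep(0.25, 4)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = freq), collapse = "")
}

## Derive k reproducible sub-seeds (< 2^31) from one master seed.
#' @noRd
derive_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max, k)
}
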