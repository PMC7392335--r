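#' Numerically stable softplus
#'
#' `softplus(x) = log(1 + exp(x))`, the positive link used both by the model
#' output heads and by the synthetic generative model, so that truth tracks
#' and predictions live in the same output family.
#'
#' @param x numeric vector or matrix.
#' @return object of the same shape with softplus applied elementwise.
#' @export
softplus <- function(x) {
  # for large x, log1p(exp(x)) overflows; softplus(x) ~ x there
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

#' Gaussian Error Linear Unit
#'
#' Exact GELU, `x * pnorm(x)`.
#' @param x numeric vector or matrix.
#' @return same shape, activated.
#' @export
gelu <- function(x) x * pnorm(x)

# derivative of exact gelu
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

#' Reverse complement of a DNA string
#'
#' @param s character scalar over A/C/G/T/N (case-insensitive).
#' @return reverse-complemented uppercase string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# split one DNA string into a character vector of single bases
str_bases <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

# deterministic child seed streams: derive distinct sub-seeds from one master
# seed without consuming the global RNG. Keeps all derived seeds < 2^31.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647L
  as.integer(h)
}

# run code under a local RNG state (restores the caller's state afterwards)
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
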