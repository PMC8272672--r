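clip01 <- function(x) {
  x[] <- pmin(1, pmax(0, x))
  x
}

#' Derive a per-module seed from a global seed
#'
#' All commands take one global seed; each module draws from its own
#' deterministic substream so that, e.g., changing the number of training
#' epochs does not perturb the phantom images.
#'
#' @param seed integer global seed.
#' @param stream short module name, e.g. \code{"phantom"}.
#' @return an integer seed below 2^31.
#' @export
deriveSeed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

sigmoid <- function(k) 1 / (1 + exp(-k))

# short deterministic hash of an R object (config fingerprinting)
objectHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  h <- 5381
  for (ch in v) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
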