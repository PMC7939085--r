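#' @useDynLib pfspike, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rpois runif coef lm median sd
#' @importFrom utils write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded placement/train
#' generation never perturbs the caller's random stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a reproducible child seed from a parent seed
#'
#' Splitting one user-facing seed into independent streams (per trial, per
#' condition) keeps every protocol reproducible from a single integer.
#'
#' @param seed parent seed
#' @param ... integer offsets identifying the stream
#' @return integer seed below 2^31
#' @export
sub_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed)
  for (k in ix) s <- (s * 69069 + 1234567 + as.double(k)) %% 2147483629
  as.integer(s) + 1L
}

#' Hash a configuration object for provenance records
#'
#' @param x any serialisable R object
#' @return md5 hex string
#' @export
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
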