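#' @useDynLib rumennet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim pchisq p.adjust wilcox.test cor cor.test dlnorm
#'   plnorm rbinom rhyper rmultinom rnorm runif setNames var sd dist
#'   complete.cases qlnorm
#' @importFrom utils read.delim write.table combn head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add-one permutation P-value
#'
#' P = (#\{|null| >= |observed|\} + 1) / (n + 1), guaranteed in (0, 1].
#'
#' @param null numeric vector of null statistics.
#' @param observed observed statistic.
#' @param absolute compare absolute values (two-sided, default) or signed
#'   exceedance.
#' @return numeric P-value.
#' @export
add_one_pvalue <- function(null, observed, absolute = TRUE) {
  stopifnot(length(observed) == 1L, is.finite(observed), length(null) >= 1L)
  if (absolute) {
    (sum(abs(null) >= abs(observed)) + 1) / (length(null) + 1)
  } else {
    (sum(null >= observed) + 1) / (length(null) + 1)
  }
}

# Deterministic 31-bit sub-seed from a master seed and index path, so nested
# stochastic steps (animal x restart x replicate) are reproducible from one
# integer without sharing a stream.
derive_subseed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (k in idx) {
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h %% 2147483629) + 1L
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

stop_id <- function(fmt, ids) {
  stop(sprintf(fmt, paste(sort(unique(ids)), collapse = ", ")), call. = FALSE)
}
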