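#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate approx ave bw.nrd0 complete.cases cor density
#'   dnorm dt isoreg ks.test median optim predict pt quantile rank rbinom
#'   rnorm runif sd setNames var
#' @importFrom utils head
NULL

# Deterministic child seed derived from a root seed and a stream tag, so each
# sub-generator consumes its own RNG stream and unrelated outputs stay fixed
# when one component's parameters change. Kept below 2^31 - 1.
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

assert_matrix_named <- function(m, what = "matrix") {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m))) {
    stop(what, " must be a matrix with row and column names", call. = FALSE)
  }
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
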