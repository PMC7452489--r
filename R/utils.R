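# Internal helpers shared across modules.

#' Evaluate code with a temporarily seeded RNG
#'
#' Restores the caller's RNG state afterwards so seeded helpers do not
#' perturb the global random stream. A `NULL` seed evaluates the code
#' under the current stream.
#'
#' @param seed integer seed or `NULL`
#' @param code expression to evaluate
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; keeps results < 2^31 - 1 so they are
# valid R integer seeds whatever base seed the caller supplies.
derive_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  k <- c(...)
  if (length(k) == 0) k <- 0
  key <- sum(as.numeric(k) * seq_along(k) * 97)
  as.integer((as.numeric(seed) * 7919 + key) %% (.Machine$integer.max - 1)) + 1L
}

stopifnot_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric", what), call. = FALSE)
  }
  invisible(x)
}

# Row-wise euclidean norms of an n x 3 matrix.
row_norms <- function(m) unname(sqrt(rowSums(m * m)))

as_matrix3 <- function(x, what = "points") {
  if (is.null(dim(x))) {
    if (length(x) != 3) stop(sprintf("`%s` must be a 3-vector or n x 3 matrix", what))
    x <- matrix(x, nrow = 1)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3) stop(sprintf("`%s` must have 3 columns", what))
  storage.mode(x) <- "double"
  x
}
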