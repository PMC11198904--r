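#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage seed derivation from a root seed. Stage names hash to
# a stable offset so every source of randomness flows from one config seed.
# Result kept strictly below 2^31 - 1.
derive_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + index * 7919) %% 2147483587)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)

#' Standardize the rows of a matrix to zero mean and unit variance
#'
#' Rows with (near-)zero variance cannot be standardized; they are returned as
#' an attribute `constant` (logical per row) and left untouched so callers can
#' drop or flag them.
#'
#' @param x numeric matrix (features x samples).
#' @param tol variance below which a row is treated as constant.
#' @return matrix of the same shape with attribute `constant`.
#' @keywords internal
standardize_rows <- function(x, tol = 1e-12) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowSums(xc^2) / (ncol(x) - 1)
  constant <- v < tol
  sdv <- sqrt(ifelse(constant, 1, v))
  out <- xc / sdv
  attr(out, "constant") <- constant
  out
}

standardize_vec <- function(y, tol = 1e-12) {
  v <- stats::var(y)
  if (!is.finite(v) || v < tol) return(structure(y - mean(y), constant = TRUE))
  structure((y - mean(y)) / sqrt(v), constant = FALSE)
}
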