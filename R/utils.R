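#' @include AllClasses.R
NULL

.stopValidation <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

.asMatrix <- function(x, ndim, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) == 0) {
      return(matrix(numeric(0), 0, ndim))
    }
    if (length(x) == ndim) {
      x <- matrix(as.numeric(x), 1, ndim)
    } else {
      .stopValidation("%s must be an n x %d matrix", what, ndim)
    }
  }
  if (ncol(x) != ndim) {
    .stopValidation("%s must have %d columns, got %d", what, ndim, ncol(x))
  }
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

.defaultPlaneAxes <- function(n, ndim) {
  ax <- array(0, c(n, 2L, ndim))
  if (n > 0) {
    ax[, 1L, 1L] <- 1
    ax[, 2L, 2L] <- 1
  }
  ax
}

# deparse a double so that as.numeric() recovers it exactly
.fullPrecision <- function(x) {
  vapply(x, function(v) {
    if (v == floor(v) && abs(v) < 1e15) {
      sprintf("%.1f", v)
    } else {
      format(v, digits = 17, scientific = FALSE, trim = TRUE)
    }
  }, character(1))
}
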