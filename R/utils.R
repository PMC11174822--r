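# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ca <- function(...) stop(..., call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_ca(what, " contains non-finite values")
  invisible(TRUE)
}

#' Round an array to single precision
#'
#' Weights are stored in checkpoints as 32-bit floats; applying the same
#' quantization at initialization makes save/load round trips exact.
#'
#' @param x numeric vector or array.
#' @return `x` with every value rounded to the nearest single-precision
#'   representable number (still stored as doubles in memory).
#' @keywords internal
quantize_f32 <- function(x) {
  d <- dim(x)
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
                 "numeric", n = length(x), size = 4L)
  dim(out) <- d
  out
}

# fan-in scaled uniform init, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_uniform <- function(dims, fan_in) {
  bound <- 1 / sqrt(max(1, fan_in))
  x <- stats::runif(prod(dims), -bound, bound)
  if (length(dims) > 1L) dim(x) <- dims
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# sum of lengths of all numeric leaves of a (possibly nested) param list
count_scalars <- function(params) {
  n <- 0
  for (p in params) {
    n <- n + if (is.list(p)) count_scalars(p) else length(p)
  }
  n
}

# flatten nested param list into a named flat list (names joined by ".")
flatten_params <- function(params, prefix = NULL) {
  out <- list()
  for (nm in names(params)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    p <- params[[nm]]
    if (is.list(p)) out <- c(out, flatten_params(p, key))
    else out[[key]] <- p
  }
  out
}

# inverse of flatten_params given a template with the desired nesting
unflatten_params <- function(flat, template, prefix = NULL) {
  out <- template
  for (nm in names(template)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    p <- template[[nm]]
    if (is.list(p)) {
      out[[nm]] <- unflatten_params(flat, p, key)
    } else {
      v <- flat[[key]]
      if (is.null(v)) stop_ca("missing parameter '", key, "'")
      dim(v) <- dim(p)
      out[[nm]] <- v
    }
  }
  out
}
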