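#' @keywords internal
"_PACKAGE"

# Canonical class order: four AML genetic subtypes, control last.
CYTOMIL_CLASSES <- c("PML_RARA", "NPM1", "CBFB_MYH11", "RUNX1_RUNX1T1", "control")

#' Default class labels
#'
#' The five diagnostic groups handled by the model, in fixed index order:
#' the four AML genetic subtypes followed by the healthy control class.
#'
#' @return Character vector of length 5.
#' @export
cytomil_classes <- function() CYTOMIL_CLASSES

# Numerically stable softmax along a vector (max subtraction).
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_field(field, "must be TRUE or FALSE")
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_field(field, sprintf("must be a single integer >= %d", min))
  }
  invisible(as.integer(x))
}

check_number <- function(x, field, min = -Inf, max = Inf,
                         strict_min = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_min) x > min else x >= min) && x <= max
  if (!ok) {
    stop_field(field, sprintf("must be a single number in %s%s, %s]",
                              if (strict_min) "(" else "[",
                              format(min), format(max)))
  }
  invisible(as.numeric(x))
}

# Derive a reproducible child seed from a master seed and a stream label.
# Stays below 2^31 - 1 so it is always a valid R integer seed.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}
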