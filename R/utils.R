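#' @keywords internal
"_PACKAGE"

#' Logistic and logit helpers
#'
#' `sigmoid()` maps log-odds to probabilities; `logit()` is its inverse.
#' `clip_prob()` clips probabilities away from 0 and 1 so that the logit is
#' finite (default bound 1e-6, the convention used throughout for Platt
#' scaling and calibration diagnostics).
#'
#' @param x numeric vector.
#' @param p numeric vector of probabilities.
#' @param eps clipping bound in (0, 0.5).
#' @return numeric vector.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @rdname sigmoid
#' @export
logit <- function(p) log(p / (1 - p))

#' @rdname sigmoid
#' @export
clip_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# scalar checks used by constructors
is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
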