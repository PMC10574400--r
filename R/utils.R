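#' Wrap hours onto the 24 h circle
#'
#' @param x numeric vector of hours.
#' @return `x` modulo 24, in `[0, 24)`.
#' @export
#' @examples
#' wrap24(c(25, -1, 24))
wrap24 <- function(x) x %% 24

#' Wrap a phase difference to the half circle
#'
#' Phase differences on a 24 h cycle are only identified modulo 24; the
#' meaningful difference is the shorter way around the circle. 23 h vs 1 h is
#' a 2 h shift, not 22 h.
#'
#' @param d numeric vector of hour differences.
#' @return `d` wrapped into `(-12, 12]`.
#' @export
#' @examples
#' wrap_phase_diff(c(22, -22, 12, -12))
wrap_phase_diff <- function(d) {
  r <- (d + 12) %% 24 - 12
  r[r <= -12] <- r[r <= -12] + 24
  r
}

# internal: stop unless cond, with sprintf-style message
.check <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

# internal: weighted mean guarding zero weights
.wmean <- function(x, w) sum(w * x) / sum(w)
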