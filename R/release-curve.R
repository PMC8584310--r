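#' Construct a cumulative release curve
#'
#' A release curve holds a time-ordered series of cumulative release
#' observations, either as raw amounts (e.g. ug/mL) or as fractions of the
#' equilibrium amount C_inf. Fractions may overshoot 1 slightly (up to 1.05)
#' to accommodate measurement noise.
#'
#' @param times Strictly increasing numeric vector of times in minutes,
#'   at least 3 points.
#' @param values Non-negative cumulative release values, same length.
#' @param value_kind `"fraction"` or `"amount"`.
#' @param c_inf Amount at equilibrium (C_inf). Required to convert an
#'   amount-scale curve to fractions for the power-law and Weibull models.
#' @return An object of class `release_curve`.
#' @examples
#' release_curve(c(1, 3, 5, 10, 20, 30), c(.70, .78, .82, .86, .89, .90))
#' @export
release_curve <- function(times, values, value_kind = c("fraction", "amount"),
                          c_inf = NULL) {
  value_kind <- match.arg(value_kind)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (length(times) < 3L) stop("a release curve needs >= 3 points", call. = FALSE)
  ord <- order(times)            # accept unsorted input; storage is time-ordered
  times <- times[ord]
  values <- values[ord]
  if (any(diff(times) <= 0)) stop("times must be distinct", call. = FALSE)
  if (any(values < 0)) stop("release values must be non-negative", call. = FALSE)
  if (value_kind == "fraction" && any(values > 1.05)) {
    stop("fraction-scale values must lie in [0, 1.05]", call. = FALSE)
  }
  if (!is.null(c_inf)) stopifnot(is.numeric(c_inf), length(c_inf) == 1L, c_inf > 0)
  structure(
    list(times = times, values = values, value_kind = value_kind, c_inf = c_inf),
    class = "release_curve"
  )
}

#' @export
print.release_curve <- function(x, ...) {
  cat(sprintf("Release curve: %d points, %s scale%s\n", length(x$times),
              x$value_kind,
              if (is.null(x$c_inf)) "" else sprintf(", C_inf = %g", x$c_inf)))
  print(data.frame(time_min = x$times, release = x$values), row.names = FALSE)
  invisible(x)
}

# Fraction-scale view of a curve; NULL when no conversion is possible.
curve_as_fraction <- function(curve) {
  if (curve$value_kind == "fraction") return(curve$values)
  if (!is.null(curve$c_inf)) return(curve$values / curve$c_inf)
  NULL
}
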