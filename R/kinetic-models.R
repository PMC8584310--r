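#' Kinetic model registry
#'
#' Seven classical dissolution/release models. Each entry records the ordered
#' parameter names, box constraints used during fitting, and whether the model
#' operates on the released fraction (power law, Weibull) or on arbitrary
#' amounts.
#'
#' Canonical forms (t in minutes):
#' \itemize{
#'   \item zero_order:      Ct = C0 + K0 t
#'   \item first_order:     Ct = Cd (1 - exp(-K1 t))
#'   \item second_order:    Ct = Cd - 1 / (1/Cd + K2 t)
#'   \item higuchi:         Ct = KH sqrt(t)
#'   \item hixson_crowell:  Ct = Cd - (Cd^(1/3) - KHC t)^3, clipped at Cd
#'   \item weibull:         Ct = Cs (1 - exp(-(t - T)^b / a))
#'   \item power_law:       C  = K t^n (Korsmeyer-Peppas), C a fraction of C_inf
#' }
#'
#' @format A named list of model specifications.
#' @keywords internal
kinetic_models <- list(
  zero_order = list(
    name = "zero_order",
    parameter_names = c("C0", "K0"),
    lower = c(C0 = -Inf, K0 = 0),
    upper = c(C0 = Inf, K0 = Inf),
    needs_fraction = FALSE
  ),
  first_order = list(
    name = "first_order",
    parameter_names = c("Cd", "K1"),
    lower = c(Cd = 1e-12, K1 = 0),
    upper = c(Cd = Inf, K1 = Inf),
    needs_fraction = FALSE
  ),
  second_order = list(
    name = "second_order",
    parameter_names = c("Cd", "K2"),
    lower = c(Cd = 1e-12, K2 = 0),
    upper = c(Cd = Inf, K2 = Inf),
    needs_fraction = FALSE
  ),
  higuchi = list(
    name = "higuchi",
    parameter_names = "KH",
    lower = c(KH = 0),
    upper = c(KH = Inf),
    needs_fraction = FALSE
  ),
  hixson_crowell = list(
    name = "hixson_crowell",
    parameter_names = c("Cd", "KHC"),
    lower = c(Cd = 1e-12, KHC = 0),
    upper = c(Cd = Inf, KHC = Inf),
    needs_fraction = FALSE
  ),
  weibull = list(
    name = "weibull",
    parameter_names = c("Cs", "T", "a", "b"),
    # Cs is the total fraction eventually released: capped at the same 1.05
    # ceiling the fraction-scale curve invariant allows for noisy data.
    lower = c(Cs = 1e-12, T = 0, a = 1e-12, b = 1e-12),
    upper = c(Cs = 1.05, T = Inf, a = Inf, b = Inf),
    needs_fraction = TRUE
  ),
  power_law = list(
    name = "power_law",
    parameter_names = c("K", "n"),
    lower = c(K = 0, n = 0),
    upper = c(K = Inf, n = Inf),
    needs_fraction = TRUE
  )
)

#' Names of the supported kinetic models
#' @return Character vector of the seven model names.
#' @export
kinetic_model_names <- function() names(kinetic_models)

#' Look up a kinetic model specification
#'
#' @param model Model name, one of [kinetic_model_names()].
#' @return A model specification list with elements `name`,
#'   `parameter_names`, `lower`, `upper`, `needs_fraction`.
#' @export
kinetic_model_spec <- function(model) {
  model <- match.arg(model, names(kinetic_models))
  kinetic_models[[model]]
}

check_params <- function(spec, params) {
  missing <- setdiff(spec$parameter_names, names(params))
  if (length(missing) > 0L) {
    stop(sprintf("model '%s' is missing parameter(s): %s",
                 spec$name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  params
}

#' Evaluate a release model at given times
#'
#' Computes the cumulative-release value predicted by one of the seven kinetic
#' models at each time point. Times are in minutes; for amount-scale models the
#' value unit follows the parameters, for the power-law and Weibull models the
#' value is a fraction of the equilibrium amount.
#'
#' @param model Model name (see [kinetic_model_names()]).
#' @param params Named list or vector of parameter values; names must match
#'   the model's `parameter_names`.
#' @param times Numeric vector of non-negative times (minutes).
#' @param second_order_sign `"standard"` uses 1/(Cd - Ct) = 1/Cd + K2 t so
#'   that release increases with time; `"printed"` uses the minus-sign
#'   convention 1/(Cd - Ct) = 1/Cd - K2 t sometimes found in print, which
#'   decreases with time for K2 > 0.
#' @param weibull_grouping `"scale_inside"` uses exp(-(t-T)^b / a) (the scale
#'   parameter a divides the powered time); `"scale_outside"` uses
#'   exp(-((t-T)/a)^b).
#' @return Numeric vector of predicted values, same length as `times`.
#' @examples
#' predict_release("zero_order", c(C0 = 0, K0 = 2), times = 5)     # 10
#' predict_release("power_law", c(K = 0.7379, n = 0.088), times = 1)
#' @export
predict_release <- function(model, params, times,
                            second_order_sign = c("standard", "printed"),
                            weibull_grouping = c("scale_inside", "scale_outside")) {
  spec <- kinetic_model_spec(model)
  second_order_sign <- match.arg(second_order_sign)
  weibull_grouping <- match.arg(weibull_grouping)
  params <- as.list(check_params(spec, params))
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  with(params, switch(
    spec$name,
    zero_order = C0 + K0 * times,
    first_order = Cd * (1 - exp(-K1 * times)),
    second_order = if (second_order_sign == "standard") {
      Cd - 1 / (1 / Cd + K2 * times)
    } else {
      Cd - 1 / (1 / Cd - K2 * times)
    },
    higuchi = KH * sqrt(times),
    hixson_crowell = Cd - pmax(Cd^(1 / 3) - KHC * times, 0)^3,
    weibull = {
      if (b < 0) stop("weibull shape b must be non-negative", call. = FALSE)
      dt <- pmax(times - T, 0)
      if (weibull_grouping == "scale_inside") {
        Cs * (1 - exp(-dt^b / a))
      } else {
        Cs * (1 - exp(-(dt / a)^b))
      }
    },
    power_law = {
      if (n < 0) stop("power-law exponent n must be non-negative", call. = FALSE)
      K * times^n
    }
  ))
}

#' Classify the release mechanism from the power-law exponent
#'
#' The Korsmeyer-Peppas exponent n diagnoses the transport mechanism of drug
#' release: n below 0.5 indicates Fickian diffusion, n between 0.5 and 1
#' anomalous (diffusion plus swelling) transport, n equal to 1 Case II
#' relaxation-controlled transport, and n above 1 Super Case II transport.
#' The boundary n = 0.5 is assigned to the anomalous class (Fickian is
#' strictly "below 0.5"); n = 1 is matched with absolute tolerance 1e-9.
#'
#' @param n Power-law release exponent (dimensionless, >= 0).
#' @return A `mechanism_call` object with fields `source`, `statistic_value`
#'   and `label` (one of `"fickian"`, `"anomalous"`, `"case_II"`,
#'   `"super_case_II"`).
#' @examples
#' classify_power_law(0.088)  # fickian
#' classify_power_law(1)      # case_II
#' @export
classify_power_law <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L)
  if (is.na(n) || n < 0) stop("power-law exponent n must be >= 0", call. = FALSE)
  label <- if (abs(n - 1) <= 1e-9) {
    "case_II"
  } else if (n < 0.5) {
    "fickian"
  } else if (n < 1) {
    "anomalous"
  } else {
    "super_case_II"
  }
  mechanism_call("power_law_n", n, label)
}

#' Classify the release mechanism from the Weibull shape parameter
#'
#' The Weibull shape b indicates the transport type: b <= 0.75 Fickian
#' diffusion, 0.75 < b <= 1 a combined mechanism (Fickian diffusion plus
#' swelling-controlled transport), b > 1 a complex mechanism.
#'
#' @param b Weibull shape parameter (dimensionless, > 0).
#' @return A `mechanism_call` object with label one of `"fickian"`,
#'   `"combined"`, `"complex"`.
#' @examples
#' classify_weibull(0.3612)  # fickian
#' classify_weibull(0.75)    # boundary: still fickian
#' @export
classify_weibull <- function(b) {
  stopifnot(is.numeric(b), length(b) == 1L)
  if (is.na(b) || b <= 0) stop("weibull shape b must be > 0", call. = FALSE)
  label <- if (b <= 0.75) "fickian" else if (b <= 1) "combined" else "complex"
  mechanism_call("weibull_b", b, label)
}

mechanism_call <- function(source, value, label) {
  structure(
    list(source = source, statistic_value = value, label = label),
    class = "mechanism_call"
  )
}

#' @export
print.mechanism_call <- function(x, ...) {
  stat <- if (x$source == "power_law_n") "n" else "b"
  cat(sprintf("Release mechanism: %s (%s = %g)\n", x$label, stat,
              x$statistic_value))
  invisible(x)
}
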