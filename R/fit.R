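#' Coefficient of determination
#'
#' R^2 = 1 - SSres/SStot with SStot the total sum of squares about the mean
#' of the observations. Can be negative for fits worse than the mean; equals
#' 1 for a perfect fit. When the observations are all identical SStot is zero
#' and R^2 is undefined: `NA` is returned as sentinel.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return A single number in (-Inf, 1], or `NA` if undefined.
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((observed - predicted)^2) / ss_tot
}

# Deterministic, data-driven starting values for nonlinear fitting.
# Power law and Higuchi start from log-log / sqrt-t regression, first and
# second order from their classical linearized forms, Weibull from
# (Cs = max value, T = 0, a = median t, b = 1).
fit_start <- function(model, times, values) {
  eps <- 1e-10
  ymax <- max(values)
  switch(model,
    zero_order = {
      co <- stats::coef(stats::lm(values ~ times))
      c(C0 = unname(co[1]), K0 = max(unname(co[2]), 0))
    },
    first_order = {
      cd0 <- ymax * 1.05 + eps
      sl <- stats::coef(stats::lm(log(pmax(cd0 - values, eps)) ~ times))[2]
      c(Cd = cd0, K1 = max(-unname(sl), 1e-6))
    },
    second_order = {
      cd0 <- ymax * 1.05 + eps
      sl <- stats::coef(stats::lm(I(1 / pmax(cd0 - values, eps)) ~ times))[2]
      c(Cd = cd0, K2 = max(unname(sl), 1e-8))
    },
    higuchi = {
      st <- sqrt(times)
      c(KH = max(sum(values * st) / sum(st^2), eps))
    },
    hixson_crowell = {
      cd0 <- ymax * 1.05 + eps
      lhs <- cd0^(1 / 3) - pmax(cd0 - values, 0)^(1 / 3)
      c(Cd = cd0, KHC = max(sum(lhs * times) / sum(times^2), 1e-8))
    },
    weibull = c(Cs = ymax, T = 0, a = stats::median(times), b = 1),
    power_law = {
      keep <- times > 0 & values > 0
      if (sum(keep) >= 2L) {
        co <- stats::coef(stats::lm(log(values[keep]) ~ log(times[keep])))
        c(K = exp(unname(co[1])), n = max(unname(co[2]), 0))
      } else {
        c(K = max(ymax, eps), n = 0.5)
      }
    }
  )
}

fit_result <- function(model, estimates, r_squared, fit_scale, residuals,
                       converged = TRUE, degenerate = FALSE, message = NULL) {
  structure(
    list(model = model, estimates = estimates, r_squared = r_squared,
         fit_scale = fit_scale, residuals = residuals, converged = converged,
         degenerate = degenerate, message = message),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Kinetic fit: %s (%s scale)%s\n", x$model, x$fit_scale,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$estimates)) {
    cat("  ", paste(sprintf("%s = %.6g", names(x$estimates), x$estimates),
                    collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("  R^2 = %s\n",
              if (is.na(x$r_squared)) "undefined" else format(x$r_squared)))
  if (!is.null(x$message)) cat("  note:", x$message, "\n")
  invisible(x)
}

# Values the model is fitted against: raw amounts for amount-scale models,
# fraction of C_inf for the power-law and Weibull models.
fit_values <- function(curve, spec) {
  if (!spec$needs_fraction) return(curve$values)
  y <- curve_as_fraction(curve)
  if (is.null(y)) {
    stop(sprintf(
      "model '%s' requires fraction-scale values (set value_kind = 'fraction' or supply c_inf)",
      spec$name), call. = FALSE)
  }
  y
}

#' Fit a single kinetic model to a release curve
#'
#' Estimates the model parameters by least squares. The default `"natural"`
#' scale performs nonlinear least squares (Levenberg-Marquardt, via
#' \pkg{minpack.lm}) on the untransformed values with deterministic,
#' data-driven starting values. The `"linearized"` scale performs ordinary
#' regression on the model's classical linear form (e.g. log C vs log t for
#' the power law, ln(Cd - Ct) vs t for first order) where one exists; R^2 is
#' then reported on that transformed scale.
#'
#' @param curve A [release_curve()].
#' @param model Model name (see [kinetic_model_names()]).
#' @param scale `"natural"` or `"linearized"`.
#' @param fix_c0_zero For the zero-order model, fix C0 = 0 (the usual
#'   convention for release that starts from nothing).
#' @param ... Passed on to [predict_release()] (sign/grouping conventions).
#' @return A `fit_result` with elements `estimates`, `r_squared`,
#'   `fit_scale`, `residuals`, `converged`, `degenerate`.
#' @export
fit_model <- function(curve, model, scale = c("natural", "linearized"),
                      fix_c0_zero = FALSE, ...) {
  stopifnot(inherits(curve, "release_curve"))
  scale <- match.arg(scale)
  spec <- kinetic_model_spec(model)
  times <- curve$times
  y <- fit_values(curve, spec)
  if (length(times) < length(spec$parameter_names) + 1L) {
    stop(sprintf("model '%s' needs at least %d points, got %d",
                 spec$name, length(spec$parameter_names) + 1L, length(times)),
         call. = FALSE)
  }
  degenerate <- stats::var(y) == 0
  if (scale == "linearized") {
    return(fit_model_linearized(spec, times, y, curve, degenerate, ...))
  }

  start <- fit_start(spec$name, times, y)
  if (fix_c0_zero && spec$name == "zero_order") {
    resid_fn <- function(p) y - predict_release("zero_order",
                                                c(C0 = 0, K0 = p[["K0"]]),
                                                times, ...)
    fit <- try(minpack.lm::nls.lm(
      par = start["K0"], lower = 0, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) {
      return(fit_result(spec$name, start, NA_real_, "natural", NULL,
                        converged = FALSE, message = as.character(fit)))
    }
    est <- c(C0 = 0, K0 = unname(stats::coef(fit)[1]))
  } else {
    resid_fn <- function(p) {
      y - predict_release(spec$name, stats::setNames(as.list(p),
                                                     spec$parameter_names),
                          times, ...)
    }
    fit <- try(minpack.lm::nls.lm(
      par = start, lower = spec$lower[spec$parameter_names],
      upper = spec$upper[spec$parameter_names], fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15)
    ), silent = TRUE)
    if (inherits(fit, "try-error") || fit$info %in% c(0L, 5L, 9L)) {
      msg <- if (inherits(fit, "try-error")) as.character(fit) else fit$message
      return(fit_result(spec$name, start, NA_real_, "natural", NULL,
                        converged = FALSE, message = msg))
    }
    est <- stats::setNames(stats::coef(fit), spec$parameter_names)
  }
  pred <- predict_release(spec$name, as.list(est), times, ...)
  fit_result(spec$name, est, r_squared(y, pred), "natural", y - pred,
             degenerate = degenerate)
}

# Classical linearized regressions. Models whose linear form involves an
# unknown saturation amount (first/second order, Hixson-Crowell, Weibull)
# fix it at c_inf when available, otherwise at 1.05 * max(value).
fit_model_linearized <- function(spec, times, y, curve, degenerate, ...) {
  eps <- 1e-10
  cd_fix <- if (!is.null(curve$c_inf) && !spec$needs_fraction) curve$c_inf
            else 1.05 * max(y) + eps
  out <- switch(spec$name,
    zero_order = {
      co <- stats::coef(stats::lm(y ~ times))
      list(est = c(C0 = unname(co[1]), K0 = unname(co[2])), obs = y,
           pred = co[1] + co[2] * times)
    },
    higuchi = {
      st <- sqrt(times)
      kh <- sum(y * st) / sum(st^2)
      list(est = c(KH = kh), obs = y, pred = kh * st)
    },
    power_law = {
      keep <- times > 0 & y > 0
      lt <- log(times[keep]); ly <- log(y[keep])
      co <- stats::coef(stats::lm(ly ~ lt))
      list(est = c(K = exp(unname(co[1])), n = unname(co[2])), obs = ly,
           pred = co[1] + co[2] * lt)
    },
    first_order = {
      obs <- log(pmax(cd_fix - y, eps))
      co <- stats::coef(stats::lm(obs ~ times))
      list(est = c(Cd = cd_fix, K1 = -unname(co[2])), obs = obs,
           pred = co[1] + co[2] * times)
    },
    second_order = {
      obs <- 1 / pmax(cd_fix - y, eps)
      co <- stats::coef(stats::lm(obs ~ times))
      list(est = c(Cd = cd_fix, K2 = unname(co[2])), obs = obs,
           pred = co[1] + co[2] * times)
    },
    hixson_crowell = {
      obs <- cd_fix^(1 / 3) - pmax(cd_fix - y, 0)^(1 / 3)
      khc <- sum(obs * times) / sum(times^2)
      list(est = c(Cd = cd_fix, KHC = khc), obs = obs, pred = khc * times)
    },
    weibull = {
      cs_fix <- 1.05 * max(y) + eps
      keep <- times > 0 & y > 0 & y < cs_fix
      lt <- log(times[keep])
      obs <- log(-log(1 - y[keep] / cs_fix))
      co <- stats::coef(stats::lm(obs ~ lt))
      list(est = c(Cs = cs_fix, T = 0, b = unname(co[2]),
                   a = exp(-unname(co[1]))),
           obs = obs, pred = co[1] + co[2] * lt)
    }
  )
  est <- out$est[spec$parameter_names]
  fit_result(spec$name, est, r_squared(out$obs, out$pred), "linearized",
             out$obs - out$pred, degenerate = degenerate)
}

#' Fit all seven kinetic models and rank them by R^2
#'
#' Fits every model in [kinetic_model_names()] (or a subset) to the curve and
#' orders the results by decreasing coefficient of determination. The model
#' with the R^2 closest to 1 is the preferred description of the release
#' profile. Models that fail to converge are kept (flagged) and ranked after
#' every converged fit; exact ties are broken by fewer parameters, then by
#' model name.
#'
#' @inheritParams fit_model
#' @param models Character vector of model names to fit.
#' @return An object of class `release_fit_list`: a ranked list of
#'   `fit_result`s with a `summary` data.frame attached (columns `model`,
#'   `r_squared`, `converged`, `n_params`).
#' @export
fit_all <- function(curve, models = kinetic_model_names(),
                    scale = c("natural", "linearized"), ...) {
  stopifnot(inherits(curve, "release_curve"))
  scale <- match.arg(scale)
  if (length(curve$times) < 3L) stop("need >= 3 points", call. = FALSE)
  models <- match.arg(models, kinetic_model_names(), several.ok = TRUE)
  fits <- lapply(models, function(m) {
    tryCatch(fit_model(curve, m, scale = scale, ...),
             error = function(e) fit_result(m, numeric(), NA_real_, scale,
                                            NULL, converged = FALSE,
                                            message = conditionMessage(e)))
  })
  r2 <- vapply(fits, function(f) if (isTRUE(f$converged) && !is.na(f$r_squared))
    f$r_squared else -Inf, numeric(1))
  np <- vapply(models, function(m)
    length(kinetic_model_spec(m)$parameter_names), integer(1))
  ord <- order(-r2, np, models)
  fits <- fits[ord]
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    n_params = np[ord],
    row.names = NULL
  )
  structure(fits, class = "release_fit_list", summary = tab)
}

#' @export
print.release_fit_list <- function(x, ...) {
  cat("Kinetic model ranking (by R^2):\n")
  print(attr(x, "summary"), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.release_fit_list <- function(x, ...) attr(x, "summary")

#' Mechanism calls from a ranked fit list
#'
#' Extracts the fitted power-law exponent n and Weibull shape b from a
#' [fit_all()] result and classifies the release mechanism from each.
#'
#' @param fits A `release_fit_list`.
#' @return Named list with elements `power_law` and `weibull`, each a
#'   `mechanism_call` or `NULL` if that model did not converge.
#' @export
mechanism_calls <- function(fits) {
  stopifnot(inherits(fits, "release_fit_list"))
  get_fit <- function(name) {
    for (f in fits) if (f$model == name && isTRUE(f$converged)) return(f)
    NULL
  }
  pl <- get_fit("power_law")
  wb <- get_fit("weibull")
  list(
    power_law = if (!is.null(pl)) classify_power_law(unname(pl$estimates["n"])),
    weibull = if (!is.null(wb)) classify_weibull(unname(wb$estimates["b"]))
  )
}
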