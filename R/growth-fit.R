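#' Fit a sigmoid growth model to weight-by-age records
#'
#' Estimates the parameters (A, B, k) of one of the three sigmoid growth
#' models by multi-start nonlinear least squares, and computes goodness-of-fit
#' diagnostics: the residual sum of squares RSE, the total sum of squares
#' about the mean RST, and the coefficient of determination
#' R^2 = 1 - RSE / RST.
#'
#' Starting values follow a standard self-start strategy: the asymptote is
#' seeded at multiples of the maximum observed weight, the rate constant `k`
#' and shape constant `B` from a log-linearisation of the model at that
#' asymptote. Several starts are attempted and the best converged
#' least-squares solution is kept; if no start converges an error is raised
#' carrying the best parameter set seen.
#'
#' @param data A data frame with columns `age_days` and `weight_kg`; at least
#'   4 rows, ages distinct and non-negative, weights positive. Row order does
#'   not matter.
#' @param model One of [growth_models()].
#' @return An object of class `growth_fit`: a list with elements `model`,
#'   `coefficients` (named A, B, k), `data`, `fitted`, `residuals`,
#'   `rse`, `rst`, `r2`, and `n_obs`.
#' @seealso [inflection_point()], [compare_models()], [predict.growth_fit()]
#' @examples
#' obs <- simulate_growth(growth_sim_config(noise_sd = 0))
#' fit <- fit_growth_model(obs, "von_bertalanffy")
#' glance(fit)
#' @export
fit_growth_model <- function(data, model = growth_models()) {
  model <- match_growth_model(match.arg(model))
  data <- validate_growth_data(data)
  t <- data$age_days
  w <- data$weight_kg

  rst <- sum((w - mean(w))^2)
  if (rst <= 0) {
    stop("degenerate input: all weights identical (total sum of squares is 0)",
         call. = FALSE)
  }

  starts <- growth_start_values(model, t, w)
  best <- NULL
  best_obj <- Inf
  form <- switch(model,
    logistic        = weight_kg ~ A / (1 + B * exp(-k * age_days)),
    gompertz        = weight_kg ~ A * exp(-B * exp(-k * age_days)),
    von_bertalanffy = weight_kg ~ A * (1 - B * exp(-k * age_days))^3
  )
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        form, data = data, start = st,
        lower = c(A = 1e-8, B = 1e-8, k = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) next
    obj <- sum(stats::resid(fit)^2)
    if (obj < best_obj) {
      best <- fit
      best_obj <- obj
    }
  }
  if (is.null(best)) {
    best_start <- starts[[1L]]
    stop("growth-model fit did not converge from any start; best starting ",
         "values were A=", signif(best_start$A, 6), ", B=",
         signif(best_start$B, 6), ", k=", signif(best_start$k, 6),
         call. = FALSE)
  }

  cf <- stats::coef(best)
  fitted <- growth_curve(model, t, cf[["A"]], cf[["B"]], cf[["k"]])
  rse <- sum((w - fitted)^2)
  structure(
    list(
      model = model,
      coefficients = c(A = unname(cf[["A"]]), B = unname(cf[["B"]]),
                       k = unname(cf[["k"]])),
      data = data,
      fitted = fitted,
      residuals = w - fitted,
      rse = rse,
      rst = rst,
      r2 = 1 - rse / rst,
      n_obs = length(t)
    ),
    class = "growth_fit"
  )
}

# Self-start values: asymptote multiples of max weight, (B, k) from the
# log-linearisation of each model at that asymptote.
growth_start_values <- function(model, t, w) {
  starts <- list()
  for (mult in c(1.2, 1.05, 1.5, 2.5)) {
    A0 <- mult * max(w)
    y <- switch(model,
      logistic        = A0 / w - 1,
      gompertz        = -log(pmin(w / A0, 1 - 1e-9)),
      von_bertalanffy = 1 - pmin(w / A0, 1 - 1e-9)^(1 / 3)
    )
    ok <- is.finite(y) & y > 0
    if (sum(ok) >= 2L) {
      lf <- stats::lm.fit(cbind(1, t[ok]), log(y[ok]))
      k0 <- -lf$coefficients[[2L]]
      B0 <- exp(lf$coefficients[[1L]])
      if (is.finite(k0) && k0 > 0 && is.finite(B0) && B0 > 0) {
        starts <- c(starts, list(list(A = A0, B = B0, k = k0)))
      }
    }
  }
  # generic fallbacks in case every log-linearisation degenerates
  starts <- c(starts, list(
    list(A = 1.2 * max(w), B = 1, k = 2 / max(t)),
    list(A = 2 * max(w), B = 5, k = 0.5 / max(t))
  ))
  starts
}

#' @export
print.growth_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Sigmoid growth fit:", x$model, "\n")
  cat(sprintf("  A = %.4f kg, B = %.6g, k = %.6g /day  (n = %d)\n",
              cf[["A"]], cf[["B"]], cf[["k"]], x$n_obs))
  cat(sprintf("  RSE = %.4f kg^2, RST = %.4f kg^2, R^2 = %.6f\n",
              x$rse, x$rst, x$r2))
  invisible(x)
}

#' Predict weight from a fitted growth model
#'
#' @param object A `growth_fit`.
#' @param newdata Optional data frame with an `age_days` column; defaults to
#'   the training ages.
#' @param t Optional numeric vector of ages in days (shortcut for `newdata`).
#' @param ... Unused.
#' @return Numeric vector of predicted weights in kg.
#' @export
predict.growth_fit <- function(object, newdata = NULL, t = NULL, ...) {
  if (is.null(t)) {
    t <- if (is.null(newdata)) object$data$age_days else newdata$age_days
  }
  cf <- object$coefficients
  growth_curve(object$model, t, cf[["A"]], cf[["B"]], cf[["k"]])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a growth-model fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return For `tidy()`, a tibble with one row per parameter (`term`,
#'   `estimate`); for `glance()`, a one-row tibble with `model`, `rse`,
#'   `rst`, `r2` and `n_obs`.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(model = x$model, rse = x$rse, rst = x$rst, r2 = x$r2,
                 n_obs = x$n_obs)
}

#' Fit and rank all three sigmoid growth models
#'
#' Fits the logistic, Gompertz and Von Bertalanffy models to the same
#' weight-by-age records and ranks them by descending R^2 (ties within 1e-6
#' broken alphabetically by model name). A model that fails to fit is kept in
#' the table with `ok = FALSE` and its error message; the others are still
#' ranked.
#'
#' @inheritParams fit_growth_model
#' @return A tibble of class `growth_comparison` with one row per model:
#'   parameter estimates, diagnostics, the inflection triple (age, weight,
#'   maximum daily gain in kg/day and g/day) and an `ok` flag. The fitted
#'   `growth_fit` objects are attached as attribute `"fits"`.
#' @examples
#' obs <- simulate_growth(growth_sim_config(noise_sd = 0))
#' compare_models(obs)
#' @export
compare_models <- function(data) {
  rows <- purrr::map(growth_models(), function(m) {
    fit <- tryCatch(fit_growth_model(data, m), error = function(e) e)
    if (inherits(fit, "error")) {
      return(list(
        fit = NULL,
        row = tibble::tibble(
          model = m, ok = FALSE, A = NA_real_, B = NA_real_, k = NA_real_,
          rse = NA_real_, rst = NA_real_, r2 = NA_real_,
          t_star_days = NA_real_, w_star_kg = NA_real_,
          g_max_kg_day = NA_real_, g_max_g_day = NA_real_,
          message = conditionMessage(fit)
        )
      ))
    }
    ip <- inflection_point(fit)
    cf <- fit$coefficients
    list(
      fit = fit,
      row = tibble::tibble(
        model = m, ok = TRUE, A = cf[["A"]], B = cf[["B"]], k = cf[["k"]],
        rse = fit$rse, rst = fit$rst, r2 = fit$r2,
        t_star_days = ip$t_star_days, w_star_kg = ip$w_star_kg,
        g_max_kg_day = ip$g_max_kg_day, g_max_g_day = ip$g_max_g_day,
        message = NA_character_
      )
    )
  })
  out <- dplyr::bind_rows(purrr::map(rows, "row"))
  # rank: failed fits last; R2 ties within 1e-6 broken by model name
  r2_key <- ifelse(out$ok, round(out$r2 / 1e-6) * 1e-6, -Inf)
  out <- out[order(-r2_key, out$model), , drop = FALSE]
  fits <- purrr::map(rows, "fit")
  names(fits) <- growth_models()
  attr(out, "fits") <- fits
  class(out) <- c("growth_comparison", class(out))
  out
}
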