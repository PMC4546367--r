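#' Closed-form inflection analytics of a sigmoid growth curve
#'
#' The inflection point is the age at which daily gain (the first derivative
#' of the growth curve) is maximal. Each model admits closed forms:
#'
#' | model | inflection age t* | inflection weight W* | max daily gain G_max |
#' |---|---|---|---|
#' | logistic | ln(B)/k | A/2 | kA/4 = kW*/2 |
#' | gompertz | ln(B)/k | A/e | kA/e = kW* |
#' | von_bertalanffy | ln(3B)/k | 8A/27 | 4Ak/9 = 3kW*/2 |
#'
#' A shape constant small enough to put the inflection before birth
#' (t* < 0) is returned as-is with a warning and `before_birth = TRUE`.
#'
#' @param fit A `growth_fit`, or a model name (then supply `A`, `B`, `k`).
#' @param A,B,k Parameters when `fit` is a model name; all must be `> 0`.
#' @return A one-row tibble: `model`, `t_star_days`, `w_star_kg`,
#'   `g_max_kg_day`, `g_max_g_day` (same gain in g/day) and `before_birth`.
#' @examples
#' inflection_point("logistic", A = 100, B = 9, k = 0.1)
#' @export
inflection_point <- function(fit, A = NULL, B = NULL, k = NULL) {
  p <- growth_params(fit, A, B, k)
  with(p, {
    res <- switch(model,
      logistic        = c(log(B) / k,     A / 2,      k * A / 4),
      gompertz        = c(log(B) / k,     A / exp(1), k * A / exp(1)),
      von_bertalanffy = c(log(3 * B) / k, 8 * A / 27, 4 * A * k / 9)
    )
    before_birth <- res[1L] < 0
    if (before_birth) {
      warning("inflection age is negative (inflection before birth) for ",
              model, " with B = ", signif(B, 6), call. = FALSE)
    }
    tibble::tibble(
      model = model, t_star_days = res[1L], w_star_kg = res[2L],
      g_max_kg_day = res[3L], g_max_g_day = res[3L] * 1000,
      before_birth = before_birth
    )
  })
}

#' Numeric inflection point by grid search on the derivative
#'
#' Locates the inflection age by maximising a central-difference
#' approximation of the daily gain over a dense grid, refining a coarse pass
#' to `grid_step` resolution. Serves as a model-agnostic cross-check of
#' [inflection_point()]'s closed forms; the two agree within the grid
#' resolution for any valid parameter set.
#'
#' @inheritParams inflection_point
#' @param grid_step Final grid resolution in days (`> 0`).
#' @return Same shape as [inflection_point()] (without `before_birth`); the
#'   weight and gain are evaluated at the grid optimum.
#' @export
inflection_point_numeric <- function(fit, A = NULL, B = NULL, k = NULL,
                                     grid_step = 0.001) {
  stopifnot(is.numeric(grid_step), length(grid_step) == 1L, grid_step > 0)
  p <- growth_params(fit, A, B, k)
  f <- function(t) growth_curve(p$model, t, p$A, p$B, p$k)

  # expand the window until the curve is essentially at its asymptote
  upper <- 10 / p$k
  while (f(upper) < 0.999 * p$A) upper <- upper * 2

  h <- grid_step / 2
  deriv <- function(t) (f(t + h) - f(pmax(t - h, 0))) / (t + h - pmax(t - h, 0))

  coarse_step <- max(upper / 4000, grid_step)
  tg <- seq(0, upper, by = coarse_step)
  dg <- deriv(tg)
  # unimodality check: the derivative must rise to one peak then fall
  # (changes below float noise relative to the peak gain are ignored)
  dd <- diff(dg)
  dd[abs(dd) < 1e-9 * max(abs(dg))] <- 0
  sgn <- sign(dd)
  runs <- rle(sgn[sgn != 0])$values
  if (length(runs) > 2L || (length(runs) == 2L && !identical(runs, c(1, -1)))) {
    stop("daily-gain curve is not unimodal on the search window", call. = FALSE)
  }
  i <- which.max(dg)

  lo <- max(tg[max(i - 1L, 1L)], 0)
  hi <- tg[min(i + 1L, length(tg))]
  tf <- seq(lo, hi, by = grid_step)
  df <- deriv(tf)
  # the sampled derivative is flat at float precision near its peak; take
  # the midpoint of the near-maximal plateau rather than the raw argmax
  plateau <- tf[df >= max(df) - 1e-8 * max(abs(df))]
  t_star <- mean(range(plateau))

  tibble::tibble(
    model = p$model, t_star_days = t_star, w_star_kg = f(t_star),
    g_max_kg_day = max(df), g_max_g_day = max(df) * 1000
  )
}

growth_params <- function(fit, A, B, k) {
  if (inherits(fit, "growth_fit")) {
    cf <- fit$coefficients
    p <- list(model = fit$model, A = cf[["A"]], B = cf[["B"]], k = cf[["k"]])
  } else {
    p <- list(model = match_growth_model(fit), A = A, B = B, k = k)
  }
  if (!all(vapply(p[c("A", "B", "k")], function(x)
        is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, TRUE))) {
    stop("A, B and k must be single positive numbers", call. = FALSE)
  }
  p
}

#' Back-solve sigmoid parameters from an inflection triple
#'
#' Inverts the closed forms of [inflection_point()]: given the inflection age
#' (days), inflection weight (kg) and maximum daily gain (kg/day) of a model,
#' returns the unique (A, B, k) producing them. Useful for reconstructing a
#' growth curve from reported inflection analytics when the raw records are
#' unavailable.
#'
#' @param model One of [growth_models()].
#' @param t_star_days,w_star_kg,g_max_kg_day The inflection triple.
#' @return Named numeric vector `c(A, B, k)`.
#' @examples
#' params_from_inflection("von_bertalanffy", 193.40, 62.61, 0.45543)
#' @export
params_from_inflection <- function(model, t_star_days, w_star_kg,
                                   g_max_kg_day) {
  model <- match_growth_model(model)
  stopifnot(w_star_kg > 0, g_max_kg_day > 0)
  switch(model,
    logistic = {
      A <- 2 * w_star_kg
      k <- 4 * g_max_kg_day / A
      c(A = A, B = exp(k * t_star_days), k = k)
    },
    gompertz = {
      A <- exp(1) * w_star_kg
      k <- g_max_kg_day / w_star_kg
      c(A = A, B = exp(k * t_star_days), k = k)
    },
    von_bertalanffy = {
      A <- 27 * w_star_kg / 8
      k <- 9 * g_max_kg_day / (4 * A)
      c(A = A, B = exp(k * t_star_days) / 3, k = k)
    }
  )
}
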