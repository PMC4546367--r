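#' Sigmoid growth-model curves
#'
#' The three classical sigmoid growth functions used for livestock
#' weight-by-age modelling, each with three parameters: the mature-weight
#' asymptote `A` (kg), the curve-shape constant `B` (dimensionless) and the
#' intrinsic growth-rate constant `k` (per day).
#'
#' * logistic: `W(t) = A / (1 + B * exp(-k t))`
#' * gompertz: `W(t) = A * exp(-B * exp(-k t))`
#' * von_bertalanffy: `W(t) = A * (1 - B * exp(-k t))^3`
#'
#' For the Von Bertalanffy model a base `1 - B exp(-k t) < 0` is *not*
#' clamped: the signed cube is returned so that a least-squares objective
#' over the curve stays smooth near t = 0 for B > 1.
#'
#' @param model One of `"logistic"`, `"gompertz"`, `"von_bertalanffy"`.
#' @param t Age in days (vectorised, must be `>= 0`).
#' @param A,B,k Model parameters; all `> 0` for a valid growth curve.
#' @return Predicted weight in kg, same length as `t`.
#' @examples
#' growth_curve("logistic", t = log(9) / 0.1, A = 100, B = 9, k = 0.1) # A/2
#' @export
growth_curve <- function(model, t, A, B, k) {
  model <- match_growth_model(model)
  stopifnot(is.numeric(t), all(t >= 0))
  switch(model,
    logistic        = A / (1 + B * exp(-k * t)),
    gompertz        = A * exp(-B * exp(-k * t)),
    von_bertalanffy = A * (1 - B * exp(-k * t))^3
  )
}

#' @rdname growth_curve
#' @export
growth_models <- function() c("logistic", "gompertz", "von_bertalanffy")

match_growth_model <- function(model) {
  if (!is.character(model) || length(model) != 1L || !model %in% growth_models()) {
    stop("unknown growth model: ", paste(model, collapse = ", "),
         " (expected one of ", paste(growth_models(), collapse = ", "), ")",
         call. = FALSE)
  }
  model
}

# First derivative dW/dt in kg/day, used for daily-gain analytics.
growth_rate <- function(model, t, A, B, k) {
  e <- exp(-k * t)
  switch(model,
    logistic        = A * B * k * e / (1 + B * e)^2,
    gompertz        = A * B * k * e * exp(-B * e),
    von_bertalanffy = 3 * A * B * k * e * (1 - B * e)^2
  )
}

validate_growth_data <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("age_days", "weight_kg") %in% names(data))) {
    stop("growth data needs columns `age_days` and `weight_kg`", call. = FALSE)
  }
  data <- dplyr::arrange(tibble::as_tibble(data), .data$age_days)
  if (nrow(data) < 4L) {
    stop("at least 4 observations are required to fit a 3-parameter model",
         call. = FALSE)
  }
  if (anyDuplicated(data$age_days)) {
    stop("ages must be distinct within a growth dataset", call. = FALSE)
  }
  if (any(data$age_days < 0) || any(data$weight_kg <= 0)) {
    stop("ages must be >= 0 and weights > 0", call. = FALSE)
  }
  data
}
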