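#' Published PCT regression models
#'
#' The five fitted simple linear models that link the PCT quadrilateral
#' parameters to the two quantities measurable on any AP hip radiograph:
#' the neck-shaft angle (NSA, degrees) and the femoral head radius (R, mm):
#' \deqn{\alpha = 100.51 - 0.498 \cdot NSA}
#' \deqn{\beta = 79.49 - 0.50 \cdot NSA}
#' \deqn{\delta = 13.262 - 0.101 \cdot NSA}
#' \deqn{L_{top} = -7.695 + 1.306 \cdot R}
#' \deqn{L_{bottom} = 0.839 + 0.799 \cdot R}
#'
#' @return A data.frame with columns `response`, `predictor`, `intercept`,
#'   `slope`, `r_squared`.
#' @seealso [predict_params()], [localize_pct()]
#' @export
pct_models <- function() {
  data.frame(
    response  = c("alpha", "beta", "delta", "L_top", "L_bottom"),
    predictor = c("NSA", "NSA", "NSA", "R", "R"),
    intercept = c(100.51, 79.49, 13.262, -7.695, 0.839),
    slope     = c(-0.498, -0.50, -0.101, 1.306, 0.799),
    r_squared = c(0.474, 0.478, 0.237, 0.388, 0.182),
    stringsAsFactors = FALSE
  )
}

#' Reference morphometry distribution parameters
#'
#' Means, SDs and ranges of the proximal-femur morphometry parameters by
#' gender and in total, as used for the cohort simulator defaults and for
#' phantom parameterization. `R` is the femoral head radius (mm), `meanHU`
#' the mean Hounsfield unit value of the femoral head, `NSA` the neck-shaft
#' angle (degrees), `alpha`/`beta` the PCT-axis angles (degrees), `delta`
#' the signed PCT-axis offset (mm), and `L_bottom`/`L_top` the quadrilateral
#' boundary lengths (mm).
#'
#' @return Nested list with `$male`, `$female`, `$total` (each a list of
#'   `c(mean, sd)` per variable), `$hu_range` per gender, and `$n` counts.
#' @export
reference_morphometry <- function() {
  list(
    n = c(male = 41, female = 84, total = 125),
    male = list(R = c(23.91, 1.22), meanHU = c(178.46, 53.25),
                NSA = c(126.95, 5.76), alpha = c(37.12, 4.01),
                beta = c(15.93, 4.39), delta = c(0.30, 1.27),
                L_bottom = c(19.86, 3.39), L_top = c(23.63, 3.27)),
    female = list(R = c(21.43, 1.14), meanHU = c(136.93, 38.85),
                  NSA = c(126.79, 5.93), alpha = c(37.44, 4.36),
                  beta = c(15.77, 4.20), delta = c(0.44, 1.20),
                  L_bottom = c(18.02, 2.75), L_top = c(20.26, 2.99)),
    total = list(R = c(22.25, 1.65), meanHU = c(150.55, 48.05),
                 NSA = c(126.85, 5.85), alpha = c(37.33, 4.23),
                 beta = c(15.82, 4.25), delta = c(0.39, 1.22),
                 L_bottom = c(18.62, 3.08), L_top = c(21.37, 3.46)),
    hu_range = list(male = c(102, 308), female = c(66, 271),
                    total = c(66, 308))
  )
}

#' Predict PCT parameters from NSA and R
#'
#' Evaluates the five published linear models at a given neck-shaft angle
#' and head radius. `beta` is reported twice: from its own fitted model and
#' from the angle identity \eqn{\beta = 180 - NSA - \alpha}; the (small)
#' discrepancy between the two is returned as `beta_discrepancy`.
#'
#' @param NSA neck-shaft angle, degrees, in (90, 180).
#' @param R femoral head radius, mm, > 0.
#' @param models model table as returned by [pct_models()].
#' @return A one-row data.frame with `alpha`, `beta`, `beta_identity`,
#'   `beta_discrepancy`, `delta`, `L_bottom`, `L_top`.
#' @examples
#' predict_params(NSA = 126.68, R = 26.51)
#' @export
predict_params <- function(NSA, R, models = pct_models()) {
  if (any(NSA <= 90 | NSA >= 180)) stop("NSA must be in (90, 180) degrees")
  if (any(R <= 0)) stop("R must be positive")
  ev <- function(resp) {
    m <- models[models$response == resp, ]
    x <- if (m$predictor == "NSA") NSA else R
    m$intercept + m$slope * x
  }
  alpha <- ev("alpha")
  beta <- ev("beta")
  data.frame(alpha = alpha, beta = beta,
             beta_identity = 180 - NSA - alpha,
             beta_discrepancy = (180 - NSA - alpha) - beta,
             delta = ev("delta"),
             L_bottom = ev("L_bottom"), L_top = ev("L_top"))
}
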