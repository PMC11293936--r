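#' Parameters for a simulated morphometry cohort
#'
#' Defines a parameter-level synthetic cohort whose marginal distributions
#' and regression structure match the published morphometry: per-gender
#' normal head radius R and mean head HU (HU truncated to the published
#' per-gender ranges), normal NSA, and responses generated as the published
#' regression prediction plus a Gaussian residual whose SD is chosen by
#' variance decomposition so the marginal SD matches the published SD.
#' beta is set to the identity `180 - NSA - alpha`.
#'
#' @param n number of cases.
#' @param frac_male fraction of male cases (default 41/125).
#' @param ref reference distribution list, see [reference_morphometry()].
#' @param models regression table, see [pct_models()].
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(n = 125, frac_male = 41 / 125,
                          ref = reference_morphometry(),
                          models = pct_models()) {
  stopifnot(n >= 1, frac_male >= 0, frac_male <= 1)
  sds <- c(vapply(ref$male, `[`, 0, 2), vapply(ref$female, `[`, 0, 2),
           vapply(ref$total, `[`, 0, 2))
  if (any(sds <= 0)) stop("all SDs must be positive")
  structure(list(n = as.integer(n), frac_male = frac_male, ref = ref,
                 models = models),
            class = "cohort_params")
}

# marginal variance of a 2-component gaussian mixture
mixture_var <- function(p, m1, s1, m2, s2) {
  p * s1^2 + (1 - p) * s2^2 + p * (1 - p) * (m1 - m2)^2
}

residual_sd <- function(sd_y, slope, var_x, pair) {
  s2 <- sd_y^2 - slope^2 * var_x
  if (s2 <= 0) {
    stop("infeasible residual variance for ", pair,
         ": slope^2 * Var(predictor) exceeds Var(response)")
  }
  sqrt(s2)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Simulate a morphometry cohort
#'
#' Generates `n` cases with gender, head radius R (mm), mean head HU,
#' neck-shaft angle NSA (degrees), PCT angles alpha and beta (degrees),
#' PCT-axis offset delta (mm) and boundary lengths L_bottom / L_top (mm).
#' With the default parameters the simulated population reproduces the
#' published correlation structure (e.g. r(alpha, NSA) = -0.689) because
#' the implied correlation `slope * SD(x) / SD(y)` of the published numbers
#' is preserved by construction.
#'
#' @param params a [cohort_params()].
#' @param seed integer seed; the same seed gives an identical table.
#' @return A data.frame with one row per case.
#' @examples
#' tab <- simulate_cohort(cohort_params(n = 125), seed = 1)
#' cor(tab$alpha, tab$NSA)
#' @export
simulate_cohort <- function(params = cohort_params(), seed = 1) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(seed)
  ref <- params$ref
  n <- params$n
  male <- stats::runif(n) < params$frac_male
  gender <- ifelse(male, "male", "female")
  draw_gender <- function(var) {
    out <- numeric(n)
    for (g in c("male", "female")) {
      i <- gender == g
      if (!any(i)) next
      ms <- ref[[g]][[var]]
      out[i] <- stats::rnorm(sum(i), ms[1], ms[2])
    }
    out
  }
  R <- draw_gender("R")
  meanHU <- numeric(n)
  for (g in c("male", "female")) {
    i <- gender == g
    if (!any(i)) next
    ms <- ref[[g]]$meanHU
    rg <- ref$hu_range[[g]]
    meanHU[i] <- rnorm_trunc(sum(i), ms[1], ms[2], rg[1], rg[2])
  }
  NSA <- stats::rnorm(n, ref$total$NSA[1], ref$total$NSA[2])
  var_nsa <- ref$total$NSA[2]^2
  var_r <- mixture_var(params$frac_male,
                       ref$male$R[1], ref$male$R[2],
                       ref$female$R[1], ref$female$R[2])
  mdl <- function(resp) params$models[params$models$response == resp, ]
  gen <- function(resp, x, var_x) {
    m <- mdl(resp)
    s <- residual_sd(ref$total[[resp]][2], m$slope, var_x,
                     paste0(resp, " ~ ", m$predictor))
    m$intercept + m$slope * x + stats::rnorm(n, 0, s)
  }
  alpha <- gen("alpha", NSA, var_nsa)
  delta <- gen("delta", NSA, var_nsa)
  L_top <- gen("L_top", R, var_r)
  L_bottom <- gen("L_bottom", R, var_r)
  data.frame(case = seq_len(n), gender = gender, R = R, meanHU = meanHU,
             NSA = NSA, alpha = alpha, beta = 180 - NSA - alpha,
             delta = delta, L_bottom = L_bottom, L_top = L_top,
             stringsAsFactors = FALSE)
}
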