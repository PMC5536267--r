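# The seven subjective-value discounting models and their registry.
#
# Every model maps (A, E) -> SV, where A is the nominal reward amount (PLN),
# E the effort intensity (task units), l >= 0 the discounting-rate
# ("laziness") parameter and s the second free parameter where present:
# an exponent in the hyperboloid and power models, an asymptote (PLN) in the
# two-parameter exponential. The parabolic and power models are concave and
# may predict negative subjective values at high effort; these are retained
# unclamped, since the ability to cross zero is a substantive feature of
# concave effort-discounting curves.

.model_defs <- list(
  hyperbolic = list(
    label = "Hyperbolic", n_par = 1L,
    fn = function(A, E, l, s = NULL) A / (1 + l * E)
  ),
  exponential = list(
    label = "Exponential", n_par = 1L,
    fn = function(A, E, l, s = NULL) A * exp(-l * E)
  ),
  parabolic = list(
    label = "Parabolic", n_par = 1L,
    fn = function(A, E, l, s = NULL) A - l * E^2
  ),
  myerson_green = list(
    label = "Myerson & Green hyperboloid", n_par = 2L,
    fn = function(A, E, l, s) A / (1 + l * E)^s
  ),
  rachlin = list(
    label = "Rachlin hyperboloid", n_par = 2L,
    fn = function(A, E, l, s) A / (1 + l * E^s)
  ),
  exp2 = list(
    label = "Two-parameter exponential", n_par = 2L,
    fn = function(A, E, l, s) (A - s) * exp(-l * E) + s
  ),
  power = list(
    label = "Two-parameter power", n_par = 2L,
    fn = function(A, E, l, s) A - l * E^s
  )
)

#' Registry of the seven discounting models
#'
#' Stable order: the three one-parameter models first (hyperbolic,
#' exponential, parabolic), then the four two-parameter models
#' (Myerson-Green, Rachlin, two-parameter exponential, power).
#'
#' @return A data.frame with columns `model`, `label` and `n_par` (free
#'   parameters per reward magnitude: 1 or 2).
#' @export
disc_models <- function() {
  data.frame(model = names(.model_defs),
             label = vapply(.model_defs, `[[`, "", "label"),
             n_par = vapply(.model_defs, `[[`, 0L, "n_par"),
             row.names = NULL, stringsAsFactors = FALSE)
}

match_model <- function(model) {
  if (!is.character(model) || length(model) != 1L ||
      !model %in% names(.model_defs)) {
    stop_effdisc(sprintf("unknown model '%s'; available: %s",
                         paste(model, collapse = ","),
                         paste(names(.model_defs), collapse = ", ")),
                 "effdisc_unknown_model")
  }
  .model_defs[[model]]
}

#' Subjective value under a discounting model
#'
#' Evaluates the chosen model's subjective-value function. Parameter domains:
#' `l >= 0` for every model; `s > 0` for the Myerson-Green, Rachlin and power
#' models; `s < A` (any sign) for the two-parameter exponential, where it is
#' the asymptote in PLN. The parabolic and power models are not clamped and
#' may return negative values.
#'
#' @param model Model name, one of `disc_models()$model`.
#' @param A Reward amount (PLN, > 0).
#' @param E Effort intensity (task units, >= 0); vectorised.
#' @param l Discounting-rate parameter (>= 0).
#' @param s Second parameter, required for two-parameter models.
#' @return Numeric vector of subjective values (PLN).
#' @examples
#' sv("hyperbolic", A = 80, E = 30, l = 1 / 30)  # 40
#' sv("power", A = 80, E = 30, l = 1, s = 1)     # 50
#' @export
sv <- function(model, A, E, l, s = NULL) {
  def <- match_model(model)
  assert_scalar_number(A, "A")
  if (A <= 0) stop_effdisc("A must be positive", "effdisc_domain_error")
  if (!is.numeric(E) || any(!is.finite(E)) || any(E < 0)) {
    stop_effdisc("E must be finite and non-negative", "effdisc_domain_error")
  }
  assert_scalar_number(l, "l")
  if (l < 0) stop_effdisc("l must be non-negative", "effdisc_domain_error")
  if (def$n_par == 2L) {
    if (is.null(s)) {
      stop_effdisc(sprintf("model '%s' requires parameter s", model),
                   "effdisc_domain_error")
    }
    assert_scalar_number(s, "s")
    if (model %in% c("myerson_green", "rachlin", "power") && s <= 0) {
      stop_effdisc("s must be positive for exponent-type models",
                   "effdisc_domain_error")
    }
  } else if (!is.null(s)) {
    stop_effdisc(sprintf("model '%s' has no s parameter", model),
                 "effdisc_domain_error")
  }
  def$fn(A, E, l, s)
}

# Internal, unchecked evaluation used inside optimisation loops.
sv_eval <- function(fn, A, E, theta, n_par) {
  if (n_par == 1L) fn(A, E, theta[1L]) else fn(A, E, theta[1L], theta[2L])
}
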