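#' Simulated observer: cumulative-Gaussian psychometric model
#'
#' Probability of a correct response as a function of modulation depth,
#' \deqn{p(d) = \tfrac12\left[1 + \mathrm{erf}\!\left(\frac{d - \mu}{\sigma\sqrt2}\right)\right]
#'       = \Phi\!\left(\frac{d - \mu}{\sigma}\right),}
#' i.e. a Gaussian CDF with midpoint \eqn{\mu} (the 50\%-correct depth) and
#' spread \eqn{\sigma}, both in dB. The defaults describe an observer with a
#' -9 dB modulation detection threshold and a 2 dB spread.
#'
#' `guess_rate` optionally floors performance at the chance level of a forced
#' choice task (1/3 for 3-AFC), giving
#' \eqn{p = g + (1-g)\,\Phi((d-\mu)/\sigma)}. It defaults to 0: responses are
#' generated directly from the sigmoid, without a guessing correction.
#'
#' @param midpoint Depth (dB) of 50\% correct before guessing correction.
#' @param std Spread (dB) of the sigmoid; > 0.
#' @param guess_rate Lower asymptote in [0, 1); default 0.
#' @return An object of class `"psychometric_model"`.
#' @examples
#' obs <- psychometric_model(-9, 2)
#' prob_correct(-7.3622, obs)  # ~0.794
#' @export
psychometric_model <- function(midpoint = -9, std = 2, guess_rate = 0) {
  if (!is.finite(std) || std <= 0)
    stop_amtrack("'std' must be positive", class = "amtrack_spec_error")
  if (guess_rate < 0 || guess_rate >= 1)
    stop_amtrack("'guess_rate' must be in [0, 1)", class = "amtrack_spec_error")
  structure(list(midpoint = midpoint, std = std, guess_rate = guess_rate),
            class = "psychometric_model")
}

#' @export
print.psychometric_model <- function(x, ...) {
  cat(sprintf("<psychometric_model: midpoint %g dB, std %g dB%s>\n",
              x$midpoint, x$std,
              if (x$guess_rate > 0) sprintf(", guess rate %g", x$guess_rate) else ""))
  invisible(x)
}

#' Probability of a correct response
#'
#' @param depth Modulation depth(s) in dB; vectorized.
#' @param model A [psychometric_model()].
#' @return Probabilities in [0, 1], strictly increasing in `depth`.
#' @export
prob_correct <- function(depth, model) {
  stopifnot(inherits(model, "psychometric_model"))
  g <- model$guess_rate
  g + (1 - g) * stats::pnorm(depth, mean = model$midpoint, sd = model$std)
}

#' @export
predict.psychometric_model <- function(object, depth, ...) {
  prob_correct(depth, object)
}

#' Draw one simulated response
#'
#' A correct answer is returned with probability `prob_correct(depth, model)`
#' by comparing a uniform draw from R's random stream against the sigmoid;
#' seed the stream with [set.seed()] for reproducibility.
#'
#' @param depth Modulation depth in dB.
#' @param model A [psychometric_model()].
#' @return Logical.
#' @export
simulate_answer <- function(depth, model) {
  stats::runif(1) < prob_correct(depth, model)
}

#' Targeted probability of an n-down-1-up staircase
#'
#' At convergence a down step (n consecutive correct) is as likely as an up
#' step, so the equilibrium response probability solves \eqn{p^n = 1/2},
#' giving \eqn{p = 0.5^{1/n}} -- 0.794 for the 3-down-1-up rule.
#'
#' @param n_down Consecutive-correct criterion (>= 1).
#' @return Probability in (0, 1].
#' @export
convergence_probability <- function(n_down) {
  if (any(n_down < 1) || any(n_down != round(n_down)))
    stop_amtrack("'n_down' must be a positive integer", class = "amtrack_spec_error")
  0.5^(1 / n_down)
}

#' Expected convergence depth of an n-down-1-up staircase
#'
#' The unique depth at which the observer's probability of a correct response
#' equals [convergence_probability()], obtained by inverting the sigmoid:
#' \eqn{d^\ast = \mu + \sigma\,\Phi^{-1}(p^\ast)} (with the guessing
#' correction removed first when `guess_rate > 0`). For the default observer
#' (midpoint -9 dB, std 2 dB) and a 3-down rule this is -7.3622 dB.
#'
#' @param model A [psychometric_model()].
#' @param n_down Consecutive-correct criterion.
#' @return Depth in dB.
#' @export
expected_convergence_depth <- function(model, n_down = 3) {
  stopifnot(inherits(model, "psychometric_model"))
  p <- convergence_probability(n_down)
  g <- model$guess_rate
  if (p <= g)
    stop_amtrack("target probability is below the guess rate",
                 class = "amtrack_spec_error")
  model$midpoint + model$std * stats::qnorm((p - g) / (1 - g))
}
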