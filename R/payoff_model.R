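#' Construct a signaling environment
#'
#' Bundles the audience and signal parameters of the expected-payoff model
#' for identity signaling to a mixed audience. An audience of size `n`
#' contains a proportion `d` of outgroup members. Overt signals are received
#' (their identity content perceived) by every audience member with
#' probability `R`; covert signals are received by ingroup members with
#' probability `r_I` and by outgroup members with probability `r_O`.
#' Members who perceive similarity like the signal, adding `b` to the
#' signaler's payoff; members who perceive dissimilarity dislike it,
#' subtracting `c`; `w0` is the baseline payoff. Currency units are cents
#' throughout, matching a 1-cent like bonus and 0.5/1-cent dislike cost.
#'
#' The model assumes `r_O <= r_I <= R`. By default ties are allowed with a
#' warning (the calibrated estimates 0.5 < 0.6 < 0.8 are strict); set
#' `strict = TRUE` to require strict inequalities.
#'
#' @param n Audience size, a positive integer.
#' @param d Outgroup proportion of the audience, in `[0, 1]`.
#' @param R Overt reception probability, in `[0, 1]`.
#' @param r_I Covert ingroup reception probability.
#' @param r_O Covert outgroup reception probability.
#' @param b Benefit per like, cents, `>= 0`.
#' @param c Cost per dislike, cents, `>= 0`.
#' @param w0 Baseline payoff, cents.
#' @param strict Require `r_O < r_I < R` strictly?
#' @return An object of class `"signaling_env"`: a named list of the
#'   validated parameters.
#' @examples
#' env <- signaling_env(n = 10, d = 0.9, R = 0.8, r_I = 0.6, r_O = 0.5,
#'                      b = 1, c = 1)
#' payoff_advantage(env)
#' @export
signaling_env <- function(n = 10, d = 0.5, R = 0.8, r_I = 0.6, r_O = 0.5,
                          b = 1, c = 1, w0 = 0, strict = FALSE) {
  stopifnot(length(n) == 1, length(d) == 1, length(R) == 1,
            length(r_I) == 1, length(r_O) == 1,
            length(b) == 1, length(c) == 1, length(w0) == 1)
  if (!is.numeric(n) || n < 1 || n != round(n))
    stop("`n` must be a positive integer audience size", call. = FALSE)
  if (!is.numeric(d) || d < 0 || d > 1)
    stop("`d` must be an outgroup proportion in [0, 1]", call. = FALSE)
  for (p in c(R = R, r_I = r_I, r_O = r_O)) {
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("reception probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (b < 0 || c < 0)
    stop("`b` and `c` must be non-negative", call. = FALSE)
  if (r_O > r_I || r_I > R)
    stop("reception probabilities must satisfy r_O <= r_I <= R", call. = FALSE)
  if (strict && (r_O >= r_I || r_I >= R))
    stop("strict mode requires r_O < r_I < R", call. = FALSE)
  if (!strict && (r_O == r_I || r_I == R))
    warning("tied reception probabilities: the model assumes r_O < r_I < R",
            call. = FALSE)
  structure(
    list(n = as.integer(n), d = d, R = R, r_I = r_I, r_O = r_O,
         b = b, c = c, w0 = w0),
    class = "signaling_env"
  )
}

#' @export
print.signaling_env <- function(x, ...) {
  cat("Signaling environment\n")
  cat(sprintf("  audience: n = %d, outgroup proportion d = %g\n", x$n, x$d))
  cat(sprintf("  reception: R = %g (overt), r_I = %g, r_O = %g (covert)\n",
              x$R, x$r_I, x$r_O))
  cat(sprintf("  payoffs: b = %g, c = %g, w0 = %g (cents)\n", x$b, x$c, x$w0))
  invisible(x)
}

as_signaling_env <- function(env) {
  if (!inherits(env, "signaling_env"))
    stop("expected a `signaling_env` object; see signaling_env()",
         call. = FALSE)
  env
}

#' Expected payoff of an overt signal
#'
#' Computes `w0 + R * ((1 - d) * n * b - d * n * c)`: every audience member
#' receives the signal with probability `R`; ingroup receivers like it
#' (+`b`), outgroup receivers dislike it (-`c`).
#'
#' @param env A [signaling_env()].
#' @return Expected payoff in cents.
#' @export
expected_payoff_overt <- function(env) {
  env <- as_signaling_env(env)
  with(env, w0 + R * ((1 - d) * n * b - d * n * c))
}

#' Expected payoff of a covert signal
#'
#' Computes `w0 + r_I * (1 - d) * n * b - r_O * d * n * c`: ingroup members
#' receive (and like) the covert signal with probability `r_I`, outgroup
#' members receive (and dislike) it with probability `r_O`.
#'
#' @inheritParams expected_payoff_overt
#' @return Expected payoff in cents.
#' @export
expected_payoff_covert <- function(env) {
  env <- as_signaling_env(env)
  with(env, w0 + r_I * (1 - d) * n * b - r_O * d * n * c)
}

#' Covert-vs-overt payoff comparison
#'
#' Returns both expected payoffs and the covert advantage
#' `W_C - W_O`, which is affine in the outgroup proportion `d`:
#' positive advantage favors covert signaling. The advantage does not
#' depend on `w0`.
#'
#' @inheritParams expected_payoff_overt
#' @return A `"payoff_result"` list with elements `overt`, `covert`, and
#'   `advantage = covert - overt` (cents).
#' @export
payoff_advantage <- function(env) {
  env <- as_signaling_env(env)
  overt <- expected_payoff_overt(env)
  covert <- expected_payoff_covert(env)
  structure(list(overt = overt, covert = covert, advantage = covert - overt),
            class = "payoff_result")
}

#' @export
print.payoff_result <- function(x, ...) {
  cat(sprintf("overt %.4g, covert %.4g, covert advantage %.4g cents\n",
              x$overt, x$covert, x$advantage))
  invisible(x)
}

#' Covert-favorability threshold in outgroup proportion
#'
#' Solves `advantage(d) = 0` for the outgroup proportion above which covert
#' signaling has the higher expected payoff:
#' `d* = b (R - r_I) / (b (R - r_I) + c (R - r_O))`.
#' For `d > d*` the covert advantage is positive, for `d < d*` negative.
#'
#' When the advantage does not depend on `d` (degenerate denominator, e.g.
#' `R = r_I = r_O` or `b = c = 0`) there is no threshold; the function
#' returns `NA` flagged with `attr(, "all_equal") = TRUE` and warns.
#'
#' @inheritParams expected_payoff_overt
#' @return The threshold `d*` in `[0, 1]`, or flagged `NA` when the
#'   advantage is constant in `d`.
#' @export
covert_threshold <- function(env) {
  env <- as_signaling_env(env)
  num <- with(env, b * (R - r_I))
  den <- with(env, b * (R - r_I) + c * (R - r_O))
  if (den <= 0) {
    warning("covert and overt payoffs do not cross: advantage is constant in d",
            call. = FALSE)
    return(structure(NA_real_, all_equal = TRUE))
  }
  num / den
}

#' Payoff curve over outgroup proportions
#'
#' Evaluates the payoff model on a grid of outgroup proportions, e.g. to
#' reproduce the covert-advantage curve under low- and high-cost
#' conditions.
#'
#' @inheritParams expected_payoff_overt
#' @param d_values Numeric vector of outgroup proportions in `[0, 1]`.
#' @return A data frame with columns `d`, `overt`, `covert`, `advantage`,
#'   ordered as `d_values`.
#' @export
payoff_curve <- function(env, d_values) {
  env <- as_signaling_env(env)
  if (length(d_values) == 0)
    return(data.frame(d = numeric(0), overt = numeric(0),
                      covert = numeric(0), advantage = numeric(0)))
  if (any(!is.finite(d_values)) || any(d_values < 0 | d_values > 1))
    stop("all `d_values` must lie in [0, 1]", call. = FALSE)
  rows <- lapply(d_values, function(d) {
    e <- env
    e$d <- d
    r <- payoff_advantage(e)
    data.frame(d = d, overt = r$overt, covert = r$covert,
               advantage = r$advantage)
  })
  do.call(rbind, rows)
}

#' Expected payoff of a mixed signaling strategy
#'
#' Convenience extension beyond the pure-strategy analysis: because payoffs
#' are linear in the signal mix, a signaler sending a fraction `q` of
#' covert signals earns `q * W_C + (1 - q) * W_O` in expectation.
#'
#' @inheritParams expected_payoff_overt
#' @param q Fraction of signals sent covertly, in `[0, 1]`.
#' @return Expected payoff in cents.
#' @export
mixed_strategy_payoff <- function(env, q) {
  if (any(q < 0 | q > 1)) stop("`q` must lie in [0, 1]", call. = FALSE)
  r <- payoff_advantage(env)
  q * r$covert + (1 - q) * r$overt
}

#' Monte-Carlo simulation of one signaling round
#'
#' Draws per-member Bernoulli reception for `n_reps` independent audiences
#' and returns the realized payoffs. Under the overt strategy every member
#' receives the signal with probability `R`; under the covert strategy
#' ingroup members receive with probability `r_I` and outgroup members with
#' `r_O`. Receiving ingroup members like (+`b`), receiving outgroup members
#' dislike (-`c`); `w0` is added to every rep. The sample mean converges to
#' the corresponding analytic expected payoff.
#'
#' The integer outgroup count is `d * n`. When that is not an integer the
#' `rounding` policy applies: `"nearest"` rounds to the nearest count and
#' records the realized proportion in `attr(, "realized_d")`; `"error"`
#' refuses.
#'
#' @inheritParams expected_payoff_overt
#' @param strategy `"overt"` or `"covert"`.
#' @param n_reps Number of independent audience draws, `>= 1`.
#' @param seed Optional integer seed for reproducibility.
#' @param rounding Policy for non-integer `d * n`: `"nearest"` or `"error"`.
#' @return Numeric vector of `n_reps` realized payoffs (cents) with
#'   attributes `realized_d` and `n_outgroup`.
#' @export
simulate_signaling_round <- function(env, strategy = c("overt", "covert"),
                                     n_reps = 10000L, seed = NULL,
                                     rounding = c("nearest", "error")) {
  env <- as_signaling_env(env)
  strategy <- match.arg(strategy)
  rounding <- match.arg(rounding)
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  n_out_exact <- env$d * env$n
  if (abs(n_out_exact - round(n_out_exact)) > 1e-9 && rounding == "error")
    stop("d * n is not an integer; set rounding = \"nearest\"", call. = FALSE)
  n_out <- as.integer(round(n_out_exact))
  n_in <- env$n - n_out
  if (!is.null(seed)) set.seed(seed)
  p_in <- if (strategy == "overt") env$R else env$r_I
  p_out <- if (strategy == "overt") env$R else env$r_O
  likes <- stats::rbinom(n_reps, n_in, p_in)
  dislikes <- stats::rbinom(n_reps, n_out, p_out)
  payoff <- env$w0 + env$b * likes - env$c * dislikes
  structure(payoff, realized_d = n_out / env$n, n_outgroup = n_out)
}
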