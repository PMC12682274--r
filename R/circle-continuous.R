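#' Normalized tie distances for one ego
#'
#' Converts an ego's positive tie weights (grooming investment per partner)
#' into normalized distances \eqn{t_i = (s_{max} - s_i)/(s_{max} - s_{min})},
#' so that \eqn{t = 0} is the strongest tie and \eqn{t = 1} the weakest.
#' The mean relational cost \eqn{\sigma} is the arithmetic mean of the
#' weights, and the mean distance
#' \eqn{\bar t = (s_{max} - \sigma)/(s_{max} - s_{min})} equals the mean of
#' the \eqn{t_i}.
#'
#' By default the bounds \eqn{s_{max}, s_{min}} are taken per ego from the
#' observed weights, so every ego has at least one tie at \eqn{t = 0} and one
#' at \eqn{t = 1}. Dataset-wide bounds can be supplied instead via `s_max`
#' and `s_min` (they must enclose the observed weights).
#'
#' @param weights Numeric vector of strictly positive tie weights, one per
#'   distinct partner (counts or durations).
#' @param s_max,s_min Optional global bounds overriding the per-ego
#'   convention. Both or neither must be given.
#' @param ego_id Optional identifier carried through for error messages.
#'
#' @return A list of class `tie_distances` with elements `t_values`,
#'   `t_bar`, `s_max`, `s_min`, `sigma`, `L` and `ego_id`.
#' @examples
#' nd <- normalize_distances(c(1, 1, 10))
#' nd$t_values # 1 1 0
#' nd$t_bar    # 2/3
#' @export
normalize_distances <- function(weights, s_max = NULL, s_min = NULL,
                                ego_id = NULL) {
  weights <- as.numeric(weights)
  if (length(weights) < 2) {
    stop("need at least 2 tie weights to normalize, got ", length(weights),
         call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("tie weights must be finite and strictly positive", call. = FALSE)
  }
  if (is.null(s_max) != is.null(s_min)) {
    stop("supply both `s_max` and `s_min`, or neither", call. = FALSE)
  }
  if (is.null(s_max)) {
    s_max <- max(weights)
    s_min <- min(weights)
  } else {
    if (s_max < max(weights) || s_min > min(weights)) {
      stop("global bounds [", s_min, ", ", s_max,
           "] do not enclose the observed weights", call. = FALSE)
    }
  }
  if (s_max <= s_min) {
    stop(degenerate_weights_error(ego_id, length(weights)))
  }
  t_values <- (s_max - weights) / (s_max - s_min)
  sigma <- mean(weights)
  structure(
    list(
      t_values = t_values,
      t_bar = (s_max - sigma) / (s_max - s_min),
      s_max = s_max,
      s_min = s_min,
      sigma = sigma,
      L = length(weights),
      ego_id = ego_id
    ),
    class = "tie_distances"
  )
}

degenerate_weights_error <- function(ego_id, L) {
  msg <- paste0(
    "degenerate weights: all ", L, " ties have equal weight (s_max = s_min)",
    if (!is.null(ego_id)) paste0(" for ego '", ego_id, "'"),
    "; eta is undefined and the ego must be excluded"
  )
  structure(
    class = c("groomcircles_degenerate_weights", "error", "condition"),
    list(message = msg, call = NULL)
  )
}

#' Mean normalized distance as a function of eta
#'
#' The implicit equation linking the circle-model parameter \eqn{\eta} to the
#' mean normalized distance:
#' \deqn{g(\eta) = \frac{e^\eta}{e^\eta - 1} - \frac{1}{\eta},}
#' with the removable singularity \eqn{g(0) = 1/2}. \eqn{g} is strictly
#' increasing from 0 to 1 and satisfies \eqn{g(-\eta) = 1 - g(\eta)}.
#'
#' Evaluated in overflow-safe form: \eqn{1/(1 - e^{-\eta}) - 1/\eta} for
#' \eqn{\eta > 0}, the symmetry for \eqn{\eta < 0}, and the series
#' \eqn{1/2 + \eta/12 - \eta^3/720} for \eqn{|\eta| < 10^{-2}} (where the
#' closed form cancels catastrophically and the series truncation error is
#' below \eqn{4 \times 10^{-15}}).
#'
#' @param eta Numeric vector of finite circle-model parameters.
#' @return The mean normalized distance \eqn{\bar t \in (0, 1)}, vectorized
#'   over `eta`.
#' @examples
#' mean_distance_curve(0) # 0.5
#' mean_distance_curve(6) # 0.8358...
#' @export
mean_distance_curve <- function(eta) {
  stopifnot(is.numeric(eta), all(is.finite(eta)))
  out <- numeric(length(eta))
  small <- abs(eta) < 1e-2
  out[small] <- 0.5 + eta[small] / 12 - eta[small]^3 / 720
  pos <- !small & eta > 0
  out[pos] <- 1 / (-expm1(-eta[pos])) - 1 / eta[pos]
  neg <- !small & eta < 0
  out[neg] <- 1 - (1 / (-expm1(eta[neg])) - 1 / (-eta[neg]))
  out
}

#' Solve the implicit equation for eta
#'
#' Inverts [mean_distance_curve()]: finds the \eqn{\eta} whose model mean
#' distance equals the observed \eqn{\bar t}. Monotone bisection
#' (via [stats::uniroot()]) on an overflow-safe evaluation; the bracket is
#' widened automatically for \eqn{\bar t} extremely close to 0 or 1. Near
#' \eqn{\bar t = 1/2} the series inverse \eqn{\eta \approx 12(\bar t - 1/2)}
#' is used to avoid the removable singularity.
#'
#' @param t_bar Mean normalized distance, strictly inside (0, 1).
#' @param tol Absolute tolerance on \eqn{\eta} (default `1e-9`).
#' @param bracket Initial symmetric search bracket (default `c(-700, 700)`),
#'   widened as needed.
#' @param series_cutoff Half-width around 1/2 inside which the series inverse
#'   is used (default `1e-6`).
#' @return The estimate \eqn{\hat\eta}; positive for \eqn{\bar t > 1/2}
#'   (normal regime), negative below (inverted regime).
#' @examples
#' solve_eta(0.5)        # 0
#' solve_eta(2 / 3)      # ~2.15
#' @export
solve_eta <- function(t_bar, tol = 1e-9, bracket = c(-700, 700),
                      series_cutoff = 1e-6) {
  if (!is.numeric(t_bar) || length(t_bar) != 1 || !is.finite(t_bar) ||
      t_bar <= 0 || t_bar >= 1) {
    stop("`t_bar` must lie strictly inside (0, 1); got ", format(t_bar),
         ". t_bar at 0 or 1 puts all mass at one endpoint and eta diverges.",
         call. = FALSE)
  }
  if (abs(t_bar - 0.5) < series_cutoff) {
    return(12 * (t_bar - 0.5))
  }
  lo <- bracket[1]
  hi <- bracket[2]
  # widen until the root is enclosed (g is strictly increasing)
  while (mean_distance_curve(hi) < t_bar) hi <- hi * 2
  while (mean_distance_curve(lo) > t_bar) lo <- lo * 2
  stats::uniroot(
    function(eta) mean_distance_curve(eta) - t_bar,
    lower = lo, upper = hi, tol = tol
  )$root
}

#' Cumulative circle-size curve (continuous model)
#'
#' Fraction of an ego's relationships with normalized cost at most `t`:
#' \deqn{\chi(t) = \frac{e^{\eta t} - 1}{e^\eta - 1},}
#' with the uniform limit \eqn{\chi(t) = t} at \eqn{\eta = 0}. Non-decreasing
#' in `t` with \eqn{\chi(0) = 0} and \eqn{\chi(1) = 1}.
#'
#' @param t Numeric vector of normalized distances in \[0, 1\].
#' @param eta Circle-model parameter (scalar).
#' @return Cumulative relationship fractions, same length as `t`.
#' @examples
#' chi_continuous(0.5, 6) # 0.0474...
#' @export
chi_continuous <- function(t, eta) {
  stopifnot(is.numeric(t), all(t >= 0 & t <= 1),
            is.numeric(eta), length(eta) == 1, is.finite(eta))
  if (abs(eta) < 1e-10) {
    return(as.numeric(t))
  }
  if (eta > 0) {
    # exp(eta*(t-1)) * (1 - e^{-eta t}) / (1 - e^{-eta}) avoids overflow
    exp(eta * (t - 1)) * (-expm1(-eta * t)) / (-expm1(-eta))
  } else {
    expm1(eta * t) / expm1(eta)
  }
}

#' Logarithmic derivative of the circle-size curve
#'
#' \deqn{\frac{\dot\chi(t)}{\chi(t)} = \frac{\eta e^{\eta t}}{e^{\eta t} - 1},}
#' the local scaling rate of circle sizes. For large positive \eqn{\eta} it
#' tends to \eqn{\eta} (the scaling-ratio regime); for \eqn{\eta \to -\infty}
#' it tends to 0. Singular at \eqn{t = 0}.
#'
#' @param t Normalized distance in (0, 1].
#' @param eta Finite circle-model parameter.
#' @return The log-derivative, vectorized over `t`.
#' @export
log_derivative_chi <- function(t, eta) {
  stopifnot(is.numeric(t), is.numeric(eta), length(eta) == 1, is.finite(eta))
  if (any(t <= 0) || any(t > 1)) {
    stop("`t` must lie in (0, 1]: the log-derivative is singular at t = 0",
         call. = FALSE)
  }
  if (abs(eta) < 1e-10) {
    return(rep(1, length(t)) / t) # eta -> 0 limit of eta e^{eta t}/(e^{eta t}-1)
  }
  x <- eta * t
  # eta * e^x / (e^x - 1) = eta / (1 - e^{-x}); stable for both signs of x
  eta / (-expm1(-x))
}

#' Log-likelihood of eta for a set of normalized distances
#'
#' Under the continuous model, normalized distances have density
#' \eqn{f(t; \eta) = \eta e^{\eta t}/(e^\eta - 1)} on \[0, 1\] (a truncated
#' exponential; the circle-size curve \eqn{\chi} is its CDF). The
#' log-likelihood of \eqn{L} distances is
#' \deqn{\ell(\eta) = L \log|\eta| + \eta \sum_i t_i - L \log|e^\eta - 1|,}
#' with \eqn{\ell(0) = 0} (uniform density). Its unique stationary point is
#' the root of the implicit mean-distance equation, so the ML estimate
#' coincides with [solve_eta()] applied to \eqn{\bar t}.
#'
#' @param nd A `tie_distances` object from [normalize_distances()], or a
#'   bare numeric vector of distances in \[0, 1\].
#' @param eta Circle-model parameter (scalar, finite).
#' @return The log-likelihood value.
#' @export
log_likelihood <- function(nd, eta) {
  t_values <- if (inherits(nd, "tie_distances")) nd$t_values else as.numeric(nd)
  stopifnot(is.numeric(eta), length(eta) == 1, is.finite(eta))
  L <- length(t_values)
  S <- sum(t_values)
  if (abs(eta) < 1e-4) {
    # ell = L*log(eta/(e^eta-1)) + eta*S; log(eta/(e^eta-1)) ~ -eta/2 - eta^2/24
    return(eta * (S - L / 2) - L * eta^2 / 24)
  }
  # log|e^eta - 1|, overflow-safe
  log_abs_expm1 <- if (eta > 0) eta + log1p(-exp(-eta)) else log(-expm1(eta))
  L * log(abs(eta)) + eta * S - L * log_abs_expm1
}

#' Likelihood-ratio confidence interval for eta
#'
#' Inverts the likelihood-ratio statistic: the 1 - 2\eqn{\delta} interval is
#' the set of \eqn{\eta} with
#' \eqn{2\{\ell(\hat\eta) - \ell(\eta)\} \le \chi^2_1(1 - 2\delta)}.
#' The log-likelihood is strictly concave in \eqn{\eta} (one-parameter
#' exponential family), so each endpoint is a unique root found by
#' [stats::uniroot()], searching outward from \eqn{\hat\eta}.
#'
#' @param nd A `tie_distances` object (or numeric distance vector).
#' @param eta_hat The ML estimate for `nd` (from [solve_eta()]).
#' @param delta Tail mass per side; the interval has nominal coverage
#'   \eqn{1 - 2\delta} (default 0.025, i.e. 95%).
#' @param max_halfwidth Maximum distance from `eta_hat` searched for an
#'   endpoint before declaring non-convergence (default 100).
#' @return Numeric vector `c(lo, hi)` with `lo <= eta_hat <= hi`.
#' @export
eta_confidence_interval <- function(nd, eta_hat, delta = 0.025,
                                    max_halfwidth = 100) {
  stopifnot(is.numeric(delta), length(delta) == 1, delta > 0, delta < 0.5)
  q <- stats::qchisq(1 - 2 * delta, df = 1)
  ll_hat <- log_likelihood(nd, eta_hat)
  drop_fun <- function(eta) 2 * (ll_hat - log_likelihood(nd, eta)) - q

  find_endpoint <- function(direction) {
    step <- 0.5
    repeat {
      cand <- eta_hat + direction * step
      if (drop_fun(cand) > 0) break
      step <- step * 2
      if (step > max_halfwidth) {
        stop("confidence-interval endpoint search exceeded eta_hat ± ",
             max_halfwidth, "; likelihood too flat", call. = FALSE)
      }
    }
    stats::uniroot(drop_fun, lower = min(eta_hat, cand),
                   upper = max(eta_hat, cand), tol = 1e-8)$root
  }

  c(find_endpoint(-1), find_endpoint(+1))
}

#' Fit the continuous circle model to one ego
#'
#' Chains normalization, the implicit-equation ML estimate and the
#' likelihood-ratio confidence interval, and labels the regime: `normal` for
#' \eqn{\eta > 0} (few intense ties, expanding weaker circles), `inverted`
#' for \eqn{\eta < 0} (most ties in the innermost circle), `boundary` at
#' \eqn{\eta = 0}.
#'
#' @inheritParams normalize_distances
#' @inheritParams eta_confidence_interval
#' @param tol Solver tolerance passed to [solve_eta()].
#' @return An object of class `circle_fit`: a list with `ego_id`, `eta`,
#'   `ci_low`, `ci_high`, `delta`, `regime`, `t_bar`, `sigma`, `s_max`,
#'   `s_min` and `L`. Use [generics::tidy()] for a one-row tibble.
#' @examples
#' fit <- fit_ego(c(1, 1, 10))
#' fit$eta # ~2.15, normal regime
#' @export
fit_ego <- function(weights, delta = 0.025, s_max = NULL, s_min = NULL,
                    ego_id = NULL, tol = 1e-9) {
  nd <- normalize_distances(weights, s_max = s_max, s_min = s_min,
                            ego_id = ego_id)
  eta <- solve_eta(nd$t_bar, tol = tol)
  ci <- eta_confidence_interval(nd, eta, delta = delta)
  regime <- if (abs(eta) < 1e-12) "boundary" else if (eta > 0) "normal" else "inverted"
  structure(
    list(
      ego_id = ego_id,
      eta = eta,
      ci_low = ci[1],
      ci_high = ci[2],
      delta = delta,
      regime = regime,
      t_bar = nd$t_bar,
      sigma = nd$sigma,
      s_max = nd$s_max,
      s_min = nd$s_min,
      L = nd$L,
      t_values = nd$t_values
    ),
    class = "circle_fit"
  )
}

#' @export
print.circle_fit <- function(x, ...) {
  cat("Continuous circle-model fit",
      if (!is.null(x$ego_id)) paste0("for ego '", x$ego_id, "'"), "\n")
  cat(sprintf("  eta = %.4f  [%.4f, %.4f]  (delta = %g, %s regime)\n",
              x$eta, x$ci_low, x$ci_high, x$delta, x$regime))
  cat(sprintf("  L = %d ties, sigma = %.3f, t_bar = %.4f\n",
              x$L, x$sigma, x$t_bar))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_ego
#' @param x A `circle_fit` object.
#' @param ... Unused.
#' @export
tidy.circle_fit <- function(x, ...) {
  tibble::tibble(
    ego_id = x$ego_id %||% NA_character_,
    L = x$L,
    sigma = x$sigma,
    t_bar = x$t_bar,
    eta = x$eta,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    regime = x$regime
  )
}

#' @rdname fit_ego
#' @export
glance.circle_fit <- function(x, ...) {
  tibble::tibble(
    L = x$L,
    delta = x$delta,
    ci_width = x$ci_high - x$ci_low,
    log_lik = log_likelihood(x$t_values, x$eta)
  )
}
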