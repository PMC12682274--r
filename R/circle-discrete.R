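#' Discrete maximum-entropy layer model
#'
#' In the discrete circle model an ego's relationships fall into `r`
#' categories with strictly decreasing costs
#' \eqn{s_1 > s_2 > \dots > s_r}. The maximum-entropy probability that a
#' relationship belongs to category \eqn{k} is
#' \deqn{p_k = Z_r^{-1} e^{-\hat\mu s_k}, \qquad
#'       Z_r = \sum_{k=1}^r e^{-\hat\mu s_k}.}
#' The reduced parameter \eqn{\mu = \hat\mu (s_{max} - s_{min})/(r - 1)}
#' drives the cumulative circle sizes \eqn{\chi_k} (see [chi_discrete()]).
#'
#' @param costs Strictly decreasing numeric vector of category costs
#'   (\eqn{s_1 = s_{max}} down to \eqn{s_r = s_{min}}), length \eqn{r \ge 2}.
#' @param mu_hat The max-entropy Lagrange multiplier \eqn{\hat\mu}.
#' @return A list of class `layer_model` with `r`, `costs`, `mu_hat`, `mu`,
#'   `probs` (summing to 1) and `circle_sizes` (\eqn{\chi_1, \dots, \chi_r}).
#' @examples
#' discrete_layer_probs(c(1, 0), log(2))$probs # 1/3, 2/3
#' @export
discrete_layer_probs <- function(costs, mu_hat) {
  costs <- as.numeric(costs)
  r <- length(costs)
  if (r < 2) stop("need at least r = 2 cost categories", call. = FALSE)
  if (any(diff(costs) >= 0)) {
    stop("`costs` must be strictly decreasing (s_1 > s_2 > ... > s_r)",
         call. = FALSE)
  }
  stopifnot(is.numeric(mu_hat), length(mu_hat) == 1, is.finite(mu_hat))
  logw <- -mu_hat * costs
  logw <- logw - max(logw) # overflow-safe softmax
  probs <- exp(logw) / sum(exp(logw))
  mu <- mu_hat * (costs[1] - costs[r]) / (r - 1)
  structure(
    list(
      r = r,
      costs = costs,
      mu_hat = mu_hat,
      mu = mu,
      probs = probs,
      circle_sizes = chi_discrete(seq_len(r), r, mu)
    ),
    class = "layer_model"
  )
}

#' Cumulative circle sizes (discrete model)
#'
#' Expected cumulative fraction of relationships in circles 1..k:
#' \deqn{\chi_k = \frac{e^{k\mu} - 1}{e^{r\mu} - 1},}
#' with uniform limit \eqn{k/r} at \eqn{\mu = 0} and \eqn{\chi_r = 1}.
#' For large \eqn{\mu} consecutive ratios \eqn{\chi_{k+1}/\chi_k} approach
#' the scaling ratio \eqn{e^\mu} (the empirical value near 3 for human
#' ego-networks corresponds to \eqn{\mu \approx \log 3}).
#'
#' @param k Integer circle index (vectorized), \eqn{1 \le k \le r}.
#' @param r Number of circles, \eqn{r \ge 2}.
#' @param mu Reduced layer parameter.
#' @return Cumulative fractions \eqn{\chi_k}.
#' @examples
#' chi_discrete(1:4, 4, log(3)) # 0.025 0.100 0.325 1.000
#' @export
chi_discrete <- function(k, r, mu) {
  stopifnot(is.numeric(r), length(r) == 1, r >= 2, r == as.integer(r),
            is.numeric(mu), length(mu) == 1, is.finite(mu))
  k <- as.numeric(k)
  if (any(k < 1) || any(k > r) || any(k != as.integer(k))) {
    stop("circle index `k` must be an integer in [1, ", r, "]", call. = FALSE)
  }
  if (abs(mu) < 1e-12) {
    return(k / r)
  }
  if (mu > 0) {
    # exp((k-r)mu) * (1 - e^{-k mu}) / (1 - e^{-r mu}); safe for large mu
    exp((k - r) * mu) * (-expm1(-k * mu)) / (-expm1(-r * mu))
  } else {
    expm1(k * mu) / expm1(r * mu)
  }
}

#' Map the discrete layer parameter to continuous eta
#'
#' The discrete and continuous formalisms are linked by matching scaling
#' behavior, giving \deqn{\eta \approx (r - 1)(e^\mu - 1).} With the
#' conventional \eqn{r = 4} layers and the empirical scaling ratio
#' \eqn{e^\mu \approx 3} this yields \eqn{\eta \approx 6}.
#'
#' @param mu Reduced layer parameter (vectorized).
#' @param r Number of circles, \eqn{r \ge 2}.
#' @return The equivalent continuous-model \eqn{\eta}.
#' @examples
#' eta_from_mu(log(3), 4) # 6
#' @export
eta_from_mu <- function(mu, r = 4) {
  stopifnot(is.numeric(mu), all(is.finite(mu)),
            is.numeric(r), length(r) == 1, r >= 2)
  (r - 1) * expm1(mu)
}

#' @export
print.layer_model <- function(x, ...) {
  cat(sprintf("Discrete layer model: r = %d, mu_hat = %.4f, mu = %.4f\n",
              x$r, x$mu_hat, x$mu))
  cat("  p_k:  ", paste(sprintf("%.4f", x$probs), collapse = " "), "\n")
  cat("  chi_k:", paste(sprintf("%.4f", x$circle_sizes), collapse = " "), "\n")
  invisible(x)
}

#' @rdname discrete_layer_probs
#' @param x A `layer_model` object.
#' @param ... Unused.
#' @export
tidy.layer_model <- function(x, ...) {
  tibble::tibble(
    k = seq_len(x$r),
    cost = x$costs,
    prob = x$probs,
    chi = x$circle_sizes
  )
}
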