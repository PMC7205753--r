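#' Prior specification for the log-normal linkage model
#'
#' Priors for the Bayesian log-normal accelerated-failure-time regression of
#' log event time on the surrogate score: a flat improper prior on the
#' intercept and slope, and a Gamma(shape, rate) prior on either the
#' precision \eqn{1/\sigma^2} (the conjugate default) or on \eqn{\sigma}
#' directly.
#'
#' @param shape Positive shape of the Gamma prior. Default 0.001
#'   (noninformative).
#' @param rate Positive rate of the Gamma prior. Default 0.001.
#' @param prior_on Either \code{"precision"} (Gamma prior on
#'   \eqn{1/\sigma^2}, Gibbs-conjugate) or \code{"sigma"} (Gamma prior on
#'   \eqn{\sigma} itself, updated by a Metropolis step on \eqn{\log\sigma}).
#' @return An object of class \code{"prior_spec"}.
#' @export
prior_spec <- function(shape = 0.001, rate = 0.001,
                       prior_on = c("precision", "sigma")) {
  prior_on <- match.arg(prior_on)
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) ||
      shape <= 0) {
    stop("prior shape must be a positive finite number")
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) ||
      rate <= 0) {
    stop("prior rate must be a positive finite number")
  }
  structure(list(shape = shape, rate = rate, prior_on = prior_on),
            class = "prior_spec")
}

validate_historical_data <- function(data) {
  req <- c("surrogate", "time_weeks", "event")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    stop("historical data must be a data.frame with columns ",
         paste(req, collapse = ", "))
  }
  if (any(!is.finite(data$surrogate))) {
    stop("all surrogate values must be finite")
  }
  if (any(!is.finite(data$time_weeks)) || any(data$time_weeks <= 0)) {
    stop("all times must be finite and > 0")
  }
  if (!all(data$event %in% c(0, 1))) {
    stop("event indicators must be 0 or 1")
  }
  if (sum(data$event == 1) < 3L) {
    stop("at least 3 uncensored records are required for the regression ",
         "to be identifiable")
  }
  invisible(data)
}

#' Generate a synthetic historical dataset from the log-normal linkage model
#'
#' Draws surrogate scores from a specified law and event times from
#' \eqn{\log T = a + bX + \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2)}.
#' Optionally applies administrative right-censoring at a fixed time.
#'
#' @param n Number of subjects.
#' @param a Intercept on the log-week scale.
#' @param b Slope (log-weeks per surrogate unit).
#' @param sigma Residual SD on the log scale (\eqn{\ge 0}).
#' @param surrogate_law A list describing the surrogate distribution:
#'   \code{list(dist = "uniform", min, max)} (default \code{[-4, 4]}, the
#'   scale of the ordinal improvement score) or
#'   \code{list(dist = "normal", mean, sd)}.
#' @param censor_time Optional censoring time in weeks; records with latent
#'   time beyond it are censored there with \code{event = 0}.
#' @param seed Integer seed.
#' @param label Free-text provenance label attached as an attribute.
#' @return A data.frame with columns \code{surrogate}, \code{time_weeks},
#'   \code{event}.
#' @examples
#' hd <- generate_historical_data(200, a = 0.16, b = -1.37, sigma = 1.53,
#'                                seed = 1)
#' summary(hd$time_weeks)
#' @export
generate_historical_data <- function(n, a, b, sigma,
                                     surrogate_law = list(dist = "uniform",
                                                          min = -4, max = 4),
                                     censor_time = NULL, seed = 1L,
                                     label = "synthetic") {
  if (n < 1L) stop("n must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  if (!is.list(surrogate_law) || is.null(surrogate_law$dist)) {
    stop("surrogate_law must be a list with a 'dist' element")
  }
  set.seed(seed)
  x <- switch(surrogate_law$dist,
    uniform = stats::runif(n, surrogate_law$min, surrogate_law$max),
    normal = stats::rnorm(n, surrogate_law$mean, surrogate_law$sd),
    stop("unknown surrogate_law dist: ", surrogate_law$dist)
  )
  logt <- a + b * x + stats::rnorm(n, 0, sigma)
  time <- exp(logt)
  event <- rep(1, n)
  if (!is.null(censor_time)) {
    cens <- time > censor_time
    time[cens] <- censor_time
    event[cens] <- 0
  }
  out <- data.frame(surrogate = x, time_weeks = time, event = event)
  attr(out, "label") <- label
  out
}

#' Fit the Bayesian log-normal linkage model by Gibbs sampling
#'
#' Fits \eqn{\log T = a + bX + \epsilon}, \eqn{\epsilon \sim N(0,\sigma^2)},
#' to subject-level historical records with flat priors on \eqn{(a, b)} and
#' a Gamma prior on the precision (default) or on \eqn{\sigma}. Right-
#' censored log-times are handled by truncated-normal data augmentation, so
#' the conditional updates for the regression coefficients and the precision
#' remain conjugate.
#'
#' @param data Historical data.frame with columns \code{surrogate},
#'   \code{time_weeks}, \code{event} (1 = event observed).
#' @param prior A \code{\link{prior_spec}}.
#' @param n_draws Total MCMC iterations, including burn-in. Must leave at
#'   least 1000 retained draws.
#' @param n_burnin Iterations discarded as burn-in.
#' @param seed Integer seed.
#' @return An object of class \code{"posterior_draws"}: a list with vectors
#'   \code{a}, \code{b}, \code{sigma} (post burn-in), plus \code{n_burnin}
#'   and \code{seed}.
#' @export
fit_lognormal_model <- function(data, prior = prior_spec(),
                                n_draws = 6000L, n_burnin = 1000L,
                                seed = 1L) {
  validate_historical_data(data)
  stopifnot(inherits(prior, "prior_spec"))
  if (n_draws < n_burnin + 1000L) {
    stop("n_draws must be >= n_burnin + 1000")
  }
  set.seed(seed)
  x <- data$surrogate
  logc <- log(data$time_weeks)
  obs <- data$event == 1
  n <- length(x)
  X <- cbind(1, x)
  XtX <- crossprod(X)
  XtX_inv <- solve(XtX)
  R <- chol(XtX_inv)

  # initial values from the uncensored least-squares fit
  fit0 <- stats::lm.fit(X[obs, , drop = FALSE], logc[obs])
  beta <- fit0$coefficients
  sigma <- max(sqrt(mean(fit0$residuals^2)), 1e-3)
  y <- logc  # latent log-times; censored entries get augmented each sweep

  keep <- n_draws - n_burnin
  a_draws <- numeric(keep)
  b_draws <- numeric(keep)
  s_draws <- numeric(keep)
  n_cens <- sum(!obs)

  for (it in seq_len(n_draws)) {
    if (n_cens > 0L) {
      mu_c <- beta[1] + beta[2] * x[!obs]
      lo <- stats::pnorm(logc[!obs], mu_c, sigma)
      # guard against lo == 1 in the extreme tail
      lo <- pmin(lo, 1 - 1e-12)
      u <- lo + stats::runif(n_cens) * (1 - lo)
      y[!obs] <- stats::qnorm(u, mu_c, sigma)
    }
    # regression coefficients: N(betahat, sigma^2 (X'X)^{-1})
    betahat <- XtX_inv %*% crossprod(X, y)
    beta <- as.numeric(betahat + sigma * t(R) %*% stats::rnorm(2))
    resid <- y - X %*% beta
    rss <- sum(resid^2)
    if (prior$prior_on == "precision") {
      tau <- stats::rgamma(1, shape = prior$shape + n / 2,
                           rate = prior$rate + rss / 2)
      sigma <- 1 / sqrt(tau)
    } else {
      # Gamma(shape, rate) prior on sigma itself; random-walk Metropolis on
      # log(sigma) with the exact conditional log-density
      logpost <- function(s) {
        -n * log(s) - rss / (2 * s^2) +
          (prior$shape - 1) * log(s) - prior$rate * s
      }
      prop <- sigma * exp(stats::rnorm(1, 0, 0.15))
      # Jacobian of the log-scale walk: + log(prop) - log(sigma)
      if (log(stats::runif(1)) <
          logpost(prop) - logpost(sigma) + log(prop) - log(sigma)) {
        sigma <- prop
      }
    }
    if (it > n_burnin) {
      a_draws[it - n_burnin] <- beta[1]
      b_draws[it - n_burnin] <- beta[2]
      s_draws[it - n_burnin] <- sigma
    }
  }
  structure(list(a = a_draws, b = b_draws, sigma = s_draws,
                 n_burnin = n_burnin, seed = seed),
            class = "posterior_draws")
}

#' Summarize posterior draws of the linkage model
#'
#' Posterior means of \eqn{(a, b, \sigma)} and the equal-tailed 95\%
#' credible interval of the slope.
#'
#' @param draws A \code{"posterior_draws"} object (or a list with numeric
#'   vectors \code{a}, \code{b}, \code{sigma}).
#' @return An object of class \code{"model_summary"} with elements
#'   \code{a_mean}, \code{b_mean}, \code{sigma_mean}, \code{b_ci95}.
#' @export
summarize_posterior <- function(draws) {
  if (length(draws$a) == 0L || length(draws$b) == 0L ||
      length(draws$sigma) == 0L) {
    stop("posterior draws are empty")
  }
  if (length(unique(c(length(draws$a), length(draws$b),
                      length(draws$sigma)))) != 1L) {
    stop("draw vectors must have equal length")
  }
  ci <- unname(stats::quantile(draws$b, c(0.025, 0.975), type = 7))
  structure(list(a_mean = mean(draws$a),
                 b_mean = mean(draws$b),
                 sigma_mean = mean(draws$sigma),
                 b_ci95 = ci),
            class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  cat("Log-normal linkage model (posterior means)\n")
  cat(sprintf("  log(T) = %.3f X + %.3f,  sigma = %.3f\n",
              x$b_mean, x$a_mean, x$sigma_mean))
  cat(sprintf("  95%% CrI for slope: [%.3f, %.3f]%s\n",
              x$b_ci95[1], x$b_ci95[2],
              if (check_slope_validity(x)) "  (excludes zero)" else
                "  (covers zero)"))
  invisible(x)
}

#' Check that the slope credible interval excludes zero
#'
#' The interim decision rule is only valid when the surrogate demonstrably
#' predicts the primary endpoint, i.e. when the 95\% credible interval of
#' the slope excludes zero. The interval is treated as closed, so an
#' endpoint exactly at zero counts as covering it.
#'
#' @param summary A \code{"model_summary"}.
#' @return \code{TRUE} if zero lies outside the closed interval.
#' @export
check_slope_validity <- function(summary) {
  ci <- summary$b_ci95
  if (length(ci) != 2L || any(!is.finite(ci))) stop("invalid slope interval")
  !(ci[1] <= 0 && 0 <= ci[2])
}

#' Read a historical dataset from CSV
#'
#' Expects a header row with columns \code{surrogate,time_weeks,event}.
#'
#' @param path Path to a CSV file.
#' @return A validated historical data.frame.
#' @export
read_historical_data <- function(path) {
  data <- utils::read.csv(path)
  validate_historical_data(data)
  data
}

#' Write posterior draws to CSV (columns a, b, sigma)
#' @param draws A \code{"posterior_draws"} object.
#' @param path Output path.
#' @export
write_posterior_draws <- function(draws, path) {
  utils::write.csv(data.frame(a = draws$a, b = draws$b,
                              sigma = draws$sigma),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read posterior draws from CSV (columns a, b, sigma)
#' @param path Path to a CSV written by \code{\link{write_posterior_draws}}.
#' @return A \code{"posterior_draws"} object.
#' @export
read_posterior_draws <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("a", "b", "sigma") %in% names(d))) {
    stop("posterior CSV must have columns a, b, sigma")
  }
  if (any(d$sigma <= 0)) stop("all sigma draws must be positive")
  structure(list(a = d$a, b = d$b, sigma = d$sigma,
                 n_burnin = NA_integer_, seed = NA_integer_),
            class = "posterior_draws")
}
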