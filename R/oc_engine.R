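#' Monte-Carlo configuration for operating characteristics
#'
#' @param n_replicates Number of simulated trials. Default 5000
#'   (Monte-Carlo SE of a probability at most about 0.7 percentage points).
#' @param parameter_mode \code{"fixed"}: every replicate uses
#'   \code{fixed_params}; \code{"posterior_draws"}: replicate i consumes the
#'   i-th posterior draw of \eqn{(a, b, \sigma)}, propagating the
#'   uncertainty of the historical linkage fit.
#' @param fixed_params Named vector \code{c(a=, b=, sigma=)} used in fixed
#'   mode. Default: the posterior means of the reference historical fit.
#' @param master_seed Integer master seed; per-replicate seeds are derived
#'   from it reproducibly.
#' @param compute_counterfactual Whether stopped trials are re-completed
#'   with the observed-best arm to estimate the false-stopping ("flip-flop")
#'   probability.
#' @return An object of class \code{"oc_config"}.
#' @export
oc_config <- function(n_replicates = 5000L,
                      parameter_mode = c("fixed", "posterior_draws"),
                      fixed_params = c(a = 0.16, b = -1.37, sigma = 1.53),
                      master_seed = 1L,
                      compute_counterfactual = TRUE) {
  parameter_mode <- match.arg(parameter_mode)
  if (n_replicates < 100L) stop("n_replicates must be >= 100")
  if (parameter_mode == "fixed") {
    if (!all(c("a", "b", "sigma") %in% names(fixed_params))) {
      stop("fixed_params must have elements a, b, sigma")
    }
    if (fixed_params[["sigma"]] < 0) stop("sigma must be >= 0")
  }
  structure(list(n_replicates = as.integer(n_replicates),
                 parameter_mode = parameter_mode,
                 fixed_params = fixed_params,
                 master_seed = as.integer(master_seed),
                 compute_counterfactual = isTRUE(compute_counterfactual)),
            class = "oc_config")
}

# one replicate under forced continuation: the observed-best arm is always
# carried to stage 2 so that a single realization can be re-decided at any
# threshold (the selection and the stage-2 data do not depend on the
# threshold given continuation). Returns the observed margin, the best arm,
# whether the closed combination test rejects its hypothesis, and the
# accounting counts.
.simulate_replicate <- function(config, a, b, sigma, compute_tests = TRUE) {
  pre <- .simulate_preia(config, a, b, sigma)
  means <- .interim_means(config, pre)
  margins <- means[-1L] - means[1L]
  best_set <- which(margins == max(margins))
  best <- if (length(best_set) > 1L) {
    best_set[sample.int(length(best_set), 1L)]
  } else best_set
  margin <- margins[[best]]
  ia <- pre$ia_week
  fu <- config$followup_weeks
  excluded <- sum(!pre$mature & !(pre$arm %in% c(0L, best)))
  if (!compute_tests) {
    return(list(margin = margin, best = best, rejected = NA,
                n_full = NA_integer_, n_ia = pre$n_ia,
                excluded = excluded))
  }
  # stage-1 statistics: mature subjects only, censored at the IA
  k <- config$n_active
  z1 <- numeric(k)
  uv1_best <- NULL
  for (i in seq_len(k)) {
    sel <- pre$mature & (pre$arm == 0L | pre$arm == i)
    horiz <- pmin(ia - pre$enroll[sel], pre$dropout[sel], fu)
    tt <- pmin(pre$latent[sel], horiz)
    ev <- as.numeric(pre$latent[sel] <= horiz)
    uv <- logrank_uv(tt, ev, pre$arm[sel] == i)
    z1[i] <- if (uv$v > 0) uv$u / sqrt(uv$v) else 0
    if (i == best) uv1_best <- uv
  }
  # stage 2: all subjects of the continuing arms, followed followup_weeks
  s2 <- .simulate_stage2(config, pre, best, a, b, sigma)
  keep <- pre$arm == 0L | pre$arm == best
  arm_f <- c(pre$arm[keep], s2$arm)
  lat_f <- c(pre$latent[keep], s2$latent)
  drp_f <- c(pre$dropout[keep], s2$dropout)
  horiz <- pmin(drp_f, fu)
  tt <- pmin(lat_f, horiz)
  ev <- as.numeric(lat_f <= horiz)
  uv2 <- logrank_uv(tt, ev, arm_f == best)
  sw <- stagewise_z(uv1_best, uv2)
  rejected <- .reject_selected(z1, sw$z2, best,
                               config$alpha_one_sided, config$weights)
  list(margin = margin, best = best, rejected = rejected,
       n_full = pre$n_ia + length(s2$arm), n_ia = pre$n_ia,
       excluded = excluded)
}

# run n_replicates forced-continuation replicates; returns a data.frame
.simulate_batch <- function(design, oc, draws = NULL,
                            compute_tests = TRUE) {
  n <- oc$n_replicates
  if (oc$parameter_mode == "posterior_draws") {
    if (is.null(draws) || length(draws$a) < n) {
      stop("posterior mode requires at least n_replicates draws")
    }
    av <- draws$a[seq_len(n)]; bv <- draws$b[seq_len(n)]
    sv <- draws$sigma[seq_len(n)]
  } else {
    av <- rep(oc$fixed_params[["a"]], n)
    bv <- rep(oc$fixed_params[["b"]], n)
    sv <- rep(oc$fixed_params[["sigma"]], n)
  }
  set.seed(oc$master_seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(rep_seeds[i])
    out[[i]] <- .simulate_replicate(design, av[i], bv[i], sv[i],
                                    compute_tests)
  }
  data.frame(margin = vapply(out, `[[`, numeric(1), "margin"),
             best = vapply(out, `[[`, numeric(1), "best"),
             rejected = vapply(out, function(r) as.logical(r$rejected),
                               logical(1)),
             n_full = vapply(out, function(r) as.numeric(r$n_full),
                             numeric(1)),
             n_ia = vapply(out, `[[`, numeric(1), "n_ia"),
             excluded = vapply(out, `[[`, numeric(1), "excluded"))
}

.binom_se <- function(p, n) sqrt(pmax(p * (1 - p), 0) / n)

# aggregate a replicate batch at a given threshold
.aggregate_oc <- function(batch, delta, k, arm_names, compute_counterfactual,
                          compute_tests = TRUE) {
  n <- nrow(batch)
  continued <- batch$margin >= delta
  p_carry <- mean(continued)
  p_select <- vapply(seq_len(k), function(j) mean(continued & batch$best == j),
                     numeric(1))
  names(p_select) <- arm_names[-1L]
  if (compute_tests) {
    overall <- mean(continued & batch$rejected)
    conditional <- if (p_carry > 0) overall / p_carry else NA_real_
    false_stop <- if (compute_counterfactual) {
      mean(!continued & batch$rejected)
    } else NA_real_
    expected_n <- mean(ifelse(continued, batch$n_full, batch$n_ia))
    analysed <- mean(ifelse(continued, batch$n_full - batch$excluded,
                            batch$n_ia))
  } else {
    overall <- conditional <- false_stop <- NA_real_
    expected_n <- analysed <- NA_real_
  }
  structure(list(threshold_delta = delta,
                 p_select = p_select,
                 p_carry_forward = p_carry,
                 p_futility = 1 - p_carry,
                 overall_power = overall,
                 conditional_power = conditional,
                 false_stopping = false_stop,
                 expected_n = expected_n,
                 mean_analysed_n = analysed,
                 n_replicates = n,
                 mc_se = list(p_carry_forward = .binom_se(p_carry, n),
                              overall_power = .binom_se(overall, n),
                              false_stopping = .binom_se(false_stop, n),
                              p_select = .binom_se(p_select, n))),
            class = "oc_result")
}

#' @export
print.oc_result <- function(x, ...) {
  pct <- function(p) sprintf("%.1f%%", 100 * p)
  cat(sprintf("Operating characteristics (%d replicates, delta = %g)\n",
              x$n_replicates, x$threshold_delta))
  cat("  carry forward:", pct(x$p_carry_forward),
      " futility:", pct(x$p_futility), "\n")
  cat("  selection:", paste(names(x$p_select), pct(x$p_select),
                            collapse = ", "), "\n")
  if (!is.na(x$overall_power)) {
    cat("  overall power:", pct(x$overall_power),
        " conditional power:", pct(x$conditional_power), "\n")
    if (!is.na(x$false_stopping)) {
      cat("  false stopping:", pct(x$false_stopping), "\n")
    }
    cat(sprintf("  expected N: %.1f (analysed %.1f)\n",
                x$expected_n, x$mean_analysed_n))
  }
  invisible(x)
}

#' Estimate operating characteristics of the adaptive design
#'
#' Simulates \code{n_replicates} trials and aggregates selection
#' probabilities, carry-forward/futility probabilities, overall and
#' conditional power (rejecting at least one elementary hypothesis via the
#' closed combination test), the false-stopping probability (joint: stopped
#' at the IA and counterfactually significant had the best arm been carried
#' forward), and the expected enrolled sample size.
#'
#' @param design A \code{\link{design_config}}.
#' @param oc An \code{\link{oc_config}}.
#' @param draws Optional \code{"posterior_draws"} (required in posterior
#'   mode).
#' @param compute_tests If \code{FALSE}, only interim quantities (selection,
#'   carry-forward, futility) are computed; power fields are \code{NA}.
#' @return An object of class \code{"oc_result"}.
#' @examples
#' \donttest{
#' res <- run_oc(design_config(), oc_config(n_replicates = 200))
#' res$p_carry_forward
#' }
#' @export
run_oc <- function(design, oc = oc_config(), draws = NULL,
                   compute_tests = TRUE) {
  stopifnot(inherits(design, "design_config"), inherits(oc, "oc_config"))
  batch <- .simulate_batch(design, oc, draws, compute_tests)
  .aggregate_oc(batch, design$threshold_delta, design$n_active,
                design$arm_names, oc$compute_counterfactual, compute_tests)
}

#' Sweep the interim threshold over a grid
#'
#' Re-decides a common set of simulated trial realizations at each
#' threshold (common random numbers), so that carry-forward probabilities
#' are monotone in the threshold replicate-wise.
#'
#' @inheritParams run_oc
#' @param thresholds Sorted numeric vector of candidate thresholds.
#' @return A list of \code{"oc_result"} objects, one per threshold, with a
#'   \code{summary} data.frame attribute via \code{\link{oc_table}}.
#' @export
threshold_sweep <- function(design, thresholds, oc = oc_config(),
                            draws = NULL, compute_tests = TRUE) {
  if (length(thresholds) == 0L) stop("thresholds must be non-empty")
  if (is.unsorted(thresholds)) stop("thresholds must be sorted")
  batch <- .simulate_batch(design, oc, draws, compute_tests)
  out <- lapply(thresholds, function(d) {
    .aggregate_oc(batch, d, design$n_active, design$arm_names,
                  oc$compute_counterfactual, compute_tests)
  })
  names(out) <- as.character(thresholds)
  out
}

#' False-stopping ("flip-flop") probability
#'
#' Joint probability that a trial stops for futility at the IA and that its
#' counterfactual continuation (the observed-best arm carried forward)
#' would have rejected at least one hypothesis at the final analysis.
#'
#' @inheritParams run_oc
#' @return A single probability.
#' @export
false_stopping_probability <- function(design, oc = oc_config(),
                                       draws = NULL) {
  if (!oc$compute_counterfactual) {
    stop("false_stopping_probability requires compute_counterfactual = TRUE")
  }
  run_oc(design, oc, draws)$false_stopping
}

#' Smallest stage-2 sample size reaching a target overall power
#'
#' Bisection over a sorted grid of per-arm stage-2 sizes with common random
#' numbers across candidates (the same master seed is reused, so estimated
#' power is empirically non-decreasing in the stage-2 size). Combination
#' weights are recomputed for each candidate from the information fractions.
#'
#' @inheritParams run_oc
#' @param target_power Required overall power (e.g. 0.90).
#' @param n_grid Sorted integer grid of candidate stage-2 sizes per arm.
#' @return The smallest grid value whose estimated power reaches the
#'   target.
#' @export
find_stage2_n <- function(design, target_power, oc = oc_config(),
                          draws = NULL, n_grid = seq(60L, 200L, by = 4L)) {
  if (is.unsorted(n_grid)) stop("n_grid must be sorted")
  power_at <- function(n2) {
    d2 <- design_config(
      event_rates_3yr = design$event_rates_3yr,
      n_stage1_per_arm = design$n_stage1_per_arm,
      n_stage2_per_arm = n2,
      threshold_delta = design$threshold_delta,
      surrogate_maturation_weeks = design$surrogate_maturation_weeks,
      followup_weeks = design$followup_weeks,
      enrollment_rate = design$enrollment_rate,
      dropout_3yr = design$dropout_3yr,
      alpha_one_sided = design$alpha_one_sided,
      arm_names = design$arm_names)
    run_oc(d2, oc, draws)$overall_power
  }
  lo <- 1L; hi <- length(n_grid)
  if (power_at(n_grid[hi]) < target_power) {
    stop("target power unreachable on the supplied grid")
  }
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (power_at(n_grid[mid]) >= target_power) hi <- mid else lo <- mid + 1L
  }
  n_grid[lo]
}

#' Per-arm sample size of the traditional single-stage design
#'
#' Simulates the non-adaptive k-active-arm design: all subjects enrolled to
#' every arm, followed for the full horizon, one log-rank comparison per
#' active arm, Dunnett-adjusted testing at the one-sided level. Power is
#' the probability of claiming significance for at least one active arm.
#' The smallest per-arm n reaching the target is found by bisection with
#' common random numbers.
#'
#' @param event_rates 3-year event probabilities, control first.
#' @param alpha One-sided level. Default 0.025.
#' @param target_power Required power. Default 0.90.
#' @param followup_weeks Follow-up horizon in weeks. Default 156.
#' @param dropout_3yr Dropout probability by the horizon. Default 0.05.
#' @param oc An \code{\link{oc_config}} (replicates and master seed).
#' @param n_grid Sorted integer grid of candidate per-arm sizes.
#' @return Smallest per-arm n on the grid with estimated power at or above
#'   the target.
#' @export
traditional_design_n <- function(event_rates, alpha = 0.025,
                                 target_power = 0.90,
                                 followup_weeks = 156, dropout_3yr = 0.05,
                                 oc = oc_config(),
                                 n_grid = seq(40L, 160L, by = 1L)) {
  if (is.unsorted(n_grid)) stop("n_grid must be sorted")
  k <- length(event_rates) - 1L
  hazard <- event_rate_to_hazard(event_rates, followup_weeks)
  crit <- dunnett_critical_value(k, alpha)
  drop_rate <- if (dropout_3yr > 0) {
    event_rate_to_hazard(dropout_3yr, followup_weeks)
  } else 0
  power_at <- function(n) {
    set.seed(oc$master_seed)
    rep_seeds <- sample.int(.Machine$integer.max - 1L, oc$n_replicates)
    hits <- logical(oc$n_replicates)
    for (r in seq_len(oc$n_replicates)) {
      set.seed(rep_seeds[r])
      arm <- rep(0:k, each = n)
      latent <- stats::rexp((k + 1L) * n, rate = 1) / hazard[arm + 1L]
      horiz <- if (drop_rate > 0) {
        pmin(stats::rexp((k + 1L) * n, drop_rate), followup_weeks)
      } else rep(followup_weeks, (k + 1L) * n)
      tt <- pmin(latent, horiz)
      ev <- as.numeric(latent <= horiz)
      zmax <- -Inf
      for (i in seq_len(k)) {
        selc <- arm == 0L | arm == i
        uv <- logrank_uv(tt[selc], ev[selc], arm[selc] == i)
        z <- if (uv$v > 0) uv$u / sqrt(uv$v) else 0
        if (z > zmax) zmax <- z
      }
      hits[r] <- zmax > crit
    }
    mean(hits)
  }
  lo <- 1L; hi <- length(n_grid)
  if (power_at(n_grid[hi]) < target_power) {
    stop("target power unreachable on the supplied grid")
  }
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (power_at(n_grid[mid]) >= target_power) hi <- mid else lo <- mid + 1L
  }
  n_grid[lo]
}

#' Familywise type-I-error scan over the global null space
#'
#' For each common event rate, all arms (control and active) are set to
#' that rate and the full adaptive pipeline (interim selection, closed
#' combination test) is simulated; the familywise error rate is the
#' fraction of replicates rejecting at least one (true) hypothesis. Each
#' rate is evaluated once and re-decided at every threshold.
#'
#' @param null_rates Vector of common 3-year event rates in (0, 1).
#' @param thresholds Sorted vector of interim thresholds.
#' @param design Template \code{\link{design_config}} (arm structure,
#'   stage sizes, weights); its event rates are replaced per scan cell.
#' @param oc An \code{\link{oc_config}}.
#' @param draws Optional posterior draws for posterior mode.
#' @return A data.frame with columns \code{null_rate}, \code{threshold},
#'   \code{fwer}, \code{mc_se}.
#' @export
type_one_error_scan <- function(null_rates, thresholds, design, oc,
                                draws = NULL) {
  if (any(null_rates <= 0 | null_rates >= 1)) {
    stop("null rates must lie in (0, 1)")
  }
  rows <- list()
  for (rate in null_rates) {
    d0 <- design_config(
      event_rates_3yr = rep(rate, design$n_arms),
      n_stage1_per_arm = design$n_stage1_per_arm,
      n_stage2_per_arm = design$n_stage2_per_arm,
      threshold_delta = design$threshold_delta,
      surrogate_maturation_weeks = design$surrogate_maturation_weeks,
      followup_weeks = design$followup_weeks,
      enrollment_rate = design$enrollment_rate,
      dropout_3yr = design$dropout_3yr,
      alpha_one_sided = design$alpha_one_sided,
      weights = design$weights,
      arm_names = design$arm_names)
    batch <- .simulate_batch(d0, oc, draws, compute_tests = TRUE)
    for (d in thresholds) {
      fw <- mean(batch$margin >= d & batch$rejected)
      rows[[length(rows) + 1L]] <-
        data.frame(null_rate = rate, threshold = d, fwer = fw,
                   mc_se = .binom_se(fw, nrow(batch)))
    }
  }
  do.call(rbind, rows)
}
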