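#' Design configuration for a two-stage adaptive dose-selection trial
#'
#' Captures every design constant of the seamless phase 2/3 design: one
#' control plus k active arms with assumed 3-year event rates, stage sample
#' sizes, the interim surrogate threshold, enrollment and follow-up
#' structure, dropout, the one-sided significance level, and the
#' inverse-normal combination weights.
#'
#' @param event_rates_3yr Numeric vector of event probabilities by 156 weeks,
#'   control first. All in (0, 1). Higher event rate means benefit: the
#'   primary endpoint is time to confirmed improvement.
#' @param n_stage1_per_arm Subjects per arm whose mature surrogate triggers
#'   the interim analysis (IA). Default 20.
#' @param n_stage2_per_arm Preplanned stage-2 subjects per continuing arm;
#'   this quota includes the pre-IA enrollees of continuing arms whose
#'   surrogate was immature at the IA. Default 124.
#' @param threshold_delta Interim selection threshold on the surrogate mean
#'   difference (best active minus control). Default 0.3. A value of
#'   \code{-Inf} forces continuation (useful for strong-control checks).
#' @param surrogate_maturation_weeks Weeks until the surrogate is observed.
#'   Default 26.
#' @param followup_weeks Per-subject administrative follow-up for the primary
#'   endpoint, in weeks. Default 156 (3 years).
#' @param enrollment_rate Subjects per week, constant. Default
#'   \code{n_arms * n_stage1_per_arm / surrogate_maturation_weeks}, which
#'   places the IA at twice the maturation time (week 52 at the defaults).
#' @param dropout_3yr Probability of dropout by 156 weeks (exponential,
#'   independent of the event process). Default 0.05.
#' @param alpha_one_sided One-sided familywise significance level.
#'   Default 0.025.
#' @param n_select Number of active arms carried forward. Only 1 is
#'   supported; the field is reserved.
#' @param weights Optional length-2 vector \code{(w1, w2)} of combination
#'   weights with \code{w1^2 + w2^2 = 1}. Default: square roots of the
#'   per-comparison information fractions,
#'   \code{w1 = sqrt(n1 / (n1 + n2))} with \code{n1 = 2 n_stage1_per_arm}
#'   and \code{n2 = 2 n_stage2_per_arm}.
#' @param arm_names Optional character names, control first.
#' @return An object of class \code{"design_config"}.
#' @examples
#' design_config()  # the default 4-arm design, Scenario 1 rates
#' @export
design_config <- function(event_rates_3yr = c(0.10, 0.15, 0.25, 0.30),
                          n_stage1_per_arm = 20L,
                          n_stage2_per_arm = 124L,
                          threshold_delta = 0.3,
                          surrogate_maturation_weeks = 26,
                          followup_weeks = 156,
                          enrollment_rate = NULL,
                          dropout_3yr = 0.05,
                          alpha_one_sided = 0.025,
                          n_select = 1L,
                          weights = NULL,
                          arm_names = NULL) {
  k <- length(event_rates_3yr) - 1L
  if (k < 1L) stop("need at least one active arm beside the control")
  if (any(event_rates_3yr <= 0 | event_rates_3yr >= 1)) {
    stop("all 3-year event rates must lie strictly in (0, 1)")
  }
  if (n_stage1_per_arm < 2L) stop("n_stage1_per_arm must be >= 2")
  if (n_stage2_per_arm < 0L) stop("n_stage2_per_arm must be >= 0")
  if (followup_weeks < surrogate_maturation_weeks) {
    stop("followup_weeks must be >= surrogate_maturation_weeks")
  }
  if (dropout_3yr < 0 || dropout_3yr >= 1) {
    stop("dropout_3yr must be in [0, 1)")
  }
  if (alpha_one_sided <= 0 || alpha_one_sided >= 1) {
    stop("alpha_one_sided must be in (0, 1)")
  }
  if (n_select != 1L) {
    stop("only n_select = 1 is supported in this engine")
  }
  n_arms <- k + 1L
  if (is.null(enrollment_rate)) {
    enrollment_rate <- n_arms * n_stage1_per_arm / surrogate_maturation_weeks
  }
  if (enrollment_rate <= 0) stop("enrollment_rate must be positive")
  if (is.null(weights)) {
    n1 <- 2 * n_stage1_per_arm
    n2 <- 2 * n_stage2_per_arm
    weights <- c(sqrt(n1 / (n1 + n2)), sqrt(n2 / (n1 + n2)))
  }
  if (length(weights) != 2L || any(weights < 0) ||
      abs(sum(weights^2) - 1) > 1e-9) {
    stop("weights must be nonnegative with w1^2 + w2^2 = 1")
  }
  if (is.null(arm_names)) {
    arm_names <- c("control", paste0("active", seq_len(k)))
  }
  structure(list(event_rates_3yr = event_rates_3yr,
                 n_arms = n_arms, n_active = k,
                 n_stage1_per_arm = as.integer(n_stage1_per_arm),
                 n_stage2_per_arm = as.integer(n_stage2_per_arm),
                 threshold_delta = threshold_delta,
                 surrogate_maturation_weeks = surrogate_maturation_weeks,
                 followup_weeks = followup_weeks,
                 enrollment_rate = enrollment_rate,
                 dropout_3yr = dropout_3yr,
                 alpha_one_sided = alpha_one_sided,
                 n_select = as.integer(n_select),
                 weights = weights,
                 arm_names = arm_names),
            class = "design_config")
}

#' @export
print.design_config <- function(x, ...) {
  cat("Adaptive two-stage design:", x$n_active, "active arms + control\n")
  cat("  3-yr event rates:", paste(x$event_rates_3yr, collapse = "/"), "\n")
  cat(sprintf("  stage 1: %d/arm, stage 2: %d/arm, threshold delta = %g\n",
              x$n_stage1_per_arm, x$n_stage2_per_arm, x$threshold_delta))
  cat(sprintf("  maturation %g wk, follow-up %g wk, %.3g subj/wk, dropout %g\n",
              x$surrogate_maturation_weeks, x$followup_weeks,
              x$enrollment_rate, x$dropout_3yr))
  cat(sprintf("  one-sided alpha %g, weights (%.4f, %.4f)\n",
              x$alpha_one_sided, x$weights[1], x$weights[2]))
  invisible(x)
}

#' Convert a 3-year event rate to a weekly exponential hazard
#'
#' Under an exponential event-time law, a cumulative event probability
#' \eqn{p} by \code{horizon_weeks} corresponds to the constant hazard
#' \eqn{\lambda = -\log(1 - p) / \mathrm{horizon}}.
#'
#' @param rate_3yr Event probability in (0, 1) by the horizon.
#' @param horizon_weeks Horizon in weeks. Default 156.
#' @return Hazard per week.
#' @examples
#' event_rate_to_hazard(0.10)  # 6.756e-04
#' @export
event_rate_to_hazard <- function(rate_3yr, horizon_weeks = 156) {
  if (any(rate_3yr <= 0 | rate_3yr >= 1)) {
    stop("rate_3yr must lie strictly in (0, 1)")
  }
  -log(1 - rate_3yr) / horizon_weeks
}

#' Simulate surrogate scores from latent event times
#'
#' Inverts the linkage model \eqn{\log T = a + bX + \epsilon}: given the
#' latent (uncensored) event time the surrogate is
#' \eqn{X = (\log T - a)/b + \epsilon'} with
#' \eqn{\epsilon' = -\epsilon/b \sim N(0, (\sigma/|b|)^2)}. No direct
#' treatment effect on the surrogate is assumed; the effect is induced
#' entirely through the event-time distribution.
#'
#' @param latent_event_week Vector of latent event times in weeks (> 0).
#' @param a,b,sigma Linkage model parameters; \code{|b|} must exceed 1e-6.
#' @return Vector of surrogate scores (uses the current RNG stream).
#' @export
simulate_surrogate <- function(latent_event_week, a, b, sigma) {
  if (abs(b) < 1e-6) {
    stop("degenerate slope: |b| < 1e-6, surrogate inversion undefined")
  }
  if (any(latent_event_week <= 0)) stop("latent event times must be > 0")
  (log(latent_event_week) - a) / b +
    stats::rnorm(length(latent_event_week), 0, sigma / abs(b))
}

#' Apply the interim selection / futility rule
#'
#' Selects the active arm with the largest observed surrogate mean when its
#' margin over the control mean reaches the threshold; otherwise declares
#' futility. Exact ties among maximal arms are broken uniformly at random.
#'
#' @param active_means Named or unnamed numeric vector of per-active-arm
#'   surrogate means at the IA.
#' @param control_mean Control-arm surrogate mean at the IA.
#' @param delta Selection threshold on the mean difference.
#' @return An object of class \code{"interim_decision"}: list with
#'   \code{selected_arms} (integer indices into \code{active_means}, empty
#'   on futility), \code{futility_stop}, and \code{observed_means}.
#' @examples
#' apply_decision_rule(c(0.2, 0.9, 0.85), control_mean = 0.5, delta = 0.3)
#' @export
apply_decision_rule <- function(active_means, control_mean, delta) {
  if (length(active_means) == 0L) stop("no active-arm means supplied")
  if (any(!is.finite(active_means)) || !is.finite(control_mean)) {
    stop("means must be finite")
  }
  best_set <- which(active_means == max(active_means))
  best <- if (length(best_set) > 1L) {
    best_set[sample.int(length(best_set), 1L)]
  } else best_set
  margin <- active_means[best] - control_mean
  futility <- margin < delta
  structure(list(selected_arms = if (futility) integer(0) else
                   as.integer(best),
                 futility_stop = futility,
                 observed_means = c(control = unname(control_mean),
                                    active_means)),
            class = "interim_decision")
}

# block-randomize n subjects over the given arm codes (permuted blocks of
# size length(arms)); returns integer arm code per subject in enrollment
# order, consuming the current RNG stream
.block_randomize <- function(n, arms) {
  k <- length(arms)
  nb <- ceiling(n / k)
  block_id <- rep(seq_len(nb), each = k)[seq_len(nb * k)]
  out <- integer(nb * k)
  out[order(block_id, stats::runif(nb * k))] <- rep(arms, nb)
  out[seq_len(n)]
}

# pre-IA state shared by simulate_trial and the OC engine. Consumes the
# current RNG stream. Returns arm codes (0 = control), enrollment weeks,
# latent event and dropout times, surrogates, the IA calendar week and the
# maturity flags.
.simulate_preia <- function(config, a, b, sigma) {
  r <- config$enrollment_rate
  mat <- config$surrogate_maturation_weeks
  n_arms <- config$n_arms
  n_mature <- n_arms * config$n_stage1_per_arm
  ia_week <- mat + n_mature / r
  n_ia <- floor(ia_week * r + 1e-9)
  hazard <- event_rate_to_hazard(config$event_rates_3yr,
                                 config$followup_weeks)
  arm <- .block_randomize(n_ia, 0:(n_arms - 1L))
  enroll <- seq_len(n_ia) / r
  latent <- stats::rexp(n_ia, rate = 1) / hazard[arm + 1L]
  dropout <- if (config$dropout_3yr > 0) {
    stats::rexp(n_ia, rate = event_rate_to_hazard(config$dropout_3yr,
                                                  config$followup_weeks))
  } else rep(Inf, n_ia)
  surrogate <- simulate_surrogate(latent, a, b, sigma)
  mature <- seq_len(n_ia) <= n_mature
  list(arm = arm, enroll = enroll, latent = latent, dropout = dropout,
       surrogate = surrogate, mature = mature, ia_week = ia_week,
       n_ia = n_ia, hazard = hazard)
}

# stage-2 enrollment for continuing arms (control + selected), topping each
# continuing arm up to n_stage1 + n_stage2 subjects. Consumes the RNG.
.simulate_stage2 <- function(config, pre, selected, a, b, sigma) {
  target <- config$n_stage1_per_arm + config$n_stage2_per_arm
  cont <- c(0L, selected)
  have <- vapply(cont, function(g) sum(pre$arm == g), integer(1))
  need <- target - have
  if (any(need < 0L)) {
    stop("stage-2 quota unreachable: continuing arms already exceed ",
         "n_stage1_per_arm + n_stage2_per_arm before the IA")
  }
  n2 <- sum(need)
  if (n2 == 0L) {
    return(list(arm = integer(0), enroll = numeric(0), latent = numeric(0),
                dropout = numeric(0), surrogate = numeric(0)))
  }
  # permuted blocks over open arms until quotas fill; tail assignments go to
  # whichever arm still needs subjects
  arm <- integer(n2)
  raw <- .block_randomize(n2 + length(cont), cont)
  left <- need; j <- 1L
  for (g in raw) {
    idx <- match(g, cont)
    if (left[idx] > 0L) {
      arm[j] <- g; left[idx] <- left[idx] - 1L; j <- j + 1L
      if (j > n2) break
    }
  }
  if (any(left > 0L)) {  # fill any remainder deterministically
    for (idx in which(left > 0L)) {
      arm[j:(j + left[idx] - 1L)] <- cont[idx]
      j <- j + left[idx]
    }
  }
  enroll <- (pre$n_ia + seq_len(n2)) / config$enrollment_rate
  latent <- stats::rexp(n2, rate = 1) / pre$hazard[arm + 1L]
  dropout <- if (config$dropout_3yr > 0) {
    stats::rexp(n2, rate = event_rate_to_hazard(config$dropout_3yr,
                                                config$followup_weeks))
  } else rep(Inf, n2)
  surrogate <- simulate_surrogate(latent, a, b, sigma)
  list(arm = arm, enroll = enroll, latent = latent, dropout = dropout,
       surrogate = surrogate)
}

# per-arm means of the mature surrogate observations at the IA
.interim_means <- function(config, pre) {
  s <- pre$surrogate[pre$mature]
  g <- pre$arm[pre$mature]
  means <- as.numeric(rowsum(s, g) / tabulate(g + 1L, config$n_arms))
  names(means) <- config$arm_names
  means
}

#' Simulate one adaptive trial end-to-end
#'
#' Enrollment is deterministic at a constant rate with permuted-block
#' randomization over all arms before the IA and over control plus the
#' selected arm after it. Each subject receives an exponential latent event
#' time from their arm's hazard, an independent exponential dropout time
#' calibrated to the 3-year dropout probability, and a surrogate score from
#' the linkage model via \code{\link{simulate_surrogate}}. The IA occurs
#' when \code{n_stage1_per_arm} subjects per arm have mature surrogate data;
#' the decision uses mature subjects only. On futility the trial stops with
#' no stage-2 enrollment; otherwise enrollment continues until each
#' continuing arm reaches its stage-1 + stage-2 quota.
#'
#' @param config A \code{\link{design_config}}.
#' @param a,b,sigma Linkage model parameters.
#' @param seed Optional integer seed (set before any draw).
#' @return An object of class \code{"trial_dataset"}: list with a
#'   \code{subjects} data.frame (id, arm, enroll_week, latent_event_week,
#'   dropout_week, surrogate, surrogate_mature_at_ia, in_analysis_set),
#'   \code{ia_calendar_week}, \code{final_calendar_week}, and the
#'   \code{decision}.
#' @export
simulate_trial <- function(config, a, b, sigma, seed = NULL) {
  stopifnot(inherits(config, "design_config"))
  if (!is.null(seed)) set.seed(seed)
  pre <- .simulate_preia(config, a, b, sigma)
  means <- .interim_means(config, pre)
  decision <- apply_decision_rule(means[-1L], means[1L],
                                  config$threshold_delta)
  if (decision$futility_stop) {
    subjects <- data.frame(
      id = seq_len(pre$n_ia), arm = pre$arm, enroll_week = pre$enroll,
      latent_event_week = pre$latent, dropout_week = pre$dropout,
      surrogate = pre$surrogate, surrogate_mature_at_ia = pre$mature,
      in_analysis_set = TRUE)
    return(structure(list(subjects = subjects,
                          ia_calendar_week = pre$ia_week,
                          final_calendar_week = pre$ia_week,
                          decision = decision, config = config),
                     class = "trial_dataset"))
  }
  sel <- decision$selected_arms
  s2 <- .simulate_stage2(config, pre, sel, a, b, sigma)
  dropped <- !(pre$arm %in% c(0L, sel))
  in_set_pre <- !(dropped & !pre$mature)
  subjects <- data.frame(
    id = seq_len(pre$n_ia + length(s2$arm)),
    arm = c(pre$arm, s2$arm),
    enroll_week = c(pre$enroll, s2$enroll),
    latent_event_week = c(pre$latent, s2$latent),
    dropout_week = c(pre$dropout, s2$dropout),
    surrogate = c(pre$surrogate, s2$surrogate),
    surrogate_mature_at_ia = c(pre$mature, rep(FALSE, length(s2$arm))),
    in_analysis_set = c(in_set_pre, rep(TRUE, length(s2$arm))))
  final_week <- max(subjects$enroll_week[subjects$in_analysis_set]) +
    config$followup_weeks
  structure(list(subjects = subjects, ia_calendar_week = pre$ia_week,
                 final_calendar_week = final_week, decision = decision,
                 config = config),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("Simulated adaptive trial:", nrow(x$subjects), "subjects,",
      "IA at week", round(x$ia_calendar_week, 1), "\n")
  if (x$decision$futility_stop) {
    cat("  stopped for futility at the IA\n")
  } else {
    cat("  selected arm:",
        x$config$arm_names[x$decision$selected_arms + 1L], "\n")
  }
  invisible(x)
}

#' Sample-size accounting for a simulated trial
#'
#' @param trial A \code{"trial_dataset"} from \code{\link{simulate_trial}}.
#' @param config The matching \code{\link{design_config}}.
#' @return A list with \code{enrolled}, \code{analysed}, \code{excluded}
#'   (pre-IA immature subjects of dropped arms), and \code{stopped}.
#' @export
sample_size_accounting <- function(trial, config = trial$config) {
  s <- trial$subjects
  enrolled <- nrow(s)
  excluded <- sum(!s$in_analysis_set)
  list(enrolled = enrolled, analysed = enrolled - excluded,
       excluded = excluded, stopped = trial$decision$futility_stop)
}

#' Write a simulated trial's subject table to CSV
#' @param trial A \code{"trial_dataset"}.
#' @param path Output path.
#' @export
write_trial_csv <- function(trial, path) {
  utils::write.csv(trial$subjects, path, row.names = FALSE)
  invisible(path)
}
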