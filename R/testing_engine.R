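#' Unstandardized log-rank statistic and its variance
#'
#' Observed-minus-expected events in the active group summed over distinct
#' event times, with the hypergeometric variance (the standard tie-corrected
#' formula). Orientation: positive \code{u} means the active arm has more
#' events; since the primary endpoint is time to confirmed improvement,
#' more events indicate benefit and large positive standardized statistics
#' favour the active arm.
#'
#' @param time Follow-up times (event or censoring), one per subject.
#' @param event Event indicators (1 = event).
#' @param group Logical (or 0/1) vector, \code{TRUE} = active arm.
#' @return An object of class \code{"logrank_stat"}: list with \code{u} and
#'   \code{v}. With no events at all, \code{(0, 0)}.
#' @examples
#' logrank_uv(c(1, 2), c(1, 0), c(TRUE, FALSE))  # u = 0.5, v = 0.25
#' @export
logrank_uv <- function(time, event, group) {
  group <- as.logical(group)
  if (!any(group) || all(group)) stop("need subjects in both groups")
  if (length(time) != length(event) || length(time) != length(group)) {
    stop("time, event, group must have equal length")
  }
  o <- order(time)
  t_s <- time[o]; e_s <- event[o]; g_s <- group[o]
  N <- length(t_s)
  first <- !duplicated(t_s)
  pos <- which(first)
  idx <- cumsum(first)
  d_tot <- as.numeric(rowsum(e_s, idx))
  d_act <- as.numeric(rowsum(e_s * g_s, idx))
  n_tot <- N - pos + 1
  n_act <- sum(g_s) - c(0, cumsum(g_s))[pos]
  keep <- d_tot > 0
  d <- d_tot[keep]; d1 <- d_act[keep]
  n <- n_tot[keep]; n1 <- n_act[keep]
  u <- sum(d1 - d * n1 / n)
  vterm <- ifelse(n > 1, d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1), 0)
  v <- sum(vterm)
  structure(list(u = u, v = v), class = "logrank_stat")
}

#' Stagewise independent-increment Z statistics
#'
#' From the interim statistic \eqn{(U_1, V_1)} and the final statistic
#' \eqn{(U_2, V_2)} on the cumulative data, forms
#' \eqn{Z_1 = U_1/\sqrt{V_1}} and the increment
#' \eqn{Z_2 = (U_2 - U_1)/\sqrt{V_2 - V_1}}, which is asymptotically
#' independent of \eqn{Z_1} by the independent-increments property of
#' log-rank scores. Degenerate stages (zero information) yield a Z of 0.
#'
#' @param interim \code{"logrank_stat"} at the interim cut.
#' @param final \code{"logrank_stat"} on the full data; must carry at least
#'   as much information (\code{final$v >= interim$v}).
#' @return An object of class \code{"stagewise_stats"}: list with
#'   \code{z1}, \code{z2}, \code{u1}, \code{v1}, \code{u2}, \code{v2}.
#' @export
stagewise_z <- function(interim, final) {
  u1 <- interim$u; v1 <- interim$v
  u2 <- final$u; v2 <- final$v
  if (v2 < v1 - 1e-9) {
    stop("information must be non-decreasing: final v < interim v")
  }
  z1 <- if (v1 > 0) u1 / sqrt(v1) else 0
  dv <- v2 - v1
  z2 <- if (dv > 1e-12) (u2 - u1) / sqrt(dv) else 0
  structure(list(z1 = z1, z2 = z2, u1 = u1, v1 = v1, u2 = u2, v2 = v2),
            class = "stagewise_stats")
}

#' Dunnett many-to-one correlation matrix
#'
#' Correlation of the k active-vs-control test statistics under equal
#' variance: \eqn{\rho_{ij} = \sqrt{n_i n_j / ((n_i + n_0)(n_j + n_0))}}.
#' With equal allocation this is equicorrelation 1/2.
#'
#' @param n_active Vector of active-arm sizes (or a single common size).
#' @param n_control Control-arm size.
#' @param k Number of comparisons when \code{n_active} is scalar.
#' @return A k x k correlation matrix.
#' @export
dunnett_correlation <- function(n_active, n_control = n_active[1],
                                k = length(n_active)) {
  if (length(n_active) == 1L) n_active <- rep(n_active, k)
  f <- sqrt(n_active / (n_active + n_control))
  R <- outer(f, f)
  diag(R) <- 1
  R
}

# P(all components of MVN(0, corr) < q), deterministic algorithms only
.mvn_lower_orthant <- function(q, corr) {
  m <- nrow(corr)
  if (m == 1L) return(stats::pnorm(q))
  alg <- if (m <= 3L) mvtnorm::TVPACK(abseps = 1e-8) else
    mvtnorm::Miwa(steps = 512)
  as.numeric(mvtnorm::pmvnorm(lower = rep(-Inf, m), upper = rep(q, m),
                              corr = corr, algorithm = alg))
}

#' One-sided Dunnett-adjusted p-value
#'
#' For the maximum of the supplied comparison statistics, the adjusted
#' p-value is \eqn{1 - P(\max_i Z_i < z_{\max})} under a zero-mean
#' multivariate normal with the given correlation.
#'
#' @param z_values Observed statistics for the comparisons in the subset.
#' @param correlation Correlation matrix (unit diagonal, PSD). Default:
#'   equicorrelation 1/2 of the matching dimension.
#' @return Adjusted p-value in [0, 1].
#' @examples
#' dunnett_adjusted_p(stats::qnorm(0.95))  # 0.05 for a single comparison
#' @export
dunnett_adjusted_p <- function(z_values, correlation = NULL) {
  m <- length(z_values)
  if (m == 0L) stop("z_values must be non-empty")
  if (is.null(correlation)) {
    correlation <- matrix(0.5, m, m); diag(correlation) <- 1
  }
  if (!is.matrix(correlation) || nrow(correlation) != m ||
      ncol(correlation) != m) {
    stop("correlation must be a ", m, " x ", m, " matrix")
  }
  if (any(abs(diag(correlation) - 1) > 1e-9)) {
    stop("correlation must have unit diagonal")
  }
  p <- 1 - .mvn_lower_orthant(max(z_values), correlation)
  min(max(p, 0), 1)
}

#' Weighted inverse-normal combination function
#'
#' \eqn{C(p_1, p_2) = 1 - \Phi[w_1 \Phi^{-1}(1 - p_1) +
#' w_2 \Phi^{-1}(1 - p_2)]} with prespecified weights satisfying
#' \eqn{w_1^2 + w_2^2 = 1}. Monotonically increasing in both arguments.
#' Inputs are clipped to \eqn{[10^{-15}, 1 - 10^{-15}]}; a weight of zero
#' removes its stage entirely (even at a boundary p-value).
#'
#' @param p1,p2 Stagewise p-values in (0, 1) (boundary values are clipped;
#'   \code{p2 = 1} with positive \code{w2} gives \code{C = 1}).
#' @param w1,w2 Nonnegative weights with \code{w1^2 + w2^2 = 1}.
#' @return Combined p-value.
#' @examples
#' inverse_normal_combination(0.05, 0.05, sqrt(0.5), sqrt(0.5))
#' @export
inverse_normal_combination <- function(p1, p2, w1, w2) {
  if (abs(w1^2 + w2^2 - 1) > 1e-9 || w1 < 0 || w2 < 0) {
    stop("weights must be nonnegative with w1^2 + w2^2 = 1")
  }
  eps <- 1e-15
  # p2 exactly 1 encodes an empty selected intersection: C = 1 when its
  # weight is positive (the limit of the formula)
  if (w2 > 0 && p2 >= 1) return(1)
  if (w1 > 0 && p1 >= 1) return(1)
  p1 <- min(max(p1, eps), 1 - eps)
  p2 <- min(max(p2, eps), 1 - eps)
  t1 <- if (w1 > 0) w1 * stats::qnorm(1 - p1) else 0
  t2 <- if (w2 > 0) w2 * stats::qnorm(1 - p2) else 0
  min(max(1 - stats::pnorm(t1 + t2), eps), 1 - eps)
}

# all non-empty subsets of 1..k as a list of integer vectors
.subsets <- function(k) {
  out <- vector("list", 2^k - 1)
  i <- 1L
  for (m in seq_len(k)) {
    cm <- utils::combn(k, m)
    for (j in seq_len(ncol(cm))) { out[[i]] <- cm[, j]; i <- i + 1L }
  }
  out
}

#' Closed testing with the weighted inverse-normal combination
#'
#' Enumerates every non-empty intersection hypothesis over the k elementary
#' comparisons. For each subset S the stage-1 p-value is the Dunnett-
#' adjusted p over the stage-1 statistics of S; the stage-2 p-value is the
#' unadjusted one-sided p of the selected arm's stage-2 increment when S
#' intersects the selected set, and 1 otherwise (the empty-selection
#' convention). An elementary hypothesis is rejected iff every subset
#' containing it has combination value below alpha. A trial stopped for
#' futility (empty selection) performs no final test and rejects nothing.
#'
#' @param stage1_z Stage-1 standardized statistics, one per comparison.
#' @param stage2_z Stage-2 increment statistic of the selected arm (scalar;
#'   ignored when \code{selected} is empty).
#' @param selected Integer index (in 1..k) of the selected arm, or
#'   \code{integer(0)} on futility.
#' @param alpha One-sided familywise level.
#' @param weights Length-2 combination weights, \code{w1^2 + w2^2 = 1}.
#' @param correlation_stage1 Correlation matrix of the k stage-1 statistics
#'   (default equicorrelation 1/2).
#' @return An object of class \code{"closed_test_result"}: list with
#'   \code{rejected} (logical per elementary hypothesis) and \code{details}
#'   (data.frame: subset, p1, p2, combined).
#' @export
closed_testing <- function(stage1_z, stage2_z, selected, alpha = 0.025,
                           weights = c(sqrt(0.5), sqrt(0.5)),
                           correlation_stage1 = NULL) {
  k <- length(stage1_z)
  if (k < 1L || k > 5L) stop("supported for 1 to 5 comparisons")
  if (length(selected) > 1L) stop("at most one selected arm is supported")
  if (length(selected) == 1L && (selected < 1L || selected > k)) {
    stop("selected arm index outside 1..k")
  }
  if (is.null(correlation_stage1)) {
    correlation_stage1 <- matrix(0.5, k, k); diag(correlation_stage1) <- 1
  }
  p2_sel <- if (length(selected) == 1L) {
    min(max(1 - stats::pnorm(stage2_z), 1e-15), 1 - 1e-15)
  } else NA_real_
  subsets <- .subsets(k)
  n_s <- length(subsets)
  p1 <- numeric(n_s); p2 <- numeric(n_s); comb <- numeric(n_s)
  lab <- character(n_s)
  for (i in seq_len(n_s)) {
    S <- subsets[[i]]
    lab[i] <- paste(S, collapse = "+")
    p1[i] <- dunnett_adjusted_p(stage1_z[S],
                                correlation_stage1[S, S, drop = FALSE])
    hit <- length(selected) == 1L && selected %in% S
    p2[i] <- if (hit) p2_sel else 1
    comb[i] <- inverse_normal_combination(p1[i], p2[i],
                                          weights[1], weights[2])
  }
  rejected <- vapply(seq_len(k), function(h) {
    all(comb[vapply(subsets, function(S) h %in% S, logical(1))] < alpha)
  }, logical(1))
  if (length(selected) == 0L) rejected[] <- FALSE
  structure(list(rejected = rejected,
                 details = data.frame(subset = lab, p1 = p1, p2 = p2,
                                      combined = comb)),
            class = "closed_test_result")
}

# fast path used in the Monte-Carlo engine: with a single selected arm only
# its hypothesis can be rejected (every other elementary hypothesis has a
# singleton subset with p2 = 1). Returns TRUE iff H_selected is rejected.
.reject_selected <- function(stage1_z, stage2_z, selected, alpha, weights) {
  k <- length(stage1_z)
  p2 <- min(max(1 - stats::pnorm(stage2_z), 1e-15), 1 - 1e-15)
  q2 <- weights[2] * stats::qnorm(1 - p2)
  others <- setdiff(seq_len(k), selected)
  for (m in 0:length(others)) {
    sets <- if (m == 0L) list(integer(0)) else {
      cm <- utils::combn(others, m); lapply(seq_len(ncol(cm)),
                                            function(j) cm[, j])
    }
    for (S0 in sets) {
      S <- c(selected, S0)
      corr <- matrix(0.5, length(S), length(S)); diag(corr) <- 1
      p1 <- 1 - .mvn_lower_orthant(max(stage1_z[S]), corr)
      p1 <- min(max(p1, 1e-15), 1 - 1e-15)
      cval <- 1 - stats::pnorm(weights[1] * stats::qnorm(1 - p1) + q2)
      if (cval >= alpha) return(FALSE)
    }
  }
  TRUE
}

#' Single-stage Dunnett test (traditional design)
#'
#' Rejects each elementary hypothesis whose Dunnett-adjusted p-value over
#' the full family is below alpha, i.e. \eqn{z_i} exceeds the one-sided
#' Dunnett critical value.
#'
#' @param z_values k comparison statistics.
#' @param alpha One-sided level.
#' @param correlation Correlation matrix (default equicorrelation 1/2).
#' @return Logical vector of rejections.
#' @export
single_stage_dunnett_test <- function(z_values, alpha = 0.025,
                                      correlation = NULL) {
  k <- length(z_values)
  if (is.null(correlation)) {
    correlation <- matrix(0.5, k, k); diag(correlation) <- 1
  }
  crit <- dunnett_critical_value(k, alpha, correlation)
  z_values > crit
}

#' One-sided Dunnett critical value
#'
#' The \eqn{1 - \alpha} quantile of the maximum of a zero-mean multivariate
#' normal with the given correlation, found by root search on the
#' deterministic orthant probability.
#'
#' @inheritParams single_stage_dunnett_test
#' @param k Number of comparisons.
#' @return Critical value c with \eqn{P(\max_i Z_i < c) = 1 - \alpha}.
#' @export
dunnett_critical_value <- function(k, alpha = 0.025, correlation = NULL) {
  if (is.null(correlation)) {
    correlation <- matrix(0.5, k, k); diag(correlation) <- 1
  }
  if (k == 1L) return(stats::qnorm(1 - alpha))
  stats::uniroot(function(c) .mvn_lower_orthant(c, correlation) -
                   (1 - alpha),
                 interval = c(0, 6), tol = 1e-8)$root
}
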