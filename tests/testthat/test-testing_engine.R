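test_that("log-rank u and v match hand computation on the 2-subject case", {
  lr <- logrank_uv(c(1, 2), c(1, 0), c(TRUE, FALSE))
  expect_equal(lr$u, 0.5)
  expect_equal(lr$v, 0.25)
})

test_that("log-rank statistic is antisymmetric under group exchange", {
  set.seed(31)
  d <- random_survival_data()
  a <- logrank_uv(d$time, d$event, d$group)
  b <- logrank_uv(d$time, d$event, !d$group)
  expect_equal(a$u, -b$u, tolerance = 1e-12)
  expect_equal(a$v, b$v, tolerance = 1e-12)
})

test_that("log-rank agrees with a naive risk-set enumeration on 500 datasets", {
  set.seed(32)
  for (i in 1:500) {
    d <- random_survival_data()
    got <- logrank_uv(d$time, d$event, d$group)
    ref <- naive_logrank_uv(d$time, d$event, d$group)
    expect_equal(got$u, ref$u, tolerance = 1e-10)
    expect_equal(got$v, ref$v, tolerance = 1e-10)
  }
})

test_that("log-rank agrees with survival::survdiff", {
  skip_if_not_installed("survival")
  set.seed(33)
  for (i in 1:20) {
    d <- random_survival_data(40)
    got <- logrank_uv(d$time, d$event, d$group)
    sd_fit <- survival::survdiff(
      survival::Surv(d$time, d$event) ~ factor(d$group))
    # survdiff orders groups FALSE, TRUE; observed - expected for TRUE
    expect_equal(got$u, unname(sd_fit$obs[2] - sd_fit$exp[2]),
                 tolerance = 1e-8)
    expect_equal(got$v, unname(sd_fit$var[2, 2]), tolerance = 1e-8)
  }
})

test_that("log-rank with no events returns (0, 0)", {
  lr <- logrank_uv(c(1, 2, 3, 4), c(0, 0, 0, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(lr$u, 0)
  expect_equal(lr$v, 0)
})

test_that("stagewise statistics follow the increment formulas", {
  s <- stagewise_z(list(u = 0.5, v = 0.25), list(u = 2.5, v = 1.25))
  expect_equal(s$z1, 1.0)
  expect_equal(s$z2, 2.0)
  # zero-information stage 1
  s0 <- stagewise_z(list(u = 0, v = 0), list(u = 2, v = 4))
  expect_equal(s0$z1, 0)
  expect_equal(s0$z2, 1)
  # degenerate increment guard
  sg <- stagewise_z(list(u = 1, v = 1), list(u = 1, v = 1))
  expect_equal(sg$z2, 0)
  expect_error(stagewise_z(list(u = 1, v = 2), list(u = 1, v = 1)),
               "non-decreasing")
})

test_that("stagewise increments are empirically uncorrelated under the null", {
  set.seed(34)
  n_rep <- 800
  z1 <- numeric(n_rep); z2 <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    n <- 500  # the increment independence is asymptotic in the arm size
    grp <- rep(c(TRUE, FALSE), n / 2)
    tt <- rexp(n, 0.05)
    # interim look censors at 15, final at 60
    uv1 <- logrank_uv(pmin(tt, 15), as.numeric(tt <= 15), grp)
    uv2 <- logrank_uv(pmin(tt, 60), as.numeric(tt <= 60), grp)
    s <- stagewise_z(uv1, uv2)
    z1[r] <- s$z1; z2[r] <- s$z2
  }
  expect_lt(abs(cor(z1, z2)), 3 / sqrt(n_rep))
})

test_that("Dunnett adjusted p reduces to the one-sided p for one comparison", {
  expect_equal(dunnett_adjusted_p(qnorm(0.95)), 0.05, tolerance = 1e-8)
})

test_that("Dunnett adjusted p matches a Monte-Carlo max-statistic oracle", {
  z <- c(1.96, 1.0, 0.5)
  got <- dunnett_adjusted_p(z)
  set.seed(35)
  n_mc <- 2e6
  zmat <- requicorr_half(n_mc, 3)
  p_mc <- mean(pmax(zmat[, 1], zmat[, 2], zmat[, 3]) >= max(z))
  expect_lt(abs(got - p_mc), 3 * sqrt(p_mc * (1 - p_mc) / n_mc))
})

test_that("Dunnett adjusted p is bounded below by the unadjusted max p", {
  set.seed(36)
  for (i in 1:20) {
    z <- rnorm(sample(2:5, 1))
    expect_gte(dunnett_adjusted_p(z) + 1e-12, 1 - pnorm(max(z)))
  }
})

test_that("the inverse-normal combination evaluates its closed form", {
  # degenerate weight keeps only stage 1
  expect_equal(inverse_normal_combination(0.07, 0.9, 1, 0), 0.07,
               tolerance = 1e-12)
  w <- sqrt(0.5)
  expect_equal(inverse_normal_combination(0.05, 0.05, w, w),
               1 - pnorm(sqrt(2) * qnorm(0.95)), tolerance = 1e-10)
  expect_error(inverse_normal_combination(0.05, 0.05, 0.5, 0.5), "w1\\^2")
})

test_that("the combination function is monotone in both arguments", {
  w1 <- sqrt(0.3); w2 <- sqrt(0.7)
  ps <- seq(0.01, 0.99, length.out = 50)
  grid <- outer(ps, ps, Vectorize(function(p1, p2) {
    inverse_normal_combination(p1, p2, w1, w2)
  }))
  expect_true(all(diff(grid) >= 0))        # rows: increasing p1
  expect_true(all(t(diff(t(grid))) >= 0))  # cols: increasing p2
})

test_that("information-fraction weights satisfy the constraint exactly", {
  for (n1 in c(1, 40, 37)) {
    for (n2 in c(1, 248, 101)) {
      w <- c(sqrt(n1 / (n1 + n2)), sqrt(n2 / (n1 + n2)))
      expect_equal(w[1]^2 + w[2]^2, 1, tolerance = 1e-15)
    }
  }
})

test_that("closed testing matches a hand enumeration for k = 3", {
  # selected arm 3 with overwhelming stage-2 evidence; moderate stage-1
  z1 <- c(0.2, -0.5, 1.0)
  z2 <- 4.5
  w <- c(sqrt(40 / 288), sqrt(248 / 288))
  res <- closed_testing(z1, z2, selected = 3L, alpha = 0.025, weights = w)
  # hand enumeration of the four intersections containing H3
  p2 <- 1 - pnorm(z2)
  subsets <- list(3L, c(1L, 3L), c(2L, 3L), c(1L, 2L, 3L))
  all_pass <- all(vapply(subsets, function(S) {
    R <- matrix(0.5, length(S), length(S)); diag(R) <- 1
    p1 <- dunnett_adjusted_p(z1[S], R)
    inverse_normal_combination(p1, p2, w[1], w[2]) < 0.025
  }, logical(1)))
  expect_true(all_pass)
  expect_true(res$rejected[3])
  # hypotheses of unselected arms carry a singleton with p2 = 1
  expect_false(res$rejected[1])
  expect_false(res$rejected[2])
  expect_equal(nrow(res$details), 7L)
  expect_equal(res$details$p2[res$details$subset == "1+2"], 1)
})

test_that("futility performs no final test and rejects nothing", {
  res <- closed_testing(c(3, 3, 3), 5, selected = integer(0))
  expect_false(any(res$rejected))
})

test_that("rejection is monotone in the stage-2 evidence", {
  z1 <- c(0.5, 0.2, 0.8)
  w <- c(sqrt(0.5), sqrt(0.5))
  res_lo <- closed_testing(z1, 2.2, 3L, weights = w)
  res_hi <- closed_testing(z1, 3.5, 3L, weights = w)
  if (res_lo$rejected[3]) expect_true(res_hi$rejected[3])
  expect_true(all(res_hi$details$combined <= res_lo$details$combined))
})

test_that("closure consonance holds structurally on random statistics", {
  set.seed(37)
  for (i in 1:40) {
    k <- sample(2:4, 1)
    sel <- sample(k, 1)
    res <- closed_testing(rnorm(k), rnorm(1, 1.5), sel)
    subsets <- surradapt:::.subsets(k)
    for (h in seq_len(k)) {
      covering <- vapply(subsets, function(S) h %in% S, logical(1))
      expect_equal(res$rejected[h],
                   all(res$details$combined[covering] < 0.025))
    }
  }
})

test_that("the fast selected-arm path agrees with full closed testing", {
  set.seed(38)
  for (i in 1:60) {
    k <- 3L
    z1 <- rnorm(k)
    z2 <- rnorm(1, 2, 1.5)
    sel <- sample(k, 1)
    w <- c(sqrt(40 / 288), sqrt(248 / 288))
    full <- closed_testing(z1, z2, sel, alpha = 0.025, weights = w)
    fast <- surradapt:::.reject_selected(z1, z2, sel, 0.025, w)
    expect_equal(fast, full$rejected[sel])
    expect_false(any(full$rejected[-sel]))
  }
})

test_that("the single-stage Dunnett test matches its critical value", {
  expect_equal(dunnett_critical_value(1, 0.025), qnorm(0.975))
  expect_true(all(single_stage_dunnett_test(rep(10, 3))))
  expect_equal(unname(single_stage_dunnett_test(c(3.0, 1.0, 0.2))),
               c(TRUE, FALSE, FALSE))
  # critical value vs Monte-Carlo 97.5th percentile of the max
  crit <- dunnett_critical_value(3, 0.025)
  set.seed(39)
  zm <- requicorr_half(2e6, 3)
  zmax <- pmax(zm[, 1], zm[, 2], zm[, 3])
  expect_lt(abs(crit - quantile(zmax, 0.975)), 0.005)
})
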