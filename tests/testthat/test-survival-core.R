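test_that("risk table reproduces classical hypergeometric bookkeeping", {
  co <- survival_cohort(c(1, 2, 3, 4), c(1, 1, 1, 1))
  rt <- build_risk_table(co, one_hot(c(0, 1, 0, 1)))
  expect_equal(rt$event_times, 1:4)
  expect_equal(rt$at_risk[1, ], c(2, 2))
  expect_equal(rt$d[1], 1)
  expect_equal(rt$observed[1, ], c(1, 0))
  expect_equal(rt$expected[1, ], c(0.5, 0.5))
})

test_that("uniform soft assignment spreads observed and expected events equally", {
  co <- rand_cohort(30, seed = 11)
  for (k in 2:4) {
    rt <- build_risk_table(co, matrix(1 / k, co$n, k))
    expect_equal(rt$observed, matrix(rt$d / k, length(rt$d), k))
    expect_equal(rt$expected, matrix(rt$d / k, length(rt$d), k))
  }
})

test_that("risk tables conserve events and at-risk mass for any assignment", {
  for (s in 1:10) {
    co <- rand_cohort(25, censor_frac = 0.4, seed = 100 + s)
    p <- rand_soft(co$n, sample(2:4, 1))
    rt <- build_risk_table(co, p)
    expect_lt(max(abs(rowSums(rt$observed) - rt$d)), 1e-9)
    expect_lt(max(abs(rowSums(rt$expected) - rt$d)), 1e-9)
    expect_lt(max(abs(rowSums(rt$at_risk) - rt$total_at_risk)), 1e-9)
    expect_true(all(rt$at_risk >= -1e-12))
    expect_true(all(diff(rt$total_at_risk) <= 1e-9))   # risk sets shrink
  }
})

test_that("risk table rejects degenerate or mismatched inputs", {
  co_noev <- survival_cohort(c(1, 2, 3), c(0, 0, 0))
  expect_error(build_risk_table(co_noev, matrix(1 / 2, 3, 2)), "degenerate")
  co <- rand_cohort(10, seed = 1)
  expect_error(build_risk_table(co, matrix(1 / 2, 9, 2)), "dimension")
})

test_that("covariance matches the direct hypergeometric evaluation", {
  # one event, two groups with one subject each at risk
  co <- survival_cohort(c(1, 1.5), c(1, 0))
  rt <- build_risk_table(co, one_hot(c(0, 1), 2))
  V <- covariance_matrix(rt)
  expect_equal(V, matrix(c(0.25, -0.25, -0.25, 0.25), 2), tolerance = 1e-12)
})

test_that("a time where one group holds all at-risk mass adds no variance", {
  co <- survival_cohort(c(1, 2, 3), c(1, 1, 1))
  # after t=2 only group 0 remains
  rt <- build_risk_table(co, one_hot(c(0, 1, 0), 2))
  V3 <- covariance_matrix(list(event_times = rt$event_times[3], d = rt$d[3],
                               at_risk = rt$at_risk[3, , drop = FALSE],
                               total_at_risk = rt$total_at_risk[3],
                               observed = rt$observed[3, , drop = FALSE],
                               expected = rt$expected[3, , drop = FALSE],
                               k = 2))
  expect_equal(V3, matrix(0, 2, 2))
})

test_that("covariance and statistic agree with the reference k-sample logrank", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(10:50, 1); k <- sample(2:3, 1)
    co <- rand_cohort(n, censor_frac = runif(1, 0, 0.5))
    g <- sample(0:(k - 1), n, replace = TRUE)
    if (length(unique(g)) < k || sum(co$event) < 2) next
    rt <- build_risk_table(co, one_hot(g, k))
    res <- multivariate_logrank(rt, ridge_eps = 0)
    expect_lt(abs(res$statistic - ref_logrank(co, g)), 1e-8)
    # V is symmetric PSD with zero row sums
    expect_equal(res$V, t(res$V))
    expect_lt(max(abs(rowSums(res$V))), 1e-8)
    expect_gt(min(eigen(res$V, only.values = TRUE)$values), -1e-10)
    expect_lt(abs(sum(res$Z)), 1e-8)
  }
})

test_that("duplicate groups and uniform assignments give a null statistic", {
  set.seed(7)
  ti <- rexp(10); ev <- rbinom(10, 1, 0.8); ev[1] <- 1
  co <- survival_cohort(c(ti, ti), c(ev, ev))
  g <- rep(c(0, 1), each = 10)
  res <- multivariate_logrank(build_risk_table(co, one_hot(g, 2)))
  expect_lt(abs(res$statistic), 1e-8)
  expect_equal(res$p_value, 1)
  co2 <- rand_cohort(20, seed = 9)
  res2 <- multivariate_logrank(build_risk_table(co2, matrix(1 / 3, 20, 3)))
  expect_lt(abs(res2$statistic), 1e-8)
})

test_that("k=2 hard-label statistic is the squared standardized two-sample score", {
  set.seed(13)
  for (rep in 1:10) {
    co <- rand_cohort(30, censor_frac = 0.3)
    g <- sample(0:1, 30, replace = TRUE)
    if (length(unique(g)) < 2) next
    rt <- build_risk_table(co, one_hot(g, 2))
    res <- multivariate_logrank(rt, 0)
    z <- res$Z[1] / sqrt(res$V[1, 1])
    expect_lt(abs(res$statistic - z^2), 1e-8)
  }
})

test_that("statistic, penalty and loss are invariant under group relabelling", {
  co <- rand_cohort(25, seed = 21)
  p <- rand_soft(25, 3, seed = 22)
  cfg <- loss_config(3, lambda_penalty = 0.7, ridge_eps = 0)
  base <- partial_logrank_loss(co, p, cfg)
  for (perm in list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1))) {
    alt <- partial_logrank_loss(co, p[, perm], cfg)
    expect_equal(as.numeric(alt), as.numeric(base), tolerance = 1e-10)
    expect_equal(attr(alt, "statistic"), attr(base, "statistic"), tolerance = 1e-10)
  }
})

test_that("balance barrier is zero at uniform, exact at hand-computed points", {
  for (k in 2:8)
    expect_lt(abs(balance_penalty(rep(1 / k, k))), 1e-12)
  # k = 2: alpha = 1, both terms 1/(0.9 - 0.81) = 1/(0.1 - 0.01) = 1/0.09
  expect_equal(balance_penalty(c(0.9, 0.1)), 1 / 0.09 - 4, tolerance = 1e-12)
  expect_lt(abs(balance_penalty(c(0.9, 0.1)) - 7.1111), 1e-3)
})

test_that("balance barrier rises monotonically and explodes near the boundary", {
  k <- 3
  eps_path <- seq(0, 0.3, by = 0.03)
  vals <- vapply(eps_path, function(e)
    balance_penalty(c(1 / k + 2 * e, 1 / k - e, 1 / k - e)), 0)
  expect_true(all(diff(vals) > 0))
  expect_gt(balance_penalty(c(1 - 1e-4, 1e-4)), 1e3)
  expect_error(balance_penalty(c(1, 0)), "domain")
})

test_that("loss reduces to the reference statistic for hard labels at lambda 0", {
  set.seed(31)
  for (rep in 1:5) {
    co <- rand_cohort(40, censor_frac = 0.3)
    g <- sample(0:2, 40, replace = TRUE)
    if (length(unique(g)) < 3) next
    cfg <- loss_config(3, lambda_penalty = 0, ridge_eps = 0)
    val <- partial_logrank_loss(co, one_hot(g, 3), cfg)
    expect_lt(abs(as.numeric(val) + ref_logrank(co, g)), 1e-8)
  }
})

test_that("batches without events raise a distinguishable degenerate condition", {
  co <- survival_cohort(c(1, 2, 3), c(0, 0, 0))
  cfg <- loss_config(2)
  expect_error(partial_logrank_loss(co, matrix(0.5, 3, 2), cfg),
               class = "logrankclust_degenerate")
})

test_that("analytic gradient matches central finite differences", {
  set.seed(77)
  worst <- 0
  for (rep in 1:6) {
    n <- 20; k <- sample(2:4, 1)
    co <- rand_cohort(n, censor_frac = 0.3)
    p <- rand_soft(n, k)
    cfg <- loss_config(k, lambda_penalty = runif(1, 0, 1), ridge_eps = 1e-6)
    G <- partial_logrank_grad(co, p, cfg)
    h <- 1e-5
    for (probe in 1:8) {
      i <- sample(n, 1); g <- sample(k, 1)
      pp <- p; pp[i, g] <- p[i, g] + h
      pm <- p; pm[i, g] <- p[i, g] - h
      fd <- (logrankclust:::partial_loss_value(co, pp, cfg) -
             logrankclust:::partial_loss_value(co, pm, cfg)) / (2 * h)
      worst <- max(worst, abs(G[i, g] - fd) / max(abs(fd), 1e-6))
    }
  }
  expect_lt(worst, 1e-4)
})
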