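test_that("cluster matching recovers identity, swaps, and brute-force optima", {
  truth <- c(0, 0, 1, 1, 2, 2)
  expect_equal(match_clusters(truth, truth, 3), 0:2)
  swapped <- c(1, 1, 0, 0, 2, 2)
  expect_equal(match_clusters(swapped, truth, 3), c(1L, 0L, 2L))
  # random fixtures: enumeration oracle over all 6 permutations
  set.seed(17)
  for (rep in 1:20) {
    pred <- sample(0:2, 40, replace = TRUE)
    tr <- sample(0:2, 40, replace = TRUE)
    perm <- match_clusters(pred, tr, 3)
    agree <- function(p) sum(p[pred + 1] == tr)
    best <- max(vapply(logrankclust:::all_permutations(3),
                       function(p) agree(p - 1L), 0))
    expect_equal(agree(perm), best)
  }
})

test_that("assignment DP equals exhaustive matching on larger k", {
  set.seed(23)
  for (rep in 1:10) {
    k <- 5
    conf <- matrix(rpois(k * k, 4), k)
    dp <- logrankclust:::assignment_dp(conf)
    perms <- logrankclust:::all_permutations(k)
    best <- max(vapply(perms, function(p) sum(conf[cbind(1:k, p)]), 0))
    expect_equal(sum(conf[cbind(1:k, dp)]), best)
  }
})

test_that("per-class AUROC/AUPRC hit their closed-form anchors", {
  truth <- c(0, 0, 1, 1, 2, 2)
  perfect <- one_hot(truth, 3) * 0.98 + 0.01
  m <- per_class_auroc_auprc(perfect, truth, 0:2)
  expect_equal(m$auroc, rep(1, 3))
  expect_equal(m$auprc, rep(1, 3))
  flat <- matrix(1 / 3, 6, 3)
  mf <- per_class_auroc_auprc(flat, truth, 0:2)
  expect_equal(mf$auroc, rep(0.5, 3))
  # an absent class is reported as missing, not dropped
  truth2 <- c(0, 0, 1, 1, 1, 1)
  m2 <- per_class_auroc_auprc(perfect, truth2, 0:2)
  expect_true(is.na(m2$auroc[3]))
})

test_that("AUROC equals exhaustive pair counting and the pROC reference", {
  score <- c(0.9, 0.8, 0.35, 0.6, 0.2, 0.1)   # one inversion
  pos <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  pairs <- expand.grid(i = which(pos), j = which(!pos))
  brute <- mean(ifelse(score[pairs$i] > score[pairs$j], 1,
                       ifelse(score[pairs$i] == score[pairs$j], 0.5, 0)))
  expect_equal(logrankclust:::auroc_score(score, pos), brute)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(pos, score, quiet = TRUE))))
  expect_equal(logrankclust:::auroc_score(score, pos), ref)
})

test_that("AUROC and AUPRC are invariant under monotone score transforms", {
  set.seed(29)
  score <- runif(50)
  pos <- runif(50) < 0.4
  for (f in list(function(s) 3 * s + 2, function(s) s^3, exp)) {
    expect_equal(logrankclust:::auroc_score(f(score), pos),
                 logrankclust:::auroc_score(score, pos))
    expect_equal(logrankclust:::auprc_score(f(score), pos),
                 logrankclust:::auprc_score(score, pos))
  }
})

test_that("concordance matches brute-force pair enumeration with censoring", {
  co <- survival_cohort(c(2, 5, 5, 3, 8, 1, 7, 4), c(1, 0, 1, 1, 0, 1, 1, 0))
  risk <- c(2, 0, 1, 1, 0, 2, 0, 1)
  expect_equal(cluster_c_index(risk, co, 0:2), brute_cindex(risk, co))
  set.seed(37)
  for (rep in 1:10) {
    con <- rand_cohort(15, censor_frac = 0.4)
    rk <- sample(0:2, 15, replace = TRUE)
    expect_equal(logrankclust:::concordance_from_risk(rk, con),
                 brute_cindex(rk, con))
  }
  # cross-check against the survival package on a no-tie fixture
  set.seed(38)
  con <- rand_cohort(40, censor_frac = 0.3)
  rk <- rnorm(40)
  ref <- survival::concordance(survival::Surv(con$time, con$event) ~ rk,
                               reverse = TRUE)$concordance
  expect_equal(logrankclust:::concordance_from_risk(rk, con), ref)
})

test_that("concordance anchors: perfect ordering, single cluster, reversal", {
  # singleton clusters whose ranks order all event times perfectly
  co1 <- survival_cohort(c(1, 2), c(1, 1))
  expect_equal(cluster_c_index(c(1, 0), co1, 0:1), 1)
  # grouped risks leave within-cluster ties at credit 1/2
  co <- survival_cohort(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(cluster_c_index(c(1, 1, 0, 0), co, 0:1), (4 + 0.5 * 2) / 6)
  expect_equal(cluster_c_index(rep(0, 4), co, 0), 0.5)
  set.seed(39)
  con <- rand_cohort(20, censor_frac = 0.2)
  rk <- sample(0:3, 20, replace = TRUE)
  c1 <- logrankclust:::concordance_from_risk(rk, con)
  c2 <- logrankclust:::concordance_from_risk(-rk, con)
  expect_equal(c1 + c2, 1)
})

test_that("risk ordering follows training Kaplan-Meier medians", {
  # disjoint time ranges: cluster 1 lives longer -> risk rank 0
  co <- survival_cohort(c(1, 2, 3, 10, 11, 12), rep(1, 6))
  lab <- c(0, 0, 0, 1, 1, 1)
  expect_equal(derive_risk_order(lab, co, 2), c(1L, 0L))
  # identical clusters: deterministic id tie-break
  co2 <- survival_cohort(rep(c(1, 2, 3), 2), rep(1, 6))
  expect_equal(derive_risk_order(c(0, 0, 0, 1, 1, 1), co2, 2), c(0L, 1L))
  # three clusters, hand-computed KM medians 2, 6, 20
  co3 <- survival_cohort(c(1, 2, 3, 5, 6, 7, 15, 20, 30), rep(1, 9))
  lab3 <- rep(0:2, each = 3)
  expect_equal(derive_risk_order(lab3, co3, 3), c(2L, 1L, 0L))
  expect_error(derive_risk_order(c(0, 0, 0), survival_cohort(1:3, rep(1, 3)), 2),
               "empty")
})

test_that("KM curve equals hand computation and the survival reference", {
  co <- survival_cohort(1:4, rep(1, 4))
  km <- km_curve(co)
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)
  allc <- survival_cohort(1:5, rep(0, 5))
  kmc <- km_curve(allc)
  expect_true(all(kmc$surv == 1))
  expect_true(is.na(kmc$median))
  # mixed fixture against survfit directly
  co2 <- survival_cohort(c(1, 2, 2, 3, 5, 6), c(1, 0, 1, 1, 0, 1))
  km2 <- km_curve(co2)
  fit <- survival::survfit(survival::Surv(co2$time, co2$event) ~ 1)
  expect_equal(km2$surv[km2$time %in% fit$time], fit$surv, tolerance = 1e-10)
  # no censoring: KM equals the empirical survival function
  co3 <- rand_cohort(30, censor_frac = 0, seed = 3)
  km3 <- km_curve(co3)
  emp <- 1 - ecdf(co3$time)(km3$time)
  expect_equal(km3$surv, emp, tolerance = 1e-10)
})

test_that("bootstrap c-index is seeded, covers its point estimate, and degenerates to width zero", {
  co <- rand_cohort(60, censor_frac = 0.3, seed = 43)
  risk <- as.numeric(co$time < median(co$time))
  b1 <- bootstrap_cindex(risk, co, n_boot = 300, seed = 11)
  b2 <- bootstrap_cindex(risk, co, n_boot = 300, seed = 11)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$ci[1] <= b1$median && b1$median <= b1$ci[2])
  # constant c-index: all subjects one group, ties everywhere -> CI width 0
  bd <- bootstrap_cindex(rep(0, 60), co, n_boot = 150, seed = 12)
  expect_equal(unname(diff(bd$ci)), 0)
  expect_equal(bd$median, 0.5)
})

test_that("paired bootstrap self-comparison is exactly indifferent", {
  co <- rand_cohort(80, censor_frac = 0.3, seed = 47)
  risk <- rnorm(80)
  cmp <- paired_bootstrap_pvalue(risk, risk, co, n_boot = 300, seed = 13)
  expect_equal(cmp$p_one_sided, 0.5)
  expect_equal(cmp$delta_median, 0)
  # a strictly dominant model reports p below bootstrap resolution
  risk_good <- rank(co$time) * -1
  cmp2 <- paired_bootstrap_pvalue(risk_good, rnorm(80), co,
                                  n_boot = 200, seed = 14)
  expect_lte(cmp2$p_one_sided, 1 / 200 + 0.05)
  expect_error(paired_bootstrap_pvalue(risk[1:10], risk, co, 200, 1),
               "same subjects")
})

test_that("evaluation report assembles matched metrics and survival summaries", {
  spec <- synthetic_spec(n_subjects = 200, seed = 53)
  sim <- simulate_tabular_cohort(spec)
  # synthetic 'cv' whose assignments are noisy versions of the truth
  set.seed(54)
  probs <- one_hot(sim$labels, 3) * 0.8 + 0.2 / 3 +
    matrix(runif(600, 0, 0.05), 200, 3)
  probs <- probs / rowSums(probs)
  cv <- list(assignments = probs, fold = rep(1:5, 40))
  rep <- evaluate_clustering(cv, sim$cohort, sim$labels,
                             horizons = c(0.5, 1), n_boot = 200, seed = 15)
  expect_true(all(rep$auroc_per_class > 0.9))
  expect_true(all(rep$auroc_per_class <= 1))
  expect_equal(sort(rep$permutation), 0:2)
  expect_true(rep$c_index > 0.5 && rep$c_index <= 1)
  expect_lt(rep$logrank_p, 0.01)
  expect_equal(length(rep$km_summaries), 3)
})
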