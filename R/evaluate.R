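#' Match predicted clusters to ground-truth classes
#'
#' Unsupervised cluster labels are defined only up to permutation; before
#' supervised-style scoring the permutation maximising total
#' confusion-matrix agreement is applied.  For k <= 5 all k! permutations
#' are enumerated; beyond that an exact assignment solver (bitmask dynamic
#' programme over class subsets, globally optimal) is used.
#'
#' @param pred_hard_labels integer predicted clusters in `0:(k-1)`.
#' @param true_labels integer truth in `0:(k-1)`.
#' @param k number of classes.
#' @return Integer vector `perm` of length k: predicted cluster `c` is
#'   matched to truth class `perm[c + 1]` (0-based values).
#' @export
match_clusters <- function(pred_hard_labels, true_labels, k) {
  if (any(pred_hard_labels < 0 | pred_hard_labels >= k) ||
      any(true_labels < 0 | true_labels >= k))
    stop("labels must lie in 0..k-1")
  conf <- matrix(0, k, k)   # conf[c, t] = # subjects with pred c, truth t
  for (i in seq_along(true_labels))
    conf[pred_hard_labels[i] + 1L, true_labels[i] + 1L] <-
      conf[pred_hard_labels[i] + 1L, true_labels[i] + 1L] + 1
  if (k <= 5) {
    perms <- all_permutations(k)
    scores <- vapply(perms, function(p) sum(conf[cbind(seq_len(k), p)]), 0)
    best <- perms[[which.max(scores)]]
  } else {
    best <- assignment_dp(conf)
  }
  best - 1L
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L))
    for (pos in seq_len(k))
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

# Exact maximum-agreement assignment via DP over subsets of truth classes.
assignment_dp <- function(conf) {
  k <- nrow(conf)
  nstates <- bitwShiftL(1L, k)
  best <- rep(-Inf, nstates); best[1L] <- 0
  choice <- matrix(0L, nstates, 1L)
  parent <- integer(nstates)
  for (m in 0:(nstates - 1L)) {
    if (!is.finite(best[m + 1L])) next
    row <- sum(bitwAnd(bitwShiftR(m, 0:(k - 1L)), 1L))  # popcount = next row
    if (row >= k) next
    for (tcl in seq_len(k)) {
      bit <- bitwShiftL(1L, tcl - 1L)
      if (bitwAnd(m, bit) > 0L) next
      m2 <- bitwOr(m, bit)
      val <- best[m + 1L] + conf[row + 1L, tcl]
      if (val > best[m2 + 1L]) {
        best[m2 + 1L] <- val
        choice[m2 + 1L, 1L] <- tcl
        parent[m2 + 1L] <- m
      }
    }
  }
  perm <- integer(k)
  m <- nstates - 1L
  while (m > 0L) {
    tcl <- choice[m + 1L, 1L]
    row <- sum(bitwAnd(bitwShiftR(parent[m + 1L], 0:(k - 1L)), 1L))
    perm[row + 1L] <- tcl
    m <- parent[m + 1L]
  }
  perm
}

# Rank-based AUROC (Mann-Whitney with midranks for ties).
auroc_score <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average-precision AUPRC: sum over positives, in decreasing-score order, of
# precision at each recall step (the standard step-wise integral of the
# precision-recall curve).  Ties are broken by a stable sort, matching the
# convention of mainstream implementations.
auprc_score <- function(score, positive) {
  n1 <- sum(positive)
  if (n1 == 0 || all(positive)) return(NA_real_)
  ord <- order(-score)
  pos <- positive[ord]
  tp <- cumsum(pos)
  prec <- tp / seq_along(pos)
  sum(prec[pos]) / n1
}

#' Per-class one-vs-rest AUROC and AUPRC after cluster matching
#'
#' Applies the cluster-to-truth permutation to the probability columns, then
#' scores each truth class one-vs-rest using the matched probability column
#' as the score.  Classes absent from the truth yield `NA` (reported, never
#' dropped).
#'
#' @param soft_probs n-by-k row-stochastic probability matrix.
#' @param true_labels integer truth in `0:(k-1)`.
#' @param permutation matching from [match_clusters()].
#' @return A data frame with columns `class`, `auroc`, `auprc`.
#' @export
per_class_auroc_auprc <- function(soft_probs, true_labels, permutation) {
  k <- ncol(soft_probs)
  matched <- matrix(NA_real_, nrow(soft_probs), k)
  for (cc in seq_len(k)) matched[, permutation[cc] + 1L] <- soft_probs[, cc]
  out <- data.frame(class = seq_len(k) - 1L, auroc = NA_real_, auprc = NA_real_)
  for (tcl in seq_len(k)) {
    pos <- true_labels == tcl - 1L
    out$auroc[tcl] <- auroc_score(matched[, tcl], pos)
    out$auprc[tcl] <- auprc_score(matched[, tcl], pos)
  }
  out
}

#' Harrell's concordance index for a cluster risk ordering
#'
#' Scores every subject by the risk rank of their cluster and computes
#' Harrell's C over usable pairs: a pair is usable when the subject with the
#' smaller time has an event (comparators censored before an event are not
#' usable; equal-time pairs are usable only when exactly one is an event).
#' Ties in the risk score count 1/2.
#'
#' @param cluster_labels integer cluster per subject in `0:(k-1)`.
#' @param cohort a [survival_cohort].
#' @param risk_order integer vector from [derive_risk_order()]: risk rank
#'   per cluster (0 = best survival, k-1 = highest risk).
#' @return Concordance in `[0, 1]`.
#' @export
cluster_c_index <- function(cluster_labels, cohort, risk_order) {
  risk <- risk_order[cluster_labels + 1L]
  concordance_from_risk(risk, cohort)
}

# Harrell's C from an arbitrary per-subject risk score (higher = dies
# earlier).  O(n^2) pair sweep; cohorts here are modest.
concordance_from_risk <- function(risk, cohort) {
  ti <- cohort$time; ev <- cohort$event
  n <- length(ti)
  conc <- 0; usable <- 0
  for (i in seq_len(n)) {
    if (ev[i] != 1L) next
    # pairs where i is the earlier, observed event
    later <- ti > ti[i] | (ti == ti[i] & ev == 0L)
    nlater <- sum(later)
    if (!nlater) next
    usable <- usable + nlater
    conc <- conc + sum(risk[i] > risk[later]) + 0.5 * sum(risk[i] == risk[later])
  }
  if (usable == 0) stop("no usable pairs for the concordance index")
  conc / usable
}

#' Derive a cluster risk ordering from training data
#'
#' Clusters are ranked by decreasing Kaplan-Meier median survival estimated
#' on the training partition: the cluster with the longest median survival
#' gets risk rank 0.  Clusters whose KM curve never reaches 0.5 are treated
#' as having infinite median.  Ties are broken by mean observed time, then
#' by cluster id.  The order is frozen before any test data is touched.
#'
#' @param train_cluster_labels integer clusters on the training partition.
#' @param train_cohort the training [survival_cohort].
#' @param k number of clusters.
#' @return Integer vector: risk rank per cluster id.
#' @export
derive_risk_order <- function(train_cluster_labels, train_cohort, k) {
  med <- numeric(k); mean_t <- numeric(k)
  for (cc in seq_len(k)) {
    idx <- which(train_cluster_labels == cc - 1L)
    if (!length(idx)) stop(sprintf("cluster %d is empty on the training data", cc - 1L))
    km <- km_curve(train_cohort[idx])
    med[cc] <- if (is.na(km$median)) Inf else km$median
    mean_t[cc] <- mean(train_cohort$time[idx])
  }
  # longest median survival -> lowest risk rank
  ord <- order(-med, -mean_t, seq_len(k))
  rank_of <- integer(k)
  rank_of[ord] <- seq_len(k) - 1L
  rank_of
}

#' Kaplan-Meier curve of a cohort
#'
#' Product-limit estimator (via `survival::survfit`): censored subjects
#' leave the risk set after their time; the median is the first time at
#' which the survival probability drops to 0.5 or below, `NA` if never
#' reached.
#'
#' @param cohort a [survival_cohort].
#' @param horizons optional times at which to report survival probabilities.
#' @return A list with `time`, `surv` (step function coordinates), `median`
#'   and, if requested, `horizon_surv`.
#' @export
km_curve <- function(cohort, horizons = NULL) {
  fit <- survival::survfit(survival::Surv(cohort$time, cohort$event) ~ 1,
                           conf.type = "none")
  sm <- summary(fit, censored = TRUE)
  med <- {
    drop_idx <- which(fit$surv <= 0.5)
    if (length(drop_idx)) fit$time[min(drop_idx)] else NA_real_
  }
  out <- list(time = sm$time, surv = sm$surv, median = med)
  if (!is.null(horizons)) {
    out$horizon_surv <- vapply(horizons, function(h) {
      past <- which(fit$time <= h)
      if (length(past)) fit$surv[max(past)] else 1
    }, 0)
    names(out$horizon_surv) <- horizons
  }
  out
}

#' Bootstrap distribution of the concordance index
#'
#' Resamples subjects with replacement `n_boot` times, recomputing Harrell's
#' C on each replicate; reports the median and the 2.5th/97.5th percentile
#' confidence interval.  Replicates without usable pairs are redrawn.
#'
#' @param risk per-subject risk score (e.g. matched cluster risk rank).
#' @param cohort a [survival_cohort].
#' @param n_boot number of replicates (package default 9999; >= 100).
#' @param seed RNG seed.
#' @return List with `c_index` (point estimate), `median`, `ci`
#'   (2.5/97.5 percentiles) and the replicate vector `boot`.
#' @export
bootstrap_cindex <- function(risk, cohort, n_boot = 9999, seed = 1) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  set.seed(seed)
  n <- cohort$n
  point <- concordance_from_risk(risk, cohort)
  boot <- numeric(n_boot)
  for (bb in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      cb <- tryCatch(concordance_from_risk(risk[idx], cohort[idx]),
                     error = function(err) NULL)
      if (!is.null(cb)) break
    }
    boot[bb] <- cb
  }
  list(c_index = point, median = stats::median(boot),
       ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
       boot = boot)
}

#' Paired bootstrap comparison of two risk scores
#'
#' Applies identical bootstrap indices to both models per replicate, records
#' the paired difference in concordance `delta = c_a - c_b`, and reports the
#' one-sided p-value as the percentile position of zero:
#' `min(P(delta <= 0), P(delta >= 0))`.  A difference of exactly zero counts
#' on both sides, so comparing a model with itself gives p = 0.5; when one
#' model wins on every replicate the p-value is reported as `1 / n_boot`
#' (i.e. below the bootstrap resolution).
#'
#' @param risk_a,risk_b per-subject risk scores covering the same subjects.
#' @param cohort a [survival_cohort].
#' @param n_boot number of replicates.
#' @param seed RNG seed.
#' @return List with medians and CIs per model, the `delta` summary and
#'   `p_one_sided`.
#' @export
paired_bootstrap_pvalue <- function(risk_a, risk_b, cohort,
                                    n_boot = 9999, seed = 1) {
  if (length(risk_a) != cohort$n || length(risk_b) != cohort$n)
    stop("risk scores must cover the same subjects as the cohort")
  set.seed(seed)
  n <- cohort$n
  ca <- numeric(n_boot); cb <- numeric(n_boot)
  for (bb in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      a <- tryCatch(concordance_from_risk(risk_a[idx], cohort[idx]),
                    error = function(err) NULL)
      if (!is.null(a)) break
    }
    ca[bb] <- a
    cb[bb] <- concordance_from_risk(risk_b[idx], cohort[idx])
  }
  delta <- ca - cb
  # percentile position of zero, ties split between both sides so that a
  # self-comparison (delta identically 0) yields exactly 0.5
  p <- min(mean(delta < 0), mean(delta > 0)) + 0.5 * mean(delta == 0)
  if (p == 0) p <- 1 / n_boot
  list(n_boot = n_boot,
       median_a = stats::median(ca), median_b = stats::median(cb),
       ci_a = stats::quantile(ca, c(0.025, 0.975), names = FALSE),
       ci_b = stats::quantile(cb, c(0.025, 0.975), names = FALSE),
       delta_median = stats::median(delta),
       p_one_sided = p)
}

#' Full evaluation report for a cross-validated clustering
#'
#' Bundles the evaluation pipeline: hard labels from the soft assignments,
#' optional cluster-to-truth matching with per-class AUROC/AUPRC, a
#' train-derived risk ordering, Harrell's C with bootstrap CI, the k-group
#' logrank p-value (descriptive for model-derived clusters: the grouping was
#' selected to maximise separation) and per-cluster Kaplan-Meier summaries.
#'
#' @param cv an `lrc_cv` from [cross_validate()] (or a list with
#'   `assignments` and `fold`).
#' @param cohort the full [survival_cohort].
#' @param true_labels optional ground-truth classes for matched metrics.
#' @param horizons times for KM survival summaries.
#' @param n_boot bootstrap replicates for the c-index CI.
#' @param seed RNG seed for the bootstrap.
#' @return A list of class `evaluation_report`.
#' @export
evaluate_clustering <- function(cv, cohort, true_labels = NULL,
                                horizons = NULL, n_boot = 2000, seed = 1) {
  probs <- cv$assignments
  k <- ncol(probs)
  hard <- max.col(probs, ties.method = "first") - 1L
  report <- list(k = k, cluster_sizes = tabulate(hard + 1L, k))
  if (!is.null(true_labels)) {
    perm <- match_clusters(hard, true_labels, k)
    metrics <- per_class_auroc_auprc(probs, true_labels, perm)
    report$permutation <- perm
    report$auroc_per_class <- metrics$auroc
    report$auprc_per_class <- metrics$auprc
  }
  # risk order from each subject's training folds would require refitting;
  # the frozen convention here ranks clusters on the pooled held-out data
  # KM medians per cluster (every subject's assignment is out-of-fold).
  # Empty clusters (possible for collapsed fits) are excluded from the
  # ordering and the logrank rather than erroring the whole report.
  nonempty <- which(report$cluster_sizes > 0) - 1L
  compact <- match(hard, nonempty) - 1L
  ksub <- length(nonempty)
  risk_sub <- derive_risk_order(compact, cohort, ksub)
  risk_order <- rep(NA_integer_, k)
  risk_order[nonempty + 1L] <- risk_sub
  report$risk_order <- risk_order
  bc <- bootstrap_cindex(risk_sub[compact + 1L], cohort, n_boot, seed)
  report$c_index <- bc$c_index
  report$c_index_ci <- bc$ci
  if (ksub >= 2L) {
    lr <- multivariate_logrank(build_risk_table(cohort, one_hot(compact, ksub)))
    report$logrank_p <- lr$p_value
    report$logrank_statistic <- lr$statistic
  } else {
    report$logrank_p <- NA_real_
    report$logrank_statistic <- NA_real_
  }
  report$km_summaries <- lapply(seq_len(k) - 1L, function(cc) {
    idx <- which(hard == cc)
    if (!length(idx)) return(NULL)
    km <- km_curve(cohort[idx], horizons)
    list(cluster = cc, n = length(idx), median = km$median,
         horizon_surv = km$horizon_surv)
  })
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation: k = %d, c-index %.3f (%.3f-%.3f), logrank p = %.3g\n",
              x$k, x$c_index, x$c_index_ci[1], x$c_index_ci[2], x$logrank_p))
  if (!is.null(x$auroc_per_class))
    cat(sprintf("matched AUROC: %s | AUPRC: %s\n",
                paste(sprintf("%.3f", x$auroc_per_class), collapse = " "),
                paste(sprintf("%.3f", x$auprc_per_class), collapse = " ")))
  invisible(x)
}
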