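#' Loss configuration for the partial multivariate logrank objective
#'
#' Bundles the group count `k`, the balance-penalty weight `lambda_penalty`,
#' the barrier exponent (a pure function of `k`) and the ridge added to the
#' reduced covariance block during training.
#'
#' The barrier exponent is `alpha = log(1/2) / log(1/k)`, chosen so that the
#' uniform proportion `1/k` is mapped to `1/2`, the minimum of the barrier
#' integrand, making the penalty exactly zero at balanced assignments.
#'
#' @param k number of groups (>= 2).
#' @param lambda_penalty nonnegative penalty weight (default 0).
#' @param ridge_eps nonnegative ridge added to the reduced covariance block
#'   before inversion; use 0 for exact agreement with the classical statistic
#'   and a small positive value (e.g. 1e-6) during network training.
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(k, lambda_penalty = 0, ridge_eps = 0) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (lambda_penalty < 0) stop("lambda_penalty must be >= 0")
  if (ridge_eps < 0) stop("ridge_eps must be >= 0")
  structure(list(k = k,
                 lambda_penalty = lambda_penalty,
                 alpha_exponent = log(1 / 2) / log(1 / k),
                 ridge_eps = ridge_eps),
            class = "loss_config")
}

# Per-event-time multiplier of the hypergeometric covariance term,
# d_j (N_j - d_j) / (N_j - 1).  For a single event (d_j = 1) this ratio is
# identically 1 for every N_j != 1, so its continuous extension (= 1) is used
# at N_j = 1 as well, keeping the relaxed soft-assignment functional smooth;
# with hard labels the N_j = 1 term is structurally zero either way.  Tied
# events imply N_j >= d_j >= 2, where the formula is regular; the undefined
# combination (N_j <= 1 with d_j > 1) cannot arise and contributes zero.
hyper_factor <- function(d, N) {
  ifelse(d == 1, 1, ifelse(N > 1, d * (N - d) / (N - 1), 0))
}

# Shared per-cohort bookkeeping: unique event times, at-risk and event
# incidence matrices.  s[i, j] = 1 iff subject i is still at risk at t_j
# (T_i >= t_j: subjects censored exactly at t_j remain in the risk set);
# e[i, j] = 1 iff subject i experiences the event at t_j.
risk_structure <- function(cohort) {
  check_has_events(cohort)
  t_ev <- sort(unique(cohort$time[cohort$event == 1L]))
  s <- outer(cohort$time, t_ev, ">=") * 1
  e <- outer(cohort$time, t_ev, "==") * cohort$event
  list(event_times = t_ev, s = s, e = e, d = colSums(e))
}

#' Build the per-event-time risk table for a (soft) group assignment
#'
#' For each unique event time `t_j` computes the number of events `d_j`, the
#' (probability-weighted) group-wise at-risk masses `R_g(t_j)`, the observed
#' group events `O_{g,j}` (a probability-weighted sum over subjects failing
#' at `t_j`) and the expected events `E_{g,j} = d_j R_g(t_j) / |R(t_j)|`.
#' With one-hot assignment rows this reduces to the classical k-sample
#' logrank bookkeeping.
#'
#' @param cohort a [survival_cohort] with at least one event.
#' @param assignment n-by-k row-stochastic matrix of group probabilities.
#' @return An object of class `risk_table`: a list with `event_times`, `d`,
#'   `at_risk` (J-by-k), `total_at_risk`, `observed`, `expected` and `k`.
#' @examples
#' co <- survival_cohort(1:4, rep(1, 4))
#' rt <- build_risk_table(co, one_hot(c(0, 1, 0, 1)))
#' rt$at_risk[1, ]   # both groups fully at risk at the first event time
#' @export
build_risk_table <- function(cohort, assignment) {
  assignment <- as.matrix(assignment)
  if (nrow(assignment) != cohort$n)
    stop(sprintf("dimension error: assignment has %d rows but cohort has %d subjects",
                 nrow(assignment), cohort$n))
  soft_assignment(assignment)
  rs <- risk_structure(cohort)
  at_risk <- crossprod(rs$s, assignment)          # J x k
  observed <- crossprod(rs$e, assignment)         # J x k
  total <- rowSums(at_risk)
  expected <- at_risk * (rs$d / total)
  structure(list(event_times = rs$event_times, d = rs$d,
                 at_risk = at_risk, total_at_risk = total,
                 observed = observed, expected = expected,
                 k = ncol(assignment)),
            class = "risk_table")
}

#' @export
print.risk_table <- function(x, ...) {
  cat(sprintf("Risk table: %d event times, %d events, k = %d groups\n",
              length(x$event_times), sum(x$d), x$k))
  invisible(x)
}

#' Hypergeometric variance-covariance matrix of the logrank score
#'
#' Sums, over event times, the conditional (hypergeometric) covariance of the
#' allocation of the `d_j` events across groups given the at-risk margins:
#' `V = sum_j d_j (N_j - d_j) / (N_j - 1) * (diag(r_j) - r_j r_j')` with
#' `r_j = R(t_j) / N_j`.  Event times with `N_j <= 1` contribute zero (the
#' conditional variance is undefined there and the classical statistic drops
#' them).
#'
#' @param table a `risk_table` from [build_risk_table()].
#' @return A symmetric positive semidefinite k-by-k matrix with zero row sums.
#' @export
covariance_matrix <- function(table) {
  N <- table$total_at_risk
  d <- table$d
  r <- table$at_risk / N
  cj <- hyper_factor(d, N)
  V <- diag(colSums(cj * r), table$k) - crossprod(r, cj * r)
  (V + t(V)) / 2
}

#' Partial multivariate logrank statistic
#'
#' Computes `Z_g = sum_j (O_{g,j} - E_{g,j})` and the quadratic-form
#' statistic `L = Z' V^- Z`.  Because row-stochastic assignments force the
#' rows of `V` (and the entries of `Z`) to sum to zero, the full system is
#' rank k-1; the statistic is evaluated on the leading (k-1)-dimensional
#' block, optionally ridge-regularised, and referred to a chi-square
#' distribution on k-1 degrees of freedom.  With one-hot assignments this is
#' the classical k-sample logrank test; with soft assignments the p-value is
#' descriptive (the sampling distribution is no longer exact chi-square).
#'
#' @param table a `risk_table`.
#' @param ridge_eps nonnegative ridge added to the reduced covariance block.
#' @return An object of class `logrank_result`: list with `Z`, `V`,
#'   `statistic`, `dof`, `p_value`.
#' @export
multivariate_logrank <- function(table, ridge_eps = 0) {
  k <- table$k
  if (k < 2L) stop("k must be >= 2")
  Z <- colSums(table$observed - table$expected)
  V <- covariance_matrix(table)
  idx <- seq_len(k - 1L)
  Vr <- V[idx, idx, drop = FALSE] + diag(ridge_eps, k - 1L)
  sol <- tryCatch(solve(Vr, Z[idx]), error = function(err) NULL)
  if (is.null(sol) || !all(is.finite(sol)))
    stop("conditioning error: reduced covariance block is numerically singular; increase ridge_eps")
  statistic <- max(0, sum(Z[idx] * sol))
  structure(list(Z = Z, V = V, statistic = statistic, dof = k - 1L,
                 p_value = stats::pchisq(statistic, df = k - 1L,
                                         lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Multivariate logrank: chisq = %.4f on %d df, p = %.3g\n",
              x$statistic, x$dof, x$p_value))
  invisible(x)
}

#' Asymmetric balance barrier on mean assignment proportions
#'
#' `P(p) = (1/k) * sum_g 1 / (p_g^a - (p_g^a)^2) - 4` with
#' `a = log(1/2)/log(1/k)`.  The exponent maps the uniform proportion `1/k`
#' to `1/2`, the minimum of `x -> 1/(x - x^2)`, so the barrier is exactly 0
#' at balanced proportions and diverges as any proportion approaches 0 or 1,
#' preventing cluster collapse when subtracted (with weight lambda) from the
#' logrank objective.
#'
#' @param mean_probs length-k vector of mean assignment proportions, each in
#'   the open interval (0, 1), summing to 1.  Callers must clamp first; see
#'   [partial_logrank_loss()].
#' @param k number of groups (defaults to `length(mean_probs)`).
#' @return Nonnegative scalar penalty.
#' @examples
#' balance_penalty(c(0.5, 0.5))        # 0
#' balance_penalty(c(0.9, 0.1))        # approx. 7.111
#' @export
balance_penalty <- function(mean_probs, k = length(mean_probs)) {
  if (length(mean_probs) != k) stop("mean_probs must have length k")
  if (any(mean_probs <= 0) || any(mean_probs >= 1))
    stop("domain error: mean proportions must lie strictly inside (0, 1); clamp before calling")
  if (abs(sum(mean_probs) - 1) > 1e-9)
    stop("mean proportions must sum to 1")
  barrier_value(mean_probs, k)
}

# Separable barrier, no simplex validation: also evaluated at perturbed
# (non-simplex) points during finite-difference gradient checks.
barrier_value <- function(p, k) {
  alpha <- log(1 / 2) / log(1 / k)
  y <- p^alpha
  sum(1 / (y - y^2)) / k - 4
}

# Clamp bound applied to mean proportions before the barrier only (never
# before the statistic): keeps the barrier finite at degenerate assignments.
PENALTY_CLAMP <- 1e-7

# Relaxed objective evaluated at an arbitrary nonnegative assignment matrix
# (no row-sum validation): the functional the analytic gradient
# differentiates.  d_j is the data-side event count, independent of P.
partial_loss_value <- function(cohort, probs, config) {
  rs <- risk_structure(cohort)
  eval_partial_loss(rs, probs, config)$loss
}

eval_partial_loss <- function(rs, probs, config) {
  k <- config$k
  at_risk <- crossprod(rs$s, probs)
  observed <- crossprod(rs$e, probs)
  N <- rowSums(at_risk)
  d <- rs$d
  expected <- at_risk * (d / N)
  Z <- colSums(observed - expected)
  r <- at_risk / N
  cj <- hyper_factor(d, N)
  V <- diag(colSums(cj * r), k) - crossprod(r, cj * r)
  idx <- seq_len(k - 1L)
  Vr <- V[idx, idx, drop = FALSE] + diag(config$ridge_eps, k - 1L)
  w <- tryCatch(solve(Vr, Z[idx]), error = function(err) NULL)
  if (is.null(w) || !all(is.finite(w)))
    stop("conditioning error: reduced covariance block is numerically singular; increase ridge_eps")
  L <- sum(Z[idx] * w)
  pbar <- pmin(pmax(colMeans(probs), PENALTY_CLAMP), 1 - PENALTY_CLAMP)
  pen <- barrier_value(pbar, k)
  list(loss = -L + config$lambda_penalty * pen,
       statistic = L, penalty = pen,
       w = w, Z = Z, r = r, N = N, d = d, cj = cj)
}

#' Partial multivariate logrank training loss
#'
#' The minimisation-form objective `-L + lambda * P(pbar)`, where `L` is the
#' partial multivariate logrank statistic of the soft assignment and `P` the
#' balance barrier evaluated at the column means `pbar` of the assignment
#' over the batch.  Minimising it drives assignments toward maximal survival
#' heterogeneity while the barrier keeps group proportions away from
#' collapse.  Mean proportions are clamped to `[1e-7, 1 - 1e-7]` before the
#' barrier only; the statistic is never clamped.
#'
#' @param cohort a [survival_cohort]; must contain at least one event
#'   (a batch without events raises a condition of class
#'   `logrankclust_degenerate`, distinguishable from numeric failure).
#' @param assignment n-by-k matrix of assignment probabilities
#'   (row-stochastic when `validate = TRUE`).
#' @param config a [loss_config()].
#' @param validate validate row-stochasticity (default TRUE).  With
#'   `validate = FALSE` the relaxed functional is evaluated at an arbitrary
#'   nonnegative matrix — the function the analytic gradient
#'   [partial_logrank_grad()] differentiates, used for finite-difference
#'   verification.
#' @return Scalar loss with attributes `statistic` (the partial logrank
#'   statistic) and `penalty` (the barrier value).
#' @export
partial_logrank_loss <- function(cohort, assignment, config, validate = TRUE) {
  assignment <- as.matrix(assignment)
  if (ncol(assignment) != config$k)
    stop("assignment column count must equal config$k")
  if (nrow(assignment) != cohort$n)
    stop("dimension error: assignment rows must equal cohort size")
  if (validate) soft_assignment(assignment)
  if (n_events(cohort) < 1L)
    stop(structure(class = c("logrankclust_degenerate", "error", "condition"),
                   list(message = "degenerate batch: no observed events",
                        call = sys.call())))
  ev <- eval_partial_loss(risk_structure(cohort), assignment, config)
  structure(ev$loss, statistic = ev$statistic, penalty = ev$penalty)
}

#' Exact gradient of the partial logrank loss
#'
#' Analytic gradient of [partial_logrank_loss()] (the relaxed functional,
#' `validate = FALSE`) with respect to every assignment probability.
#' Differentiates through the observed events, the probability-weighted
#' at-risk masses (including the total `N_j`), the hypergeometric covariance
#' and the ridge-regularised quadratic form, plus the clamped balance
#' barrier.  Agreement with central finite differences is part of the test
#' contract.
#'
#' @inheritParams partial_logrank_loss
#' @return n-by-k matrix `d loss / d p_{ig}`.
#' @export
partial_logrank_grad <- function(cohort, assignment, config) {
  probs <- as.matrix(assignment)
  if (ncol(probs) != config$k) stop("assignment column count must equal config$k")
  if (nrow(probs) != cohort$n) stop("dimension error: assignment rows must equal cohort size")
  check_has_events(cohort, "batch")
  rs <- risk_structure(cohort)
  ev <- eval_partial_loss(rs, probs, config)
  k <- config$k
  n <- cohort$n
  d <- ev$d; N <- ev$N; r <- ev$r; cj <- ev$cj
  wbar <- c(ev$w, 0)                      # score weights, padded for group k
  cpj <- ifelse(d == 1, 0,
                ifelse(N > 1, d * (d - 1) / (N - 1)^2, 0))  # d c_j / d N_j
  u <- as.vector(r %*% wbar)
  q <- as.vector(r %*% wbar^2)
  alpha_j <- 2 * d * u / N - cpj * (q - u^2) + (cj / N) * (q - 2 * u^2)
  beta_j <- (-2 * d + 2 * cj * u) / N
  gamma_j <- -cj / N
  delta <- rowSums(rs$e)                   # event indicator per subject
  A <- as.vector(rs$s %*% alpha_j)
  B <- as.vector(rs$s %*% beta_j)
  C <- as.vector(rs$s %*% gamma_j)
  G_stat <- 2 * outer(delta, wbar) + A +
    outer(B, wbar) + outer(C, wbar^2)
  # barrier gradient through the clamped column means
  pbar <- colMeans(probs)
  clamped <- pbar < PENALTY_CLAMP | pbar > 1 - PENALTY_CLAMP
  pb <- pmin(pmax(pbar, PENALTY_CLAMP), 1 - PENALTY_CLAMP)
  a <- config$alpha_exponent
  y <- pb^a
  dP_dpbar <- ifelse(clamped, 0,
                     -(1 - 2 * y) / (y - y^2)^2 * a * pb^(a - 1) / k)
  G_pen <- matrix(dP_dpbar / n, n, k, byrow = TRUE)
  -G_stat + config$lambda_penalty * G_pen
}
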