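# Shared fixture builders: small random cohorts and assignments, built in
# code so the repository carries no data files.

rand_cohort <- function(n, censor_frac = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  time <- rexp(n, rate = 1)
  event <- as.integer(runif(n) > censor_frac)
  if (sum(event) == 0L) event[1L] <- 1L
  survival_cohort(time, event)
}

rand_soft <- function(n, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- matrix(rexp(n * k), n, k)
  p / rowSums(p)
}

# k-sample logrank chi-square from the survival package (reference oracle).
ref_logrank <- function(cohort, labels) {
  survival::survdiff(survival::Surv(cohort$time, cohort$event) ~ labels)$chisq
}

# brute-force Harrell concordance by explicit pair enumeration
brute_cindex <- function(risk, cohort) {
  ti <- cohort$time; ev <- cohort$event
  conc <- 0; usable <- 0
  n <- length(ti)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- i; b <- j
    if (ti[a] == ti[b]) {
      if (ev[a] + ev[b] != 1L) next
      if (ev[b] == 1L) { a <- j; b <- i }
    } else {
      if (ti[a] > ti[b]) { a <- j; b <- i }
      if (ev[a] != 1L) next
    }
    usable <- usable + 1
    if (risk[a] > risk[b]) conc <- conc + 1
    else if (risk[a] == risk[b]) conc <- conc + 0.5
  }
  conc / usable
}
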