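#' Construct a survival cohort
#'
#' A minimal right-censored survival container: one observed time and one
#' event indicator per subject.  Times must be strictly positive (a consistent
#' unit such as days is assumed throughout); `event = 1` marks an observed
#' event, `event = 0` right censoring.
#'
#' @param time numeric vector of strictly positive follow-up times.
#' @param event integer/numeric vector of 0/1 event indicators, same length.
#' @return An object of class `survival_cohort`: a list with elements
#'   `time`, `event` (integer) and `n`.
#' @examples
#' co <- survival_cohort(c(3, 5, 7, 9), c(1, 0, 1, 1))
#' co$n
#' @export
survival_cohort <- function(time, event) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(event))
    stop("`time` and `event` must have the same length")
  if (length(time) == 0L)
    stop("empty cohort")
  if (anyNA(time) || anyNA(event))
    stop("`time` and `event` must not contain missing values")
  if (any(time <= 0)) {
    bad <- which(time <= 0)[1L]
    stop(sprintf("all times must be strictly positive (row %d has time = %g)",
                 bad, time[bad]))
  }
  if (!all(event %in% c(0, 1))) {
    bad <- which(!(event %in% c(0, 1)))[1L]
    stop(sprintf("event indicators must be 0 or 1 (row %d has event = %g)",
                 bad, event[bad]))
  }
  structure(list(time = time, event = as.integer(event), n = length(time)),
            class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("Survival cohort: %d subjects, %d events (%.1f%% censored)\n",
              x$n, sum(x$event), 100 * mean(x$event == 0)))
  invisible(x)
}

n_events <- function(cohort) sum(cohort$event)

check_has_events <- function(cohort, what = "cohort") {
  if (n_events(cohort) < 1L)
    stop(sprintf("degenerate %s: no observed events", what), call. = FALSE)
  invisible(TRUE)
}

#' Subset a survival cohort
#' @param x a `survival_cohort`.
#' @param i index vector.
#' @param ... unused.
#' @export
`[.survival_cohort` <- function(x, i, ...) {
  survival_cohort(x$time[i], x$event[i])
}

#' Validate a soft assignment matrix
#'
#' A soft assignment is an n-by-k row-stochastic matrix: row i is a
#' categorical distribution over the k candidate groups for subject i.
#' A classical hard labelling is the special case of one-hot rows.
#'
#' @param probs numeric matrix, n rows (subjects) by k columns (groups).
#' @param tol tolerance on the row-sum deviation from 1 (default 1e-9).
#' @return `probs`, invisibly, after validation.
#' @export
soft_assignment <- function(probs, tol = 1e-9) {
  probs <- as.matrix(probs)
  if (ncol(probs) < 2L) stop("a soft assignment needs k >= 2 columns")
  if (any(probs < 0) || any(probs > 1))
    stop("assignment probabilities must lie in [0, 1]")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > tol))
    stop(sprintf("assignment rows must sum to 1 (max deviation %.3g)",
                 max(abs(rs - 1))))
  invisible(probs)
}

#' One-hot assignment matrix from hard labels
#'
#' @param labels integer vector with values in `0:(k-1)` (or `1:k`).
#' @param k number of groups; defaults to the number of distinct labels.
#' @return An n-by-k 0/1 matrix with a single 1 per row.
#' @export
one_hot <- function(labels, k = NULL) {
  labels <- as.integer(labels)
  if (min(labels) == 1L && is.null(k)) labels <- labels - 1L
  if (min(labels) == 1L && !is.null(k) && max(labels) == k) labels <- labels - 1L
  if (is.null(k)) k <- max(labels) + 1L
  if (any(labels < 0L | labels >= k)) stop("labels out of range for k groups")
  m <- matrix(0, length(labels), k)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

#' Read a survival cohort with features from CSV
#'
#' Expects a header row with mandatory columns `time` and `event`; every
#' remaining column is treated as a feature.  Missing feature cells are kept
#' as `NA` for downstream train-only imputation; `time`/`event` must be
#' complete and valid.  Subject order is preserved.
#'
#' @param path path to a UTF-8 CSV file.
#' @return A list with `cohort` (a [survival_cohort]), `features` (numeric
#'   matrix, possibly 0 columns) and, when a `label` column is present,
#'   `labels` (integer vector).
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  for (col in c("time", "event"))
    if (!col %in% names(df))
      stop(sprintf("schema error: mandatory column `%s` missing in %s", col, path))
  cohort <- survival_cohort(df$time, df$event)
  labels <- NULL
  if ("label" %in% names(df)) labels <- as.integer(df$label)
  feat_cols <- setdiff(names(df), c("time", "event", "label"))
  features <- if (length(feat_cols))
    as.matrix(df[, feat_cols, drop = FALSE]) else
    matrix(numeric(0), nrow(df), 0)
  storage.mode(features) <- "double"
  list(cohort = cohort, features = features, labels = labels)
}

#' Write a survival cohort with features to CSV
#'
#' Inverse of [read_cohort_csv()]: columns `time,event[,label],f0..f{d-1}`
#' (feature column names are preserved if present).
#'
#' @param cohort a `survival_cohort`.
#' @param path output path.
#' @param features optional numeric matrix of per-subject features.
#' @param labels optional integer class labels.
#' @export
write_cohort_csv <- function(cohort, path, features = NULL, labels = NULL) {
  df <- data.frame(time = cohort$time, event = cohort$event)
  if (!is.null(labels)) df$label <- as.integer(labels)
  if (!is.null(features) && ncol(features) > 0) {
    fn <- colnames(features)
    if (is.null(fn)) fn <- paste0("f", seq_len(ncol(features)) - 1L)
    feat_df <- as.data.frame(features)
    names(feat_df) <- fn
    df <- cbind(df, feat_df)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
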