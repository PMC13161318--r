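#' Fit train-only imputation and standardisation parameters
#'
#' Computes per-feature means (used both for mean-imputation of missing
#' cells and for centring) and standard deviations from the training
#' partition only, so that no information from held-out subjects leaks into
#' preprocessing.  Constant features (sd = 0) are centred and passed through
#' with a unit divisor, yielding all-zero columns.
#'
#' @param train_features numeric matrix (rows = training subjects); may
#'   contain `NA`s.
#' @return An object of class `preprocessor` with `center`, `scale` and
#'   `impute` vectors; apply with [apply_preprocessor()] or `predict()`.
#' @export
fit_preprocessor <- function(train_features) {
  train_features <- as.matrix(train_features)
  if (nrow(train_features) < 2L) stop("need >= 2 training rows")
  all_missing <- apply(train_features, 2, function(col) all(is.na(col)))
  if (any(all_missing)) {
    nm <- colnames(train_features)
    if (is.null(nm)) nm <- paste0("column ", which(all_missing))
    stop(sprintf("feature `%s` has no non-missing training values",
                 nm[which(all_missing)[1L]]))
  }
  mu <- colMeans(train_features, na.rm = TRUE)
  sdv <- apply(train_features, 2, stats::sd, na.rm = TRUE)
  sdv[is.na(sdv) | sdv == 0] <- 1
  structure(list(center = mu, scale = sdv, impute = mu,
                 p = ncol(train_features)),
            class = "preprocessor")
}

#' Apply a fitted preprocessor
#'
#' Missing cells are replaced by the training mean of their feature, then
#' every feature is standardised with the training mean/sd.
#'
#' @param object a `preprocessor` from [fit_preprocessor()].
#' @param features numeric matrix with the same columns as the training data.
#' @return Standardised matrix without missing values.
#' @export
apply_preprocessor <- function(object, features) {
  features <- as.matrix(features)
  if (ncol(features) != object$p)
    stop("feature count differs from the fitted preprocessor")
  for (jj in seq_len(ncol(features))) {
    miss <- is.na(features[, jj])
    if (any(miss)) features[miss, jj] <- object$impute[jj]
  }
  sweep(sweep(features, 2, object$center), 2, object$scale, "/")
}

#' @export
predict.preprocessor <- function(object, newdata, ...) {
  apply_preprocessor(object, newdata)
}

#' Zero-signal preserving contrast enhancement
#'
#' Standardises tissue pixel intensities (mean 0, sd 1 over the tissue mask)
#' while leaving background pixels bit-unchanged, amplifying intensity
#' variation within tissue without disturbing the zero background.  Tissue
#' is the set of non-zero pixels unless an explicit mask is supplied.
#'
#' @param image 2D numeric matrix, or a 3D array (stack, first dim = subject).
#' @param mask optional logical matrix marking tissue pixels.
#' @return The enhanced image (same shape).  An all-background image is
#'   returned unchanged with a warning.
#' @export
zero_signal_contrast_enhance <- function(image, mask = NULL) {
  if (length(dim(image)) == 3L) {
    for (i in seq_len(dim(image)[1]))
      image[i, , ] <- zero_signal_contrast_enhance(image[i, , ])
    return(image)
  }
  if (is.null(mask)) mask <- image != 0
  if (!any(mask)) {
    warning("all-background image: nothing to enhance")
    return(image)
  }
  v <- image[mask]
  # population sd: the mask is the full tissue population of this image
  sdv <- sqrt(mean((v - mean(v))^2))
  if (sdv == 0) sdv <- 1
  image[mask] <- (v - mean(v)) / sdv
  image
}
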