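#' Training configuration
#'
#' Defaults follow the package's reference hyper-parameterisations: for the
#' tabular MLP a learning rate of `10^-3.9`, 20 epochs, mini-batches of 128,
#' decoupled weight decay `10^-2.2` and balance-penalty weight `10^-0.7`;
#' for the image CNN a learning rate of `10^-3`, mini-batches of 32, weight
#' decay `10^-1` and penalty weight `10^-1` (100 epochs at full scale; the
#' desk-scale image profile trains for 40).  Optimisation is AdamW
#' (adaptive moments with decoupled weight decay) throughout.
#'
#' @param kind `"mlp"` or `"cnn"` (selects the default block).
#' @param learning_rate,epochs,batch_size,weight_decay,lambda_penalty,n_folds,seed
#'   overrides of the defaults.
#' @param ridge_eps ridge used inside the loss during training.
#' @return A list of class `train_config`.
#' @export
train_config <- function(kind = c("mlp", "cnn"),
                         learning_rate = NULL, epochs = NULL,
                         batch_size = NULL, weight_decay = NULL,
                         lambda_penalty = NULL, n_folds = 5,
                         seed = 20260101, ridge_eps = 1e-6) {
  kind <- match.arg(kind)
  def <- switch(kind,
    mlp = list(lr = 10^-3.9, epochs = 20L, batch = 128L,
               wd = 10^-2.2, lambda = 10^-0.7),
    cnn = list(lr = 10^-3, epochs = 40L, batch = 32L,
               wd = 10^-1, lambda = 10^-1))
  lr <- if (is.null(learning_rate)) def$lr else learning_rate
  if (lr > 1e-2)
    warning("learning rates above 1e-2 can overpower the balance penalty; consider a slower rate")
  structure(list(kind = kind, learning_rate = lr,
                 epochs = as.integer(if (is.null(epochs)) def$epochs else epochs),
                 batch_size = as.integer(if (is.null(batch_size)) def$batch else batch_size),
                 weight_decay = if (is.null(weight_decay)) def$wd else weight_decay,
                 lambda_penalty = if (is.null(lambda_penalty)) def$lambda else lambda_penalty,
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 ridge_eps = ridge_eps),
            class = "train_config")
}

model_init <- function(model_spec) {
  switch(model_spec$kind, mlp = init_mlp(model_spec), cnn = init_cnn(model_spec),
         stop("unknown model kind"))
}

model_forward <- function(model, x, cache = FALSE) {
  if (inherits(model, "lrc_mlp")) mlp_forward(model, x, cache)
  else cnn_forward(model, x, cache)
}

model_backward <- function(model, fwd, dprobs) {
  if (inherits(model, "lrc_mlp")) mlp_backward(model, fwd, dprobs)
  else cnn_backward(model, fwd, dprobs)
}

subset_inputs <- function(x, idx) {
  if (length(dim(x)) == 3L) x[idx, , , drop = FALSE] else x[idx, , drop = FALSE]
}

#' Train a clustering network against the partial logrank objective
#'
#' Minimises `-L + lambda * P(pbar)` by mini-batch AdamW: each batch's soft
#' assignments enter the partial multivariate logrank statistic and the
#' balance barrier, and the exact analytic gradient is backpropagated
#' through the softmax network.  A sampled mini-batch without events is
#' resampled once and then skipped with a logged warning.  Training is fully
#' reproducible from `config$seed`.
#'
#' @param cohort a [survival_cohort].
#' @param x preprocessed inputs: n-by-d feature matrix (MLP) or n-by-H-by-W
#'   image array (CNN).
#' @param model_spec an [mlp_spec()] or [cnn_spec()].
#' @param config a [train_config()].
#' @return A list of class `lrc_fit`: `model`, `log` (per-epoch data frame
#'   with loss, full-data statistic and cluster balance) and `config`.
#' @export
train_cluster_model <- function(cohort, x, model_spec, config) {
  check_has_events(cohort)
  n <- cohort$n
  if (config$batch_size > n) stop("batch_size exceeds the training set size")
  k <- model_spec$k_outputs
  lcfg <- loss_config(k, config$lambda_penalty, config$ridge_eps)
  set.seed(config$seed)
  model <- model_init(model_spec)
  state <- adamw_state(model$layers)
  step <- 0L
  log_rows <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    epoch_losses <- c()
    for (st in starts) {
      idx <- ord[st:min(st + config$batch_size - 1L, n)]
      if (length(idx) < 2L) next
      if (sum(cohort$event[idx]) == 0L) {       # resample once, then skip
        idx <- sample.int(n, length(idx))
        if (sum(cohort$event[idx]) == 0L) {
          warning("skipping a mini-batch without events")
          next
        }
      }
      batch_cohort <- cohort[idx]
      fwd <- model_forward(model, subset_inputs(x, idx), cache = TRUE)
      ev <- eval_partial_loss(risk_structure(batch_cohort), fwd$probs, lcfg)
      if (!is.finite(ev$loss))
        stop(sprintf("NaN/Inf loss in epoch %d (statistic %.3g, penalty %.3g); aborting",
                     epoch, ev$statistic, ev$penalty))
      dprobs <- partial_logrank_grad(batch_cohort, fwd$probs, lcfg)
      grads <- model_backward(model, fwd, dprobs)
      step <- step + 1L
      upd <- adamw_step(model$layers, grads, state, config$learning_rate,
                        config$weight_decay, t = step)
      model$layers <- upd$params
      state <- upd$state
      epoch_losses <- c(epoch_losses, ev$loss)
    }
    probs_full <- model_forward(model, x)
    full <- eval_partial_loss(risk_structure(cohort), probs_full, lcfg)
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, mean_batch_loss = mean(epoch_losses),
      statistic = full$statistic, penalty = full$penalty,
      balance_min = min(colMeans(probs_full)),
      balance_max = max(colMeans(probs_full)))
  }
  structure(list(model = model, log = do.call(rbind, log_rows),
                 config = config, model_spec = model_spec),
            class = "lrc_fit")
}

#' @export
predict.lrc_fit <- function(object, newdata, ...) {
  model_forward(object$model, newdata)
}

#' @export
print.lrc_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf("Trained %s: %d epochs, final statistic %.2f, balance [%.2f, %.2f]\n",
              x$model_spec$kind, nrow(x$log), last$statistic,
              last$balance_min, last$balance_max))
  invisible(x)
}

# Column order that sorts a fold's clusters by train-derived risk rank
# (first column = best survival).  Clusters empty on train keep their
# position at the end, deterministically.
align_by_risk <- function(hard_train, train_cohort, k) {
  sizes <- tabulate(hard_train + 1L, k)
  nonempty <- which(sizes > 0L)
  if (length(nonempty) < 2L) return(seq_len(k))
  compact <- match(hard_train, nonempty - 1L) - 1L
  rk <- derive_risk_order(compact, train_cohort, length(nonempty))
  c(nonempty[order(rk)], which(sizes == 0L))
}

# Event-stratified fold assignment: events and censored subjects are dealt
# to folds separately so every fold retains events.
stratified_folds <- function(event, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(event))
  for (grp in list(which(event == 1L), which(event == 0L))) {
    if (!length(grp)) next
    fold[sample(grp)] <- rep_len(seq_len(n_folds), length(grp))
  }
  fold
}

#' Cross-validated survival-guided clustering
#'
#' Splits the cohort into event-stratified folds, fits the preprocessor and
#' the network on each training partition only, and predicts soft
#' assignments for the held-out fold; held-out predictions are returned in
#' the original subject order.  Per-fold seeds are derived deterministically
#' from the global seed (`seed + fold`).
#'
#' @inheritParams train_cluster_model
#' @param preprocess `"standardize"` (tabular: train-only mean imputation and
#'   standardisation), `"contrast"` (images: zero-signal preserving contrast
#'   enhancement, a per-image operation) or `"none"`.
#' @return A list of class `lrc_cv`: `assignments` (n-by-k held-out soft
#'   probabilities), `fold` (1-based fold id per subject), `fits` and
#'   `preprocessors` per fold.
#' @export
cross_validate <- function(cohort, x, model_spec, config,
                           preprocess = c("standardize", "contrast", "none")) {
  preprocess <- match.arg(preprocess)
  n <- cohort$n
  if (n < config$n_folds * model_spec$k_outputs)
    stop("cohort too small for the requested number of folds")
  fold <- stratified_folds(cohort$event, config$n_folds, config$seed)
  if (any(tapply(cohort$event, fold, sum) == 0))
    stop("a fold has no events; use stratified folding (enabled by default) or fewer folds")
  assignments <- matrix(NA_real_, n, model_spec$k_outputs)
  fits <- vector("list", config$n_folds)
  preps <- vector("list", config$n_folds)
  if (preprocess == "contrast") x <- zero_signal_contrast_enhance(x)
  for (f in seq_len(config$n_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    x_tr <- subset_inputs(x, tr); x_te <- subset_inputs(x, te)
    if (preprocess == "standardize") {
      pp <- fit_preprocessor(x_tr)
      x_tr <- apply_preprocessor(pp, x_tr)
      x_te <- apply_preprocessor(pp, x_te)
      preps[[f]] <- pp
    }
    fold_config <- config
    fold_config$seed <- config$seed + f
    fits[[f]] <- train_cluster_model(cohort[tr], x_tr, model_spec, fold_config)
    # Cluster labels are arbitrary per fold (label switching); align columns
    # across folds by each fold's TRAIN-derived survival risk order so that
    # pooled column g always means "risk rank g" (0 = best survival).  Uses
    # only training data, so no held-out leakage.
    p_tr <- predict(fits[[f]], x_tr)
    hard_tr <- max.col(p_tr, ties.method = "first") - 1L
    perm <- align_by_risk(hard_tr, cohort[tr], model_spec$k_outputs)
    fits[[f]]$risk_alignment <- perm
    p_te <- predict(fits[[f]], x_te)
    assignments[te, ] <- p_te[, perm, drop = FALSE]
  }
  structure(list(assignments = assignments, fold = fold, fits = fits,
                 preprocessors = preps, k = model_spec$k_outputs),
            class = "lrc_cv")
}
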