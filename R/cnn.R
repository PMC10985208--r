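#' Configuration of the precursor classifier network
#'
#' Fixes the layer stack and training hyperparameters:
#' conv(2x2, `n_filters1`, ReLU) -> max-pool 2x2 ->
#' conv(2x2, `n_filters2`, ReLU) -> max-pool 2x2 -> flatten ->
#' FC(`fc_units`, identity) -> FC(2) -> softmax, stride 1 and no padding
#' in the convolutions, pooling stride equal to the window. Training
#' minimises the negative log likelihood with AdaDelta; inverted dropout
#' with retain probability `dropout_retain` is applied after each hidden
#' block at training time only. Weights are Xavier (Glorot uniform)
#' initialised. `dropout_retain = 0.9` follows the convention that the
#' "dropout coefficient" is the probability of keeping a unit.
#'
#' @param L input matrix width (the encoded precursor length).
#' @param n_filters1,n_filters2 filters in the two convolution layers.
#' @param fc_units units in the hidden fully connected layer.
#' @param dropout_retain retain probability in (0, 1].
#' @param epochs,batch_size training schedule.
#' @param rho,eps AdaDelta decay and stabiliser.
#' @return an object of class `mircnn_config`.
#' @export
mircnn_config <- function(L = 200L, n_filters1 = 20L, n_filters2 = 60L,
                          fc_units = 500L, dropout_retain = 0.9,
                          epochs = 12L, batch_size = 32L,
                          rho = 0.95, eps = 1e-6) {
  stopifnot(dropout_retain > 0, dropout_retain <= 1, epochs >= 0,
            batch_size >= 1, rho > 0, rho < 1, eps > 0)
  cfg <- structure(list(L = as.integer(L), n_filters1 = as.integer(n_filters1),
                        n_filters2 = as.integer(n_filters2),
                        fc_units = as.integer(fc_units),
                        dropout_retain = dropout_retain,
                        epochs = as.integer(epochs),
                        batch_size = as.integer(batch_size),
                        rho = rho, eps = eps),
                   class = "mircnn_config")
  model_shapes(cfg)   # validates the shape chain
  cfg
}

#' Layer-by-layer shape chain of the network
#'
#' @param config a `mircnn_config`.
#' @return a named list of integer shape vectors, from the (1, 7, L)
#'   input through both conv/pool blocks to the flatten size and the two
#'   fully connected layers. Errors with a per-layer trace when any
#'   feature map collapses.
#' @export
model_shapes <- function(config) {
  L <- config$L
  sh <- list(input = c(1L, 7L, L))
  sh$conv1 <- c(config$n_filters1, 6L, L - 1L)
  sh$pool1 <- c(config$n_filters1, 3L, (L - 1L) %/% 2L)
  sh$conv2 <- c(config$n_filters2, 2L, sh$pool1[3] - 1L)
  sh$pool2 <- c(config$n_filters2, 1L, sh$conv2[3] %/% 2L)
  sh$flatten <- config$n_filters2 * sh$pool2[3]
  sh$fc <- config$fc_units
  sh$output <- 2L
  for (nm in c("conv1", "pool1", "conv2", "pool2")) {
    if (any(sh[[nm]] < 1))
      stop("invalid shape chain at ", nm, ": ",
           paste(sh[[nm]], collapse = "x"),
           " (input width L = ", L, " too small)")
  }
  sh
}

#' @export
print.mircnn_config <- function(x, ...) {
  sh <- model_shapes(x)
  fmt <- function(s) paste(s, collapse = "x")
  cat("mircnn_config: ",
      fmt(sh$input), " -> ", fmt(sh$conv1), " -> ", fmt(sh$pool1),
      " -> ", fmt(sh$conv2), " -> ", fmt(sh$pool2), " -> ", sh$flatten,
      " -> ", sh$fc, " -> 2\n",
      "dropout retain ", x$dropout_retain, ", AdaDelta(rho = ", x$rho,
      ", eps = ", x$eps, "), epochs ", x$epochs, ", batch ", x$batch_size,
      "\n", sep = "")
  invisible(x)
}

xavier_mat <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained, Xavier-initialised model
#'
#' @param config a `mircnn_config`.
#' @param seed integer seed for the weight initialisation.
#' @return an object of class `mircnn` (untrained).
#' @export
mircnn_build <- function(config = mircnn_config(), seed = 1L) {
  sh <- model_shapes(config)
  weights <- with_local_seed(seed, {
    list(W1 = xavier_mat(config$n_filters1, 4L, 4, 4 * config$n_filters1),
         b1 = numeric(config$n_filters1),
         W2 = xavier_mat(config$n_filters2, 4L * config$n_filters1,
                         4 * config$n_filters1, 4 * config$n_filters2),
         b2 = numeric(config$n_filters2),
         W3 = xavier_mat(config$fc_units, sh$flatten, sh$flatten,
                         config$fc_units),
         b3 = numeric(config$fc_units),
         W4 = xavier_mat(2L, config$fc_units, config$fc_units, 2),
         b4 = numeric(2L))
  })
  structure(list(config = config, weights = weights,
                 training_log = numeric(0), seed = as.integer(seed),
                 trained = FALSE),
            class = "mircnn")
}

as_input_cube <- function(x, L) {
  if (is.list(x) && !is.array(x)) {
    arr <- array(0, dim = c(7L, L, length(x)))
    for (i in seq_along(x)) arr[, , i] <- x[[i]]
    x <- arr
  }
  if (length(dim(x)) == 2) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 3 || dim(x)[1] != 7 || dim(x)[2] != L)
    stop("input must be 7 x ", L, " matrices (got ",
         paste(dim(x), collapse = "x"), ")")
  x
}

#' Fit the precursor classifier
#'
#' Trains the network of [mircnn_config()] on encoded precursor matrices
#' by minimising the negative log likelihood with AdaDelta and dropout.
#' All randomness (initial weights, epoch shuffling, dropout masks) flows
#' from `seed`, so a fixed seed reproduces the fit bit for bit.
#'
#' @param x encoded inputs: array of dim (7, L, N), or a list of
#'   `encoded_matrix`.
#' @param y labels, 1 = miRNA, 0 = other (taken from `attr(x, "labels")`
#'   when omitted).
#' @param config a `mircnn_config`.
#' @param seed integer seed.
#' @param model optionally, an existing `mircnn` to continue training.
#' @param sample_idx optional integer vector of (possibly repeated)
#'   training indices into `x`, e.g. from [oversample_minority()];
#'   defaults to all samples.
#' @return a fitted object of class `mircnn` with elements `config`,
#'   `weights`, `training_log` (mean per-epoch training loss), `seed`.
#' @seealso [predict.mircnn()], [mircnn_cv()]
#' @export
mircnn_fit <- function(x, y = NULL, config = mircnn_config(), seed = 1L,
                       model = NULL, sample_idx = NULL) {
  if (is.null(y)) y <- attr(x, "labels")
  if (is.null(y)) stop("labels are required (y or attr(x, 'labels'))")
  X <- as_input_cube(x, config$L)
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("labels must be 0 (other) or 1 (miRNA), no NA")
  if (dim(X)[3] != length(y)) stop("number of samples and labels differ")
  if (is.null(sample_idx)) sample_idx <- seq_along(y)
  if (is.null(model)) model <- mircnn_build(config, seed)
  if (length(unique(y[sample_idx])) < 2)
    stop("training data must contain both classes")
  res <- .cnn_train_cpp(X, y, as.integer(sample_idx) - 1L, model$weights,
                        config$epochs, config$batch_size,
                        config$dropout_retain, config$rho, config$eps,
                        as.integer(seed))
  model$weights <- res$weights
  model$training_log <- c(model$training_log, res$epoch_loss)
  model$trained <- TRUE
  model$n_train <- length(sample_idx)
  model
}

#' Predict miRNA probabilities for encoded precursors
#'
#' Runs the inference-mode forward pass (dropout inactive). A precursor
#' is called miRNA when its softmax probability is at least 0.5 (ties go
#' to the positive class).
#'
#' @param object a `mircnn`.
#' @param newdata encoded inputs as in [mircnn_fit()].
#' @param type `"class"` for labels, `"prob"` for the probability matrix.
#' @param ... unused.
#' @return factor of classes, or an N x 2 matrix with columns `other`,
#'   `miRNA`.
#' @export
predict.mircnn <- function(object, newdata,
                           type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as_input_cube(newdata, object$config$L)
  P <- .cnn_predict_cpp(X, object$weights)
  colnames(P) <- c("other", "miRNA")
  if (type == "prob") return(P)
  factor(ifelse(P[, "miRNA"] >= 0.5, "miRNA", "other"),
         levels = c("other", "miRNA"))
}

#' @export
print.mircnn <- function(x, ...) {
  cat("mircnn precursor classifier (",
      if (x$trained) "trained" else "untrained", ")\n", sep = "")
  print(x$config)
  if (length(x$training_log))
    cat("final training loss: ",
        signif(x$training_log[length(x$training_log)], 4), " after ",
        length(x$training_log), " epoch(s)\n", sep = "")
  invisible(x)
}

#' @export
summary.mircnn <- function(object, ...) {
  np <- sum(vapply(object$weights, length, 0L))
  cat("Parameters:", np, "\n")
  print(object)
  invisible(object)
}

#' @export
plot.mircnn <- function(x, ...) {
  if (!length(x$training_log)) stop("model has no training log")
  plot(seq_along(x$training_log), x$training_log, type = "b", pch = 16,
       xlab = "epoch", ylab = "training NLL", main = "mircnn training loss",
       ...)
  invisible(x)
}

#' Oversample the minority class to exact parity
#'
#' Returns training indices consisting of every original sample plus
#' minority-class samples drawn with replacement until both classes have
#' exactly the same count. Applied to training splits only, never to
#' held-out data.
#'
#' @param y 0/1 labels of the training split.
#' @return integer vector of indices into `y`.
#' @export
oversample_minority <- function(y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  if (n1 == n0) return(seq_along(y))
  minority <- if (n1 < n0) which(y == 1L) else which(y == 0L)
  extra <- sample(minority, abs(n0 - n1), replace = TRUE)
  c(seq_along(y), extra)
}

#' Stratified fold assignment
#'
#' Randomly partitions samples into `k` folds of (as near as possible)
#' equal size while preserving the class ratio in every fold. Each sample
#' appears in exactly one fold.
#'
#' @param y 0/1 labels.
#' @param k number of folds.
#' @return integer vector of fold ids in 1..k.
#' @export
stratified_folds <- function(y, k = 5L) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated training and evaluation of the classifier
#'
#' Stratified random partition into `folds` equal subsets; for every
#' fold the remaining data are oversampled to exact class parity
#' ([oversample_minority()], training portion only), a fresh network is
#' trained, and the held-out fold is scored. Reported are the per-fold
#' confusion counts and metrics, their unweighted mean across folds (the
#' headline numbers), and the pooled counts.
#'
#' @param x encoded inputs as in [mircnn_fit()].
#' @param y 0/1 labels (default `attr(x, "labels")`).
#' @param folds number of folds (>= 2).
#' @param config a `mircnn_config`.
#' @param seed integer seed driving the fold split, oversampling, weight
#'   initialisation and dropout.
#' @param keep_models keep the per-fold fitted models (large); default
#'   FALSE.
#' @return an object of class `mircnn_cv`: `fold_assignment`,
#'   `fold_metrics` (list of `metrics_report`), `mean_metrics`,
#'   `pooled`, `initial_weights` (fold-1 starting weights, for
#'   reproducibility checks), and optionally `models`.
#' @export
mircnn_cv <- function(x, y = NULL, folds = 5L, config = mircnn_config(),
                      seed = 1L, keep_models = FALSE) {
  if (is.null(y)) y <- attr(x, "labels")
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("dataset must contain both classes")
  stopifnot(folds >= 2)
  X <- as_input_cube(x, config$L)

  out <- with_local_seed(seed, {
    assignment <- stratified_folds(y, folds)
    fold_metrics <- list(); models <- list(); init_w <- NULL
    oversample_sizes <- integer(folds)
    for (f in seq_len(folds)) {
      tr <- which(assignment != f); te <- which(assignment == f)
      os <- tr[oversample_minority(y[tr])]
      oversample_sizes[f] <- length(os)
      mdl <- mircnn_build(config, seed = seed + f)
      if (f == 1L) init_w <- mdl$weights
      mdl <- mircnn_fit(X[, , , drop = FALSE], y, config,
                        seed = seed + f, model = mdl, sample_idx = os)
      pred <- predict(mdl, X[, , te, drop = FALSE], type = "class")
      cm <- confusion(y[te], as.integer(pred == "miRNA"))
      fold_metrics[[f]] <- classification_metrics(cm)
      if (keep_models) models[[f]] <- mdl
    }
    list(assignment = assignment, fold_metrics = fold_metrics,
         models = models, init_w = init_w,
         oversample_sizes = oversample_sizes)
  })

  mk <- function(what) mean(vapply(out$fold_metrics, `[[`, 0, what))
  pooled_counts <- Reduce(`+`, lapply(out$fold_metrics, function(m)
    c(TP = m$TP, FP = m$FP, TN = m$TN, FN = m$FN)))
  structure(list(folds = folds, config = config, seed = seed,
                 fold_assignment = out$assignment,
                 fold_metrics = out$fold_metrics,
                 mean_metrics = list(accuracy = mk("accuracy"),
                                     precision = mk("precision"),
                                     recall = mk("recall"),
                                     f1 = mk("f1")),
                 pooled = classification_metrics(pooled_counts),
                 oversample_sizes = out$oversample_sizes,
                 initial_weights = out$init_w,
                 models = if (keep_models) out$models),
            class = "mircnn_cv")
}

#' @export
print.mircnn_cv <- function(x, digits = 4, ...) {
  cat(x$folds, "-fold cross-validation (seed ", x$seed, ")\n", sep = "")
  m <- x$mean_metrics
  cat("mean held-out metrics: accuracy ", round(m$accuracy, digits),
      ", precision ", round(m$precision, digits),
      ", recall ", round(m$recall, digits),
      ", F1 ", round(m$f1, digits), "\n", sep = "")
  invisible(x)
}

#' @export
summary.mircnn_cv <- function(object, digits = 4, ...) {
  print(object, digits = digits)
  for (f in seq_along(object$fold_metrics)) {
    cat("fold ", f, ": ", sep = "")
    print(object$fold_metrics[[f]], digits = digits)
  }
  invisible(object)
}

#' Generic convolution layer forward pass
#'
#' Valid cross-correlation (stride 1, no padding) of a C x H x W input
#' with K kernels, with optional ReLU. Exposed for verification against
#' naive-loop oracles; the trainer uses the same arithmetic in its
#' batched path.
#'
#' @param input numeric array, dim (C, H, W).
#' @param kernels numeric array, dim (K, C, kh, kw).
#' @param bias numeric vector of length K (default zeros).
#' @param activation `"relu"` or `"identity"`.
#' @return numeric array, dim (K, H - kh + 1, W - kw + 1).
#' @export
conv_forward <- function(input, kernels, bias = NULL,
                         activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (is.null(bias)) bias <- numeric(dim(kernels)[1])
  .conv_forward_cpp(input, kernels, bias, activation == "relu")
}

#' Generic max-pooling forward pass
#'
#' Non-overlapping windows with stride equal to the window size;
#' trailing rows/columns that do not fill a window are dropped.
#'
#' @param input numeric array, dim (C, H, W).
#' @param window integer c(ph, pw) (default 2x2).
#' @return numeric array, dim (C, H %/% ph, W %/% pw).
#' @export
maxpool_forward <- function(input, window = c(2L, 2L)) {
  .maxpool_forward_cpp(input, as.integer(window[1]), as.integer(window[2]))
}
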