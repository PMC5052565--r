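#' Train the L2-regularized logistic regression classifier
#'
#' Fits a ridge-penalized logistic regression of the class label (coding
#' = positive = 1) on the feature matrix. The inverse regularization
#' strength `C` is chosen from a logarithmic grid by stratified k-fold
#' cross-validation maximizing held-out accuracy at probability cutoff
#' 0.5 (ties break toward the smaller `C`, i.e. stronger
#' regularization); the model is then refit on all data at the chosen
#' `C`. Fits are delegated to \pkg{glmnet} with `alpha = 0` and
#' `lambda = 1 / (n C)`. Features are used unscaled by default;
#' `standardize = TRUE` stores the training means/sds in the model and
#' applies them at prediction time.
#'
#' @param features Numeric matrix (rows = transcripts, named columns).
#' @param labels Vector of `"coding"`/`"noncoding"` (or 1/0); both
#'   classes must be present.
#' @param folds Number of CV folds (default 10).
#' @param C_grid Candidate inverse-regularization strengths (default 10
#'   log-spaced points, 1e-4 to 1e4).
#' @param seed Integer seed controlling fold assignment.
#' @param standardize Center/scale features before fitting.
#' @param cutoff Decision cutoff stored in the model (default 0.5; see
#'   [best_accuracy_cutoff()] and [default_cutoff()] for calibrated
#'   operating points).
#' @param hexamer_table Optional `hexamer_table` to embed in the model so
#'   a single file suffices for prediction; its digest is recorded either
#'   way when supplied.
#' @return Object of class `lnc_model`: `weights` (named), `intercept`,
#'   `C`, `lambda`, `cutoff`, `feature_names`, `standardize`
#'   (NULL or list(center, scale)), `hexamer_table`,
#'   `hexamer_table_digest`, `provenance` (n per class, folds, seed,
#'   C grid, per-C CV accuracies, format version, distance/CSP
#'   conventions).
#' @export
train_classifier <- function(features, labels, folds = 10L,
                             C_grid = 10^seq(-4, 4, length.out = 10L),
                             seed = 0L, standardize = FALSE, cutoff = 0.5,
                             hexamer_table = NULL) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as_binary_label(labels)
  if (length(y) != nrow(x)) stop("labels length != feature rows")
  if (length(unique(y)) < 2L) stop("both classes must be present in training data")
  if (nrow(x) < 2L * folds) stop("need at least 2 observations per fold")
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-finite feature value at row ", bad[1L, 1L], " ('",
         rownames(x)[bad[1L, 1L]] %||% bad[1L, 1L], "'), column '",
         colnames(x)[bad[1L, 2L]], "'")
  }
  if (!(cutoff > 0 && cutoff < 1)) stop("cutoff must lie in (0, 1)")
  C_grid <- sort(unique(C_grid))

  ctr <- NULL
  if (standardize) {
    ctr <- list(center = colMeans(x), scale = apply(x, 2L, stats::sd))
    ctr$scale[ctr$scale == 0] <- 1
    x <- scale(x, ctr$center, ctr$scale)
  }

  fold_id <- stratified_folds(y, folds, seed)
  cv_acc <- matrix(NA_real_, nrow = length(C_grid), ncol = folds)
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    lam <- sort(1 / (sum(tr) * C_grid), decreasing = TRUE)
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = 0, lambda = lam, standardize = FALSE,
                          thresh = 1e-9, maxit = 1e6)
    p <- stats::predict(fit, x[!tr, , drop = FALSE],
                        s = 1 / (sum(tr) * C_grid), type = "response")
    cv_acc[, k] <- colMeans((p >= 0.5) == (y[!tr] == 1L))
  }
  mean_acc <- rowMeans(cv_acc)
  best_C <- min(C_grid[mean_acc == max(mean_acc)])

  lam_all <- sort(1 / (nrow(x) * C_grid), decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lam_all, standardize = FALSE, thresh = 1e-9, maxit = 1e6)
  co <- as.numeric(stats::coef(fit, s = 1 / (nrow(x) * best_C)))
  weights <- co[-1L]
  names(weights) <- colnames(x)

  structure(list(
    weights = weights,
    intercept = co[1L],
    C = best_C,
    lambda = 1 / (nrow(x) * best_C),
    cutoff = cutoff,
    feature_names = colnames(x),
    standardize = ctr,
    hexamer_table = hexamer_table,
    hexamer_table_digest = if (is.null(hexamer_table)) NA_character_
                           else hexamer_table_digest(hexamer_table),
    provenance = list(
      n_coding = sum(y == 1L), n_noncoding = sum(y == 0L),
      folds = folds, seed = seed, C_grid = C_grid,
      cv_accuracy = stats::setNames(mean_acc, formatC(C_grid)),
      cv_accuracy_best = max(mean_acc),
      distance_definition = "sum_i(Sm - Si)/2",
      csp_definition = "Sm/(S1+S2+S3), 1.0 if sum <= 0",
      format_version = "1.0",
      trained = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "lnc_model")
}

#' @export
print.lnc_model <- function(x, ...) {
  cat(sprintf("<lnc_model> %d features; C = %g; cutoff = %g; CV accuracy = %.4f\n",
              length(x$weights), x$C, x$cutoff, x$provenance$cv_accuracy_best))
  invisible(x)
}

as_binary_label <- function(labels) {
  if (is.numeric(labels) || is.logical(labels)) {
    y <- as.integer(labels)
    if (!all(y %in% c(0L, 1L))) stop("numeric labels must be 0/1")
    return(y)
  }
  l <- as.character(labels)
  if (!all(l %in% c("coding", "noncoding"))) {
    stop("labels must be 'coding'/'noncoding' or 0/1")
  }
  as.integer(l == "coding")
}

# Per-class shuffle, folds assigned round-robin; RNG state restored.
stratified_folds <- function(y, k, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Coding probabilities from a trained model
#'
#' `p = 1 / (1 + exp(-(w . x + b)))`, the probability that each
#' transcript is protein-coding. Row order is preserved.
#'
#' @param model An `lnc_model`.
#' @param features Numeric matrix whose columns match
#'   `model$feature_names` (reordered by name when named).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, features) {
  x <- as.matrix(features)
  if (!is.null(colnames(x))) {
    missing <- setdiff(model$feature_names, colnames(x))
    extra <- setdiff(colnames(x), model$feature_names)
    if (length(missing) > 0L || length(extra) > 0L) {
      stop("feature columns do not match the model: missing [",
           paste(missing, collapse = ", "), "], extra [",
           paste(extra, collapse = ", "), "]")
    }
    x <- x[, model$feature_names, drop = FALSE]
  } else if (ncol(x) != length(model$feature_names)) {
    stop("feature matrix has ", ncol(x), " columns; model expects ",
         length(model$feature_names))
  }
  if (!is.null(model$standardize)) {
    x <- scale(x, model$standardize$center, model$standardize$scale)
  }
  as.numeric(stats::plogis(drop(x %*% model$weights) + model$intercept))
}

#' Turn coding probabilities into class labels
#'
#' A transcript is called coding iff `p >= cutoff`.
#'
#' @param probs Numeric vector of coding probabilities.
#' @param cutoff Decision threshold in (0, 1).
#' @return Character vector of `"coding"`/`"noncoding"`.
#' @export
classify <- function(probs, cutoff = 0.5) {
  if (!(is.numeric(cutoff) && length(cutoff) == 1L && cutoff > 0 && cutoff < 1)) {
    stop("cutoff must be a single number in (0, 1)")
  }
  ifelse(probs >= cutoff, "coding", "noncoding")
}

#' Packaged species default cutoffs
#'
#' Operating cutoffs calibrated (by best accuracy on full-length test
#' sets) for the human and mouse reference models: 0.5654 and 0.4567.
#'
#' @param species `"human"` or `"mouse"`.
#' @return A probability cutoff.
#' @export
default_cutoff <- function(species = c("human", "mouse")) {
  switch(match.arg(species), human = 0.5654, mouse = 0.4567)
}

#' Save / load a trained model
#'
#' A single human-readable JSON file with a format version tag; the
#' embedded hexamer table (when present) makes the file self-contained
#' for prediction. Loading verifies the version and, when a table is
#' embedded, that its digest matches the recorded one.
#'
#' @param model An `lnc_model`.
#' @param path Output path.
#' @return `path` (save) or the reloaded `lnc_model` (load).
#' @export
save_model <- function(model, path) {
  obj <- unclass(model)
  if (!is.null(obj$hexamer_table)) obj$hexamer_table <- unclass(obj$hexamer_table)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ver <- obj$provenance$format_version
  if (is.null(ver) || !identical(ver, "1.0")) {
    stop("model file '", path, "': unsupported or missing format version '",
         ver %||% "", "'")
  }
  if (length(obj$weights) != length(obj$feature_names)) {
    stop("model file '", path, "': weight/feature-name length mismatch")
  }
  if (!is.null(obj$hexamer_table)) {
    class(obj$hexamer_table) <- "hexamer_table"
    d <- hexamer_table_digest(obj$hexamer_table)
    recorded <- obj$hexamer_table_digest
    if (is.character(recorded) && length(recorded) == 1L && !is.na(recorded) &&
        !identical(d, recorded)) {
      warning("hexamer table digest mismatch: model records ",
              obj$hexamer_table_digest, ", embedded table hashes to ", d)
    }
  }
  if (is.list(obj$standardize) && length(obj$standardize) == 0L) {
    obj$standardize <- NULL
  }
  obj$weights <- stats::setNames(as.numeric(obj$weights), obj$feature_names)
  class(obj) <- "lnc_model"
  obj
}
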