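#' Hexamer-table training inputs from a synthetic dataset
#'
#' Extracts the in-frame CDS substrings of the full-length coding
#' transcripts (truncated transcripts are skipped: their surviving CDS
#' is frame-shifted and partial) and the noncoding sequences.
#'
#' @param dataset A [generate_dataset()] result.
#' @return List with `cds_seqs` and `noncoding_seqs`.
#' @export
hexamer_training_sequences <- function(dataset) {
  tr <- dataset$truth
  seqs <- vapply(dataset$records, `[[`, character(1), "sequence")
  full_coding <- which(tr$label == "coding" & !tr$truncated)
  list(cds_seqs = substring(seqs[full_coding], tr$cds_start[full_coding] + 1L,
                            tr$cds_end[full_coding]),
       noncoding_seqs = seqs[tr$label == "noncoding"])
}

#' End-to-end benchmark on synthetic transcripts
#'
#' The package's reference experiment: generate a full-length training
#' set and a test set whose coding half is partially truncated, build
#' the hexamer table from the training CDS, train the full 11-feature
#' model and single-group models (exon, MCSS, ORF), and measure AUC
#' separately on the full-length and partial-length coding test
#' transcripts (each against all noncoding test transcripts), plus the
#' operating-cutoff sweep on the full-length subset.
#'
#' Default sizes: 500 coding + 500 noncoding transcripts for training
#' (full length), 200 + 200 for testing with half of the coding
#' transcripts truncated — large enough for stable AUCs, small enough to
#' run in a couple of minutes on one CPU.
#'
#' @param seed Integer seed; training uses `seed`, testing `seed + 1`,
#'   CV folds `seed`.
#' @param n_train,n_test Per-class transcript counts.
#' @param partial_fraction_test Share of coding test transcripts
#'   truncated.
#' @param folds CV folds for regularization selection.
#' @param threads Workers for feature computation.
#' @return List: `model`, `group_models`, `cv_accuracy`, `auc_full`,
#'   `auc_partial`, `group_auc_full`, `group_auc_partial`,
#'   `best_cutoff`, `metrics_at_best_cutoff`, `table`, plus the feature
#'   matrices and index sets.
#' @export
synthetic_benchmark <- function(seed = 42L, n_train = 500L, n_test = 200L,
                                partial_fraction_test = 0.5, folds = 10L,
                                threads = 1L) {
  train_cfg <- generator_config(seed = seed, n_coding = n_train,
                                n_noncoding = n_train, partial_fraction = 0)
  test_cfg <- generator_config(seed = seed + 1L, n_coding = n_test,
                               n_noncoding = n_test,
                               partial_fraction = partial_fraction_test)
  train <- generate_dataset(train_cfg)
  test <- generate_dataset(test_cfg)

  hx <- hexamer_training_sequences(train)
  table <- build_hexamer_table(hx$cds_seqs, hx$noncoding_seqs)

  x_train <- feature_matrix(table, train$records, threads)
  y_train <- vapply(train$records, `[[`, character(1), "label")
  x_test <- feature_matrix(table, test$records, threads)
  y_test <- vapply(test$records, `[[`, character(1), "label")

  model <- train_classifier(x_train, y_train, folds = folds, seed = seed,
                            hexamer_table = table)

  groups <- list(
    exon = c("exon_hexamer_score", "exon_hexamer_distance", "exon_gc"),
    mcss = c("mcss_length", "mcss_score", "mcss_score_percentage"),
    orf = c("orf_length", "orf_coverage", "orf_fickett",
            "orf_hexamer_score", "orf_hexamer_distance"))
  group_models <- lapply(groups, function(cols) {
    train_classifier(x_train[, cols, drop = FALSE], y_train, folds = folds,
                     seed = seed)
  })

  is_partial <- test$truth$truncated
  full_idx <- which(y_test == "noncoding" | !is_partial)
  partial_idx <- which(y_test == "noncoding" | is_partial)
  auc_on <- function(m, cols, idx) {
    roc_auc(predict_proba(m, x_test[idx, cols, drop = FALSE]), y_test[idx])
  }
  p_full <- predict_proba(model, x_test[full_idx, , drop = FALSE])
  best <- best_accuracy_cutoff(p_full, y_test[full_idx])
  metrics <- confusion_metrics(classify(p_full, best$cutoff), y_test[full_idx])

  list(model = model, group_models = group_models, table = table,
       cv_accuracy = model$provenance$cv_accuracy_best,
       auc_full = auc_on(model, feature_names(), full_idx),
       auc_partial = auc_on(model, feature_names(), partial_idx),
       group_auc_full = vapply(names(groups), function(g) {
         auc_on(group_models[[g]], groups[[g]], full_idx)
       }, numeric(1)),
       group_auc_partial = vapply(names(groups), function(g) {
         auc_on(group_models[[g]], groups[[g]], partial_idx)
       }, numeric(1)),
       best_cutoff = best, metrics_at_best_cutoff = metrics,
       x_train = x_train, y_train = y_train, x_test = x_test,
       y_test = y_test, full_idx = full_idx, partial_idx = partial_idx,
       test_truth = test$truth)
}

#' Build a small deterministic demonstration model
#'
#' Trains a self-contained model (hexamer table embedded) on a compact
#' synthetic dataset. Deterministic for a given seed; used by the
#' examples, the command-line demo, and the thread-invariance checks.
#' The model is synthetic-trained: it demonstrates the machinery and is
#' not a substitute for a model trained on curated genome annotation.
#'
#' @param seed Integer seed.
#' @param n Per-class training size.
#' @param path Optional path; when given the model JSON is written there.
#' @return The `lnc_model` (invisibly when `path` is given).
#' @export
demo_model <- function(seed = 7L, n = 120L, path = NULL) {
  ds <- generate_dataset(generator_config(seed = seed, n_coding = n,
                                          n_noncoding = n,
                                          partial_fraction = 0))
  hx <- hexamer_training_sequences(ds)
  table <- build_hexamer_table(hx$cds_seqs, hx$noncoding_seqs)
  x <- feature_matrix(table, ds$records)
  y <- vapply(ds$records, `[[`, character(1), "label")
  model <- train_classifier(x, y, folds = 5L, seed = seed,
                            hexamer_table = table)
  if (!is.null(path)) {
    save_model(model, path)
    return(invisible(model))
  }
  model
}
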