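test_that("a separable problem trains to near-perfect accuracy", {
  set.seed(51)
  n <- 200
  x <- cbind(a = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
             b = rnorm(n))
  y <- rep(c("noncoding", "coding"), each = n / 2)
  m <- train_classifier(x, y, folds = 5, seed = 0)
  acc <- mean(classify(predict_proba(m, x), 0.5) == y)
  expect_gte(acc, 0.99)
  expect_gt(m$weights[["a"]], 0)
})

test_that("shuffled labels give chance-level cross-validated accuracy", {
  set.seed(7)
  n <- 500
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- sample(rep(c(1, 0), each = n / 2))
  m <- train_classifier(x, y, folds = 10, seed = 7)
  expect_lt(abs(m$provenance$cv_accuracy_best - 0.5), 0.08)
})

test_that("probabilities equal the closed-form logistic of the linear predictor", {
  set.seed(52)
  w <- rnorm(11)
  model <- structure(list(weights = stats::setNames(w, feature_names()),
                          intercept = 0.3, feature_names = feature_names(),
                          standardize = NULL, cutoff = 0.5),
                     class = "lnc_model")
  x <- matrix(rnorm(20 * 11), 20, 11, dimnames = list(NULL, feature_names()))
  p <- predict_proba(model, x)
  expect_equal(p, as.numeric(1 / (1 + exp(-(x %*% w + 0.3)))),
               tolerance = 1e-12)
  # zero weights -> 0.5 everywhere; saturation -> ~1
  model0 <- model; model0$weights[] <- 0; model0$intercept <- 0
  expect_equal(predict_proba(model0, x), rep(0.5, 20))
  model1 <- model; model1$intercept <- 1e4
  expect_true(all(predict_proba(model1, x) > 1 - 1e-10))
})

test_that("column mismatches are reported by name", {
  model <- structure(list(weights = c(a = 1, b = 2), intercept = 0,
                          feature_names = c("a", "b"), standardize = NULL),
                     class = "lnc_model")
  x <- matrix(0, 2, 2, dimnames = list(NULL, c("a", "zzz")))
  expect_error(predict_proba(model, x), "missing \\[b\\].*extra \\[zzz\\]")
  # named columns in a different order are realigned
  x2 <- matrix(c(1, 1, 0, 0), 2, 2, dimnames = list(NULL, c("b", "a")))
  expect_equal(predict_proba(model, x2), rep(stats::plogis(2), 2))
})

test_that("classification respects the >= cutoff boundary", {
  expect_equal(classify(c(0.5654, 0.5653, 0.9), 0.5654),
               c("coding", "noncoding", "coding"))
  expect_true(all(classify(c(0.1, 0.2), 0.9) == "noncoding"))
  expect_error(classify(0.5, 1.5), "cutoff")
  expect_error(classify(0.5, 0), "cutoff")
  p <- runif(50)
  expect_equal(classify(p, 0.3), ifelse(p >= 0.3, "coding", "noncoding"))
})

test_that("species presets match the packaged operating cutoffs", {
  expect_equal(default_cutoff("human"), 0.5654)
  expect_equal(default_cutoff("mouse"), 0.4567)
})

test_that("training errors are actionable", {
  x <- matrix(rnorm(100 * 2), 100, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(train_classifier(x, rep("coding", 100), folds = 5),
               "both classes")
  x2 <- x; x2[3, 2] <- NA
  expect_error(train_classifier(x2, rep(c("coding", "noncoding"), 50),
                                folds = 5), "row 3.*column 'b'")
})

test_that("models round-trip through JSON and reapply identically", {
  set.seed(53)
  ds <- generate_dataset(generator_config(seed = 53, n_coding = 30,
                                          n_noncoding = 30))
  hx <- hexamer_training_sequences(ds)
  tab <- build_hexamer_table(hx$cds_seqs, hx$noncoding_seqs)
  x <- feature_matrix(tab, ds$records)
  y <- vapply(ds$records, `[[`, character(1), "label")
  m <- train_classifier(x, y, folds = 5, seed = 1, hexamer_table = tab)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_equal(m2$intercept, m$intercept, tolerance = 1e-12)
  expect_equal(m2$C, m$C)
  expect_equal(m2$cutoff, m$cutoff)
  expect_identical(m2$feature_names, m$feature_names)
  expect_equal(predict_proba(m2, x), predict_proba(m, x), tolerance = 1e-12)
  # corrupt file: parse error, no partial model
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(readLines(f), collapse = ""), 1, 500), bad)
  expect_error(load_model(bad))
  # version gate
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$provenance$format_version <- "0.9"
  jsonlite::write_json(obj, bad, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(load_model(bad), "format version")
})

test_that("CV selection is deterministic and prefers stronger regularization on ties", {
  set.seed(54)
  x <- matrix(rnorm(120 * 3), 120, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c("coding", "noncoding"), 60)
  m1 <- train_classifier(x, y, folds = 6, seed = 9)
  m2 <- train_classifier(x, y, folds = 6, seed = 9)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$C, m2$C)
  expect_identical(m1$provenance$cv_accuracy, m2$provenance$cv_accuracy)
  acc <- m1$provenance$cv_accuracy
  expect_equal(m1$C, min(m1$provenance$C_grid[acc == max(acc)]))
})

test_that("raising a positive-weight feature never lowers the probability", {
  set.seed(55)
  ds <- generate_dataset(generator_config(seed = 55, n_coding = 40,
                                          n_noncoding = 40))
  tab <- shared_table()
  x <- feature_matrix(tab, ds$records)
  y <- vapply(ds$records, `[[`, character(1), "label")
  m <- train_classifier(x, y, folds = 5, seed = 2)
  pos <- names(which(m$weights > 0))[1]
  x2 <- x
  x2[, pos] <- x2[, pos] + 1
  expect_true(all(predict_proba(m, x2) >= predict_proba(m, x)))
})
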