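test_that("accuracy is the percentage of matching labels", {
  expect_equal(accuracy(c(rep("a", 95), rep("b", 5)), rep("a", 100)), 95)
  expect_equal(accuracy(1:4, 1:4), 100)
  expect_equal(accuracy(rep(1, 4), rep(2, 4)), 0)
  expect_error(accuracy(integer(), integer()), "empty")
  expect_error(accuracy(1:3, 1:4), "differ")
})

test_that("stratified folds deal each class round-robin with counts differing by <= 1", {
  cfg <- cv_config(folds = 10, seed = 1)
  set.seed(1)
  lab <- c(rep(1, 60), rep(2, 40))
  fold <- stratified_folds(lab, cfg)
  for (f in 1:10) {
    expect_identical(sum(lab == 1 & fold == f), 6L)
    expect_identical(sum(lab == 2 & fold == f), 4L)
  }

  # 306 rows split 225/81 (the survival-study class structure)
  lab2 <- c(rep(1, 225), rep(2, 81))
  set.seed(2)
  fold2 <- stratified_folds(lab2, cfg)
  c1 <- table(fold2[lab2 == 1])
  c2 <- table(fold2[lab2 == 2])
  expect_true(all(c1 %in% c(22, 23)))
  expect_true(all(c2 %in% c(8, 9)))
  expect_identical(sum(c1) + sum(c2), 306L)
  expect_identical(sort(unique(fold2)), 1:10)

  set.seed(7); a <- stratified_folds(lab2, cfg)
  set.seed(7); b <- stratified_folds(lab2, cfg)
  expect_identical(a, b)
  set.seed(8); d <- stratified_folds(lab2, cfg)
  expect_false(identical(a, d))
  expect_error(stratified_folds(rep(1, 5), cv_config(folds = 10)), "fewer instances")
})

test_that("cross-validation is perfect on 10-sigma-separated blobs", {
  fs <- make_blobs(blob_spec(means = rbind(c(-10, 0), c(10, 0)), sigma = 1,
                             counts = c(50, 50), seed = 5))
  res <- cross_validate(fs, "chat-ohm", cv_config(folds = 10, repeats = 3, seed = 4))
  expect_equal(res$mean, 100)
  expect_true(all(res$rates == 100))
})

test_that("a constant classifier scores exactly the majority share under even stratification", {
  fs <- make_blobs(blob_spec(means = rbind(c(0, 0), c(1, 1)), sigma = 3,
                             counts = c(70, 30), seed = 2))
  constant <- list(fit = function(d) d$label_map[1],
                   predict = function(model, X) rep(model, nrow(X)))
  res <- cross_validate(fs, constant, cv_config(folds = 10, repeats = 2, seed = 3))
  expect_equal(res$mean, 70)
  expect_true(all(res$rates == 70))
})

test_that("cross-validation is deterministic in the master seed and every instance is tested once", {
  fs <- random_blob_set(61, sep = 3, counts = c(18, 12), n = 2)
  cfg <- cv_config(folds = 5, repeats = 3, seed = 42)
  a <- cross_validate(fs, "chat-ohm", cfg)
  b <- cross_validate(fs, "chat-ohm", cfg)
  expect_identical(a, b)
  expect_equal(a$mean, mean(a$rates))
  expect_equal(a$per_repeat_means, rowMeans(a$rates), ignore_attr = TRUE)

  # fold partition: folds cover all rows exactly once
  set.seed(4242)
  fold <- stratified_folds(fs$labels, cfg)
  expect_identical(length(fold), nrow(fs$X))
  expect_identical(sum(tabulate(fold, 5)), nrow(fs$X))
  expect_true(all(fold %in% 1:5))
})

test_that("per-fold preprocessing fits statistics on training folds only", {
  fs <- make_blobs(blob_spec(means = rbind(c(-6, 0), c(6, 0)), sigma = 1,
                             counts = c(20, 20), seed = 12))
  train_means <- list()
  probe <- list(
    fit = function(d) {
      train_means[[length(train_means) + 1]] <<- colMeans(d$X)
      d
    },
    predict = function(model, X) rep(model$label_map[1], nrow(X)))

  # per-fold mode: z-score statistics come from the training folds only, so
  # every training matrix the classifier sees is centered on itself
  invisible(cross_validate(fs, probe, cv_config(folds = 5, repeats = 1, seed = 9),
                           stages = "normalize", per_fold = TRUE))
  expect_true(all(vapply(train_means, function(mu) max(abs(mu)) < 1e-10,
                         logical(1))))

  # global mode: statistics include the held-out fold, so training subsets
  # are generally NOT centered on themselves
  train_means <- list()
  invisible(cross_validate(fs, probe, cv_config(folds = 5, repeats = 1, seed = 9),
                           stages = "normalize", per_fold = FALSE))
  expect_true(any(vapply(train_means, function(mu) max(abs(mu)) > 1e-6,
                         logical(1))))

  # and per-fold wilson keeps the held-out fold intact: rates computed on
  # every test row (fold sizes sum to p per repeat)
  res2 <- cross_validate(fs, "chat-ohm", cv_config(folds = 5, repeats = 1, seed = 9),
                         stages = c("normalize", "wilson_edit"), per_fold = TRUE)
  expect_true(res2$mean >= 0 && res2$mean <= 100)
})

test_that("cross-validation results export to CSV and JSON", {
  fs <- random_blob_set(71, counts = c(10, 10), n = 2)
  res <- cross_validate(fs, "chat", cv_config(folds = 4, repeats = 2, seed = 5))
  csv <- tempfile(fileext = ".csv")
  cv_to_csv(res, csv)
  tab <- read.csv(csv)
  expect_identical(nrow(tab), 8L)
  expect_equal(mean(tab$accuracy), res$mean)
  js <- tempfile(fileext = ".json")
  cv_to_json(res, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$mean, res$mean)
})
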