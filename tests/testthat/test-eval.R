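test_that("confusion counts match brute-force pair counting", {
  labs <- c("a", "a", "b", "b", "a")
  pred <- c("a", "b", "b", "a", "a")
  cc <- confusion(labs, pred)
  for (cl in c("a", "b")) {
    tp <- fp <- tn <- fn <- 0
    for (i in seq_along(labs)) {
      if (labs[i] == cl && pred[i] == cl) tp <- tp + 1
      if (labs[i] != cl && pred[i] == cl) fp <- fp + 1
      if (labs[i] != cl && pred[i] != cl) tn <- tn + 1
      if (labs[i] == cl && pred[i] != cl) fn <- fn + 1
    }
    expect_equal(cc[[cl]], list(tp = tp, fp = fp, tn = tn, fn = fn))
  }

  perfect <- confusion(labs, labs)
  expect_true(all(vapply(perfect, function(k) k$fp + k$fn, 0) == 0))

  wrong <- confusion(c("a", "b"), c("b", "a"))
  expect_true(all(vapply(wrong, function(k) k$tp + k$tn, 0) == 0))

  expect_error(confusion(labs, c("a", "a", "c", "b", "a")), "unknown")
})

test_that("macro metrics reproduce the degenerate-predictor closed forms", {
  # constant majority-class predictor, 11 of 18 in the majority
  cc <- confusion(rep(c("alc", "ctl"), c(11, 7)), rep("alc", 18))
  m <- macro_metrics(cc)
  expect_equal(round(m[["accuracy"]], 2), 61.11)
  expect_equal(round(m[["precision"]], 2), 30.56)
  expect_equal(round(m[["recall"]], 2), 50.00)
  expect_equal(round(m[["f1"]], 2), 37.93)

  # constant minority-class predictor, 7 of 18
  m2 <- macro_metrics(confusion(rep(c("alc", "ctl"), c(11, 7)),
                                rep("ctl", 18)))
  expect_equal(round(m2[["accuracy"]], 2), 38.89)
  expect_equal(round(m2[["precision"]], 2), 19.44)
  expect_equal(round(m2[["f1"]], 2), 28.00)
  expect_equal(m2[["recall"]], 50)

  perfect <- macro_metrics(confusion(rep(c("a", "b"), 5), rep(c("a", "b"), 5)))
  expect_equal(unname(perfect), rep(100, 4))
})

test_that("constant predictors have macro recall exactly 50", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(4:40, 1)
    labs <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    m <- macro_metrics(confusion(labs, rep("a", n)))
    expect_equal(m[["recall"]], 50)
    expect_equal(m[["accuracy"]], 100 * mean(labs == "a"))
    expect_equal(m[["precision"]], m[["accuracy"]] / 2)
  }
})

test_that("accuracy is invariant to class renaming", {
  labs <- rep(c("a", "b"), c(6, 4))
  pred <- c(rep("a", 5), rep("b", 5))
  m1 <- macro_metrics(confusion(labs, pred))
  swap <- c(a = "z", b = "q")
  m2 <- macro_metrics(confusion(swap[labs], swap[pred]))
  expect_equal(m1[["accuracy"]], m2[["accuracy"]])
  expect_equal(m1[["recall"]], m2[["recall"]])
})

test_that("perfectly separable data scores 100 +/- 0 with kNN", {
  x <- matrix(c(seq(0, 1, length.out = 20), seq(5, 6, length.out = 20)),
              ncol = 1)
  y <- rep(c("control", "alcoholic"), each = 20)
  ev <- evaluate(x, y, "knn", n_splits = 5, seed = 3, n_iter = 3,
                 inner_folds = 5)
  expect_equal(unname(ev$mean["accuracy"]), 100)
  expect_equal(unname(ev$sd["accuracy"]), 0)
  expect_s3_class(ev, "eeg_eval")
  expect_identical(nrow(ev$per_split), 5L)
})

test_that("label-shuffled features hover at chance level", {
  set.seed(12)
  x <- matrix(rnorm(60 * 4), 60, 4)
  y <- sample(rep(c("control", "alcoholic"), each = 30))
  ev <- evaluate(x, y, "nb", n_splits = 10, seed = 5)
  sigma <- max(ev$sd[["accuracy"]] / sqrt(ev$n_splits), 1)
  expect_lt(abs(ev$mean[["accuracy"]] - 50), 3 * ev$sd[["accuracy"]] + 3 * sigma)
})

test_that("evaluation is reproducible and records chosen parameters", {
  set.seed(13)
  x <- matrix(rnorm(80), 40, 2); x[1:20, 1] <- x[1:20, 1] + 3
  y <- rep(c("a", "b"), each = 20)
  a <- evaluate(x, y, "knn", n_splits = 3, seed = 9, n_iter = 3,
                inner_folds = 5)
  b <- evaluate(x, y, "knn", n_splits = 3, seed = 9, n_iter = 3,
                inner_folds = 5)
  expect_identical(a$per_split, b$per_split)
  expect_identical(a$chosen_params, b$chosen_params)
  expect_length(a$chosen_params, 3)
  expect_true(all(vapply(a$chosen_params, function(p)
    p$k %in% seq(3, 15, 2), TRUE)))
  expect_error(evaluate(x, rep("a", 40), "knn"), "two classes")
})
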