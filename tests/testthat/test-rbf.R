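test_that("the 2:1:1 split follows the allocation rule", {
  s400 <- split_cohort(paste0("c", 1:400), seed = 1)
  expect_identical(unname(lengths(s400)), c(200L, 100L, 100L))
  s4 <- split_cohort(letters[1:4], seed = 1)
  expect_identical(unname(lengths(s4)), c(2L, 1L, 1L))
  s619 <- split_cohort(paste0("c", 1:619), seed = 9)
  expect_identical(unname(lengths(s619)), c(309L, 154L, 156L))

  # disjoint, exhaustive, deterministic
  all_ids <- unname(unlist(s619))
  expect_identical(sort(all_ids), sort(paste0("c", 1:619)))
  expect_identical(split_cohort(paste0("c", 1:619), seed = 9), s619)
  expect_false(identical(split_cohort(paste0("c", 1:619), seed = 10), s619))

  expect_error(split_cohort(letters[1:3], seed = 1), "at least 4")
})

test_that("min-max scaling hits the bounds and inverts exactly", {
  expect_identical(minimax_scale(2, 2, 10), 0)
  expect_identical(minimax_scale(10, 2, 10), 1)
  set.seed(12)
  v <- runif(100, -50, 50)
  expect_equal(minimax_unscale(minimax_scale(v, -3, 17), -3, 17), v,
               tolerance = 1e-12)
})

test_that("constant targets give zero unit weights and constant output", {
  tf <- tiny_features()
  m <- fit_rbf(tf$x, rep(100, nrow(tf$x)), H = 3, seed = 2)
  H <- length(m$widths)
  expect_equal(m$weights[seq_len(H)], rep(0, H), tolerance = 1e-6)
  expect_equal(predict(m, tf$x), rep(100, nrow(tf$x)), tolerance = 1e-6)
})

test_that("H = n_train with ridge 0 interpolates the training data", {
  tf <- tiny_features(n = 10)
  m <- fit_rbf(tf$x, tf$y, H = nrow(tf$x), seed = 3, ridge = 0)
  expect_lt(rmse_scaled(m, tf$x, tf$y), 1e-6)
  expect_error(fit_rbf(tf$x, tf$y, H = nrow(tf$x) + 1, seed = 1),
               "exceeds")
})

test_that("output weights solve the assembled normal equations", {
  for (seed in 1:3) {
    tf <- tiny_features(n = 5 + seed, seed = seed)
    ridge <- 1e-6
    m <- fit_rbf(tf$x, tf$y, H = 2, seed = seed, ridge = ridge)
    phi <- oracle_activations(m, tf$x)
    A <- cbind(phi, 1)
    ys <- (tf$y - m$scale$ymin) / (m$scale$ymax - m$scale$ymin)
    w <- solve(crossprod(A) + ridge * diag(c(1, 1, 0)), crossprod(A, ys))
    expect_equal(m$weights, drop(w), tolerance = 1e-8)
  }
})

test_that("training RMSE is non-increasing over nested center sets", {
  tf <- tiny_features(n = 12, seed = 9)
  scale <- dentage:::fit_scale_params(tf$x, tf$y)
  xs <- dentage:::scale_inputs(tf$x, scale)
  ys <- minimax_scale(tf$y, scale$ymin, scale$ymax)
  all_centers <- unique(xs)[1:6, , drop = FALSE]
  wid_all <- dentage:::choose_widths(all_centers, xs, 2)
  rmse <- vapply(1:6, function(H) {
    ctr <- all_centers[1:H, , drop = FALSE]
    wid <- wid_all[1:H]
    phi <- dentage:::rbf_activations(xs, ctr, wid)
    w <- dentage:::solve_output_weights(phi, ys, 0)
    sqrt(mean((cbind(phi, 1) %*% w - ys)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) <= 1e-10))
})

test_that("predictions follow the hand-evaluated RBF form", {
  tf <- tiny_features(n = 6)
  # zero weights, bias b: every prediction is the inverse-scaled bias
  m <- fit_rbf(tf$x, tf$y, H = 2, seed = 1)
  m$weights <- c(0, 0, 0.25)
  expect_equal(predict(m, tf$x),
               rep(minimax_unscale(0.25, m$scale$ymin, m$scale$ymax), 6),
               tolerance = 1e-12)

  # single hand-built unit: center, width 1, weight 1, bias 0
  m1 <- fit_rbf(tf$x, tf$y, H = 1, seed = 1)
  m1$centers[1, ] <- 0.5
  m1$widths <- 1
  m1$weights <- c(1, 0)
  xs <- dentage:::scale_inputs(tf$x, m1$scale)
  g <- exp(-rowSums((xs - 0.5)^2) / 2)
  expect_equal(predict(m1, tf$x),
               minimax_unscale(g, m1$scale$ymin, m1$scale$ymax),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(predict(m1, tf$x[, 1:2]), "missing model input")
})

test_that("degenerate inputs and capacity are rejected", {
  tf <- tiny_features()
  xc <- cbind(tf$x, CONST = 1)
  expect_error(fit_rbf(xc, tf$y, H = 2), "CONST")
})

test_that("clamping restricts predictions to the validity window", {
  tf <- tiny_features(n = 12, seed = 2)
  y <- seq(40, 180, length.out = 12)  # wider than the window on purpose
  m <- fit_rbf(tf$x, y, H = 3, seed = 1)
  p <- predict(m, tf$x, clamp = TRUE)
  expect_true(all(p >= 48 & p <= 144))
})

test_that("quality is the prediction-target correlation", {
  expect_equal(quality(1:10, 1:10), 1, tolerance = 1e-12)
  expect_equal(quality(-(1:10), 1:10), -1, tolerance = 1e-12)
  pred <- c(1, 2, 3, 4); obs <- c(1, 2, 4, 3)
  # direct formula oracle
  r <- sum((pred - mean(pred)) * (obs - mean(obs))) /
    sqrt(sum((pred - mean(pred))^2) * sum((obs - mean(obs))^2))
  expect_equal(quality(pred, obs), r, tolerance = 1e-12)
  expect_error(quality(rep(1, 4), 1:4), "zero variance")
  expect_error(quality(1, 1), "at least 2")
})

test_that("scaled RMSE matches hand-computed values", {
  tf <- tiny_features(n = 6)
  m <- fit_rbf(tf$x, tf$y, H = nrow(tf$x), seed = 1, ridge = 0)
  expect_lt(rmse_scaled(m, tf$x, tf$y), 1e-6)

  # constant offset delta in scaled units
  span <- m$scale$ymax - m$scale$ymin
  expect_equal(rmse_scaled(m, tf$x, tf$y + 0.1 * span), 0.1,
               tolerance = 1e-6)

  # 3-case direct formula
  p <- predict(m, tf$x[1:3, ])
  y3 <- tf$y[1:3] + c(1, -2, 3)
  expect_equal(rmse_scaled(m, tf$x[1:3, ], y3),
               sqrt(mean(((p - y3) / span)^2)), tolerance = 1e-9)

  expect_error(rmse_scaled(m, tf$x[0, , drop = FALSE], numeric(0)),
               "empty")
})

test_that("topology strings parse and format both ways", {
  expect_identical(parse_topology("RBF 22:22-15-1:1"),
                   c(inputs = 22L, hidden = 15L, outputs = 1L))
  expect_identical(parse_topology("RBF 13:13-1-1:1"),
                   c(inputs = 13L, hidden = 1L, outputs = 1L))
  expect_identical(format_topology(18, 1), "RBF 18:18-1-1:1")
  for (s in c("RBF 22:22-15-1:1", "RBF 13:13-1-1:1", "RBF 18:18-1-1:1")) {
    p <- parse_topology(s)
    expect_identical(format_topology(p["inputs"], p["hidden"]), s)
  }
  expect_error(parse_topology("RBF 22-15-1"), "malformed")
  expect_error(parse_topology("RBF 22:21-15-1:1"), "malformed")
})

test_that("designer search ranks by validation error with diversity", {
  co <- small_cohort(30, 30)
  f <- assemble_features(co)
  s <- split_cohort(rownames(f$x), seed = 4)
  kept <- designer_search(f, s, H_candidates = c(2, 4, 8),
                          n_test = 20, n_retain = 10, seed = 4)
  expect_lte(length(kept), 10L)
  rmses <- vapply(kept, `[[`, numeric(1), "valid_rmse")
  expect_false(is.unsorted(rmses))
  expect_true(all(table(vapply(kept, `[[`, integer(1), "H")) <= 5))

  # deterministic
  again <- designer_search(f, s, H_candidates = c(2, 4, 8),
                           n_test = 20, n_retain = 10, seed = 4)
  expect_identical(lapply(kept, `[[`, "model"),
                   lapply(again, `[[`, "model"))

  one <- designer_search(f, s, H_candidates = 3, n_test = 1, n_retain = 1,
                         seed = 4)
  expect_length(one, 1L)
  expect_error(designer_search(f, s, integer(0)), "non-empty")
})

test_that("search never loses to the single-unit candidate", {
  # noiseless linear target: exhaustive oracle over the same grid
  set.seed(6)
  x <- matrix(runif(120), 60, 2, dimnames = list(paste0("c", 1:60),
                                                 c("V1", "V2")))
  y <- 50 + 40 * x[, 1]
  f <- structure(list(x = x, y = setNames(y, rownames(x)),
                      names = colnames(x)), class = "feature_set")
  s <- split_cohort(rownames(x), seed = 2)
  kept <- designer_search(f, s, H_candidates = c(1, 3, 6), n_test = 12,
                          n_retain = 6, seed = 2)
  tr <- dentage:::feature_rows(f, s$train)
  va <- dentage:::feature_rows(f, s$valid)
  h1 <- fit_rbf(tr$x, tr$y, H = 1, seed = 2)
  expect_lte(kept[[1]]$valid_rmse, rmse_scaled(h1, va$x, va$y) + 1e-12)
})

test_that("model reports carry six partition metrics", {
  co <- small_cohort(20, 20, seed = 3)
  f <- assemble_features(co)
  s <- split_cohort(rownames(f$x), seed = 3)
  tr <- dentage:::feature_rows(f, s$train)
  m <- fit_rbf(tr$x, tr$y, H = nrow(tr$x), seed = 3, ridge = 0)
  rep <- model_report(m, f, s)
  expect_identical(rep$metric,
                   c("training quality", "validation quality",
                     "testing quality", "training error",
                     "validation error", "testing error"))
  expect_equal(rep$value[rep$metric == "training quality"], 1,
               tolerance = 1e-6)
  expect_lt(rep$value[rep$metric == "training error"], 1e-6)

  # invariant to case order within partitions
  s2 <- s
  s2$train <- rev(s2$train); s2$test <- sample(s2$test)
  expect_equal(model_report(m, f, s2), rep, tolerance = 1e-12)
})

test_that("saved models reload and predict identically", {
  tf <- tiny_features(n = 9)
  m <- fit_rbf(tf$x, tf$y, H = 4, seed = 8)
  f <- withr::local_tempfile(fileext = ".json")
  save_rbf(m, f)
  m2 <- load_rbf(f)
  set.seed(10)
  probe <- matrix(runif(150), 50, 3, dimnames = list(NULL, colnames(tf$x)))
  expect_equal(predict(m2, probe), predict(m, probe), tolerance = 1e-12)

  # byte-identical re-save
  f2 <- withr::local_tempfile(fileext = ".json")
  save_rbf(m2, f2)
  expect_identical(readLines(f2), readLines(f))

  # schema guards
  doc <- jsonlite::fromJSON(readLines(f), simplifyVector = FALSE)
  doc$widths <- NULL
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), f2)
  expect_error(load_rbf(f2), "widths")
  doc$schema_version <- 99
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), f2)
  expect_error(load_rbf(f2), "schema")
})

test_that("identical seeds reproduce the whole fit", {
  tf <- tiny_features(n = 20, seed = 13)
  m1 <- fit_rbf(tf$x, tf$y, H = 5, seed = 42)
  m2 <- fit_rbf(tf$x, tf$y, H = 5, seed = 42)
  expect_identical(m1, m2)
})
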