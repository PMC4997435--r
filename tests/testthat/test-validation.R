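test_that("outlier removal keeps values at the threshold and drops those
           strictly above", {
  s <- st_samples(data.frame(site_id = c("a", "b", "c", "d"),
                             x = c(0, 1, 0, 1), y = c(0, 0, 1, 1),
                             t = c(1L, 1L, 2L, 2L),
                             w = c(10, 250, 250.1, 3)))
  res <- remove_outliers(s)
  expect_equal(res$removed, 1L)
  expect_setequal(res$samples$w, c(10, 250, 3))
  all_in <- remove_outliers(s, threshold = 1000)
  expect_equal(all_in$removed, 0L)
  expect_equal(nrow(all_in$samples), 4L)
})

test_that("fold sizes are near-equal and assignments reproducible", {
  f <- kfold_split(100, 10, seed = 1)
  expect_equal(unname(table(f$fold_of)), rep(10L, 10), ignore_attr = TRUE)
  f2 <- kfold_split(103, 10, seed = 1)
  sizes <- sort(as.integer(table(f2$fold_of)))
  expect_equal(sizes, c(rep(10L, 7), rep(11L, 3)))
  expect_identical(kfold_split(57, 10, seed = 7)$fold_of,
                   kfold_split(57, 10, seed = 7)$fold_of)
  expect_false(identical(kfold_split(57, 10, seed = 7)$fold_of,
                         kfold_split(57, 10, seed = 8)$fold_of))
  expect_error(kfold_split(5, 10), "cannot split")
})

test_that("error statistics match a loop-based recomputation", {
  withr::with_seed(41, {
    for (rep in 1:100) {
      n <- sample(3:40, 1)
      O <- runif(n, 0.5, 30)
      I <- O + rnorm(n, 0, 3)
      got <- error_stats(I, O)
      expect_equal(got, loop_stats(I, O), tolerance = 1e-12)
    }
  })
})

test_that("error statistics handle the worked example and the degenerate
           cases", {
  st <- error_stats(c(2, 2, 2), c(1, 2, 3))
  expect_equal(unname(st["mae"]), 2 / 3)
  expect_equal(unname(st["mse"]), 2 / 3)
  expect_equal(unname(st["rmse"]), sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(unname(st["mare"]), 4 / 9, tolerance = 1e-12)
  expect_equal(unname(st["r2cv"]), 0)
  # perfect prediction on a nonconstant set
  expect_equal(unname(error_stats(c(1, 2, 3), c(1, 2, 3))),
               c(0, 0, 0, 0, 1))
  # constant observed set with imperfect predictions: clamp to 0
  expect_warning(st0 <- error_stats(c(1, 2), c(5, 5)), "constant")
  expect_equal(unname(st0["r2cv"]), 0)
  expect_error(error_stats(c(1, 2), c(1, 0)), "> 0")
  expect_error(error_stats(numeric(0), numeric(0)), "empty")
  expect_error(error_stats(1:3, 1:2), "equal length")
})

test_that("cross-validation scores a smooth field well and is internally
           consistent", {
  f <- function(x, y, t) 8 + 3 * x + 2 * y + 0.2 * t
  s <- st_samples(make_cloud(150, seed = 44, value_fn = f))
  r_idw <- cross_validate(s, "idw", time_scale(0.1), k = 5,
                          n_neighbors = 4, exponent = 2)
  expect_lt(r_idw$averaged[["mae"]], (max(s$w) - min(s$w)) / 20)
  expect_equal(r_idw$per_fold$rmse, sqrt(r_idw$per_fold$mse),
               tolerance = 1e-9)
  expect_equal(unname(r_idw$averaged["mae"]), mean(r_idw$per_fold$mae))
  r_sf <- cross_validate(s, "sf", time_scale(0.1), k = 5)
  expect_lt(r_sf$averaged[["mae"]], 1e-8)  # linear reproduction
  # determinism and seed sensitivity
  again <- cross_validate(s, "idw", time_scale(0.1), k = 5,
                          n_neighbors = 4, exponent = 2)
  expect_identical(r_idw$per_fold, again$per_fold)
  other <- cross_validate(s, "idw", time_scale(0.1), k = 5, seed = 99,
                          n_neighbors = 4, exponent = 2)
  expect_false(identical(r_idw$per_fold$mae, other$per_fold$mae))
})

test_that("leave-one-out cross-validation equals a hand-rolled loop", {
  s <- st_samples(make_cloud(30, seed = 46))
  sc <- time_scale(0.1)
  got <- suppressWarnings(
    cross_validate(s, "idw", sc, k = 30, n_neighbors = 3, exponent = 2))
  hand <- t(vapply(seq_len(30), function(i) {
    pred <- brute_idw(s[-i, ], s[i, , drop = FALSE], 3, 2, sc)
    suppressWarnings(error_stats(pred, s$w[i]))
  }, numeric(5)))
  # folds are singletons, so sorting per-fold MAEs aligns the two loops
  expect_equal(sort(got$per_fold$mae), sort(hand[, "mae"]),
               tolerance = 1e-12)
  expect_equal(unname(got$averaged["mae"]), mean(hand[, "mae"]),
               tolerance = 1e-12)
})

test_that("averaged statistics are invariant to fold relabeling", {
  s <- st_samples(make_cloud(60, seed = 47))
  folds <- kfold_split(60, 5, seed = 2)
  relab <- folds
  perm <- c(3L, 5L, 1L, 2L, 4L)
  relab$fold_of <- perm[folds$fold_of]
  a <- cross_validate(s, "idw", time_scale(0.1), n_neighbors = 3,
                      exponent = 2, folds = folds)
  b <- cross_validate(s, "idw", time_scale(0.1), n_neighbors = 3,
                      exponent = 2, folds = relab)
  expect_equal(a$averaged, b$averaged, tolerance = 1e-12)
})

test_that("grid search ranks deterministically and matches the plain
           cross-validation path", {
  s <- st_samples(make_cloud(80, seed = 48))
  gs <- grid_search(s, "idw", scales = list(time_scale(0.1)),
                    n_neighbors = c(3, 5), exponents = c(1, 2),
                    criterion = "mare", k = 5)
  expect_equal(nrow(gs$table), 4L)
  expect_equal(gs$table$rank, 1:4)
  expect_false(is.unsorted(gs$table$mare))
  # the fast shared-neighbour path must equal cross_validate exactly
  folds <- kfold_split(80, 5, seed = gs$seed)
  ref <- cross_validate(s, "idw", time_scale(0.1), n_neighbors = 3,
                        exponent = 2, folds = folds)
  row <- gs$table[gs$table$n_neighbors == 3 & gs$table$exponent == 2, ]
  expect_equal(row$mare, unname(ref$averaged["mare"]), tolerance = 1e-12)
  expect_equal(row$rmse, unname(ref$averaged["rmse"]), tolerance = 1e-12)
  # repeatability under the same seed
  gs2 <- grid_search(s, "idw", scales = list(time_scale(0.1)),
                     n_neighbors = c(3, 5), exponents = c(1, 2),
                     criterion = "mare", k = 5)
  expect_identical(gs$table, gs2$table)
  # structural shapes: one report per scale for SF, single row degenerate
  gs_sf <- grid_search(s, "sf", scales = time_scale_presets(), k = 5)
  expect_equal(length(gs_sf$reports), 4L)
  gs1 <- grid_search(s, "idw", scales = list(time_scale(0.1)),
                     n_neighbors = 3, exponents = 2, k = 5)
  expect_equal(nrow(gs1$table), 1L)
  expect_error(grid_search(s, "idw", criterion = "banana"))
  # r2cv ranks descending
  gsr <- grid_search(s, "idw", scales = list(time_scale(0.1)),
                     n_neighbors = c(3, 5), exponents = c(1, 2),
                     criterion = "r2cv", k = 5)
  expect_false(is.unsorted(-gsr$table$r2cv))
})
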