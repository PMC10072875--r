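test_that("outlier removal drops only trials beyond 10x the mean SD", {
  withr::with_seed(1, base <- matrix(rnorm(20 * 50, sd = 1), 20, 50))
  out <- remove_outliers(base)
  expect_equal(attr(out, "dropped"), integer(0))
  # one wild trial at 20x the group mean SD is removed
  bad <- rbind(base, rnorm(50, sd = 40))
  out2 <- remove_outliers(bad)
  expect_equal(attr(out2, "dropped"), 21L)
  expect_equal(nrow(out2), 20)
  # exactly at the factor: retained (strict inequality). With n unit-scale
  # rows plus one at scale s, s sits on the boundary when
  # s = 10 * (n + s) / (n + 1), i.e. s = 10n / (n - 9); n = 15 gives s = 25.
  pattern <- rep(c(-1, 1), 25)
  rows <- matrix(pattern, 15, 50, byrow = TRUE)
  probe <- rbind(rows, pattern * 25)
  expect_equal(attr(remove_outliers(probe), "dropped"), integer(0))
  # epsilon beyond the boundary is dropped
  probe2 <- rbind(rows, pattern * 25.01)
  expect_equal(attr(remove_outliers(probe2), "dropped"), 16L)
})

test_that("min/max normalization maps to [0,1] and exempts raw extremes", {
  d <- tibble::tibble(
    f_base_mean = c(2, 4, 6), f_cue_mean = c(-1, 0, 3),
    f_base_min = c(5, 6, 7), f_cue_max = c(1, 2, 9),
    label = c("a", "b", "a"))
  out <- normalize_features(d)
  expect_equal(out$f_base_mean, c(0, 0.5, 1))
  expect_equal(range(out$f_cue_mean), c(0, 1))
  expect_equal(out$f_base_min, c(5, 6, 7)) # untouched
  expect_equal(out$f_cue_max, c(1, 2, 9)) # untouched
  expect_identical(out$label, d$label)
  # constant column dropped with a warning
  d$f_cue_sd <- 1
  expect_warning(out2 <- normalize_features(d), "constant")
  expect_false("f_cue_sd" %in% names(out2))
})

test_that("SMOTE+Tomek reaches near 50:50 from 10/90 imbalance", {
  d <- make_feature_matrix(200, 20, seed = 5)
  bal <- rebalance(d, seed = 7)
  expect_gte(minority_fraction(bal), 0.45)
  expect_lte(minority_fraction(bal), 0.55)
  expect_gt(nrow(bal), 200)
})

test_that("synthetic points are convex combinations of minority neighbours", {
  d <- make_feature_matrix(60, 10, p = 4, seed = 2)
  bal <- rebalance(d, seed = 3)
  cols <- paste0("f_", 1:4)
  x_min <- as.matrix(d[d$label == "minority", cols])
  synth <- as.matrix(bal[attr(bal, "is_synthetic"), cols])
  expect_equal(nrow(synth), attr(bal, "n_synthetic"))
  for (i in seq_len(nrow(synth))) {
    # a convex combination p + u(q - p) satisfies, per coordinate,
    # min(p,q) <= s <= max(p,q) for SOME minority pair p, q
    ok <- FALSE
    for (a in seq_len(nrow(x_min))) {
      p <- x_min[a, ]
      d_ap <- synth[i, ] - p
      for (b in seq_len(nrow(x_min))) {
        if (a == b) next
        q <- x_min[b, ]
        dir <- q - p
        u <- sum(d_ap * dir) / sum(dir * dir)
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            sqrt(sum((p + u * dir - synth[i, ])^2)) < 1e-8) {
          ok <- TRUE; break
        }
      }
      if (ok) break
    }
    expect_true(ok)
  }
})

test_that("rebalance is label-symmetric and leaves balanced input almost alone", {
  d <- make_feature_matrix(60, 10, p = 4, seed = 9)
  swapped <- d
  swapped$label <- ifelse(d$label == "minority", "majority", "minority")
  b1 <- rebalance(d, seed = 1)
  b2 <- rebalance(swapped, seed = 1)
  expect_equal(minority_fraction(b1), minority_fraction(b2))
  expect_equal(attr(b1, "n_synthetic"), attr(b2, "n_synthetic"))
  # balanced input: only Tomek removals can change the composition
  even <- make_feature_matrix(40, 20, p = 4, seed = 4)
  b3 <- rebalance(even, seed = 2)
  expect_equal(attr(b3, "n_synthetic"), 0L)
  expect_lte(nrow(even) - nrow(b3), attr(b3, "n_tomek_removed"))
})

test_that("separable labels decode near perfectly; same seed reproduces", {
  d <- make_feature_matrix(80, 30, p = 6, seed = 3, shift = 4)
  r1 <- crossval_auc(d, k = 5, repeats = 1, nrounds = 40, seed = 11)
  expect_gte(r1$mean_auc, 0.95)
  r2 <- crossval_auc(d, k = 5, repeats = 1, nrounds = 40, seed = 11)
  expect_identical(r1$fold_aucs, r2$fold_aucs)
  # seed changes reshuffle folds on non-separable data
  dn <- make_feature_matrix(80, 30, p = 6, seed = 3, shift = 0.5)
  n1 <- crossval_auc(dn, k = 5, repeats = 1, nrounds = 40, seed = 11)
  n2 <- crossval_auc(dn, k = 5, repeats = 1, nrounds = 40, seed = 12)
  expect_false(identical(n1$fold_aucs$auc, n2$fold_aucs$auc))
})

test_that("uninformative features stay at chance (no leakage through SMOTE)", {
  aucs <- vapply(1:4, function(seed) {
    d <- make_feature_matrix(100, 30, p = 8, seed = seed, shift = 0)
    crossval_auc(d, k = 5, repeats = 1, nrounds = 40, seed = seed)$mean_auc
  }, numeric(1))
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})

test_that("null model: permuted labels at chance; identity hook equals real", {
  d <- make_feature_matrix(80, 30, p = 6, seed = 6, shift = 4)
  real <- crossval_auc(d, k = 5, repeats = 2, nrounds = 40, seed = 2)
  nulled <- null_model(d, real, seed = 2)
  expect_gte(nulled$null$null_mean_auc, 0.35)
  expect_lte(nulled$null$null_mean_auc, 0.65)
  expect_lt(nulled$null$p_value, 0.01)
  # identity permutation reproduces the real folds exactly
  ident <- null_model(d, real, seed = 2, shuffle_fn = seq_len)
  expect_equal(ident$null$null_fold_aucs$auc, real$fold_aucs$auc)
})

test_that("tidy and glance expose the report in broom style", {
  d <- make_feature_matrix(60, 25, p = 4, seed = 8, shift = 3)
  r <- crossval_auc(d, k = 4, repeats = 1, nrounds = 20, seed = 1)
  r <- null_model(d, r, seed = 1)
  td <- tidy(r)
  expect_true(all(c("model", "rep", "fold", "auc") %in% names(td)))
  expect_equal(nrow(td), 8)
  gl <- glance(r)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$mean_auc, r$mean_auc)
  expect_false(is.na(gl$p_value))
})
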