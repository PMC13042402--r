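test_that("feature_dropout zeroes whole columns by the floor rule", {
  x <- toy_matrix(6, 10) + 1
  expect_identical(feature_dropout(x, 0, seed = 1)[, ], x[, ])
  expect_true(all(feature_dropout(x, 100, seed = 1) == 0))
  half <- feature_dropout(x, 50, seed = 2)
  zero_cols <- colSums(half == 0) == nrow(x)
  expect_equal(sum(zero_cols), 5)
  # zeroed columns are identical across samples; selection is seeded
  expect_identical(feature_dropout(x, 50, seed = 2), half)
  expect_equal(sum(colSums(feature_dropout(x, 37, seed = 3) == 0) == 6),
               floor(0.37 * 10))
})

test_that("ablation series is cumulative: each step masks a superset", {
  x <- toy_matrix(4, 6) + 1
  ranking <- paste0("g", c(3, 1, 5, 2, 6, 4)) # most important first
  series <- shap_ablation_series(x, ranking, "high_to_low")
  expect_length(series, 7)
  expect_identical(series$step0, x[, ])
  expect_true(all(series$step6 == 0))
  prev <- character(0)
  for (k in 1:6) {
    masked <- colnames(x)[colSums(series[[k + 1]] == 0) == nrow(x)]
    expect_true(all(prev %in% masked))
    expect_length(masked, k)
    prev <- masked
  }
  # high_to_low masks the top-ranked feature first
  expect_true(all(series$step1[, "g3"] == 0))
  low <- shap_ablation_series(x, ranking, "low_to_high", steps = 1)
  expect_true(all(low$step1[, "g4"] == 0))
  expect_error(shap_ablation_series(x, ranking[-1]), "cover")
})

test_that("mask_uniform hits the target count exactly and is seeded", {
  x <- toy_matrix(4, 4) + 1   # dense
  expect_identical(mask_uniform(x, 0, seed = 1), x[, ])
  m25 <- mask_uniform(x, 25, seed = 7)
  expect_equal(sum(m25 == 0), 4)
  expect_identical(mask_uniform(x, 25, seed = 7), m25)
  # surviving entries are untouched
  expect_true(all(m25[m25 != 0] == x[m25 != 0]))
  # target below current sparsity errors
  xs <- x; xs[1:8] <- 0
  expect_error(mask_uniform(xs, 10, seed = 1), "below the current")
  # target equal to current sparsity is the identity
  expect_identical(mask_uniform(xs, 50, seed = 1), xs[, ])
})

test_that("poisson_mask: gamma 0 reduces to uniform expected rates and
          larger expression means smaller dropout probability", {
  set.seed(3)
  x <- matrix(rexp(2000, rate = 0.2), 40, 50,
              dimnames = list(NULL, paste0("g", 1:50)))
  # gamma = 0: p = 1 everywhere, so s = sp_nz and every entry is equally
  # likely to drop; realized sparsity concentrates near the target
  reps <- vapply(1:6, function(s) sparsity(poisson_mask(x, 0, 30, seed = s)),
                 numeric(1))
  expect_lt(abs(mean(reps) - 0.30), 0.02)
  # monotonicity: dropout probability decreasing in expression for gamma > 0
  nz <- which(x != 0)
  p95 <- quantile(x[nz], 0.95, names = FALSE)
  p <- exp(-2 * pmax(x[nz] / p95, 1e-12))
  expect_true(all(diff(p[order(x[nz])]) <= 0))
  # seeded determinism
  expect_identical(poisson_mask(x, 0.5, 40, seed = 11),
                   poisson_mask(x, 0.5, 40, seed = 11))
  # only zeros are introduced, surviving values unchanged
  masked <- poisson_mask(x, 0.5, 40, seed = 11)
  expect_true(all(masked[masked != 0] == x[masked != 0]))
})

test_that("poisson_mask realized sparsity tracks the target within 2 points
          averaged over the default seeds", {
  set.seed(17)
  x <- matrix(rexp(300 * 200, 0.3), 300, 200)
  for (g in c(0.1, 0.5, 2)) {
    reps <- vapply(c(62, 567, 309, 39, 675, 42), function(s) {
      sparsity(suppressWarnings(poisson_mask(x, g, 50, seed = s)))
    }, numeric(1))
    expect_lt(abs(mean(reps) - 0.5), 0.02)
  }
})

test_that("gamma ordering: dropout concentrates in the lowest-expression
          decile as gamma grows", {
  set.seed(23)
  x <- matrix(rexp(5000, 0.2), 50, 100)
  cutoff <- quantile(x[x != 0], 0.1)
  frac_low_dropped <- vapply(c(0, 0.5, 2, 5), function(g) {
    masked <- suppressWarnings(poisson_mask(x, g, 40, seed = 9))
    dropped <- x != 0 & masked == 0
    low <- x != 0 & x <= cutoff
    sum(dropped & low) / sum(low)
  }, numeric(1))
  expect_true(all(diff(frac_low_dropped) >= -0.02))
  expect_gt(frac_low_dropped[4], frac_low_dropped[1])
})

test_that("umi_downsample draws multinomial pseudo-counts with the stated
          moments", {
  x <- matrix(c(10, 30, 60, 25, 25, 50), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
  # depth 1: exactly one nonzero entry per sample, value 1
  d1 <- umi_downsample(x, depth = 1, seed = 4)
  expect_true(all(rowSums(d1) == 1))
  expect_true(all(d1 %in% c(0L, 1L)))
  # large depth: count fractions converge to the probability vector
  big <- umi_downsample(x, depth = 1e7, seed = 4)
  expect_equal(big[1, ] / 1e7, x[1, ] / sum(x[1, ]), tolerance = 1e-3)
  # expectation over repeated draws ~ depth * p within 3 SE
  depth <- 500
  draws <- vapply(1:500, function(s) umi_downsample(x, depth = depth,
                                                    seed = s)[1, ],
                  numeric(3))
  p <- x[1, ] / sum(x[1, ])
  se <- sqrt(depth * p * (1 - p) / 500)
  expect_true(all(abs(rowMeans(draws) - depth * p) < 3 * se))
  expect_error(umi_downsample(matrix(0, 1, 2,
                                     dimnames = list("s", c("a", "b")))),
               "all-zero")
})

test_that("downsample_plus_poisson composes the two stages with the
          adjusted target", {
  # direct arithmetic of the adjustment: sp_down 0.5, target 0.8 -> 0.6
  expect_equal((0.8 - 0.5) / (1 - 0.5), 0.6)
  set.seed(31)
  x <- matrix(rexp(200 * 150, 0.1), 200, 150)
  out <- downsample_plus_poisson(x, 70, gamma = 0.5, seed = 6)
  sp_down <- attr(out, "sp_down")
  expect_equal(attr(out, "sp_target_adjusted"),
               (0.7 - sp_down) / (1 - sp_down))
  expect_lt(abs(sparsity(out) - 0.7), 0.02)
  # target equal to the down-sampling sparsity: Poisson stage is identity
  down_only <- umi_downsample(x, seed = 6)
  same <- downsample_plus_poisson(x, 100 * sparsity(down_only), seed = 6)
  expect_equal(same[, ], down_only[, ], ignore_attr = TRUE)
  expect_error(downsample_plus_poisson(x, 0.1, seed = 6), "below")
})

test_that("the stress grid reproduces the clean evaluation at level 0 and
          degrades monotonically under uniform masking", {
  sim <- tiny_bulk()
  fit <- tiny_fit()
  ho <- tiny_heldout()
  x_expr <- (2^ho$X - 1)   # back to FPKM scale
  grid <- stress_grid("mask_uniform", levels = c(0, 30, 60, 90),
                      seeds = c(62, 567))
  res <- run_stress_grid(fit, x_expr, ho$Y, grid)
  expect_equal(nrow(res), 8)
  expect_true(all(res$realized_sparsity_pre_z[res$level == 0] ==
                    sparsity(x_expr)))
  # level-0 rows equal the unperturbed pipeline exactly
  clean_pred <- predict(fit, unclass(zscore_genes(x_expr)))
  clean <- evaluate_predictions(unclass(zscore_genes(ho$Y)), clean_pred,
                                axis = "per_mirna")
  expect_equal(res$mean_pcc[res$level == 0],
               rep(clean$summary$mean_pcc, 2), tolerance = 1e-12)
  # post-z-score sparsity is 0 when no gene is constant
  expect_true(all(res$realized_sparsity_post_z == 0))
  # mean PCC non-increasing in level, per seed
  for (s in c(62, 567)) {
    curve <- res$mean_pcc[res$seed == s][order(res$level[res$seed == s])]
    expect_lte(cor(curve, sort(unique(res$level)), method = "spearman"), 0)
  }
})

test_that("stress grid rows carry regime labels consistent with metrics", {
  fit <- tiny_fit()
  ho <- tiny_heldout()
  x_expr <- (2^ho$X - 1)
  res <- run_stress_grid(fit, x_expr, ho$Y,
                         stress_grid("mask_uniform", levels = c(0, 95),
                                     seeds = 62))
  for (i in seq_len(nrow(res))) {
    expect_equal(res$regime[i],
                 classify_regime(res$mean_pcc[i], res$mean_r2[i]))
  }
  expect_gt(res$mean_pcc[res$level == 0], res$mean_pcc[res$level == 95])
})
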