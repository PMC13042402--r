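test_that("align_to_landmarks zero-fills missing panel genes and reports them", {
  panel <- paste0("g", 1:6)
  m <- toy_matrix(3, 4)          # g1..g4
  out <- align_to_landmarks(m, panel)
  expect_identical(colnames(out$x), panel)
  expect_setequal(out$missing, c("g5", "g6"))
  expect_true(all(unclass(out$x)[, c("g5", "g6")] == 0))
  expect_equal(unclass(out$x)[, 1:4], m, ignore_attr = TRUE)
  expect_equal(out$n_matched, 4L)
})

test_that("align_to_landmarks drops extras and preserves matched values", {
  panel <- paste0("g", 1:3)
  m <- toy_matrix(2, 5)          # g1..g5: g4, g5 are extras
  out <- align_to_landmarks(m, panel)
  expect_identical(colnames(out$x), panel)
  expect_setequal(out$dropped, c("g4", "g5"))
  expect_equal(unclass(out$x), m[, 1:3], ignore_attr = TRUE)
})

test_that("duplicate symbols collapse by mean and alignment is idempotent", {
  m <- matrix(c(2, 4, 7), 1, 3,
              dimnames = list("s1", c("gA", "gA", "gB")))
  out <- align_to_landmarks(m, c("gA", "gB"))
  expect_equal(as.numeric(unclass(out$x)), c(3, 7))

  again <- align_to_landmarks(out$x, c("gA", "gB"))
  expect_equal(unclass(again$x), unclass(out$x), ignore_attr = TRUE)
  expect_length(again$missing, 0)
})

test_that("zero overlap with the panel is an error naming the sizes", {
  m <- toy_matrix(2, 3)
  expect_error(align_to_landmarks(m, c("x1", "x2")), "0/2")
})

test_that("log_cpm matches its formula and is scale invariant per cell", {
  counts <- matrix(c(10, 90, 20, 180), 2, 2, byrow = TRUE,
                   dimnames = list(c("c1", "c2"), c("g1", "g2")))
  out <- log_cpm(counts)
  # count 10 in a library of 100: ln(10/100 * 1e4 + 1) = ln(1001)
  expect_equal(unclass(out)[1, 1], log(1001), tolerance = 1e-12)
  # doubling all counts in a cell leaves its normalized vector unchanged
  expect_equal(unclass(out)[1, ], unclass(out)[2, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero counts map to 0 exactly
  z <- matrix(c(0, 5), 1, 2, dimnames = list("c", c("a", "b")))
  expect_identical(unclass(log_cpm(z))[1, 1], 0)
  # log2 flag
  expect_equal(unclass(log_cpm(counts, base = "log2"))[1, 1], log2(1001))
})

test_that("log_cpm inverts back to CPM within 1e-9 relative error", {
  counts <- toy_matrix(4, 6) * 50
  out <- unclass(log_cpm(counts))
  cpm <- sweep(counts, 1, rowSums(counts), "/") * 1e4
  expect_equal(expm1(out), cpm, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("log_cpm rejects negative input and all-zero cells", {
  expect_error(log_cpm(matrix(-1, 1, 1, dimnames = list("c", "g"))),
               "nonnegative")
  z <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("ok", "empty"), c("g1", "g2")))
  expect_error(log_cpm(z), "empty")
})

test_that("zscore_genes gives population z-scores, maps constants to zero,
          and eliminates numerical sparsity", {
  m <- matrix(c(1, 2, 3, 5, 5, 5, 0, 0, 3), 3, 3,
              dimnames = list(paste0("s", 1:3), c("var", "const", "sparse")))
  z <- zscore_genes(m)
  expect_equal(unclass(z)[, "var"],
               c(s1 = -1, s2 = 0, s3 = 1) / 0.81649658, tolerance = 1e-7)
  expect_equal(unclass(z)[, "const"], c(s1 = 0, s2 = 0, s3 = 0))
  expect_identical(attr(z, "constant_genes"), "const")
  # zeros of a sparse non-constant gene map to finite values (a value can
  # still land on 0 if it equals the gene mean exactly, as in "var" here)
  expect_equal(sparsity(unclass(z)[, "sparse", drop = FALSE]), 0)
  # per-gene mean 0, population sd 1
  expect_equal(colMeans(unclass(z))[["var"]], 0, tolerance = 1e-12)
  expect_equal(mean(unclass(z)[, "var"]^2), 1, tolerance = 1e-12)
})

test_that("zscore_genes is idempotent for non-constant genes", {
  m <- toy_matrix(5, 4)
  z1 <- unclass(zscore_genes(m))
  z2 <- unclass(zscore_genes(z1))
  expect_equal(z2, z1, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zscore_genes refuses single-sample input", {
  expect_error(zscore_genes(toy_matrix(1, 3)), "2 samples")
})

test_that("qc_filter_cells applies the atlas and lenient presets", {
  genes <- c(paste0("G", 1:300), "MT-CO1")
  counts <- matrix(0L, 4, 301, dimnames = list(paste0("c", 1:4), genes))
  counts[1, 1:150] <- 1L                     # 150 features: dropped (atlas)
  counts[2, 1:250] <- 1L                     # 250 features, no mt: kept
  counts[3, 1:250] <- 1L; counts[3, 301] <- 19L  # mt ~7%: preset-dependent
  counts[4, 1:201] <- 1L                     # 202 features with mt
  counts[4, 301] <- 1L

  atlas <- qc_filter_cells(counts)
  expect_false("c1" %in% atlas$kept)
  expect_true("c2" %in% atlas$kept)
  expect_false("c3" %in% atlas$kept)        # 19/269 = 7.1% >= 5%
  lenient <- qc_filter_cells(counts, preset = "lenient")
  expect_true("c3" %in% lenient$kept)       # 7.1% <= 10%
  expect_false("c1" %in% lenient$kept)      # 150 < 200 fails either preset
})

test_that("qc_filter_cells boundary strictness matches the presets", {
  genes <- paste0("G", 1:2600)
  counts <- matrix(0L, 2, 2600, dimnames = list(c("at200", "at2500"), genes))
  counts[1, 1:200] <- 1L
  counts[2, 1:2500] <- 1L
  # atlas preset is strict: exactly 200 fails > 200, exactly 2500 fails < 2500
  expect_error(qc_filter_cells(counts), "all cells removed")
  lenient <- qc_filter_cells(counts, preset = "lenient")
  expect_true("at200" %in% lenient$kept)     # inclusive >= 200
  expect_true("at2500" %in% lenient$kept)    # no upper bound
})

test_that("disabling all thresholds is the identity and total removal errors", {
  counts <- matrix(1L, 3, 5, dimnames = list(paste0("c", 1:3),
                                             paste0("g", 1:5)))
  out <- qc_filter_cells(counts, min_features = -Inf, max_features = Inf,
                         max_mt_pct = Inf)
  expect_identical(rownames(out$counts), rownames(counts))
  expect_error(qc_filter_cells(counts, min_features = 10),
               "all cells removed")
})

test_that("sparsity counts zero entries", {
  expect_equal(sparsity(matrix(0, 2, 2)), 1)
  expect_equal(sparsity(matrix(1:4, 2, 2)), 0)
  expect_equal(sparsity(matrix(c(0, 1, 2, 3), 2, 2)), 0.25)
  expect_error(sparsity(matrix(numeric(0), 0, 0)), "empty")
})
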