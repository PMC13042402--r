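#' Feature dropout: zero whole gene columns
#'
#' Masks `floor(pct * n_genes / 100)` randomly chosen genes by setting their
#' expression to zero for all samples, emulating missing landmark features.
#'
#' @param x samples x genes matrix.
#' @param pct percentage of genes to mask, in `[0, 100]`.
#' @param seed RNG seed for the column selection.
#' @return matrix with the selected columns zeroed; attribute
#'   `masked_genes` lists them.
#' @export
feature_dropout <- function(x, pct, seed = 1L) {
  check_that(pct >= 0 && pct <= 100, "pct must be in [0, 100]")
  values <- as_matrix(x)
  k <- floor(pct * ncol(values) / 100)
  masked <- if (k > 0) with_seed(seed, sample.int(ncol(values), k)) else
    integer(0)
  values[, masked] <- 0
  attr(values, "masked_genes") <- colnames(values)[masked]
  values
}

#' Cumulative SHAP-guided ablation series
#'
#' Given an importance ordering of the features, produces cumulatively masked
#' copies of the input: at step `k` the first `k` features of the ordered
#' list are zeroed jointly (step 0 is the identity), either from the least
#' important end (`"low_to_high"`) or the most important end
#' (`"high_to_low"`).
#'
#' @param x samples x genes matrix.
#' @param feature_ranking character vector of all gene names ordered by
#'   decreasing importance (e.g. from [rank_features()]).
#' @param direction `"low_to_high"` or `"high_to_low"`.
#' @param steps integer vector of cumulative mask sizes `k` (default: every
#'   feature count from 0 to all).
#' @return named list of masked matrices, one per step (`step0`, `step1`, ...).
#' @export
shap_ablation_series <- function(x, feature_ranking,
                                 direction = c("low_to_high", "high_to_low"),
                                 steps = NULL) {
  direction <- match.arg(direction)
  values <- as_matrix(x)
  if (!setequal(feature_ranking, colnames(values)) ||
      length(feature_ranking) != ncol(values)) {
    stop("feature_ranking must cover exactly the matrix's genes")
  }
  order_used <- if (direction == "high_to_low") feature_ranking else
    rev(feature_ranking)
  if (is.null(steps)) steps <- 0:length(order_used)
  check_that(all(steps >= 0 & steps <= length(order_used)),
             "steps out of range")
  out <- lapply(steps, function(k) {
    m <- values
    if (k > 0) m[, order_used[seq_len(k)]] <- 0
    m
  })
  names(out) <- paste0("step", steps)
  out
}

#' Uniform masking to an exact target sparsity
#'
#' Zeros a random subset of the currently non-zero entries so that the
#' realized overall sparsity hits the target exactly (the count of entries
#' to drop is computed deterministically; only their positions are random).
#'
#' @param x samples x genes matrix.
#' @param target_sparsity_pct target overall sparsity, percent.
#' @param seed RNG seed.
#' @return masked matrix.
#' @export
mask_uniform <- function(x, target_sparsity_pct, seed = 1L) {
  check_that(target_sparsity_pct >= 0 && target_sparsity_pct <= 100,
             "target must be in [0, 100]")
  values <- as_matrix(x)
  total <- length(values)
  nz <- which(values != 0)
  z_now <- total - length(nz)
  z_target <- round(target_sparsity_pct / 100 * total)
  if (z_target < z_now) {
    stop(sprintf("target sparsity %.1f%% is below the current %.1f%%",
                 target_sparsity_pct, 100 * z_now / total))
  }
  k <- z_target - z_now
  if (k > 0) {
    drop <- with_seed(seed, sample(nz, k))
    values[drop] <- 0
  }
  values
}

#' Poisson-based expression-dependent masking
#'
#' Mimics scRNA-seq dropout, where low-abundance entries vanish first. For
#' every non-zero entry `x`, a rate `lambda = max(x / p95, 1e-12)` is formed
#' (`p95` = 95th percentile of the non-zero entries, globally by default),
#' the dropout propensity is `p = exp(-gamma * lambda)`, and a scale
#' `s = sp_nz / mean(p)` calibrates the expected number of new zeros to the
#' target: each non-zero entry is dropped independently with probability
#' `min(s * p, 1)`. `gamma = 0` makes every propensity 1, i.e. uniform
#' masking at the target rate; larger `gamma` concentrates dropout in the
#' lowest-abundance entries.
#'
#' @param x expression-scale (nonnegative) samples x genes matrix, e.g. FPKM.
#' @param gamma dropout shape, `>= 0`.
#' @param target_sparsity_pct target overall sparsity, percent.
#' @param seed RNG seed.
#' @param percentile_scope `"global"` (95th percentile over all non-zero
#'   entries, default) or `"per_gene"`.
#' @return masked matrix with attributes `expected_sparsity` (the achievable
#'   expectation after probability clipping) and `clipped_fraction`. Warns
#'   when clipping makes the target unreachable in expectation.
#' @export
poisson_mask <- function(x, gamma, target_sparsity_pct, seed = 1L,
                         percentile_scope = c("global", "per_gene")) {
  percentile_scope <- match.arg(percentile_scope)
  check_that(gamma >= 0, "gamma must be >= 0")
  values <- as_matrix(x)
  if (any(values < 0)) stop("poisson_mask expects expression-scale input")
  total <- length(values)
  nz <- which(values != 0)
  z_now <- total - length(nz)
  z_target <- target_sparsity_pct / 100 * total
  if (z_target < z_now) {
    stop(sprintf("target sparsity %.1f%% is below the current %.1f%%",
                 target_sparsity_pct, 100 * z_now / total))
  }
  if (length(nz) == 0L) return(values)
  sp_nz <- (z_target - z_now) / length(nz) # fraction of non-zeros to drop
  if (percentile_scope == "global") {
    p95 <- quantile(values[nz], 0.95, names = FALSE)
    lambda <- pmax(values[nz] / max(p95, .Machine$double.eps), 1e-12)
  } else {
    p95_gene <- apply(values, 2L, function(col) {
      v <- col[col != 0]
      if (length(v)) quantile(v, 0.95, names = FALSE) else 1
    })
    p95_mat <- matrix(p95_gene, nrow(values), ncol(values), byrow = TRUE)
    lambda <- pmax(values[nz] / pmax(p95_mat[nz], .Machine$double.eps), 1e-12)
  }
  p <- exp(-gamma * lambda)
  s <- sp_nz / mean(p)
  prob <- pmin(s * p, 1)
  clipped <- mean(s * p > 1)
  expected <- (z_now + sum(prob)) / total
  if (expected + 1e-9 < z_target / total) {
    warning(sprintf(paste0("target sparsity %.1f%% unreachable after ",
                           "probability clipping; expected %.1f%%"),
                    target_sparsity_pct, 100 * expected))
  }
  drop <- with_seed(seed, runif(length(nz)) < prob)
  values[nz[drop]] <- 0
  attr(values, "expected_sparsity") <- expected
  attr(values, "clipped_fraction") <- clipped
  values
}

#' Multinomial UMI down-sampling
#'
#' Simulates reduced sequencing depth: for each sample the expression vector
#' is normalized to a probability distribution and pseudo-UMI counts are
#' drawn `Multinomial(depth, p)`.
#'
#' @param x expression-scale (nonnegative) samples x genes matrix.
#' @param depth pseudo-UMI total per sample; default: median per-sample sum,
#'   scaled by `depth_factor` and rounded.
#' @param depth_factor multiplier on the default depth.
#' @param seed RNG seed.
#' @return integer matrix of pseudo-UMI counts; attribute `depth` records the
#'   depth used.
#' @export
umi_downsample <- function(x, depth = NULL, depth_factor = 1, seed = 1L) {
  values <- as_matrix(x)
  if (any(values < 0)) stop("umi_downsample expects nonnegative input")
  row_sums <- rowSums(values)
  if (any(row_sums == 0)) {
    stop("all-zero sample(s): ",
         paste(head(rownames(values)[row_sums == 0], 5L), collapse = ", "))
  }
  if (is.null(depth)) depth <- max(1L, round(median(row_sums) * depth_factor))
  check_that(depth >= 1, "depth must be >= 1")
  out <- with_seed(seed, {
    t(vapply(seq_len(nrow(values)), function(i) {
      as.integer(rmultinom(1L, size = depth, prob = values[i, ] / row_sums[i]))
    }, integer(ncol(values))))
  })
  dimnames(out) <- dimnames(values)
  attr(out, "depth") <- depth
  out
}

#' Down-sampling followed by Poisson-based masking
#'
#' Two-stage sparsification: first multinomial UMI down-sampling, whose
#' realized sparsity `sp_down` is measured, then Poisson-based masking of the
#' surviving non-zero entries with the adjusted target
#' `sp'_target = (sp_target - sp_down) / (1 - sp_down)`, so the combined
#' realized sparsity approximates `sp_target`.
#'
#' @param x expression-scale samples x genes matrix.
#' @param target_sparsity_pct combined target sparsity, percent.
#' @param gamma Poisson-mask shape (default 0.5).
#' @param depth,depth_factor see [umi_downsample()].
#' @param seed RNG seed (stage seeds are derived from it).
#' @return masked count matrix with attributes `sp_down` (realized
#'   down-sampling sparsity), `sp_target_adjusted` (the Poisson-stage target
#'   among surviving non-zeros) and `depth`.
#' @export
downsample_plus_poisson <- function(x, target_sparsity_pct, gamma = 0.5,
                                    depth = NULL, depth_factor = 1,
                                    seed = 1L) {
  down <- umi_downsample(x, depth = depth, depth_factor = depth_factor,
                         seed = seed)
  sp_down <- sparsity(down)
  target <- target_sparsity_pct / 100
  if (target < sp_down) {
    stop(sprintf(paste0("target sparsity %.3f is below the realized ",
                        "down-sampling sparsity %.3f"), target, sp_down))
  }
  sp_adj <- (target - sp_down) / (1 - sp_down)
  out <- if (sp_adj > 0) {
    poisson_mask(down, gamma = gamma, target_sparsity_pct = target * 100,
                 seed = seed + 1L)
  } else down
  attr(out, "sp_down") <- sp_down
  attr(out, "sp_target_adjusted") <- sp_adj
  attr(out, "depth") <- attr(down, "depth")
  out
}

#' Stress-test grid specification
#'
#' The default levels and seed sets follow the published stress protocol:
#' feature-level schemes use percentages `0,1,5,10,...,90` with seeds
#' `101, 204, 387, 1567, 640, 912`; sparsity schemes use
#' `0, 0.1, 1, 5, 10, ..., 90` with seeds `62, 567, 309, 39, 675, 42`.
#'
#' @param scheme one of `"feature_random"`, `"feature_shap_low_high"`,
#'   `"feature_shap_high_low"`, `"mask_uniform"`, `"mask_poisson"`,
#'   `"downsample"`, `"downsample_plus_poisson"`.
#' @param levels percentages in `[0, 100]`: masked-feature percentage for
#'   feature schemes, target sparsity for masking schemes, depth *reduction*
#'   percentage for `"downsample"` (level 20 keeps 80% of the median depth).
#' @param gamma Poisson-mask shape parameter.
#' @param seeds integer seeds replicating each level.
#' @param feature_ranking importance ordering, required by the SHAP-guided
#'   schemes.
#' @param track_zscore_sparsity also record post-z-scoring sparsity.
#' @return an object of class `stress_grid`.
#' @export
stress_grid <- function(scheme = c("mask_uniform", "mask_poisson",
                                   "downsample", "downsample_plus_poisson",
                                   "feature_random", "feature_shap_low_high",
                                   "feature_shap_high_low"),
                        levels = NULL, gamma = 0.5, seeds = NULL,
                        feature_ranking = NULL,
                        track_zscore_sparsity = TRUE) {
  scheme <- match.arg(scheme)
  feature_scheme <- startsWith(scheme, "feature")
  if (is.null(levels)) {
    levels <- if (feature_scheme) {
      c(0, 1, 5, 10, 20, 30, 40, 50, 60, 70, 80, 90)
    } else {
      c(0, 0.1, 1, 5, 10, 20, 30, 40, 50, 60, 70, 80, 90)
    }
  }
  if (is.null(seeds)) {
    seeds <- if (feature_scheme) c(101L, 204L, 387L, 1567L, 640L, 912L) else
      c(62L, 567L, 309L, 39L, 675L, 42L)
  }
  check_that(all(levels >= 0 & levels <= 100), "levels must be in [0, 100]")
  check_that(length(seeds) > 0, "at least one seed required")
  check_that(gamma >= 0, "gamma must be >= 0")
  if (feature_scheme && scheme != "feature_random" &&
      is.null(feature_ranking)) {
    stop("SHAP-guided schemes need `feature_ranking`")
  }
  structure(list(scheme = scheme, levels = levels, gamma = gamma,
                 seeds = as.integer(seeds),
                 feature_ranking = feature_ranking,
                 track_zscore_sparsity = track_zscore_sparsity),
            class = "stress_grid")
}

#' Run a perturbation stress grid through the model
#'
#' For every (level, seed) cell: perturb the expression-scale input, z-score
#' the perturbed matrix per gene, predict, evaluate against the (fixed,
#' z-scored) ground truth, and classify the performance regime. Level 0 is
#' the unperturbed baseline for every scheme (the input passes through
#' untouched, so level-0 rows reproduce the clean evaluation exactly).
#' Sparsity is
#' recorded before and after z-scoring; because z-scoring maps zeros of
#' non-constant genes to finite values, the post-z-score sparsity (computed
#' over non-constant genes) is 0 throughout — numerical sparsity is hidden,
#' not repaired.
#'
#' @param model a trained [landmir_model][build_model()].
#' @param x expression-scale input, samples x genes matching the model panel
#'   (e.g. FPKM).
#' @param y ground-truth miRNA matrix on its measurement scale (z-scored
#'   internally, once).
#' @param grid a [stress_grid()].
#' @return data.frame of class `stress_result`: one row per (level, seed)
#'   with scheme, realized sparsity pre/post z-scoring, mean PCC/R2/MSE/RMSE
#'   and the regime label.
#' @export
run_stress_grid <- function(model, x, y, grid) {
  stopifnot(inherits(grid, "stress_grid"))
  x <- as_matrix(x); y <- as_matrix(y)
  check_that(ncol(x) == model$in_dim, "input width does not match the model")
  y_z <- as_matrix(zscore_genes(y))
  rows <- list()
  for (level in grid$levels) {
    for (seed in grid$seeds) {
      perturbed <- if (level == 0) x else switch(grid$scheme,
        feature_random = feature_dropout(x, level, seed),
        feature_shap_low_high = shap_ablation_series(
          x, grid$feature_ranking, "low_to_high",
          steps = floor(level * ncol(x) / 100))[[1L]],
        feature_shap_high_low = shap_ablation_series(
          x, grid$feature_ranking, "high_to_low",
          steps = floor(level * ncol(x) / 100))[[1L]],
        mask_uniform = mask_uniform(x, level, seed),
        mask_poisson = poisson_mask(x, grid$gamma, level, seed),
        downsample = umi_downsample(x, depth_factor = 1 - level / 100,
                                    seed = seed),
        downsample_plus_poisson = downsample_plus_poisson(
          x, level, gamma = grid$gamma, seed = seed)
      )
      sp_pre <- sparsity(perturbed)
      z <- zscore_genes(perturbed)
      const <- attr(z, "constant_genes")
      sp_post <- if (grid$track_zscore_sparsity) {
        keep <- setdiff(colnames(x) %||% as.character(seq_len(ncol(x))),
                        const)
        zz <- as_matrix(z)
        colnames(zz) <- colnames(x) %||% as.character(seq_len(ncol(x)))
        if (length(keep)) sparsity(zz[, keep, drop = FALSE]) else NA_real_
      } else NA_real_
      pred <- predict(model, as_matrix(z))
      rep_i <- evaluate_predictions(y_z, pred, axis = "per_mirna")
      s <- rep_i$summary
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = grid$scheme, level = level, seed = seed,
        realized_sparsity_pre_z = sp_pre,
        realized_sparsity_post_z = sp_post,
        mean_pcc = s$mean_pcc, mean_r2 = s$mean_r2,
        mean_mse = s$mean_mse, mean_rmse = s$mean_rmse,
        regime = classify_regime(s$mean_pcc, s$mean_r2))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("stress_result", class(out))
  out
}
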