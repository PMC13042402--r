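#' Pseudo-bulk pooling plan
#'
#' Controls how single-cell profiles are aggregated before prediction.
#' `"average"` takes one arithmetic mean per cell type; `"bootstrap"` draws
#' `n_pools` pseudo-bulk samples per type, each the mean of
#' `floor(frac * n_type)` cells sampled *without* replacement; `"auto"`
#' routes types with more than `min_cells_for_bootstrap` cells to bootstrap
#' pooling and the rest to averaging.
#'
#' @param mode `"auto"`, `"average"` or `"bootstrap"`.
#' @param frac sampled fraction per pool, in (0, 1] (default 0.8).
#' @param n_pools pools per eligible cell type (default 10).
#' @param min_cells_for_bootstrap auto-mode routing threshold (default 400).
#' @param seed RNG seed for pool membership.
#' @return an object of class `pooling_plan`.
#' @export
pooling_plan <- function(mode = c("auto", "average", "bootstrap"),
                         frac = 0.8, n_pools = 10L,
                         min_cells_for_bootstrap = 400L, seed = 1L) {
  mode <- match.arg(mode)
  check_that(frac > 0 && frac <= 1, "frac must be in (0, 1]")
  check_that(n_pools >= 1, "n_pools must be >= 1")
  structure(list(mode = mode, frac = frac, n_pools = as.integer(n_pools),
                 min_cells_for_bootstrap = as.integer(min_cells_for_bootstrap),
                 seed = as.integer(seed)),
            class = "pooling_plan")
}

#' Cell-type average pooling
#'
#' @param x cells x genes matrix.
#' @param labels cell-type labels, length `nrow(x)`.
#' @return matrix with one row per cell type (type names as rownames), the
#'   arithmetic mean of its cells.
#' @export
celltype_average <- function(x, labels) {
  values <- as_matrix(x)
  if (length(labels) != nrow(values)) {
    stop("labels length ", length(labels), " does not match ", nrow(values),
         " cells")
  }
  labels <- as.factor(labels)
  out <- t(vapply(levels(labels), function(lv) {
    colMeans(values[labels == lv, , drop = FALSE])
  }, numeric(ncol(values))))
  rownames(out) <- levels(labels)
  colnames(out) <- colnames(values)
  out
}

#' Bootstrap pseudo-bulk pooling
#'
#' For each cell type routed to bootstrapping, draws `plan$n_pools` pools;
#' each pool is the mean of `floor(frac * n_type)` distinct cells (sampling
#' without replacement). In `"auto"` mode, types with at most
#' `min_cells_for_bootstrap` cells fall back to a single average row, as do
#' types with fewer than 2 cells in any mode. Pool membership is seeded and
#' recorded in the provenance.
#'
#' @param x cells x genes matrix (typically log-CPM normalized).
#' @param labels cell-type labels, length `nrow(x)`.
#' @param plan a [pooling_plan()].
#' @return list with `pooled` (pooled matrix; bootstrap rows named
#'   `<type>.pool<k>`, average rows named by type), `provenance` (per-pool
#'   sampled cell ids, plus the plan), and `mode_used` (named by type).
#' @export
bootstrap_pool <- function(x, labels, plan = pooling_plan()) {
  values <- as_matrix(x)
  if (length(labels) != nrow(values)) {
    stop("labels length ", length(labels), " does not match ", nrow(values),
         " cells")
  }
  labels <- as.factor(labels)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("cell%05d", seq_len(nrow(values)))
  }
  with_seed(plan$seed, {
    rows <- list(); row_names <- character(0)
    provenance <- list(plan = unclass(plan), pools = list())
    mode_used <- character(0)
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      n_type <- length(idx)
      use_bootstrap <- switch(plan$mode,
        average = FALSE,
        bootstrap = TRUE,
        auto = n_type > plan$min_cells_for_bootstrap)
      if (use_bootstrap && n_type < 2L) use_bootstrap <- FALSE # tiny type
      if (use_bootstrap) {
        size <- floor(plan$frac * n_type)
        if (size < 1L) {
          stop("frac * n_type < 1 for type '", lv, "' (", n_type, " cells)")
        }
        for (p in seq_len(plan$n_pools)) {
          take <- idx[sample.int(n_type, size)] # without replacement
          rows[[length(rows) + 1L]] <-
            colMeans(values[take, , drop = FALSE])
          nm <- sprintf("%s.pool%02d", lv, p)
          row_names <- c(row_names, nm)
          provenance$pools[[nm]] <- rownames(values)[take]
        }
        mode_used[lv] <- "bootstrap"
      } else {
        rows[[length(rows) + 1L]] <- colMeans(values[idx, , drop = FALSE])
        row_names <- c(row_names, lv)
        provenance$pools[[lv]] <- rownames(values)[idx]
        mode_used[lv] <- "average"
      }
    }
    pooled <- do.call(rbind, rows)
    rownames(pooled) <- row_names
    colnames(pooled) <- colnames(values)
    list(pooled = pooled, provenance = provenance, mode_used = mode_used)
  })
}

#' Sparsity before and after pooling
#'
#' Pooling averages many cells per output row, so an entry is zero only when
#' every contributing cell is zero; pooled sparsity can therefore only drop.
#'
#' @param raw the cells x genes input matrix.
#' @param pooled the pooled matrix.
#' @return list with `before`, `after` and `reduction` (percentage points).
#' @export
pooled_sparsity_report <- function(raw, pooled) {
  before <- sparsity(raw)
  after <- sparsity(pooled)
  list(before = before, after = after,
       reduction = 100 * (before - after))
}
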