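#' Align an expression matrix to a landmark panel
#'
#' Reorders columns to the panel order, drops genes outside the panel,
#' collapses duplicated symbols by their mean, and fills panel genes that are
#' missing from the input with all-zero columns (the convention for absent
#' landmarks). The operation is idempotent.
#'
#' @param x an [expression_matrix()] or samples-x-genes matrix with gene
#'   symbols as colnames.
#' @param panel ordered character vector of panel gene symbols, e.g.
#'   [landmark_panel()].
#' @return a list with `x` (the aligned [expression_matrix()], columns exactly
#'   `panel`), `missing` (panel genes absent from the input, zero-filled),
#'   `dropped` (input genes outside the panel) and `n_matched`.
#' @export
align_to_landmarks <- function(x, panel) {
  values <- as_matrix(x)
  state <- norm_state(x)
  if (is.na(state)) state <- "raw_counts"
  genes <- colnames(values)
  if (is.null(genes) || length(genes) == 0L) stop("input has no gene ids")
  if (anyDuplicated(panel)) stop("panel contains duplicated symbols")

  if (anyDuplicated(genes)) {
    # collapse duplicate symbols by mean
    idx <- split(seq_along(genes), genes)
    collapsed <- vapply(idx, function(j) {
      if (length(j) == 1L) values[, j] else rowMeans(values[, j, drop = FALSE])
    }, numeric(nrow(values)))
    if (nrow(values) == 1L) collapsed <- matrix(collapsed, nrow = 1L,
                                                dimnames = list(rownames(values),
                                                                names(idx)))
    values <- collapsed
    genes <- colnames(values)
  }

  matched <- intersect(panel, genes)
  if (length(matched) == 0L) {
    stop("no overlap between input genes and the ", length(panel),
         "-gene panel (0/", length(panel), " matched)")
  }
  missing <- setdiff(panel, genes)
  dropped <- setdiff(genes, panel)

  out <- matrix(0, nrow = nrow(values), ncol = length(panel),
                dimnames = list(rownames(values), panel))
  out[, matched] <- values[, matched]
  list(x = expression_matrix(out, norm_state = state),
       missing = missing, dropped = dropped, n_matched = length(matched))
}

#' Library-size normalization with log transform (log-CPM)
#'
#' Per cell: `log(count / library_size * scale + 1)`, the Seurat-style
#' `CPM x 1e4` convention with natural log by default (base-2 available).
#' Doubling every count in a cell leaves its normalized vector unchanged.
#'
#' @param x raw counts, samples(cells) x genes; nonnegative.
#' @param scale scale factor (default `1e4`).
#' @param base `"natural"` (default) or `"log2"`.
#' @return an [expression_matrix()] tagged `cpm_log`.
#' @export
log_cpm <- function(x, scale = 1e4, base = c("natural", "log2")) {
  base <- match.arg(base)
  values <- as_matrix(x)
  if (any(values < 0)) stop("log_cpm expects nonnegative counts")
  lib <- rowSums(values)
  if (any(lib == 0)) {
    bad <- rownames(values)[lib == 0]
    stop("all-zero cell(s): ", paste(head(bad, 5L), collapse = ", "))
  }
  norm <- values / lib * scale
  out <- if (base == "natural") log1p(norm) else log2(norm + 1)
  expression_matrix(out, norm_state = "cpm_log")
}

#' Per-gene z-scoring across samples
#'
#' Centers and scales every gene to mean 0 and population (ddof = 0) standard
#' deviation 1 across samples. Zero-variance genes map to all-zero columns
#' rather than NaN, so averaging-then-z-scoring degenerate inputs stays
#' finite. Because zeros are mapped to finite values, the output restricted
#' to non-constant genes has numerical sparsity 0 no matter how sparse the
#' input was.
#'
#' @param x samples x genes matrix, at least 2 samples.
#' @param center,scale optional per-gene statistics to apply instead of
#'   computing them from `x` (used to freeze training-set statistics).
#' @return an [expression_matrix()] tagged `zscored`, with attributes
#'   `center` and `scale` (the statistics used; `scale` is 0 for constant
#'   genes) and `constant_genes` (their names).
#' @export
zscore_genes <- function(x, center = NULL, scale = NULL) {
  values <- as_matrix(x)
  if (nrow(values) < 2L && is.null(center)) {
    stop("z-scoring needs at least 2 samples")
  }
  if (is.null(center)) center <- colMeans(values)
  if (is.null(scale)) {
    scale <- sqrt(colMeans(sweep(values, 2L, center)^2)) # population sd
  }
  out <- sweep(values, 2L, center)
  nz <- scale > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, scale[nz], "/")
  out[, !nz] <- 0
  out <- expression_matrix(out, norm_state = "zscored")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  attr(out, "constant_genes") <- colnames(values)[!nz]
  out
}

#' Invert a per-gene z-score transform
#'
#' @param z z-scored matrix (samples x genes).
#' @param center,scale per-gene statistics, e.g. the attributes stored by
#'   [zscore_genes()] or the training statistics kept on a fitted model.
#' @return matrix on the original expression scale.
#' @export
zscore_invert <- function(z, center, scale) {
  values <- as_matrix(z)
  out <- sweep(sweep(values, 2L, scale, "*"), 2L, center, "+")
  out
}

#' Quality-control filtering of cells
#'
#' Removes cells outside feature-count and mitochondrial-fraction bounds.
#' Two presets reflect common practice for atlas-scale versus permissive
#' processing: `"atlas"` keeps cells with `nFeature > 200`, `< 2500` and
#' mitochondrial percentage `< 5` (strict inequalities); `"lenient"` keeps
#' `nFeature >= 200` with mitochondrial percentage `<= 10` and no upper
#' feature bound. Any bound can be disabled with `NULL`/`Inf`.
#'
#' @param counts raw counts, cells x genes.
#' @param min_features,max_features bounds on the number of detected
#'   (non-zero) genes per cell.
#' @param max_mt_pct bound on the mitochondrial read percentage.
#' @param mt_prefix gene-symbol prefix identifying mitochondrial genes.
#' @param preset `"atlas"` (default) or `"lenient"`; explicit arguments
#'   override the preset.
#' @param strict use strict (`>`, `<`) rather than inclusive (`>=`, `<=`)
#'   comparisons; set by the preset.
#' @return list with `counts` (kept cells), `kept`, `dropped` (cell ids) and
#'   `drop_reasons` (per-rule drop counts).
#' @export
qc_filter_cells <- function(counts, min_features = NULL, max_features = NULL,
                            max_mt_pct = NULL, mt_prefix = "MT-",
                            preset = c("atlas", "lenient"), strict = NULL) {
  preset <- match.arg(preset)
  defaults <- if (preset == "atlas") {
    list(min_features = 200, max_features = 2500, max_mt_pct = 5,
         strict = TRUE)
  } else {
    list(min_features = 200, max_features = Inf, max_mt_pct = 10,
         strict = FALSE)
  }
  if (is.null(min_features)) min_features <- defaults$min_features
  if (is.null(max_features)) max_features <- defaults$max_features
  if (is.null(max_mt_pct)) max_mt_pct <- defaults$max_mt_pct
  if (is.null(strict)) strict <- defaults$strict

  values <- as_matrix(counts)
  n_feat <- rowSums(values > 0)
  mt_genes <- startsWith(colnames(values), mt_prefix)
  lib <- rowSums(values)
  mt_pct <- if (any(mt_genes)) {
    100 * rowSums(values[, mt_genes, drop = FALSE]) / pmax(lib, 1)
  } else rep(0, nrow(values))

  gt <- if (strict) `>` else `>=`
  lt <- if (strict) `<` else `<=`
  pass_min <- if (is.finite(min_features)) gt(n_feat, min_features) else TRUE
  pass_max <- if (is.finite(max_features)) lt(n_feat, max_features) else TRUE
  pass_mt <- if (is.finite(max_mt_pct)) lt(mt_pct, max_mt_pct) else TRUE
  keep <- pass_min & pass_max & pass_mt

  drop_reasons <- c(low_features = sum(!pass_min),
                    high_features = sum(!pass_max),
                    high_mt = sum(!pass_mt))
  if (!any(keep)) {
    stop("all cells removed by QC (low_features: ", drop_reasons[1L],
         ", high_features: ", drop_reasons[2L],
         ", high_mt: ", drop_reasons[3L], ")")
  }
  out <- values[keep, , drop = FALSE]
  state <- norm_state(counts)
  list(counts = expression_matrix(out, norm_state =
                                    if (is.na(state)) "raw_counts" else state),
       kept = rownames(values)[keep],
       dropped = rownames(values)[!keep],
       drop_reasons = drop_reasons)
}
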