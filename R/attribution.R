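# internal: Jacobian of the inference-mode network at one input point,
# returned features x outputs. In inference mode the network is piecewise
# linear (batch norm is a fixed affine map, dropout is off), so the Jacobian
# is an explicit product of the layer maps with the ReLU activation pattern
# at the point.
model_jacobian <- function(model, z) {
  eps <- model$config$bn_eps
  h <- matrix(z, nrow = 1L)
  scales <- list(); masks <- list()
  for (l in model$layers) {
    pre <- as.numeric(h %*% l$W) + l$b
    s <- l$gamma / sqrt(l$run_var + eps)
    a <- s * (pre - l$run_mean) + l$beta
    scales[[length(scales) + 1L]] <- s
    masks[[length(masks) + 1L]] <- as.numeric(a > 0)
    h <- matrix(pmax(a, 0), nrow = 1L)
  }
  G <- model$W_out # h_last x out
  for (l in rev(seq_along(model$layers))) {
    G <- G * (scales[[l]] * masks[[l]]) # row-scale
    G <- model$layers[[l]]$W %*% G
  }
  G
}

#' Expected-gradients SHAP attribution
#'
#' Gradient-based SHAP estimator: the attribution of feature `j` to output
#' `k` for an explained sample `x` is the expectation, over baselines `b`
#' from the background set and path positions `alpha ~ U(0,1)`, of
#' `(x_j - b_j) * dF_k/dx_j` evaluated at `b + alpha (x - b)`. Two
#' variance-reduction choices are built in: baselines are cycled through the
#' background set (balanced assignment, seeded order) rather than resampled
#' i.i.d., and the path positions `alpha` are stratified over `[0, 1]`; for
#' a linear model the estimator is then exact. Attributions are averaged
#' over the explained samples. The completeness identity holds in
#' expectation: column sums approximate
#' `mean F_k(x_explain) - mean F_k(background)`.
#'
#' @param model a trained [landmir_model][build_model()] (inference mode).
#' @param x_background background matrix, samples x features, on the model's
#'   input scale (z-scored).
#' @param x_explain samples to explain, same width.
#' @param n_draws path samples per explained row (default 200).
#' @param seed RNG seed for baseline order and path positions.
#' @return an object of class `attribution_matrix`: features x outputs matrix
#'   of mean attributions, with attributes `background_size`,
#'   `n_samples_explained`, `seed`, and `fk_gap` (the per-output
#'   `mean F(explain) - mean F(background)` for completeness checks).
#' @export
gradient_shap <- function(model, x_background, x_explain, n_draws = 200L,
                          seed = 1L) {
  xb <- as_matrix(x_background)
  xe <- as_matrix(x_explain)
  if (nrow(xb) == 0L) stop("background set is empty")
  if (ncol(xb) != model$in_dim || ncol(xe) != model$in_dim) {
    stop("feature width mismatch: background ", ncol(xb), ", explain ",
         ncol(xe), ", model ", model$in_dim)
  }
  attr_sum <- matrix(0, model$in_dim, model$out_dim)
  base_weight <- rep(0, nrow(xb)) # realized baseline multiset, all samples
  with_seed(seed, {
    for (i in seq_len(nrow(xe))) {
      x <- xe[i, ]
      # balanced baseline assignment: shuffled repetition of the background;
      # path positions stratified over [0,1] (one per draw, shuffled so
      # strata are not tied to particular baselines)
      base_idx <- rep_len(sample.int(nrow(xb)), n_draws)
      alphas <- (sample.int(n_draws) - runif(n_draws)) / n_draws
      acc <- matrix(0, model$in_dim, model$out_dim)
      for (d in seq_len(n_draws)) {
        b <- xb[base_idx[d], ]
        J <- model_jacobian(model, b + alphas[d] * (x - b))
        acc <- acc + (x - b) * J
      }
      attr_sum <- attr_sum + acc / n_draws
      tab <- tabulate(base_idx, nbins = nrow(xb))
      base_weight <- base_weight + tab / n_draws
    }
  })
  base_weight <- base_weight / nrow(xe)
  out <- attr_sum / nrow(xe)
  feat <- model$input_panel %||% colnames(xe) %||%
    sprintf("feature%d", seq_len(model$in_dim))
  outs <- model$output_panel %||% sprintf("output%d", seq_len(model$out_dim))
  dimnames(out) <- list(feat, outs)
  # completeness reference: mean prediction of the explained samples minus
  # the prediction mean over the realized baseline multiset (weights differ
  # from uniform only when n_draws is not a multiple of the background size)
  fk_gap <- colMeans(nn_forward_eval(model, xe)) -
    as.numeric(crossprod(base_weight, nn_forward_eval(model, xb)))
  structure(out, class = c("attribution_matrix", "matrix"),
            background_size = nrow(xb), n_samples_explained = nrow(xe),
            seed = seed, fk_gap = fk_gap)
}

#' Rank features by attribution
#'
#' Orders features by the mean absolute attribution over outputs (optionally
#' restricted to a hub subset), descending, with deterministic alphabetical
#' tie-breaking.
#'
#' @param attr an [attribution_matrix][gradient_shap()] (features x outputs).
#' @param aggregate `"mean_abs"` over all outputs or `"mean_abs_hub"` over
#'   the subset in `hub`.
#' @param hub character vector of output (miRNA) names for
#'   `"mean_abs_hub"`.
#' @param signed aggregate signed values instead of absolute values.
#' @return character vector of feature names, most important first.
#' @export
rank_features <- function(attr, aggregate = c("mean_abs", "mean_abs_hub"),
                          hub = NULL, signed = FALSE) {
  aggregate <- match.arg(aggregate)
  values <- unclass(attr)
  if (aggregate == "mean_abs_hub") {
    if (is.null(hub)) stop("`hub` is required for mean_abs_hub")
    missing_hub <- setdiff(hub, colnames(values))
    if (length(missing_hub)) {
      stop("hub miRNAs not in the attribution matrix: ",
           paste(head(missing_hub, 5L), collapse = ", "))
    }
    values <- values[, hub, drop = FALSE]
  }
  score <- if (signed) rowMeans(values) else rowMeans(abs(values))
  feat <- rownames(values)
  feat[order(-score, feat)]
}

#' Select hub miRNAs from an evaluation report
#'
#' Hub miRNAs are those whose expression is tightly coupled to the mRNA
#' state, operationalized as an (independent-test) per-miRNA prediction PCC
#' at or above the threshold; 0.8 marks the elbow above which miRNAs show a
#' pronounced increase in cross-cancer involvement.
#'
#' @param report an [evaluate_predictions()] report with a `per_mirna` table
#'   (or the table itself).
#' @param threshold inclusive PCC threshold (default 0.8).
#' @return data.frame `mirna`, `pcc`, sorted by decreasing PCC.
#' @export
select_hub_mirnas <- function(report, threshold = 0.8) {
  tab <- if (inherits(report, "evaluation_report")) report$per_mirna else
    report
  if (is.null(tab) || !all(c("mirna", "pcc") %in% names(tab))) {
    stop("need a per-miRNA table with `mirna` and `pcc` columns")
  }
  keep <- !is.na(tab$pcc) & tab$pcc >= threshold
  out <- tab[keep, c("mirna", "pcc")]
  out[order(-out$pcc), , drop = FALSE]
}

#' Export a SHAP-weighted gene-to-miRNA edge network
#'
#' Filters the attribution matrix into a weighted bipartite edge list, either
#' by an absolute-weight threshold or by keeping the top `k` genes per miRNA
#' (mutually exclusive). Signed weights are preserved.
#'
#' @param attr an [attribution_matrix][gradient_shap()].
#' @param min_abs_weight keep edges with `|weight| >= min_abs_weight`.
#' @param top_k keep the `top_k` genes with largest `|weight|` per miRNA.
#' @return data.frame `gene`, `mirna`, `weight`.
#' @export
shap_edge_network <- function(attr, min_abs_weight = NULL, top_k = NULL) {
  if (!is.null(min_abs_weight) && !is.null(top_k)) {
    stop("`min_abs_weight` and `top_k` are mutually exclusive")
  }
  if (is.null(min_abs_weight) && is.null(top_k)) {
    stop("supply one of `min_abs_weight` or `top_k`")
  }
  values <- unclass(attr)
  genes <- rownames(values); mirnas <- colnames(values)
  rows <- list()
  for (k in seq_along(mirnas)) {
    w <- values[, k]
    keep <- if (!is.null(min_abs_weight)) {
      which(abs(w) >= min_abs_weight)
    } else {
      head(order(-abs(w), genes), top_k)
    }
    if (length(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(gene = genes[keep],
                                              mirna = mirnas[k],
                                              weight = as.numeric(w[keep]))
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(0), mirna = character(0),
                      weight = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an edge list to disk
#'
#' @param edges data.frame from [shap_edge_network()].
#' @param path output path.
#' @param format `"tsv"` (tab-delimited) or `"graphml"` (GraphML XML, genes
#'   and miRNAs as typed nodes, signed `weight` edge attribute).
#' @return `path`, invisibly.
#' @export
write_edge_network <- function(edges, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    data.table::fwrite(edges, path, sep = "\t")
  } else {
    nodes <- unique(c(edges$gene, edges$mirna))
    types <- ifelse(nodes %in% edges$gene, "gene", "mirna")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="type" for="node" attr.name="type" attr.type="string"/>',
      '  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
      '  <graph edgedefault="directed">'), con)
    for (i in seq_along(nodes)) {
      writeLines(sprintf('    <node id="%s"><data key="type">%s</data></node>',
                         nodes[i], types[i]), con)
    }
    for (i in seq_len(nrow(edges))) {
      writeLines(sprintf(paste0('    <edge source="%s" target="%s">',
                                '<data key="weight">%.10g</data></edge>'),
                         edges$gene[i], edges$mirna[i], edges$weight[i]), con)
    }
    writeLines(c('  </graph>', '</graphml>'), con)
  }
  invisible(path)
}
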