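#' Regression evaluation metrics
#'
#' Per-miRNA (column-wise) metrics between ground truth `y` and prediction
#' `yhat`: Pearson correlation (`pcc`), mean squared error (`mse`), its root
#' (`rmse`), and the coefficient of determination (`r2`), defined as
#' `1 - SSE/SST` with `SST` taken about the ground-truth mean, so `r2 = 0`
#' means the model does no better than predicting that mean and `r2 < 0`
#' means it does worse.
#'
#' @param y,yhat numeric vectors of equal length (`>= 2` for `pcc`).
#' @return a single numeric value. `pcc` and `r2` return `NaN` (with a
#'   warning) when the relevant vector is constant.
#' @export
#' @examples
#' pcc(c(1, 2, 3), c(3, 2, 1))   # -1
#' r2(c(0, 2), c(1, 1))          # 0: the mean predictor
pcc <- function(y, yhat) {
  check_that(length(y) == length(yhat), "lengths differ")
  check_that(length(y) >= 2L, "need at least 2 observations")
  if (sd(y) == 0 || sd(yhat) == 0) {
    warning("constant input: PCC undefined, returning NaN")
    return(NaN)
  }
  cor(y, yhat)
}

#' @rdname pcc
#' @export
mse <- function(y, yhat) {
  check_that(length(y) == length(yhat), "lengths differ")
  mean((yhat - y)^2)
}

#' @rdname pcc
#' @export
rmse <- function(y, yhat) sqrt(mse(y, yhat))

#' @rdname pcc
#' @export
r2 <- function(y, yhat) {
  check_that(length(y) == length(yhat), "lengths differ")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    warning("constant ground truth: R^2 undefined, returning NaN")
    return(NaN)
  }
  1 - sum((yhat - y)^2) / sst
}

#' Evaluate a prediction matrix against ground truth
#'
#' Computes per-miRNA (column-wise) PCC/MSE/RMSE/R-squared and per-sample
#' (row-wise) PCC, plus summary means. Columns that are constant in the
#' ground truth are flagged and excluded from the summary means (their
#' correlation is undefined) rather than propagating NaN.
#'
#' @param y ground-truth matrix, samples x miRNAs.
#' @param yhat prediction matrix of identical shape.
#' @param axis which tables to compute: `"both"` (default), `"per_mirna"`, or
#'   `"per_sample"`.
#' @return an object of class `evaluation_report`: list with `per_mirna`
#'   (data.frame mirna/pcc/mse/rmse/r2/constant), `per_sample` (data.frame
#'   sample/pcc), `summary` (named list of means over non-constant columns),
#'   and `n_constant`.
#' @export
evaluate_predictions <- function(y, yhat,
                                 axis = c("both", "per_mirna", "per_sample")) {
  axis <- match.arg(axis)
  y <- as_matrix(y); yhat <- as_matrix(yhat)
  if (!all(dim(y) == dim(yhat))) {
    stop("shape mismatch: ", paste(dim(y), collapse = "x"), " vs ",
         paste(dim(yhat), collapse = "x"))
  }
  out <- list(per_mirna = NULL, per_sample = NULL, summary = list(),
              n_constant = 0L)
  class(out) <- "evaluation_report"

  if (axis %in% c("both", "per_mirna")) {
    n <- ncol(y)
    ids <- colnames(y) %||% sprintf("col%d", seq_len(n))
    pccs <- mses <- r2s <- numeric(n)
    const <- logical(n)
    for (k in seq_len(n)) {
      const[k] <- sd(y[, k]) == 0
      mses[k] <- mse(y[, k], yhat[, k])
      if (const[k]) {
        pccs[k] <- NaN; r2s[k] <- NaN
      } else {
        pccs[k] <- suppressWarnings(pcc(y[, k], yhat[, k]))
        r2s[k] <- r2(y[, k], yhat[, k])
      }
    }
    out$per_mirna <- data.frame(mirna = ids, pcc = pccs, mse = mses,
                                rmse = sqrt(mses), r2 = r2s,
                                constant = const, row.names = NULL)
    keep <- !const
    out$n_constant <- sum(const)
    out$summary$mean_pcc <- mean(pccs[keep], na.rm = TRUE)
    out$summary$mean_mse <- mean(mses[keep])
    out$summary$mean_rmse <- mean(sqrt(mses)[keep])
    out$summary$mean_r2 <- mean(r2s[keep], na.rm = TRUE)
  }
  if (axis %in% c("both", "per_sample")) {
    ids <- rownames(y) %||% sprintf("row%d", seq_len(nrow(y)))
    sp <- vapply(seq_len(nrow(y)), function(i) {
      if (sd(y[i, ]) == 0 || sd(yhat[i, ]) == 0) NaN else cor(y[i, ], yhat[i, ])
    }, numeric(1L))
    out$per_sample <- data.frame(sample = ids, pcc = sp, row.names = NULL)
    out$summary$mean_sample_pcc <- mean(sp, na.rm = TRUE)
  }
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  for (nm in names(x$summary)) {
    cat(sprintf("  %-16s %.4f\n", nm, x$summary[[nm]]))
  }
  if (x$n_constant > 0) {
    cat("  (", x$n_constant, "constant ground-truth columns excluded )\n")
  }
  invisible(x)
}

#' Classify a performance regime
#'
#' Bands performance into the regimes used when stress-testing the model:
#' `"collapsed"` — indistinguishable from an average predictor
#' (`R^2 <= 0` and `|PCC| <= pcc_eps`); `"nontrivial"` — `PCC > 0.2` and
#' `R^2 > 0`; anything else is `"intermediate"`.
#'
#' @param mean_pcc,mean_r2 summary metrics (finite).
#' @param pcc_eps tolerance operationalizing "PCC = 0" (default 0.05).
#' @return one of `"collapsed"`, `"nontrivial"`, `"intermediate"`.
#' @export
#' @examples
#' classify_regime(0.0, -0.1)   # collapsed
#' classify_regime(0.25, 0.01)  # nontrivial
classify_regime <- function(mean_pcc, mean_r2, pcc_eps = 0.05) {
  check_that(is.finite(mean_pcc) && is.finite(mean_r2),
             "inputs must be finite")
  if (mean_r2 <= 0 && abs(mean_pcc) <= pcc_eps) return("collapsed")
  if (mean_pcc > 0.2 && mean_r2 > 0) return("nontrivial")
  "intermediate"
}
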