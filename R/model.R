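#' Network hyperparameter configuration
#'
#' Defaults reproduce the published tuning of the landmark-to-miRNA
#' regression network: two hidden blocks of 1024 units, each
#' `linear -> batch norm -> ReLU -> dropout(0.3)`, a linear output layer,
#' plain SGD with learning rate 0.4 on an MSE loss, early stopping after 20
#' epochs without validation improvement with the best-validation weights
#' restored, and a 20% validation split drawn by `val_seed`.
#'
#' The large learning rate is stable because inputs and targets are z-scored
#' and every hidden block is batch-normalized; the trainer nevertheless
#' aborts with a diagnostic if the loss turns non-finite.
#'
#' @param n_hidden_layers number of hidden blocks (0 gives a plain linear
#'   map).
#' @param hidden_size units per hidden block.
#' @param dropout dropout fraction in `[0, 1)`.
#' @param learning_rate SGD learning rate.
#' @param optimizer only `"sgd"`.
#' @param momentum SGD momentum (default 0).
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience in epochs; default 20, capped at
#'   `max_epochs`.
#' @param val_fraction fraction of rows held out for validation, in (0, 1).
#' @param val_seed seed for the validation split.
#' @param batch_size minibatch size.
#' @param init_seed seed for weight initialization.
#' @param shuffle_seed seed for epoch shuffling and dropout draws; defaults to
#'   `init_seed + 1000`.
#' @param bn_momentum,bn_eps batch-normalization running-statistics momentum
#'   and variance floor.
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_hidden_layers = 2L, hidden_size = 1024L,
                         dropout = 0.3, learning_rate = 0.4,
                         optimizer = "sgd", momentum = 0,
                         max_epochs = 200L, patience = NULL,
                         val_fraction = 0.2, val_seed = 42L,
                         batch_size = 128L, init_seed = 1L,
                         shuffle_seed = NULL,
                         bn_momentum = 0.1, bn_eps = 1e-5) {
  optimizer <- match.arg(optimizer, "sgd")
  check_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  check_that(val_fraction > 0 && val_fraction < 1,
             "val_fraction must be in (0, 1)")
  if (is.null(patience)) patience <- min(20L, max_epochs)
  check_that(patience <= max_epochs, "patience must be <= max_epochs")
  check_that(n_hidden_layers >= 0, "n_hidden_layers must be >= 0")
  if (is.null(shuffle_seed)) shuffle_seed <- as.integer(init_seed) + 1000L
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 hidden_size = as.integer(hidden_size), dropout = dropout,
                 learning_rate = learning_rate, optimizer = optimizer,
                 momentum = momentum, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, val_seed = as.integer(val_seed),
                 batch_size = as.integer(batch_size),
                 init_seed = as.integer(init_seed),
                 shuffle_seed = as.integer(shuffle_seed),
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "model_config")
}

#' Build an untrained network
#'
#' Architecture: `[linear -> batch norm -> ReLU -> dropout] x n_hidden_layers
#' -> linear`. Weights are initialized uniformly in
#' `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`, deterministically given
#' `config$init_seed`.
#'
#' @param config a [model_config()].
#' @param in_dim input width (number of landmark genes).
#' @param out_dim output width (number of miRNAs).
#' @return an object of class `landmir_model`.
#' @export
build_model <- function(config = model_config(), in_dim, out_dim) {
  check_that(in_dim >= 1 && out_dim >= 1, "dimensions must be positive")
  with_seed(config$init_seed, {
    layers <- list()
    fan_in <- in_dim
    for (l in seq_len(config$n_hidden_layers)) {
      h <- config$hidden_size
      bound <- 1 / sqrt(fan_in)
      layers[[l]] <- list(
        W = matrix(runif(fan_in * h, -bound, bound), fan_in, h),
        b = runif(h, -bound, bound),
        gamma = rep(1, h), beta = rep(0, h),
        run_mean = rep(0, h), run_var = rep(1, h))
      fan_in <- h
    }
    bound <- 1 / sqrt(fan_in)
    structure(list(config = config, in_dim = as.integer(in_dim),
                   out_dim = as.integer(out_dim), layers = layers,
                   W_out = matrix(runif(fan_in * out_dim, -bound, bound),
                                  fan_in, out_dim),
                   b_out = runif(out_dim, -bound, bound),
                   input_panel = NULL, output_panel = NULL,
                   x_center = NULL, x_scale = NULL,
                   y_center = NULL, y_scale = NULL,
                   history = NULL, best_epoch = NA_integer_,
                   trained = FALSE),
              class = "landmir_model")
  })
}

#' Number of trainable parameters
#' @param model a [landmir_model][build_model()].
#' @return integer count of trainable weights (batch-norm running statistics
#'   are not trainable and are not counted).
#' @export
n_parameters <- function(model) {
  n <- length(model$W_out) + length(model$b_out)
  for (l in model$layers) {
    n <- n + length(l$W) + length(l$b) + length(l$gamma) + length(l$beta)
  }
  as.integer(n)
}

# internal: inference-mode forward pass (running statistics, no dropout)
nn_forward_eval <- function(model, X) {
  eps <- model$config$bn_eps
  H <- X
  for (l in model$layers) {
    Z <- sweep(H %*% l$W, 2L, l$b, "+")
    Z <- sweep(Z, 2L, l$run_mean)
    Z <- sweep(Z, 2L, sqrt(l$run_var + eps), "/")
    Z <- sweep(sweep(Z, 2L, l$gamma, "*"), 2L, l$beta, "+")
    H <- pmax(Z, 0)
  }
  sweep(H %*% model$W_out, 2L, model$b_out, "+")
}

# internal: one training forward+backward+SGD step on a minibatch.
# Mutates `model` (an environment holding layers/W_out/b_out) in place.
nn_train_step <- function(env, X, Y) {
  cfg <- env$config
  eps <- cfg$bn_eps
  B <- nrow(X)
  nl <- length(env$layers)
  cache <- vector("list", nl)
  H <- X
  for (l in seq_len(nl)) {
    ly <- env$layers[[l]]
    Z <- sweep(H %*% ly$W, 2L, ly$b, "+")
    mu <- colMeans(Z)
    v <- colMeans(Z^2) - mu^2
    v[v < 0] <- 0
    inv <- 1 / sqrt(v + eps)
    Xhat <- sweep(sweep(Z, 2L, mu), 2L, inv, "*")
    A <- sweep(sweep(Xhat, 2L, ly$gamma, "*"), 2L, ly$beta, "+")
    R <- pmax(A, 0)
    if (cfg$dropout > 0) {
      M <- matrix((runif(length(R)) >= cfg$dropout) / (1 - cfg$dropout),
                  nrow(R), ncol(R))
      Hn <- R * M
    } else {
      M <- NULL
      Hn <- R
    }
    # running statistics (unbiased variance, torch convention)
    vb <- if (B > 1L) v * B / (B - 1L) else v
    env$layers[[l]]$run_mean <- (1 - cfg$bn_momentum) * ly$run_mean +
      cfg$bn_momentum * mu
    env$layers[[l]]$run_var <- (1 - cfg$bn_momentum) * ly$run_var +
      cfg$bn_momentum * vb
    cache[[l]] <- list(input = H, Xhat = Xhat, inv = inv, A = A, M = M)
    H <- Hn
  }
  Yhat <- sweep(H %*% env$W_out, 2L, env$b_out, "+")
  err <- Yhat - Y
  loss <- mean(err^2)
  if (!is.finite(loss)) {
    stop("training diverged: non-finite loss; z-score the inputs/targets or ",
         "lower the learning rate", call. = FALSE)
  }
  lr <- cfg$learning_rate
  mom <- cfg$momentum
  if (mom > 0 && is.null(env$vel)) {
    env$vel <- list(W_out = 0 * env$W_out, b_out = 0 * env$b_out,
                    layers = lapply(env$layers, function(ly) {
                      list(W = 0 * ly$W, b = 0 * ly$b,
                           gamma = 0 * ly$gamma, beta = 0 * ly$beta)
                    }))
  }
  upd <- function(slot_val, grad, vel_path) {
    if (mom > 0) {
      v <- mom * vel_path + grad
      list(param = slot_val - lr * v, vel = v)
    } else {
      list(param = slot_val - lr * grad, vel = NULL)
    }
  }
  dY <- err * (2 / length(err))
  # output layer
  dW_out <- crossprod(H, dY)
  db_out <- colSums(dY)
  dH <- dY %*% t(env$W_out)
  u <- upd(env$W_out, dW_out, if (mom > 0) env$vel$W_out)
  env$W_out <- u$param; if (mom > 0) env$vel$W_out <- u$vel
  u <- upd(env$b_out, db_out, if (mom > 0) env$vel$b_out)
  env$b_out <- u$param; if (mom > 0) env$vel$b_out <- u$vel
  # hidden blocks, reversed
  for (l in rev(seq_len(nl))) {
    ly <- env$layers[[l]]
    cc <- cache[[l]]
    dR <- if (is.null(cc$M)) dH else dH * cc$M
    dA <- dR * (cc$A > 0)
    dgamma <- colSums(dA * cc$Xhat)
    dbeta <- colSums(dA)
    dXhat <- sweep(dA, 2L, ly$gamma, "*")
    # batch-norm backward (population-variance normalization)
    m1 <- colMeans(dXhat)
    m2 <- colMeans(dXhat * cc$Xhat)
    dZ <- sweep(dXhat, 2L, m1)
    dZ <- dZ - sweep(cc$Xhat, 2L, m2, "*")
    dZ <- sweep(dZ, 2L, cc$inv, "*")
    dW <- crossprod(cc$input, dZ)
    db <- colSums(dZ)
    if (l > 1L) dH <- dZ %*% t(ly$W)
    if (mom > 0) {
      vl <- env$vel$layers[[l]]
      vl$W <- mom * vl$W + dW
      vl$b <- mom * vl$b + db
      vl$gamma <- mom * vl$gamma + dgamma
      vl$beta <- mom * vl$beta + dbeta
      env$vel$layers[[l]] <- vl
      env$layers[[l]]$W <- ly$W - lr * vl$W
      env$layers[[l]]$b <- ly$b - lr * vl$b
      env$layers[[l]]$gamma <- ly$gamma - lr * vl$gamma
      env$layers[[l]]$beta <- ly$beta - lr * vl$beta
    } else {
      env$layers[[l]]$W <- ly$W - lr * dW
      env$layers[[l]]$b <- ly$b - lr * db
      env$layers[[l]]$gamma <- ly$gamma - lr * dgamma
      env$layers[[l]]$beta <- ly$beta - lr * dbeta
    }
  }
  loss
}

#' Train the landmark-to-miRNA regression network
#'
#' Minimizes the mean squared error, averaged over samples and output
#' dimensions, by minibatch SGD. A `val_fraction` share of the rows (drawn by
#' `config$val_seed`) is held out; after every epoch the validation loss is
#' computed in inference mode, and training stops once it has not improved
#' for `config$patience` epochs. The returned model carries the weights of
#' the best-validation epoch and the full loss history. Training is
#' reproducible: fixed `init_seed`, `val_seed` and `shuffle_seed` give
#' identical weights on CPU.
#'
#' @param X z-scored input matrix, samples x genes.
#' @param Y z-scored target matrix, samples x miRNAs, row-aligned with `X`.
#' @param config a [model_config()].
#' @param model optionally, a pre-built [build_model()] to train (its config
#'   wins); by default a fresh model of matching dimensions is built.
#' @param input_panel,output_panel identifier vectors stored on the model;
#'   default to the matrix colnames.
#' @param x_stats,y_stats optional `list(center=, scale=)` per-gene
#'   normalization statistics captured at fit time (see [fit_mirna_model()]);
#'   stored for later inverse-transformation of predictions.
#' @param verbose print per-epoch losses.
#' @return a trained `landmir_model` with `history` (data.frame epoch /
#'   train_loss / val_loss) and `best_epoch`.
#' @export
train_model <- function(X, Y, config = model_config(), model = NULL,
                        input_panel = colnames(X),
                        output_panel = colnames(Y),
                        x_stats = NULL, y_stats = NULL, verbose = FALSE) {
  X <- as_matrix(X); Y <- as_matrix(Y)
  if (nrow(X) != nrow(Y)) {
    stop("X and Y must be row-aligned (", nrow(X), " vs ", nrow(Y), " rows)")
  }
  if (is.null(model)) {
    model <- build_model(config, ncol(X), ncol(Y))
  } else {
    config <- model$config
    check_that(model$in_dim == ncol(X) && model$out_dim == ncol(Y),
               "model dimensions do not match the data")
  }
  n <- nrow(X)
  n_val <- max(1L, round(config$val_fraction * n))
  val_idx <- with_seed(config$val_seed, sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0L) stop("no training rows left after the split")
  Xtr <- X[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
  Xva <- X[val_idx, , drop = FALSE]; Yva <- Y[val_idx, , drop = FALSE]

  env <- list2env(model[c("config", "layers", "W_out", "b_out")],
                  envir = new.env(parent = emptyenv()))
  best <- list(val = Inf, epoch = 0L, layers = NULL, W_out = NULL,
               b_out = NULL)
  hist_train <- hist_val <- numeric(0)
  with_seed(config$shuffle_seed, {
    epochs_no_improve <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(nrow(Xtr))
      starts <- seq(1L, nrow(Xtr), by = config$batch_size)
      batch_losses <- numeric(length(starts))
      for (i in seq_along(starts)) {
        rows <- perm[starts[i]:min(starts[i] + config$batch_size - 1L,
                                   nrow(Xtr))]
        batch_losses[i] <- nn_train_step(env, Xtr[rows, , drop = FALSE],
                                         Ytr[rows, , drop = FALSE])
      }
      snapshot <- list(config = config, layers = env$layers,
                       W_out = env$W_out, b_out = env$b_out)
      val_loss <- mean((nn_forward_eval(snapshot, Xva) - Yva)^2)
      hist_train <- c(hist_train, mean(batch_losses))
      hist_val <- c(hist_val, val_loss)
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        mean(batch_losses), val_loss))
      }
      if (val_loss < best$val) {
        best <- list(val = val_loss, epoch = epoch, layers = env$layers,
                     W_out = env$W_out, b_out = env$b_out)
        epochs_no_improve <- 0L
      } else {
        epochs_no_improve <- epochs_no_improve + 1L
        if (epochs_no_improve >= config$patience) break
      }
    }
  })

  model$layers <- best$layers
  model$W_out <- best$W_out
  model$b_out <- best$b_out
  model$best_epoch <- best$epoch
  model$history <- data.frame(epoch = seq_along(hist_train),
                              train_loss = hist_train, val_loss = hist_val)
  model$input_panel <- input_panel
  model$output_panel <- output_panel
  if (!is.null(x_stats)) { model$x_center <- x_stats$center
                           model$x_scale <- x_stats$scale }
  if (!is.null(y_stats)) { model$y_center <- y_stats$center
                           model$y_scale <- y_stats$scale }
  model$trained <- TRUE
  model
}

#' Fit the model on expression-scale paired matrices
#'
#' Convenience wrapper: z-scores `mrna` and `mirna` per gene (capturing the
#' statistics on the model for later inverse transformation), then calls
#' [train_model()].
#'
#' @param mrna expression-scale mRNA matrix, samples x genes (e.g.
#'   log2(FPKM+1)).
#' @param mirna expression-scale miRNA matrix, samples x miRNAs (e.g. RPM).
#' @param config a [model_config()].
#' @param verbose print per-epoch losses.
#' @return a trained `landmir_model` carrying the z-score statistics.
#' @export
fit_mirna_model <- function(mrna, mirna, config = model_config(),
                            verbose = FALSE) {
  Xz <- zscore_genes(mrna)
  Yz <- zscore_genes(mirna)
  train_model(as_matrix(Xz), as_matrix(Yz), config,
              input_panel = colnames(mrna), output_panel = colnames(mirna),
              x_stats = list(center = attr(Xz, "center"),
                             scale = attr(Xz, "scale")),
              y_stats = list(center = attr(Yz, "center"),
                             scale = attr(Yz, "scale")),
              verbose = verbose)
}

#' Predict miRNA profiles
#'
#' Deterministic inference: dropout off, batch normalization driven by the
#' running statistics captured during training (so a single-row input is
#' valid). Input columns must match the model's input panel.
#'
#' @param object a trained `landmir_model`.
#' @param newdata z-scored input matrix, samples x genes (align with
#'   [align_to_landmarks()] and [zscore_genes()] first). If the model was fit
#'   via [fit_mirna_model()] and `rescale_input = TRUE`, expression-scale
#'   input is z-scored with the stored training statistics.
#' @param output `"zscore"` (the training scale, default) or `"expression"`
#'   (inverse-transformed with the stored target statistics).
#' @param rescale_input z-score `newdata` with the stored training statistics
#'   before the forward pass.
#' @param ... unused.
#' @return matrix of predictions, rows aligned with `newdata`.
#' @export
predict.landmir_model <- function(object, newdata,
                                  output = c("zscore", "expression"),
                                  rescale_input = FALSE, ...) {
  output <- match.arg(output)
  X <- as_matrix(newdata)
  if (ncol(X) != object$in_dim) {
    stop("input width ", ncol(X), " does not match the model's expected ",
         object$in_dim, " features")
  }
  if (!is.null(object$input_panel) && !is.null(colnames(X)) &&
      !identical(colnames(X), as.character(object$input_panel))) {
    stop("input columns do not match the model's input panel; ",
         "run align_to_landmarks() first")
  }
  if (rescale_input) {
    if (is.null(object$x_center)) stop("model carries no input statistics")
    X <- sweep(X, 2L, object$x_center)
    nz <- object$x_scale > 0
    X[, nz] <- sweep(X[, nz, drop = FALSE], 2L, object$x_scale[nz], "/")
    X[, !nz] <- 0
  }
  Yhat <- nn_forward_eval(object, X)
  rownames(Yhat) <- rownames(X)
  colnames(Yhat) <- object$output_panel
  if (output == "expression") {
    if (is.null(object$y_center)) {
      stop("model carries no target statistics; fit with fit_mirna_model()")
    }
    Yhat <- zscore_invert(Yhat, object$y_center, object$y_scale)
  }
  Yhat
}

#' @export
print.landmir_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<landmir_model> %d -> %s -> %d (%s)\n", x$in_dim,
              paste(rep(cfg$hidden_size, cfg$n_hidden_layers),
                    collapse = " -> "),
              x$out_dim, if (x$trained) {
                sprintf("trained, best epoch %d, val MSE %.4f", x$best_epoch,
                        min(x$history$val_loss))
              } else "untrained"))
  cat(sprintf("  %s params, dropout %.2f, lr %.2g\n",
              format(n_parameters(x), big.mark = ","), cfg$dropout,
              cfg$learning_rate))
  invisible(x)
}

#' Save / load a fitted model
#'
#' Checkpoints are single-file RDS archives holding the weights, config,
#' panels and normalization statistics, with a format version tag.
#'
#' @param model a `landmir_model`.
#' @param path checkpoint path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "landmir_model"))
  saveRDS(list(format = "landmir_checkpoint", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "landmir_checkpoint")) {
    stop("not a landmiR checkpoint: ", path)
  }
  obj$model
}

#' Stratified k-fold cross-validation
#'
#' Splits the rows into `k` folds (stratified by `strata` when given, so each
#' fold preserves class proportions within one sample), trains a fresh model
#' on each training split and evaluates on the held-out fold. Validation
#' seeds rotate through `seeds` across folds.
#'
#' @param X,Y z-scored paired matrices, rows aligned.
#' @param k number of folds (`>= 2`).
#' @param strata optional stratification labels (e.g. cancer type), length
#'   `nrow(X)`; every stratum must have at least `k` members.
#' @param seeds validation-split seeds, recycled across folds.
#' @param config a [model_config()] used for every fold.
#' @return list with `per_fold` (data.frame fold / mean_pcc / mean_r2 /
#'   mean_mse), `reports` (per-fold [evaluate_predictions()] reports),
#'   `mean_pcc`, `se_pcc` (standard error across folds), and `folds` (the
#'   held-out row indices).
#' @export
cross_validate <- function(X, Y, k = 3L, strata = NULL,
                           seeds = c(42L, 52L, 62L),
                           config = model_config()) {
  check_that(k >= 2L, "k must be >= 2")
  X <- as_matrix(X); Y <- as_matrix(Y)
  n <- nrow(X)
  check_that(n == nrow(Y), "X and Y must be row-aligned")
  folds <- with_seed(seeds[1L], {
    assign_fold <- integer(n)
    if (is.null(strata)) strata <- rep(1L, n)
    check_that(length(strata) == n, "strata length must match rows")
    for (s in unique(strata)) {
      idx <- which(strata == s)
      if (length(idx) < k) {
        stop("stratum '", s, "' has ", length(idx), " rows, fewer than k = ", k)
      }
      assign_fold[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(k), length(idx))
    }
    split(seq_len(n), assign_fold)
  })
  reports <- vector("list", k)
  per_fold <- data.frame(fold = seq_len(k), mean_pcc = NA_real_,
                         mean_r2 = NA_real_, mean_mse = NA_real_)
  for (i in seq_len(k)) {
    test_idx <- folds[[i]]
    train_idx <- setdiff(seq_len(n), test_idx)
    cfg <- config
    cfg$val_seed <- as.integer(seeds[((i - 1L) %% length(seeds)) + 1L])
    fit <- train_model(X[train_idx, , drop = FALSE],
                       Y[train_idx, , drop = FALSE], cfg)
    pred <- predict(fit, X[test_idx, , drop = FALSE])
    rep_i <- evaluate_predictions(Y[test_idx, , drop = FALSE], pred,
                                  axis = "per_mirna")
    reports[[i]] <- rep_i
    per_fold$mean_pcc[i] <- rep_i$summary$mean_pcc
    per_fold$mean_r2[i] <- rep_i$summary$mean_r2
    per_fold$mean_mse[i] <- rep_i$summary$mean_mse
  }
  list(per_fold = per_fold, reports = reports,
       mean_pcc = mean(per_fold$mean_pcc),
       se_pcc = sd(per_fold$mean_pcc) / sqrt(k),
       folds = folds)
}
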