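#' Specification for the single-cell count simulator
#'
#' Describes synthetic single-cell counts over the landmark genes:
#' cell-type-specific mean profiles, log-normal library-size variation,
#' multinomial sampling of counts, and expression-dependent dropout
#' (an entry of mean expression `lambda` is zeroed with probability
#' `exp(-gamma * lambda)`, so low-abundance genes drop out preferentially).
#'
#' @param n_types number of cell types.
#' @param cells_per_type cells per type.
#' @param depth_mean mean library size (UMI) per cell; `> 0`.
#' @param depth_cv coefficient of variation of the library size.
#' @param dropout_gamma dropout shape `gamma >= 0`; 0 disables dropout,
#'   large values push the dropout probability of expressed genes to 0 while
#'   concentrating zeros among near-silent genes.
#' @param de_fraction fraction of miRNA families dysregulated between the
#'   first and second cell type, in `[0, 1]`.
#' @param de_fold multiplicative shift applied to the FPKM of the coupled
#'   gene programs in the perturbed type (`>= 1`; the direction alternates
#'   up/down across the selected families).
#' @param seed integer RNG seed.
#' @return an object of class `single_cell_sim_spec`.
#' @export
single_cell_sim_spec <- function(n_types = 2L, cells_per_type = 500L,
                                 depth_mean = 20000, depth_cv = 0.3,
                                 dropout_gamma = 0.5, de_fraction = 0.2,
                                 de_fold = 4, seed = 1L) {
  check_that(n_types >= 1 && cells_per_type >= 1, "dimensions must be positive")
  check_that(depth_mean > 0, "depth_mean must be > 0")
  check_that(depth_cv >= 0, "depth_cv must be >= 0")
  check_that(dropout_gamma >= 0, "dropout_gamma must be >= 0")
  check_that(de_fraction >= 0 && de_fraction <= 1,
             "de_fraction must be in [0, 1]")
  check_that(de_fold >= 1, "de_fold must be >= 1")
  structure(list(n_types = as.integer(n_types),
                 cells_per_type = as.integer(cells_per_type),
                 depth_mean = depth_mean, depth_cv = depth_cv,
                 dropout_gamma = dropout_gamma, de_fraction = de_fraction,
                 de_fold = de_fold, seed = as.integer(seed)),
            class = "single_cell_sim_spec")
}

#' Simulate single-cell counts with known dysregulated miRNAs
#'
#' Builds one mean FPKM profile per cell type — either derived from a paired
#' bulk simulation (`bulk`, the output of [simulate_bulk_paired()]) or passed
#' explicitly (`type_profiles`, one row per type) — then draws per-cell counts:
#' library size `~ LogNormal` matched to `depth_mean`/`depth_cv`, counts
#' `~ Multinomial(library, profile)`, and expression-dependent dropout with
#' probability `exp(-gamma * lambda)` where `lambda` is the profile FPKM
#' scaled by the 95th percentile of its non-zero entries (floored at 1e-12).
#'
#' When `bulk` is given, dysregulation between type 1 and type 2 is created by
#' multiplying the FPKM of the gene programs of `de_fraction` of the miRNA
#' families by `de_fold` (alternating up/down), and the true DE-miRNA list is
#' emitted: the members of the shifted families, with the direction computed
#' from the generative map applied to the two type profiles.
#'
#' @param spec a [single_cell_sim_spec()].
#' @param bulk output of [simulate_bulk_paired()]; its mean expression defines
#'   the base profile and its coupling weights define the DE ground truth.
#' @param type_profiles alternative to `bulk`: numeric matrix of FPKM-scale
#'   mean profiles, `n_types` x genes (no coupling available, so the DE list
#'   is empty unless profiles differ by construction and `de_fraction = 0`).
#' @return list with `counts` (integer cells x genes [expression_matrix()]),
#'   `labels` (cell-type factor), `de_mirnas` (data.frame `mirna`,
#'   `direction` in `up`/`down`, `log2fc_true`), `type_profiles` (FPKM),
#'   `type_mirna` (noiseless miRNA profile per type, when `bulk` is given),
#'   `library_sizes` (drawn, pre-dropout), and `spec`.
#' @export
simulate_single_cell <- function(spec, bulk = NULL, type_profiles = NULL) {
  stopifnot(inherits(spec, "single_cell_sim_spec"))
  if (is.null(bulk) == is.null(type_profiles)) {
    stop("supply exactly one of `bulk` or `type_profiles`")
  }
  with_seed(spec$seed, {
    if (!is.null(type_profiles)) {
      type_profiles <- as_matrix(type_profiles)
      if (nrow(type_profiles) != spec$n_types) {
        stop("type_profiles has ", nrow(type_profiles),
             " rows but spec$n_types = ", spec$n_types)
      }
      de <- data.frame(mirna = character(0), direction = character(0),
                       log2fc_true = numeric(0))
      type_mirna <- NULL
    } else {
      base <- colMeans(as_matrix(bulk$mrna))       # FPKM-scale base profile
      g <- length(base)
      type_profiles <- matrix(rep(base, each = spec$n_types),
                              nrow = spec$n_types,
                              dimnames = list(sprintf("type%d", seq_len(spec$n_types)),
                                              names(base)))
      fam <- bulk$families
      n_fam <- max(fam)
      n_de_fam <- round(spec$de_fraction * n_fam)
      de_fams <- if (n_de_fam > 0) sort(sample.int(n_fam, n_de_fam)) else integer(0)
      if (spec$n_types < 2L && n_de_fam > 0) {
        stop("dysregulation needs at least two cell types")
      }
      # shift the coupled gene programs of the selected families in type 2
      for (i in seq_along(de_fams)) {
        f <- de_fams[i]
        members <- which(fam == f)
        sup <- which(colSums(abs(bulk$weights[members, , drop = FALSE])) > 0)
        fold <- if (i %% 2L == 1L) spec$de_fold else 1 / spec$de_fold
        type_profiles[2L, sup] <- type_profiles[2L, sup] * fold
      }
      # noiseless generative miRNA profile per type -> true directions
      L_type <- sweep(log2(type_profiles + 1), 2L, bulk$gene_centers)
      type_mirna <- softplus(tcrossprod(L_type, bulk$weights) +
                               matrix(bulk$intercepts, spec$n_types,
                                      length(bulk$intercepts), byrow = TRUE))
      colnames(type_mirna) <- rownames(bulk$weights)
      de_members <- which(fam %in% de_fams)
      if (length(de_members)) {
        lfc <- log2((type_mirna[2L, de_members] + 1e-9) /
                      (type_mirna[1L, de_members] + 1e-9))
        de <- data.frame(mirna = rownames(bulk$weights)[de_members],
                         direction = ifelse(lfc > 0, "up", "down"),
                         log2fc_true = as.numeric(lfc),
                         row.names = NULL)
      } else {
        de <- data.frame(mirna = character(0), direction = character(0),
                         log2fc_true = numeric(0))
      }
    }

    g <- ncol(type_profiles)
    genes <- colnames(type_profiles)
    if (is.null(genes)) genes <- sprintf("LMG%04d", seq_len(g))
    n_cells <- spec$n_types * spec$cells_per_type
    labels <- factor(rep(rownames(type_profiles) %||% sprintf("type%d", seq_len(spec$n_types)),
                         each = spec$cells_per_type))

    # log-normal library sizes matched to depth_mean / depth_cv
    cv2 <- spec$depth_cv^2
    sdlog <- sqrt(log1p(cv2))
    meanlog <- log(spec$depth_mean) - sdlog^2 / 2
    lib <- pmax(1L, as.integer(round(rlnorm(n_cells, meanlog, sdlog))))

    counts <- matrix(0L, n_cells, g,
                     dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                                     genes))
    for (t in seq_len(spec$n_types)) {
      prof <- type_profiles[t, ]
      p <- prof / sum(prof)
      idx <- which(as.integer(labels) == t)
      for (ci in idx) {
        counts[ci, ] <- as.integer(rmultinom(1L, size = lib[ci], prob = p))
      }
      # expression-dependent dropout on the type profile scale
      if (spec$dropout_gamma > 0) {
        nz <- prof[prof > 0]
        p95 <- if (length(nz)) quantile(nz, 0.95, names = FALSE) else 1
        lambda <- pmax(prof / max(p95, .Machine$double.eps), 1e-12)
        p_drop <- exp(-spec$dropout_gamma * lambda)
        for (ci in idx) {
          drop <- runif(g) < p_drop
          counts[ci, drop] <- 0L
        }
      }
    }

    list(counts = expression_matrix(counts, norm_state = "raw_counts"),
         labels = labels, de_mirnas = de, type_profiles = type_profiles,
         type_mirna = type_mirna, library_sizes = lib, spec = spec)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
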