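#' Specification for the paired bulk expression simulator
#'
#' Describes a synthetic paired mRNA/miRNA bulk design with known
#' miRNA-to-mRNA coupling, emulating the structure of matched bulk RNA-seq
#' (log2(FPKM+1) convention) and miRNA-seq (RPM convention) compendia that
#' landmark-gene imputation models are trained on. miRNAs are organized in
#' "families": members of a family share the same support (the same coupled
#' gene set) and a common positive weight component, so within-family
#' expression correlation exceeds between-family correlation — the co-targeting
#' structure real miRNA families display.
#'
#' @param n_samples number of samples.
#' @param n_genes number of landmark genes (default 977).
#' @param n_mirnas number of miRNAs.
#' @param n_families number of co-regulated miRNA families (each miRNA belongs
#'   to exactly one; must not exceed `n_mirnas`).
#' @param coupling_density fraction of genes in each family's support, in
#'   `[0, 1]`. Density 0 decouples miRNAs from mRNA entirely.
#' @param noise_sd standard deviation of additive Gaussian noise on the miRNA
#'   values (RPM-like scale); `>= 0`.
#' @param coupling_strength overall scale of the coupling weights. Controls
#'   the between-sample dynamic range of the simulated miRNAs: the default
#'   gives order-of-magnitude variation (softplus-argument spread of a few
#'   units), matching the wide dispersion of real mature-miRNA RPM profiles.
#' @param n_factors number of latent co-expression factors driving the mRNA
#'   profiles. Transcriptomes are strongly co-expressed — a few dozen latent
#'   programs explain most landmark-gene variance — so the simulated
#'   log-expression is `mu + F %*% Lambda + idio noise` rather than
#'   independent genes.
#' @param idio_sd standard deviation of the per-gene idiosyncratic noise on
#'   the log2 scale (on top of the factor structure).
#' @param seed integer RNG seed.
#' @return an object of class `bulk_sim_spec`.
#' @export
bulk_sim_spec <- function(n_samples = 2000L, n_genes = 977L,
                          n_mirnas = 300L, n_families = 30L,
                          coupling_density = 0.02, noise_sd = 0,
                          coupling_strength = 3, n_factors = 40L,
                          idio_sd = 0.3, seed = 1L) {
  check_that(n_samples >= 1 && n_genes >= 1 && n_mirnas >= 1,
             "dimensions must be positive")
  check_that(n_families >= 1 && n_families <= n_mirnas,
             "n_families must be in [1, n_mirnas]")
  check_that(coupling_density >= 0 && coupling_density <= 1,
             "coupling_density must be in [0, 1]")
  check_that(noise_sd >= 0, "noise_sd must be >= 0")
  check_that(coupling_strength > 0, "coupling_strength must be > 0")
  check_that(n_factors >= 1, "n_factors must be >= 1")
  check_that(idio_sd >= 0, "idio_sd must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_mirnas = as.integer(n_mirnas),
                 n_families = as.integer(n_families),
                 coupling_density = coupling_density,
                 noise_sd = noise_sd, coupling_strength = coupling_strength,
                 n_factors = as.integer(n_factors),
                 idio_sd = idio_sd, seed = as.integer(seed)),
            class = "bulk_sim_spec")
}

#' Simulate paired bulk mRNA and miRNA expression with known coupling
#'
#' Generates an FPKM-scale mRNA matrix and a coupled RPM-like miRNA matrix:
#' `miRNA = softplus(W %*% (log2(FPKM + 1) - mu) + b) + noise`, where `mu` is
#' the per-gene reference baseline. The coupling matrix
#' `W` (miRNAs x genes) is returned so that model-recovery tests can compare
#' a trained network against the generative map. Same spec and seed give
#' bit-identical output.
#'
#' @param spec a [bulk_sim_spec()].
#' @return list with elements
#'   `mrna` ([expression_matrix()], FPKM scale, samples x genes),
#'   `mrna_log2` (the log2(FPKM+1) matrix actually coupled to the miRNAs),
#'   `mirna` ([expression_matrix()], RPM-like scale, samples x miRNAs),
#'   `weights` (miRNAs x genes coupling matrix `W`),
#'   `intercepts`, `gene_centers` (the reference log2 baseline the coupling
#'   is centered on), `families` (family index per miRNA), and `spec`.
#' @export
#' @examples
#' sim <- simulate_bulk_paired(bulk_sim_spec(n_samples = 50, n_genes = 40,
#'                                           n_mirnas = 10, n_families = 3,
#'                                           coupling_density = 0.1, seed = 7))
#' dim(sim$mrna); dim(sim$mirna)
simulate_bulk_paired <- function(spec) {
  stopifnot(inherits(spec, "bulk_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples; g <- spec$n_genes; m <- spec$n_mirnas
    genes <- sprintf("LMG%04d", seq_len(g))
    mirnas <- sprintf("syn-miR-%04d", seq_len(m))
    samples <- sprintf("S%04d", seq_len(n))

    # log2(FPKM+1) profiles: per-gene baseline + latent co-expression
    # factors (transcriptome-like low-rank covariance) + idiosyncratic noise
    mu <- runif(g, 1, 8)
    K <- spec$n_factors
    Lambda <- matrix(rnorm(K * g, sd = 1), K, g) / sqrt(K)
    FF <- matrix(rnorm(n * K), n, K)
    L <- FF %*% Lambda
    if (spec$idio_sd > 0) L <- L + matrix(rnorm(n * g, sd = spec$idio_sd), n, g)
    L <- pmax(sweep(L, 2L, mu, "+"), 0)
    dimnames(L) <- list(samples, genes)
    fpkm <- 2^L - 1

    # family-structured coupling: shared support, shared positive component.
    # Supports are disjoint gene programs when the panel is large enough
    # (so perturbing one family's program never cancels against another's);
    # otherwise they are drawn independently and may overlap.
    families <- rep(seq_len(spec$n_families), length.out = m)
    support_size <- max(0L, round(spec$coupling_density * g))
    W <- matrix(0, m, g, dimnames = list(mirnas, genes))
    disjoint <- support_size * spec$n_families <= g
    gene_perm <- sample.int(g)
    if (support_size > 0L) {
      for (f in seq_len(spec$n_families)) {
        sup <- if (disjoint) {
          gene_perm[((f - 1L) * support_size + 1L):(f * support_size)]
        } else {
          sample.int(g, support_size)
        }
        shared <- abs(rnorm(support_size, mean = 1, sd = 0.25))
        members <- which(families == f)
        for (k in members) {
          idio <- rnorm(support_size, sd = 0.3)
          W[k, sup] <- spec$coupling_strength * (shared + idio) / support_size
        }
      }
    }
    # miRNA responds to deviations of the gene programs from the reference
    # baseline (centered coupling), keeping softplus at a responsive
    # operating point so dysregulated programs translate into real fold
    # changes rather than vanishing against a large constant offset
    b <- runif(m, 1, 3)
    signal <- softplus(tcrossprod(sweep(L, 2L, mu), W) +
                         matrix(b, n, m, byrow = TRUE))
    noise <- if (spec$noise_sd > 0) {
      matrix(rnorm(n * m, sd = spec$noise_sd), n, m)
    } else 0
    mirna <- signal + noise
    dimnames(mirna) <- list(samples, mirnas)

    list(mrna = expression_matrix(fpkm, norm_state = "fpkm"),
         mrna_log2 = expression_matrix(L, norm_state = "fpkm_log2"),
         mirna = expression_matrix(mirna, norm_state = "rpm"),
         weights = W, intercepts = b, gene_centers = mu,
         families = families, spec = spec)
  })
}
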