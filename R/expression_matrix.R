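#' Expression matrix container
#'
#' A thin wrapper around a numeric `samples x genes` matrix that carries a
#' normalization-state tag so downstream steps can refuse inputs on the wrong
#' scale. Rows are samples (or cells), columns are genes (or miRNAs);
#' dimnames are mandatory.
#'
#' @param values numeric matrix, samples (rows) by genes (columns).
#' @param sample_ids optional character vector of row identifiers; defaults to
#'   existing rownames.
#' @param gene_ids optional character vector of column identifiers; defaults to
#'   existing colnames.
#' @param norm_state normalization state tag, one of
#'   `"raw_counts"`, `"fpkm"`, `"fpkm_log2"`, `"rpm"`, `"cpm_log"`,
#'   `"zscored"`.
#'
#' @return a numeric matrix of class `expression_matrix` with a `norm_state`
#'   attribute.
#' @export
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
#' x <- expression_matrix(m, norm_state = "raw_counts")
#' norm_state(x)
expression_matrix <- function(values, sample_ids = rownames(values),
                              gene_ids = colnames(values),
                              norm_state = "raw_counts") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("empty expression matrix (", nrow(values), " x ", ncol(values), ")")
  }
  if (is.null(sample_ids) || is.null(gene_ids)) {
    stop("sample and gene identifiers are required")
  }
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != nrow(values) || length(gene_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  norm_state <- match.arg(norm_state, .norm_states)
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(values, norm_state = norm_state,
            class = c("expression_matrix", class(values)))
}

.norm_states <- c("raw_counts", "fpkm", "fpkm_log2", "rpm", "cpm_log",
                  "zscored")

#' Normalization state of an expression matrix
#'
#' @param x an [expression_matrix()] (a bare matrix returns `NA`).
#' @return the `norm_state` tag, or `NA_character_` when absent.
#' @export
norm_state <- function(x) {
  ns <- attr(x, "norm_state", exact = TRUE)
  if (is.null(ns)) NA_character_ else ns
}

#' @rdname norm_state
#' @param value new normalization state tag.
#' @export
`norm_state<-` <- function(x, value) {
  attr(x, "norm_state") <- match.arg(value, .norm_states)
  x
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d samples x %d genes [%s]\n",
              nrow(x), ncol(x), norm_state(x)))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

# internal: coerce to plain matrix, keep dimnames
as_matrix <- function(x) {
  if (inherits(x, "expression_matrix")) {
    attr(x, "norm_state") <- NULL
    class(x) <- "matrix"
    x <- unclass(x)
  }
  as.matrix(x)
}

# internal: carry a norm_state onto a plain matrix result
restate <- function(values, norm_state) {
  expression_matrix(values, norm_state = norm_state)
}

#' Fraction of zero entries in a matrix
#'
#' Sparsity is tracked before and after perturbation/normalization in the
#' stress-test suite: per-gene z-scoring maps zeros to finite values, so the
#' post-z-score sparsity of non-constant genes is 0 even when the input is
#' overwhelmingly sparse.
#'
#' @param x numeric matrix (or [expression_matrix()]).
#' @return fraction of entries equal to zero, in `[0, 1]`.
#' @export
#' @examples
#' sparsity(matrix(c(0, 1, 2, 0), 2, 2)) # 0.5
sparsity <- function(x) {
  x <- as_matrix(x)
  if (length(x) == 0L) stop("empty matrix has no defined sparsity")
  mean(x == 0)
}
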