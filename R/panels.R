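#' Landmark-gene and miRNA identifier panels
#'
#' The model input is fixed to an ordered panel of 977 landmark-gene symbols
#' (the L1000 set minus XBP1, which is zero in the paired training compendium)
#' and the output to an ordered panel of 1,298 mature-miRNA names. The package
#' bundles *synthetic stand-in* panels (placeholder identifiers of the correct
#' size and structure) under `inst/extdata`; supply `path` to use a real panel,
#' one identifier per line.
#'
#' @param path optional path to a plain-text file with one identifier per line.
#' @param n expected panel length; set to `NULL` to skip the length check.
#' @return character vector of panel identifiers, in file order.
#' @export
#' @examples
#' length(landmark_panel()) # 977
landmark_panel <- function(path = NULL, n = 977L) {
  if (is.null(path)) {
    path <- system.file("extdata", "landmark_panel_synthetic.txt",
                        package = "landmiR", mustWork = TRUE)
  }
  read_panel(path, n, what = "landmark gene")
}

#' @rdname landmark_panel
#' @export
#' @examples
#' length(mirna_panel()) # 1298
mirna_panel <- function(path = NULL, n = 1298L) {
  if (is.null(path)) {
    path <- system.file("extdata", "mirna_panel_synthetic.txt",
                        package = "landmiR", mustWork = TRUE)
  }
  read_panel(path, n, what = "miRNA")
}

read_panel <- function(path, n, what) {
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) {
    stop("duplicated ", what, " identifiers in panel file ", path)
  }
  if (!is.null(n) && length(ids) != n) {
    stop("expected ", n, " ", what, " identifiers, found ", length(ids),
         " in ", path)
  }
  ids
}
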