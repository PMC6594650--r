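#' Read a Newick tree
#'
#' Standard Newick with branch lengths; integer internal-node labels are
#' interpreted as bootstrap supports. Malformed input is an error.
#'
#' @param path Path to a Newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(txt)) abort("read_newick: empty file")
  n_open <- str_count(txt, "\\(")
  n_close <- str_count(txt, "\\)")
  if (n_open != n_close) {
    abort("read_newick: unbalanced parentheses")
  }
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                   error = function(e) NULL)
  if (is.null(tree)) abort(sprintf("read_newick: cannot parse %s", path))
  tree
}

#' Write a tree as Newick
#'
#' Branch lengths and internal-node support labels are preserved, so
#' `read_newick(write_newick(tree))` is the identity up to rotation.
#'
#' @param tree A `phylo` object (or `grpfam_boot`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "grpfam_boot")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}
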