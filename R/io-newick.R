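# Newick tree I/O via ape, with validation of branch lengths and support
# labels. Internal-node labels are the conventional carrier for bootstrap
# support percentages.

#' Read a newick tree
#'
#' @param path Path to a single-tree newick file. Internal node labels
#'   (e.g. bootstrap support) and branch lengths are preserved.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed newick in ", path)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length in ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf label: '",
         tree$tip.label[duplicated(tree$tip.label)][1], "'")
  tree
}

#' Write a tree to newick
#'
#' @param tree A `"phylo"` object.
#' @param path Output path.
#' @param digits Decimal precision for branch lengths.
#' @export
write_newick <- function(tree, path, digits = 10L) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}
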