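#' Parse a Newick string into a validated time tree
#'
#' A time tree is an [ape::read.tree()] `phylo` object whose branch lengths
#' are divergence times in million years (Myr). Parsing enforces the
#' invariants the downstream rate machinery relies on: unique non-empty leaf
#' names, a branch length on every edge, and non-negative lengths.
#'
#' @param text a Newick string (must end in `;`).
#' @return an object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:50,B:50):50,(C:50,D:50):50);")
#' total_tree_length(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("Newick parse error: not a valid tree", call. = FALSE)
  validate_time_tree(tree)
  tree
}

#' Read a time tree from a Newick file
#'
#' @param path path to a Newick file.
#' @param units `"Myr"` (default) or `"Byr"`; trees calibrated in billion
#'   years are converted to Myr on read.
#' @return a `phylo` object with branch lengths in Myr.
#' @export
read_time_tree <- function(path, units = c("Myr", "Byr")) {
  units <- match.arg(units)
  tree <- parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
  if (units == "Byr") {
    tree$edge.length <- tree$edge.length * 1000
    if (!is.null(tree$root.edge)) tree$root.edge <- tree$root.edge * 1000
  }
  tree
}

#' @keywords internal
validate_time_tree <- function(tree) {
  tips <- tree$tip.label
  if (any(is.na(tips)) || any(!nzchar(tips)))
    stop("tree has empty leaf names", call. = FALSE)
  dup <- unique(tips[duplicated(tips)])
  if (length(dup))
    stop("duplicate leaf names in tree: ", paste(dup, collapse = ", "),
         call. = FALSE)
  bl <- tree$edge.length
  if (is.null(bl))
    stop("tree has no branch lengths", call. = FALSE)
  bad <- which(is.na(bl) | is.nan(bl))
  if (length(bad)) {
    nodes <- tree$edge[bad, 2]
    labs <- ifelse(nodes <= length(tips), tips[nodes],
                   paste0("internal node ", nodes))
    stop("missing branch length above: ", paste(labs, collapse = ", "),
         call. = FALSE)
  }
  if (any(bl < 0))
    stop("negative branch length in tree", call. = FALSE)
  invisible(tree)
}

#' Total branch length of a time tree
#'
#' Sum of all branch lengths (including a root stem edge if the Newick
#' carried one), in the tree's units (Myr by convention).
#'
#' @param tree a `phylo` object.
#' @return numeric scalar.
#' @export
total_tree_length <- function(tree) {
  sum(tree$edge.length) + if (is.null(tree$root.edge)) 0 else tree$root.edge
}

#' Prune a time tree to a set of taxa
#'
#' Returns the induced subtree spanning exactly the requested leaves:
#' pass-through (degree-2) nodes are collapsed with branch lengths summed,
#' and no stem edge is retained above the most recent common ancestor of the
#' retained taxa — time that does not separate the observed taxa cannot host
#' observable substitutions. Pruning to a single taxon yields a degenerate
#' one-leaf tree with total length 0 for the same reason.
#'
#' @param tree a `phylo` object.
#' @param taxa character vector of leaf names to keep (non-empty subset of
#'   `tree$tip.label`).
#' @return a `phylo` object.
#' @export
prune_to_taxa <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stop("empty taxon set", call. = FALSE)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("taxa not in tree: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(taxa) == 1L) {
    out <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = taxa,
                edge.length = 0, Nnode = 1L)
    class(out) <- "phylo"
    return(out)
  }
  out <- ape::keep.tip(tree, taxa)
  out$root.edge <- NULL
  out
}
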