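#' Six-taxon primate species tree
#'
#' Unrooted topology over human (`hsap`), chimpanzee (`ptro`), gorilla
#' (`ggor`), orangutan (`pabe`), gibbon (`nleu`) and rhesus (`mmul`), with the
#' internal great-ape branches labelled `Hominini` (human + chimp stem),
#' `Homininae` (+ gorilla) and `Hominidae` (great-ape stem). Branch lengths
#' are expected codon substitutions per site; the defaults are the package's
#' simulation settings (of the order of, but somewhat longer than, real
#' great-ape divergences, so that a few hundred codons carry measurable
#' signal).
#'
#' @param branch_lengths Optional named numeric vector overriding default
#'   lengths; names are the branch names returned by [foreground_branches()].
#' @return An `ape::phylo` object (unrooted, 9 edges).
#' @export
great_ape_tree <- function(branch_lengths = NULL) {
  nwk <- paste0(
    "((((hsap:0.25,ptro:0.25)Hominini:0.08,ggor:0.18)Homininae:0.08,",
    "pabe:0.25)Hominidae:0.12,nleu:0.35,mmul:0.45);"
  )
  tree <- ape::read.tree(text = nwk)
  if (!is.null(branch_lengths)) {
    for (nm in names(branch_lengths)) {
      e <- branch_edge(tree, nm)
      tree$edge.length[e] <- branch_lengths[[nm]]
    }
  }
  tree
}

#' Branches testable as foreground
#'
#' The four terminal great-ape branches and the three internal great-ape stem
#' branches, each of which is labelled foreground in its own branch-site test.
#'
#' @return Character vector of branch names.
#' @export
foreground_branches <- function() {
  c("hsap", "ptro", "Hominini", "ggor", "Homininae", "pabe", "Hominidae")
}

# Edge index (row of tree$edge) of the branch subtending the named tip or
# labelled internal node.
branch_edge <- function(tree, name) {
  tip <- match(name, tree$tip.label)
  if (!is.na(tip)) {
    e <- which(tree$edge[, 2] == tip)
  } else {
    nd <- match(name, tree$node.label)
    if (is.na(nd)) stop("unknown branch name: ", name)
    node <- length(tree$tip.label) + nd
    e <- which(tree$edge[, 2] == node)
    if (length(e) == 0L) stop("branch '", name, "' has no parent edge (root)")
  }
  e
}

#' Label a foreground branch on a tree
#'
#' Wraps a phylogeny together with one designated foreground branch, the unit
#' on which a branch-site or relaxation test runs. All other branches are
#' background.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param foreground Branch name: a tip label or an internal node label.
#' @return A `labeled_tree` object.
#' @export
labeled_tree <- function(tree, foreground) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (any(tree$edge.length < 0)) stop("negative branch length")
  e <- branch_edge(tree, foreground)
  structure(
    list(tree = tree, foreground = foreground, fg_edge = e),
    class = "labeled_tree"
  )
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat("Labeled tree:", length(x$tree$tip.label), "tips,",
      "foreground branch:", x$foreground, "\n")
  invisible(x)
}

# Postorder edge data for the likelihood core: 0-based parent/child vectors,
# branch lengths, foreground flags, total node count.
tree_edge_data <- function(ltree) {
  tree <- ape::reorder.phylo(ltree$tree, "postorder")
  # foreground edge must be re-located after reordering
  fg <- branch_edge(tree, ltree$foreground)
  list(
    parent = as.integer(tree$edge[, 1] - 1L),
    child = as.integer(tree$edge[, 2] - 1L),
    blen = tree$edge.length,
    fg = as.integer(seq_len(nrow(tree$edge)) %in% fg),
    ntip = length(tree$tip.label),
    nnode = length(tree$tip.label) + tree$Nnode,
    tip_labels = tree$tip.label
  )
}

#' Write a tree with the foreground branch marked
#'
#' Writes newick with the conventional `#1` suffix on the label of the
#' foreground branch's subtended clade (tip name or internal node label).
#'
#' @param ltree A [labeled_tree()].
#' @param path Output file.
#' @export
write_labeled_tree <- function(ltree, path) {
  tree <- ltree$tree
  nm <- ltree$foreground
  tip <- match(nm, tree$tip.label)
  if (!is.na(tip)) {
    tree$tip.label[tip] <- paste0(nm, "#1")
  } else {
    nd <- match(nm, tree$node.label)
    tree$node.label[nd] <- paste0(nm, "#1")
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a tree with a `#1` foreground mark
#'
#' @param path Newick file in which exactly one tip or internal-node label
#'   carries the suffix `#1`.
#' @return A [labeled_tree()].
#' @export
read_labeled_tree <- function(path) {
  tree <- ape::read.tree(path)
  tips_marked <- grepl("#1$", tree$tip.label)
  nodes_marked <- if (is.null(tree$node.label)) logical(0) else
    grepl("#1$", tree$node.label)
  n_marked <- sum(tips_marked) + sum(nodes_marked)
  if (n_marked != 1L) stop("expected exactly one '#1' foreground mark, found ",
                           n_marked)
  tree$tip.label <- sub("#1$", "", tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- sub("#1$", "", tree$node.label)
  fg <- if (any(tips_marked)) tree$tip.label[tips_marked] else
    tree$node.label[nodes_marked]
  labeled_tree(tree, fg)
}
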