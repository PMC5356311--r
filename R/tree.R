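#' Read a rooted phylogeny with branch lengths from a Newick file
#'
#' The tree must carry branch lengths (expected substitutions/site) on every
#' edge and unique leaf names. An unrooted tree is refused unless `root_on`
#' names a leaf to use as outgroup; guessing a root silently is never done.
#'
#' @param path Newick file containing a single tree.
#' @param root_on Optional leaf name to root on when the input is unrooted.
#' @return An [ape::read.tree()] `phylo` object, rooted, with internal nodes
#'   labelled (existing labels kept, missing ones auto-filled as `N<k>`).
#' @export
read_tree <- function(path, root_on = NULL) {
  if (!file.exists(path)) abort(paste0("tree file not found: ", path))
  phy <- ape::read.tree(path)
  if (inherits(phy, "multiPhylo")) abort("expected a single Newick tree")
  if (is.null(phy)) abort("could not parse Newick tree")
  validate_tree(phy, root_on = root_on)
}

validate_tree <- function(phy, root_on = NULL) {
  if (is.null(phy$edge.length) || anyNA(phy$edge.length)) {
    abort("tree has missing branch lengths; lengths are required on every edge")
  }
  if (any(phy$edge.length < 0)) abort("negative branch length in tree")
  if (anyDuplicated(phy$tip.label)) {
    abort(paste0("duplicate leaf names: ",
                 paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
                       collapse = ", ")))
  }
  if (!ape::is.rooted(phy)) {
    if (is.null(root_on)) {
      abort("tree is unrooted; supply `root_on = <leaf name>` to root it")
    }
    if (!root_on %in% phy$tip.label) {
      abort(paste0("root_on leaf not in tree: ", root_on))
    }
    phy <- ape::root(phy, outgroup = root_on, resolve.root = TRUE)
  }
  label_internal_nodes(phy)
}

label_internal_nodes <- function(phy) {
  n_int <- phy$Nnode
  auto <- paste0("N", seq_len(n_int))
  if (is.null(phy$node.label)) {
    phy$node.label <- auto
  } else {
    blank <- is.na(phy$node.label) | phy$node.label == ""
    phy$node.label[blank] <- auto[blank]
  }
  if (anyDuplicated(phy$node.label)) abort("duplicate internal node labels")
  phy
}

#' Write a tree to Newick
#'
#' @param phy A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}

# Indexed form of a rooted phylo used by the likelihood machinery:
# postorder node sequence, children lists, branch length above each node.
tree_index <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  parent <- integer(n_node); parent[] <- NA_integer_
  blen <- rep(NA_real_, n_node)
  children <- vector("list", n_node)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; c <- phy$edge[i, 2]
    parent[c] <- p
    blen[c] <- phy$edge.length[i]
    children[[p]] <- c(children[[p]], c)
  }
  root <- n_tip + 1L
  po <- ape::reorder.phylo(phy, "postorder")
  post_nodes <- unique(c(po$edge[, 2], root))  # children before parents; root last
  labels <- c(phy$tip.label, phy$node.label)
  list(n_tip = n_tip, n_node = n_node, root = root, parent = parent,
       blen = blen, children = children, postorder = post_nodes,
       labels = labels, phy = phy)
}

# Node label -> node number (tips and internal nodes).
node_number <- function(phy, label) {
  labels <- c(phy$tip.label, phy$node.label)
  i <- match(label, labels)
  if (is.na(i)) abort(paste0("unknown node label: ", label))
  i
}

# Leaf tips descending from a node number.
descendant_tips <- function(idx, node) {
  if (node <= idx$n_tip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    v <- stack[[1]]; stack <- stack[-1]
    kids <- idx$children[[v]]
    out <- c(out, kids[kids <= idx$n_tip])
    stack <- c(stack, kids[kids > idx$n_tip])
  }
  out
}
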