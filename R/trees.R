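#' Default seven-species tactile-foraging study tree
#'
#' Fixed topology `((ostrich,(kiwi,tinamou)),((chicken,mallard),(egret,ibis)))`
#' with the three independent tactile-foraging lineages (kiwi, mallard,
#' ibis) flagged as foreground and ostrich as outgroup. `"time"` mode
#' returns an ultrametric tree (default depth 111 time units) for
#' gene-family evolution; `"sequence"` mode returns substitution-scale
#' branch lengths (default 0.1 per branch) for sequence simulation.
#'
#' @param mode `"sequence"` or `"time"`.
#' @param depth Root-to-tip depth of the time tree, in time units.
#' @param branch_length Per-branch length of the sequence tree, in
#'   expected substitutions per site.
#' @return An [ape::phylo] tree with node labels and attributes
#'   `foreground` (tip labels) and `outgroup` (single tip label).
#' @export
make_default_tree <- function(mode = c("sequence", "time"), depth = 111,
                              branch_length = 0.1) {
  mode <- match.arg(mode)
  if (mode == "time") {
    # internal node ages scaled so the root sits at `depth`
    s <- depth / 111
    a <- c(root = 111, palaeo = 73, kiwi_tinamou = 60, neo = 88,
           chicken_mallard = 80, egret_ibis = 45) * s
    nwk <- sprintf(
      "((ostrich:%.12g,(kiwi:%.12g,tinamou:%.12g)kiwi_tinamou:%.12g)palaeo:%.12g,((chicken:%.12g,mallard:%.12g)chicken_mallard:%.12g,(egret:%.12g,ibis:%.12g)egret_ibis:%.12g)neo:%.12g)root;",
      a["palaeo"], a["kiwi_tinamou"], a["kiwi_tinamou"],
      a["palaeo"] - a["kiwi_tinamou"], a["root"] - a["palaeo"],
      a["chicken_mallard"], a["chicken_mallard"],
      a["neo"] - a["chicken_mallard"], a["egret_ibis"], a["egret_ibis"],
      a["neo"] - a["egret_ibis"], a["root"] - a["neo"])
  } else {
    b <- branch_length
    nwk <- sprintf(
      "((ostrich:%.12g,(kiwi:%.12g,tinamou:%.12g)kiwi_tinamou:%.12g)palaeo:%.12g,((chicken:%.12g,mallard:%.12g)chicken_mallard:%.12g,(egret:%.12g,ibis:%.12g)egret_ibis:%.12g)neo:%.12g)root;",
      b, b, b, b, b, b, b, b, b, b, b, b)
  }
  tree <- ape::read.tree(text = nwk)
  attr(tree, "foreground") <- c("kiwi", "mallard", "ibis")
  attr(tree, "outgroup") <- "ostrich"
  tree
}

#' Foreground tips of a species tree
#' @param tree A phylo tree carrying a `foreground` attribute.
#' @return Character vector of foreground tip labels.
#' @export
foreground_tips <- function(tree) attr(tree, "foreground")

#' Outgroup tip of a species tree
#' @param tree A phylo tree carrying an `outgroup` attribute.
#' @return Single outgroup tip label.
#' @export
outgroup_tip <- function(tree) attr(tree, "outgroup")

# Node label lookup covering tips and internal nodes: node number -> label.
node_labels <- function(tree) {
  nl <- tree$node.label
  if (is.null(nl) || any(nl == ""))
    nl <- paste0("node", seq_len(tree$Nnode) + length(tree$tip.label))
  c(tree$tip.label, nl)
}

# Edges in postorder with child labels; each branch is named by its child
# node. Returns data.frame(parent, child, length, name).
edge_table <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  labs <- node_labels(tree)
  data.frame(parent = po$edge[, 1], child = po$edge[, 2],
             length = po$edge.length, name = labs[po$edge[, 2]],
             stringsAsFactors = FALSE)
}

root_node <- function(tree) length(tree$tip.label) + 1L

# Edges whose subtree is one of the named tips' pendant branches, or
# generally: edge names for a set of tip labels (pendant branches).
pendant_edges <- function(tree, tips) {
  et <- edge_table(tree)
  stopifnot(all(tips %in% tree$tip.label))
  et$name[match(tips, et$name)]
}

# Validate an ultrametric time tree; error names offending tip depths.
check_ultrametric <- function(tree, tol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (diff(range(d)) > tol * max(d)) {
    bad <- paste(sprintf("%s=%.6g", tree$tip.label, d), collapse = ", ")
    stop("tree is not ultrametric; tip depths: ", bad)
  }
  invisible(tree)
}
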