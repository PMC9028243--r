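#' Simulate a codon alignment under a GY94 model with branch-specific omega
#'
#' Evolves sense codons down the tree under the Goldman-Yang 61-state
#' model. Branch-specific dN/dS values are supplied as a named vector
#' keyed by branch (each branch is named after its child node or tip);
#' unnamed branches use `omega_default`. Alternatively a branch-site
#' regime is given as `site_classes` (columns `weight`, `omega_bg`,
#' `omega_fg`): each site draws a class, foreground branches use the
#' `omega_fg` column, and all classes share one time scale per branch
#' (mixture-average rate one substitution per unit length), matching the
#' likelihood convention of [codon_log_likelihood()]. Stop codons are
#' never emitted (the state space excludes them).
#'
#' @param tree Phylo tree, branch lengths in expected substitutions per
#'   codon.
#' @param length_codons Number of codons (>= 1).
#' @param kappa Transition/transversion ratio (> 0).
#' @param omega_map Named numeric vector, branch name -> omega; names
#'   must be existing branch (child-node) names.
#' @param omega_default Omega for branches absent from `omega_map`.
#' @param frequencies Optional length-61 codon frequencies (default
#'   uniform over sense codons).
#' @param seed Integer RNG seed.
#' @param site_classes Optional data frame (`weight`, `omega_bg`,
#'   `omega_fg`) describing a site-class mixture; overrides `omega_map`.
#' @param foreground Branch names using the `omega_fg` column (default:
#'   the tree's foreground tips).
#' @return List of class `codon_sim`: `alignment` (a `codon_alignment`),
#'   `ancestral` (internal-node codon matrix), `tree`, `kappa`,
#'   `omega_edges` (per-branch omega of the first/only class),
#'   `site_class` (per-site class index).
#' @export
simulate_codon_alignment <- function(tree, length_codons, kappa = 2,
                                     omega_map = NULL, omega_default = 0.2,
                                     frequencies = NULL, seed = 1L,
                                     site_classes = NULL,
                                     foreground = NULL) {
  if (length_codons < 1) stop("'length_codons' must be >= 1")
  if (kappa <= 0) stop("'kappa' must be positive")
  if (!is.null(omega_map)) {
    if (is.null(names(omega_map)) || any(names(omega_map) == ""))
      stop("'omega_map' must be a named vector (branch = child node name)")
    if (any(omega_map < 0)) stop("omega values must be >= 0")
  }
  et <- edge_table(tree)
  unknown <- setdiff(names(omega_map), et$name)
  if (length(unknown))
    stop("'omega_map' names branches absent from the tree: ",
         paste(unknown, collapse = ", "))
  if (omega_default < 0) stop("'omega_default' must be >= 0")
  S <- length(.CODONS)
  pi <- if (is.null(frequencies)) rep(1 / S, S) else {
    stopifnot(length(frequencies) == S)
    frequencies / sum(frequencies)
  }
  E <- nrow(et)
  if (is.null(site_classes)) {
    w_edge <- stats::setNames(rep(omega_default, E), et$name)
    if (!is.null(omega_map)) w_edge[names(omega_map)] <- omega_map
    omega_edges <- matrix(unname(w_edge), E, 1)
    weights <- 1
  } else {
    stopifnot(all(c("weight", "omega_bg", "omega_fg") %in%
                    names(site_classes)),
              abs(sum(site_classes$weight) - 1) < 1e-8)
    if (is.null(foreground)) foreground <- foreground_tips(tree)
    is_fg <- et$name %in% foreground
    omega_edges <- sapply(seq_len(nrow(site_classes)), function(cl)
      ifelse(is_fg, site_classes$omega_fg[cl], site_classes$omega_bg[cl]))
    omega_edges <- matrix(omega_edges, nrow = E)
    weights <- site_classes$weight
  }
  # classes share one time scale per branch (mixture-average rate 1), so
  # simulation matches the likelihood's normalisation convention
  parts <- gy94_rate_parts(kappa, pi)
  rmat <- parts["A"] + omega_edges * parts["B"]
  f <- as.vector(rmat %*% weights)
  uniq <- unique(as.vector(omega_edges))
  eigs <- lapply(uniq, function(w) gy94_eigen(kappa, w, pi))
  names(eigs) <- as.character(uniq)

  set.seed(seed)
  L <- as.integer(length_codons)
  site_class <- if (length(weights) == 1L) rep(1L, L) else
    sample.int(length(weights), L, replace = TRUE, prob = weights)
  ntip <- length(tree$tip.label)
  total <- ntip + tree$Nnode
  states <- matrix(NA_integer_, total, L)
  states[root_node(tree), ] <- sample.int(S, L, replace = TRUE, prob = pi)
  for (e in rev(seq_len(nrow(et)))) {            # preorder
    ps <- states[et$parent[e], ]
    out <- integer(L)
    for (cl in unique(site_class)) {
      w <- omega_edges[e, cl]
      t_eff <- et$length[e] * (parts["A"] + w * parts["B"]) / f[e]
      P <- prob_matrix(eigs[[as.character(w)]], t_eff)
      sites <- which(site_class == cl)
      pcl <- ps[sites]
      for (s in unique(pcl)) {
        i <- sites[pcl == s]
        out[i] <- sample.int(S, length(i), replace = TRUE, prob = P[s, ])
      }
    }
    states[et$child[e], ] <- out
  }
  labs <- node_labels(tree)
  aln <- states[seq_len(ntip), , drop = FALSE]
  rownames(aln) <- labs[seq_len(ntip)]
  anc <- states[(ntip + 1L):total, , drop = FALSE]
  rownames(anc) <- labs[(ntip + 1L):total]
  structure(list(alignment = as_codon_alignment(aln), ancestral = anc,
                 tree = tree, kappa = kappa,
                 omega_edges = stats::setNames(omega_edges[, 1], et$name),
                 site_class = site_class,
                 site_classes = site_classes),
            class = "codon_sim")
}

#' Concatenate codon alignments column-wise
#' @param ... `codon_alignment` objects with identical row sets.
#' @return A single `codon_alignment`.
#' @export
cbind_codon_alignments <- function(...) {
  parts <- lapply(list(...), as_codon_alignment)
  rn <- rownames(parts[[1]])
  parts <- lapply(parts, function(p) p[rn, , drop = FALSE])
  as_codon_alignment(do.call(cbind, parts))
}
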