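#' Simulate a protein alignment under JTT with discrete-gamma rates
#'
#' Draws a root sequence from the JTT stationary frequencies and evolves
#' it down every branch with transition matrices `expm(Q t r_k)`, where
#' `r_k` is the per-site discrete-gamma category rate. True ancestral
#' sequences are recorded, so simulations double as ground truth for
#' ancestral-reconstruction and convergence tests. Bit-reproducible for a
#' given seed.
#'
#' @param tree A phylo tree with branch lengths in expected
#'   substitutions per site (see [make_default_tree()]).
#' @param length Number of alignment columns (>= 1).
#' @param alpha Gamma shape for among-site rate variation (> 0).
#' @param n_categories Number of discrete-gamma categories.
#' @param seed Integer RNG seed.
#' @return An object of class `protein_sim`: list with `alignment` (tip
#'   character matrix), `ancestral` (internal-node character matrix,
#'   rownames = node labels), `categories` (per-site rate category),
#'   `alpha`, `tree`, and `truth` (empty until
#'   [inject_convergent_sites()] is applied).
#' @export
simulate_protein_alignment <- function(tree, length, alpha = 1,
                                       n_categories = 4L, seed = 1L) {
  if (length < 1) stop("'length' must be >= 1")
  model <- jtt_model(alpha, n_categories)   # validates alpha
  set.seed(seed)
  L <- as.integer(length)
  K <- model$n_categories
  categories <- sample.int(K, L, replace = TRUE)
  ntip <- base::length(tree$tip.label)
  total <- ntip + tree$Nnode
  states <- matrix(NA_integer_, total, L)
  rt <- root_node(tree)
  states[rt, ] <- sample.int(20L, L, replace = TRUE, prob = model$pi)
  et <- edge_table(tree)
  for (e in rev(seq_len(nrow(et)))) {            # preorder
    p <- et$parent[e]; ch <- et$child[e]; t <- et$length[e]
    for (k in seq_len(K)) {
      sites <- which(categories == k)
      if (!base::length(sites)) next
      P <- prob_matrix(model$eig, t * model$rates[k])
      ps <- states[p, sites]
      out <- integer(base::length(sites))
      for (s in unique(ps)) {
        i <- which(ps == s)
        out[i] <- sample.int(20L, base::length(i), replace = TRUE,
                             prob = P[s, ])
      }
      states[ch, sites] <- out
    }
  }
  labs <- node_labels(tree)
  chars <- matrix(.AA[states], total, L)
  tips <- chars[seq_len(ntip), , drop = FALSE]
  rownames(tips) <- labs[seq_len(ntip)]
  anc <- chars[(ntip + 1L):total, , drop = FALSE]
  rownames(anc) <- labs[(ntip + 1L):total]
  structure(list(alignment = tips, ancestral = anc,
                 categories = categories, alpha = alpha, tree = tree,
                 truth = NULL),
            class = "protein_sim")
}

#' Plant convergent amino-acid substitutions into a simulated alignment
#'
#' Chooses columns where all background tips (every non-foreground tip,
#' including the outgroup) and all true ancestral sequences already share
#' a single residue, then overwrites the foreground tips at those columns
#' with one common residue that differs from it. True ancestors are left
#' untouched, so the three convergence criteria hold by construction when
#' reconstruction is exact. Selected columns are recorded as ground truth.
#'
#' @param sim A `protein_sim` from [simulate_protein_alignment()].
#' @param n_sites Number of columns to modify.
#' @param seed Integer RNG seed.
#' @return The modified `protein_sim`, with `truth` set to a data frame
#'   (site, fg_residue, bg_residue).
#' @export
inject_convergent_sites <- function(sim, n_sites, seed = 1L) {
  stopifnot(inherits(sim, "protein_sim"))
  tree <- sim$tree
  fg <- foreground_tips(tree)
  if (is.null(fg) || !base::length(fg))
    stop("tree carries no foreground tips")
  bg <- setdiff(rownames(sim$alignment), fg)
  if (n_sites == 0) {
    sim$truth <- data.frame(site = integer(), fg_residue = character(),
                            bg_residue = character())
    return(sim)
  }
  shared <- apply(rbind(sim$alignment[bg, , drop = FALSE], sim$ancestral),
                  2, function(col) if (all(col == col[1])) col[1] else NA)
  eligible <- which(!is.na(shared))
  if (n_sites > base::length(eligible))
    stop("only ", base::length(eligible),
         " eligible columns available for injection; asked for ", n_sites)
  set.seed(seed)
  sites <- sort(sample(eligible, n_sites))
  fg_res <- character(n_sites)
  for (i in seq_along(sites)) {
    y <- shared[[sites[i]]]
    cand <- setdiff(.AA, y)
    x <- sample(cand, 1, prob = .JTT_FREQ[match(cand, .AA)])
    sim$alignment[fg, sites[i]] <- x
    fg_res[i] <- x
  }
  sim$truth <- data.frame(site = sites, fg_residue = fg_res,
                          bg_residue = unlist(shared[sites]),
                          row.names = NULL)
  sim
}
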