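# Shared pruning context: postorder edges, integer tip states, pattern
# compression. Reused across optimizer evaluations.
aa_prune_context <- function(tree, aln) {
  ts <- aa_tipstate(tree, aln)
  pat <- compress_patterns(ts)
  list(et = edge_table(tree), states = pat$states, weights = pat$weights,
       index = pat$index, n_node = tree$Nnode)
}

# Per-pattern log-likelihood under a JTT+gamma model, mixing the K
# equiprobable rate categories.
aa_pattern_loglik <- function(ctx, model, branch_lengths = NULL) {
  bl <- if (is.null(branch_lengths)) ctx$et$length else branch_lengths
  K <- length(model$rates)
  Plist <- lapply(seq_len(K), function(k)
    cpp_edge_pmats(model$eig$A, model$eig$Ainv, model$eig$values,
                   bl * model$rates[k]))
  class_idx <- matrix(rep(seq_len(K), each = nrow(ctx$et)), nrow(ctx$et))
  storage.mode(class_idx) <- "integer"
  ll <- cpp_prune_multi(ctx$et$parent, ctx$et$child, Plist, class_idx,
                        ctx$states, model$pi, ctx$n_node)
  logsumexp_rows(ll) - log(K)
}

#' Protein alignment log-likelihood under JTT + discrete gamma
#'
#' Felsenstein pruning per site, averaging the site likelihood over the
#' equiprobable discrete-gamma rate categories, with per-node scaling for
#' numerical stability.
#'
#' @param tree Phylo tree whose tips are a subset of the alignment rows.
#' @param aln Character matrix amino-acid alignment (gap-free; see
#'   [strip_gap_columns()]).
#' @param model An `aa_model` from [jtt_model()].
#' @return Total log-likelihood (numeric scalar).
#' @export
protein_loglik <- function(tree, aln, model) {
  ctx <- aa_prune_context(tree, aln)
  sum(ctx$weights * aa_pattern_loglik(ctx, model))
}

#' Fit branch lengths and the gamma shape by maximum likelihood
#'
#' Coordinate-wise bounded optimisation: each branch length is optimised
#' on `[1e-8, 10]` and the gamma shape on `[0.05, 50]` (log scale),
#' sweeping until the log-likelihood improves by less than `tol`.
#' Deterministic given its inputs; the log-likelihood never decreases
#' across sweeps.
#'
#' @param tree Phylo tree (topology fixed; branch lengths are starting
#'   values, missing/zero lengths start at 0.05).
#' @param aln Gap-free amino-acid character matrix.
#' @param n_categories Discrete-gamma category count.
#' @param alpha Fix the shape at this value instead of fitting it.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_sweeps Cap on coordinate sweeps.
#' @return List of class `aa_fit`: `tree` (fitted branch lengths),
#'   `alpha`, `logLik`, `model` (the fitted `aa_model`), `n_sweeps`,
#'   `trace` (per-sweep log-likelihoods).
#' @export
fit_protein_model <- function(tree, aln, n_categories = 4L, alpha = NULL,
                              tol = 1e-4, max_sweeps = 20L) {
  if (nrow(aln) < 2L) stop("need at least two sequences")
  if (ncol(aln) == 0L) stop("alignment is empty")
  ctx <- aa_prune_context(tree, aln)
  bl <- ctx$et$length
  bl[is.na(bl) | bl <= 0] <- 0.05
  fit_alpha <- is.null(alpha)
  a <- if (fit_alpha) 1 else alpha
  model <- jtt_model(a, n_categories)
  obj <- function(bl, a) {
    model$alpha <- a
    model$rates <- discrete_gamma_rates(a, n_categories)
    sum(ctx$weights * aa_pattern_loglik(ctx, model, bl))
  }
  cur <- obj(bl, a)
  trace <- cur
  for (sweep in seq_len(max_sweeps)) {
    for (e in seq_along(bl)) {
      o <- stats::optimize(function(x) { b <- bl; b[e] <- x; obj(b, a) },
                           interval = c(1e-8, 10), maximum = TRUE,
                           tol = 1e-6)
      if (o$objective > cur) { bl[e] <- o$maximum; cur <- o$objective }
    }
    if (fit_alpha) {
      o <- stats::optimize(function(la) obj(bl, exp(la)),
                           interval = log(c(0.05, 50)), maximum = TRUE,
                           tol = 1e-4)
      if (o$objective > cur) { a <- exp(o$maximum); cur <- o$objective }
    }
    trace <- c(trace, cur)
    if (cur - trace[length(trace) - 1L] < tol) break
  }
  fitted <- tree
  # write branch lengths back in the tree's own edge order
  fitted$edge.length <- bl[match(tree$edge[, 2], ctx$et$child)]
  model$alpha <- a
  model$rates <- discrete_gamma_rates(a, n_categories)
  structure(list(tree = fitted, alpha = a, logLik = cur, model = model,
                 n_sweeps = sweep, trace = trace), class = "aa_fit")
}

#' Marginal ancestral state reconstruction under JTT + gamma
#'
#' For every internal node and site, the posterior distribution over the
#' 20 residues given the tips, tree and model: the product of the
#' partial likelihood below the node and the likelihood of the rest of
#' the tree above it, mixed over rate categories weighted by each
#' category's site likelihood. The MAP residue and its posterior are
#' recorded, and each site is flagged as consistent or not with the
#' outgroup: the flag fails where the MAP state of the outgroup's
#' attachment node differs from the outgroup tip residue.
#'
#' @param tree Phylo tree with fitted branch lengths (e.g. from
#'   [fit_protein_model()]).
#' @param aln Gap-free amino-acid character matrix.
#' @param model An `aa_model`.
#' @param kept_sites Original column coordinates of the alignment
#'   columns (from [strip_gap_columns()]); defaults to `1:ncol(aln)`.
#' @return Object of class `ancestral_reconstruction`: `posterior`
#'   (array node x site x residue), `map` (character matrix), `map_prob`
#'   (numeric matrix), `consistent` (per-site logical), `kept_sites`,
#'   `tree`.
#' @export
marginal_ancestral_states <- function(tree, aln, model,
                                      kept_sites = NULL) {
  ctx <- aa_prune_context(tree, aln)
  M <- ncol(ctx$states)
  K <- length(model$rates)
  ntip <- nrow(ctx$states)
  n_int <- ctx$n_node
  total <- ntip + n_int
  et <- ctx$et
  post <- array(0, c(n_int, M, 20))
  catll <- matrix(0, M, K)
  post_k <- vector("list", K)
  for (k in seq_len(K)) {
    Pk <- lapply(seq_len(nrow(et)), function(e)
      prob_matrix(model$eig, et$length[e] * model$rates[k]))
    # downward partials with scaling
    D <- vector("list", total)
    logscale <- numeric(M)
    for (i in seq_len(ntip)) {
      D[[i]] <- matrix(0, 20, M)
      D[[i]][cbind(ctx$states[i, ], seq_len(M))] <- 1
    }
    for (v in (ntip + 1L):total) D[[v]] <- matrix(1, 20, M)
    msg <- vector("list", nrow(et))       # message child -> parent per edge
    for (e in seq_len(nrow(et))) {
      ch <- et$child[e]
      if (ch > ntip) {
        mx <- apply(D[[ch]], 2, max)
        mx[mx == 0] <- 1
        D[[ch]] <- sweep(D[[ch]], 2, mx, "/")
        logscale <- logscale + log(mx)
      }
      msg[[e]] <- Pk[[e]] %*% D[[ch]]
      D[[et$parent[e]]] <- D[[et$parent[e]]] * msg[[e]]
    }
    rt <- root_node(tree)
    catll[, k] <- log(colSums(model$pi * D[[rt]])) + logscale
    # upward messages: likelihood of everything outside v's subtree, as a
    # function of v's state
    Fmsg <- vector("list", total)
    Fmsg[[rt]] <- matrix(model$pi, 20, M)
    for (e in rev(seq_len(nrow(et)))) {   # preorder
      p <- et$parent[e]; ch <- et$child[e]
      sib <- which(et$parent == p & et$child != ch)
      Fp <- Fmsg[[p]]
      for (s in sib) Fp <- Fp * msg[[s]]
      Fmsg[[ch]] <- crossprod(Pk[[e]], Fp)
    }
    pk <- array(0, c(n_int, M, 20))
    for (v in (ntip + 1L):total) {
      pr <- t(D[[v]] * if (v == rt) matrix(model$pi, 20, M) else Fmsg[[v]])
      pk[v - ntip, , ] <- pr / rowSums(pr)
    }
    post_k[[k]] <- pk
  }
  w <- exp(catll - apply(catll, 1, max))
  w <- w / rowSums(w)
  for (k in seq_len(K))
    post <- post + post_k[[k]] * rep(w[, k], each = n_int)
  # expand patterns back to alignment columns
  post <- post[, ctx$index, , drop = FALSE]
  nsite <- length(ctx$index)
  labs <- node_labels(tree)[(ntip + 1L):total]
  dimnames(post) <- list(labs, NULL, .AA)
  mapi <- apply(post, c(1, 2), which.max)
  map <- matrix(.AA[mapi], n_int, nsite, dimnames = list(labs, NULL))
  map_prob <- matrix(apply(post, c(1, 2), max), n_int, nsite,
                     dimnames = list(labs, NULL))
  og <- outgroup_tip(tree)
  consistent <- rep(TRUE, nsite)
  if (!is.null(og) && og %in% tree$tip.label) {
    og_tip <- match(og, tree$tip.label)
    og_parent <- et$parent[et$child == og_tip]
    pl <- node_labels(tree)[og_parent]
    consistent <- map[pl, ] == aln[og, ]
  }
  structure(list(posterior = post, map = map, map_prob = map_prob,
                 consistent = consistent,
                 kept_sites = if (is.null(kept_sites)) seq_len(nsite)
                              else kept_sites,
                 tree = tree),
            class = "ancestral_reconstruction")
}
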