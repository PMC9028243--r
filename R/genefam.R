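#' Birth-death transition probability for gene-family size
#'
#' Probability that a linear birth-death chain with equal per-gene birth
#' and death rate `lambda` moves from `s` to `c` genes in time `t`:
#' with `a = lambda*t/(1 + lambda*t)`, the sum over `j = 0..min(s, c)` of
#' `choose(s, j) * choose(s + c - j - 1, s - 1) * a^(s + c - 2j) *
#' (1 - 2a)^j`. Size 0 is absorbing.
#'
#' @param s Parent count (>= 0).
#' @param c Child count (>= 0).
#' @param t Elapsed time (>= 0).
#' @param lambda Per-gene rate (>= 0).
#' @return Transition probability.
#' @export
bdi_transition_prob <- function(s, c, t, lambda) {
  if (any(c(s, c, t, lambda) < 0)) stop("arguments must be non-negative")
  if (s == 0) return(as.numeric(c == 0))
  a <- lambda * t / (1 + lambda * t)
  if (a == 0) return(as.numeric(c == s))
  j <- 0:min(s, c)
  # (1 - 2a) is negative for a > 1/2: carry its sign explicitly
  terms <- lchoose(s, j) + lchoose(s + c - j - 1, s - 1) +
    (s + c - 2 * j) * log(a) + j * log(abs(1 - 2 * a))
  sgn <- sign(1 - 2 * a)^j
  max(0, sum(sgn * exp(terms)))
}

# Full transition matrix over states 0..C (rows = parent, cols = child).
bdi_transition_matrix <- function(C, t, lambda) {
  S <- C + 1L
  P <- matrix(0, S, S)
  P[1, 1] <- 1
  a <- lambda * t / (1 + lambda * t)
  if (a == 0) return(diag(S))
  la <- log(a); l12a <- log(abs(1 - 2 * a)); sg <- sign(1 - 2 * a)
  for (s in 1:C) {
    for (cc in 0:C) {
      j <- 0:min(s, cc)
      P[s + 1, cc + 1] <- max(0, sum(sg^j * exp(
        lchoose(s, j) + lchoose(s + cc - j - 1, s - 1) +
          (s + cc - 2 * j) * la + j * l12a)))
    }
  }
  P
}

# Probability that a single gene at the root leaves no descendant at any
# tip (closed-form recursion using the geometric offspring law of the
# equal-rate chain).
bdi_root_extinction <- function(tree, lambda) {
  et <- edge_table(tree)
  ntip <- length(tree$tip.label)
  g <- rep(NA_real_, ntip + tree$Nnode)
  g[seq_len(ntip)] <- 0
  for (e in seq_len(nrow(et))) {          # postorder: children first
    p <- et$parent[e]
    a <- lambda * et$length[e] / (1 + lambda * et$length[e])
    gc <- g[et$child[e]]
    # sum_k P(1 -> k) gc^k = a + (1-a)^2 gc / (1 - a gc)
    val <- a + (1 - a)^2 * gc / (1 - a * gc)
    g[p] <- if (is.na(g[p])) val else g[p] * val
  }
  g[root_node(tree)]
}

# Conditional log-likelihood of one or more families at rate lambda:
# pruning over count states with a uniform root prior on 1..max_root,
# conditioned on >= 1 surviving tip.
bdi_family_loglik <- function(tree, counts, lambda, C, max_root) {
  et <- edge_table(tree)
  ntip <- length(tree$tip.label)
  Pcube <- array(0, c(C + 1, C + 1, nrow(et)))
  for (e in seq_len(nrow(et)))
    Pcube[, , e] <- bdi_transition_matrix(C, et$length[e], lambda)
  prior <- c(0, rep(1 / max_root, max_root), rep(0, C - max_root))
  q <- bdi_root_extinction(tree, lambda)
  log_cond <- log(1 - sum(prior[2:(max_root + 1)] * q^(1:max_root)))
  counts <- matrix(counts, ncol = ntip,
                   dimnames = list(NULL, colnames(counts)))
  tipstate <- counts[, tree$tip.label, drop = FALSE] + 1L   # state index
  storage.mode(tipstate) <- "integer"
  ll <- cpp_prune_loglik(et$parent, et$child, Pcube, t(tipstate), prior,
                         tree$Nnode)
  as.vector(ll) - log_cond
}

#' Fit the global birth-death rate of gene-family evolution
#'
#' Maximises, over a single lambda, the summed pruning likelihood of all
#' families on the ultrametric time tree, with the root size
#' marginalised over a uniform prior on `1..max_root` and each family
#' conditioned on having at least one surviving gene.
#'
#' @param tree Ultrametric phylo time tree.
#' @param counts Families x species integer matrix (column names =
#'   species); every family needs >= 1 nonzero tip.
#' @param lambda_range Search interval for lambda.
#' @return Object of class `bdi_model`: `lambda`, `logLik`,
#'   `per_family_loglik`, state cap `C`, `max_root`, `tree`.
#' @export
fit_lambda <- function(tree, counts, lambda_range = c(1e-7, 0.5)) {
  check_ultrametric(tree)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (any(rowSums(counts) == 0))
    stop("each family must be present in at least one species")
  if (!all(tree$tip.label %in% colnames(counts)))
    stop("count matrix lacks columns for some tips")
  C <- max(16L, 2L * max(counts))
  max_root <- min(C, max(2L, 2L * max(counts)))
  f <- function(loglam)
    sum(bdi_family_loglik(tree, counts, exp(loglam), C, max_root))
  o <- stats::optimize(f, interval = log(lambda_range), maximum = TRUE,
                       tol = 1e-4)
  lambda <- exp(o$maximum)
  # keep the boundary if it is as good (all-constant data)
  lo <- f(log(lambda_range[1]))
  if (lo >= o$objective) lambda <- lambda_range[1]
  pf <- bdi_family_loglik(tree, counts, lambda, C, max_root)
  structure(list(lambda = lambda, logLik = sum(pf),
                 per_family_loglik = stats::setNames(pf, rownames(counts)),
                 C = C, max_root = max_root, tree = tree),
            class = "bdi_model")
}

#' @export
print.bdi_model <- function(x, ...) {
  cat(sprintf("Birth-death gene-family model: lambda = %.5g, lnL = %.2f (%d families)\n",
              x$lambda, x$logLik, length(x$per_family_loglik)))
  invisible(x)
}

# Root partial likelihoods for a batch of families: (C+1) x nfam matrix
# of log P(tip counts | root size), computed by pruning with families in
# the pattern dimension.
bdi_root_logpartials <- function(tree, counts, lambda, C) {
  et <- edge_table(tree)
  ntip <- length(tree$tip.label)
  nf <- nrow(counts)
  S <- C + 1L
  Pm <- lapply(seq_len(nrow(et)), function(e)
    bdi_transition_matrix(C, et$length[e], lambda))
  L <- vector("list", ntip + tree$Nnode)
  for (v in (ntip + 1L):(ntip + tree$Nnode)) L[[v]] <- matrix(1, S, nf)
  obs <- t(counts[, tree$tip.label, drop = FALSE])   # tips x fam
  logscale <- numeric(nf)
  for (e in seq_len(nrow(et))) {
    ch <- et$child[e]
    if (ch <= ntip) {
      msg <- Pm[[e]][, obs[ch, ] + 1L, drop = FALSE]
    } else {
      mx <- apply(L[[ch]], 2, max)
      mx[mx == 0] <- 1
      L[[ch]] <- sweep(L[[ch]], 2, mx, "/")
      logscale <- logscale + log(mx)
      msg <- Pm[[e]] %*% L[[ch]]
    }
    L[[et$parent[e]]] <- L[[et$parent[e]]] * msg
  }
  log(L[[root_node(tree)]]) + rep(logscale, each = S)
}

# Family score: conditional log-likelihood profiled (maximised) over the
# root size, so the statistic reflects how well the best-supported root
# explains the tips rather than which root was drawn.
bdi_family_scores <- function(model, counts) {
  lp <- bdi_root_logpartials(model$tree, counts, model$lambda, model$C)
  q <- bdi_root_extinction(model$tree, model$lambda)
  r <- seq_len(model$max_root)
  apply(lp[r + 1L, , drop = FALSE] - log(1 - q^r), 2, max)
}

# Simulate the null score distribution under the fitted model,
# conditional on a root size (families whose size evolution is tested
# are compared against null families started from their own best
# supported root, so the statistic is not confounded by family size).
bdi_null_stats <- function(model, n, seed, root_size) {
  sim <- simulate_family_counts(model$tree, model$lambda, n,
                                root_size_range = rep(root_size, 2L),
                                seed = seed)
  counts <- pmin(sim$counts, model$C)     # truncation guard
  bdi_family_scores(model, counts)
}

# Profile-maximising root size of each family.
bdi_root_argmax <- function(model, counts) {
  lp <- bdi_root_logpartials(model$tree, counts, model$lambda, model$C)
  q <- bdi_root_extinction(model$tree, model$lambda)
  r <- seq_len(model$max_root)
  apply(lp[r + 1L, , drop = FALSE] - log(1 - q^r), 2, which.max)
}

#' Family-wide p-value by Monte Carlo under the fitted model
#'
#' The statistic is the family's conditional log-likelihood maximised
#' over the root size; it is compared against `n_montecarlo` null
#' families simulated from the fitted model starting at the family's
#' own best-supported root size (conditioned on non-extinction), as the
#' CAFE-style test does, and the add-one fraction of null families
#' scoring at or below the observed one is reported: unusually evolving
#' families have unusually low likelihood. Never exactly zero.
#'
#' @param family_counts Named integer vector (species -> count) or
#'   one-row matrix.
#' @param model A `bdi_model` from [fit_lambda()].
#' @param n_montecarlo Number of simulated families (warning below 100).
#' @param seed Integer RNG seed.
#' @param null_stats Optional pre-computed null statistics for this
#'   family's root size (see [family_pvalues()] for sharing across
#'   families).
#' @return P-value in `[1/(n+1), 1]`.
#' @export
family_pvalue <- function(family_counts, model, n_montecarlo = 1000L,
                          seed = 1L, null_stats = NULL) {
  stopifnot(inherits(model, "bdi_model"))
  if (n_montecarlo < 100L)
    warning("n_montecarlo < 100 gives a coarse p-value")
  if (is.matrix(family_counts)) family_counts <- family_counts[1, ]
  cm <- matrix(pmin(as.integer(family_counts), model$C), nrow = 1,
               dimnames = list(NULL, names(family_counts)))
  if (is.null(null_stats))
    null_stats <- bdi_null_stats(model, n_montecarlo, seed,
                                 bdi_root_argmax(model, cm))
  obs <- bdi_family_scores(model, cm)
  (1 + sum(null_stats <= obs)) / (length(null_stats) + 1)
}

#' Family-wide p-values for a whole count table
#'
#' [family_pvalue()] for every row of a count matrix, sharing one null
#' simulation per distinct best-supported root size.
#'
#' @param model A `bdi_model`.
#' @param counts Families x species count matrix.
#' @param n_montecarlo Null families per root size.
#' @param seed Integer RNG seed.
#' @return Named numeric vector of p-values.
#' @export
family_pvalues <- function(model, counts, n_montecarlo = 1000L, seed = 1L) {
  cm <- pmin(counts, model$C)
  roots <- bdi_root_argmax(model, cm)
  obs <- bdi_family_scores(model, cm)
  p <- numeric(nrow(cm))
  for (r in unique(roots)) {
    ns <- bdi_null_stats(model, n_montecarlo, seed + r, r)
    i <- roots == r
    p[i] <- vapply(obs[i], function(o) (1 + sum(ns <= o)) / (length(ns) + 1),
                   0)
  }
  stats::setNames(p, rownames(counts))
}

#' Per-branch Viterbi p-values and expansion/contraction calls
#'
#' Reconstructs the most probable ancestral size configuration of a
#' family by max-product dynamic programming over count states (ties
#' broken toward the smaller count), then scores each branch: with
#' parent size s and child size c, the Viterbi p-value is the
#' probability of a change at least as extreme as c in its direction
#' (`c' >= c` when c > s, `c' <= c` when c < s, 1 when c = s). Branches
#' with p below `p_threshold` are called expansions or contractions.
#'
#' @param family_counts Named integer vector (species -> count).
#' @param model A `bdi_model`.
#' @param p_threshold Call threshold (study value 0.05).
#' @return Data frame per branch: `branch`, `parent_size`, `child_size`,
#'   `p_value`, `call` in `{expansion, contraction, none}`.
#' @export
branch_viterbi_pvalues <- function(family_counts, model,
                                   p_threshold = 0.05) {
  tree <- model$tree
  et <- edge_table(tree)
  ntip <- length(tree$tip.label)
  C <- model$C
  S <- C + 1L
  Pmats <- lapply(seq_len(nrow(et)), function(e)
    bdi_transition_matrix(C, et$length[e], model$lambda))
  logP <- lapply(Pmats, function(P) log(P))
  V <- matrix(-Inf, ntip + tree$Nnode, S)
  obs <- as.integer(family_counts[tree$tip.label])
  for (i in seq_len(ntip)) V[i, obs[i] + 1L] <- 0
  V[(ntip + 1):(ntip + tree$Nnode), ] <- 0
  back <- vector("list", nrow(et))
  for (e in seq_len(nrow(et))) {           # postorder
    ch <- et$child[e]
    sc <- sweep(logP[[e]], 2, V[ch, ], "+")   # rows s, cols child state
    best <- apply(sc, 1, max)
    arg <- apply(sc, 1, which.max)            # ties -> smallest count
    back[[e]] <- arg
    V[et$parent[e], ] <- V[et$parent[e], ] + best
  }
  rt <- root_node(tree)
  prior <- c(0, rep(1 / model$max_root, model$max_root),
             rep(0, C - model$max_root))
  rv <- log(prior) + V[rt, ]
  state <- integer(ntip + tree$Nnode)
  state[rt] <- which.max(rv) - 1L
  for (e in rev(seq_len(nrow(et))))        # preorder
    state[et$child[e]] <- if (et$child[e] <= ntip) obs[et$child[e]] else
      back[[e]][state[et$parent[e]] + 1L] - 1L
  rows <- lapply(seq_len(nrow(et)), function(e) {
    s <- state[et$parent[e]]; cc <- state[et$child[e]]
    P <- Pmats[[e]]
    p <- if (cc == s) 1 else if (cc > s)
      max(0, 1 - sum(P[s + 1L, seq_len(cc)])) else
      sum(P[s + 1L, seq_len(cc + 1L)])
    call <- if (p < p_threshold && cc > s) "expansion" else
      if (p < p_threshold && cc < s) "contraction" else "none"
    data.frame(branch = et$name[e], parent_size = s, child_size = cc,
               p_value = p, call = call)
  })
  do.call(rbind, rows)
}
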