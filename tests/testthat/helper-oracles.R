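# Independent oracles used by the tests. These deliberately avoid the
# package's pruning / counting code paths: likelihoods are computed by
# exhaustive enumeration over ancestral states and NG86 counts by direct
# recursive enumeration over mutational pathways.

aa_letters <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# All internal-node state assignments of a rooted tree, likelihood summed
# exhaustively. tree: ape phylo; aln: character matrix; Q scaled rate
# matrix with stationary pi; rates: per-category rates (equal weights).
enum_loglik <- function(tree, aln, Q, pi, rates = 1, states = aa_letters) {
  S <- length(pi)
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  n_int <- tree$Nnode
  x <- match(aln[tree$tip.label, , drop = FALSE], states)
  dim(x) <- c(ntip, ncol(aln))
  total <- 0
  site_ll <- numeric(ncol(aln))
  for (site in seq_len(ncol(aln))) {
    lik <- 0
    for (k in seq_along(rates)) {
      P <- lapply(seq_len(nrow(po$edge)), function(e)
        as.matrix(Matrix::expm(Q * po$edge.length[e] * rates[k])))
      grid <- as.matrix(expand.grid(rep(list(seq_len(S)), n_int)))
      for (g in seq_len(nrow(grid))) {
        assign_state <- function(v)
          if (v <= ntip) x[v, site] else grid[g, v - ntip]
        pr <- pi[assign_state(ntip + 1L)]
        for (e in seq_len(nrow(po$edge)))
          pr <- pr * P[[e]][assign_state(po$edge[e, 1]),
                            assign_state(po$edge[e, 2])]
        lik <- lik + pr / length(rates)
      }
    }
    site_ll[site] <- log(lik)
    total <- total + log(lik)
  }
  list(total = total, site = site_ll)
}

# Bayes-rule marginal ancestral posteriors by the same enumeration.
enum_asr_posterior <- function(tree, aln, Q, pi, rates = 1,
                               states = aa_letters) {
  S <- length(pi)
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  n_int <- tree$Nnode
  x <- match(aln[tree$tip.label, , drop = FALSE], states)
  dim(x) <- c(ntip, ncol(aln))
  post <- array(0, c(n_int, ncol(aln), S))
  for (site in seq_len(ncol(aln))) {
    joint <- matrix(0, nrow = S^n_int, ncol = 1)
    grid <- as.matrix(expand.grid(rep(list(seq_len(S)), n_int)))
    for (k in seq_along(rates)) {
      P <- lapply(seq_len(nrow(po$edge)), function(e)
        as.matrix(Matrix::expm(Q * po$edge.length[e] * rates[k])))
      for (g in seq_len(nrow(grid))) {
        assign_state <- function(v)
          if (v <= ntip) x[v, site] else grid[g, v - ntip]
        pr <- pi[assign_state(ntip + 1L)]
        for (e in seq_len(nrow(po$edge)))
          pr <- pr * P[[e]][assign_state(po$edge[e, 1]),
                            assign_state(po$edge[e, 2])]
        joint[g] <- joint[g] + pr / length(rates)
      }
    }
    joint <- joint / sum(joint)
    for (v in seq_len(n_int))
      for (s in seq_len(S))
        post[v, site, s] <- sum(joint[grid[, v] == s])
  }
  post
}

# Random small rooted binary tree with the given tips.
random_small_tree <- function(ntip, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntip, rooted = TRUE,
                   tip.label = letters[seq_len(ntip)])
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.02, 0.4)
  tr
}

# --- NG86 oracle -----------------------------------------------------------

ng86_oracle_tables <- local({
  nt <- c("T", "C", "A", "G")
  all64 <- apply(expand.grid(nt, nt, nt)[, 3:1], 1, paste, collapse = "")
  aa <- Biostrings::GENETIC_CODE[all64]
  list(codons = all64[aa != "*"], aa = aa)
})

# Fraction of synonymous sites of one codon; stop-bound changes count as
# nonsynonymous.
ng86_oracle_sites <- function(codon) {
  nt <- c("T", "C", "A", "G")
  aa <- ng86_oracle_tables$aa
  ch <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) for (n in nt[nt != ch[p]]) {
    mut <- ch; mut[p] <- n
    mc <- paste(mut, collapse = "")
    if (aa[mc] != "*" && aa[mc] == aa[codon]) syn <- syn + 1
  }
  syn / 3
}

# Pathway-averaged difference counts by recursive enumeration; paths
# through stop codons discarded (fallback: count all paths ignoring
# stops).
ng86_oracle_diffs <- function(c1, c2, allow_stops = FALSE) {
  aa <- ng86_oracle_tables$aa
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  d <- which(a != b)
  if (!length(d)) return(c(0, 0))
  acc <- list()
  recurse <- function(cur, remaining, sd, nd) {
    if (!length(remaining)) { acc[[length(acc) + 1L]] <<- c(sd, nd); return() }
    for (p in remaining) {
      nxt <- cur; nxt[p] <- b[p]
      cs <- paste(cur, collapse = ""); ns <- paste(nxt, collapse = "")
      if (!allow_stops && aa[ns] == "*") next
      recurse(nxt, setdiff(remaining, p),
              sd + (aa[cs] == aa[ns]), nd + (aa[cs] != aa[ns]))
    }
  }
  recurse(a, d, 0, 0)
  if (!length(acc)) return(ng86_oracle_diffs(c1, c2, allow_stops = TRUE))
  colMeans(do.call(rbind, acc))
}

ng86_oracle <- function(s1, s2) {
  c1 <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  c2 <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
  S <- (sum(sapply(c1, ng86_oracle_sites)) +
          sum(sapply(c2, ng86_oracle_sites))) / 2
  d <- rowSums(mapply(ng86_oracle_diffs, c1, c2))
  list(S = S, N = 3 * length(c1) - S, Sd = d[1], Nd = d[2])
}

random_sense_codons <- function(n, seed) {
  set.seed(seed)
  sample(ng86_oracle_tables$codons, n, replace = TRUE)
}
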