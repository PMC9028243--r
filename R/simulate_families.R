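# One exact Gillespie realisation of the equal-rate linear birth-death
# chain (per-gene birth = death = lambda) from count n over time t.
gillespie_bd <- function(n, t, lambda) {
  if (lambda <= 0 || n == 0L) return(n)
  now <- 0
  repeat {
    rate <- 2 * lambda * n
    if (rate <= 0) return(n)
    now <- now + stats::rexp(1, rate)
    if (now > t) return(n)
    n <- n + sample(c(1L, -1L), 1L)
  }
}

#' Simulate gene-family size evolution along a time tree
#'
#' Each family starts from a root size drawn uniformly from
#' `root_size_range` and evolves down the ultrametric tree as a linear
#' birth-death chain with equal per-gene birth and death rate
#' `lambda_rate`, stepped exactly (event-driven Gillespie, no matrix
#' approximation). A planted event replaces the stochastic step on its
#' branch with a deterministic jump from the parent's count (clamped at
#' zero), so the child always differs from its parent by exactly the
#' planted amount. Families extinct in all species are discarded and
#' redrawn; the number of redraws is recorded.
#'
#' @param tree Ultrametric phylo time tree.
#' @param lambda_rate Per-gene, per-unit-time birth (= death) rate >= 0.
#' @param n_families Number of families to return.
#' @param root_size_range Integer interval (length-2) of root sizes,
#'   minimum 1.
#' @param seed Integer RNG seed.
#' @param planted_events Optional named list/vector: branch (child node
#'   or tip name) -> integer jump, applied to every family when
#'   `planted_families` is `NULL`, or only to the families listed there.
#' @param planted_families Optional integer vector of family indices
#'   receiving the planted events.
#' @return Object of class `family_sim`: `counts` (families x species
#'   integer matrix), `ancestral` (families x internal-node matrix),
#'   `lambda`, `tree`, `truth` (planted events and affected families),
#'   `n_redraws`.
#' @export
simulate_family_counts <- function(tree, lambda_rate, n_families,
                                   root_size_range = c(1L, 20L), seed = 1L,
                                   planted_events = NULL,
                                   planted_families = NULL) {
  if (lambda_rate < 0) stop("'lambda_rate' must be >= 0")
  if (length(root_size_range) != 2L || any(is.na(root_size_range)) ||
      root_size_range[2] < root_size_range[1])
    stop("'root_size_range' must be a non-empty integer interval")
  if (root_size_range[1] < 1L) stop("root sizes must be >= 1")
  check_ultrametric(tree)
  if (!is.null(planted_events)) {
    bad <- setdiff(names(planted_events), edge_table(tree)$name)
    if (length(bad))
      stop("planted_events names branches absent from the tree: ",
           paste(bad, collapse = ", "))
  }
  set.seed(seed)
  et <- edge_table(tree)
  ntip <- length(tree$tip.label)
  labs <- node_labels(tree)
  counts <- matrix(0L, n_families, ntip,
                   dimnames = list(paste0("fam", seq_len(n_families)),
                                   tree$tip.label))
  anc <- matrix(0L, n_families, tree$Nnode,
                dimnames = list(rownames(counts),
                                labs[(ntip + 1):(ntip + tree$Nnode)]))
  n_redraws <- 0L
  for (f in seq_len(n_families)) {
    planted <- is.null(planted_families) || f %in% planted_families
    repeat {
      state <- integer(ntip + tree$Nnode)
      state[root_node(tree)] <-
        sample(root_size_range[1]:root_size_range[2], 1L)
      for (e in rev(seq_len(nrow(et)))) {    # preorder
        n <- if (planted && et$name[e] %in% names(planted_events))
          max(0L, state[et$parent[e]] +
                as.integer(planted_events[[et$name[e]]]))
        else gillespie_bd(state[et$parent[e]], et$length[e], lambda_rate)
        state[et$child[e]] <- n
      }
      if (any(state[seq_len(ntip)] > 0L)) break
      n_redraws <- n_redraws + 1L
    }
    counts[f, ] <- state[seq_len(ntip)]
    anc[f, ] <- state[(ntip + 1):(ntip + tree$Nnode)]
  }
  truth <- list(lambda = lambda_rate, planted_events = planted_events,
                planted_families = if (is.null(planted_families) &&
                                       !is.null(planted_events))
                  seq_len(n_families) else planted_families)
  structure(list(counts = counts, ancestral = anc, lambda = lambda_rate,
                 tree = tree, truth = truth, n_redraws = n_redraws),
            class = "family_sim")
}

#' Simulate an all-vs-all similarity edge table from planted families
#'
#' Emits BLAST-tabular-style (12 column) rows: every ordered pair of
#' genes within a planted family receives a strong hit with e-value
#' below the conventional 1e-5 threshold; pairs from different families
#' receive, at rate `between_noise_rate`, a weak hit with e-value above
#' it. Byte-identical output for a given seed.
#'
#' @param genes Data frame with columns `gene`, `species`, `family`.
#' @param within_score_range Range of `-log10(evalue)` for within-family
#'   hits (both ends > 5).
#' @param between_noise_rate Probability in `[0, 1)` of a noise hit for
#'   any cross-family ordered pair.
#' @param seed Integer RNG seed.
#' @return Data frame with the 12 standard columns (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`).
#' @export
simulate_similarity_graph <- function(genes, within_score_range = c(20, 180),
                                      between_noise_rate = 0.01, seed = 1L) {
  stopifnot(all(c("gene", "species", "family") %in% names(genes)))
  if (between_noise_rate < 0 || between_noise_rate >= 1)
    stop("'between_noise_rate' must be in [0, 1)")
  if (min(within_score_range) <= 5)
    stop("'within_score_range' must keep within-family e-values below 1e-5")
  set.seed(seed)
  rows <- list()
  fams <- split(genes$gene, genes$family)
  k <- 0L
  for (members in fams) {
    if (length(members) < 2L) next
    pr <- t(utils::combn(members, 2L))
    for (i in seq_len(nrow(pr))) {
      sc <- stats::runif(1, within_score_range[1], within_score_range[2])
      ev <- 10^-sc
      bs <- round(50 + 2 * sc, 1)
      len <- sample(100:500, 1L)
      for (d in 1:2) {
        q <- pr[i, d]; s <- pr[i, 3 - d]
        k <- k + 1L
        rows[[k]] <- data.frame(
          qseqid = q, sseqid = s,
          pident = round(stats::runif(1, 60, 100), 2), length = len,
          mismatch = sample(0:50, 1L), gapopen = sample(0:5, 1L),
          qstart = 1L, qend = len, sstart = 1L, send = len,
          evalue = ev, bitscore = bs)
      }
    }
  }
  if (between_noise_rate > 0 && length(fams) > 1L) {
    gene_fam <- stats::setNames(genes$family, genes$gene)
    all_pairs <- t(utils::combn(genes$gene, 2L))
    cross <- all_pairs[gene_fam[all_pairs[, 1]] != gene_fam[all_pairs[, 2]],
                       , drop = FALSE]
    hit <- stats::runif(nrow(cross)) < between_noise_rate
    for (i in which(hit)) {
      sc <- stats::runif(1, 0, 4.5)       # e-value in (10^-4.5, 1) > 1e-5
      len <- sample(30:80, 1L)
      k <- k + 1L
      rows[[k]] <- data.frame(
        qseqid = cross[i, 1], sseqid = cross[i, 2],
        pident = round(stats::runif(1, 20, 40), 2), length = len,
        mismatch = sample(10:60, 1L), gapopen = sample(0:5, 1L),
        qstart = 1L, qend = len, sstart = 1L, send = len,
        evalue = 10^-sc, bitscore = round(20 + 2 * sc, 1))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
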