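#' Call convergent amino-acid sites at conserved positions (CCS)
#'
#' A column is called convergent iff (1) all foreground tips share one
#' residue X; (2) all background tips and the MAP reconstructed residues
#' of every checked ancestral node share one residue Y (each accepted
#' ancestor state must reach the minimum posterior); and (3) X differs
#' from Y. Columns whose reconstruction is inconsistent with the
#' outgroup are skipped (most conservative reading of the outgroup
#' check); the outgroup tip itself is not part of the background set.
#'
#' @param aln Gap-free amino-acid character matrix the reconstruction was
#'   produced on.
#' @param recon An `ancestral_reconstruction` on the same alignment and
#'   tree.
#' @param tree The tree used for reconstruction.
#' @param foreground Foreground tip labels (default: the tree's
#'   `foreground` attribute).
#' @param background Background tip labels (default: all tips except
#'   foreground and outgroup).
#' @param min_anc_posterior Minimum MAP posterior to accept a
#'   reconstructed ancestral state (default 0.8).
#' @param ancestor_mode `"all"`: every internal node must match Y
#'   (strictest reading); `"parents"`: only the parent nodes of the
#'   foreground branches are checked.
#' @param check_outgroup Skip columns flagged inconsistent with the
#'   outgroup (default `TRUE`).
#' @return Data frame of calls: `site` (original column coordinate),
#'   `fg_residue`, `bg_residue`, `min_anc_posterior`.
#' @export
detect_convergent_sites <- function(aln, recon, tree, foreground = NULL,
                                    background = NULL,
                                    min_anc_posterior = 0.8,
                                    ancestor_mode = c("all", "parents"),
                                    check_outgroup = TRUE) {
  ancestor_mode <- match.arg(ancestor_mode)
  stopifnot(inherits(recon, "ancestral_reconstruction"))
  if (is.null(foreground)) foreground <- foreground_tips(tree)
  og <- outgroup_tip(tree)
  if (is.null(background))
    background <- setdiff(tree$tip.label, c(foreground, og))
  if (length(intersect(foreground, background)))
    stop("foreground and background tip sets overlap")
  stopifnot(all(c(foreground, background) %in% rownames(aln)))
  anc_nodes <- if (ancestor_mode == "all") rownames(recon$map) else {
    et <- edge_table(tree)
    labs <- node_labels(tree)
    unique(labs[et$parent[match(match(foreground, tree$tip.label),
                                et$child)]])
  }
  nsite <- ncol(aln)
  fgm <- aln[foreground, , drop = FALSE]
  bgm <- aln[background, , drop = FALSE]
  fg_same <- colSums(fgm == fgm[rep(1, nrow(fgm)), , drop = FALSE]) ==
    nrow(fgm)
  bg_same <- colSums(bgm == bgm[rep(1, nrow(bgm)), , drop = FALSE]) ==
    nrow(bgm)
  anc_map <- recon$map[anc_nodes, , drop = FALSE]
  anc_prob <- recon$map_prob[anc_nodes, , drop = FALSE]
  calls <- list()
  for (s in which(fg_same & bg_same)) {
    x <- fgm[1, s]; y <- bgm[1, s]
    if (x == y) next
    if (check_outgroup && !recon$consistent[s]) next
    if (any(anc_map[, s] != y)) next
    mp <- min(anc_prob[, s])
    if (mp < min_anc_posterior) next
    calls[[length(calls) + 1L]] <-
      data.frame(site = recon$kept_sites[s], fg_residue = x,
                 bg_residue = y, min_anc_posterior = mp)
  }
  if (!length(calls))
    return(data.frame(site = integer(), fg_residue = character(),
                      bg_residue = character(),
                      min_anc_posterior = numeric()))
  do.call(rbind, calls)
}

#' Random-trio false-positive control for convergence calls
#'
#' Abolishes the foreground/background grouping: three species are
#' chosen (at random, or the given trio) as a surrogate foreground and
#' the remaining non-outgroup species as background, convergence is
#' re-called on every gene, and the result is compared with the
#' true-foreground run at the gene level and, within overlapping genes,
#' at the site level.
#'
#' @param genes Named list, one entry per gene, each a list with
#'   `alignment` (gap-free character matrix) and `reconstruction`
#'   (matching `ancestral_reconstruction`).
#' @param tree The species tree (with foreground/outgroup attributes).
#' @param trio Character vector of 3 species to use as surrogate
#'   foreground; must not contain the outgroup (it anchors ancestral
#'   polarity). If `NULL`, sampled with `seed`.
#' @param seed RNG seed for trio sampling.
#' @param ... Passed to [detect_convergent_sites()].
#' @return Object of class `trio_comparison`: `trio`, `tg_calls` and
#'   `trio_calls` (per-gene call tables), `tg_genes`, `trio_genes`,
#'   `overlap_genes`, and `site_overlap` (per overlapping gene: sites
#'   called in each run and shared sites).
#' @export
random_trio_control <- function(genes, tree, trio = NULL, seed = 1L, ...) {
  og <- outgroup_tip(tree)
  candidates <- setdiff(tree$tip.label, og)
  if (is.null(trio)) {
    set.seed(seed)
    trio <- sort(sample(candidates, 3L))
  }
  if (length(trio) != 3L || !all(trio %in% tree$tip.label))
    stop("'trio' must be three species of the tree")
  if (og %in% trio)
    stop("the trio must not contain the outgroup '", og, "'")
  run <- function(fg) {
    lapply(genes, function(g)
      detect_convergent_sites(g$alignment, g$reconstruction, tree,
                              foreground = fg,
                              background = setdiff(candidates, fg), ...))
  }
  tg_calls <- run(foreground_tips(tree))
  trio_calls <- run(trio)
  tg_genes <- names(genes)[vapply(tg_calls, nrow, 1L) > 0]
  trio_genes <- names(genes)[vapply(trio_calls, nrow, 1L) > 0]
  overlap <- intersect(tg_genes, trio_genes)
  site_overlap <- do.call(rbind, c(list(
    data.frame(gene = character(), n_tg_sites = integer(),
               n_trio_sites = integer(), n_shared_sites = integer())),
    lapply(overlap, function(g)
      data.frame(gene = g, n_tg_sites = nrow(tg_calls[[g]]),
                 n_trio_sites = nrow(trio_calls[[g]]),
                 n_shared_sites = length(intersect(tg_calls[[g]]$site,
                                                   trio_calls[[g]]$site))))))
  structure(list(trio = trio, tg_calls = tg_calls, trio_calls = trio_calls,
                 tg_genes = tg_genes, trio_genes = trio_genes,
                 overlap_genes = overlap, site_overlap = site_overlap),
            class = "trio_comparison")
}

#' @export
print.trio_comparison <- function(x, ...) {
  cat("Random-trio control (trio:", paste(x$trio, collapse = ", "), ")\n",
      length(x$tg_genes), "genes called under the true foreground;",
      length(x$trio_genes), "under the trio;",
      length(x$overlap_genes), "overlap\n")
  if (nrow(x$site_overlap)) print(x$site_overlap)
  invisible(x)
}

#' Gene-level summary of convergent-site calls
#'
#' @param calls Named list of per-gene call tables (as returned by
#'   [detect_convergent_sites()]), or a single data frame with a `gene`
#'   column.
#' @return Data frame: `gene`, `n_sites`, `sites` (comma-separated
#'   ascending original coordinates), sorted by descending count then
#'   gene id. Genes with no calls are omitted.
#' @export
summarize_convergent_genes <- function(calls) {
  if (is.data.frame(calls)) calls <- split(calls, calls$gene)
  rows <- lapply(names(calls), function(g) {
    n <- nrow(calls[[g]])
    if (!n) return(NULL)
    data.frame(gene = g, n_sites = n,
               sites = paste(sort(calls[[g]]$site), collapse = ","))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(gene = character(), n_sites = integer(),
                      sites = character()))
  out <- do.call(rbind, rows)
  out[order(-out$n_sites, out$gene), , drop = FALSE]
}
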