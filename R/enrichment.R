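#' Hypergeometric over-representation test with BH-FDR
#'
#' For each term, the upper-tail hypergeometric probability of seeing at
#' least the observed overlap between the gene set and the term's
#' members within the universe, followed by Benjamini-Hochberg
#' adjustment across all tested terms. One-sided (over-representation
#' only); terms with zero overlap are reported with p = 1.
#'
#' @param genes Character vector of genes of interest (must lie in the
#'   universe).
#' @param term_map Data frame with columns `term`, `name`, `category`,
#'   `gene`.
#' @param universe Character vector of all genes under consideration.
#' @return Data frame sorted by `q` then `p`: `id`, `term`, `category`,
#'   `overlap`, `term_size`, `p`, `q`.
#' @export
hypergeom_enrich <- function(genes, term_map, universe) {
  if (!length(universe)) stop("empty universe")
  stopifnot(all(c("term", "name", "category", "gene") %in% names(term_map)))
  genes <- unique(genes)
  if (!all(genes %in% universe))
    stop("gene set contains genes outside the universe: ",
         paste(utils::head(setdiff(genes, universe), 5), collapse = ", "))
  universe <- unique(universe)
  tm <- term_map[term_map$gene %in% universe, , drop = FALSE]
  N <- length(universe)
  n <- length(genes)
  terms <- split(tm, tm$term)
  rows <- lapply(terms, function(t) {
    members <- unique(t$gene)
    K <- length(members)
    k <- length(intersect(members, genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(id = t$term[1], term = t$name[1], category = t$category[1],
               overlap = k, term_size = K, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$q, out$p, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
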