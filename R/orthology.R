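#' Filter a proteome to one clean longest transcript per gene
#'
#' Applies the standard pre-clustering filters: sequences shorter than 30
#' residues are dropped (`too_short`), sequences containing an internal
#' stop symbol `*` are dropped (`internal_stop`; a single trailing `*`
#' terminator is tolerated and stripped), and among a gene's surviving
#' transcripts only the longest is kept (ties broken by transcript id;
#' the others are marked `not_longest`).
#'
#' @param records Data frame with columns `gene`, `transcript`,
#'   `sequence` (amino acids), and optionally `species`.
#' @param species Species identifier (defaults to the `species` column's
#'   unique value, else `NA`).
#' @return Object of class `annotated_proteome`: list with `species` and
#'   `records` (the input plus a `status` column in
#'   `{kept, too_short, internal_stop, not_longest}`).
#' @export
filter_proteome <- function(records, species = NULL) {
  stopifnot(all(c("gene", "transcript", "sequence") %in% names(records)))
  key <- paste(records$gene, records$transcript)
  if (anyDuplicated(key))
    stop("duplicate (gene, transcript) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (is.null(species))
    species <- if ("species" %in% names(records))
      unique(records$species)[1] else NA_character_
  seqs <- sub("\\*$", "", records$sequence)
  status <- rep("kept", nrow(records))
  status[nchar(seqs) < 30L] <- "too_short"
  status[status == "kept" & grepl("\\*", seqs)] <- "internal_stop"
  ord <- order(records$gene, -nchar(seqs), records$transcript)
  surviving <- ord[status[ord] == "kept"]
  dup <- surviving[duplicated(records$gene[surviving])]
  status[dup] <- "not_longest"
  out <- records
  out$sequence <- seqs
  out$status <- status
  structure(list(species = species, records = out),
            class = "annotated_proteome")
}

#' @export
print.annotated_proteome <- function(x, ...) {
  cat("Annotated proteome:", x$species, "\n")
  print(table(x$records$status))
  invisible(x)
}

#' Markov clustering of a protein similarity graph into gene families
#'
#' Builds a symmetric weighted graph over all genes whose best hits pass
#' the e-value cutoff (weight = `-log10(evalue)` capped at 200 and
#' averaged over the two hit directions, or the bit score), adds
#' self-loops equal to each gene's maximum incident weight, and iterates
#' MCL: column normalisation, expansion (matrix squaring), inflation
#' (element-wise power then renormalisation) and pruning of entries below
#' 1e-6, until the maximum entry change drops below `tol`. Clusters are
#' the connected components of the limit matrix's support. Genes with no
#' qualifying edge are reported as unclustered.
#'
#' @param edges 12-column BLAST-tabular data frame (see
#'   [simulate_similarity_graph()]); at minimum `qseqid`, `sseqid`,
#'   `evalue`, `bitscore`.
#' @param inflation Inflation exponent (> 1); the study value is 1.5.
#' @param evalue_cutoff Hits with larger e-value are ignored.
#' @param weight `"evalue"` (default) or `"bitscore"`.
#' @param genes Optional character vector of all gene ids (so isolated
#'   genes can be reported as unclustered); defaults to ids in `edges`.
#' @param species_map Named vector gene -> species; if `NULL`, species is
#'   parsed from a `species|gene` id prefix.
#' @param tol,max_iter,prune Convergence tolerance on the maximum entry
#'   change, iteration cap, and pruning threshold.
#' @return Object of class `family_catalogue`: `families` (data frame
#'   family/gene/species), `counts` (family x species matrix),
#'   `unclustered` (gene ids), `species` (levels).
#' @export
mcl_cluster <- function(edges, inflation = 1.5, evalue_cutoff = 1e-5,
                        weight = c("evalue", "bitscore"), genes = NULL,
                        species_map = NULL, tol = 1e-8, max_iter = 200L,
                        prune = 1e-6) {
  weight <- match.arg(weight)
  if (inflation <= 1) stop("'inflation' must be > 1")
  keep <- edges$evalue <= evalue_cutoff & edges$qseqid != edges$sseqid
  e <- edges[keep, , drop = FALSE]
  w <- if (weight == "evalue") pmin(-log10(pmax(e$evalue, 1e-200)), 200)
       else e$bitscore
  universe <- unique(c(genes, edges$qseqid, edges$sseqid))
  connected <- unique(c(e$qseqid, e$sseqid))
  unclustered <- setdiff(universe, connected)
  members <- list()
  if (length(connected)) {
    n <- length(connected)
    A <- matrix(0, n, n, dimnames = list(connected, connected))
    i <- match(e$qseqid, connected); j <- match(e$sseqid, connected)
    # average over the two directed hits
    Wsum <- matrix(0, n, n); Wn <- matrix(0, n, n)
    idx <- cbind(pmin(i, j), pmax(i, j))
    for (r in seq_along(w)) {
      Wsum[idx[r, 1], idx[r, 2]] <- Wsum[idx[r, 1], idx[r, 2]] + w[r]
      Wn[idx[r, 1], idx[r, 2]] <- Wn[idx[r, 1], idx[r, 2]] + 1
    }
    up <- Wn > 0
    A[up] <- Wsum[up] / Wn[up]
    A <- A + t(A)
    diag(A) <- apply(A, 2, max)               # self-loop regularisation
    M <- sweep(A, 2, colSums(A), "/")
    it <- 0L
    repeat {
      it <- it + 1L
      M2 <- M %*% M
      M2 <- M2^inflation
      M2[M2 < prune] <- 0
      cs <- colSums(M2)
      cs[cs == 0] <- 1
      M2 <- sweep(M2, 2, cs, "/")
      delta <- max(abs(M2 - M))
      M <- M2
      if (delta < tol) break
      if (it >= max_iter)
        stop("MCL did not converge after ", max_iter,
             " iterations (last max change ", signif(delta, 3), ")")
    }
    g <- igraph::graph_from_adjacency_matrix(M > 0, mode = "max")
    comp <- igraph::components(g)$membership
    members <- split(connected, comp)
    members <- members[order(vapply(members, min, character(1)))]
  }
  build_catalogue(members, universe, unclustered, species_map)
}

# Assemble a family_catalogue from cluster membership lists.
build_catalogue <- function(members, universe, unclustered, species_map) {
  if (is.null(species_map)) {
    sp <- sub("\\|.*$", "", universe)
    species_map <- stats::setNames(sp, universe)
  }
  species <- sort(unique(unname(species_map[universe])))
  fam_ids <- sprintf("F%04d", seq_along(members))
  families <- if (length(members))
    data.frame(family = rep(fam_ids, lengths(members)),
               gene = unlist(members, use.names = FALSE)) else
    data.frame(family = character(), gene = character())
  families$species <- unname(species_map[families$gene])
  counts <- matrix(0L, length(members), length(species),
                   dimnames = list(fam_ids, species))
  if (nrow(families)) {
    tab <- table(families$family, families$species)
    counts[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  structure(list(families = families, counts = counts,
                 unclustered = unclustered, species = species,
                 species_map = species_map),
            class = "family_catalogue")
}

#' @export
print.family_catalogue <- function(x, ...) {
  cat("Family catalogue:", nrow(x$counts), "families over",
      length(x$species), "species;", length(x$unclustered),
      "unclustered genes\n")
  invisible(x)
}

#' Per-species five-category gene tallies
#'
#' Partitions each species' genes into the five standard clustering
#' categories: single-copy (families with exactly one gene in every
#' species), multiple-copy (families represented in all species where
#' this species holds >= 2 copies), unique (families whose members all
#' come from this species), unclustered (genes in no family), and other
#' (all remaining clustered genes). Tallies partition each species' gene
#' set by construction.
#'
#' @param catalogue A `family_catalogue`.
#' @return Data frame: species, single_copy, multiple_copy, unique,
#'   other, unclustered, total.
#' @export
classify_families <- function(catalogue) {
  stopifnot(inherits(catalogue, "family_catalogue"))
  cn <- catalogue$counts
  species <- catalogue$species
  all_one <- rowSums(cn == 1L) == ncol(cn)
  in_all <- rowSums(cn >= 1L) == ncol(cn)
  n_species_in_fam <- rowSums(cn >= 1L)
  out <- lapply(species, function(sp) {
    spc <- cn[, sp]
    single <- sum(spc[all_one])
    multiple <- sum(spc[in_all & spc >= 2L])
    uniq <- sum(spc[n_species_in_fam == 1L & spc >= 1L])
    uncl <- sum(catalogue$species_map[catalogue$unclustered] == sp)
    total_clustered <- sum(spc)
    other <- total_clustered - single - multiple - uniq
    data.frame(species = sp, single_copy = single, multiple_copy = multiple,
               unique = uniq, other = other, unclustered = uncl,
               total = total_clustered + uncl)
  })
  out <- do.call(rbind, out)
  stopifnot(all(out$single_copy + out$multiple_copy + out$unique +
                out$other + out$unclustered == out$total))
  out
}

#' Extract 1:1 single-copy family ids
#'
#' Families with exactly one member in every species.
#'
#' @param catalogue A `family_catalogue`.
#' @return Character vector of family ids.
#' @export
extract_single_copy <- function(catalogue) {
  stopifnot(inherits(catalogue, "family_catalogue"))
  cn <- catalogue$counts
  rownames(cn)[rowSums(cn == 1L) == ncol(cn)]
}
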