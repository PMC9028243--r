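#' Read an alignment from FASTA into a character matrix
#'
#' @param path FASTA file.
#' @param type `"AA"` or `"DNA"`.
#' @return Character matrix, one row per sequence (rownames = ids), one
#'   column per alignment column.
#' @export
read_fasta_matrix <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::readAAStringSet(path)
       else Biostrings::readDNAStringSet(path)
  if (length(unique(Biostrings::width(x))) != 1L)
    stop("sequences in ", path, " are not aligned (unequal lengths)")
  m <- do.call(rbind, strsplit(as.character(x), ""))
  rownames(m) <- names(x)
  m
}

#' Write a character-matrix alignment to FASTA
#' @param aln Character matrix with rownames.
#' @param path Output file.
#' @export
write_fasta_matrix <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln)))
    writeLines(c(paste0(">", rownames(aln)[i]),
                 paste(aln[i, ], collapse = "")), con)
  invisible(path)
}

#' Remove alignment columns containing gaps or ambiguous residues
#'
#' Columns holding any character outside the 20 standard amino acids are
#' dropped (the usual pre-processing before likelihood work); the indices
#' of the surviving columns are kept so downstream site calls can be
#' reported in original coordinates.
#'
#' @param aln Character matrix alignment.
#' @return List with `alignment` (stripped matrix) and `kept` (original
#'   column indices of the surviving columns).
#' @export
strip_gap_columns <- function(aln) {
  ok <- apply(aln, 2, function(col) all(col %in% .AA))
  list(alignment = aln[, ok, drop = FALSE], kept = which(ok))
}

# Integer-encode an amino-acid alignment in tree tip order; errors name
# missing tips and invalid characters.
aa_tipstate <- function(tree, aln) {
  missing <- setdiff(tree$tip.label, rownames(aln))
  if (length(missing))
    stop("alignment has no row for tip(s): ", paste(missing, collapse = ", "))
  m <- aln[tree$tip.label, , drop = FALSE]
  x <- match(m, .AA)
  if (anyNA(x))
    stop("alignment contains non-standard characters; strip gaps first ",
         "(strip_gap_columns)")
  matrix(x, nrow = nrow(m), dimnames = dimnames(m))
}

# Collapse identical columns into patterns. Returns list(states, weights,
# index) where index maps original columns to patterns.
compress_patterns <- function(tipstate) {
  key <- apply(tipstate, 2, paste, collapse = ".")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  list(states = tipstate[, first, drop = FALSE],
       weights = as.vector(table(factor(idx, levels = seq_len(sum(first))))),
       index = idx)
}

# Consistent TSV writer used for all pipeline outputs (deterministic,
# diffable).
write_tsv <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}
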