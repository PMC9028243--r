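# Sense-codon machinery for the GY94 codon model. Tables are built once
# at install time from the standard genetic code.
.codon_tables <- local({
  nt <- c("T", "C", "A", "G")
  all64 <- apply(expand.grid(nt, nt, nt)[, 3:1], 1, paste, collapse = "")
  aa <- Biostrings::GENETIC_CODE[all64]
  sense <- all64[aa != "*"]
  aa <- aa[aa != "*"]
  S <- length(sense)                      # 61
  pos <- do.call(rbind, strsplit(sense, ""))
  is_ti <- function(x, y) (x %in% c("A", "G") & y %in% c("A", "G")) |
                          (x %in% c("C", "T") & y %in% c("C", "T"))
  ii <- jj <- integer(0); ti <- ns <- logical(0)
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    d <- which(pos[i, ] != pos[j, ])
    if (length(d) == 1L) {
      ii <- c(ii, i); jj <- c(jj, j)
      ti <- c(ti, is_ti(pos[i, d], pos[j, d]))
      ns <- c(ns, aa[i] != aa[j])
    }
  }
  list(codons = sense, aa = unname(aa), pos = pos,
       pair_i = ii, pair_j = jj, pair_ti = ti, pair_ns = ns)
})

.CODONS <- .codon_tables$codons
.CODON_AA <- .codon_tables$aa

#' GY94 codon rate matrix
#'
#' Goldman-Yang-style 61-state rate matrix: zero for multi-nucleotide
#' changes; otherwise the target-codon frequency times `kappa` for
#' transitions and times `omega` for nonsynonymous changes. Scaled to one
#' expected substitution per codon per unit branch length at
#' stationarity.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi Length-61 sense-codon frequencies (default uniform).
#' @return 61 x 61 rate matrix with codon dimnames.
#' @export
gy94_matrix <- function(kappa, omega, pi = NULL) {
  if (kappa <= 0) stop("'kappa' must be positive")
  if (omega < 0) stop("'omega' must be >= 0")
  S <- length(.CODONS)
  if (is.null(pi)) pi <- rep(1 / S, S)
  stopifnot(length(pi) == S)
  tb <- .codon_tables
  Q <- matrix(0, S, S, dimnames = list(.CODONS, .CODONS))
  rate <- ifelse(tb$pair_ti, kappa, 1) * ifelse(tb$pair_ns, omega, 1)
  Q[cbind(tb$pair_i, tb$pair_j)] <- rate * pi[tb$pair_j]
  Q[cbind(tb$pair_j, tb$pair_i)] <- rate * pi[tb$pair_i]
  diag(Q) <- -rowSums(Q)
  scale <- sum(pi * -diag(Q))
  if (scale > 0) Q <- Q / scale
  Q
}

# Eigendecomposition for a (kappa, omega) GY94 matrix.
gy94_eigen <- function(kappa, omega, pi = NULL) {
  S <- length(.CODONS)
  if (is.null(pi)) pi <- rep(1 / S, S)
  rev_eigen(gy94_matrix(kappa, omega, pi), pi)
}

# Mean substitution rate of the *unnormalised* GY94 generator, linear in
# omega: r(omega) = A + omega * B with A the synonymous and B the
# nonsynonymous flux. Used to put site classes of a mixture on a common
# time scale (the scaled matrix of a single-class model has rate 1, so
# single-class likelihoods are unaffected).
gy94_rate_parts <- function(kappa, pi = NULL) {
  S <- length(.CODONS)
  if (is.null(pi)) pi <- rep(1 / S, S)
  tb <- .codon_tables
  flux <- 2 * pi[tb$pair_i] * pi[tb$pair_j] * ifelse(tb$pair_ti, kappa, 1)
  c(A = sum(flux[!tb$pair_ns]), B = sum(flux[tb$pair_ns]))
}

#' F3x4 codon frequencies from an alignment
#'
#' Position-specific nucleotide frequencies multiplied across the three
#' codon positions, restricted to sense codons and renormalised.
#' Zero-count nucleotide frequencies are floored at 1e-6.
#'
#' @param caln A `codon_alignment` (integer matrix of sense-codon
#'   indices) or nucleotide character matrix.
#' @return Length-61 frequency vector (sums to 1), named by codon.
#' @export
f3x4_frequencies <- function(caln) {
  caln <- as_codon_alignment(caln)
  nt <- c("T", "C", "A", "G")
  pos <- .codon_tables$pos
  f <- matrix(0, 3, 4, dimnames = list(NULL, nt))
  for (k in 1:3) {
    tab <- table(factor(pos[as.vector(caln), k], levels = nt))
    fk <- as.numeric(tab) / sum(tab)
    fk <- pmax(fk, 1e-6)
    f[k, ] <- fk / sum(fk)
  }
  pi <- f[1, pos[, 1]] * f[2, pos[, 2]] * f[3, pos[, 3]]
  stats::setNames(pi / sum(pi), .CODONS)
}

#' Coerce to a codon alignment
#'
#' @param x Integer matrix of sense-codon indices (returned as is),
#'   nucleotide character matrix (columns a multiple of 3), or character
#'   vector of nucleotide strings.
#' @return Integer matrix (rows = sequences) of indices into the 61
#'   sense codons, class `codon_alignment`. Stop codons are an error.
#' @export
as_codon_alignment <- function(x) {
  if (inherits(x, "codon_alignment")) return(x)
  if (is.character(x) && is.null(dim(x))) {
    x <- do.call(rbind, strsplit(toupper(x), ""))
  }
  if (is.character(x)) {
    if (ncol(x) %% 3 != 0)
      stop("nucleotide alignment length is not a multiple of 3")
    n <- ncol(x) / 3
    idx <- matrix(NA_integer_, nrow(x), n)
    for (j in seq_len(n)) {
      cod <- paste0(x[, 3 * j - 2], x[, 3 * j - 1], x[, 3 * j])
      m <- match(cod, .CODONS)
      if (anyNA(m)) {
        bad <- which(is.na(m))[1]
        stop("stop or invalid codon '", cod[bad], "' in sequence ",
             if (!is.null(rownames(x))) rownames(x)[bad] else bad,
             " at codon position ", j)
      }
      idx[, j] <- m
    }
    rownames(idx) <- rownames(x)
    x <- idx
  }
  stopifnot(is.numeric(x))
  structure(matrix(as.integer(x), nrow(x), ncol(x),
                   dimnames = dimnames(x)),
            class = "codon_alignment")
}

#' Codon alignment to nucleotide character matrix
#' @param caln A `codon_alignment`.
#' @return Character matrix of single nucleotides.
#' @export
codon_to_dna_matrix <- function(caln) {
  caln <- as_codon_alignment(caln)
  out <- matrix("", nrow(caln), 3L * ncol(caln))
  for (j in seq_len(ncol(caln)))
    out[, (3 * j - 2):(3 * j)] <-
      do.call(rbind, strsplit(.CODONS[caln[, j]], ""))
  rownames(out) <- rownames(caln)
  out
}
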