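#' @useDynLib phyloccs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Amino acids in the conventional (PAML) order used throughout the package.
.AA <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# JTT (Jones-Taylor-Thornton 1992) empirical exchangeabilities, lower
# triangle column-wise in .AA order, and the matching stationary
# frequencies. Published values as distributed with standard phylogenetics
# software.
.JTT_EXCH <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64,
  126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232,
  8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46,
  31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26,
  597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
  5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47,
  16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40,
  245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47,
  103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62,
  285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112, 71, 25, 16)

.JTT_FREQ <- c(
  0.07674792325, 0.05169094831, 0.04264495736, 0.05154394846,
  0.01980298020, 0.04075195925, 0.06182993817, 0.07315192685,
  0.02294397706, 0.05376094624, 0.09190390810, 0.05867594132,
  0.02382597617, 0.04012595987, 0.05090094910, 0.06876493124,
  0.05856494144, 0.01426098574, 0.03210196790, 0.06600493400)

#' JTT amino-acid substitution model with discrete-gamma rates
#'
#' Builds the 20-state JTT rate matrix (exchangeabilities times stationary
#' frequencies, rows summing to zero, scaled to one expected substitution
#' per unit branch length) together with `n_categories` equal-probability
#' discrete-gamma rate categories of shape `alpha`.
#'
#' @param alpha Gamma shape parameter for among-site rate variation
#'   (must be > 0). Smaller values mean stronger rate heterogeneity.
#' @param n_categories Number of equal-probability rate categories
#'   (default 4).
#' @param frequencies Optional length-20 vector of stationary frequencies
#'   in `ARNDCQEGHILKMFPSTWYV` order replacing the JTT frequencies (the
#'   "+F" option); must sum to 1.
#' @return An object of class `aa_model` with elements `Q` (scaled rate
#'   matrix), `pi` (stationary frequencies), `alpha`, `rates`
#'   (category-mean rates, mean 1), and an eigendecomposition used to
#'   compute transition matrices.
#' @export
jtt_model <- function(alpha = 1, n_categories = 4L, frequencies = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a single positive number")
  if (n_categories < 1L)
    stop("'n_categories' must be >= 1")
  pi <- if (is.null(frequencies)) .JTT_FREQ else {
    stopifnot(length(frequencies) == 20L, all(frequencies > 0))
    frequencies / sum(frequencies)
  }
  S <- matrix(0, 20, 20, dimnames = list(.AA, .AA))
  S[lower.tri(S)] <- .JTT_EXCH
  S <- S + t(S)
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(pi * -diag(Q))            # mean rate 1
  dimnames(Q) <- list(.AA, .AA)
  structure(list(Q = Q, pi = stats::setNames(pi, .AA), alpha = alpha,
                 n_categories = as.integer(n_categories),
                 rates = discrete_gamma_rates(alpha, n_categories),
                 eig = rev_eigen(Q, pi)),
            class = "aa_model")
}

#' Equal-probability discrete-gamma category rates
#'
#' Mean rate of each of `k` equal-probability categories of a
#' Gamma(alpha, alpha) distribution (mean 1), the usual discretisation for
#' among-site rate variation.
#'
#' @param alpha Shape parameter (> 0).
#' @param k Number of categories.
#' @return Numeric vector of `k` category-mean rates averaging exactly 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  if (alpha <= 0) stop("'alpha' must be positive")
  k <- as.integer(k)
  if (k == 1L) return(1)
  q <- stats::qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  p <- c(0, stats::pgamma(q, shape = alpha + 1, rate = alpha), 1)
  k * diff(p)
}

# Eigendecomposition of a reversible rate matrix Q with stationary pi,
# via the symmetric similarity transform. Returns A, Ainv, values such
# that expm(Q t) = A diag(exp(values t)) Ainv.
rev_eigen <- function(Q, pi) {
  sq <- sqrt(pi)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(A = diag(1 / sq) %*% e$vectors,
       Ainv = t(e$vectors) %*% diag(sq),
       values = e$values)
}

# Transition probability matrix P(t) for a model eigendecomposition;
# clamps tiny negative round-off to zero.
prob_matrix <- function(eig, t) {
  P <- eig$A %*% (exp(eig$values * t) * eig$Ainv)
  P[P < 0] <- 0
  P
}
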