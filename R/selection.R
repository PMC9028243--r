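# Synonymous/nonsynonymous site counts of one sense codon (stop-bound
# mutations counted as nonsynonymous so N + S = 3).
ng86_site_counts <- function(codon_idx) {
  nt <- c("T", "C", "A", "G")
  cod <- .CODONS[codon_idx]
  aa <- .CODON_AA[codon_idx]
  chars <- strsplit(cod, "")[[1]]
  s <- 0
  for (p in 1:3) for (n in setdiff(nt, chars[p])) {
    alt <- chars; alt[p] <- n
    alt_cod <- paste(alt, collapse = "")
    j <- match(alt_cod, .CODONS)
    if (!is.na(j) && .CODON_AA[j] == aa) s <- s + 1 / 3
  }
  c(S = s, N = 3 - s)
}

# Pathway-averaged synonymous/nonsynonymous difference counts between two
# sense codons; paths through stop codons are discarded (all-blocked
# pairs fall back to averaging over every path).
ng86_diff_counts <- function(i, j) {
  if (i == j) return(c(Sd = 0, Nd = 0))
  a <- strsplit(.CODONS[i], "")[[1]]
  b <- strsplit(.CODONS[j], "")[[1]]
  d <- which(a != b)
  perms <- if (length(d) == 1L) list(d) else
    if (length(d) == 2L) list(d, rev(d)) else
    lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
           function(o) d[o])
  score_path <- function(ord) {
    cur <- a; sd <- nd <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      ci <- match(paste(cur, collapse = ""), .CODONS)
      cj <- match(paste(nxt, collapse = ""), .CODONS)
      if (is.na(cj)) return(NULL)                      # through a stop
      if (.CODON_AA[ci] == .CODON_AA[cj]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  sc <- lapply(perms, score_path)
  ok <- sc[!vapply(sc, is.null, TRUE)]
  if (!length(ok)) {       # every path blocked: count ignoring stops
    ok <- lapply(perms, function(ord) {
      cur <- a; sd <- nd <- 0
      for (p in ord) {
        nxt <- cur; nxt[p] <- b[p]
        aai <- Biostrings::GENETIC_CODE[paste(cur, collapse = "")]
        aaj <- Biostrings::GENETIC_CODE[paste(nxt, collapse = "")]
        if (aai == aaj) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    })
  }
  m <- colMeans(do.call(rbind, ok))
  c(Sd = m[1], Nd = m[2])
}

#' Nei-Gojobori (1986) pairwise dN/dS
#'
#' Counts synonymous and nonsynonymous sites per codon (fractional,
#' N + S = 3), averages pathway differences over all mutational orders
#' between each codon pair, and applies the Jukes-Cantor correction.
#'
#' @param a,b In-frame coding sequences: nucleotide strings, nucleotide
#'   character vectors, or rows of a `codon_alignment`.
#' @return List: `dN`, `dS`, `omega` (`NA` when `dS` is 0 or
#'   uncorrectable), site counts `N`, `S`, difference counts `Nd`, `Sd`.
#' @export
ng86_pairwise <- function(a, b) {
  to_idx <- function(x) {
    if (is.character(x) && length(x) == 1L) x <- strsplit(x, "")[[1]]
    if (is.character(x)) {
      if (length(x) %% 3 != 0)
        stop("sequence length is not a multiple of 3")
      as.vector(as_codon_alignment(matrix(x, nrow = 1)))
    } else as.integer(x)
  }
  ia <- to_idx(a); ib <- to_idx(b)
  if (length(ia) != length(ib)) stop("sequences differ in length")
  SA <- vapply(ia, function(i) ng86_site_counts(i)["S"], 0)
  SB <- vapply(ib, function(i) ng86_site_counts(i)["S"], 0)
  S <- (sum(SA) + sum(SB)) / 2
  N <- 3 * length(ia) - S
  dif <- mapply(function(i, j) ng86_diff_counts(i, j), ia, ib)
  Sd <- sum(dif["Sd", ]); Nd <- sum(dif["Nd", ])
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  dS <- if (S > 0) jc(Sd / S) else NA_real_
  dN <- if (N > 0) jc(Nd / N) else NA_real_
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  list(dN = dN, dS = dS, omega = omega, N = N, S = S, Nd = Nd, Sd = Sd)
}

# ---- GY94 likelihood ------------------------------------------------------

codon_prune_context <- function(tree, caln) {
  caln <- as_codon_alignment(caln)
  missing <- setdiff(tree$tip.label, rownames(caln))
  if (length(missing))
    stop("codon alignment has no row for tip(s): ",
         paste(missing, collapse = ", "))
  x <- unclass(caln)[tree$tip.label, , drop = FALSE]
  pat <- compress_patterns(x)
  list(et = edge_table(tree), states = pat$states, weights = pat$weights,
       index = pat$index, n_node = tree$Nnode)
}

#' Codon substitution model specification
#'
#' Describes a GY94 model for [codon_log_likelihood()]: either a branch
#' model (`omega` scalar for one ratio, or `foreground` branches with
#' their own `omega_fg` for a two-ratio model) or a branch-site mixture
#' (`site_classes`: data frame with columns `weight`, `omega_bg`,
#' `omega_fg`, in which case `foreground` names the branches using the
#' `omega_fg` column).
#'
#' @param kappa Transition/transversion ratio.
#' @param frequencies Length-61 sense-codon frequencies (e.g.
#'   [f3x4_frequencies()]); default uniform.
#' @param omega Background/global dN/dS.
#' @param foreground Branch (child node/tip) names forming the
#'   foreground class; `NULL` for a homogeneous model.
#' @param omega_fg Foreground dN/dS (two-ratio model).
#' @param site_classes Optional mixture data frame (`weight`,
#'   `omega_bg`, `omega_fg`); weights must sum to 1.
#' @return Object of class `codon_model`.
#' @export
codon_model <- function(kappa, frequencies = NULL, omega = 1,
                        foreground = NULL, omega_fg = NULL,
                        site_classes = NULL) {
  if (kappa <= 0) stop("'kappa' must be positive")
  if (!is.null(site_classes)) {
    stopifnot(all(c("weight", "omega_bg", "omega_fg") %in%
                    names(site_classes)))
    if (abs(sum(site_classes$weight) - 1) > 1e-8)
      stop("site class weights must sum to 1")
    if (any(site_classes$omega_bg < 0) || any(site_classes$omega_fg < 0))
      stop("omega values must be >= 0")
  } else if (any(omega < 0) || (!is.null(omega_fg) && omega_fg < 0))
    stop("omega values must be >= 0")
  structure(list(kappa = kappa, frequencies = frequencies, omega = omega,
                 foreground = foreground, omega_fg = omega_fg,
                 site_classes = site_classes),
            class = "codon_model")
}

# Mixture site log-likelihood core. classes: weights plus an E x nclass
# matrix of per-edge omegas. Site classes share one time scale per
# branch (each branch normalised to one expected substitution per unit
# length averaged over classes, so faster omega classes genuinely evolve
# faster, as in codeml). Duplicate classes are merged before pruning.
codon_mix_loglik <- function(ctx, kappa, pi, weights, omega_edges) {
  parts <- gy94_rate_parts(kappa, pi)
  rmat <- parts["A"] + omega_edges * parts["B"]     # E x nclass rates
  f <- as.vector(rmat %*% weights)                  # per-branch scale
  keep <- weights > 1e-12
  weights <- weights[keep]
  omega_edges <- omega_edges[, keep, drop = FALSE]
  key <- apply(omega_edges, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w_merged <- vapply(key[first], function(k) sum(weights[key == k]), 0)
  omega_edges <- omega_edges[, first, drop = FALSE]
  uniq <- sort(unique(as.vector(omega_edges)))
  eigs <- lapply(uniq, function(w) gy94_eigen(kappa, w, pi))
  # scaled matrices have rate 1; stretch branch time by r(omega)/f_e
  Plist <- lapply(seq_along(uniq), function(u)
    cpp_edge_pmats(eigs[[u]]$A, eigs[[u]]$Ainv, eigs[[u]]$values,
                   ctx$et$length *
                     (parts["A"] + uniq[u] * parts["B"]) / f))
  class_idx <- matrix(match(omega_edges, uniq), nrow(omega_edges))
  storage.mode(class_idx) <- "integer"
  ll <- cpp_prune_multi(ctx$et$parent, ctx$et$child, Plist, class_idx,
                        ctx$states, pi, ctx$n_node)
  site <- logsumexp_rows(sweep(ll, 2, log(w_merged), "+"))
  sum(ctx$weights * site)
}

# Expand a codon_model into mixture weights + per-edge omega matrix.
codon_model_classes <- function(model, ctx) {
  E <- nrow(ctx$et)
  is_fg <- ctx$et$name %in% model$foreground
  if (!is.null(model$site_classes)) {
    sc <- model$site_classes
    omega_edges <- sapply(seq_len(nrow(sc)), function(cl)
      ifelse(is_fg, sc$omega_fg[cl], sc$omega_bg[cl]))
    list(weights = sc$weight,
         omega_edges = matrix(omega_edges, nrow = E))
  } else if (!is.null(model$foreground) && !is.null(model$omega_fg)) {
    list(weights = 1,
         omega_edges = matrix(ifelse(is_fg, model$omega_fg, model$omega),
                              ncol = 1))
  } else if (length(model$omega) > 1L) {     # named branch -> omega map
    stopifnot(!is.null(names(model$omega)))
    w <- rep(model$omega[1], E)
    m <- match(ctx$et$name, names(model$omega))
    w[!is.na(m)] <- model$omega[m[!is.na(m)]]
    list(weights = 1, omega_edges = matrix(unname(w), ncol = 1))
  } else {
    list(weights = 1, omega_edges = matrix(model$omega, E, 1))
  }
}

#' Codon alignment log-likelihood under a GY94 model
#'
#' Felsenstein pruning over the 61 sense codons with per-node scaling;
#' site-class mixtures are summed at the site level. Rates follow the
#' GY94 scheme (zero for multi-nucleotide changes, target frequency
#' times `kappa` for transitions and times omega for nonsynonymous
#' changes), each class matrix normalised to one expected substitution
#' per unit branch length.
#'
#' @param tree Phylo tree, tips matching alignment rows.
#' @param caln Codon alignment (see [as_codon_alignment()]).
#' @param model A [codon_model()].
#' @return Total log-likelihood.
#' @export
codon_log_likelihood <- function(tree, caln, model) {
  stopifnot(inherits(model, "codon_model"))
  ctx <- codon_prune_context(tree, caln)
  pi <- if (is.null(model$frequencies)) rep(1 / 61, 61) else model$frequencies
  cls <- codon_model_classes(model, ctx)
  codon_mix_loglik(ctx, model$kappa, pi, cls$weights, cls$omega_edges)
}

# Multi-start bounded quasi-Newton maximisation: starts screened at loose
# tolerance, best refined tightly. fn returns the log-likelihood.
ml_maximize <- function(fn, starts, lower, upper) {
  neg <- function(p) -fn(p)
  best <- NULL
  for (s in starts) {
    o <- tryCatch(stats::optim(s, neg, method = "L-BFGS-B", lower = lower,
                               upper = upper,
                               control = list(maxit = 60, factr = 1e10)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    stop("optimizer failed from every start")
  o <- tryCatch(stats::optim(best$par, neg, method = "L-BFGS-B",
                             lower = lower, upper = upper,
                             control = list(maxit = 300, factr = 1e7)),
                error = function(e) best)
  if (o$value <= best$value) best <- o
  list(par = best$par, logLik = -best$value)
}

# Branch-site Model A class structure from (p0, p1, w0, w2):
# classes 0, 1, 2a, 2b with weights p0, p1, p2*p0/(p0+p1), p2*p1/(p0+p1).
model_a_classes <- function(p0, p1, w0, w2) {
  p2 <- 1 - p0 - p1
  data.frame(weight = c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1)),
             omega_bg = c(w0, 1, w0, 1),
             omega_fg = c(w0, 1, w2, w2))
}

#' Branch-site positive-selection likelihood ratio test
#'
#' Fits branch-site Model A (site classes 0, 1, 2a, 2b; foreground
#' omega2 free, >= 1) and its null with omega2 fixed at 1, and tests
#' 2(lnL_alt - lnL_null), clamped at 0, against chi-squared with one
#' degree of freedom. Codon frequencies are F3x4 from the alignment;
#' branch lengths are taken from the tree.
#'
#' @param tree Phylo tree (branch lengths in expected substitutions per
#'   codon).
#' @param caln Codon alignment.
#' @param foreground Foreground branch (child node/tip) names; default
#'   the tree's foreground tips.
#' @param p_threshold Significance threshold (study value 0.05).
#' @return Object of class `selection_result` with `lnL_null`,
#'   `lnL_alt`, `lrt`, `p_value`, `significant`, `kappa`, `omega0`,
#'   `omega2`, `proportions`.
#' @export
branch_site_lrt <- function(tree, caln, foreground = NULL,
                            p_threshold = 0.05) {
  if (is.null(foreground)) foreground <- foreground_tips(tree)
  if (is.null(foreground) || !length(foreground))
    stop("no foreground branches given")
  ctx <- codon_prune_context(tree, caln)
  if (!all(foreground %in% ctx$et$name))
    stop("unknown foreground branch name(s): ",
         paste(setdiff(foreground, ctx$et$name), collapse = ", "))
  pi <- f3x4_frequencies(as_codon_alignment(caln))
  is_fg <- ctx$et$name %in% foreground
  E <- nrow(ctx$et)
  omega_mat <- function(sc)
    sapply(seq_len(nrow(sc)), function(cl)
      ifelse(is_fg, sc$omega_fg[cl], sc$omega_bg[cl]))
  # parameters: log kappa, a0, a1 (softmax for p0,p1,p2), qlogis(w0),
  # and for the alternative log(w2 - 1)
  unpack <- function(par, alt) {
    ex <- exp(c(par[2], par[3], 0))
    p <- ex / sum(ex)
    list(kappa = exp(par[1]), p0 = p[1], p1 = p[2],
         w0 = stats::plogis(par[4]),
         w2 = if (alt) 1 + exp(par[5]) else 1)
  }
  fn <- function(par, alt) {
    q <- unpack(par, alt)
    sc <- model_a_classes(q$p0, q$p1, q$w0, q$w2)
    codon_mix_loglik(ctx, q$kappa, pi, sc$weight, omega_mat(sc))
  }
  starts0 <- list(c(log(2), 1, 1, 0), c(log(2), 2, 0, -1.5),
                  c(log(4), 0.5, 0.5, 1))
  lo0 <- c(log(0.1), -8, -8, -8); hi0 <- c(log(20), 8, 8, 8)
  fit0 <- ml_maximize(function(p) fn(p, FALSE), starts0, lo0, hi0)
  starts1 <- list(c(fit0$par, log(1.001 - 1 + 1e-3)), c(fit0$par, 0),
                  c(fit0$par, 1.5))
  lo1 <- c(lo0, -9); hi1 <- c(hi0, 5)
  fit1 <- ml_maximize(function(p) fn(p, TRUE), starts1, lo1, hi1)
  lnL0 <- fit0$logLik
  lnL1 <- max(fit1$logLik, lnL0)    # nested models: alt >= null
  lrt <- max(0, 2 * (lnL1 - lnL0))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  q <- unpack(fit1$par, TRUE)
  structure(list(lnL_null = lnL0, lnL_alt = lnL1, lrt = lrt, p_value = p,
                 significant = p < p_threshold, kappa = q$kappa,
                 omega0 = q$w0, omega2 = q$w2,
                 proportions = c(p0 = q$p0, p1 = q$p1,
                                 p2 = 1 - q$p0 - q$p1)),
            class = "selection_result")
}

#' Foreground/background omega difference (two-ratio test)
#'
#' Fits a two-ratio branch model (one dN/dS for the foreground branches,
#' one for the background) against a one-ratio null, reports both
#' estimates, their difference omega(TG) - omega(BG), and a chi-squared
#' (1 df) p-value for the likelihood-ratio test.
#'
#' @param tree Phylo tree.
#' @param caln Codon alignment.
#' @param foreground Foreground branch names (default: foreground tips).
#' @param background Background branch names (default: all other
#'   branches); must be disjoint from `foreground`.
#' @param p_threshold Significance threshold (study value 0.01).
#' @return Object of class `selection_result` with `omega_tg`,
#'   `omega_bg`, `difference`, `lnL_null`, `lnL_alt`, `lrt`, `p_value`,
#'   `significant`, `kappa`.
#' @export
group_omega_difference <- function(tree, caln, foreground = NULL,
                                   background = NULL, p_threshold = 0.01) {
  if (is.null(foreground)) foreground <- foreground_tips(tree)
  ctx <- codon_prune_context(tree, caln)
  if (is.null(background)) background <- setdiff(ctx$et$name, foreground)
  if (length(intersect(foreground, background)))
    stop("foreground and background branch sets overlap")
  pi <- f3x4_frequencies(as_codon_alignment(caln))
  is_fg <- ctx$et$name %in% foreground
  one <- function(par)   # log kappa, log omega
    codon_mix_loglik(ctx, exp(par[1]), pi, 1,
                     matrix(exp(par[2]), nrow(ctx$et), 1))
  two <- function(par)   # log kappa, log omega_tg, log omega_bg
    codon_mix_loglik(ctx, exp(par[1]), pi, 1,
                     matrix(ifelse(is_fg, exp(par[2]), exp(par[3])),
                            ncol = 1))
  s0 <- list(c(log(2), log(0.3)), c(log(2), log(1)), c(log(4), log(0.1)))
  fit0 <- ml_maximize(one, s0, c(log(0.1), log(1e-4)),
                      c(log(20), log(20)))
  s1 <- list(c(fit0$par[1], fit0$par[2], fit0$par[2]),
             c(fit0$par[1], fit0$par[2] + 0.5, fit0$par[2] - 0.5),
             c(log(2), log(0.5), log(0.2)))
  fit1 <- ml_maximize(two, s1, c(log(0.1), log(1e-4), log(1e-4)),
                      c(log(20), log(20), log(20)))
  lnL0 <- fit0$logLik
  lnL1 <- max(fit1$logLik, lnL0)
  lrt <- max(0, 2 * (lnL1 - lnL0))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  w_tg <- exp(fit1$par[2]); w_bg <- exp(fit1$par[3])
  structure(list(omega_tg = w_tg, omega_bg = w_bg,
                 difference = w_tg - w_bg, lnL_null = lnL0,
                 lnL_alt = lnL1, lrt = lrt, p_value = p,
                 significant = p < p_threshold, kappa = exp(fit1$par[1])),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  if (!is.null(x$omega2))
    cat(sprintf(
      "Branch-site LRT: lnL0 = %.3f, lnL1 = %.3f, 2dL = %.3f, p = %.3g%s\n",
      x$lnL_null, x$lnL_alt, x$lrt, x$p_value,
      if (x$significant) " *" else ""))
  else
    cat(sprintf(
      "Two-ratio: w(TG) = %.3f, w(BG) = %.3f, diff = %+.3f, p = %.3g%s\n",
      x$omega_tg, x$omega_bg, x$difference, x$p_value,
      if (x$significant) " *" else ""))
  invisible(x)
}
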