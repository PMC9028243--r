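test_that("NG86 handles the textbook cases", {
  s <- strrep("ATGAAA", 10)
  r <- ng86_pairwise(s, s)
  expect_identical(r$Nd + r$Sd, 0)
  expect_true(is.na(r$omega))
  # one 4-fold-degenerate third-position change in a longer frame
  r2 <- ng86_pairwise(paste0(strrep("CTG", 5), "GGG"),
                      paste0(strrep("CTG", 5), "GGC"))
  expect_identical(r2$Nd, 0)
  expect_identical(r2$Sd, 1)
  expect_gt(r2$dS, 0)
  expect_identical(r2$dN, 0)
  expect_error(ng86_pairwise("ATGAA", "ATGAAA"), "multiple of 3")
  expect_error(ng86_pairwise("ATGTAA", "ATGAAA"), "stop")
})

test_that("every sense codon splits its three sites into N + S = 3", {
  for (i in seq_len(61)) {
    cnt <- phyloccs:::ng86_site_counts(i)
    expect_equal(unname(cnt["N"] + cnt["S"]), 3, tolerance = 1e-12)
  }
})

test_that("NG86 counts match the pathway-enumeration oracle exactly", {
  set.seed(77)
  for (rep in 1:200) {
    a <- paste(random_sense_codons(6, 1000 + rep), collapse = "")
    b <- paste(random_sense_codons(6, 3000 + rep), collapse = "")
    got <- ng86_pairwise(a, b)
    want <- ng86_oracle(a, b)
    expect_lt(abs(got$S - want$S), 1e-12)
    expect_lt(abs(got$N - want$N), 1e-12)
    expect_lt(abs(got$Sd - want$Sd), 1e-12)
    expect_lt(abs(got$Nd - want$Nd), 1e-12)
  }
})

test_that("the GY94 generator satisfies detailed balance", {
  pi <- as.numeric(f3x4_frequencies(
    simulate_codon_alignment(ape::read.tree(text = "(a:0.2,b:0.2);"),
                             200, seed = 5)$alignment))
  Q <- gy94_matrix(kappa = 3, omega = 0.4, pi = pi)
  lhs <- pi * Q
  expect_lt(max(abs(lhs - t(lhs))), 1e-12)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_equal(sum(pi * -diag(Q)), 1, tolerance = 1e-12)
})

test_that("codon pruning matches enumeration and degenerate limits", {
  # one codon, zero branch lengths: likelihood is the root frequency
  tr0 <- ape::read.tree(text = "(a:0,b:0,c:0);")
  caln <- as_codon_alignment(matrix(match("AAA", phyloccs:::.CODONS), 3, 1,
                                    dimnames = list(c("a", "b", "c"), NULL)))
  pi <- rep(1 / 61, 61)
  m <- codon_model(kappa = 2, frequencies = pi, omega = 0.5)
  expect_equal(codon_log_likelihood(tr0, caln, m), log(1 / 61),
               tolerance = 1e-10)
  # 3-taxon enumeration
  tr <- ape::read.tree(text = "((a:0.2,b:0.15):0.1,c:0.25);")
  s <- simulate_codon_alignment(tr, 4, kappa = 2, omega_default = 0.5,
                                seed = 3)
  got <- codon_log_likelihood(tr, s$alignment, m)
  Q <- gy94_matrix(2, 0.5, pi)
  dna <- matrix(phyloccs:::.CODONS[unclass(s$alignment)],
                nrow = 3, dimnames = list(rownames(s$alignment), NULL))
  want <- enum_loglik(tr, dna, Q, pi, states = phyloccs:::.CODONS)$total
  expect_lt(abs(got - want), 1e-8)
})

test_that("the likelihood is maximal near the generating omega", {
  tr <- make_default_tree("sequence")
  s <- simulate_codon_alignment(tr, 400, kappa = 2, omega_default = 0.3,
                                seed = 17)
  pi <- f3x4_frequencies(s$alignment)
  ll <- sapply(c(0.05, 0.15, 0.3, 0.6, 1.5), function(w)
    codon_log_likelihood(tr, s$alignment,
                         codon_model(2, pi, omega = w)))
  expect_identical(which.max(ll), 3L)
  expect_true(all(diff(ll[1:3]) > 0) && all(diff(ll[3:5]) < 0))
})

test_that("branch-site LRT respects nesting and flags planted selection", {
  tr <- make_default_tree("sequence")
  sc <- data.frame(weight = c(0.9, 0.1), omega_bg = 0.2,
                   omega_fg = c(0.2, 4))
  s <- simulate_codon_alignment(tr, 300, kappa = 2, site_classes = sc,
                                seed = 23)
  bs <- branch_site_lrt(tr, s$alignment)
  expect_gte(bs$lnL_alt, bs$lnL_null - 1e-6)
  expect_gte(bs$lrt, 0)
  expect_true(bs$p_value >= 0 && bs$p_value <= 1)
  expect_lt(bs$p_value, 0.05)
  expect_gte(bs$omega2, 1)
  expect_error(branch_site_lrt(tr, s$alignment, foreground = "nosuch"),
               "foreground")
})

test_that("two-ratio fit recovers the sign and magnitude of omega shifts", {
  tr <- make_default_tree("sequence")
  fg <- foreground_tips(tr)
  s <- simulate_codon_alignment(tr, 500, kappa = 2,
                                omega_map = setNames(rep(0.8, 3), fg),
                                omega_default = 0.2, seed = 29)
  r <- group_omega_difference(tr, s$alignment)
  expect_identical(r$difference > 0, r$omega_tg > r$omega_bg)
  expect_gt(r$difference, 0)
  expect_lt(r$p_value, 0.01)
  expect_gte(r$lnL_alt, r$lnL_null - 1e-6)
  expect_error(group_omega_difference(tr, s$alignment,
                                      foreground = fg, background = fg),
               "overlap")
})

test_that("kappa and omega are recovered on a long two-taxon alignment", {
  tr2 <- ape::read.tree(text = "(a:0.3,b:0.3);")
  s <- simulate_codon_alignment(tr2, 1000, kappa = 3, omega_default = 0.4,
                                seed = 31)
  pi <- f3x4_frequencies(s$alignment)
  ctx_fit <- function(par)
    codon_log_likelihood(tr2, s$alignment,
                         codon_model(exp(par[1]), pi, omega = exp(par[2])))
  o <- stats::optim(c(log(2), log(1)), function(p) -ctx_fit(p),
                    method = "L-BFGS-B", lower = log(c(0.2, 0.01)),
                    upper = log(c(15, 5)))
  expect_lt(abs(exp(o$par[1]) - 3) / 3, 0.25)
  expect_lt(abs(exp(o$par[2]) - 0.4) / 0.4, 0.25)
})
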