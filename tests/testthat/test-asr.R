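test_that("degenerate chains reduce to stationary frequencies", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  m <- jtt_model(1, n_categories = 1)
  aln <- matrix("A", 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(protein_loglik(tr, aln, m), log(unname(m$pi["A"])),
               tolerance = 1e-10)
})

test_that("pruning log-likelihood matches exhaustive enumeration", {
  m <- jtt_model(0.7, n_categories = 2)
  for (seed in 1:3) {
    tr <- random_small_tree(3, seed)
    s <- simulate_protein_alignment(tr, 5, alpha = 0.7, seed = seed + 10)
    got <- protein_loglik(tr, s$alignment, m)
    want <- enum_loglik(tr, s$alignment, m$Q, m$pi, m$rates)$total
    expect_lt(abs(got - want), 1e-10)
  }
  # invariance to the order of alignment rows
  tr <- random_small_tree(4, 9)
  s <- simulate_protein_alignment(tr, 20, alpha = 1, seed = 2)
  perm <- s$alignment[rev(rownames(s$alignment)), ]
  expect_equal(protein_loglik(tr, s$alignment, m),
               protein_loglik(tr, perm, m), tolerance = 1e-12)
})

test_that("branch-length and shape fitting behaves at the boundaries", {
  tr <- make_default_tree("sequence")
  aln <- matrix(rep(sample(phyloccs:::.AA, 60, replace = TRUE), each = 7),
                nrow = 7, dimnames = list(tr$tip.label, NULL))
  fit <- fit_protein_model(tr, aln, alpha = 1)
  expect_true(all(fit$tree$edge.length < 1e-6))
  expect_true(all(diff(fit$trace) > -1e-9))   # monotone improvement
})

test_that("two-taxon ML distance agrees with a 1-D grid-and-refine oracle", {
  tr2 <- ape::read.tree(text = "(a:0.1,b:0.1);")
  s <- simulate_protein_alignment(tr2, 800, alpha = 1, seed = 21)
  m <- jtt_model(1, n_categories = 1)
  fit <- fit_protein_model(tr2, s$alignment, n_categories = 1, alpha = 1,
                           tol = 1e-8)
  # independent 1-D optimisation of the total path length
  f <- function(d) {
    t2 <- tr2; t2$edge.length <- c(d / 2, d / 2)
    protein_loglik(t2, s$alignment, m)
  }
  grid <- seq(0.01, 1, by = 0.01)
  g0 <- grid[which.max(sapply(grid, f))]
  opt <- stats::optimize(f, c(max(1e-6, g0 - 0.02), g0 + 0.02),
                         maximum = TRUE, tol = 1e-9)
  expect_lt(abs(sum(fit$tree$edge.length) - opt$maximum), 1e-4)
})

test_that("marginal posteriors match Bayes-rule enumeration", {
  m <- jtt_model(0.9, n_categories = 2)
  for (seed in 4:5) {
    tr <- random_small_tree(3, seed)
    s <- simulate_protein_alignment(tr, 4, alpha = 0.9, seed = seed)
    rec <- marginal_ancestral_states(tr, s$alignment, m)
    want <- enum_asr_posterior(tr, s$alignment, m$Q, m$pi, m$rates)
    expect_lt(max(abs(rec$posterior - want)), 1e-10)
    sums <- apply(rec$posterior, c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-9)
    expect_equal(rec$map_prob, apply(rec$posterior, c(1, 2), max))
  }
})

test_that("near-constant columns reconstruct with high confidence", {
  tr <- make_default_tree("sequence", branch_length = 0.01)
  aln <- matrix("R", 7, 3, dimnames = list(tr$tip.label, NULL))
  rec <- marginal_ancestral_states(tr, aln, jtt_model(1))
  expect_true(all(rec$map == "R"))
  expect_true(all(rec$map_prob > 0.99))
  expect_true(all(rec$consistent))
})

test_that("reconstruction beats a frequency-only guesser on the root", {
  tr <- make_default_tree("sequence", branch_length = 0.1)
  s <- simulate_protein_alignment(tr, 500, alpha = 0.7, seed = 31)
  fit <- fit_protein_model(tr, s$alignment, alpha = 0.7)
  rec <- marginal_ancestral_states(fit$tree, s$alignment, fit$model)
  acc <- mean(rec$map["root", ] == s$ancestral["root", ])
  base <- mean(s$ancestral["root", ] == "L")   # most frequent JTT residue
  expect_gt(acc, base + 0.2)
})

test_that("likelihood agrees with an independent JTT+gamma implementation", {
  tr <- make_default_tree("sequence")
  s <- simulate_protein_alignment(tr, 100, alpha = 0.7, seed = 5)
  ours <- protein_loglik(tr, s$alignment, jtt_model(0.7, 4))
  fit <- phangorn::pml(tr, phangorn::phyDat(s$alignment, type = "AA"),
                       model = "JTT", k = 4, shape = 0.7)
  expect_lt(abs(ours - fit$logLik), 1e-6)
})

test_that("gap columns are stripped and coordinates preserved", {
  aln <- matrix(c("A", "A", "-", "R", "R", "R", "X", "K", "K"), nrow = 3)
  rownames(aln) <- c("a", "b", "c")
  st <- strip_gap_columns(aln)
  expect_identical(st$kept, 2L)
  expect_identical(ncol(st$alignment), 1L)
  expect_error(protein_loglik(ape::read.tree(text = "(a:1,b:1,c:1);"),
                              aln, jtt_model(1)), "strip")
})
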