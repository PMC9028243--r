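test_that("default tree encodes the seven-species study design", {
  tt <- make_default_tree("time")
  depths <- ape::node.depth.edgelength(tt)[seq_along(tt$tip.label)]
  expect_lt(diff(range(depths)), 1e-9)
  expect_equal(max(depths), 111)
  ts <- make_default_tree("sequence")
  expect_length(foreground_tips(ts), 3L)
  expect_setequal(foreground_tips(ts), c("kiwi", "mallard", "ibis"))
  expect_identical(outgroup_tip(ts), "ostrich")
  expect_false(outgroup_tip(ts) %in% foreground_tips(ts))
  expect_error(make_default_tree("banana"))
  # configurable scales
  expect_equal(max(ape::node.depth.edgelength(
    make_default_tree("time", depth = 50))), 50)
})

test_that("protein simulator is seed-reproducible and respects the chain", {
  tr <- make_default_tree("sequence")
  a <- simulate_protein_alignment(tr, 50, alpha = 0.7, seed = 7)
  b <- simulate_protein_alignment(tr, 50, alpha = 0.7, seed = 7)
  expect_identical(a$alignment, b$alignment)
  expect_identical(a$ancestral, b$ancestral)
  # zero branch lengths freeze the chain at the root sequence
  tr0 <- make_default_tree("sequence", branch_length = 0)
  z <- simulate_protein_alignment(tr0, 40, alpha = 1, seed = 3)
  for (i in seq_len(nrow(z$alignment)))
    expect_identical(unname(z$alignment[i, ]), unname(z$ancestral["root", ]))
  expect_error(simulate_protein_alignment(tr, 10, alpha = -1), "alpha")
})

test_that("long simulations reach JTT stationary frequencies", {
  tr <- make_default_tree("sequence")
  s <- simulate_protein_alignment(tr, 10000, alpha = 1, seed = 11)
  pi <- jtt_model(1)$pi
  # sites are independent within a row, so each row is a multinomial
  # sample from the stationary law (tips are correlated across rows)
  for (row in list(s$ancestral["root", ], s$alignment["chicken", ])) {
    obs <- table(factor(row, levels = names(pi)))
    n <- sum(obs)
    for (a in names(pi)) {
      se <- sqrt(pi[a] * (1 - pi[a]) / n)
      expect_lt(abs(obs[a] / n - pi[a]), 3 * se + 1e-12)
    }
  }
})

test_that("discrete gamma categories average to rate one", {
  for (alpha in c(0.2, 0.7, 2, 10)) {
    r <- discrete_gamma_rates(alpha, 4)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    expect_true(all(diff(r) > 0))
  }
  expect_error(discrete_gamma_rates(0), "positive")
})

test_that("convergent-site injection satisfies the CCS layout", {
  tr <- make_default_tree("sequence", branch_length = 0.05)
  s <- simulate_protein_alignment(tr, 400, alpha = 0.7, seed = 5)
  s0 <- inject_convergent_sites(s, 0, seed = 1)
  expect_identical(s0$alignment, s$alignment)
  expect_identical(nrow(s0$truth), 0L)
  si <- inject_convergent_sites(s, 5, seed = 2)
  expect_identical(nrow(si$truth), 5L)
  expect_false(anyDuplicated(si$truth$site) > 0)
  fg <- foreground_tips(tr)
  bg <- setdiff(rownames(si$alignment), fg)
  for (r in seq_len(nrow(si$truth))) {
    st <- si$truth[r, ]
    # foreground share one residue, background+ancestors share another
    expect_true(all(si$alignment[fg, st$site] == st$fg_residue))
    expect_true(all(si$alignment[bg, st$site] == st$bg_residue))
    expect_true(all(si$ancestral[, st$site] == st$bg_residue))
    expect_false(st$fg_residue == st$bg_residue)
  }
  expect_error(inject_convergent_sites(s, 1e6, seed = 1), "eligible")
})

test_that("codon simulator honours omega and the sense-codon space", {
  tr3 <- ape::read.tree(text = "((a:0.3,b:0.3):0.1,c:0.4);")
  # omega = 0 forbids nonsynonymous differences between tips
  s <- simulate_codon_alignment(tr3, 150, kappa = 2, omega_default = 0,
                                seed = 4)
  aa <- phyloccs:::.CODON_AA
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c")))
    expect_identical(aa[unclass(s$alignment)[pair[1], ]],
                     aa[unclass(s$alignment)[pair[2], ]])
  expect_true(all(unclass(s$alignment) %in% seq_len(61)))
  dna <- codon_to_dna_matrix(s$alignment)
  cods <- apply(dna, 1, function(x)
    paste0(x[c(TRUE, FALSE, FALSE)], x[c(FALSE, TRUE, FALSE)],
           x[c(FALSE, FALSE, TRUE)]))
  expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
  expect_error(simulate_codon_alignment(tr3, 10, omega_map = c(zz = 1)),
               "absent")
})

test_that("neutral codon simulation gives NG86 omega near one", {
  tr2 <- ape::read.tree(text = "(a:0.4,b:0.4);")
  s <- simulate_codon_alignment(tr2, 1500, kappa = 2, omega_default = 1,
                                seed = 8)
  r <- ng86_pairwise(unclass(s$alignment)["a", ], unclass(s$alignment)["b", ])
  expect_gt(r$omega, 0.8)
  expect_lt(r$omega, 1.25)
})

test_that("family counts follow the equal-rate birth-death chain", {
  tt <- make_default_tree("time")
  frozen <- simulate_family_counts(tt, 0, 20, root_size_range = c(3L, 9L),
                                   seed = 2)
  expect_true(all(frozen$counts == frozen$ancestral[, "root"]))
  # martingale: mean tip count stays near the mean root size
  sim <- simulate_family_counts(tt, 0.002, 500, root_size_range = c(5L, 15L),
                                seed = 3)
  mu <- mean(sim$ancestral[, "root"])
  x <- as.vector(sim$counts)
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mu), 3 * se)
  # planted jump bookkeeping at lambda = 0
  pj <- simulate_family_counts(tt, 0, 3, root_size_range = c(5L, 5L),
                               seed = 4, planted_events = list(kiwi = 5L))
  expect_true(all(pj$counts[, "kiwi"] - pj$ancestral[, "kiwi_tinamou"] == 5L))
  expect_error(simulate_family_counts(tt, 0.1, 5,
                                      root_size_range = c(3L, 1L)),
               "interval")
  expect_error(simulate_family_counts(tt, -1, 5), ">= 0")
})

test_that("similarity graph is faithful to planted families and the seed", {
  sp <- make_default_tree("sequence")$tip.label
  genes <- do.call(rbind, lapply(1:5, function(f)
    data.frame(gene = paste0(sp, "|g", f), species = sp,
               family = paste0("fam", f))))
  e0 <- simulate_similarity_graph(genes, between_noise_rate = 0, seed = 6)
  g <- igraph::graph_from_data_frame(e0[, c("qseqid", "sseqid")],
                                     directed = FALSE)
  comp <- igraph::components(g)$membership
  expect_identical(length(unique(comp)), 5L)
  expect_true(all(e0$evalue < 1e-5))
  e1 <- simulate_similarity_graph(genes, between_noise_rate = 0.05, seed = 6)
  noise <- e1[e1$evalue > 1e-5, ]
  expect_gt(nrow(noise), 0)
  gf <- setNames(genes$family, genes$gene)
  expect_true(all(gf[noise$qseqid] != gf[noise$sseqid]))
  # byte-identical TSV for one seed
  f1 <- tempfile(); f2 <- tempfile()
  phyloccs:::write_tsv(simulate_similarity_graph(genes, seed = 9), f1)
  phyloccs:::write_tsv(simulate_similarity_graph(genes, seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))
})
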