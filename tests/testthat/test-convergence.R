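# One reconstructed gene reused across tests in this file.
local_gene <- local({
  tr <- make_default_tree("sequence", branch_length = 0.05)
  s <- simulate_protein_alignment(tr, 600, alpha = 0.7, seed = 101)
  s <- inject_convergent_sites(s, 6, seed = 102)
  fit <- fit_protein_model(tr, s$alignment, alpha = 0.7)
  rec <- marginal_ancestral_states(fit$tree, s$alignment, fit$model)
  list(tree = tr, sim = s, rec = rec)
})

test_that("the three CCS criteria drive convergent-site calls", {
  g <- local_gene
  calls <- detect_convergent_sites(g$sim$alignment, g$rec, g$tree)
  # planted columns dominate the call set
  expect_gte(sum(g$sim$truth$site %in% calls$site), 5)
  planted <- calls[calls$site %in% g$sim$truth$site, ]
  tr_truth <- g$sim$truth[match(planted$site, g$sim$truth$site), ]
  expect_identical(planted$fg_residue, tr_truth$fg_residue)
  expect_identical(planted$bg_residue, tr_truth$bg_residue)
  expect_true(all(planted$fg_residue != planted$bg_residue))
  # an invariant column is never called (criterion 3)
  aln2 <- g$sim$alignment
  inv <- which(apply(aln2, 2, function(x) all(x == x[1])))[1]
  expect_false(inv %in% calls$site)
  # breaking criterion 2 on one background tip removes the call
  s1 <- g$sim$truth$site[1]
  aln2["chicken", s1] <- g$sim$truth$fg_residue[1]
  calls2 <- detect_convergent_sites(aln2, g$rec, g$tree)
  expect_false(s1 %in% calls2$site)
  expect_error(detect_convergent_sites(g$sim$alignment, g$rec, g$tree,
                                       foreground = c("kiwi", "mallard"),
                                       background = c("kiwi", "egret")),
               "overlap")
})

test_that("calls are monotone in the posterior floor and stable under
           background permutation", {
  g <- local_gene
  loose <- detect_convergent_sites(g$sim$alignment, g$rec, g$tree,
                                   min_anc_posterior = 0.5)
  strict <- detect_convergent_sites(g$sim$alignment, g$rec, g$tree,
                                    min_anc_posterior = 0.95)
  expect_true(all(strict$site %in% loose$site))
  a <- detect_convergent_sites(g$sim$alignment, g$rec, g$tree,
                               background = c("egret", "chicken", "tinamou"))
  b <- detect_convergent_sites(g$sim$alignment, g$rec, g$tree,
                               background = c("tinamou", "egret", "chicken"))
  expect_identical(a, b)
  # parents-only ancestor mode can only add calls relative to all-nodes
  allm <- detect_convergent_sites(g$sim$alignment, g$rec, g$tree,
                                  ancestor_mode = "all")
  par <- detect_convergent_sites(g$sim$alignment, g$rec, g$tree,
                                 ancestor_mode = "parents")
  expect_true(all(allm$site %in% par$site))
})

test_that("random-trio control compares gene and site levels", {
  g <- local_gene
  genes <- list(geneA = list(alignment = g$sim$alignment,
                             reconstruction = g$rec))
  # trio = the true foreground reproduces the TG run exactly
  tg <- random_trio_control(genes, g$tree,
                            trio = c("kiwi", "mallard", "ibis"))
  expect_identical(tg$tg_genes, tg$trio_genes)
  expect_identical(tg$overlap_genes, tg$tg_genes)
  expect_true(all(tg$site_overlap$n_shared_sites ==
                    tg$site_overlap$n_tg_sites))
  # the study's preset control trio is accepted
  ctrl <- random_trio_control(genes, g$tree,
                              trio = c("ibis", "chicken", "tinamou"))
  expect_setequal(ctrl$trio, c("ibis", "chicken", "tinamou"))
  expect_error(random_trio_control(genes, g$tree,
                                   trio = c("ostrich", "kiwi", "egret")),
               "outgroup")
})

test_that("gene-level summaries sort and coordinate correctly", {
  empty <- summarize_convergent_genes(list(g1 = data.frame(site = integer())))
  expect_identical(nrow(empty), 0L)
  calls <- list(
    g1 = data.frame(site = c(40L, 7L, 12L)),
    g2 = data.frame(site = 3L),
    g3 = data.frame(site = integer()))
  out <- summarize_convergent_genes(calls)
  expect_identical(out$gene, c("g1", "g2"))
  expect_identical(out$n_sites, c(3L, 1L))
  expect_identical(out$sites[1], "7,12,40")
})
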