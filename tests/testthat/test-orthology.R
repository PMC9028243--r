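test_that("proteome filtering applies the three removal rules", {
  rec <- data.frame(
    gene = c("g1", "g1", "g2", "g3", "g4"),
    transcript = c("t1", "t2", "t1", "t1", "t1"),
    sequence = c(strrep("A", 100), strrep("A", 150),
                 strrep("M", 29),                     # too short
                 paste0(strrep("M", 5), "*", strrep("A", 40)), # internal stop
                 paste0(strrep("W", 60), "*")))       # trailing stop ok
  p <- filter_proteome(rec, species = "sp")
  st <- setNames(p$records$status, paste(p$records$gene, p$records$transcript))
  expect_identical(st[["g1 t2"]], "kept")        # longest transcript
  expect_identical(st[["g1 t1"]], "not_longest")
  expect_identical(st[["g2 t1"]], "too_short")
  expect_identical(st[["g3 t1"]], "internal_stop")
  expect_identical(st[["g4 t1"]], "kept")
  kept <- p$records[p$records$status == "kept", ]
  expect_false(anyDuplicated(kept$gene) > 0)
  expect_true(all(nchar(kept$sequence) >= 30))
  expect_false(any(grepl("\\*", kept$sequence)))
  expect_error(filter_proteome(rec[c(1, 1), ]), "duplicate")
})

make_edges <- function(pairs, evalue = 1e-50) {
  do.call(rbind, lapply(pairs, function(p)
    data.frame(qseqid = p[1], sseqid = p[2], pident = 90, length = 100,
               mismatch = 1, gapopen = 0, qstart = 1, qend = 100,
               sstart = 1, send = 100, evalue = evalue, bitscore = 200)))
}

test_that("MCL separates disjoint cliques and reports isolated genes", {
  cl1 <- c("s1|a", "s2|b", "s3|c")
  cl2 <- c("s1|d", "s2|e", "s3|f")
  pairs <- c(combn(cl1, 2, simplify = FALSE), combn(cl2, 2, simplify = FALSE))
  cat <- mcl_cluster(make_edges(pairs), genes = c(cl1, cl2, "s1|lonely"))
  expect_identical(nrow(cat$counts), 2L)
  sizes <- table(cat$families$family)
  expect_true(all(sizes == 3))
  expect_identical(cat$unclustered, "s1|lonely")
  # an edge above the cutoff does not rescue an isolated gene
  weak <- rbind(make_edges(pairs), make_edges(list(c("s1|a", "s1|w")), 1e-3))
  cat2 <- mcl_cluster(weak, genes = c(cl1, cl2, "s1|w"))
  expect_true("s1|w" %in% cat2$unclustered)
})

test_that("MCL recovers a planted partition and ignores weight scale", {
  sp <- make_default_tree("sequence")$tip.label
  genes <- do.call(rbind, lapply(1:5, function(f)
    data.frame(gene = paste0(sp, "|g", f), species = sp,
               family = paste0("fam", f))))
  edges <- simulate_similarity_graph(genes, between_noise_rate = 0.01,
                                     seed = 13)
  norm_part <- function(cat)
    sort(vapply(split(cat$families$gene, cat$families$family),
                function(x) paste(sort(x), collapse = ","), ""))
  planted <- sort(vapply(split(genes$gene, genes$family),
                         function(x) paste(sort(x), collapse = ","), ""))
  cat1 <- mcl_cluster(edges, genes = genes$gene)
  expect_identical(unname(norm_part(cat1)), unname(planted))
  # uniform scaling of weights (bitscore mode) leaves the partition alone
  cat_b <- mcl_cluster(edges, weight = "bitscore", genes = genes$gene)
  edges2 <- edges; edges2$bitscore <- edges2$bitscore * 37
  cat_b2 <- mcl_cluster(edges2, weight = "bitscore", genes = genes$gene)
  expect_identical(norm_part(cat_b), norm_part(cat_b2))
})

test_that("family classification partitions each species' genes", {
  sp <- make_default_tree("sequence")$tip.label
  layout <- phyloccs:::planted_family_layout(sp, 6L)
  edges <- simulate_similarity_graph(layout$genes, between_noise_rate = 0,
                                     seed = 3)
  cat <- mcl_cluster(edges, genes = c(layout$genes$gene, layout$unclustered))
  tal <- classify_families(cat)
  expect_true(all(tal$single_copy + tal$multiple_copy + tal$unique +
                    tal$other + tal$unclustered == tal$total))
  # the 1:1 families are single-copy for every species
  expect_true(all(tal$single_copy >= 6))
  # mallard holds a planted 4-gene unique family
  expect_identical(tal$unique[tal$species == "mallard"], 4L)
  # the duplicated-copy families count as multiple-copy where count >= 2
  expect_identical(tal$multiple_copy[tal$species == "ostrich"], 2L)
  sc <- extract_single_copy(cat)
  expect_identical(length(sc), 6L)
  expect_true(all(rowSums(cat$counts[sc, , drop = FALSE] == 1L) == 7))
})

test_that("single-copy extraction keeps exactly the 1:1 families", {
  counts <- rbind(F1 = rep(1L, 7), F2 = c(2L, rep(1L, 6)),
                  F3 = c(0L, rep(1L, 6)))
  colnames(counts) <- make_default_tree("sequence")$tip.label
  cat <- structure(list(counts = counts), class = "family_catalogue")
  expect_identical(extract_single_copy(cat), "F1")
})
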