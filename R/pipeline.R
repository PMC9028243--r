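#' Configuration for a full synthetic pipeline run
#'
#' Bundles the study design (seven species, three tactile-foraging
#' foreground lineages, ostrich outgroup), the planted-signal layout of
#' the synthetic data, and the decision thresholds used by every stage.
#'
#' @param seed Master RNG seed; every stage derives its own seed from it.
#' @param out_dir Output directory (created if needed).
#' @param n_single_copy_families 1:1 families planted in the similarity
#'   graph (the first `n_analysis_genes` are carried into the
#'   sequence-level analyses).
#' @param n_analysis_genes Single-copy families given protein and codon
#'   alignments.
#' @param aa_length,alpha Protein alignment length and gamma shape.
#' @param branch_length Sequence-tree branch length (substitutions/site).
#' @param convergent_genes Indices of analysis genes receiving planted
#'   convergent sites; `sites_per_gene` sites each.
#' @param sites_per_gene Convergent columns injected per planted gene.
#' @param codon_length,codon_branch_length,kappa,omega_bg Codon
#'   alignment length, codon-tree branch length (substitutions/codon)
#'   and GY94 parameters.
#' @param positive_genes Indices of genes simulated with a branch-site
#'   positive fraction (`positive_fraction` of sites at `omega2` on the
#'   foreground branches).
#' @param shift_genes Indices of genes simulated with foreground omega
#'   raised to `omega_fg` on all sites.
#' @param omega2,positive_fraction,omega_fg Planted selection effect
#'   sizes.
#' @param n_count_families,family_lambda,tree_depth,root_size_range
#'   Gene-family count simulation: family number, birth-death rate per
#'   gene per time unit, time-tree depth, and root-size interval.
#' @param planted_family_events Data frame (`family`, `branch`, `jump`)
#'   of deterministic size jumps planted on pendant branches.
#' @param n_montecarlo Simulated families behind each family-wide
#'   p-value.
#' @param trio Control trio for the convergence false-positive check.
#' @param thresholds Named list: `lrt_p`, `omega_diff_p`, `family_p`,
#'   `viterbi_p`, `enrich_q`.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(
    seed = 1L, out_dir = file.path(tempdir(), "phyloccs_run"),
    n_single_copy_families = 12L, n_analysis_genes = 6L,
    aa_length = 300L, alpha = 0.7, branch_length = 0.05,
    convergent_genes = 1:3, sites_per_gene = 4L,
    codon_length = 300L, codon_branch_length = 0.1, kappa = 2,
    omega_bg = 0.2,
    positive_genes = 1:3, shift_genes = 2:4,
    omega2 = 4, positive_fraction = 0.1, omega_fg = 0.8,
    n_count_families = 40L, family_lambda = 0.002, tree_depth = 111,
    root_size_range = c(5L, 15L),
    planted_family_events = data.frame(
      family = 1:3, branch = c("mallard", "kiwi", "ibis"),
      jump = c(8L, 8L, -8L)),
    n_montecarlo = 500L,
    trio = c("ibis", "chicken", "tinamou"),
    thresholds = list(lrt_p = 0.05, omega_diff_p = 0.01, family_p = 0.05,
                      viterbi_p = 0.05, enrich_q = 0.05)) {
  stopifnot(all(unlist(thresholds) > 0), all(unlist(thresholds) < 1))
  cfg <- as.list(environment())
  tree <- make_default_tree("sequence")
  if (outgroup_tip(tree) %in% trio)
    stop("trio must not contain the outgroup")
  stopifnot(n_analysis_genes <= n_single_copy_families,
            max(convergent_genes) <= n_analysis_genes,
            max(positive_genes) <= n_analysis_genes,
            max(shift_genes) <= n_analysis_genes)
  structure(cfg, class = "run_config")
}

# Synthetic proteome records for one species: clean genes for every
# planted gene id, plus records exercising each filter rule.
synth_proteome <- function(species, gene_ids, seed) {
  set.seed(seed)
  rand_aa <- function(n) paste(sample(.AA, n, replace = TRUE,
                                      prob = .JTT_FREQ), collapse = "")
  rec <- data.frame(gene = gene_ids, transcript = "t1",
                    sequence = vapply(sample(60:200, length(gene_ids),
                                             replace = TRUE),
                                      rand_aa, ""))
  # a second, shorter transcript for the first two genes
  extra <- data.frame(gene = gene_ids[1:2], transcript = "t2",
                      sequence = vapply(c(40L, 45L), rand_aa, ""))
  junk <- data.frame(
    gene = paste0(species, "|junk1"),
    transcript = "t1", sequence = rand_aa(12))        # too short
  stopper <- data.frame(
    gene = paste0(species, "|junk2"), transcript = "t1",
    sequence = paste0(rand_aa(30), "*", rand_aa(30))) # internal stop
  filter_proteome(rbind(rec, extra, junk, stopper), species = species)
}

# Planted family layout over the seven species. Returns
# data.frame(gene, species, family) plus unclustered gene ids.
planted_family_layout <- function(species, n_single) {
  gid <- function(sp, tag) paste0(sp, "|", tag)
  rows <- list()
  for (i in seq_len(n_single))
    rows[[length(rows) + 1L]] <-
      data.frame(gene = gid(species, sprintf("sc%02d", i)),
                 species = species,
                 family = sprintf("SC%02d", i))
  for (i in 1:3) {
    dup <- species[i]
    g <- c(gid(species, sprintf("mc%d", i)), gid(dup, sprintf("mc%db", i)))
    rows[[length(rows) + 1L]] <-
      data.frame(gene = g, species = c(species, dup),
                 family = sprintf("MC%d", i))
  }
  uniq_sp <- c("kiwi", "mallard", "chicken")
  for (i in 1:3) {
    g <- gid(rep(uniq_sp[i], 4), sprintf("uq%d_%d", i, 1:4))
    rows[[length(rows) + 1L]] <-
      data.frame(gene = g, species = uniq_sp[i],
                 family = sprintf("UQ%d", i))
  }
  genes <- do.call(rbind, rows)
  unclustered <- gid(c("kiwi", "egret", "ostrich"), "orphan")
  list(genes = genes, unclustered = unclustered)
}

#' Run the full synthetic comparative-genomics pipeline
#'
#' Executes filter, similarity-graph simulation, Markov clustering and
#' family classification, single-copy extraction, per-gene ancestral
#' reconstruction and convergence calling with the random-trio control,
#' branch-site and two-ratio selection tests, birth-death gene-family
#' evolution, and enrichment of the expanded families, writing every
#' stage's table plus a run manifest to `config$out_dir`. Re-running
#' with the same configuration reproduces all outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (invisibly a list), also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "phyloccs",
                   version = as.character(utils::packageVersion("phyloccs")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "out_dir")],
                   stages = list())
  persist <- function() jsonlite::write_json(
    manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      persist()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seed <- config$seed
  tree_seq <- make_default_tree("sequence",
                                branch_length = config$branch_length)
  tree_codon <- make_default_tree("sequence",
                                  branch_length = config$codon_branch_length)
  tree_time <- make_default_tree("time", depth = config$tree_depth)
  species <- tree_seq$tip.label
  fg <- foreground_tips(tree_seq)

  ## 1. proteome filtering -------------------------------------------------
  layout <- planted_family_layout(species, config$n_single_copy_families)
  proteomes <- stage("filter", lapply(seq_along(species), function(i) {
    sp <- species[i]
    ids <- c(layout$genes$gene[layout$genes$species == sp],
             layout$unclustered[startsWith(layout$unclustered,
                                           paste0(sp, "|"))])
    synth_proteome(sp, ids, seed + 500L + i)
  }))
  filt <- do.call(rbind, lapply(proteomes, function(p)
    cbind(species = p$species,
          as.data.frame(as.list(table(factor(p$records$status,
            levels = c("kept", "too_short", "internal_stop",
                       "not_longest")))))))
  )
  write_tsv(filt, file.path(config$out_dir, "filter_summary.tsv"))
  kept <- unlist(lapply(proteomes,
                        function(p) p$records$gene[p$records$status == "kept"]))
  manifest$stages$filter <- list(records_in = sum(filt[, -1]),
                                 kept = length(kept))

  ## 2. similarity graph + clustering --------------------------------------
  edges <- stage("similarity",
                 simulate_similarity_graph(layout$genes,
                                           between_noise_rate = 0.01,
                                           seed = seed + 1L))
  write_tsv(edges, file.path(config$out_dir, "edges.tsv"))
  catalogue <- stage("cluster",
                     mcl_cluster(edges, genes = kept))
  write_tsv(catalogue$families, file.path(config$out_dir, "families.tsv"))
  tallies <- classify_families(catalogue)
  write_tsv(tallies, file.path(config$out_dir, "category_tallies.tsv"))
  single_copy <- extract_single_copy(catalogue)
  manifest$stages$cluster <- list(n_edges = nrow(edges),
                                  n_families = nrow(catalogue$counts),
                                  n_unclustered = length(catalogue$unclustered),
                                  n_single_copy = length(single_copy))

  ## 3. convergence on single-copy genes ------------------------------------
  genes <- paste0("gene", sprintf("%02d", seq_len(config$n_analysis_genes)))
  conv <- stage("convergence", {
    sims <- lapply(seq_along(genes), function(i) {
      s <- simulate_protein_alignment(tree_seq, config$aa_length,
                                      alpha = config$alpha,
                                      seed = seed + 10L + i)
      if (i %in% config$convergent_genes)
        s <- inject_convergent_sites(s, config$sites_per_gene,
                                     seed = seed + 40L + i)
      s
    })
    recons <- lapply(sims, function(s) {
      fit <- fit_protein_model(tree_seq, s$alignment, alpha = NULL)
      marginal_ancestral_states(fit$tree, s$alignment, fit$model)
    })
    gene_objs <- stats::setNames(lapply(seq_along(genes), function(i)
      list(alignment = sims[[i]]$alignment,
           reconstruction = recons[[i]])), genes)
    calls <- lapply(gene_objs, function(g)
      detect_convergent_sites(g$alignment, g$reconstruction, tree_seq))
    trio <- random_trio_control(gene_objs, tree_seq, trio = config$trio)
    list(sims = sims, calls = calls, trio = trio)
  })
  call_tab <- do.call(rbind, c(list(
    data.frame(gene = character(), site = integer(),
               fg_residue = character(), bg_residue = character(),
               min_anc_posterior = numeric())),
    lapply(genes, function(g)
      if (nrow(conv$calls[[g]])) cbind(gene = g, conv$calls[[g]]))))
  write_tsv(call_tab, file.path(config$out_dir, "convergence_calls.tsv"))
  conv_genes <- summarize_convergent_genes(conv$calls)
  write_tsv(conv_genes, file.path(config$out_dir, "convergent_genes.tsv"))
  write_tsv(conv$trio$site_overlap,
            file.path(config$out_dir, "trio_comparison.tsv"))
  truth_sites <- lapply(conv$sims, function(s)
    if (is.null(s$truth)) integer() else s$truth$site)
  manifest$stages$convergence <- list(
    n_genes = length(genes), n_calls = nrow(call_tab),
    genes_called = conv_genes$gene,
    genes_planted = genes[config$convergent_genes],
    trio_genes_called = conv$trio$trio_genes)

  ## 4. codon selection ------------------------------------------------------
  sel <- stage("selection", lapply(seq_along(genes), function(i) {
    w_fg <- if (i %in% config$shift_genes) config$omega_fg else
      config$omega_bg
    p2 <- if (i %in% config$positive_genes) config$positive_fraction else 0
    sc <- data.frame(weight = c(1 - p2, p2),
                     omega_bg = config$omega_bg,
                     omega_fg = c(w_fg, config$omega2))
    sc <- sc[sc$weight > 0, ]
    sim <- simulate_codon_alignment(tree_codon, config$codon_length,
                                    kappa = config$kappa,
                                    site_classes = sc, foreground = fg,
                                    seed = seed + 60L + i)
    caln <- sim$alignment
    bs <- branch_site_lrt(tree_codon, caln, foreground = fg,
                          p_threshold = config$thresholds$lrt_p)
    tr <- group_omega_difference(tree_codon, caln, foreground = fg,
                                 p_threshold = config$thresholds$omega_diff_p)
    data.frame(gene = genes[i], lnL_null_bs = bs$lnL_null,
               lnL_alt_bs = bs$lnL_alt, lrt_bs = bs$lrt,
               p_bs = bs$p_value, positively_selected = bs$significant,
               omega_tg = tr$omega_tg, omega_bg = tr$omega_bg,
               omega_difference = tr$difference, p_diff = tr$p_value,
               diff_significant = tr$significant)
  }))
  sel <- do.call(rbind, sel)
  write_tsv(sel, file.path(config$out_dir, "selection.tsv"))
  manifest$stages$selection <- list(
    n_genes = nrow(sel),
    positively_selected = sel$gene[sel$positively_selected],
    omega_diff_significant = sel$gene[sel$diff_significant])

  ## 5. gene-family evolution ------------------------------------------------
  fam <- stage("genefam", {
    sim <- simulate_family_counts(tree_time, config$family_lambda,
                                  config$n_count_families,
                                  root_size_range = config$root_size_range,
                                  seed = seed + 7L)
    counts <- sim$counts
    pe <- config$planted_family_events
    et <- phyloccs:::edge_table(tree_time)
    labs <- phyloccs:::node_labels(tree_time)
    for (r in seq_len(nrow(pe))) {   # deterministic jump from the parent
      par_lab <- labs[et$parent[et$name == pe$branch[r]]]
      counts[pe$family[r], pe$branch[r]] <-
        max(0L, sim$ancestral[pe$family[r], par_lab] + pe$jump[r])
    }
    model <- fit_lambda(tree_time, counts)
    pv_all <- family_pvalues(model, counts, config$n_montecarlo,
                             seed = seed + 8L)
    res <- lapply(seq_len(nrow(counts)), function(f) {
      pv <- pv_all[f]
      vb <- branch_viterbi_pvalues(counts[f, ], model,
                                   p_threshold = config$thresholds$viterbi_p)
      vb$call[pv >= config$thresholds$family_p] <- "none"
      cbind(family = rownames(counts)[f], family_p = unname(pv), vb)
    })
    list(sim = sim, counts = counts, model = model,
         results = do.call(rbind, res))
  })
  write_tsv(fam$results, file.path(config$out_dir, "family_results.tsv"))
  branch_tallies <- do.call(rbind, lapply(
    split(fam$results, fam$results$branch), function(d)
      data.frame(branch = d$branch[1],
                 n_expanded = sum(d$call == "expansion"),
                 n_contracted = sum(d$call == "contraction"))))
  branch_tallies <- branch_tallies[order(branch_tallies$branch), ]
  write_tsv(branch_tallies, file.path(config$out_dir, "branch_tallies.tsv"))
  manifest$stages$genefam <- list(
    lambda_hat = fam$model$lambda,
    n_families = nrow(fam$counts),
    n_expanded_calls = sum(fam$results$call == "expansion"),
    n_contracted_calls = sum(fam$results$call == "contraction"))

  ## 6. enrichment of expanded families --------------------------------------
  enr <- stage("enrichment", {
    universe <- rownames(fam$counts)
    changed <- unique(fam$results$family[fam$results$call != "none"])
    set.seed(seed + 9L)
    terms <- do.call(rbind, lapply(1:10, function(t)
      data.frame(term = sprintf("T%03d", t),
                 name = sprintf("synthetic term %d", t),
                 category = "Biological Process",
                 gene = sample(universe, sample(5:12, 1)))))
    planted_term <- data.frame(
      term = "T100", name = "planted family-change term",
      category = "Biological Process",
      gene = rownames(fam$counts)[config$planted_family_events$family])
    list(changed = changed,
         table = hypergeom_enrich(changed, rbind(terms, planted_term),
                                  universe))
  })
  write_tsv(enr$table, file.path(config$out_dir, "enrichment.tsv"))
  manifest$stages$enrichment <- list(
    n_changed = length(enr$changed),
    n_terms_tested = nrow(enr$table),
    n_significant = sum(enr$table$q < config$thresholds$enrich_q))

  ## 7. report ----------------------------------------------------------------
  report <- write_report(
    list(tallies = tallies, branch_tallies = branch_tallies,
         selection = sel, convergent_genes = conv_genes),
    config$out_dir)
  manifest$stages$report <- report
  manifest$species <- species
  manifest$foreground <- fg
  manifest$outgroup <- outgroup_tip(tree_seq)
  persist()
  invisible(manifest)
}

#' Write the paper-shaped summary tables
#'
#' Emits the per-species five-category tallies, the per-branch
#' expansion/contraction counts, the Venn counts between the
#' positively-selected and omega-difference gene sets, and the genes
#' ranked by omega(TG) - omega(BG).
#'
#' @param stages List with `tallies`, `branch_tallies`, `selection`
#'   (per-gene selection table), `convergent_genes`.
#' @param out_dir Output directory.
#' @return List of summary counts (Venn sizes and file names).
#' @export
write_report <- function(stages, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sel <- stages$selection
  A <- sel$gene[sel$positively_selected]
  B <- sel$gene[sel$diff_significant]
  venn <- data.frame(set = c("positively_selected", "omega_difference",
                             "intersection"),
                     n = c(length(A), length(B),
                           length(intersect(A, B))))
  write_tsv(venn, file.path(out_dir, "venn_counts.tsv"))
  ranking <- sel[order(-sel$omega_difference),
                 c("gene", "omega_tg", "omega_bg", "omega_difference",
                   "p_diff", "diff_significant")]
  write_tsv(ranking, file.path(out_dir, "omega_ranking.tsv"))
  list(venn = stats::setNames(venn$n, venn$set),
       files = c("category_tallies.tsv", "branch_tallies.tsv",
                 "venn_counts.tsv", "omega_ranking.tsv",
                 "convergent_genes.tsv"))
}
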