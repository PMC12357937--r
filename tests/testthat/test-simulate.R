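# Synthetic-data generator: determinism, truth replay, end-to-end recovery.

run_pipeline <- function(sim) {
  sites <- do.call(rbind, lapply(sim$structures, derive_intron_sites))
  proj <- project_introns(sim$alignment, sites)
  cl <- cluster_introns(proj)
  leaves <- names(sim$structures)
  m <- build_presence_matrix(cl, stats::setNames(leaves, leaves))
  list(clusters = cl, matrix = m,
       fit = dollo_reconstruct(sim$tree, m))
}

test_that("identical seed and config reproduce the dataset byte for byte", {
  tr <- "((a:1,b:1):1,(c:1,(d:1,e:1):1):1);"
  cfg <- sim_config(tr, root_codons = 80, gain_rate = 1, loss_rate = 0.2,
                    seed = 9)
  s1 <- simulate_genes(cfg)
  s2 <- simulate_genes(cfg)
  expect_identical(s1$contigs, s2$contigs)
  expect_identical(as.character(s1$alignment), as.character(s2$alignment))
  expect_identical(s1$truth, s2$truth)
  ## a different seed changes the draw
  s3 <- simulate_genes(sim_config(tr, root_codons = 80, gain_rate = 1,
                                  loss_rate = 0.2, seed = 10))
  expect_false(identical(s1$contigs, s3$contigs))
})

test_that("zero rates leave every leaf with the root structure and no turnover", {
  tr <- "((a:1,b:1):1,(c:1,d:1):1);"
  sim <- simulate_genes(sim_config(tr, root_codons = 60, gain_rate = 0,
                                   loss_rate = 0, subst_rate = 0, seed = 2))
  exon_counts <- vapply(sim$structures, function(g) nrow(g$exons), 0L)
  expect_true(all(exon_counts == 2L))      # the one ancient root intron
  res <- run_pipeline(sim)
  expect_equal(ncol(res$matrix), 1L)
  expect_equal(sum(res$fit$n_losses), 0L)
  ## the ancient character is reconstructed at the root
  root_lab <- res$fit$tree$node.label[1]
  expect_equal(unname(res$fit$gain_node), root_lab)
})

test_that("every simulated intron respects the gt-ag rule and the site-count invariant", {
  set.seed(70)
  tr <- ape::rtree(6)
  sim <- simulate_genes(sim_config(tr, root_codons = 90, gain_rate = 1.5,
                                   loss_rate = 0.3, seed = 3))
  for (leaf in names(sim$structures)) {
    g <- sim$structures[[leaf]]
    s <- derive_intron_sites(g)
    expect_equal(nrow(s), nrow(g$exons) - 1L)
    v <- validate_splice_sites(g, sim$contigs[[leaf]])
    expect_true(all(v$starts_gt & v$ends_ag))
  }
  ## both strands exercised somewhere in the draw
  strands <- vapply(sim$structures, function(g) g$strand, "")
  expect_setequal(unique(strands), c("+", "-"))
})

test_that("truth replay along the tree reproduces each leaf's intron set", {
  set.seed(71)
  tr <- ape::rtree(6)
  sim <- simulate_genes(sim_config(tr, root_codons = 100, gain_rate = 1.2,
                                   loss_rate = 0.4, seed = 8))
  sites <- do.call(rbind, lapply(sim$structures, derive_intron_sites))
  proj <- project_introns(sim$alignment, sites)
  truth_key <- stats::setNames(
    paste(sim$truth$characters$column, sim$truth$characters$phase),
    sim$truth$characters$character)
  for (leaf in names(sim$structures)) {
    replayed <- replay_truth_to_leaf(sim, leaf)
    leaf_keys <- paste(proj$column[proj$gene_id == leaf],
                       proj$phase[proj$gene_id == leaf])
    expect_setequal(leaf_keys, unname(truth_key[replayed]))
  }
})

test_that("end-to-end recovery is exact over 20 seeded replicates without losses", {
  for (rep in 1:20) {
    set.seed(100 + rep)
    tr <- ape::rtree(6)
    sim <- simulate_genes(sim_config(tr, root_codons = 100, gain_rate = 0.8,
                                     loss_rate = 0, seed = rep))
    truth <- sim$truth$characters
    res <- run_pipeline(sim)
    ## character inventory matches the planted truth exactly
    key_t <- paste(truth$column, truth$phase)
    key_r <- paste(res$clusters$clusters$column, res$clusters$clusters$phase)
    expect_setequal(key_t, key_r)
    expect_equal(ncol(res$matrix), nrow(truth))
    ## presence matrix equals truth possession per leaf
    for (leaf in rownames(res$matrix)) {
      replayed <- replay_truth_to_leaf(sim, leaf)
      expect_equal(sum(res$matrix[leaf, ]), length(replayed))
    }
    ## the event map equals the planted gain log (no losses planted)
    expect_equal(sum(res$fit$n_losses), 0L)
    ids <- res$clusters$clusters$character_id[match(key_t, key_r)]
    expect_equal(unname(res$fit$gain_node[ids]), truth$child,
                 info = sprintf("replicate %d", rep))
  }
})

test_that("with losses enabled, parsimony totals match the planted event count on a clean draw", {
  set.seed(229)
  tr <- ape::rtree(7)
  sim <- simulate_genes(sim_config(tr, root_codons = 120, gain_rate = 1,
                                   loss_rate = 0.25, seed = 229))
  truth <- sim$truth
  expect_gt(nrow(truth$losses), 0L)     # the draw exercises losses at all
  ## every character must still be possessed somewhere
  possessed_by <- lapply(names(sim$structures), function(l)
    replay_truth_to_leaf(sim, l))
  names(possessed_by) <- names(sim$structures)
  expect_setequal(unique(unlist(possessed_by)), truth$characters$character)
  ## clean draw: per character, the planted loss count is already minimal
  ## (checked against the exhaustive single-origin oracle, independent of
  ## the reconstruction under test)
  trlab <- read_species_tree(sim$tree)
  for (ch in truth$characters$character) {
    poss <- names(possessed_by)[vapply(possessed_by, function(p)
      ch %in% p, TRUE)]
    tips <- stats::setNames(as.integer(trlab$tip.label %in% poss),
                            trlab$tip.label)
    expect_equal(dollo_oracle_losses(trlab, tips),
                 sum(truth$losses$character == ch), info = ch)
  }
  ## given a clean draw, the pipeline recovers exactly the planted totals
  res <- run_pipeline(sim)
  planted_total <- nrow(truth$characters) + nrow(truth$losses)
  expect_equal(total_events(res$fit), planted_total)
})

test_that("impossible gain demands fail with a collision error", {
  tr <- "((a:1,b:1):1,(c:1,d:1):1);"
  expect_error(
    simulate_genes(sim_config(tr, root_codons = 50, gain_rate = 200,
                              seed = 4)),
    "collision")
})

test_that("a written dataset round-trips through the standard formats", {
  set.seed(72)
  tr <- ape::rtree(5)
  sim <- simulate_genes(sim_config(tr, root_codons = 70, gain_rate = 1,
                                   loss_rate = 0, seed = 6))
  dir <- tempfile("simds")
  write_sim_dataset(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("structures.tsv", "contigs.fasta", "cds.fasta", "proteins.fasta",
      "alignment.fasta", "tree.nwk", "truth.json")))))
  gs <- read_gene_structures(file.path(dir, "structures.tsv"), "tsv")
  expect_setequal(names(gs), names(sim$structures))
  for (leaf in names(gs))
    expect_equal(gs[[leaf]]$exons, sim$structures[[leaf]]$exons)
  aln <- read_msa(file.path(dir, "alignment.fasta"))
  expect_identical(as.character(aln), as.character(sim$alignment))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$schema_version, 1L)
  expect_equal(truth$seed, 6L)
})
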