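test_that("the default tree is ultrametric with a monophyletic focal clade", {
  tp <- make_default_tree()
  expect_equal(ape::Ntip(tp$tree), 9L)
  expect_true(ape::is.ultrametric(tp$tree, tol = 1e-6))
  expect_true(ape::is.monophyletic(tp$tree, tp$focal_tips))
  expect_length(tp$focal_tips, 5L)
  # identical under repeated construction
  expect_identical(ape::write.tree(tp$tree),
                   ape::write.tree(make_default_tree()$tree))
})

test_that("generators are pure functions of config and seed", {
  tp <- make_default_tree()
  t1 <- simulate_traits(tp$tree, tp$painting, 2, 1, 900, 25, seed = 5)
  t2 <- simulate_traits(tp$tree, tp$painting, 2, 1, 900, 25, seed = 5)
  expect_identical(t1, t2)
  t3 <- simulate_traits(tp$tree, tp$painting, 2, 1, 900, 25, seed = 6)
  expect_false(identical(t1, t3))

  m1 <- make_mirnas(12, seed = 9)
  expect_identical(m1, make_mirnas(12, seed = 9))

  s1 <- make_similarity_table(5, c("s1", "s2", "s3"), seed = 3)
  expect_identical(s1, make_similarity_table(5, c("s1", "s2", "s3"),
                                             seed = 3))

  a1 <- assign_terms(sprintf("g%d", 1:50), n_terms = 5, seed = 4)
  expect_identical(a1, assign_terms(sprintf("g%d", 1:50), n_terms = 5,
                                    seed = 4))
})

test_that("zero rates propagate the root value to every tip", {
  tp <- make_default_tree()
  tr <- simulate_traits(tp$tree, tp$painting, 0, 0, 777, 5, seed = 2)
  expect_true(all(as.matrix(tr[, tp$tree$tip.label]) == 777))
})

test_that("tip variance scales linearly with the BM rate", {
  tp <- make_default_tree()
  depth <- max(ape::node.depth.edgelength(tp$tree))
  for (s2 in c(1, 4)) {
    tr <- simulate_traits(tp$tree, tp$painting, s2, s2, 0, 5000,
                          seed = 13)
    v <- stats::var(tr$D_rerio)
    expect_lt(abs(v - s2 * depth) / (s2 * depth), 0.05)
  }
})

test_that("genome building round-trips planted 3' UTR lengths exactly", {
  cfg <- simulation_config(seed = 33, n_genes = 25)
  tp <- make_default_tree(cfg)
  traits <- floor_trait_lengths(
    simulate_traits(tp$tree, tp$painting, 1, 1, cfg$root_length,
                    cfg$n_genes, seed = cfg$seed),
    cfg$min_utr_length)
  genomes <- build_genomes(traits, cfg)
  for (sp in c("M_zebra", "D_rerio")) {
    gdat <- genomes[[sp]]
    gff <- tempfile(fileext = ".gff3")
    write_gff3(gdat$gff, gff, seed = cfg$seed)
    models <- read_transcript_models(gff, gdat$genome, quiet = TRUE)
    expect_equal(nrow(attr(models, "rejected")), 0L)
    canon <- select_canonical(models)
    # the planted canonical isoform is selected for every gene
    expect_equal(nrow(canon), cfg$n_genes)
    expect_true(all(grepl("\\.t1$", canon$transcript_id)))
    # stopless decoys are present in the models but never selected
    expect_true(any(grepl("\\.t3$", models$transcript_id)) ||
                  cfg$stopless_rate == 0)
    feats <- extract_features(canon, gdat$genome)
    truth <- gdat$truth[match(feats$gene_id, gdat$truth$gene_id), ]
    expect_equal(feats$utr3_len, truth$utr3_len)
    # length conservation across every transcript
    all_feats <- extract_features(models, gdat$genome)
    spliced_len <- vapply(models$exons,
                          function(e) sum(e$end - e$start + 1), 0)
    expect_equal(all_feats$utr5_len + all_feats$cds_len +
                   all_feats$utr3_len, as.integer(spliced_len))
  }
})

test_that("planted repeat densities are recovered within tolerance", {
  cfg <- simulation_config(seed = 55, n_genes = 40)
  tp <- make_default_tree(cfg)
  traits <- floor_trait_lengths(
    simulate_traits(tp$tree, tp$painting, 1, 1, cfg$root_length,
                    cfg$n_genes, seed = cfg$seed), cfg$min_utr_length)
  genomes <- build_genomes(traits, cfg)
  pl <- plant_repeats(genomes, cfg$repeat_densities, seed = 56)
  for (sp in c("O_niloticus", "A_mexicanus")) {
    gdat <- pl$genomes[[sp]]
    feats <- split(gdat$features[, c("chrom", "start", "end")],
                   gdat$features$feature)
    reps <- dplyr::filter(pl$repeats, .data$species == sp)
    sizes <- c(chr1 = sum(Biostrings::width(gdat$genome)))
    rf <- repeat_fraction(feats, reps, sizes)
    for (cls in c("genome", "utr3", "utr5", "cds")) {
      expect_lt(abs(rf$fraction[rf$feature == cls] -
                      cfg$repeat_densities[[cls]]), 0.02)
    }
  }
  # zero densities give an empty repeat track
  pl0 <- plant_repeats(genomes["M_zebra"],
                       list(genome = 0, utr3 = 0, utr5 = 0, cds = 0),
                       seed = 57)
  expect_equal(nrow(pl0$repeats), 0L)
})

test_that("similarity tables drive recovery of planted 1:1 families", {
  species <- paste0("s", 1:9)
  sim <- make_similarity_table(10, species, seed = 65)
  path <- tempfile()
  readr::write_tsv(sim$blast, path, col_names = FALSE, progress = FALSE)
  hsps <- read_similarity(path, quiet = TRUE)
  fams <- cluster_families(unique(sim$truth$gene_id), pair_scores(hsps))
  smap <- dplyr::distinct(sim$truth[, c("gene_id", "species")])
  orth <- one_to_one(fams, smap, species)
  expect_equal(nrow(orth), 10L)
  # recovered partitions equal the planted families
  planted <- unname(sort(vapply(split(sim$truth$gene_id, sim$truth$family_id),
                                function(g) paste(sort(g), collapse = "+"), "")))
  expect_equal(partition_of(fams), planted)
})

test_that("a planted within-species duplication excludes that family from 1:1", {
  species <- paste0("s", 1:4)
  sim <- make_similarity_table(6, species, seed = 66,
                               duplicated_species = list(`2` = "s3"))
  path <- tempfile()
  readr::write_tsv(sim$blast, path, col_names = FALSE, progress = FALSE)
  fams <- cluster_families(unique(sim$truth$gene_id),
                           pair_scores(read_similarity(path, quiet = TRUE)))
  orth <- one_to_one(fams, dplyr::distinct(
    sim$truth[, c("gene_id", "species")]), species)
  expect_equal(nrow(orth), 5L)
  expect_false(any(grepl("\\|fam2$", unlist(orth[, species]))))
})

test_that("HSP splitting in the similarity table exercises conjoining", {
  sim <- make_similarity_table(2, c("s1", "s2"), seed = 67,
                               noise_edges = 0)
  path <- tempfile()
  readr::write_tsv(sim$blast, path, col_names = FALSE, progress = FALSE)
  hsps <- read_similarity(path, quiet = TRUE)
  # two HSPs per pair, and the conjoined score exceeds both singles
  one_pair <- hsps[hsps$query == hsps$query[1] &
                     hsps$subject == hsps$subject[1], ]
  expect_equal(nrow(one_pair), 2L)
  expect_gt(conjoin_hsps(one_pair), max(one_pair$bitscore))
})
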