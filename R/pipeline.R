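#' Validate a simulation/pipeline configuration
#'
#' Checks numeric ranges, tree parseability and ultrametricity, the
#' presence and monophyly of the focal tips, and repeat-density bounds.
#'
#' @param config A [simulation_config()] (or a plain list with the same
#'   fields).
#' @return A tibble `field`, `message` of violations; zero rows when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  errs <- list()
  add <- function(field, message)
    errs[[length(errs) + 1L]] <<- tibble::tibble(field = field,
                                                 message = message)
  if (is.null(config$seed) || !is.finite(config$seed))
    add("seed", "seed is mandatory and must be a finite integer")
  if (is.null(config$n_genes) || config$n_genes < 1)
    add("n_genes", "need at least one gene")
  for (f in c("sig2_focal", "sig2_background"))
    if (!is.null(config[[f]]) && config[[f]] < 0)
      add(f, "rates must be non-negative")
  dens <- unlist(config$repeat_densities)
  if (any(dens < 0 | dens > 1))
    add("repeat_densities",
        paste("densities outside [0,1]:",
              paste(names(dens)[dens < 0 | dens > 1], collapse = ", ")))
  tree <- tryCatch(ape::read.tree(text = config$tree_newick),
                   error = function(e) NULL)
  if (is.null(tree)) {
    add("tree_newick", "tree does not parse as Newick")
  } else {
    missing_tips <- setdiff(config$focal_tips, tree$tip.label)
    if (length(missing_tips))
      add("focal_tips", paste("tips absent from tree:",
                              paste(missing_tips, collapse = ", ")))
    else if (length(config$focal_tips) < length(tree$tip.label) &&
             !ape::is.monophyletic(tree, config$focal_tips))
      add("focal_tips", "focal tips are not monophyletic")
    if (!ape::is.ultrametric(tree, tol = 1e-6 * max(ape::node.depth.edgelength(tree))))
      add("tree_newick", "tree is not ultrametric")
  }
  if (length(errs)) dplyr::bind_rows(errs) else
    tibble::tibble(field = character(), message = character())
}

write_stage <- function(tbl, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(tbl, path, progress = FALSE)
  path
}

#' Run the full synthetic analysis pipeline
#'
#' Generates a complete synthetic dataset from the configuration (genomes
#' with annotations, repeat track, miRNAs with planted target sites,
#' similarity table, term annotations), then runs every analysis stage in
#' dependency order: feature extraction, 1:1 orthology, repeat-content
#' accounting with the paired signed-rank test, miRNA target scanning,
#' per-gene two-regime Brownian-motion rate fitting with the log10-ratio
#' t-test, the clade length-ratio t-test, and term enrichment of the top-5%
#' length and rate gene sets. All stage tables are written as TSV under
#' `out_dir`, together with a plain-text report and a JSON manifest with
#' per-file checksums. Counts of records dropped at each filter are logged.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with every stage result: `tree`, `traits`,
#'   `lengths`, `summaries`, `orthologs`, `repeat_report`, `signed_rank`,
#'   `target_summary`, `bm_fits`, `rate_test`, `length_ratios`,
#'   `length_test`, `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  errs <- validate_config(config)
  if (nrow(errs))
    stop("invalid configuration:\n",
         paste(errs$field, errs$message, sep = ": ", collapse = "\n"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs_dir <- file.path(out_dir, "inputs")
  dir.create(inputs_dir, showWarnings = FALSE)
  say <- function(...) if (!quiet) rlang::inform(paste0(...))
  files <- character(0)
  keep <- function(path) { files <<- c(files, path); path }

  ## ---- synthetic inputs -------------------------------------------------
  say("stage simulate: tree, traits, genomes, repeats, miRNAs, terms")
  tp <- make_default_tree(config)
  traits_raw <- simulate_traits(tp$tree, tp$painting, config$sig2_focal,
                                config$sig2_background,
                                config$root_length, config$n_genes,
                                seed = config$seed)
  traits <- floor_trait_lengths(traits_raw, config$min_utr_length)
  genomes <- build_genomes(traits, config)
  planted <- plant_repeats(genomes, config$repeat_densities,
                           seed = config$seed + 1L)
  genomes <- planted$genomes
  species <- names(genomes)
  for (sp in species) {
    fa <- file.path(inputs_dir, paste0(sp, ".fa"))
    Biostrings::writeXStringSet(genomes[[sp]]$genome, fa); keep(fa)
    keep(write_gff3(genomes[[sp]]$gff,
                    file.path(inputs_dir, paste0(sp, ".gff3")),
                    seed = config$seed))
    keep(write_stage(genomes[[sp]]$features, inputs_dir,
                     paste0(sp, ".features.tsv")))
  }
  bed <- dplyr::transmute(planted$repeats, .data$species, .data$chrom,
                          start = .data$start - 1L, end = .data$end,
                          .data$class)
  keep(write_stage(bed, inputs_dir, "repeats.bed.tsv"))
  mirnas <- make_mirnas(config$n_mirnas, seed = config$seed + 2L)
  keep(write_stage(mirnas, inputs_dir, "mirnas.tsv"))
  sim_tab <- make_similarity_table(
    n_families = config$n_genes, species = species,
    seed = config$seed + 3L, gene_ids = traits$gene_id)
  blast_path <- file.path(inputs_dir, "blast.tsv")
  readr::write_tsv(sim_tab$blast, blast_path, col_names = FALSE,
                   progress = FALSE)
  keep(blast_path)

  ## ---- extract ----------------------------------------------------------
  say("stage extract: canonical transcripts and feature lengths")
  per_sp <- purrr::imap(genomes, function(gdat, sp) {
    models <- read_transcript_models(
      file.path(inputs_dir, paste0(sp, ".gff3")), gdat$genome,
      quiet = TRUE)
    canon <- select_canonical(models)
    feats <- extract_features(canon, gdat$genome)
    say(sprintf("  %s: %d transcripts, %d canonical, %d non-stop dropped",
                sp, nrow(models), nrow(canon), sum(!models$has_stop)))
    list(models = models, canonical = canon, features = feats)
  })
  lengths_tbl <- dplyr::bind_rows(purrr::imap(per_sp, function(x, sp) {
    dplyr::mutate(x$features[, c("gene_id", "transcript_id", "utr5_len",
                                 "cds_len", "utr3_len")], species = sp,
                  .before = 1L)
  }))
  keep(write_stage(lengths_tbl, out_dir, "feature_lengths.tsv"))
  summaries <- dplyr::bind_rows(purrr::imap(per_sp, function(x, sp) {
    gsize <- sum(Biostrings::width(genomes[[sp]]$genome))
    dplyr::mutate(summarize_lengths(x$features$utr3_len, gsize),
                  species = sp, .before = 1L)
  }))
  keep(write_stage(summaries, out_dir, "utr3_length_summary.tsv"))
  hist_tbl <- dplyr::bind_rows(purrr::imap(per_sp, function(x, sp) {
    dplyr::mutate(length_histogram(x$features$utr3_len), species = sp,
                  .before = 1L)
  }))
  keep(write_stage(hist_tbl, out_dir, "utr3_length_histogram.tsv"))

  ## ---- orthologs --------------------------------------------------------
  say("stage orthologs: HSP conjoining and family clustering")
  hsps <- read_similarity(blast_path, quiet = TRUE)
  edges <- pair_scores(hsps)
  all_genes <- unique(sim_tab$truth$gene_id)
  fams <- cluster_families(all_genes, edges)
  species_map <- tibble::tibble(gene_id = all_genes,
                                species = sub("\\|.*$", "", all_genes))
  orth <- one_to_one(fams, species_map, species)
  say(sprintf("  %d genes -> %d families -> %d 1:1 families",
              length(all_genes), dplyr::n_distinct(fams$family_id),
              nrow(orth)))
  keep(write_stage(fams, out_dir, "families.tsv"))
  keep(write_stage(orth, out_dir, "orthologs_1to1.tsv"))

  ## ---- repeats ----------------------------------------------------------
  say("stage repeats: per-feature repeat fractions and signed-rank test")
  rep_report <- dplyr::bind_rows(purrr::map(species, function(sp) {
    feats <- genomes[[sp]]$features
    fl <- split(feats[, c("chrom", "start", "end")], feats$feature)
    reps <- dplyr::filter(planted$repeats, .data$species == sp)
    sizes <- stats::setNames(sum(Biostrings::width(genomes[[sp]]$genome)),
                             names(genomes[[sp]]$genome))
    dplyr::mutate(repeat_fraction(fl, reps, sizes), species = sp,
                  .before = 1L)
  }))
  keep(write_stage(rep_report, out_dir, "repeat_fractions.tsv"))
  wide <- tidyr::pivot_wider(
    rep_report[, c("species", "feature", "fraction")],
    names_from = "feature", values_from = "fraction")
  sr <- paired_signed_rank(wide$genome, wide$utr3)
  keep(write_stage(sr, out_dir, "signed_rank.tsv"))

  ## ---- miRNA targets ----------------------------------------------------
  say("stage mirna: planting and scanning target sites")
  target_rows <- purrr::imap(per_sp, function(x, sp) {
    utrs <- stats::setNames(x$features$utr3_seq, x$features$gene_id)
    utrs <- utrs[nchar(utrs) >= 2L * nchar(mirnas$seq[1])]
    counts <- withr::with_seed(
      config$seed + 5L + match(sp, species),
      sample(config$mirna_site_range, length(utrs), replace = TRUE))
    pl <- plant_mirna_sites(utrs, mirnas, counts, seed = config$seed + 4L)
    scan <- scan_utrs(pl$utrs, mirnas)
    list(summary = dplyr::mutate(summarize_targets(scan$counts),
                                 species = sp, .before = 1L),
         planted = sum(counts), found = sum(scan$counts$n_sites))
  })
  target_summary <- dplyr::bind_rows(purrr::map(target_rows, "summary"))
  keep(write_stage(target_summary, out_dir, "target_summary.tsv"))

  ## ---- rates ------------------------------------------------------------
  say("stage rates: two-regime BM fits on 1:1 ortholog 3' UTR lengths")
  base_gene <- function(x) sub("^[^|]*\\|", "", x)
  orth_long <- tidyr::pivot_longer(orth, -"family_id",
                                   names_to = "species",
                                   values_to = "gene_id")
  utr_len <- stats::setNames(lengths_tbl$utr3_len,
                             paste0(lengths_tbl$species, "~",
                                    lengths_tbl$gene_id))
  orth_long$utr3_len <- utr_len[paste0(orth_long$species, "~",
                                       orth_long$gene_id)]
  trait_tbl <- orth_long |>
    dplyr::mutate(gene = base_gene(.data$gene_id)) |>
    tidyr::pivot_wider(id_cols = "gene", names_from = "species",
                       values_from = "utr3_len") |>
    dplyr::rename(gene_id = "gene") |>
    tidyr::drop_na()
  fits <- fit_bm_rates(trait_tbl, tp$tree, tp$painting)
  keep(write_stage(tidy(fits), out_dir, "bm_fits.tsv"))
  rate_test <- glance(fits)
  say(sprintf("  %d genes fit, %d flagged (boundary/degenerate)",
              nrow(fits), sum(fits$flag != "ok")))
  keep(write_stage(rate_test, out_dir, "rate_test.tsv"))

  ## ---- length ratios ----------------------------------------------------
  lr <- length_log_ratio(trait_tbl, tp$focal_tips, tp$background_tips)
  length_test <- one_sample_t(lr$log10_ratio[lr$flag == "ok"])
  keep(write_stage(lr, out_dir, "length_ratios.tsv"))
  keep(write_stage(length_test, out_dir, "length_test.tsv"))

  ## ---- enrichment -------------------------------------------------------
  say("stage enrich: top-5% gene sets vs baseline")
  universe <- trait_tbl$gene_id
  top_len <- top_fraction(
    tibble::tibble(gene_id = lr$gene_id, score = lr$log10_ratio) |>
      tidyr::drop_na())
  usable <- fits$flag == "ok" & !is.na(fits$log10_ratio)
  top_rate <- top_fraction(
    tibble::tibble(gene_id = fits$gene_id[usable],
                   score = fits$log10_ratio[usable]))
  ann <- assign_terms(universe, n_terms = config$n_terms,
                      baseline_freq = config$baseline_term_freq,
                      planted_term = "TERM:PLANTED",
                      planted_genes = top_len,
                      planted_freq = config$planted_term_freq,
                      seed = config$seed + 6L)
  keep(write_stage(ann, inputs_dir, "annotations.tsv"))
  enrich_or_empty <- function(set) {
    if (!length(set)) {
      say("  top set empty at this gene count; writing empty table")
      return(tibble::tibble(term_id = character(), k = integer(),
                            K = integer(), n = integer(), N = integer(),
                            p_value = numeric(), p_adjust = numeric()))
    }
    fisher_enrichment(set, universe, ann)
  }
  enr <- list(length = enrich_or_empty(top_len),
              rate = enrich_or_empty(top_rate))
  keep(write_stage(enr$length, out_dir, "enrichment_length.tsv"))
  keep(write_stage(enr$rate, out_dir, "enrichment_rate.tsv"))

  ## ---- report + manifest ------------------------------------------------
  report <- c(
    sprintf("utr3evo pipeline report (seed %d, %d genes, %d species)",
            config$seed, config$n_genes, length(species)),
    sprintf("1:1 ortholog families: %d", nrow(orth)),
    sprintf("signed-rank genome vs 3'UTR repeat fraction: p = %g",
            sr$p_value),
    sprintf("targets per target-bearing 3'UTR: %s",
            paste(sprintf("%s %.2f", target_summary$species,
                          target_summary$mean_sites_per_target_utr),
                  collapse = ", ")),
    sprintf("length log10-ratio t-test: mean %.4f, p = %g",
            length_test$mean, length_test$p_value),
    sprintf("rate log10-ratio t-test: mean %.4f, p = %g",
            rate_test$mean_log10_ratio, rate_test$p_value),
    if (nrow(enr$length))
      sprintf("top enriched term (length set): %s (adj p = %g)",
              enr$length$term_id[1], enr$length$p_adjust[1])
    else "top enriched term (length set): none (empty top set)")
  report_path <- file.path(out_dir, "report.txt")
  readr::write_lines(report, report_path); keep(report_path)
  manifest <- list(
    seed = config$seed,
    tool_version = as.character(utils::packageVersion("utr3evo")),
    config = unclass(config),
    files = tibble::tibble(
      path = sub(paste0("^", out_dir, "/?"), "", unique(files)),
      md5 = unname(tools::md5sum(unique(files)))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  say("pipeline complete: ", out_dir)
  invisible(list(
    tree = tp, traits = traits, lengths = lengths_tbl,
    summaries = summaries, orthologs = orth, repeat_report = rep_report,
    signed_rank = sr, target_summary = target_summary, bm_fits = fits,
    rate_test = rate_test, length_ratios = lr, length_test = length_test,
    enrichment = enr, manifest = manifest))
}
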