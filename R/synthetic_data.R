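#' Simulation configuration for the synthetic pipeline data
#'
#' Bundles every knob of the synthetic-data generators with the default
#' study conditions: a 9-taxon time-calibrated tree with a monophyletic
#' 5-species focal clade (cichlids) and 4 background teleosts, 2041 genes
#' (the 1:1 ortholog count the pipeline is sized for), equal unit
#' Brownian-motion rates, a 1000-nt root 3' UTR length, a 50-nt floor when
#' lengths are materialized into genomes, repeat densities per feature
#' class bracketed by the genome-wide > 3' UTR > 5' UTR > CDS ordering
#' observed in teleosts, 271 miRNAs, and a planted enrichment term at 40%
#' frequency in the top set versus 5% baseline.
#'
#' @param seed Integer random seed (mandatory; recorded in every output
#'   header).
#' @param n_genes Number of genes to simulate.
#' @param sig2_focal,sig2_background Brownian-motion rates (nt^2/Myr).
#' @param root_length Root state of the 3' UTR length (nt).
#' @param min_utr_length Floor applied when lengths become genome features
#'   (nt).
#' @param utr5_length,cds_length 5' UTR and CDS lengths used when building
#'   gene models (nt; CDS includes the stop codon).
#' @param intergenic_length Spacer between genes (nt).
#' @param intron_every Every k-th gene gets an intron inside its 3' UTR.
#' @param intron_length Length of that intron (nt).
#' @param decoy_rate,stopless_rate Per-gene probabilities of a shorter
#'   stop-bearing decoy isoform and of a stopless decoy isoform.
#' @param repeat_densities Named list of target repeat coverage fractions
#'   for `genome`, `utr3`, `utr5`, `cds`.
#' @param n_mirnas Number of synthetic mature miRNAs.
#' @param mirna_site_range Integer range of planted sites per UTR.
#' @param n_terms Number of annotation terms.
#' @param baseline_term_freq Baseline per-term annotation frequency.
#' @param planted_term_freq Frequency of the planted term inside the
#'   designated top set.
#' @param tree_newick Newick string of the time-calibrated tree (Myr).
#' @param focal_tips Tip labels of the focal clade.
#' @return A list of class `utr3_sim_config`.
#' @export
simulation_config <- function(seed,
                              n_genes = 2041,
                              sig2_focal = 1,
                              sig2_background = 1,
                              root_length = 1000,
                              min_utr_length = 50,
                              utr5_length = 100,
                              cds_length = 300,
                              intergenic_length = 500,
                              intron_every = 5,
                              intron_length = 150,
                              decoy_rate = 0.3,
                              stopless_rate = 0.2,
                              repeat_densities = list(
                                genome = 0.28, utr3 = 0.14,
                                utr5 = 0.08, cds = 0.03),
                              n_mirnas = 271,
                              mirna_site_range = 0:5,
                              n_terms = 50,
                              baseline_term_freq = 0.05,
                              planted_term_freq = 0.4,
                              tree_newick = default_tree_newick(),
                              focal_tips = c("M_zebra", "P_nyererei",
                                             "H_burtoni", "N_brichardi",
                                             "O_niloticus")) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            sig2_focal >= 0, sig2_background >= 0,
            all(unlist(repeat_densities) >= 0),
            all(unlist(repeat_densities) <= 1))
  structure(list(
    seed = as.integer(seed), n_genes = n_genes,
    sig2_focal = sig2_focal, sig2_background = sig2_background,
    root_length = root_length, min_utr_length = min_utr_length,
    utr5_length = utr5_length, cds_length = cds_length,
    intergenic_length = intergenic_length,
    intron_every = intron_every, intron_length = intron_length,
    decoy_rate = decoy_rate, stopless_rate = stopless_rate,
    repeat_densities = repeat_densities,
    n_mirnas = n_mirnas, mirna_site_range = mirna_site_range,
    n_terms = n_terms, baseline_term_freq = baseline_term_freq,
    planted_term_freq = planted_term_freq,
    tree_newick = tree_newick, focal_tips = focal_tips),
    class = "utr3_sim_config")
}

#' Default 9-taxon time-calibrated tree (Newick, Myr)
#'
#' Five cichlids (Oreochromis niloticus sister to a Neolamprologus +
#' haplochromine clade) plus medaka and Amazon molly as their nearest
#' outgroups, and the cavefish + zebrafish lineage splitting at the root.
#' Node depths are round figures in the range of published teleost
#' divergence-time estimates; they are configurable defaults, not
#' measurements.
#'
#' @return A Newick string.
#' @export
default_tree_newick <- function() {
  paste0("((((((M_zebra:2,P_nyererei:2):3,H_burtoni:5):5,",
         "N_brichardi:10):20,O_niloticus:30):90,",
         "(O_latipes:100,P_formosa:100):20):110,",
         "(A_mexicanus:150,D_rerio:150):80);")
}

#' Build the default tree and its regime painting
#'
#' @param config A [simulation_config()] (or `NULL` for all defaults).
#' @return A list: `tree` (ultrametric `phylo`), `painting` (from
#'   [paint_regimes()]), `focal_tips`, `background_tips`.
#' @export
make_default_tree <- function(config = NULL) {
  if (is.null(config)) config <- simulation_config(seed = 1L)
  tree <- ape::read.tree(text = config$tree_newick)
  painting <- paint_regimes(tree, config$focal_tips)
  list(tree = tree, painting = painting,
       focal_tips = config$focal_tips,
       background_tips = setdiff(tree$tip.label, config$focal_tips))
}

#' Simulate per-gene tip values under painted Brownian motion
#'
#' Each gene evolves independently from the root value by normal branch
#' increments with variance (regime rate x branch length). Values are
#' returned raw (they may be negative); apply [floor_trait_lengths()]
#' before building genomes.
#'
#' @param tree Rooted `phylo` tree.
#' @param painting Regime labels from [paint_regimes()].
#' @param sig2_focal,sig2_background Regime rates.
#' @param root_value Trait value at the root.
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @return A tibble `gene_id` plus one numeric column per tip.
#' @export
simulate_traits <- function(tree, painting, sig2_focal, sig2_background,
                            root_value, n_genes, seed) {
  stopifnot(sig2_focal >= 0, sig2_background >= 0)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  ord <- ape::reorder.phylo(tree, "postorder")
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  pre <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  X <- withr::with_seed(seed, {
    vals <- matrix(0, nrow = n_genes, ncol = nn)
    vals[, n + 1L] <- root_value
    for (i in seq_len(nrow(pre))) {
      p <- pre[i, 1]; child <- pre[i, 2]
      j <- match(paste(p, child), key)
      rate <- if (painting[j] == "focal") sig2_focal else sig2_background
      vals[, child] <- vals[, p] +
        rnorm(n_genes, 0, sqrt(rate * tree$edge.length[j]))
    }
    vals[, seq_len(n), drop = FALSE]
  })
  colnames(X) <- tree$tip.label
  dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%05d", seq_len(n_genes))),
    tibble::as_tibble(X))
}

#' Floor and round simulated trait lengths for genome building
#'
#' @param traits Trait tibble from [simulate_traits()].
#' @param min_length Minimum length (nt).
#' @return The same tibble with species columns rounded and floored.
#' @export
floor_trait_lengths <- function(traits, min_length = 50) {
  dplyr::mutate(traits, dplyr::across(
    dplyr::where(is.numeric), ~ pmax(round(.x), min_length)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Codons free of stop codons, used for CDS bodies so that any in-frame
# truncation of a decoy still ends in a non-stop codon.
stopfree_codons <- function() {
  all3 <- as.vector(outer(as.vector(outer(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T"), paste0)),
                          c("A", "C", "G", "T"), paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

mirror_iv <- function(iv, len) c(len - iv[2] + 1L, len - iv[1] + 1L)

# Build one gene's sense-strand region, isoform structures and genomic
# feature intervals. Returns sequence fragment (genomic strand), gff rows
# (fragment-local coordinates) and feature intervals.
build_gene <- function(gene_id, utr3_len, cfg, with_intron, strand,
                       add_decoy, add_stopless) {
  u5 <- cfg$utr5_length; cl <- cfg$cds_length
  n_body <- cl / 3L - 2L
  cds_seq <- paste0("ATG",
                    paste(sample(stopfree_codons(), n_body, replace = TRUE),
                          collapse = ""),
                    "TAA")
  tx_len <- u5 + cl + utr3_len
  tx_seq <- paste0(random_dna(u5), cds_seq, random_dna(utr3_len))
  # transcript -> region coordinates (intron inside the 3' UTR, 50 nt
  # after the stop codon, when present)
  if (with_intron) {
    cut <- u5 + cl + 50L
    region_seq <- paste0(substr(tx_seq, 1L, cut),
                         random_dna(cfg$intron_length),
                         substr(tx_seq, cut + 1L, tx_len))
    exons <- list(c(1L, cut),
                  c(cut + cfg$intron_length + 1L,
                    tx_len + cfg$intron_length))
  } else {
    region_seq <- tx_seq
    exons <- list(c(1L, tx_len))
  }
  rl <- nchar(region_seq)
  cds_iv <- c(u5 + 1L, u5 + cl)
  utr5_iv <- list(c(1L, u5))
  utr3_iv <- if (with_intron) {
    list(c(u5 + cl + 1L, u5 + cl + 50L),
         c(u5 + cl + 50L + cfg$intron_length + 1L, rl))
  } else list(c(u5 + cl + 1L, rl))
  isoforms <- list(list(id = paste0(gene_id, ".t1"), cds = cds_iv))
  if (add_decoy)  # shorter coding region, same stop codon
    isoforms <- c(isoforms, list(list(id = paste0(gene_id, ".t2"),
                                      cds = c(cds_iv[1] + 30L, cds_iv[2]))))
  if (add_stopless)  # terminal stop codon dropped
    isoforms <- c(isoforms, list(list(id = paste0(gene_id, ".t3"),
                                      cds = c(cds_iv[1], cds_iv[2] - 3L))))
  if (strand == "-") {
    region_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(region_seq)))
    exons <- lapply(exons, mirror_iv, len = rl)
    utr5_iv <- lapply(utr5_iv, mirror_iv, len = rl)
    utr3_iv <- lapply(utr3_iv, mirror_iv, len = rl)
    isoforms <- lapply(isoforms, function(iso) {
      iso$cds <- mirror_iv(iso$cds, rl); iso
    })
  }
  list(seq = region_seq, len = rl, exons = exons, isoforms = isoforms,
       utr5 = utr5_iv, utr3 = utr3_iv,
       cds = list(if (strand == "-") mirror_iv(cds_iv, rl) else cds_iv))
}

#' Build synthetic genomes and annotations from planted 3' UTR lengths
#'
#' For every species (tree tip column of `traits`) lays out one chromosome
#' of gene models whose canonical (longest-CDS, stop-bearing) isoform has
#' exactly the planted 3' UTR length. Genes alternate strand, every
#' `intron_every`-th gene carries an intron inside its 3' UTR, and decoy
#' isoforms (a shorter stop-bearing one and a stopless one) are added at
#' the configured rates. All CDS bodies use stop-free codons so only the
#' terminal codon is a stop.
#'
#' @param traits Floored trait tibble (see [floor_trait_lengths()]).
#' @param config A [simulation_config()].
#' @return A named list (one element per species), each with `genome`
#'   ([Biostrings::DNAStringSet], one chromosome `chr1`), `gff` (GFF3
#'   field tibble), `features` (tibble `feature`, `chrom`, `start`, `end`,
#'   `gene_id`: genomic intervals of canonical utr5/cds/utr3), and `truth`
#'   (tibble `gene_id`, `transcript_id`, `utr3_len`, `strand`).
#' @export
build_genomes <- function(traits, config) {
  species <- setdiff(names(traits), "gene_id")
  out <- purrr::imap(stats::setNames(species, species), function(sp, nm) {
    sp_i <- match(sp, species)
    withr::with_seed(config$seed + 10007L * sp_i, {
      n_genes <- nrow(traits)
      frags <- character(0)
      gff <- list(); feats <- list(); truth <- list()
      offset <- config$intergenic_length
      frags <- c(frags, random_dna(config$intergenic_length))
      for (i in seq_len(n_genes)) {
        gid <- paste0(sp, "|", traits$gene_id[i])
        g <- build_gene(
          gene_id = gid, utr3_len = as.integer(traits[[sp]][i]),
          cfg = config, with_intron = i %% config$intron_every == 0L,
          strand = if (i %% 2L == 1L) "+" else "-",
          add_decoy = runif(1) < config$decoy_rate,
          add_stopless = runif(1) < config$stopless_rate)
        strand <- if (i %% 2L == 1L) "+" else "-"
        shift <- function(iv) iv + offset
        g_start <- offset + 1L; g_end <- offset + g$len
        gff[[length(gff) + 1L]] <- tibble::tibble(
          type = "gene", start = g_start, end = g_end, strand = strand,
          attributes = paste0("ID=", gid))
        for (iso in g$isoforms) {
          gff[[length(gff) + 1L]] <- tibble::tibble(
            type = "mRNA", start = g_start, end = g_end, strand = strand,
            attributes = paste0("ID=", iso$id, ";Parent=", gid))
          for (ex in g$exons)
            gff[[length(gff) + 1L]] <- tibble::tibble(
              type = "exon", start = offset + ex[1], end = offset + ex[2],
              strand = strand, attributes = paste0("Parent=", iso$id))
          gff[[length(gff) + 1L]] <- tibble::tibble(
            type = "CDS", start = offset + iso$cds[1],
            end = offset + iso$cds[2], strand = strand,
            attributes = paste0("Parent=", iso$id))
        }
        for (fname in c("utr5", "cds", "utr3")) {
          for (iv in g[[fname]])
            feats[[length(feats) + 1L]] <- tibble::tibble(
              feature = fname, chrom = "chr1", start = offset + iv[1],
              end = offset + iv[2], gene_id = gid)
        }
        truth[[length(truth) + 1L]] <- tibble::tibble(
          gene_id = gid, transcript_id = paste0(gid, ".t1"),
          utr3_len = as.integer(traits[[sp]][i]), strand = strand)
        frags <- c(frags, g$seq, random_dna(config$intergenic_length))
        offset <- g_end + config$intergenic_length
      }
      chrom_seq <- paste(frags, collapse = "")
      genome <- Biostrings::DNAStringSet(chrom_seq)
      names(genome) <- "chr1"
      gff_tbl <- dplyr::bind_rows(gff) |>
        dplyr::mutate(seqid = "chr1", source = "utr3evo_sim",
                      score = ".", phase = ".") |>
        dplyr::select(dplyr::all_of(c("seqid", "source", "type", "start",
                                      "end", "score", "strand", "phase",
                                      "attributes")))
      list(genome = genome, gff = gff_tbl,
           features = dplyr::bind_rows(feats),
           truth = dplyr::bind_rows(truth))
    })
  })
  attr(out, "seed") <- config$seed
  out
}

#' Write a GFF3 field tibble to a file
#'
#' @param gff Tibble with the nine GFF3 columns (as in [build_genomes()]).
#' @param file Output path.
#' @param seed Optional seed recorded in the header.
#' @return `file`, invisibly.
#' @export
write_gff3 <- function(gff, file, seed = NULL) {
  header <- c("##gff-version 3",
              if (!is.null(seed)) paste0("# seed: ", seed))
  readr::write_lines(header, file)
  readr::write_tsv(gff, file, append = TRUE, col_names = FALSE,
                   progress = FALSE)
  invisible(file)
}

# Fixed small synthetic repeat library (SINE/LINE/DNA-like labels; fixed
# sequences, regenerated deterministically).
repeat_library <- function() {
  withr::with_seed(20180605L, list(
    SINE = random_dna(200L),
    LINE = random_dna(500L),
    DNA = random_dna(300L)))
}

#' Plant repeat copies into synthetic genomes at target densities
#'
#' Overwrites bases inside feature intervals (and intergenic space) with
#' tiles from a fixed synthetic repeat library so that each feature class
#' approximates its target coverage fraction; the intergenic density is
#' solved so that the genome-wide fraction approximates
#' `densities$genome`. CDS stop codons are never overwritten. Coverage is
#' allocated per interval (rounded), so measured fractions track targets
#' to within rounding on toy genomes. Infeasible targets degrade to best
#' effort with a warning.
#'
#' @param genomes Output of [build_genomes()].
#' @param densities Named list with `genome`, `utr3`, `utr5`, `cds` target
#'   fractions in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list: `genomes` (modified copy of the input) and `repeats`
#'   (tibble `species`, `chrom`, `start`, `end` 1-based inclusive,
#'   `class`).
#' @export
plant_repeats <- function(genomes, densities, seed) {
  stopifnot(all(unlist(densities) >= 0), all(unlist(densities) <= 1))
  lib <- repeat_library()
  lib_names <- names(lib)
  beds <- list()
  out <- purrr::imap(genomes, function(gdat, sp) {
    sp_i <- match(sp, names(genomes))
    withr::with_seed(seed + 7919L * sp_i, {
      chrom <- as.character(gdat$genome[[1]])
      glen <- nchar(chrom)
      feats <- gdat$features
      plant_iv <- list()
      take <- function(start, end, density) {
        w <- end - start + 1L
        cov <- round(density * w)
        if (cov < 1L) return(NULL)
        cov <- min(cov, w)
        off <- if (w > cov) sample.int(w - cov + 1L, 1L) - 1L else 0L
        c(start + off, start + off + cov - 1L)
      }
      # feature classes (stop codon shielded within CDS)
      for (cls in c("utr3", "utr5", "cds")) {
        rows <- feats[feats$feature == cls, ]
        for (r in seq_len(nrow(rows))) {
          s <- rows$start[r]; e <- rows$end[r]
          if (cls == "cds") {
            # stop codon sits at the 3' end of the CDS: shield 3 bases on
            # the strand-appropriate side; shielding both ends is simpler
            # and loses only 6 bases
            s <- s + 3L; e <- e - 3L
            if (e < s) next
          }
          iv <- take(s, e, densities[[cls]])
          if (!is.null(iv)) plant_iv[[length(plant_iv) + 1L]] <- iv
        }
      }
      # intergenic density solves for the genome-wide target
      feat_cov <- sum(vapply(plant_iv, function(iv) iv[2] - iv[1] + 1, 0))
      covered_feat_bases <- covered_bases(feats[, c("chrom", "start", "end")])
      inter_bases <- glen - covered_feat_bases
      inter_target <- densities$genome * glen - feat_cov
      inter_density <- inter_target / inter_bases
      if (inter_density > 0.95) {
        warning("intergenic repeat density infeasible; clipping to 0.95")
        inter_density <- 0.95
      }
      if (inter_density > 0) {
        feat_ir <- IRanges::reduce(IRanges::IRanges(feats$start, feats$end))
        gaps <- IRanges::gaps(feat_ir, start = 1L, end = glen)
        for (r in seq_along(gaps)) {
          iv <- take(IRanges::start(gaps)[r], IRanges::end(gaps)[r],
                     inter_density)
          if (!is.null(iv)) plant_iv[[length(plant_iv) + 1L]] <- iv
        }
      }
      if (length(plant_iv)) {
        cls_cycle <- rep_len(lib_names, length(plant_iv))
        for (j in seq_along(plant_iv)) {
          iv <- plant_iv[[j]]
          w <- iv[2] - iv[1] + 1L
          tile <- paste(rep(lib[[cls_cycle[j]]],
                            ceiling(w / nchar(lib[[cls_cycle[j]]]))),
                        collapse = "")
          substr(chrom, iv[1], iv[2]) <- substr(tile, 1L, w)
        }
        beds[[sp]] <<- tibble::tibble(
          species = sp, chrom = "chr1",
          start = vapply(plant_iv, function(iv) as.integer(iv[1]), 0L),
          end = vapply(plant_iv, function(iv) as.integer(iv[2]), 0L),
          class = cls_cycle)
      }
      g2 <- Biostrings::DNAStringSet(chrom)
      names(g2) <- names(gdat$genome)
      gdat$genome <- g2
      gdat
    })
  })
  list(genomes = out, repeats = dplyr::bind_rows(beds))
}

#' Generate synthetic mature miRNAs
#'
#' Random 22-nt RNA sequences with distinct seeds, filtered so that a
#' full-length perfect duplex scores at most `max_energy` under the
#' packaged stacking table (guaranteeing planted perfect-complement sites
#' pass the scanning cutoff).
#'
#' @param n Number of miRNAs.
#' @param seed Integer seed.
#' @param length miRNA length (nt).
#' @param max_energy Full-duplex energy ceiling (kcal/mol).
#' @return A tibble `name`, `seq`, `seed` as from [read_mirnas()].
#' @export
make_mirnas <- function(n, seed, length = 22L, max_energy = -25) {
  stacks <- load_nn_stacks()
  withr::with_seed(seed, {
    seqs <- character(0); seeds_seen <- character(0)
    while (base::length(seqs) < n) {
      s <- paste(sample(c("A", "C", "G", "U"), length, replace = TRUE),
                 collapse = "")
      sd <- substr(s, 2L, 8L)
      b <- strsplit(s, "")[[1]]
      en <- sum(stacks[paste0(b[-length], b[-1])])
      if (en <= max_energy && !sd %in% seeds_seen) {
        seqs <- c(seqs, s); seeds_seen <- c(seeds_seen, sd)
      }
    }
    tibble::tibble(name = sprintf("mir-%03d", seq_len(n)), seq = seqs,
                   seed = substr(seqs, 2L, 8L))
  })
}

# Remove every seed-complement occurrence of the given miRNAs from a DNA
# sequence by point mutation, leaving the protected intervals untouched.
scrub_seed_matches <- function(seq, mirnas, protected = NULL,
                               max_iter = 100L) {
  prot <- if (is.null(protected) || nrow(protected) == 0L) NULL else
    IRanges::IRanges(protected$start, protected$end)
  pats <- vapply(mirnas$seq, function(m)
    rna_revcomp_dna(substr(m, 2L, 8L)), "")
  for (iter in seq_len(max_iter)) {
    dirty <- FALSE
    for (p in pats) {
      hits <- stringr::str_locate_all(seq, stringr::fixed(p))[[1]]
      if (!nrow(hits)) next
      for (h in seq_len(nrow(hits))) {
        iv <- IRanges::IRanges(hits[h, 1], hits[h, 2])
        if (!is.null(prot) &&
            sum(IRanges::countOverlaps(iv, prot)) > 0) next
        pos <- hits[h, 1] + 3L
        cur <- substr(seq, pos, pos)
        substr(seq, pos, pos) <- setdiff(c("A", "C", "G", "T"), cur)[
          sample.int(3L, 1L)]
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }
  seq
}

#' Plant perfect-complement miRNA target sites into UTR sequences
#'
#' Overwrites `counts[i]` non-overlapping windows of each UTR with the
#' reverse complement of a randomly chosen miRNA (full length, so seed plus
#' extension are perfectly paired and the duplex energy is far below the
#' -20 kcal/mol cutoff), then scrubs any accidental seed matches outside
#' the planted windows so the truth table is exhaustive. UTRs too short
#' for their requested count get as many sites as fit, with a warning.
#'
#' @param utrs Named character vector of UTR sequences (DNA).
#' @param mirnas miRNA tibble ([make_mirnas()] or [read_mirnas()]).
#' @param counts Integer vector of planted site counts, one per UTR.
#' @param seed Integer seed.
#' @return A list: `utrs` (modified sequences) and `truth` (tibble
#'   `utr_id`, `mirna`, `start`, `end` of each planted window).
#' @export
plant_mirna_sites <- function(utrs, mirnas, counts, seed) {
  stopifnot(length(utrs) == length(counts), !is.null(names(utrs)))
  withr::with_seed(seed, {
    truth <- list()
    out <- utrs
    for (i in seq_along(utrs)) {
      useq <- utrs[[i]]
      L <- nchar(useq)
      k <- counts[i]
      placed <- tibble::tibble(start = integer(), end = integer(),
                               mirna = character())
      if (k > 0) {
        wlen <- nchar(mirnas$seq[1])
        # non-overlapping windows with 1-nt gaps so neighboring duplexes
        # cannot merge
        slots <- floor((L + 1) / (wlen + 1))
        if (slots < k) {
          warning(sprintf("UTR %s too short for %d sites; planting %d",
                          names(utrs)[i], k, slots))
          k <- slots
        }
        if (k > 0) {
          chosen <- sort(sample.int(slots, k))
          mi <- sample.int(nrow(mirnas), k, replace = TRUE)
          for (j in seq_len(k)) {
            s <- (chosen[j] - 1L) * (wlen + 1L) + 1L
            site <- rna_revcomp_dna(mirnas$seq[mi[j]])
            substr(useq, s, s + wlen - 1L) <- site
            placed <- dplyr::bind_rows(placed, tibble::tibble(
              start = s, end = s + wlen - 1L, mirna = mirnas$name[mi[j]]))
          }
        }
      }
      useq <- scrub_seed_matches(useq, mirnas, protected = placed)
      out[[i]] <- useq
      if (nrow(placed))
        truth[[length(truth) + 1L]] <- dplyr::mutate(
          placed, utr_id = names(utrs)[i], .before = 1L)
    }
    truth <- if (length(truth)) dplyr::bind_rows(truth) else
      tibble::tibble(utr_id = character(), start = integer(),
                     end = integer(), mirna = character())
    list(utrs = out, truth = truth)
  })
}

#' Generate a BLAST-like similarity table with planted gene families
#'
#' Every family has one gene per species (except species listed in
#' `duplicated_species`, which get a second copy, and `missing_species`,
#' which get none). Within-family cross-species hits are strong and split
#' into two colinear HSPs to exercise chaining; between-family noise hits
#' are weak. E-values are consistent with bit scores.
#'
#' @param n_families Number of planted families.
#' @param species Character vector of species names.
#' @param seed Integer seed.
#' @param gene_ids Optional family basenames (length `n_families`); gene
#'   ids are `<species>|<basename>`. Defaults to `fam1`, `fam2`, ...
#' @param duplicated_species Named list: family index -> species with a
#'   duplicate (optional).
#' @param missing_species Named list: family index -> species missing from
#'   that family (optional).
#' @param noise_edges Number of weak between-family hits.
#' @return A list: `blast` (12-column tibble in outfmt-6 order), `truth`
#'   (tibble `gene_id`, `species`, `family_id`).
#' @export
make_similarity_table <- function(n_families, species, seed,
                                  gene_ids = NULL,
                                  duplicated_species = list(),
                                  missing_species = list(),
                                  noise_edges = 2L * n_families) {
  stopifnot(length(species) >= 2L)
  if (is.null(gene_ids)) gene_ids <- paste0("fam", seq_len(n_families))
  stopifnot(length(gene_ids) == n_families)
  withr::with_seed(seed, {
    truth <- list(); genes_by_fam <- list()
    fam_of_gene <- character(0)
    for (f in seq_len(n_families)) {
      fam <- sprintf("FAM%05d", f)
      sp_here <- setdiff(species, missing_species[[as.character(f)]])
      g <- paste0(sp_here, "|", gene_ids[f])
      sp_of_g <- sp_here
      dup_sp <- duplicated_species[[as.character(f)]]
      if (!is.null(dup_sp)) {
        g <- c(g, paste0(dup_sp, "|", gene_ids[f], "b"))
        sp_of_g <- c(sp_of_g, dup_sp)
      }
      genes_by_fam[[f]] <- g
      fam_of_gene[g] <- fam
      truth[[f]] <- tibble::tibble(gene_id = g, species = sp_of_g,
                                   family_id = fam)
    }
    mk_row <- function(q, s, qs, qe, ss, se, bits, ev) {
      tibble::tibble(query = q, subject = s, pident = 90, length = qe - qs + 1,
                     mismatch = 5, gapopen = 0, qstart = qs, qend = qe,
                     sstart = ss, send = se, evalue = ev, bitscore = bits)
    }
    rows <- list()
    for (f in seq_len(n_families)) {
      g <- genes_by_fam[[f]]
      if (length(g) < 2L) next
      prs <- utils::combn(g, 2L)
      for (cidx in seq_len(ncol(prs))) {
        b1 <- 120 + runif(1, -10, 10); b2 <- 90 + runif(1, -10, 10)
        rows[[length(rows) + 1L]] <- dplyr::bind_rows(
          mk_row(prs[1, cidx], prs[2, cidx], 1, 100, 1, 100, b1, 1e-60),
          mk_row(prs[1, cidx], prs[2, cidx], 150, 250, 150, 250, b2, 1e-40))
      }
    }
    all_genes <- unlist(genes_by_fam)
    for (e in seq_len(noise_edges)) {
      gq <- sample(all_genes, 1L); gs <- sample(all_genes, 1L)
      if (gq == gs) next
      if (fam_of_gene[gq] == fam_of_gene[gs]) next
      rows[[length(rows) + 1L]] <- mk_row(gq, gs, 1, 40, 1, 40,
                                          8 + runif(1, 0, 4), 1e-12)
    }
    list(blast = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth))
  })
}

#' Assign annotation terms to genes with an optional planted enrichment
#'
#' Each background term annotates every gene independently at the baseline
#' frequency. The planted term annotates genes of the designated top set
#' at `planted_freq` and all other genes at the baseline frequency.
#'
#' @param genes Character vector: the gene universe.
#' @param n_terms Number of background terms.
#' @param baseline_freq Baseline annotation frequency.
#' @param planted_term Term id of the planted term (`NULL` for none).
#' @param planted_genes Genes in which the planted term is enriched.
#' @param planted_freq Planted term frequency inside `planted_genes`.
#' @param seed Integer seed.
#' @return A tibble `gene_id`, `term_id`, `term_name`, `category`.
#' @export
assign_terms <- function(genes, n_terms = 50, baseline_freq = 0.05,
                         planted_term = NULL, planted_genes = character(),
                         planted_freq = 0.4, seed) {
  stopifnot(baseline_freq >= 0, baseline_freq <= 1,
            planted_freq >= 0, planted_freq <= 1)
  withr::with_seed(seed, {
    cats <- c("CC", "BP", "MF", "pathway")
    rows <- purrr::map(seq_len(n_terms), function(t) {
      tid <- sprintf("TERM:%04d", t)
      hit <- genes[runif(length(genes)) < baseline_freq]
      if (!length(hit)) return(NULL)
      tibble::tibble(gene_id = hit, term_id = tid,
                     term_name = paste0("synthetic term ", t),
                     category = cats[(t - 1L) %% 4L + 1L])
    })
    out <- dplyr::bind_rows(rows)
    if (!is.null(planted_term)) {
      in_top <- genes %in% planted_genes
      p <- ifelse(in_top, planted_freq, baseline_freq)
      hit <- genes[runif(length(genes)) < p]
      out <- dplyr::bind_rows(out, tibble::tibble(
        gene_id = hit, term_id = planted_term,
        term_name = "planted enriched term", category = "BP"))
    }
    dplyr::arrange(out, .data$term_id, .data$gene_id)
  })
}
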