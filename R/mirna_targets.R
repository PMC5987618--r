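#' Read mature miRNA sequences from FASTA
#'
#' Sequences are stored 5' to 3' in the RNA alphabet (T is converted to U).
#' Entries shorter than 8 nt or containing characters outside ACGU are
#' rejected with a message. The seed is positions 2-8 (7 nt).
#'
#' @param path FASTA file of mature miRNA sequences.
#' @param quiet Suppress the rejection message.
#' @return A tibble `name`, `seq` (RNA), `seed` (positions 2-8).
#' @export
read_mirnas <- function(path, quiet = FALSE) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- chartr("t", "u", chartr("T", "U", toupper(as.character(ss))))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  ok <- nchar(seqs) >= 8L & !grepl("[^ACGU]", seqs)
  if (any(!ok) && !quiet)
    rlang::inform(sprintf("read_mirnas: rejected %d invalid entr(ies)",
                          sum(!ok)))
  tibble::tibble(name = names(seqs)[ok], seq = unname(seqs[ok]),
                 seed = substr(unname(seqs[ok]), 2L, 8L))
}

#' Load the Watson-Crick nearest-neighbor stacking table
#'
#' Free energies (Delta-G at 37 C, kcal/mol) for the 16 Watson-Crick
#' dinucleotide stacks, keyed by the top-strand (miRNA, 5' to 3') dimer,
#' shipped as a TSV data file with the package. A table missing any of the
#' 16 stacks is a fatal configuration error.
#'
#' @param path Path to a stack table TSV (`dimer`, `dg37`); defaults to the
#'   packaged table.
#' @return Named numeric vector of length 16.
#' @export
load_nn_stacks <- function(path = system.file("extdata",
                                              "rna_stack_dg37.tsv",
                                              package = "utr3evo")) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stacks <- stats::setNames(tbl$dg37, tbl$dimer)
  need <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                          paste0))
  missing <- setdiff(need, names(stacks))
  if (length(missing))
    stop("stack table is missing entries: ", paste(missing, collapse = ", "))
  stacks
}

# Reverse complement of an RNA string, returned as DNA (for matching
# against UTR sequence).
rna_revcomp_dna <- function(rna) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", rna))))
}

#' Find strict seed-match positions of a miRNA in a 3' UTR
#'
#' Returns every UTR position (1-based, sense strand) where the UTR
#' contains the reverse complement of the miRNA seed (positions 2-8) with
#' perfect Watson-Crick pairing: no G:U wobbles, no gaps. UTR windows
#' containing ambiguity codes never match. The returned position is the
#' 5'-most UTR base of the 7-nt seed duplex (which pairs miRNA position 8).
#'
#' @param utr_seq UTR sequence, DNA alphabet, uppercase.
#' @param mirna_seq Mature miRNA sequence, RNA alphabet, 5' to 3'.
#' @return Integer vector of match start positions (possibly empty).
#' @export
seed_sites <- function(utr_seq, mirna_seq) {
  pattern <- rna_revcomp_dna(substr(mirna_seq, 2L, 8L))
  hits <- stringr::str_locate_all(utr_seq, stringr::fixed(pattern))[[1]]
  as.integer(hits[, 1])
}

# TRUE where the RNA base (miRNA) and DNA base (UTR) form a strict
# Watson-Crick pair.
wc_pair <- function(rna_base, dna_base) {
  (rna_base == "A" & dna_base == "T") |
    (rna_base == "U" & dna_base == "A") |
    (rna_base == "G" & dna_base == "C") |
    (rna_base == "C" & dna_base == "G")
}

#' Duplex free energy of a seed-anchored miRNA-UTR hybrid
#'
#' Starting from a confirmed seed match, the duplex is extended ungapped in
#' both directions (miRNA position 1, and positions 9 onward) for as long
#' as bases remain strictly Watson-Crick complementary; the first mismatch
#' terminates extension on each side. The free energy is the sum of
#' nearest-neighbor stacking terms over the maximal contiguous duplex (no
#' initiation term), so more pairing never raises the energy.
#'
#' @param utr_seq UTR sequence (DNA, uppercase).
#' @param site_start Seed match start from [seed_sites()].
#' @param mirna_seq miRNA sequence (RNA, 5' to 3').
#' @param stacks Stack table from [load_nn_stacks()].
#' @return A list: `energy` (kcal/mol), `utr_start`, `utr_end` (duplex
#'   footprint on the UTR), `mirna_span` (paired miRNA positions).
#' @export
duplex_energy <- function(utr_seq, site_start, mirna_seq,
                          stacks = load_nn_stacks()) {
  m <- strsplit(mirna_seq, "")[[1]]
  nm <- length(m)
  nu <- nchar(utr_seq)
  # miRNA position k pairs UTR position s + (8 - k)
  upos <- function(k) site_start + (8L - k)
  pairs_at <- function(k) {
    u <- upos(k)
    u >= 1L && u <= nu && wc_pair(m[k], substr(utr_seq, u, u))
  }
  hi <- 8L
  while (hi < nm && pairs_at(hi + 1L)) hi <- hi + 1L
  lo <- 2L
  if (pairs_at(1L)) lo <- 1L
  ks <- lo:(hi - 1L)
  dimers <- paste0(m[ks], m[ks + 1L])
  list(energy = sum(stacks[dimers]),
       utr_start = upos(hi), utr_end = upos(lo),
       mirna_span = c(lo, hi))
}

#' Scan 3' UTRs for miRNA target sites
#'
#' For every UTR x miRNA combination, finds strict seed matches
#' ([seed_sites()]), scores each by duplex free energy ([duplex_energy()]),
#' keeps sites at or below the energy cutoff, and greedily collapses
#' overlapping sites of the same miRNA left to right. Per-UTR counts sum
#' over miRNAs.
#'
#' @param utrs Named character vector (or [Biostrings::DNAStringSet]) of
#'   UTR sequences, DNA alphabet.
#' @param mirnas miRNA tibble from [read_mirnas()].
#' @param energy_cutoff Maximum duplex free energy retained, kcal/mol
#'   (default -20).
#' @param stacks Stack table (defaults to the packaged one).
#' @return A list with `sites` (tibble `utr_id`, `start`, `end`, `mirna`,
#'   `energy`) and `counts` (tibble `utr_id`, `n_sites`, one row per input
#'   UTR including zero-count UTRs).
#' @export
scan_utrs <- function(utrs, mirnas, energy_cutoff = -20,
                      stacks = load_nn_stacks()) {
  if (methods::is(utrs, "XStringSet")) {
    utrs <- stats::setNames(as.character(utrs), names(utrs))
  }
  stopifnot(length(utrs) >= 1L, nrow(mirnas) >= 1L,
            !is.null(names(utrs)))
  utrs <- toupper(utrs)
  sites <- purrr::imap(utrs, function(useq, uid) {
    if (nchar(useq) == 0L) return(NULL)
    per_mirna <- purrr::pmap(mirnas[, c("name", "seq")],
                             function(name, seq) {
      starts <- seed_sites(useq, seq)
      if (!length(starts)) return(NULL)
      rows <- purrr::map(starts, function(s) {
        de <- duplex_energy(useq, s, seq, stacks)
        tibble::tibble(utr_id = uid, start = de$utr_start,
                       end = de$utr_end, mirna = name, energy = de$energy)
      })
      hits <- dplyr::bind_rows(rows) |>
        dplyr::filter(.data$energy <= energy_cutoff) |>
        dplyr::arrange(.data$start)
      if (nrow(hits) < 2L) return(hits)
      # greedy left-to-right collapse of overlapping sites of this miRNA
      keep <- logical(nrow(hits))
      last_end <- -Inf
      for (i in seq_len(nrow(hits))) {
        if (hits$start[i] > last_end) {
          keep[i] <- TRUE
          last_end <- hits$end[i]
        }
      }
      hits[keep, ]
    })
    dplyr::bind_rows(per_mirna)
  })
  sites <- dplyr::bind_rows(sites)
  if (nrow(sites) == 0L)
    sites <- tibble::tibble(utr_id = character(), start = integer(),
                            end = integer(), mirna = character(),
                            energy = numeric())
  counts <- tibble::tibble(utr_id = names(utrs)) |>
    dplyr::left_join(dplyr::count(sites, .data$utr_id, name = "n_sites"),
                     by = "utr_id") |>
    dplyr::mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L))
  list(sites = sites, counts = counts)
}

#' Summarize predicted target counts
#'
#' The mean is taken over target-bearing UTRs only (UTRs with at least one
#' site), matching per-species reporting of targets per 3' UTR; with no
#' target-bearing UTRs the mean is `NA`.
#'
#' @param counts Tibble `utr_id`, `n_sites` from [scan_utrs()].
#' @return One-row tibble: `n_utrs`, `n_with_sites`, `total_sites`,
#'   `mean_sites_per_target_utr`.
#' @export
summarize_targets <- function(counts) {
  with_sites <- counts$n_sites[counts$n_sites > 0]
  tibble::tibble(
    n_utrs = nrow(counts),
    n_with_sites = length(with_sites),
    total_sites = sum(counts$n_sites),
    mean_sites_per_target_utr =
      if (length(with_sites)) mean(with_sites) else NA_real_)
}
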