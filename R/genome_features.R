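#' Read a genome FASTA into a DNAStringSet
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that strips FASTA
#' description lines down to the sequence identifier, so chromosome names
#' match the first column of a GFF3 file.
#'
#' @param path Path to a (multi-record, any line wrap) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by sequence id.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Parse transcript models from a GFF3 annotation
#'
#' Reads gene/mRNA/exon/CDS records and assembles one transcript model per
#' mRNA: its exon set, CDS genomic span, spliced CDS length, and whether the
#' spliced CDS ends in a stop codon (TAA/TAG/TGA; the annotated CDS is
#' assumed to include the stop codon). Transcripts violating structural
#' invariants are rejected record-by-record with a logged reason; a
#' malformed file is a fatal error.
#'
#' Rejection reasons: missing parent link, no exons, no CDS, overlapping
#' exons, CDS outside the exon union, CDS length not a multiple of 3,
#' unknown chromosome, exon beyond chromosome end.
#'
#' @param gff Path to a GFF3 file.
#' @param genome A [Biostrings::DNAStringSet] (see [read_genome()]) or a
#'   FASTA path. Required to check stop codons and chromosome bounds.
#' @param quiet Suppress the rejection-count message.
#' @return A tibble with one row per accepted transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `exons` (list column of tibbles with
#'   1-based inclusive `start`, `end`), `cds_start`, `cds_end`, `cds_len`
#'   (spliced, nt), `has_stop`. Rejected records are attached as a tibble in
#'   `attr(, "rejected")`.
#' @export
read_transcript_models <- function(gff, genome, quiet = FALSE) {
  if (is.character(genome)) genome <- read_genome(genome)
  gr <- rtracklayer::import(gff)
  type <- as.character(gr$type)
  first_parent <- function(p) {
    vapply(as.list(p), function(x) if (length(x)) x[[1]] else NA_character_,
           character(1))
  }
  is_tx <- type %in% c("mRNA", "transcript")
  tx <- tibble::tibble(
    transcript_id = as.character(gr$ID[is_tx]),
    gene_id = first_parent(gr$Parent[is_tx]),
    chrom = as.character(GenomicRanges::seqnames(gr))[is_tx],
    strand = as.character(GenomicRanges::strand(gr))[is_tx]
  )
  sub_tbl <- function(keep) {
    tibble::tibble(
      parent = first_parent(gr$Parent[keep]),
      start = GenomicRanges::start(gr)[keep],
      end = GenomicRanges::end(gr)[keep]
    )
  }
  exons <- sub_tbl(type == "exon")
  cds <- sub_tbl(type == "CDS")

  rejected <- list()
  reject <- function(id, reason) {
    rejected[[length(rejected) + 1]] <<- tibble::tibble(
      transcript_id = id, reason = reason)
    NULL
  }
  rows <- purrr::pmap(tx, function(transcript_id, gene_id, chrom, strand) {
    if (is.na(gene_id))
      return(reject(transcript_id, "missing gene parent"))
    ex <- dplyr::arrange(
      exons[exons$parent == transcript_id, c("start", "end")], .data$start)
    cd <- cds[cds$parent == transcript_id, , drop = FALSE]
    if (nrow(ex) == 0L) return(reject(transcript_id, "no exons"))
    if (nrow(cd) == 0L) return(reject(transcript_id, "no CDS"))
    if (any(ex$end < ex$start) ||
        (nrow(ex) > 1L && any(ex$start[-1] <= ex$end[-nrow(ex)])))
      return(reject(transcript_id, "exons overlap or are inverted"))
    if (!chrom %in% names(genome))
      return(reject(transcript_id, "unknown chromosome"))
    if (max(ex$end) > length(genome[[chrom]]))
      return(reject(transcript_id, "exon beyond chromosome end"))
    cds_start <- min(cd$start); cds_end <- max(cd$end)
    # CDS span must sit inside the exon union
    covered <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
    cds_ir <- IRanges::IRanges(cd$start, cd$end)
    if (sum(IRanges::width(IRanges::intersect(cds_ir, covered))) !=
        sum(IRanges::width(IRanges::reduce(cds_ir))))
      return(reject(transcript_id, "CDS outside exons"))
    cds_len <- sum(IRanges::width(IRanges::reduce(cds_ir)))
    if (cds_len %% 3L != 0L)
      return(reject(transcript_id, "CDS length not a multiple of 3"))
    cds_seq <- spliced_seq(genome, chrom, strand, cd$start, cd$end)
    last_codon <- substr(cds_seq, nchar(cds_seq) - 2L, nchar(cds_seq))
    tibble::tibble(
      transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
      strand = strand, exons = list(ex),
      cds_start = cds_start, cds_end = cds_end, cds_len = cds_len,
      has_stop = last_codon %in% c("TAA", "TAG", "TGA"))
  })
  out <- dplyr::bind_rows(rows)
  rej <- if (length(rejected)) dplyr::bind_rows(rejected) else
    tibble::tibble(transcript_id = character(), reason = character())
  if (nrow(rej) > 0 && !quiet)
    rlang::inform(sprintf(
      "read_transcript_models: rejected %d transcript(s): %s",
      nrow(rej), paste(unique(rej$reason), collapse = "; ")))
  attr(out, "rejected") <- rej
  out
}

# Spliced sense-strand sequence of a set of exonic intervals.
spliced_seq <- function(genome, chrom, strand, starts, ends) {
  o <- order(starts)
  pieces <- Biostrings::DNAStringSet(lapply(seq_along(o), function(i) {
    Biostrings::subseq(genome[[chrom]], starts[o[i]], ends[o[i]])
  }))
  s <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Select the canonical transcript of each gene
#'
#' The canonical transcript is the stop-codon-bearing isoform with the
#' longest spliced coding region; isoforms without a terminal stop codon
#' are removed first, and genes left with none are dropped. Equal CDS
#' lengths are broken by the lexicographically smallest transcript id so
#' the choice is deterministic and independent of input order.
#'
#' @param models Transcript tibble from [read_transcript_models()].
#' @return A tibble with one row per gene (same columns as `models`).
#' @export
select_canonical <- function(models) {
  models |>
    dplyr::filter(.data$has_stop) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(dplyr::desc(.data$cds_len), .data$transcript_id,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene_id)
}

#' Extract 5' UTR, CDS and 3' UTR sequences of transcripts
#'
#' Splices each transcript's exons, orients the result 5' to 3' (minus-
#' strand transcripts are reverse-complemented), and splits it at the CDS
#' boundaries. The 3' UTR is everything strictly downstream of the stop
#' codon, so `utr5_len + cds_len + utr3_len` always equals the spliced
#' transcript length.
#'
#' @param models Transcript tibble from [read_transcript_models()] (or a
#'   [select_canonical()] subset).
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @return A tibble: `transcript_id`, `gene_id`, `utr5_seq`, `cds_seq`,
#'   `utr3_seq`, `utr5_len`, `cds_len`, `utr3_len`.
#' @export
extract_features <- function(models, genome) {
  if (is.character(genome)) genome <- read_genome(genome)
  rows <- purrr::pmap(
    models[, c("transcript_id", "gene_id", "chrom", "strand", "exons",
               "cds_start", "cds_end")],
    function(transcript_id, gene_id, chrom, strand, exons, cds_start,
             cds_end) {
      if (max(exons$end) > length(genome[[chrom]]))
        stop("exon beyond chromosome end for transcript ", transcript_id)
      tx_seq <- spliced_seq(genome, chrom, strand, exons$start, exons$end)
      # genomic coordinates of each spliced position, in mRNA orientation
      pos <- unlist(purrr::map2(exons$start, exons$end, seq))
      if (strand == "-") pos <- rev(pos)
      cds_5p <- if (strand == "+") cds_start else cds_end
      cds_3p <- if (strand == "+") cds_end else cds_start
      c1 <- match(cds_5p, pos); c2 <- match(cds_3p, pos)
      n <- length(pos)
      tibble::tibble(
        transcript_id = transcript_id, gene_id = gene_id,
        utr5_seq = substr(tx_seq, 1L, c1 - 1L),
        cds_seq = substr(tx_seq, c1, c2),
        utr3_seq = if (c2 < n) substr(tx_seq, c2 + 1L, n) else "",
        utr5_len = c1 - 1L, cds_len = c2 - c1 + 1L, utr3_len = n - c2)
    })
  dplyr::bind_rows(rows)
}

#' Histogram of feature lengths in fixed windows
#'
#' Bins are half-open and lower-inclusive: bin *i* counts lengths in
#' `[i * window, (i + 1) * window)`, so a length exactly on a boundary
#' falls in the upper bin. The total count always equals the input size.
#'
#' @param lengths Non-negative integer lengths (nt).
#' @param window Bin width in nt (default 50).
#' @return A tibble `bin_start`, `bin_end` (exclusive), `count`, covering
#'   bin 0 through the bin of the maximum length; empty input gives an
#'   empty tibble.
#' @export
length_histogram <- function(lengths, window = 50) {
  stopifnot(window > 0)
  if (any(lengths < 0)) stop("negative lengths are not allowed")
  if (length(lengths) == 0L)
    return(tibble::tibble(bin_start = numeric(), bin_end = numeric(),
                          count = integer()))
  bin <- lengths %/% window
  counts <- tabulate(bin + 1L, nbins = max(bin) + 1L)
  tibble::tibble(
    bin_start = (seq_along(counts) - 1L) * window,
    bin_end = seq_along(counts) * window,
    count = counts)
}

#' Summary statistics of feature lengths
#'
#' Reports the total feature length, its percentage of the genome, and
#' location statistics of the per-gene length distribution. Quantiles use
#' linear interpolation (R's default type 7).
#'
#' @param lengths Non-negative lengths (nt); must be non-empty.
#' @param genome_size Genome size in nt.
#' @return One-row tibble: `n`, `total_nt`, `pct_genome`, `mean_len`,
#'   `median_len`, `q25`, `q75`, `max_len`.
#' @export
summarize_lengths <- function(lengths, genome_size) {
  if (length(lengths) == 0L) stop("empty length vector")
  stopifnot(genome_size > 0)
  tibble::tibble(
    n = length(lengths),
    total_nt = sum(lengths),
    pct_genome = 100 * sum(lengths) / genome_size,
    mean_len = mean(lengths),
    median_len = stats::median(lengths),
    q25 = unname(stats::quantile(lengths, 0.25)),
    q75 = unname(stats::quantile(lengths, 0.75)),
    max_len = max(lengths))
}

#' Write a sequence column of a feature table as FASTA
#'
#' @param features Tibble from [extract_features()].
#' @param file Output FASTA path.
#' @param column Which sequence column to write (default `utr3_seq`).
#' @param id_column Column used for FASTA headers (default `gene_id`).
#' @return `file`, invisibly.
#' @export
write_feature_fasta <- function(features, file, column = "utr3_seq",
                                id_column = "gene_id") {
  keep <- nchar(features[[column]]) > 0L
  seqs <- Biostrings::DNAStringSet(features[[column]][keep])
  names(seqs) <- features[[id_column]][keep]
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}
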