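test_that("a single-gene GFF3 round-trips into a matching transcript model", {
  chrom <- toy_chrom()
  fa <- write_toy_fasta(list(chr1 = chrom))
  models <- read_transcript_models(plus_gene_gff(), fa, quiet = TRUE)
  expect_equal(nrow(models), 1L)
  expect_equal(models$transcript_id, "tA1")
  expect_equal(models$gene_id, "geneA")
  expect_equal(models$cds_start, 21)
  expect_equal(models$cds_end, 80)
  expect_equal(models$cds_len, 60)
  expect_true(models$has_stop)
  expect_equal(models$exons[[1]]$start, 1)
  expect_equal(models$exons[[1]]$end, 100)
})

test_that("structurally invalid transcripts are rejected with a reason", {
  fa <- write_toy_fasta(list(chr1 = toy_chrom()))
  # CDS length 59: not a multiple of 3
  gff <- write_toy_gff(list(
    gff_row("gene", 1, 100, "+", "ID=geneA"),
    gff_row("mRNA", 1, 100, "+", "ID=tA1;Parent=geneA"),
    gff_row("exon", 1, 100, "+", "Parent=tA1"),
    gff_row("CDS", 21, 79, "+", "Parent=tA1")))
  models <- read_transcript_models(gff, fa, quiet = TRUE)
  expect_equal(nrow(models), 0L)
  rej <- attr(models, "rejected")
  expect_equal(rej$transcript_id, "tA1")
  expect_match(rej$reason, "multiple of 3")

  # CDS outside the exon union and an unknown chromosome
  gff2 <- write_toy_gff(list(
    gff_row("gene", 1, 100, "+", "ID=geneB"),
    gff_row("mRNA", 1, 100, "+", "ID=tB1;Parent=geneB"),
    gff_row("exon", 1, 50, "+", "Parent=tB1"),
    gff_row("CDS", 40, 81, "+", "Parent=tB1"),
    gff_row("gene", 1, 100, "+", "ID=geneC", chrom = "chrX"),
    gff_row("mRNA", 1, 100, "+", "ID=tC1;Parent=geneC", chrom = "chrX"),
    gff_row("exon", 1, 100, "+", "Parent=tC1", chrom = "chrX"),
    gff_row("CDS", 21, 80, "+", "Parent=tC1", chrom = "chrX")))
  models2 <- read_transcript_models(gff2, fa, quiet = TRUE)
  expect_equal(nrow(models2), 0L)
  expect_setequal(attr(models2, "rejected")$reason,
                  c("CDS outside exons", "unknown chromosome"))
})

test_that("isoforms of one gene are grouped under the same gene id", {
  fa <- write_toy_fasta(list(chr1 = toy_chrom()))
  gff <- write_toy_gff(list(
    gff_row("gene", 1, 100, "+", "ID=geneA"),
    gff_row("mRNA", 1, 100, "+", "ID=tA1;Parent=geneA"),
    gff_row("exon", 1, 100, "+", "Parent=tA1"),
    gff_row("CDS", 21, 80, "+", "Parent=tA1"),
    gff_row("mRNA", 1, 100, "+", "ID=tA2;Parent=geneA"),
    gff_row("exon", 1, 100, "+", "Parent=tA2"),
    gff_row("CDS", 51, 80, "+", "Parent=tA2")))
  models <- read_transcript_models(gff, fa, quiet = TRUE)
  expect_equal(nrow(models), 2L)
  expect_equal(unique(models$gene_id), "geneA")
})

test_that("canonical selection follows the longest-stop-bearing-CDS rule", {
  base <- tibble::tibble(
    gene_id = "g", chrom = "chr1", strand = "+",
    exons = list(tibble::tibble(start = 1, end = 1000)),
    cds_start = 1, cds_end = 1)
  mk <- function(ids, lens, stops) dplyr::bind_rows(lapply(
    seq_along(ids), function(i) dplyr::mutate(
      base, transcript_id = ids[i], cds_len = lens[i],
      has_stop = stops[i])))

  expect_equal(select_canonical(mk(c("t1", "t2"), c(300, 452),
                                   c(TRUE, TRUE)))$transcript_id, "t2")
  expect_equal(select_canonical(mk(c("t1", "t2"), c(600, 300),
                                   c(FALSE, TRUE)))$transcript_id, "t2")
  expect_equal(select_canonical(mk(c("tB", "tA"), c(300, 300),
                                   c(TRUE, TRUE)))$transcript_id, "tA")
  # no stop-bearing isoform: gene dropped
  expect_equal(nrow(select_canonical(mk("t1", 600, FALSE))), 0L)
  # deterministic under permutation of isoform input order
  m <- mk(c("t3", "t1", "t2"), c(300, 452, 452), c(TRUE, TRUE, TRUE))
  for (perm in list(1:3, 3:1, c(2, 3, 1)))
    expect_equal(select_canonical(m[perm, ])$transcript_id, "t1")
})

test_that("feature extraction splits the spliced transcript at the CDS", {
  chrom <- toy_chrom()
  fa <- write_toy_fasta(list(chr1 = chrom))
  models <- read_transcript_models(plus_gene_gff(), fa, quiet = TRUE)
  feats <- extract_features(models, fa)
  expect_equal(feats$utr5_len, 20L)
  expect_equal(feats$cds_len, 60L)
  expect_equal(feats$utr3_len, 20L)
  expect_equal(feats$utr5_seq, substr(chrom, 1, 20))
  expect_equal(feats$cds_seq, substr(chrom, 21, 80))
  expect_equal(feats$utr3_seq, substr(chrom, 81, 100))
})

test_that("minus-strand features are reverse-complemented correctly", {
  chrom <- toy_chrom()
  fa <- write_toy_fasta(list(chr1 = chrom))
  gff <- write_toy_gff(list(
    gff_row("gene", 1, 100, "-", "ID=geneA"),
    gff_row("mRNA", 1, 100, "-", "ID=tA1;Parent=geneA"),
    gff_row("exon", 1, 100, "-", "Parent=tA1"),
    gff_row("CDS", 21, 80, "-", "Parent=tA1")))
  models <- read_transcript_models(gff, fa, quiet = TRUE)
  expect_true(models$has_stop)  # TTA at 21-23 reads TAA on the minus strand
  feats <- extract_features(models, fa)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(feats$utr3_seq, rc(substr(chrom, 1, 20)))
  expect_equal(feats$utr5_seq, rc(substr(chrom, 81, 100)))
  expect_equal(feats$utr5_len + feats$cds_len + feats$utr3_len, 100L)
})

test_that("an intron inside the 3' UTR is spliced out of the feature", {
  chrom <- fixed_dna(140, seed = 7)
  substr(chrom, 38, 40) <- "TGA"
  fa <- write_toy_fasta(list(chr1 = chrom))
  gff <- write_toy_gff(list(
    gff_row("gene", 1, 140, "+", "ID=geneA"),
    gff_row("mRNA", 1, 140, "+", "ID=tA1;Parent=geneA"),
    gff_row("exon", 1, 60, "+", "Parent=tA1"),
    gff_row("exon", 81, 140, "+", "Parent=tA1"),
    gff_row("CDS", 11, 40, "+", "Parent=tA1")))
  models <- read_transcript_models(gff, fa, quiet = TRUE)
  feats <- extract_features(models, fa)
  # independent manual splice
  expected_utr3 <- paste0(substr(chrom, 41, 60), substr(chrom, 81, 140))
  expect_equal(feats$utr3_seq, expected_utr3)
  expect_equal(feats$utr3_len, 80L)
  expect_equal(feats$utr5_len + feats$cds_len + feats$utr3_len,
               60L + 60L)
})

test_that("length histograms use half-open lower-inclusive 50-nt bins", {
  h <- length_histogram(0:49)
  expect_equal(nrow(h), 1L)
  expect_equal(h$count, 50L)
  h2 <- length_histogram(c(10, 50))
  expect_equal(h2$count, c(1L, 1L))
  expect_equal(h2$bin_start, c(0, 50))
  expect_equal(nrow(length_histogram(integer(0))), 0L)
  expect_error(length_histogram(c(-1, 5)), "negative")
  # totals preserved for any window
  withr::with_seed(1, {
    for (w in c(1, 7, 50, 211)) {
      x <- sample.int(2000, 300, replace = TRUE)
      expect_equal(sum(length_histogram(x, window = w)$count), 300L)
    }
  })
})

test_that("length summaries match an independent quantile oracle", {
  s <- summarize_lengths(c(1, 2, 3), genome_size = 100)
  expect_equal(s$total_nt, 6)
  expect_equal(s$mean_len, 2)
  expect_equal(s$median_len, 2)
  expect_equal(s$pct_genome, 6.0)

  s2 <- summarize_lengths(rep(7, 10), genome_size = 1000)
  expect_equal(c(s2$q25, s2$median_len, s2$q75, s2$max_len),
               c(7, 7, 7, 7))

  x <- 1:100
  s3 <- summarize_lengths(x, genome_size = 1e6)
  expect_equal(s3$q25, manual_quantile(x, 0.25))
  expect_equal(s3$q75, manual_quantile(x, 0.75))
  expect_true(s3$q25 <= s3$median_len && s3$median_len <= s3$q75 &&
                s3$q75 <= s3$max_len)
  expect_error(summarize_lengths(numeric(0), 100), "empty")
})
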