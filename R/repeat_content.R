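#' Read a repeat annotation into a normalized interval table
#'
#' Supports two dialects, chosen explicitly by `format` (never sniffed):
#' RepeatMasker `.out` (fixed whitespace columns, 1-based inclusive, with
#' its 3-line header) and BED (0-based half-open). Both are normalized to
#' 1-based inclusive coordinates.
#'
#' @param path Input file.
#' @param format `"bed"` or `"rmout"`.
#' @return A tibble `chrom`, `start`, `end` (1-based inclusive), `class`
#'   (repeat class/family label, `NA` if absent).
#' @export
read_repeats <- function(path, format = c("bed", "rmout")) {
  format <- match.arg(format)
  if (format == "bed") {
    bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
    tibble::tibble(
      chrom = as.character(bed[[1]]),
      start = as.integer(bed[[2]]) + 1L,
      end = as.integer(bed[[3]]),
      class = if (ncol(bed) >= 4) as.character(bed[[4]]) else NA_character_)
  } else {
    lines <- readr::read_lines(path)
    lines <- lines[-seq_len(min(3L, length(lines)))]  # header block
    lines <- lines[nzchar(trimws(lines))]
    f <- strsplit(trimws(lines), "\\s+")
    tibble::tibble(
      chrom = vapply(f, `[`, "", 5L),
      start = as.integer(vapply(f, `[`, "", 6L)),
      end = as.integer(vapply(f, `[`, "", 7L)),
      class = vapply(f, function(x) if (length(x) >= 11) x[11] else
        NA_character_, ""))
  }
}

#' Merge intervals on one chromosome into a disjoint set
#'
#' Union of 1-based inclusive intervals; output is sorted and disjoint and
#' covers exactly the same bases.
#'
#' @param intervals Tibble with `start`, `end` columns (one chromosome).
#' @return A tibble `start`, `end`, sorted and disjoint.
#' @export
merge_intervals <- function(intervals) {
  if (any(intervals$end < intervals$start)) stop("inverted interval")
  if (nrow(intervals) == 0L)
    return(tibble::tibble(start = integer(), end = integer()))
  r <- IRanges::reduce(IRanges::IRanges(intervals$start, intervals$end))
  tibble::tibble(start = IRanges::start(r), end = IRanges::end(r))
}

# Per-chromosome IRangesList from a chrom/start/end tibble.
as_ranges_by_chrom <- function(tbl) {
  split(IRanges::IRanges(tbl$start, tbl$end), tbl$chrom)
}

# Bases covered by the intersection of two chrom/start/end tables.
overlap_bases <- function(a, b) {
  ra <- as_ranges_by_chrom(a); rb <- as_ranges_by_chrom(b)
  common <- intersect(names(ra), names(rb))
  if (!length(common)) return(0)
  sum(vapply(common, function(ch) {
    sum(IRanges::width(IRanges::intersect(IRanges::reduce(ra[[ch]]),
                                          IRanges::reduce(rb[[ch]]))))
  }, 0))
}

covered_bases <- function(tbl) {
  if (nrow(tbl) == 0L) return(0)
  sum(vapply(as_ranges_by_chrom(tbl), function(r)
    sum(IRanges::width(IRanges::reduce(r))), 0))
}

#' Fraction of repeat-covered bases per genomic feature class
#'
#' Repeat intervals are merged class-agnostically, then intersected with
#' each feature class's interval set; the fraction is overlap bases over
#' feature bases. The genome row uses full chromosome lengths. Feature
#' classes with no intervals get `NA` fractions.
#'
#' @param features Named list of tibbles (`chrom`, `start`, `end`), one per
#'   feature class (e.g. `utr3`, `utr5`, `cds`), 1-based inclusive.
#' @param repeats Repeat tibble (`chrom`, `start`, `end`) as from
#'   [read_repeats()].
#' @param chrom_sizes Named numeric vector of chromosome lengths (nt).
#' @return A tibble `feature`, `feature_bases`, `repeat_bases`, `fraction`,
#'   with a `genome` row first.
#' @export
repeat_fraction <- function(features, repeats, chrom_sizes) {
  genome_tbl <- tibble::tibble(chrom = names(chrom_sizes), start = 1L,
                               end = as.integer(chrom_sizes))
  all_feats <- c(list(genome = genome_tbl), features)
  dplyr::bind_rows(purrr::imap(all_feats, function(tbl, name) {
    fb <- covered_bases(tbl)
    rb <- overlap_bases(tbl, repeats)
    tibble::tibble(feature = name, feature_bases = fb, repeat_bases = rb,
                   fraction = if (fb > 0) rb / fb else NA_real_)
  }))
}

# Exact null distribution of the Wilcoxon signed-rank statistic (sum of
# ranks of positive differences) by the generating-function recursion over
# all 2^n sign assignments; ranks may be half-integers under ties, so they
# are doubled to stay integral.
signed_rank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  probs <- 1
  offset <- 0L  # distribution over doubled rank sums starting at 0
  for (r in r2) {
    m <- length(probs)
    new <- numeric(m + r)
    new[seq_len(m)] <- probs / 2
    new[(r + 1):(r + m)] <- new[(r + 1):(r + m)] + probs / 2
    probs <- new
  }
  tibble::tibble(statistic = (seq_along(probs) - 1) / 2, prob = probs)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of paired differences `x - y`. Zero
#' differences are dropped before ranking (the classic convention).
#' For `n <= 25` retained pairs, the p-value is exact: the full null
#' distribution of the rank sum over all `2^n` sign assignments is
#' computed by a generating-function recursion (identical to literal
#' enumeration), and the two-sided p is twice the smaller tail, capped at
#' 1. Above 25 pairs a normal approximation with continuity correction and
#' tie correction is used.
#'
#' With nine pairs all deviating in the same direction the exact p is
#' 2/2^9 = 0.00390625.
#'
#' @param x,y Paired observations (e.g. per-species genome-wide and 3' UTR
#'   repeat fractions).
#' @param exact_max Largest n for which the exact distribution is used.
#' @return One-row tibble: `n_pairs` (after dropping zeros), `statistic`
#'   (rank sum of positive differences), `p_value`, `method`.
#' @export
paired_signed_rank <- function(x, y, exact_max = 25L) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero")
  rk <- rank(abs(d))
  w <- sum(rk[d > 0])
  n <- length(d)
  if (n <= exact_max) {
    null <- signed_rank_null(rk)
    lower <- sum(null$prob[null$statistic <= w + 1e-9])
    upper <- sum(null$prob[null$statistic >= w - 1e-9])
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  tibble::tibble(n_pairs = n, statistic = w, p_value = p, method = method)
}
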