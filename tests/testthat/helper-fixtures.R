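# Shared fixture builders: toy genomes/annotations written to tempfiles,
# and small deterministic sequence helpers. Everything is generated in
# code; no fixture files ship with the tests.

write_toy_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), path)
  path
}

write_toy_gff <- function(rows) {
  path <- tempfile(fileext = ".gff3")
  lines <- c("##gff-version 3",
             vapply(rows, function(r) paste(r, collapse = "\t"), ""))
  writeLines(lines, path)
  path
}

gff_row <- function(type, start, end, strand, attrs, chrom = "chr1") {
  c(chrom, "toy", type, start, end, ".", strand, ".", attrs)
}

fixed_dna <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# chr1: 100 nt, CDS 21-80 on the plus strand ends with TAA, and the
# reverse-complement layout (TTA at 21-23) supports the same span on the
# minus strand.
toy_chrom <- function() {
  s <- fixed_dna(100, seed = 42)
  substr(s, 78, 80) <- "TAA"
  substr(s, 21, 23) <- "TTA"
  s
}

plus_gene_gff <- function() {
  write_toy_gff(list(
    gff_row("gene", 1, 100, "+", "ID=geneA"),
    gff_row("mRNA", 1, 100, "+", "ID=tA1;Parent=geneA"),
    gff_row("exon", 1, 100, "+", "Parent=tA1"),
    gff_row("CDS", 21, 80, "+", "Parent=tA1")))
}

# Independent type-7 quantile: sort and linearly interpolate.
manual_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Brute-force maximum-weight colinear chain over HSP subsets (a valid
# chain, sorted by query start, must be strictly increasing and
# non-overlapping on both axes).
brute_chain_score <- function(h) {
  n <- nrow(h)
  best <- 0
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (!length(idx)) next
    sub <- h[idx[order(h$qstart[idx], h$sstart[idx])], , drop = FALSE]
    ok <- TRUE
    if (nrow(sub) > 1) {
      for (i in 2:nrow(sub)) {
        if (!(sub$qstart[i] > sub$qend[i - 1] &&
              sub$sstart[i] > sub$send[i - 1])) { ok <- FALSE; break }
      }
    }
    if (ok) best <- max(best, sum(sub$bitscore))
  }
  best
}

# Independent re-implementation of the family-merge rule for small graphs:
# average linkage over a weight matrix, candidates in descending
# between-average order (ties: lexicographically smallest pair of minimum
# member ids), accept if between-average >= ratio * internal average of
# the smaller cluster (size ties: lower internal average), merged size
# capped.
brute_cluster <- function(genes, W, min_ratio = 0.33, max_size = 1e5) {
  cl <- lapply(seq_along(genes), identity)
  int_avg <- function(ix) {
    if (length(ix) < 2) return(0)
    sum(W[ix, ix]) / (length(ix) * (length(ix) - 1))
  }
  repeat {
    if (length(cl) < 2) break
    cand <- list()
    for (a in seq_along(cl)) for (b in seq_along(cl)) {
      if (a >= b) next
      s <- sum(W[cl[[a]], cl[[b]]])
      if (s <= 0) next
      avg <- s / (length(cl[[a]]) * length(cl[[b]]))
      key <- sort(c(min(genes[cl[[a]]]), min(genes[cl[[b]]])))
      cand[[length(cand) + 1]] <- list(a = a, b = b, avg = avg,
                                       k1 = key[1], k2 = key[2])
    }
    if (!length(cand)) break
    ord <- order(-vapply(cand, `[[`, 0, "avg"),
                 vapply(cand, `[[`, "", "k1"),
                 vapply(cand, `[[`, "", "k2"))
    merged <- FALSE
    for (ci in ord) {
      a <- cand[[ci]]$a; b <- cand[[ci]]$b
      if (length(cl[[a]]) + length(cl[[b]]) > max_size) next
      ia <- int_avg(cl[[a]]); ib <- int_avg(cl[[b]])
      smaller <- if (length(cl[[a]]) != length(cl[[b]])) {
        if (length(cl[[a]]) < length(cl[[b]])) ia else ib
      } else min(ia, ib)
      if (cand[[ci]]$avg >= min_ratio * smaller) {
        cl[[a]] <- c(cl[[a]], cl[[b]]); cl[[b]] <- NULL
        merged <- TRUE; break
      }
    }
    if (!merged) break
  }
  # canonical form: sorted gene-name sets
  unname(sort(vapply(cl, function(ix) paste(sort(genes[ix]), collapse = "+"), "")))
}

partition_of <- function(fams) {
  unname(sort(vapply(split(fams$gene_id, fams$family_id),
                     function(g) paste(sort(g), collapse = "+"), "")))
}

# Literal 2^n enumeration of the signed-rank two-sided exact p-value.
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- drop(signs %*% rk)
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9),
                 mean(w_all >= w_obs - 1e-9)))
}

default_tree_painting <- function() {
  make_default_tree(simulation_config(seed = 1))
}
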