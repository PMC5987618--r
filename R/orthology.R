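#' Read a pairwise protein similarity table (BLAST tabular)
#'
#' Reads standard 12-column BLAST tabular output (outfmt 6: qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore),
#' drops HSPs above the E-value cutoff and self-hits (query equal to
#' subject), and skips malformed rows with a message.
#'
#' @param path Path to the tabular file.
#' @param evalue_cutoff Maximum E-value retained (default 1e-10).
#' @param quiet Suppress the skipped-row message.
#' @return A tibble of HSPs with columns `query`, `subject`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bitscore`.
#' @export
read_similarity <- function(path, evalue_cutoff = 1e-10, quiet = FALSE) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  hsps <- suppressWarnings(readr::read_tsv(
    path, col_names = cols, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      query = "c", subject = "c", .default = readr::col_double())))
  bad <- !stats::complete.cases(
    hsps[, c("qstart", "qend", "sstart", "send", "evalue", "bitscore")])
  if (any(bad) && !quiet)
    rlang::inform(sprintf("read_similarity: skipped %d malformed row(s)",
                          sum(bad)))
  hsps |>
    dplyr::filter(!bad,
                  .data$evalue <= evalue_cutoff,
                  .data$query != .data$subject) |>
    dplyr::select(dplyr::all_of(c("query", "subject", "qstart", "qend",
                                  "sstart", "send", "evalue", "bitscore")))
}

# Resolve overlaps among HSPs of one gene pair before chaining: HSPs are
# processed in decreasing bit-score order (ties: longer first, then query
# start); a later HSP is trimmed to its longest query/subject sub-interval
# not covered by already-kept HSPs and its score scaled by the retained
# fraction; fully shadowed HSPs are dropped.
trim_hsp_overlaps <- function(hsps) {
  h <- hsps
  # proteins: enforce forward orientation on both axes
  qs <- pmin(h$qstart, h$qend); qe <- pmax(h$qstart, h$qend)
  ss <- pmin(h$sstart, h$send); se <- pmax(h$sstart, h$send)
  o <- order(-h$bitscore, -(qe - qs), qs)
  kept <- list()
  for (i in o) {
    q <- c(qs[i], qe[i]); s <- c(ss[i], se[i])
    for (k in kept) {
      q <- clip_longest_free(q, k$q)
      s <- clip_longest_free(s, k$s)
      if (is.null(q) || is.null(s)) break
    }
    if (is.null(q) || is.null(s)) next
    frac <- min((q[2] - q[1] + 1) / (qe[i] - qs[i] + 1),
                (s[2] - s[1] + 1) / (se[i] - ss[i] + 1))
    kept[[length(kept) + 1L]] <- list(q = q, s = s,
                                      score = h$bitscore[i] * frac)
  }
  if (!length(kept))
    return(tibble::tibble(qstart = numeric(), qend = numeric(),
                          sstart = numeric(), send = numeric(),
                          bitscore = numeric()))
  tibble::tibble(
    qstart = vapply(kept, function(k) k$q[1], 0),
    qend = vapply(kept, function(k) k$q[2], 0),
    sstart = vapply(kept, function(k) k$s[1], 0),
    send = vapply(kept, function(k) k$s[2], 0),
    bitscore = vapply(kept, function(k) k$score, 0))
}

# Longest sub-interval of x (1-based inclusive c(start, end)) that does not
# intersect the blocked interval b; NULL if nothing is left.
clip_longest_free <- function(x, b) {
  if (b[2] < x[1] || b[1] > x[2]) return(x)
  left <- c(x[1], min(x[2], b[1] - 1))
  right <- c(max(x[1], b[2] + 1), x[2])
  lw <- left[2] - left[1] + 1; rw <- right[2] - right[1] + 1
  if (lw <= 0 && rw <= 0) return(NULL)
  if (lw >= rw) left else right
}

#' Conjoin the HSPs of one gene pair into a single similarity score
#'
#' Finds the maximum-weight chain of HSPs that is colinear and
#' non-overlapping in both query and subject coordinates (weight = summed
#' bit scores) by dynamic programming over HSPs sorted by query start.
#' Overlapping HSPs are first trimmed to non-overlap, the higher-scoring
#' (then longer) HSP winning. The conjoined score is therefore never below
#' the best single HSP's score.
#'
#' @param hsps Tibble of HSPs for one query/subject gene pair, with columns
#'   `qstart`, `qend`, `sstart`, `send`, `bitscore`.
#' @return The conjoined score (bits), a single number.
#' @export
conjoin_hsps <- function(hsps) {
  stopifnot(nrow(hsps) >= 1L)
  h <- trim_hsp_overlaps(hsps)
  if (nrow(h) == 0L) return(0)
  h <- dplyr::arrange(h, .data$qstart, .data$sstart)
  n <- nrow(h)
  best <- h$bitscore
  for (i in seq_len(n)) {
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      if (h$qstart[i] > h$qend[j] && h$sstart[i] > h$send[j])
        best[i] <- max(best[i], best[j] + h$bitscore[i])
    }
  }
  max(best)
}

#' Conjoined similarity scores for all gene pairs
#'
#' Applies [conjoin_hsps()] to every query/subject gene pair in an HSP
#' table, then merges the two directions of each unordered pair by taking
#' the maximum conjoined score.
#'
#' @param hsps HSP tibble from [read_similarity()].
#' @return A tibble `gene1`, `gene2` (lexicographically ordered within each
#'   row), `score`.
#' @export
pair_scores <- function(hsps) {
  hsps |>
    dplyr::group_by(.data$query, .data$subject) |>
    dplyr::summarise(score = conjoin_hsps(dplyr::pick(dplyr::everything())),
                     .groups = "drop") |>
    dplyr::mutate(gene1 = pmin(.data$query, .data$subject),
                  gene2 = pmax(.data$query, .data$subject)) |>
    dplyr::group_by(.data$gene1, .data$gene2) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop")
}

#' Cluster genes into families by hierarchical agglomeration
#'
#' Average-linkage agglomerative clustering on conjoined similarity scores.
#' Edges below `min_weight` are removed; candidate merges are considered in
#' descending order of between-cluster average similarity (the summed
#' cross-edge weight divided by the product of cluster sizes, absent edges
#' counting 0); a merge is accepted only if that average is at least
#' `min_ratio` times the internal average similarity of the smaller cluster
#' (singletons are always mergeable) and the merged size does not exceed
#' `max_size`. Ties are broken by the lexicographically smallest gene-id
#' pair, and the smaller cluster on a size tie is the one with the lower
#' internal average, so the partition is deterministic and independent of
#' input row order.
#'
#' @param genes Character vector of all gene ids (genes without retained
#'   edges become singleton families).
#' @param edges Tibble `gene1`, `gene2`, `score` from [pair_scores()].
#' @param min_weight Minimum edge weight retained (bits; default 5).
#' @param min_ratio Minimum ratio of between-cluster to internal average
#'   similarity (default 0.33).
#' @param max_size Maximum family size (default 100000).
#' @return A tibble `gene_id`, `family_id` (ids `FAM00001`, ... assigned by
#'   the lexicographically smallest member gene).
#' @export
cluster_families <- function(genes, edges, min_weight = 5,
                             min_ratio = 0.33, max_size = 100000) {
  genes <- sort(unique(genes))
  n <- length(genes)
  idx <- stats::setNames(seq_len(n), genes)
  W <- matrix(0, n, n)
  if (nrow(edges)) {
    e <- edges[edges$score >= min_weight &
                 edges$gene1 %in% genes & edges$gene2 %in% genes, ]
    if (nrow(e)) {
      i <- idx[e$gene1]; j <- idx[e$gene2]
      W[cbind(i, j)] <- pmax(W[cbind(i, j)], e$score)
      W[cbind(j, i)] <- W[cbind(i, j)]
    }
  }
  # vectorized agglomeration state: S holds summed cross-cluster edge
  # weights, int_sum the (ordered-pair) internal weight sum per cluster
  S <- W
  size <- rep(1L, n)
  int_sum <- numeric(n)
  minid <- genes
  active <- rep(TRUE, n)
  members <- as.list(seq_len(n))
  while (sum(active) >= 2L) {
    ia <- which(active)
    m <- length(ia)
    Ssub <- S[ia, ia, drop = FALSE]
    avg <- Ssub / outer(size[ia], size[ia])
    int_avg <- ifelse(size[ia] > 1L,
                      int_sum[ia] / (size[ia] * (size[ia] - 1L)), 0)
    IA <- matrix(int_avg, m, m)
    SZ <- matrix(size[ia], m, m)
    smaller_int <- ifelse(SZ < t(SZ), IA,
                          ifelse(SZ > t(SZ), t(IA), pmin(IA, t(IA))))
    admissible <- upper.tri(Ssub) & Ssub > 0 &
      avg >= min_ratio * smaller_int & (SZ + t(SZ)) <= max_size
    if (!any(admissible)) break
    best <- max(avg[admissible])
    hits <- which(admissible & avg == best, arr.ind = TRUE)
    if (nrow(hits) > 1L) {
      k1 <- pmin(minid[ia][hits[, 1]], minid[ia][hits[, 2]])
      k2 <- pmax(minid[ia][hits[, 1]], minid[ia][hits[, 2]])
      hits <- hits[order(k1, k2)[1], , drop = FALSE]
    }
    a <- ia[hits[1, 1]]; b <- ia[hits[1, 2]]
    int_sum[a] <- int_sum[a] + int_sum[b] + 2 * S[a, b]
    size[a] <- size[a] + size[b]
    minid[a] <- min(minid[a], minid[b])
    members[[a]] <- c(members[[a]], members[[b]])
    S[a, ] <- S[a, ] + S[b, ]
    S[, a] <- S[, a] + S[, b]
    S[a, a] <- 0
    S[b, ] <- 0; S[, b] <- 0
    active[b] <- FALSE
  }
  clusters <- members[active]
  clusters <- clusters[order(vapply(clusters,
                                    function(cl) min(genes[cl]), ""))]
  dplyr::bind_rows(purrr::imap(clusters, function(cl, k) {
    tibble::tibble(gene_id = sort(genes[cl]),
                   family_id = sprintf("FAM%05d", k))
  }))
}

#' Extract 1:1 ortholog families
#'
#' Keeps families that have exactly one member gene in every listed
#' species, and none outside the listed species.
#'
#' @param families Tibble `gene_id`, `family_id` from [cluster_families()].
#' @param species_map Tibble `gene_id`, `species`.
#' @param species Character vector of species that must each contribute
#'   exactly one gene.
#' @return A wide tibble: `family_id` plus one gene-id column per species.
#' @export
one_to_one <- function(families, species_map, species) {
  stopifnot(length(species) >= 1L)
  ann <- dplyr::inner_join(families, species_map, by = "gene_id")
  keep <- ann |>
    dplyr::group_by(.data$family_id) |>
    dplyr::filter(all(.data$species %in% !!species),
                  dplyr::n() == length(!!species),
                  !anyDuplicated(.data$species)) |>
    dplyr::ungroup()
  if (nrow(keep) == 0L) {
    out <- tibble::tibble(family_id = character())
    for (s in species) out[[s]] <- character()
    return(out)
  }
  tidyr::pivot_wider(keep, id_cols = "family_id",
                     names_from = "species", values_from = "gene_id") |>
    dplyr::select(dplyr::all_of(c("family_id", species))) |>
    dplyr::arrange(.data$family_id)
}
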