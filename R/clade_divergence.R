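#' Paint tree branches into focal and background regimes
#'
#' Labels every branch of a rooted time-calibrated tree as `focal` or
#' `background`. The focal regime is the crown of the monophyletic focal
#' clade plus its stem branch; everything else is background. A
#' non-monophyletic focal tip set is an error.
#'
#' @param tree A rooted [ape] `phylo` tree with branch lengths.
#' @param focal_tips Character vector of tip labels forming the focal
#'   clade.
#' @return A character vector of regime labels aligned with the rows of
#'   `tree$edge`, of class `regime_painting`, with the tree and focal tips
#'   attached as attributes.
#' @export
paint_regimes <- function(tree, focal_tips) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (!all(focal_tips %in% tree$tip.label))
    stop("focal tips absent from tree: ",
         paste(setdiff(focal_tips, tree$tip.label), collapse = ", "))
  if (length(focal_tips) < length(tree$tip.label) &&
      !ape::is.monophyletic(tree, focal_tips))
    stop("focal tip set is not monophyletic on the tree")
  if (length(focal_tips) == length(tree$tip.label)) {
    painting <- rep("focal", nrow(tree$edge))
  } else {
    mrca_node <- ape::getMRCA(tree, focal_tips)
    if (is.null(mrca_node)) mrca_node <- match(focal_tips, tree$tip.label)
    focal_nodes <- descendant_nodes(tree, mrca_node)
    # child in the focal clade (or the clade's root: the stem) => focal
    painting <- ifelse(tree$edge[, 2] %in% c(mrca_node, focal_nodes),
                       "focal", "background")
  }
  structure(painting, class = "regime_painting", tree = tree,
            focal_tips = focal_tips)
}

# All descendants (tips and internal nodes) of a node, by edge traversal.
descendant_nodes <- function(tree, node) {
  out <- integer()
  stack <- node
  while (length(stack)) {
    cur <- stack[1]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > ape::Ntip(tree)])
  }
  out
}

#' Per-regime shared path-length matrices
#'
#' For each regime r, `T_r[i, j]` is the branch length painted r on the
#' path from the root to the most recent common ancestor of tips i and j
#' (diagonal: root-to-tip). Their sum is the ordinary Brownian-motion
#' phylogenetic covariance structure `ape::vcv(tree)`.
#'
#' @param tree A rooted `phylo` tree.
#' @param painting Regime labels from [paint_regimes()].
#' @return A list `T_focal`, `T_background` of n-by-n matrices with tip
#'   labels as dimnames.
#' @export
regime_path_matrices <- function(tree, painting) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  depth_f <- depth_b <- numeric(nn)
  ord <- ape::reorder.phylo(tree, "postorder")
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  pre <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  for (i in seq_len(nrow(pre))) {
    p <- pre[i, 1]; child <- pre[i, 2]
    j <- match(paste(p, child), key)
    len <- tree$edge.length[j]
    if (painting[j] == "focal") {
      depth_f[child] <- depth_f[p] + len
      depth_b[child] <- depth_b[p]
    } else {
      depth_f[child] <- depth_f[p]
      depth_b[child] <- depth_b[p] + len
    }
  }
  M <- ape::mrca(tree)
  Tf <- matrix(depth_f[M], n, n)
  Tb <- matrix(depth_b[M], n, n)
  diag(Tf) <- depth_f[seq_len(n)]
  diag(Tb) <- depth_b[seq_len(n)]
  dimnames(Tf) <- dimnames(Tb) <- list(tree$tip.label, tree$tip.label)
  list(T_focal = Tf, T_background = Tb)
}

# Cholesky-based Gaussian quantities shared by likelihood and fitting.
# Returns NULL when V is not positive definite.
gls_pieces <- function(x, V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  n <- length(x)
  solve_chol <- function(b) backsolve(ch, forwardsolve(t(ch), b))
  Vi1 <- solve_chol(rep(1, n))
  denom <- sum(Vi1)
  mu <- sum(Vi1 * x) / denom
  r <- x - mu
  q <- sum(r * solve_chol(r))
  list(logdet = 2 * sum(log(diag(ch))), mu = mu, q = q, oneVione = denom)
}

#' Two-regime Brownian-motion log-likelihood
#'
#' Multivariate-normal log density of tip values under a painted
#' Brownian-motion model: the tip covariance is
#' `sig2_focal * T_focal + sig2_background * T_background` (see
#' [regime_path_matrices()]), with the root state profiled out analytically
#' by generalized least squares. With `reml = TRUE` the restricted
#' likelihood (accounting for the estimated root) is returned.
#'
#' @param x Named numeric vector of tip values (names matched to tips).
#' @param tree A rooted `phylo` tree.
#' @param painting Regime labels from [paint_regimes()].
#' @param sig2_focal,sig2_background Regime rates (trait variance per unit
#'   branch length); non-negative, not both zero.
#' @param reml Use restricted maximum likelihood.
#' @return The log-likelihood (scalar); `-Inf` if the implied covariance is
#'   singular.
#' @export
bm_loglik <- function(x, tree, painting, sig2_focal, sig2_background,
                      reml = FALSE) {
  stopifnot(sig2_focal >= 0, sig2_background >= 0,
            sig2_focal + sig2_background > 0)
  tm <- regime_path_matrices(tree, painting)
  x <- x[rownames(tm$T_focal)]
  V <- sig2_focal * tm$T_focal + sig2_background * tm$T_background
  g <- gls_pieces(x, V)
  if (is.null(g)) return(-Inf)
  n <- length(x)
  if (reml) {
    -0.5 * ((n - 1) * log(2 * pi) + g$logdet + log(g$oneVione) + g$q)
  } else {
    -0.5 * (n * log(2 * pi) + g$logdet + g$q)
  }
}

# One-time spectral setup for the profiled two-regime fit. With
# Tsum = Tf + Tb (the ordinary BM covariance structure, positive
# definite on a tree with distinct tips), solve the generalized
# eigenproblem Tf v = lambda Tsum v: columns of P satisfy
# P' Tsum P = I and P' Tf P = diag(lambda). Then for W = rho*Tf + Tb,
# W^-1 and log det W reduce to O(n) diagonal operations on P-rotated
# vectors, so profile-likelihood evaluations are cheap enough for
# genome-scale fitting.
bm_profile_setup <- function(Tf, Tb) {
  Tsum <- Tf + Tb
  R <- chol(Tsum)
  Ri <- backsolve(R, diag(nrow(R)))
  A <- t(Ri) %*% Tf %*% Ri
  eig <- eigen((A + t(A)) / 2, symmetric = TRUE)
  P <- Ri %*% eig$vectors
  list(P = P, lambda = pmin(pmax(eig$values, 0), 1),
       ld_tsum = 2 * sum(log(diag(R))),
       b = drop(t(P) %*% rep(1, nrow(Tf))),
       tips = rownames(Tf))
}

# Profiled one-dimensional fit over log(rho), rho = sig2_f / sig2_b; the
# scale sig2_b has a closed-form (RE)ML solution. A coarse grid locates
# the basin, then golden-section refinement. Returns rates, root state
# and log-likelihood.
fit_two_rates_profiled <- function(x, setup, reml = FALSE,
                                   log_rho_bounds = c(-18, 18)) {
  n <- length(x)
  dof <- if (reml) n - 1 else n
  a <- drop(crossprod(setup$P, x))
  b <- setup$b
  lam <- setup$lambda
  profile <- function(log_rho, full = FALSE) {
    w_inv <- 1 + (exp(log_rho) - 1) * lam
    if (any(w_inv < 1e-12)) return(if (full) NULL else Inf)
    bw <- b / w_inv
    mu <- sum(a * bw) / sum(b * bw)
    r <- a - mu * b
    q <- sum(r * r / w_inv)
    if (q <= 0) return(if (full) NULL else Inf)
    s2b <- q / dof
    ldW <- setup$ld_tsum + sum(log(w_inv))
    obj <- dof * log(s2b) + ldW +
      if (reml) log(sum(b * bw)) else 0
    if (!full) return(obj)
    ll <- if (reml) {
      -0.5 * ((n - 1) * log(2 * pi) + ldW + (n - 1) * log(s2b) +
                log(sum(b * bw)) - log(s2b) + (n - 1))
    } else {
      -0.5 * (n * log(2 * pi) + ldW + n * log(s2b) + n)
    }
    list(s2b = s2b, mu = mu, ll = ll)
  }
  grid <- seq(log_rho_bounds[1], log_rho_bounds[2], by = 3)
  vals <- vapply(grid, profile, 0)
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(profile, interval = c(lo, hi), tol = 1e-8)
  at <- profile(opt$minimum, full = TRUE)
  rho <- exp(opt$minimum)
  list(sig2_focal = rho * at$s2b, sig2_background = at$s2b,
       root_state = at$mu, loglik = at$ll,
       at_bound = opt$minimum <= log_rho_bounds[1] + 1e-6 ||
         opt$minimum >= log_rho_bounds[2] - 1e-6)
}

# Single-rate (RE)ML Brownian-motion fit on a subtree: closed form.
fit_one_rate <- function(x, C, reml = FALSE) {
  n <- length(x)
  g <- gls_pieces(x, C)
  if (is.null(g)) return(list(sig2 = NA_real_, mu = NA_real_,
                              loglik = NA_real_))
  dof <- if (reml) n - 1 else n
  s2 <- g$q / dof
  if (s2 <= 0) return(list(sig2 = 0, mu = g$mu, loglik = Inf))
  ll <- if (reml) {
    -0.5 * ((n - 1) * log(2 * pi) + g$logdet + (n - 1) * log(s2) +
              log(g$oneVione) + (n - 1))
  } else {
    -0.5 * (n * log(2 * pi) + g$logdet + n * log(s2) + n)
  }
  list(sig2 = s2, mu = g$mu, loglik = ll)
}

#' Fit per-gene two-regime Brownian-motion rates
#'
#' For each gene (row of the trait table), estimates the focal and
#' background rates of trait evolution on the painted tree by maximizing
#' the likelihood of [bm_loglik()]. The scale parameter is profiled
#' analytically, leaving a bounded one-dimensional search over the rate
#' ratio, restarted around both boundaries and the equal-rates point. Two
#' modes are available: `"joint"` (default) fits one likelihood on the
#' whole painted tree with the focal stem branch in the focal regime;
#' `"prune"` fits a single-rate model separately on each regime's induced
#' subtree (closed form). Genes whose estimates hit the rate-ratio boundary
#' or whose rates fall below `1e-9` are flagged and should be excluded from
#' downstream ratio tests; constant traits give zero rates and the
#' `degenerate` flag.
#'
#' @param traits Tibble with `gene_id` and one numeric column per tip
#'   label.
#' @param tree Rooted time-calibrated `phylo` tree.
#' @param painting Regime labels from [paint_regimes()].
#' @param mode `"joint"` or `"prune"`.
#' @param reml Use restricted maximum likelihood (default `FALSE`).
#' @return A tibble of class `utr3_bm_fits`: `gene_id`, `sig2_focal`,
#'   `sig2_background`, `root_state`, `loglik`, `rate_ratio`,
#'   `log10_ratio`, `flag` (`"ok"`, `"boundary"`, or `"degenerate"`).
#' @export
fit_bm_rates <- function(traits, tree, painting,
                         mode = c("joint", "prune"), reml = FALSE) {
  mode <- match.arg(mode)
  tips <- tree$tip.label
  stopifnot(all(tips %in% names(traits)))
  X <- as.matrix(traits[, tips])
  focal_tips <- attr(painting, "focal_tips")
  background_tips <- setdiff(tips, focal_tips)
  stopifnot(length(focal_tips) >= 2L, length(background_tips) >= 2L)

  if (mode == "joint") {
    tm <- regime_path_matrices(tree, painting)
    setup <- bm_profile_setup(tm$T_focal, tm$T_background)
    fit_one <- function(x) {
      if (stats::var(x) < .Machine$double.eps) {
        return(list(sig2_focal = 0, sig2_background = 0,
                    root_state = x[1], loglik = NA_real_, flag = "degenerate"))
      }
      f <- fit_two_rates_profiled(x[setup$tips], setup, reml = reml)
      flag <- if (f$at_bound || f$sig2_focal < 1e-9 ||
                  f$sig2_background < 1e-9) "boundary" else "ok"
      c(f[c("sig2_focal", "sig2_background", "root_state", "loglik")],
        list(flag = flag))
    }
  } else {
    tr_f <- ape::keep.tip(tree, focal_tips)
    tr_b <- ape::keep.tip(tree, background_tips)
    C_f <- ape::vcv(tr_f); C_b <- ape::vcv(tr_b)
    fit_one <- function(x) {
      if (stats::var(x) < .Machine$double.eps) {
        return(list(sig2_focal = 0, sig2_background = 0,
                    root_state = x[1], loglik = NA_real_, flag = "degenerate"))
      }
      ff <- fit_one_rate(x[rownames(C_f)], C_f, reml = reml)
      fb <- fit_one_rate(x[rownames(C_b)], C_b, reml = reml)
      flag <- if (is.na(ff$sig2) || is.na(fb$sig2)) "degenerate"
        else if (ff$sig2 < 1e-9 || fb$sig2 < 1e-9) "boundary" else "ok"
      list(sig2_focal = ff$sig2, sig2_background = fb$sig2,
           root_state = fb$mu, loglik = ff$loglik + fb$loglik, flag = flag)
    }
  }

  rows <- lapply(seq_len(nrow(X)), function(i) {
    x <- X[i, ]
    f <- fit_one(x)
    ratio <- if (f$sig2_background > 0) f$sig2_focal / f$sig2_background
      else NA_real_
    tibble::tibble(
      gene_id = traits$gene_id[i],
      sig2_focal = f$sig2_focal, sig2_background = f$sig2_background,
      root_state = unname(f$root_state), loglik = f$loglik,
      rate_ratio = ratio,
      log10_ratio = if (!is.na(ratio) && ratio > 0) log10(ratio)
        else NA_real_,
      flag = f$flag)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("utr3_bm_fits", class(out))
  attr(out, "mode") <- mode
  attr(out, "reml") <- reml
  out
}

#' Per-gene log10 ratio of mean trait values between clades
#'
#' `log10(mean over focal tips / mean over background tips)` per gene.
#' Genes where either clade mean is not strictly positive are flagged and
#' get an `NA` ratio (they are excluded from downstream t-tests).
#'
#' @param traits Tibble with `gene_id` and one numeric column per species.
#' @param focal_tips,background_tips Species (column) names of each clade.
#' @return A tibble `gene_id`, `mean_focal`, `mean_background`,
#'   `log10_ratio`, `flag`.
#' @export
length_log_ratio <- function(traits, focal_tips, background_tips) {
  mf <- rowMeans(as.matrix(traits[, focal_tips]))
  mb <- rowMeans(as.matrix(traits[, background_tips]))
  ok <- mf > 0 & mb > 0
  tibble::tibble(
    gene_id = traits$gene_id,
    mean_focal = mf, mean_background = mb,
    log10_ratio = ifelse(ok, log10(mf / mb), NA_real_),
    flag = ifelse(ok, "ok", "nonpositive mean"))
}

#' One-sample t-test against a null mean
#'
#' Classic one-sample t statistic with n - 1 degrees of freedom and a
#' two-sided p-value, as applied to per-gene log10 ratios against a null
#' mean of 0.
#'
#' @param values Numeric vector (`NA`s dropped); needs at least 2 values
#'   and nonzero variance.
#' @param mu0 Null mean (default 0).
#' @return One-row tibble: `n`, `mean`, `t`, `df`, `p_value`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 non-missing values")
  if (stats::var(values) == 0) stop("zero sample variance")
  ht <- stats::t.test(values, mu = mu0)
  tibble::tibble(n = length(values), mean = unname(ht$estimate),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' @method tidy utr3_bm_fits
#' @export
tidy.utr3_bm_fits <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance utr3_bm_fits
#' @export
glance.utr3_bm_fits <- function(x, ...) {
  usable <- x$flag == "ok" & !is.na(x$log10_ratio)
  tt <- if (sum(usable) >= 2L && stats::var(x$log10_ratio[usable]) > 0) {
    one_sample_t(x$log10_ratio[usable])
  } else {
    tibble::tibble(n = sum(usable), mean = NA_real_, t = NA_real_,
                   df = NA_real_, p_value = NA_real_)
  }
  tibble::tibble(
    n_genes = nrow(x), n_ok = sum(x$flag == "ok"),
    n_boundary = sum(x$flag == "boundary"),
    n_degenerate = sum(x$flag == "degenerate"),
    mean_log10_ratio = tt$mean, t = tt$t, df = tt$df, p_value = tt$p_value,
    mode = attr(x, "mode"), reml = attr(x, "reml"))
}
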