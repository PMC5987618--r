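test_that("regime painting labels the focal crown plus stem", {
  tp <- default_tree_painting()
  expect_equal(sum(tp$painting == "focal"), 9L)  # 8 crown edges + 1 stem
  expect_equal(length(tp$painting), nrow(tp$tree$edge))

  all_focal <- paint_regimes(tp$tree, tp$tree$tip.label)
  expect_true(all(all_focal == "focal"))

  # a set that splits a clade is rejected
  expect_error(paint_regimes(tp$tree, c("M_zebra", "D_rerio")),
               "monophyletic")
})

test_that("regime path matrices sum to the standard BM covariance", {
  tp <- default_tree_painting()
  tm <- regime_path_matrices(tp$tree, tp$painting)
  V <- ape::vcv(tp$tree)
  expect_equal(tm$T_focal + tm$T_background,
               V[rownames(tm$T_focal), colnames(tm$T_focal)],
               tolerance = 1e-12)
  expect_true(all(tm$T_focal >= 0) && all(tm$T_background >= 0))
})

test_that("two-tip REML likelihood equals the closed-form contrast density", {
  tree <- ape::read.tree(text = "(A:3,B:3);")
  painting <- paint_regimes(tree, "A")  # A focal, B background
  x <- c(A = 4.2, B = 1.1)
  s2 <- 0.7
  ll <- bm_loglik(x, tree, painting, s2, s2, reml = TRUE)
  expect_equal(ll, stats::dnorm(4.2 - 1.1, sd = sqrt(2 * s2 * 3),
                                log = TRUE))
})

test_that("equal rates reduce to the single-rate BM likelihood", {
  tp <- default_tree_painting()
  V <- ape::vcv(tp$tree)
  single_rate_ll <- function(x, s2) {
    C <- s2 * V[names(x), names(x)]
    n <- length(x)
    Ci <- solve(C)
    mu <- sum(Ci %*% x) / sum(Ci)
    r <- x - mu
    -0.5 * (n * log(2 * pi) + determinant(C)$modulus[1] +
              drop(t(r) %*% Ci %*% r))
  }
  withr::with_seed(41, {
    for (rep in 1:10) {
      x <- stats::setNames(rnorm(9, 500, 80), tp$tree$tip.label)
      s2 <- runif(1, 0.1, 5)
      expect_equal(bm_loglik(x, tp$tree, tp$painting, s2, s2),
                   single_rate_ll(x, s2), tolerance = 1e-8)
    }
  })
})

test_that("the likelihood matches an independent dense-matrix oracle", {
  tree <- ape::read.tree(text = "((a:1,b:2):1.5,((c:1,d:0.5):1,e:2):0.8);")
  painting <- paint_regimes(tree, c("a", "b"))
  # independent construction of the per-regime shared-path matrices via
  # ape::nodepath, then the profiled-mean Gaussian density
  oracle_ll <- function(x, s2f, s2b) {
    n <- ape::Ntip(tree)
    root <- n + 1
    edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
    Tf <- Tb <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      pi_ <- ape::nodepath(tree, root, i)
      pj <- ape::nodepath(tree, root, j)
      shared_edges <- intersect(
        paste(pi_[-length(pi_)], pi_[-1]),
        paste(pj[-length(pj)], pj[-1]))
      for (ek in shared_edges) {
        r <- match(ek, edge_key)
        if (painting[r] == "focal") Tf[i, j] <- Tf[i, j] +
            tree$edge.length[r]
        else Tb[i, j] <- Tb[i, j] + tree$edge.length[r]
      }
    }
    V <- s2f * Tf + s2b * Tb
    Vi <- solve(V)
    mu <- sum(Vi %*% x) / sum(Vi)
    r <- x - mu
    -0.5 * (n * log(2 * pi) + determinant(V)$modulus[1] +
              drop(t(r) %*% Vi %*% r))
  }
  withr::with_seed(42, {
    for (rep in 1:5) {
      x <- stats::setNames(rnorm(5, 10, 3), tree$tip.label)
      s2f <- runif(1, 0.2, 4); s2b <- runif(1, 0.2, 4)
      expect_equal(bm_loglik(x, tree, painting, s2f, s2b),
                   oracle_ll(x[tree$tip.label], s2f, s2b),
                   tolerance = 1e-8)
    }
  })
})

test_that("joint ML rate estimates agree with an independent multi-rate fit", {
  skip_if_not_installed("phytools")
  tp <- default_tree_painting()
  painted <- phytools::paintSubTree(
    tp$tree, node = ape::getMRCA(tp$tree, tp$focal_tips),
    state = "focal", anc.state = "background", stem = TRUE)
  traits <- simulate_traits(tp$tree, tp$painting, 3, 1, 100, 5, seed = 43)
  fits <- fit_bm_rates(traits, tp$tree, tp$painting)
  for (i in 1:5) {
    x <- stats::setNames(as.numeric(traits[i, tp$tree$tip.label]),
                         tp$tree$tip.label)
    ref <- phytools::brownie.lite(painted, x)
    expect_equal(fits$sig2_focal[i],
                 unname(ref$sig2.multiple["focal"]), tolerance = 1e-3)
    expect_equal(fits$sig2_background[i],
                 unname(ref$sig2.multiple["background"]), tolerance = 1e-3)
    expect_equal(fits$loglik[i], ref$logL.multiple, tolerance = 1e-6)
  }
})

test_that("fitted likelihood values are consistent with bm_loglik", {
  tp <- default_tree_painting()
  traits <- simulate_traits(tp$tree, tp$painting, 2, 1, 500, 4, seed = 44)
  fits <- fit_bm_rates(traits, tp$tree, tp$painting)
  for (i in 1:4) {
    x <- stats::setNames(as.numeric(traits[i, tp$tree$tip.label]),
                         tp$tree$tip.label)
    expect_equal(fits$loglik[i],
                 bm_loglik(x, tp$tree, tp$painting, fits$sig2_focal[i],
                           fits$sig2_background[i]),
                 tolerance = 1e-8)
  }
})

test_that("rate estimates are scale-equivariant", {
  tp <- default_tree_painting()
  traits <- simulate_traits(tp$tree, tp$painting, 1.5, 0.8, 300, 6,
                            seed = 45)
  f1 <- fit_bm_rates(traits, tp$tree, tp$painting)
  scaled <- dplyr::mutate(traits, dplyr::across(
    dplyr::where(is.numeric), ~ .x * 10))
  f10 <- fit_bm_rates(scaled, tp$tree, tp$painting)
  expect_equal(f10$sig2_focal, 100 * f1$sig2_focal, tolerance = 1e-5)
  expect_equal(f10$sig2_background, 100 * f1$sig2_background,
               tolerance = 1e-5)
  expect_equal(f10$log10_ratio, f1$log10_ratio, tolerance = 1e-5)
})

test_that("constant traits are flagged degenerate with zero rates", {
  tp <- default_tree_painting()
  traits <- tibble::tibble(gene_id = "g1")
  for (tip in tp$tree$tip.label) traits[[tip]] <- 700
  f <- fit_bm_rates(traits, tp$tree, tp$painting)
  expect_equal(f$flag, "degenerate")
  expect_equal(f$sig2_focal, 0)
  expect_equal(f$sig2_background, 0)
})

test_that("REML recovers mean rates within 10 percent on simulated genes", {
  tp <- default_tree_painting()
  traits <- simulate_traits(tp$tree, tp$painting, 2, 1, 1000, 600,
                            seed = 46)
  fits <- fit_bm_rates(traits, tp$tree, tp$painting, reml = TRUE)
  ok <- fits$flag == "ok"
  expect_gt(mean(ok), 0.98)
  expect_lt(abs(mean(fits$sig2_focal[ok]) - 2) / 2, 0.1)
  expect_lt(abs(mean(fits$sig2_background[ok]) - 1), 0.1)
})

test_that("prune mode fits each regime's induced subtree", {
  tp <- default_tree_painting()
  traits <- simulate_traits(tp$tree, tp$painting, 2, 1, 1000, 50,
                            seed = 47)
  fp <- fit_bm_rates(traits, tp$tree, tp$painting, mode = "prune")
  # closed-form check for one gene: single-rate ML on the focal subtree
  tr_f <- ape::keep.tip(tp$tree, tp$focal_tips)
  C <- ape::vcv(tr_f)
  x <- stats::setNames(as.numeric(traits[1, rownames(C)]), rownames(C))
  Ci <- solve(C)
  mu <- sum(Ci %*% x) / sum(Ci)
  s2_hat <- drop(t(x - mu) %*% Ci %*% (x - mu)) / length(x)
  expect_equal(fp$sig2_focal[1], s2_hat, tolerance = 1e-9)
})

test_that("clade mean log-ratios and the one-sample t-test behave as stated", {
  tp <- default_tree_painting()
  traits <- tibble::tibble(gene_id = c("g1", "g2", "g3"))
  for (tip in tp$focal_tips) traits[[tip]] <- c(100, 200, 0)
  for (tip in tp$background_tips) traits[[tip]] <- c(100, 100, 50)
  lr <- length_log_ratio(traits, tp$focal_tips, tp$background_tips)
  expect_equal(lr$log10_ratio[1], 0)
  expect_equal(lr$log10_ratio[2], log10(2))
  expect_true(is.na(lr$log10_ratio[3]))
  expect_equal(lr$flag[3], "nonpositive mean")

  # symmetric values: t = 0, p = 1
  sym <- one_sample_t(c(-2, -1, 1, 2))
  expect_equal(sym$t, 0)
  expect_equal(sym$p_value, 1)
  expect_error(one_sample_t(rep(3, 5)), "variance")

  # formula oracle on 20 fixed values
  vals <- seq(-0.5, 1.4, by = 0.1)
  res <- one_sample_t(vals)
  t_hand <- mean(vals) / (stats::sd(vals) / sqrt(20))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 19)
  expect_equal(res$t, t_hand)
  expect_equal(res$p_value, p_hand)
})

test_that("tidy and glance summarize fit tables", {
  tp <- default_tree_painting()
  traits <- simulate_traits(tp$tree, tp$painting, 2, 1, 800, 40, seed = 48)
  fits <- fit_bm_rates(traits, tp$tree, tp$painting)
  td <- tidy(fits)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 40L)
  gl <- glance(fits)
  expect_equal(gl$n_genes, 40L)
  expect_true(gl$p_value >= 0 && gl$p_value <= 1)
  expect_s3_class(autoplot(fits), "ggplot")
})
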