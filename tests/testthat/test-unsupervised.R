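test_that("OMP selects the explaining column first and enumerates all when asked", {
  set.seed(5)
  a <- rnorm(60, sd = 4)
  x <- cbind(a = a, b = 0.5 * a + rnorm(60, sd = 0.05),
             c = -0.25 * a + rnorm(60, sd = 0.05))
  expect_equal(select_peaks_omp(x, 1), 1L)

  set.seed(6)
  y <- matrix(rnorm(60 * 4), 60, 4)
  expect_setequal(select_peaks_omp(y, 4), 1:4)

  same <- cbind(a, a, a)
  expect_warning(sel <- select_peaks_omp(same, 2), "identical")
  expect_equal(length(sel), 1)
})

test_that("OMP covers the planted spatial structure within its first atoms", {
  b <- default_batch()
  tissue <- b$sim$region != "off_tissue"
  sel <- select_peaks_omp(b$fm$values[tissue, ], n_atoms = 10)
  role <- b$sim$panel$role[match(b$fm$centers[sel], b$sim$panel$mz)]
  # one representative per latent direction: the region contrast and the
  # tam-only treatment contrast (up- and down-markers share the latter, so a
  # single treatment atom spans both directions)
  expect_true(any(role %in% c("anchor", "region")))
  expect_true(any(role %in% "treatment"))
})

test_that("bisecting 2-means equals plain 2-means and recovers point clouds", {
  set.seed(9)
  x <- rbind(matrix(rnorm(100, 0, 0.2), ncol = 2),
             matrix(rnorm(100, 5, 0.2), ncol = 2))
  tree <- bisect_kmeans(x, 2, seed = 3, n_atoms = 2)
  truth <- rep(1:2, each = 50)
  expect_equal(adjusted_rand_index(tree$labels[, 2], truth), 1)

  # oracle equivalence with a direct 2-means under the same init
  xs <- sweep(x[, tree$selected_columns, drop = FALSE], 2,
              apply(x[, tree$selected_columns, drop = FALSE], 2, sd), "/")
  km <- with_seed(derive_seed(3, "bisect_level_2"),
                  stats::kmeans(xs, 2, nstart = 10, iter.max = 100))
  expect_equal(adjusted_rand_index(tree$labels[, 2], km$cluster), 1)

  expect_error(bisect_kmeans(x[1:3, ], 5, seed = 1), "fewer spectra")
  expect_error(suppressWarnings(bisect_kmeans(rbind(x[1, ], x[1, ], x[1, ]), 3,
                                               seed = 1)),
               "fewer distinct spectra|constant")
})

test_that("segmentation trees refine, are reproducible, and mirror the regions", {
  b <- default_batch()
  tissue <- b$sim$region != "off_tissue"
  tree <- bisect_kmeans(b$fm, 3, seed = derive_seed(1, "segment"), rows = tissue)
  tree2 <- bisect_kmeans(b$fm, 3, seed = derive_seed(1, "segment"), rows = tissue)
  expect_identical(tree$labels, tree2$labels)

  # refinement: each level splits exactly one segment of the previous level
  for (lev in 2:3) {
    tab <- table(tree$labels[, lev - 1], tree$labels[, lev])
    expect_true(all(rowSums(tab > 0) <= 2))
    expect_equal(sum(rowSums(tab > 0) == 2), 1)
  }

  region <- b$sim$region[tree$rows]
  group <- b$sim$group[tree$rows]
  expect_gte(adjusted_rand_index(tree$labels[, 2], region), 0.8)

  # the level-3 split divides tam by treatment group: the new segment sits
  # almost entirely inside the tam pixels of a single group
  new_seg <- tree$labels[, 3] == 3
  share <- max(mean((region == "tam" & group == "MSC_TX")[new_seg]),
               mean((region == "tam" & group == "control")[new_seg]))
  expect_gte(share, 0.8)
})

test_that("adjusted Rand index agrees with the mclust reference", {
  set.seed(12)
  a <- sample(1:3, 200, replace = TRUE)
  b <- sample(1:4, 200, replace = TRUE)
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  expect_equal(adjusted_rand_index(a, a), 1)
})

test_that("PCA honors exact low-rank structure and its scaling conventions", {
  set.seed(21)
  t1 <- rnorm(200)
  x <- cbind(t1, 2 * t1, -t1, 0.5 * t1)
  p1 <- pca_decompose(x, n_components = 1)
  expect_equal(p1$explained[1], 100, tolerance = 1e-8)

  # orthogonal two-factor toy with 4:1 variance ratio -> 80% / 20%
  n <- 20000
  set.seed(22)
  f1 <- rnorm(n, sd = 1); f2 <- rnorm(n, sd = 1)
  y <- cbind(2 * f1, f2)   # unit-variance scaling equalizes these
  # construct exactly: columns with variance 4 and 1 sharing no correlation
  y <- cbind(a = 2 * f1 + f2, b = 2 * f1 - f2)  # PCs: f1 (var 8) and f2 (var 2)
  p2 <- pca_decompose(y, n_components = 2)
  expect_equal(p2$explained, c(80, 20), tolerance = 1.5)

  # sign convention: dominant loading entry positive
  expect_true(all(apply(p2$loadings, 2, function(v) v[which.max(abs(v))] > 0)))

  # full reconstruction reproduces the standardized matrix
  xs <- scale(x + matrix(rnorm(800, sd = 0.3), 200, 4))
  pf <- pca_decompose(xs, n_components = 4)
  rec <- pf$scores %*% t(pf$loadings)
  expect_lt(max(abs(rec - scale(xs))), 1e-8)

  # constant columns are dropped with a warning
  expect_warning(pca_decompose(cbind(x, 7), n_components = 2), "constant")
})

test_that("a principal component separates treated-tam from control-tam", {
  b <- default_batch()
  tissue <- b$sim$region != "off_tissue"
  pc <- pca_decompose(b$fm, 5, rows = tissue)
  reg <- b$sim$region[pc$rows]; grp <- b$sim$group[pc$rows]
  tt <- reg == "tam" & grp == "MSC_TX"
  tc <- reg == "tam" & grp == "control"
  separated <- vapply(1:5, function(k) {
    q1 <- stats::quantile(pc$scores[tt, k], c(0.25, 0.75))
    q2 <- stats::quantile(pc$scores[tc, k], c(0.25, 0.75))
    q1[1] > q2[2] || q2[1] > q1[2]
  }, TRUE)
  expect_true(any(separated))
})

test_that("PLSA recovers an exact two-aspect mixture within TV 0.01", {
  set.seed(31)
  p <- 15
  a1 <- rexp(p); a1 <- a1 / sum(a1)
  a2 <- rexp(p); a2 <- a2 / sum(a2)
  lam <- c(0, 1, seq(0, 1, length.out = 38))
  truth <- outer(lam, a1) + outer(1 - lam, a2)
  x <- truth * 5000
  fit <- plsa_decompose(x, 2, tol = 1e-12, max_iter = 5000)
  rec <- fit$scores %*% fit$loadings
  tv <- 0.5 * rowSums(abs(rec - truth))
  expect_lt(max(tv), 0.01)
})

test_that("PLSA keeps its EM guarantees on arbitrary nonnegative data", {
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rexp(40 * 12), 40, 12)
    fit <- plsa_decompose(x, 3, tol = 1e-10, max_iter = 200)
    expect_true(all(diff(fit$log_likelihood) >= -1e-8 * abs(fit$log_likelihood[1])))
    expect_lt(max(abs(rowSums(fit$scores) - 1)), 1e-8)
    expect_lt(max(abs(rowSums(fit$loadings) - 1)), 1e-8)
    # deterministic initialization: identical reruns
    fit2 <- plsa_decompose(x, 3, tol = 1e-10, max_iter = 200)
    expect_identical(fit$scores, fit2$scores)
  }
  expect_error(plsa_decompose(matrix(c(-1, 1, 2, 3), 2), 2), "nonnegative")
})

test_that("PLSA components localize the treatment structure in tam", {
  b <- default_batch()
  tissue <- b$sim$region != "off_tissue"
  fit <- plsa_decompose(b$fm, 5, rows = tissue)
  reg <- b$sim$region[fit$rows]; grp <- b$sim$group[fit$rows]
  tt <- reg == "tam" & grp == "MSC_TX"
  tc <- reg == "tam" & grp == "control"
  n <- nrow(fit$scores)
  top_share_tt <- vapply(1:5, function(k) {
    top <- order(fit$scores[, k], decreasing = TRUE)[seq_len(floor(n / 10))]
    mean(tt[top])
  }, 0)
  expect_gte(max(top_share_tt), 0.7)
  # another component's scores rank control-tam above treated-tam
  auc_tc <- vapply(1:5, function(k) roc_auc(fit$scores[tc, k], fit$scores[tt, k]), 0)
  expect_gt(max(auc_tc[top_share_tt < 0.7]), 0.65)
})
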