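test_that("feature table has one row per scan and survives bad rows", {
  d <- withr::local_tempdir()
  man <- generate_cohort(d, n_per_group = c(HNS = 1L, HS = 1L, Mild = 1L,
                                            Mod = 1L), seed = 2, paired = 0)
  tab <- build_feature_table(file.path(d, "manifest.csv"), seed = 1)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$status == "ok"))
  expect_true(all(tab$upwards_complexity >= 0))
  expect_equal(tab$upwards_complexity_per_m,
               tab$upwards_complexity / tab$height_m)
  # a missing tree file flags its row, the others still compute
  man2 <- utils::read.csv(file.path(d, "manifest.csv"))
  man2$tree_path[2] <- "trees/nonexistent.swc"
  tab2 <- build_feature_table(man2, dir = d, seed = 1)
  expect_match(tab2$status[2], "failed")
  expect_equal(tab2$status[-2], rep("ok", 3))
  # determinism: same seed, same table
  tab3 <- build_feature_table(file.path(d, "manifest.csv"), seed = 1)
  expect_identical(tab, tab3)
  # manifest errors are fatal with a useful message
  man3 <- man2
  man3$group[1] <- "Severe"
  expect_error(build_feature_table(man3, dir = d), "unknown group")
})

test_that("pairwise distance matrices are symmetric and consistent", {
  ds <- lapply(1:5, function(s) random_diagram(10, s))
  names(ds) <- paste0("s", 1:5)
  D <- pairwise_distances(ds, metric = "wasserstein2")
  expect_equal(unname(diag(D)), rep(0, 5))
  expect_equal(D, t(D))
  expect_equal(D["s1", "s2"], wasserstein_distance(ds[[1]], ds[[2]], 2))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)
  same <- pairwise_distances(list(a = ds[[1]], b = ds[[1]], c = ds[[1]]),
                             metric = "bottleneck")
  expect_equal(unname(same), matrix(0, 3, 3), ignore_attr = TRUE)
  mixed <- list(a = ds[[1]], b = random_diagram(4, 9, degree = 1))
  expect_error(pairwise_distances(mixed), "mixed")
})

test_that("classical MDS reproduces known configurations", {
  # three points pairwise distance 1: an equilateral triangle
  D <- matrix(1, 3, 3) - diag(3)
  dimnames(D) <- list(letters[1:3], letters[1:3])
  e <- mds_embed(D)
  got <- as.matrix(dist(e[, c("x", "y")]))
  expect_equal(unname(got), unname(D), tolerance = 1e-9)
  # planar points are recovered up to rigid motion (Procrustes residual ~ 0)
  set.seed(3)
  X <- cbind(stats::rnorm(7), stats::rnorm(7))
  DX <- as.matrix(dist(X))
  dimnames(DX) <- list(paste0("p", 1:7), paste0("p", 1:7))
  e2 <- as.matrix(mds_embed(DX)[, c("x", "y")])
  Xc <- scale(X, scale = FALSE)
  Ec <- scale(e2, scale = FALSE)
  s <- svd(t(Ec) %*% Xc)
  resid <- max(abs(Ec %*% s$u %*% t(s$v) - Xc))
  expect_lt(resid, 1e-9)
  # zero matrix collapses to the origin; < 3 scans is an error
  Z <- matrix(0, 3, 3)
  ez <- suppressWarnings(mds_embed(Z))  # cmdscale notes the zero eigenvalues
  expect_equal(unname(as.matrix(ez[, c("x", "y")])), matrix(0, 3, 2))
  expect_error(mds_embed(matrix(0, 2, 2)), "at least 3")
  # deterministic: repeated embedding identical
  expect_identical(mds_embed(DX), mds_embed(DX))
})

test_that("pairwise KS reports |KS| and p per group pair", {
  tab <- data.frame(group = rep(c("HNS", "Mod"), each = 3),
                    f = c(1, 2, 3, 10, 11, 12))
  cmp <- ks_pairwise(tab, "f")
  expect_equal(cmp$ks, 1)  # disjoint supports
  same <- data.frame(group = rep(c("HNS", "HS"), each = 4),
                     f = rep(c(1, 2, 3, 4), 2))
  cs <- suppressWarnings(ks_pairwise(same, "f"))
  expect_equal(cs$ks, 0)
  expect_equal(cs$p, 1)
  # statistic equals brute-force sup over pooled breakpoints
  set.seed(8)
  tb <- data.frame(group = rep(c("HNS", "Mild"), c(14, 19)),
                   f = c(stats::rnorm(14), stats::rnorm(19, 0.6)))
  got <- ks_pairwise(tb, "f")
  x <- tb$f[tb$group == "HNS"]
  y <- tb$f[tb$group == "Mild"]
  br <- sort(unique(c(x, y)))
  want <- max(abs(stats::ecdf(x)(br) - stats::ecdf(y)(br)))
  expect_equal(got$ks, want, tolerance = 1e-12)
  # a group with < 2 observations is skipped with a warning
  one <- rbind(tb, data.frame(group = "Mod", f = 1))
  expect_warning(ks_pairwise(one, "f"), "Mod")
  expect_error(ks_pairwise(tb, "nope"), "no feature column")
})

test_that("pearson correlation handles exact and sampled relations", {
  tab <- data.frame(x = 1:10, y = 2 * (1:10) + 1, z = -(1:10), c = rep(1, 10))
  expect_equal(pearson_correlation(tab, "x", "y")$rho, 1)
  expect_equal(pearson_correlation(tab, "x", "z")$rho, -1)
  expect_error(pearson_correlation(tab, "x", "c"), "zero variance")
  set.seed(5)
  n <- 200
  x <- stats::rnorm(n)
  y <- 0.7 * x + sqrt(1 - 0.49) * stats::rnorm(n)
  r <- pearson_correlation(data.frame(a = x, b = y), "a", "b")
  expect_lt(abs(r$rho - 0.7), 0.1)
  expect_lt(r$p, 0.001)
})

test_that("KS p-values are calibrated under the null", {
  set.seed(17)
  rej <- 0L
  reps <- 2000L
  for (i in seq_len(reps)) {
    tab <- data.frame(group = rep(c("HNS", "HS"), c(18, 19)),
                      f = stats::rnorm(37))
    if (ks_pairwise(tab, "f")$p <= 0.05) rej <- rej + 1L
  }
  expect_gte(rej / reps, 0.03)
  expect_lte(rej / reps, 0.07)
})

test_that("groups that differ in turn rate separate more than equal groups", {
  # small-cohort replicates: |KS| for upwards_complexity under a real
  # difference exceeds the |KS| under identical parameters
  n_rep <- 30L
  win <- 0L
  for (r in seq_len(n_rep)) {
    gen <- function(rate, seeds) vapply(seeds, function(s)
      as.numeric(upwards_complexity(generate_airway_tree(tree_gen_params(
        generations = 4L, upward_turn_rate = rate, node_spacing_mm = 1,
        seed = s)))), 1)
    base <- 1000L * r
    a <- gen(0.2, base + 1:8)
    b <- gen(1.5, base + 11:18)
    c2 <- gen(0.2, base + 21:28)
    ks_diff <- suppressWarnings(stats::ks.test(a, b)$statistic)
    ks_same <- suppressWarnings(stats::ks.test(a, c2)$statistic)
    if (ks_diff > ks_same) win <- win + 1L
  }
  expect_gte(win / n_rep, 0.8)
})
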