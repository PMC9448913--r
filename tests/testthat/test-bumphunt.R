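test_that("clustering matches the hand example and respects chromosomes", {
  ann <- toy_annotation(c(100, 500, 1600, 1700, 3000))
  cl <- cluster_probes(ann, max_gap = 1000)
  expect_equal(cl$cluster_id, c(1, 1, 2, 2, 3))
  expect_equal(cl$clusters$n_probes, c(2, 2, 1))

  one <- cluster_probes(toy_annotation(c(0, 500, 1000, 1500)), 1000)
  expect_equal(unique(one$cluster_id), 1L)

  two <- toy_annotation(c(100, 200, 100, 200),
                        chrom = c("chr1", "chr1", "chr2", "chr2"))
  expect_equal(cluster_probes(two, 1e6)$cluster_id, c(1, 1, 2, 2))

  bad <- toy_annotation(c(100, 50))
  expect_error(cluster_probes(bad, 1000), "sorted")
})

test_that("clustering equals the pairwise-gap oracle on random probe sets", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:100, 1)
    chrom <- sort(sample(c("chr1", "chr2", "chr3"), n, replace = TRUE))
    pos <- unlist(lapply(split(seq_len(n), chrom), function(i)
      cumsum(sample(c(50:900, 1200:2000), length(i), replace = TRUE))),
      use.names = FALSE)
    ann <- toy_annotation(pos, chrom = chrom)
    got <- cluster_probes(ann, max_gap = 1000)$cluster_id
    expect_equal(got, oracle_clusters(chrom, pos, 1000))
  }
})

test_that("per-probe OLS matches hand results and the normal-equations oracle", {
  ## 4-sample toy: intercept + group, coefficient 0.4
  X <- cbind(1, c(0, 0, 1, 1))
  colnames(X) <- c("(Intercept)", "group")
  y <- named_matrix(c(0.2, 0.3, 0.6, 0.7), 1, 4)
  fit <- fit_probe_models(y, X, 2L)
  expect_equal(fit$coef, 0.4, tolerance = 1e-12)

  ## exact fit: response equal to the indicator
  fit2 <- fit_probe_models(named_matrix(c(0, 0, 1, 1), 1, 4), X, 2L)
  expect_equal(fit2$coef, 1, tolerance = 1e-12)
  expect_equal(fit2$se, 0, tolerance = 1e-10)

  ## orthogonal covariate leaves the group coefficient unchanged
  z <- c(-1, 1, -1, 1)               # orthogonal to group and intercept
  X3 <- cbind(X, z = z)
  fit3 <- fit_probe_models(y, X3, 2L)
  expect_equal(fit3$coef, fit$coef, tolerance = 1e-12)

  ## random toys vs solve(X'X, X'y)
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    k <- sample(2:3, 1)
    X <- cbind(1, matrix(rnorm(n * (k - 1)), n))
    colnames(X) <- paste0("c", seq_len(k))
    Y <- named_matrix(rnorm(n * 6), 6, n)
    fit <- fit_probe_models(Y, X, 2L)
    oracle <- apply(Y, 1, function(y) solve(crossprod(X), crossprod(X, y))[2])
    expect_equal(fit$coef, unname(oracle), tolerance = 1e-10)
  }
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  X <- cbind(`(Intercept)` = 1, a = c(0, 0, 1, 1), b = c(0, 0, 2, 2))
  expect_error(fit_probe_models(named_matrix(rnorm(4), 1, 4), X, 2L),
               "rank deficient.*b")
})

test_that("cluster-wise smoother preserves polynomials and cluster boundaries", {
  pos <- c(seq(0, 4500, by = 500), seq(20000, 24500, by = 500))
  ann <- toy_annotation(pos)
  cl <- cluster_probes(ann, 1000)
  cfg <- bump_config(n_bootstrap = 1L)
  expect_equal(length(unique(cl$cluster_id)), 2L)

  const <- rep(c(0.3, -0.2), each = 10)
  expect_equal(smooth_by_cluster(const, pos, cl, cfg), const,
               tolerance = 1e-9)

  lin <- 0.001 * pos + 0.05
  expect_equal(smooth_by_cluster(lin, pos, cl, cfg), lin, tolerance = 1e-6)

  quad <- 1e-7 * (pos - 2000)^2
  expect_equal(smooth_by_cluster(quad, pos, cl, cfg), quad, tolerance = 1e-6)

  ## small clusters pass through unsmoothed
  pos2 <- c(0, 400, 800, 10000, 10400)
  ann2 <- toy_annotation(pos2)
  cl2 <- cluster_probes(ann2, 1000)
  v <- c(0.5, -0.4, 0.2, 0.9, -0.9)
  expect_equal(smooth_by_cluster(v, pos2, cl2, cfg), v)

  ## no leakage: perturbing one cluster leaves the other untouched
  v1 <- rnorm(20)
  v2 <- v1; v2[15] <- v2[15] + 10
  s1 <- smooth_by_cluster(v1, pos, cl, cfg)
  s2 <- smooth_by_cluster(v2, pos, cl, cfg)
  expect_equal(s1[1:10], s2[1:10], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(s1[11:20], s2[11:20])))
})

test_that("running-mean smoothing averages within the bp window only", {
  pos <- seq(0, 4500, by = 500)
  cl <- cluster_probes(toy_annotation(pos), 1000)
  cfg <- bump_config(smoothing = "running_mean", smooth_span_bp = 1000,
                     n_bootstrap = 1L)
  v <- rnorm(10)
  got <- smooth_by_cluster(v, pos, cl, cfg)
  oracle <- vapply(seq_along(pos), function(i)
    mean(v[abs(pos - pos[i]) <= 500]), numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("cutoff is the interpolated quantile of the absolute profile", {
  expect_equal(pick_cutoff(rep(c(0.3, -0.3), 10), 0.95), 0.3)
  expect_equal(pick_cutoff(1:100, 0.95), 95.05)
  x <- rnorm(50)
  expect_equal(pick_cutoff(x, 0.9), pick_cutoff(-x, 0.9))
  expect_error(pick_cutoff(numeric(0)), "no finite values")
})

test_that("bump segmentation matches hand examples", {
  ann <- toy_annotation(c(100, 200, 300, 400))
  cl <- cluster_probes(ann, 1000)
  b <- find_bumps(c(0.2, 0.5, 0.6, 0.1), ann, cl, 0.4)
  expect_equal(nrow(b), 1L)
  expect_equal(b$idx_start, 2L)
  expect_equal(b$idx_end, 3L)
  expect_equal(b$area, 1.1)
  expect_equal(b$sign, 1)
  expect_equal(b$start, 200)
  expect_equal(b$end, 301)          # half-open: last pos + 1

  ann2 <- toy_annotation(c(100, 200))
  b2 <- find_bumps(c(-0.5, 0.5), ann2, cluster_probes(ann2, 1000), 0.4)
  expect_equal(nrow(b2), 2L)
  expect_equal(b2$sign, c(-1, 1))

  expect_equal(nrow(find_bumps(c(0.1, 0.2), ann2,
                               cluster_probes(ann2, 1000), 0.5)), 0L)
})

test_that("bump segmentation equals exhaustive run enumeration", {
  set.seed(11)
  for (rep in 1:200) {
    n <- 50
    cluster_id <- sort(sample.int(6, n, replace = TRUE))
    values <- rnorm(n, sd = 0.5)
    cutoff <- runif(1, 0, 0.6)
    oracle <- oracle_segments(values, cluster_id, cutoff)
    got <- dyadDMR:::run_segments(values, cluster_id, cutoff)
    expect_equal(length(got$area), length(oracle))
    if (length(oracle)) {
      expect_equal(got$idx_start, vapply(oracle, `[[`, integer(1), "start"))
      expect_equal(got$idx_end, vapply(oracle, `[[`, integer(1), "end"))
      expect_equal(got$sign, vapply(oracle, `[[`, integer(1), "sign"))
      expect_equal(got$area, vapply(oracle, `[[`, numeric(1), "area"),
                   tolerance = 1e-12)
    }
  }
})

test_that("bootstrap p-values follow the plus-one counting rule", {
  p <- dyadDMR:::null_p_values(1.1, c(0.2, 1.5, 0.3, 0.9))
  expect_equal(p, (1 + 1) / (1 + 4))
  ## larger than every null area: floor at 1/(1+N), never 0
  expect_equal(dyadDMR:::null_p_values(99, c(0.2, 1.5, 0.3, 0.9)), 1 / 5)
  ## non-increasing in area
  areas <- sort(runif(20, 0, 2))
  ps <- dyadDMR:::null_p_values(areas, runif(100, 0, 2))
  expect_true(all(diff(ps) <= 0))
  ## empty null is flagged
  expect_warning(p1 <- dyadDMR:::null_p_values(1, numeric(0)), "empty")
  expect_equal(p1, 1)
})

test_that("the full fit is deterministic and ordered by evidence", {
  cfg <- tiny_config(seed = 123L)
  sim <- simulate_cohorts(cfg, generate_annotation(cfg))
  beta <- preprocess_cohort(sim$mother, generate_annotation(cfg))
  ph <- sim$pheno[sim$pheno$role == "mother", ]
  des <- design_matrix(ph, "group", c("epithelial", "age"))
  bcfg <- bump_config(n_bootstrap = 30L, seed = 9L)
  f1 <- bump_hunt(beta, des, generate_annotation(cfg), bcfg)
  f2 <- bump_hunt(beta, des, generate_annotation(cfg), bcfg)
  expect_identical(f1$bumps, f2$bumps)
  expect_true(all(diff(f1$bumps$p_value) >= 0))
  expect_true(all(f1$bumps$area >= 0))
  ## member probes of each bump all exceed the cutoff with a common sign
  for (i in seq_len(min(5, nrow(f1$bumps)))) {
    idx <- f1$bumps$idx_start[i]:f1$bumps$idx_end[i]
    expect_true(all(abs(f1$smoothed[idx]) > f1$cutoff))
    expect_true(all(sign(f1$smoothed[idx]) == f1$bumps$sign[i]))
  }
})

test_that("bootstrap p-values are approximately uniform under a true null", {
  ## pool the bump p-values of three independent null datasets so the
  ## Kolmogorov-Smirnov check has a usable sample size
  p <- unlist(lapply(c(31L, 32L, 33L), function(seed) {
    cfg <- tiny_config(n_probes = 500L, chromosomes = c(chr1 = 500L),
                       n_mother_neglect = 20L, n_mother_control = 20L,
                       n_planted_shared = 0L, n_planted_mother_only = 0L,
                       n_planted_child_only = 0L, seed = seed)
    sim <- simulate_cohorts(cfg, generate_annotation(cfg))
    beta <- compute_beta(sim$mother)
    ph <- sim$pheno[sim$pheno$role == "mother", ]
    des <- design_matrix(ph, "group", c("epithelial", "age"))
    fit <- bump_hunt(beta, des, generate_annotation(cfg),
                     bump_config(n_bootstrap = 200L, seed = 2L))
    fit$bumps$p_value
  }))
  expect_gt(length(p), 40)
  D <- suppressWarnings(stats::ks.test(p, "punif")$statistic)
  expect_lt(unname(D), 0.2)
})
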