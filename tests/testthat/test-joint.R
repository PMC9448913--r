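test_that("z transformation matches the inverse normal CDF and is monotone", {
  expect_equal(z_transform(0.5), 0)
  expect_equal(z_transform(0.01), 2.3263, tolerance = 1e-4)
  expect_equal(z_transform(1e-4), 3.719, tolerance = 1e-3)
  ## signed two-sided convention honours the effect sign
  expect_equal(z_transform(0.05, "signed_two_sided", effect_sign = -1),
               -qnorm(1 - 0.025))
  ## strict monotonicity: smaller p, larger z
  set.seed(3)
  p <- sort(runif(100, 1e-6, 1))
  z <- z_transform(p)
  expect_true(all(diff(z) < 0))
  ## p = 0 handled via the bootstrap floor
  expect_warning(z0 <- z_transform(0, n_null = 999), "mapped")
  expect_equal(z0, qnorm(1 - 1e-3))
  expect_error(z_transform(0), "n_null")
})

test_that("region matching honours half-open overlap and the greedy rule", {
  m <- data.frame(chrom = "chr1", start = 100, end = 200)
  c1 <- data.frame(chrom = "chr1", start = 150, end = 250)
  got <- match_regions(m, c1)
  expect_equal(nrow(got), 1L)
  expect_equal(got$overlap_bp, 50L)

  ## half-open: touching intervals do not overlap
  c2 <- data.frame(chrom = "chr1", start = 200, end = 300)
  expect_equal(nrow(match_regions(m, c2)), 0L)

  ## greedy: the larger of two competing overlaps wins
  c3 <- data.frame(chrom = "chr1", start = c(170, 80),
                   end = c(260, 180))           # overlaps 30 and 80
  got3 <- match_regions(m, c3)
  expect_equal(nrow(got3), 1L)
  expect_equal(got3$child_idx, 2L)
  expect_equal(got3$overlap_bp, 80L)

  ## different chromosomes never match
  c4 <- data.frame(chrom = "chr2", start = 100, end = 200)
  expect_equal(nrow(match_regions(m, c4)), 0L)
})

test_that("matching is symmetric in input order", {
  set.seed(21)
  for (rep in 1:10) {
    mk <- function(n) {
      s <- sample.int(5000, n)
      data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                 start = s, end = s + sample.int(400, n))
    }
    a <- mk(15); b <- mk(12)
    ab <- match_regions(a, b)
    ba <- match_regions(b, a)
    expect_equal(nrow(ab), nrow(ba))
    key_ab <- sort(paste(ab$mother_idx, ab$child_idx))
    key_ba <- sort(paste(ba$child_idx, ba$mother_idx))
    expect_equal(key_ab, key_ba)
  }
})

test_that("z correlation handles perfect, inverted and degenerate inputs", {
  z <- c(0.2, 1.1, 2.3, -0.4)
  expect_equal(correlate_z(z, z)$r, 1)
  expect_equal(correlate_z(z, -z)$r, -1)
  expect_warning(out <- correlate_z(z, rep(1, 4)), "zero variance")
  expect_true(is.na(out$r))
  expect_error(correlate_z(z, z[1:3]), "equal length")
  expect_error(correlate_z(z[1:2], z[1:2]), "3 pairs")
  ## p-value comes from the t distribution on n - 2 df
  set.seed(4)
  a <- rnorm(30); b <- a + rnorm(30)
  out2 <- correlate_z(a, b)
  ct <- cor.test(a, b)
  expect_equal(out2$r, unname(ct$estimate))
  expect_equal(out2$p_value, ct$p.value)
})

test_that("joint intersection keeps doubly significant pairs at level alpha^2", {
  pairs <- data.frame(p_mother = c(0.005, 0.005, 0.5),
                      p_child = c(0.005, 0.02, 0.001))
  out <- intersect_significant(pairs, alpha = 0.01)
  expect_equal(nrow(out$shared), 1L)
  expect_equal(out$joint_level, 1e-4)
})

test_that("joint analysis of two fits reports consistent counts and shared set", {
  cfg <- tiny_config(n_probes = 1000L, chromosomes = c(chr1 = 500L, chr2 = 500L),
                     n_planted_shared = 2L, n_planted_mother_only = 1L,
                     n_planted_child_only = 1L, seed = 17L)
  sim <- simulate_cohorts(cfg, generate_annotation(cfg))
  ann <- generate_annotation(cfg)
  bcfg <- bump_config(n_bootstrap = 60L, seed = 5L)
  ph <- sim$pheno
  fit_m <- bump_hunt(compute_beta(sim$mother),
                     design_matrix(ph[ph$role == "mother", ], "group",
                                   c("epithelial", "age")), ann, bcfg)
  fit_c <- bump_hunt(compute_beta(sim$child),
                     design_matrix(ph[ph$role == "child", ], "group",
                                   c("epithelial", "age")), ann, bcfg)
  ## few matched pairs can share the bootstrap floor p, making the
  ## correlation degenerate at this toy scale — that warning is expected
  jt <- suppressWarnings(joint_dmr(fit_m, fit_c))
  expect_s3_class(jt, "joint_dmr")
  expect_lte(jt$n_shared_sig, min(jt$n_mother_sig, jt$n_child_sig))
  expect_true(all(jt$shared$p_mother < 0.01 & jt$shared$p_child < 0.01))
  expect_equal(jt$joint_level, 1e-4)
  expect_true(all(jt$pairs$overlap_bp >= 1))
  ## planted shared regions come out on top
  shared_truth <- sim$truth$planted_regions[
    sim$truth$planted_regions$cohort == "shared", ]
  for (i in seq_len(nrow(shared_truth)))
    expect_true(any(jt$shared$chrom == shared_truth$chrom[i] &
                      jt$shared$start < shared_truth$end[i] &
                      jt$shared$end > shared_truth$start[i]))
  ## z columns are finite and correlation is defined
  expect_true(all(is.finite(jt$pairs$z_mother)))
  expect_true(all(is.finite(jt$pairs$z_child)))
})
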