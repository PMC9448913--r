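test_that("annotation is sorted with strictly increasing positions per chromosome", {
  ann <- generate_annotation(tiny_config())
  expect_equal(nrow(ann), 600L)
  for (ch in unique(ann$chrom)) {
    p <- ann$pos[ann$chrom == ch]
    expect_true(all(diff(p) > 0))
  }
  ## planted regions carry their own gene label and sit inside tight clusters
  planted <- attr(ann, "planted")
  expect_equal(nrow(planted), 4L)
  for (r in seq_len(nrow(planted))) {
    idx <- planted$idx_start[r]:planted$idx_end[r]
    expect_true(all(ann$gene[idx] == planted$region_id[r]))
    expect_true(all(diff(ann$pos[idx]) <= 1000))
  }
})

test_that("contamination flags respect configured fractions and spare planted probes", {
  ann0 <- generate_annotation(tiny_config(frac_cross_reactive = 0,
                                          frac_snp = 0))
  expect_equal(sum(ann0$cross_reactive), 0L)
  expect_equal(sum(ann0$snp_overlap), 0L)

  ann <- generate_annotation(tiny_config(frac_cross_reactive = 0.1))
  expect_equal(sum(ann$cross_reactive), 60L)
  planted <- attr(ann, "planted")
  planted_idx <- unlist(Map(seq, planted$idx_start, planted$idx_end))
  expect_false(any(ann$cross_reactive[planted_idx]))
  expect_false(any(ann$snp_overlap[planted_idx]))
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 7L)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  s1 <- simulate_cohorts(cfg, a1)
  s2 <- simulate_cohorts(cfg, a2)
  expect_identical(s1, s2)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_probes = 0), "positive")
  expect_error(sim_config(effect_size = 1.2), "effect_size")
  expect_error(sim_config(frac_snp = 1.5), "fractions")
  cfg <- tiny_config()
  ann <- generate_annotation(cfg)
  expect_error(simulate_cohorts(tiny_config(n_probes = 400L,
                                            chromosomes = c(chr1 = 400L)),
                                ann), "does not match")
  expect_error(simulate_cohorts(cfg, data.frame(probe_id = "x")),
               "generate_annotation")
})

test_that("planted shift is exact on the beta scale when noise is off", {
  cfg <- tiny_config(n_planted_shared = 1L, n_planted_mother_only = 0L,
                     n_planted_child_only = 0L, effect_size = 0.1,
                     noise_sd_logit = 0, covariate_effects = numeric(0),
                     srei_effect_beta = 0)
  ann <- generate_annotation(cfg)
  sim <- simulate_cohorts(cfg, ann)
  reg <- sim$truth$planted_regions
  idx <- reg$idx_start:reg$idx_end
  for (cohort in c("mother", "child")) {
    beta <- compute_beta(sim[[cohort]])$values
    ph <- sim$pheno[sim$pheno$role == cohort, ]
    diff_g <- rowMeans(beta[idx, ph$group == "neglect", drop = FALSE]) -
      rowMeans(beta[idx, ph$group == "control", drop = FALSE])
    expect_equal(diff_g, rep(reg$sign * 0.1, length(idx)), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  ## off-region probes carry no group difference at all
  off <- setdiff(seq_len(cfg$n_probes), idx)[1:50]
  beta_m <- compute_beta(sim$mother)$values
  ph_m <- sim$pheno[sim$pheno$role == "mother", ]
  d0 <- rowMeans(beta_m[off, ph_m$group == "neglect"]) -
    rowMeans(beta_m[off, ph_m$group == "control"])
  expect_equal(unname(d0), rep(0, 50), tolerance = 1e-12)
})

test_that("zero effect size yields a null model", {
  cfg <- tiny_config(effect_size = 0, noise_sd_logit = 0,
                     covariate_effects = numeric(0))
  sim <- simulate_cohorts(cfg, generate_annotation(cfg))
  beta <- compute_beta(sim$mother)$values
  ph <- sim$pheno[sim$pheno$role == "mother", ]
  d <- rowMeans(beta[, ph$group == "neglect"]) -
    rowMeans(beta[, ph$group == "control"])
  expect_true(max(abs(d)) < 1e-12)
})

test_that("planted-effect fidelity: large groups with small noise recover the shift", {
  cfg <- tiny_config(n_probes = 300L, chromosomes = c(chr1 = 300L),
                     n_mother_neglect = 300L, n_mother_control = 300L,
                     n_child_neglect = 2L, n_child_control = 2L,
                     n_planted_shared = 1L, n_planted_mother_only = 0L,
                     n_planted_child_only = 0L,
                     effect_size = 0.1, noise_sd_logit = 0.02,
                     covariate_effects = numeric(0))
  sim <- simulate_cohorts(cfg, generate_annotation(cfg))
  reg <- sim$truth$planted_regions
  idx <- reg$idx_start:reg$idx_end
  beta <- compute_beta(sim$mother)$values
  ph <- sim$pheno[sim$pheno$role == "mother", ]
  d <- mean(rowMeans(beta[idx, ph$group == "neglect"]) -
              rowMeans(beta[idx, ph$group == "control"]))
  expect_lt(abs(d - reg$sign * 0.1), 1e-3)
})

test_that("intensities round-trip through the beta formula", {
  cfg <- tiny_config()
  sim <- simulate_cohorts(cfg, generate_annotation(cfg))
  ip <- sim$mother
  recovered <- ip$M / (ip$U + ip$M + 100)
  direct <- compute_beta(ip)$values
  expect_equal(recovered, direct, tolerance = 1e-12)
  ## total intensity is fixed, so the denominator is exactly total + 100
  expect_true(all(abs(ip$M + ip$U - 10000) < 1e-9))
})

test_that("SREI group means match the emulated cohort profile", {
  cfg <- sim_config(n_probes = 50L, chromosomes = c(chr1 = 50L),
                    n_planted_shared = 1L, n_planted_mother_only = 0L,
                    n_planted_child_only = 0L, dmr_width_probes = 7L,
                    seed = 5L)
  sim <- simulate_cohorts(cfg, generate_annotation(cfg))
  ph <- sim$pheno[sim$pheno$role == "mother", ]
  m_ng <- mean(ph$srei_total[ph$group == "neglect"])
  m_cg <- mean(ph$srei_total[ph$group == "control"])
  expect_lt(abs(m_ng - 16.76), 2 * 8.65 / sqrt(51))
  expect_lt(abs(m_cg - 11.59), 2 * 7.70 / sqrt(87))
  ## items are consistent with totals and legally scored
  items <- as.matrix(ph[sprintf("srei_item%02d", 1:16)])
  expect_true(all(items %in% c(0, 1, 3)))
  expect_equal(unname(rowSums(items)), ph$srei_total)
})

test_that("dyads link each child to exactly one same-group mother", {
  cfg <- tiny_config()
  sim <- simulate_cohorts(cfg, generate_annotation(cfg))
  ph <- sim$pheno
  kids <- ph[ph$role == "child", ]
  moms <- ph[ph$role == "mother", ]
  i <- match(kids$dyad_id, moms$dyad_id)
  expect_false(anyNA(i))
  expect_equal(moms$group[i], kids$group)
  expect_false(any(duplicated(kids$dyad_id)))
})

test_that("detection failures affect only the configured probes and samples", {
  cfg <- tiny_config(detection_fail_rate = 0.02, n_failing_samples = 2L)
  sim <- simulate_cohorts(cfg, generate_annotation(cfg))
  dp <- sim$mother$detection_p
  fail_s <- match(sim$truth$failing_samples, colnames(dp))
  expect_equal(length(fail_s), 2L)
  expect_true(all(colMeans(dp)[fail_s] > 0.1))
  fail_p <- match(sim$truth$failing_probes, rownames(dp))
  clean <- setdiff(seq_len(nrow(dp)), fail_p)
  clean_means <- rowMeans(dp[clean, -fail_s, drop = FALSE])
  expect_true(all(clean_means <= 0.05))
  expect_true(all(rowMeans(dp[fail_p, , drop = FALSE]) > 0.05))
})
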