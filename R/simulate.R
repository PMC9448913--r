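#' Simulation configuration for paired-cohort methylation data
#'
#' Builds and validates the configuration for the synthetic EPIC-like data
#' generator. Defaults emulate the study design the package targets: two
#' paired saliva cohorts (51 neglect / 87 control mothers, 40 neglect /
#' 75 control children), a reduced-scale probe set with realistic genomic
#' spacing, multi-probe planted DMRs of which a subset is shared between
#' cohorts, logit-normal measurement noise, nuisance covariate effects,
#' and contaminant (cross-reactive / SNP-overlapping) probes.
#'
#' @param n_probes total number of CpG probes across all chromosomes.
#' @param chromosomes named integer vector of probes per chromosome; by
#'   default `n_probes` is split evenly across four chromosomes.
#' @param mean_gap mean inter-probe gap in bp (geometric spacing model).
#' @param n_mother_neglect,n_mother_control,n_child_neglect,n_child_control
#'   cohort group sizes.
#' @param n_planted_shared,n_planted_mother_only,n_planted_child_only number
#'   of planted DMRs per category.
#' @param effect_size beta-scale methylation shift inside planted regions
#'   (dimensionless, typically 0.03-0.15).
#' @param dmr_width_probes probes per planted region (>= 7 so regions are
#'   wide enough for the cluster-wise smoother).
#' @param noise_sd_logit SD of logit-scale measurement noise.
#' @param covariate_effects named numeric vector of logit-scale slopes for
#'   nuisance covariates present in the phenotype table.
#' @param child_sign `"same"` (default) or `"opposite"`: sign of the child
#'   effect in shared regions relative to the mother's. Both directions are
#'   seen in real mother-child methylation data.
#' @param srei_effect_beta beta-units of methylation change per SREI
#'   adversity point, applied inside the regions named by
#'   `srei_effect_regions` (0 disables the adversity association).
#' @param srei_effect_regions which planted regions carry the SREI slope:
#'   `"shared"`, `"mother"`, `"child"`, or `"all"`.
#' @param frac_cross_reactive,frac_snp fractions of probes flagged as
#'   cross-reactive / SNP-overlapping (flags are placed on filler probes so
#'   planted ground truth survives contaminant removal).
#' @param detection_fail_rate fraction of probes whose detection p-values
#'   are elevated above the probe QC threshold.
#' @param n_failing_samples number of samples (taken from the control
#'   mothers) whose detection p-values are elevated above the sample QC
#'   threshold.
#' @param srei_mean_neglect,srei_sd_neglect,srei_mean_control,srei_sd_control
#'   group moments of the SREI total adversity score.
#' @param total_intensity fixed total M+U intensity per probe.
#' @param seed integer seed; every random draw in the generator is derived
#'   from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_probes = 4000L,
                       chromosomes = NULL,
                       mean_gap = 400,
                       n_mother_neglect = 51L, n_mother_control = 87L,
                       n_child_neglect = 40L, n_child_control = 75L,
                       n_planted_shared = 10L,
                       n_planted_mother_only = 5L,
                       n_planted_child_only = 5L,
                       effect_size = 0.1,
                       dmr_width_probes = 10L,
                       noise_sd_logit = 0.3,
                       covariate_effects = c(epithelial = 0.5, age = 0.01,
                                             education = -0.05),
                       child_sign = c("same", "opposite"),
                       srei_effect_beta = 0,
                       srei_effect_regions = c("shared", "mother", "child", "all"),
                       frac_cross_reactive = 0.05,
                       frac_snp = 0.02,
                       detection_fail_rate = 0.002,
                       n_failing_samples = 0L,
                       srei_mean_neglect = 16.76, srei_sd_neglect = 8.65,
                       srei_mean_control = 11.59, srei_sd_control = 7.70,
                       total_intensity = 10000,
                       seed = 1L) {
  child_sign <- match.arg(child_sign)
  srei_effect_regions <- match.arg(srei_effect_regions)
  n_probes <- as.integer(n_probes)
  stop_if_not(n_probes > 0, "n_probes must be positive")
  if (is.null(chromosomes)) {
    k <- min(4L, max(1L, n_probes %/% 250L))
    base <- n_probes %/% k
    chromosomes <- stats::setNames(rep(base, k), paste0("chr", seq_len(k)))
    chromosomes[k] <- chromosomes[k] + n_probes - sum(chromosomes)
  }
  stop_if_not(sum(chromosomes) == n_probes,
              "chromosome probe counts must sum to n_probes")
  counts <- c(n_mother_neglect, n_mother_control, n_child_neglect,
              n_child_control, n_planted_shared, n_planted_mother_only,
              n_planted_child_only)
  stop_if_not(all(counts >= 0), "all counts must be >= 0")
  stop_if_not(abs(effect_size) < 1, "effect_size must lie in (-1, 1)")
  stop_if_not(dmr_width_probes <= n_probes,
              "dmr_width_probes cannot exceed n_probes")
  stop_if_not(frac_cross_reactive >= 0 && frac_cross_reactive <= 1 &&
                frac_snp >= 0 && frac_snp <= 1 &&
                detection_fail_rate >= 0 && detection_fail_rate <= 1,
              "fractions must lie in [0, 1]")
  stop_if_not(noise_sd_logit >= 0, "noise_sd_logit must be >= 0")
  cfg <- list(n_probes = n_probes, chromosomes = chromosomes,
              mean_gap = mean_gap,
              n_mother_neglect = as.integer(n_mother_neglect),
              n_mother_control = as.integer(n_mother_control),
              n_child_neglect = as.integer(n_child_neglect),
              n_child_control = as.integer(n_child_control),
              n_planted_shared = as.integer(n_planted_shared),
              n_planted_mother_only = as.integer(n_planted_mother_only),
              n_planted_child_only = as.integer(n_planted_child_only),
              effect_size = effect_size,
              dmr_width_probes = as.integer(dmr_width_probes),
              noise_sd_logit = noise_sd_logit,
              covariate_effects = covariate_effects,
              child_sign = child_sign,
              srei_effect_beta = srei_effect_beta,
              srei_effect_regions = srei_effect_regions,
              frac_cross_reactive = frac_cross_reactive,
              frac_snp = frac_snp,
              detection_fail_rate = detection_fail_rate,
              n_failing_samples = as.integer(n_failing_samples),
              srei_mean_neglect = srei_mean_neglect,
              srei_sd_neglect = srei_sd_neglect,
              srei_mean_control = srei_mean_control,
              srei_sd_control = srei_sd_control,
              total_intensity = total_intensity,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

## place planted regions on the probe grid: each chromosome is divided into
## equal blocks, one region per block at a random offset, with at least one
## filler probe on each side so regions never touch
place_regions <- function(config) {
  n_regions <- config$n_planted_shared + config$n_planted_mother_only +
    config$n_planted_child_only
  cohort <- rep(c("shared", "mother", "child"),
                c(config$n_planted_shared, config$n_planted_mother_only,
                  config$n_planted_child_only))
  if (n_regions == 0L) {
    return(data.frame(region_id = character(), chrom = character(),
                      idx_start = integer(), idx_end = integer(),
                      cohort = character(), sign = integer(),
                      effect_size = numeric(), stringsAsFactors = FALSE))
  }
  w <- config$dmr_width_probes
  chroms <- names(config$chromosomes)
  sizes <- as.integer(config$chromosomes)
  ## round-robin assignment of regions to chromosomes, largest first
  ord <- order(-sizes)
  assign_chrom <- chroms[ord][1 + (seq_len(n_regions) - 1L) %% length(chroms)]
  offset <- c(0L, cumsum(sizes))[match(assign_chrom, chroms)]
  idx_start <- integer(n_regions)
  for (ch in unique(assign_chrom)) {
    sel <- which(assign_chrom == ch)
    k <- sizes[match(ch, chroms)]
    r <- length(sel)
    block <- k %/% r
    stop_if_not(block >= w + 3L,
                "chromosome ", ch, " too small for ", r,
                " planted regions of width ", w)
    off <- vapply(seq_len(r),
                  function(i) (i - 1L) * block +
                    sample.int(block - w - 1L, 1L) + 1L,
                  integer(1))
    idx_start[sel] <- offset[sel] + off
  }
  ## shuffle cohort labels across placements so cohorts mix over chromosomes
  perm <- sample.int(n_regions)
  data.frame(
    region_id = paste0("DMR", toupper(substr(cohort, 1, 1)),
                       sprintf("%02d", stats::ave(seq_len(n_regions),
                                                  cohort, FUN = seq_along))),
    chrom = assign_chrom[perm],
    idx_start = idx_start[perm],
    idx_end = idx_start[perm] + w - 1L,
    cohort = cohort,
    sign = sample(c(-1L, 1L), n_regions, replace = TRUE),
    effect_size = rep(config$effect_size, n_regions),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic probe annotation table
#'
#' Produces a probe annotation (probe id, chromosome, 0-based position, gene
#' label, contamination flags) with strictly increasing positions per
#' chromosome. Planted-region probes receive the region's synthetic gene
#' label and internal gaps below the clustering threshold; a gap larger than
#' 1000 bp is forced on both flanks of every planted region so each region
#' forms its own CpG cluster. Contamination flags are restricted to filler
#' probes.
#'
#' @param config a [sim_config()] object.
#' @return a `data.frame` with columns `probe_id`, `chrom`, `pos`, `gene`,
#'   `cross_reactive`, `snp_overlap`, sorted by (chromosome, position), with
#'   the planted-region table attached as attribute `"planted"`.
#' @export
generate_annotation <- function(config) {
  stop_if_not(inherits(config, "sim_config"), "config must be a sim_config")
  stop_if_not(config$n_probes > 0, "zero probes requested")
  set.seed(substream_seed(config$seed, 101L))

  regions <- place_regions(config)
  n <- config$n_probes
  chrom <- rep(names(config$chromosomes), config$chromosomes)
  in_region <- integer(n)            # 0 = filler, else row of `regions`
  for (r in seq_len(nrow(regions)))
    in_region[regions$idx_start[r]:regions$idx_end[r]] <- r

  ## gaps: geometric with mean mean_gap; capped inside regions, forced
  ## break (> 1000 bp) at region boundaries
  gap <- 1 + stats::rgeom(n, 1 / config$mean_gap)
  inside <- in_region > 0L & c(0L, in_region[-n]) == in_region  # not first probe
  gap[inside] <- pmin(gap[inside], 900)
  boundary <- (in_region > 0L & !inside) |                      # region start
    (c(0L, in_region[-n]) > 0L & c(0L, in_region[-n]) != in_region)  # after end
  gap[boundary] <- 1500 + sample.int(500L, sum(boundary), replace = TRUE)
  new_chrom <- c(TRUE, chrom[-1] != chrom[-n])
  gap[new_chrom] <- sample.int(20000L, sum(new_chrom), replace = TRUE)
  pos <- integer(n)
  for (ch in unique(chrom)) {
    i <- chrom == ch
    pos[i] <- cumsum(gap[i])
  }

  gene <- paste0("LOC", match(chrom, names(config$chromosomes)), "_",
                 1L + (unlist(lapply(config$chromosomes, seq_len),
                              use.names = FALSE) - 1L) %/% 25L)
  for (r in seq_len(nrow(regions)))
    gene[regions$idx_start[r]:regions$idx_end[r]] <- regions$region_id[r]

  filler <- which(in_region == 0L)
  n_cr <- round(config$frac_cross_reactive * n)
  n_snp <- round(config$frac_snp * n)
  stop_if_not(max(n_cr, n_snp) <= length(filler),
              "not enough filler probes to carry contamination flags")
  cross_reactive <- logical(n)
  snp_overlap <- logical(n)
  cross_reactive[sample(filler, n_cr)] <- TRUE
  snp_overlap[sample(filler, n_snp)] <- TRUE

  ann <- data.frame(probe_id = sprintf("cg%08d", seq_len(n)),
                    chrom = chrom, pos = pos, gene = gene,
                    cross_reactive = cross_reactive,
                    snp_overlap = snp_overlap,
                    stringsAsFactors = FALSE)
  ## genomic coordinates of regions (0-based half-open)
  if (nrow(regions)) {
    regions$start <- pos[regions$idx_start]
    regions$end <- pos[regions$idx_end] + 1L
  } else {
    regions$start <- integer(0); regions$end <- integer(0)
  }
  attr(ann, "planted") <- regions
  attr(ann, "sim_seed") <- config$seed
  ann
}

## phenotype table for one cohort
make_pheno <- function(config, role) {
  if (role == "mother") {
    n_ng <- config$n_mother_neglect; n_cg <- config$n_mother_control
  } else {
    n_ng <- config$n_child_neglect; n_cg <- config$n_child_control
  }
  n <- n_ng + n_cg
  group <- rep(c("neglect", "control"), c(n_ng, n_cg))
  if (role == "mother") {
    age <- ifelse(group == "neglect", stats::rnorm(n, 30.67, 7.36),
                  stats::rnorm(n, 33.98, 6.13))
    age <- pmax(age, 18)
    edu_p <- list(neglect = c(0.80, 0.18, 0.02), control = c(0.43, 0.52, 0.05))
    education <- vapply(group, function(g)
      sample.int(3L, 1L, prob = edu_p[[g]]), integer(1))
    data.frame(sample_id = sprintf("M%03d", seq_len(n)),
               dyad_id = sprintf("D%03d_%s", seq_len(n), substr(group, 1, 1)),
               role = "mother", group = group,
               age = age, education = education,
               epithelial = stats::runif(n, 0.5, 0.95),
               plate = sample(paste0("P", 1:4), n, replace = TRUE),
               stringsAsFactors = FALSE)
  } else {
    age <- pmin(pmax(ifelse(group == "neglect", stats::rnorm(n, 4.06, 2.77),
                            stats::rnorm(n, 3.84, 2.17)), 0.5), 7)
    data.frame(sample_id = sprintf("C%03d", seq_len(n)),
               dyad_id = NA_character_, role = "child", group = group,
               age = age, education = NA_integer_,
               epithelial = stats::runif(n, 0.5, 0.95),
               plate = sample(paste0("P", 1:4), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
}

## SREI totals as rounded truncated normals at the target group moments,
## decomposed into 16 items scored 0 / 1 / 3 by emotional impact
draw_srei <- function(n, mean, sd) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  tot <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- round_half_up(stats::rnorm(length(todo), mean[todo], sd[todo]))
    ok <- x >= 0 & x <= 48
    tot[todo[ok]] <- as.integer(x[ok])
    todo <- todo[!ok]
  }
  items <- matrix(0L, n, 16)
  for (i in seq_len(n)) {
    t_i <- tot[i]
    a_min <- max(0L, as.integer(ceiling((t_i - 16) / 2)))
    a_max <- t_i %/% 3L
    feas <- a_min:a_max
    feas <- feas[(t_i - 3L * feas) + feas <= 16L & (t_i - 3L * feas) >= 0L]
    a <- if (length(feas) == 1L) feas else sample(feas, 1L)
    b <- t_i - 3L * a
    slots <- sample.int(16L, a + b)
    if (a > 0) items[i, slots[seq_len(a)]] <- 3L
    if (b > 0) items[i, slots[a + seq_len(b)]] <- 1L
  }
  colnames(items) <- sprintf("srei_item%02d", 1:16)
  list(total = tot, items = items)
}

## logit-scale linear predictor -> beta matrix (probes x samples)
cohort_beta <- function(config, baseline, delta_logit_region, in_region,
                        regions, cohort, pheno, srei, srei_center) {
  n_probes <- length(baseline)
  n_samples <- nrow(pheno)
  eta <- matrix(logit(baseline), n_probes, n_samples)
  ## planted group effect: neglect samples, probes of matching cohort
  hit <- in_region > 0L &
    regions$cohort[pmax(in_region, 1L)] %in% c(cohort, "shared")
  if (any(hit)) {
    ng <- pheno$group == "neglect"
    eta[hit, ng] <- eta[hit, ng] + delta_logit_region[hit]
  }
  ## nuisance covariates, centred, on the logit scale
  ce <- config$covariate_effects
  for (nm in names(ce)) {
    if (!nm %in% names(pheno)) next
    v <- pheno[[nm]]
    if (!is.numeric(v) || all(is.na(v))) next
    eta <- eta + rep(ce[[nm]] * (v - mean(v, na.rm = TRUE)),
                     each = n_probes)
  }
  ## SREI adversity slope inside configured planted regions
  if (config$srei_effect_beta != 0 && !is.null(srei)) {
    tgt <- if (config$srei_effect_regions == "all") c("shared", "mother", "child")
           else config$srei_effect_regions
    sprobe <- in_region > 0L & regions$cohort[pmax(in_region, 1L)] %in% tgt
    if (any(sprobe)) {
      b0 <- baseline[sprobe]
      slope_logit <- config$srei_effect_beta / (b0 * (1 - b0))
      eta[sprobe, ] <- eta[sprobe, ] +
        outer(slope_logit, srei - srei_center)
    }
  }
  if (config$noise_sd_logit > 0)
    eta <- eta + stats::rnorm(length(eta), 0, config$noise_sd_logit)
  invlogit(eta)
}

## beta matrix -> intensity pair with fixed total intensity
beta_to_intensities <- function(beta, config, sample_ids, probe_ids,
                                fail_probes, fail_samples) {
  total <- config$total_intensity
  M <- beta * (total + 100)
  M <- pmin(M, total)
  U <- total - M
  n_probes <- nrow(beta); n_samples <- ncol(beta)
  detection_p <- matrix(stats::runif(n_probes * n_samples, 0, 0.01),
                        n_probes, n_samples)
  if (length(fail_probes))
    detection_p[fail_probes, ] <- stats::runif(length(fail_probes) * n_samples,
                                               0.08, 0.4)
  if (length(fail_samples))
    detection_p[, fail_samples] <- stats::runif(n_probes * length(fail_samples),
                                                0.12, 0.4)
  dimnames(M) <- dimnames(U) <- dimnames(detection_p) <-
    list(probe_ids, sample_ids)
  intensity_pair(M, U, detection_p)
}

#' Simulate paired mother and child methylation cohorts
#'
#' Draws beta values from a logit-normal model — per-probe baseline in
#' \[0.05, 0.95\], a planted group effect on the probes of each cohort's
#' planted regions (exact beta-scale shift `effect_size` before noise),
#' centred nuisance covariate effects, an optional SREI adversity slope,
#' and logit-scale Gaussian noise — then converts them to
#' methylated/unmethylated intensity pairs with fixed total intensity so
#' that `M / (U + M + 100)` recovers the drawn beta. SREI totals are drawn
#' per group at the configured moments and decomposed into 16 items scored
#' 0/1/3; each child is linked to one mother of the same group via a dyad
#' id and inherits the mother's SREI total as `srei_total_mother`.
#'
#' @param config a [sim_config()] object.
#' @param annotation the annotation returned by [generate_annotation()] for
#'   the same config.
#' @return a list with elements `mother` and `child` (each an
#'   [intensity_pair()]), `pheno` (one phenotype `data.frame` for all
#'   samples), and `truth` (planted regions and contaminant probes).
#' @export
simulate_cohorts <- function(config, annotation) {
  stop_if_not(inherits(config, "sim_config"), "config must be a sim_config")
  regions <- attr(annotation, "planted")
  stop_if_not(!is.null(regions),
              "annotation must come from generate_annotation()")
  stop_if_not(nrow(annotation) == config$n_probes,
              "annotation size does not match config (",
              nrow(annotation), " vs ", config$n_probes, " probes)")
  set.seed(substream_seed(config$seed, 202L))

  n <- config$n_probes
  in_region <- integer(n)
  for (r in seq_len(nrow(regions)))
    in_region[regions$idx_start[r]:regions$idx_end[r]] <- r

  baseline <- stats::runif(n, 0.05, 0.95)
  baseline[in_region > 0L] <- stats::runif(sum(in_region > 0L), 0.2, 0.8)
  ## exact beta-scale shift: logit(baseline + sign*effect) - logit(baseline)
  planted <- in_region > 0L
  delta_for <- function(flip_shared) {
    d <- numeric(n)
    if (!any(planted)) return(d)
    sgn <- regions$sign[in_region[planted]]
    if (flip_shared != 1) {
      sh <- regions$cohort[in_region[planted]] == "shared"
      sgn[sh] <- flip_shared * sgn[sh]
    }
    eff <- regions$effect_size[in_region[planted]]
    target <- pmin(pmax(baseline[planted] + sgn * eff, 0.005), 0.995)
    d[planted] <- logit(target) - logit(baseline[planted])
    d
  }
  delta_logit_region <- delta_for(1)

  pheno_m <- make_pheno(config, "mother")
  pheno_c <- make_pheno(config, "child")
  ## dyads: each child is the child of one same-group mother
  for (g in c("neglect", "control")) {
    cm <- which(pheno_m$group == g)
    cc <- which(pheno_c$group == g)
    stop_if_not(length(cc) <= length(cm),
                "more ", g, " children than mothers")
    pheno_c$dyad_id[cc] <- pheno_m$dyad_id[cm[seq_along(cc)]]
  }
  pheno_c$maternal_age_birth <-
    pheno_m$age[match(pheno_c$dyad_id, pheno_m$dyad_id)] - pheno_c$age
  pheno_m$maternal_age_birth <- NA_real_

  srei_m <- draw_srei(nrow(pheno_m),
                      ifelse(pheno_m$group == "neglect",
                             config$srei_mean_neglect, config$srei_mean_control),
                      ifelse(pheno_m$group == "neglect",
                             config$srei_sd_neglect, config$srei_sd_control))
  pheno_m <- cbind(pheno_m, srei_total = srei_m$total, srei_m$items,
                   stringsAsFactors = FALSE)
  pheno_c$srei_total <- NA_integer_
  pheno_c[colnames(srei_m$items)] <- NA_integer_
  pheno_c$srei_total_mother <-
    pheno_m$srei_total[match(pheno_c$dyad_id, pheno_m$dyad_id)]
  pheno_m$srei_total_mother <- pheno_m$srei_total
  srei_center <- mean(pheno_m$srei_total)

  delta_child <- delta_for(if (config$child_sign == "opposite") -1 else 1)

  beta_m <- cohort_beta(config, baseline, delta_logit_region, in_region,
                        regions, "mother", pheno_m,
                        pheno_m$srei_total_mother, srei_center)
  beta_c <- cohort_beta(config, baseline, delta_child,
                        in_region, regions, "child", pheno_c,
                        pheno_c$srei_total_mother, srei_center)

  fail_probes <- which(seq_len(n) %in%
                         sample.int(n, round(config$detection_fail_rate * n)) &
                         in_region == 0L)
  fail_samples_m <- if (config$n_failing_samples > 0)
    which(pheno_m$group == "control")[seq_len(config$n_failing_samples)]
  else integer(0)

  ip_m <- beta_to_intensities(beta_m, config, pheno_m$sample_id,
                              annotation$probe_id, fail_probes, fail_samples_m)
  ip_c <- beta_to_intensities(beta_c, config, pheno_c$sample_id,
                              annotation$probe_id, fail_probes, integer(0))

  truth <- list(
    planted_regions = regions[, c("region_id", "chrom", "start", "end",
                                  "idx_start", "idx_end", "cohort", "sign",
                                  "effect_size")],
    contaminant_probes = data.frame(
      probe_id = c(annotation$probe_id[annotation$cross_reactive],
                   annotation$probe_id[annotation$snp_overlap]),
      flag = rep(c("cross_reactive", "snp_overlap"),
                 c(sum(annotation$cross_reactive), sum(annotation$snp_overlap))),
      stringsAsFactors = FALSE),
    failing_probes = annotation$probe_id[fail_probes],
    failing_samples = pheno_m$sample_id[fail_samples_m])

  list(mother = ip_m, child = ip_c,
       pheno = rbind(pheno_m, pheno_c), truth = truth)
}

#' Simulate a complete dataset and optionally write it to disk
#'
#' Convenience wrapper: [generate_annotation()] + [simulate_cohorts()]; when
#' `dir` is given, writes the annotation TSV, per-cohort intensity and
#' detection-p TSVs, phenotype CSV and truth JSON.
#'
#' @param config a [sim_config()] object.
#' @param dir optional output directory.
#' @return invisibly, a list with `annotation`, `mother`, `child`, `pheno`,
#'   `truth` (and `paths` when files were written).
#' @export
simulate_dataset <- function(config, dir = NULL) {
  ann <- generate_annotation(config)
  sim <- simulate_cohorts(config, ann)
  out <- c(list(annotation = ann), sim)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      annotation = file.path(dir, "annotation.tsv"),
      pheno = file.path(dir, "pheno.csv"),
      truth = file.path(dir, "truth.json"))
    write_annotation(ann, paths$annotation)
    write_pheno(sim$pheno, paths$pheno)
    write_truth(sim$truth, paths$truth)
    for (ch in c("mother", "child")) {
      for (mat in c("M", "U", "detection_p")) {
        p <- file.path(dir, paste0(ch, "_", mat, ".tsv"))
        write_matrix_tsv(sim[[ch]][[mat]], p)
        paths[[paste0(ch, "_", mat)]] <- p
      }
    }
    out$paths <- paths
  }
  invisible(out)
}
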