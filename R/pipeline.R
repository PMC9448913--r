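#' End-to-end paired-cohort DMR pipeline
#'
#' Orchestrates the full analysis on a simulated (or previously written)
#' dataset: preprocessing of both cohorts, one bump-hunting fit per
#' cohort with the cohort-appropriate nuisance covariates, the joint
#' mother-child analysis, and (optionally) the adversity covariate
#' association within the shared regions.
#'
#' Ground truth is never consulted by any analysis stage; it is only used
#' by [evaluate_recovery()].
#'
#' @param sim a dataset from [simulate_dataset()] (list with `annotation`,
#'   `mother`, `child`, `pheno`, `truth`).
#' @param bump_cfg a [bump_config()] applied to both cohorts.
#' @param joint_cfg a [joint_config()].
#' @param thresholds a [qc_thresholds()].
#' @param mother_covariates,child_covariates nuisance covariates per
#'   cohort.
#' @param probe_filter `"joint"` (default): probe detection means are
#'   pooled across both cohorts (all samples share one probe set), so the
#'   same probes are removed from both; `"separate"`: each cohort is
#'   filtered on its own samples.
#' @param run_covariate run the SREI association on the mother cohort over
#'   the shared regions (skipped when no region is shared).
#' @param out_dir optional directory; when given, bump tables (TSV + BED),
#'   the matched-pair table, a z-z scatter data file and a JSON summary
#'   are written there.
#' @return a list of class `dyad_pipeline`: `qc` (per-cohort reports),
#'   `mother_fit`, `child_fit`, `joint`, `covariate` (or NULL).
#' @export
run_dyad_pipeline <- function(sim,
                              bump_cfg = bump_config(),
                              joint_cfg = joint_config(),
                              thresholds = qc_thresholds(),
                              mother_covariates = c("epithelial", "age",
                                                    "education"),
                              child_covariates = c("epithelial", "age",
                                                   "maternal_age_birth"),
                              probe_filter = c("joint", "separate"),
                              run_covariate = TRUE,
                              out_dir = NULL) {
  probe_filter <- match.arg(probe_filter)
  for (need in c("annotation", "mother", "child", "pheno"))
    stop_if_not(!is.null(sim[[need]]), "dataset is missing the '", need,
                "' cohort/component")
  ann <- sim$annotation
  ip_m <- sim$mother; ip_c <- sim$child

  if (probe_filter == "joint") {
    pooled <- rowMeans(cbind(ip_m$detection_p, ip_c$detection_p))
    keep <- pooled <= thresholds$probe_detection_max
    stop_if_not(any(keep), "all probes removed by pooled detection filter")
    ip_m <- subset_intensities(ip_m, probes = keep)
    ip_c <- subset_intensities(ip_c, probes = keep)
    ip_m$log <- log_filter(ip_m$log, "probe_detection_pooled", "probe",
                           sum(!keep), "pooled mean detection p > threshold")
    ip_c$log <- log_filter(ip_c$log, "probe_detection_pooled", "probe",
                           sum(!keep), "pooled mean detection p > threshold")
  }

  beta_m <- preprocess_cohort(ip_m, ann, thresholds)
  beta_c <- preprocess_cohort(ip_c, ann, thresholds)

  ph_m <- sim$pheno[sim$pheno$role == "mother" &
                      sim$pheno$sample_id %in% beta_m$sample_ids, ]
  ph_c <- sim$pheno[sim$pheno$role == "child" &
                      sim$pheno$sample_id %in% beta_c$sample_ids, ]

  des_m <- design_matrix(ph_m, "group", mother_covariates)
  des_c <- design_matrix(ph_c, "group", child_covariates)

  fit_m <- bump_hunt(beta_m, des_m, ann, bump_cfg)
  cfg_c <- bump_cfg
  cfg_c$seed <- substream_seed(bump_cfg$seed, 7L)   # independent bootstrap
  fit_c <- bump_hunt(beta_c, des_c, ann, cfg_c)

  joint <- joint_dmr(fit_m, fit_c, joint_cfg)

  covar <- NULL
  if (run_covariate && nrow(joint$shared) > 0) {
    regions <- joint$shared[c("chrom", "start", "end", "gene")]
    covar <- associate_covariate(beta_m, ph_m, ann, regions,
                                 covariate = "srei_total",
                                 covariates = c("epithelial", "age"),
                                 config = bump_cfg)
  }

  out <- structure(list(qc = list(mother = qc_report(beta_m$log),
                                  child = qc_report(beta_c$log)),
                        mother_fit = fit_m, child_fit = fit_c,
                        joint = joint, covariate = covar),
                   class = "dyad_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bumps_tsv(fit_m$bumps, file.path(out_dir, "mother_bumps.tsv"))
    write_bumps_tsv(fit_c$bumps, file.path(out_dir, "child_bumps.tsv"))
    write_bumps_bed(fit_m$bumps, file.path(out_dir, "mother_bumps.bed"))
    write_bumps_bed(fit_c$bumps, file.path(out_dir, "child_bumps.bed"))
    utils::write.table(joint$pairs, file.path(out_dir, "matched_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      joint$pairs[c("z_mother", "z_child")],
      file.path(out_dir, "zz_scatter.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_summary(
      list(correlation = joint$correlation,
           n_mother_candidates = joint$n_mother_candidates,
           n_child_candidates = joint$n_child_candidates,
           n_matched = joint$n_matched,
           n_mother_sig = joint$n_mother_sig,
           n_child_sig = joint$n_child_sig,
           n_shared_sig = joint$n_shared_sig,
           alpha = joint$alpha, joint_level = joint$joint_level,
           seed = bump_cfg$seed),
      file.path(out_dir, "joint_summary.json"))
  }
  out
}

#' @export
print.dyad_pipeline <- function(x, ...) {
  cat("Paired-cohort DMR pipeline\n\n")
  print(x$joint)
  invisible(x)
}

#' Score planted-region recovery against ground truth
#'
#' Compares detected regions with the simulation truth: a planted region
#' counts as recovered when a reported region overlaps it by at least one
#' base. Returns per-cohort sensitivity and false discovery rate at
#' `alpha`, and the sensitivity of the joint intersection for the shared
#' regions.
#'
#' @param pipeline a [run_dyad_pipeline()] result.
#' @param truth the `truth` element of the simulated dataset.
#' @param alpha significance level for calling a bump a DMR.
#' @return a list of recovery metrics.
#' @export
evaluate_recovery <- function(pipeline, truth, alpha = 0.01) {
  regions <- truth$planted_regions
  overlap_any <- function(calls, region) {
    any(calls$chrom == region$chrom &
          calls$start < region$end & calls$end > region$start)
  }
  cohort_metrics <- function(fit, cohorts) {
    planted <- regions[regions$cohort %in% cohorts, , drop = FALSE]
    calls <- fit$bumps[fit$bumps$p_value < alpha, , drop = FALSE]
    hit <- vapply(seq_len(nrow(planted)), function(i)
      overlap_any(calls, planted[i, ]), logical(1))
    fp <- vapply(seq_len(nrow(calls)), function(i)
      !overlap_any(regions, calls[i, ]), logical(1))
    list(sensitivity = if (nrow(planted)) mean(hit) else NA_real_,
         fdr = if (nrow(calls)) mean(fp) else NA_real_,
         n_called = nrow(calls))
  }
  shared <- regions[regions$cohort == "shared", , drop = FALSE]
  joint_calls <- pipeline$joint$shared
  shared_hit <- vapply(seq_len(nrow(shared)), function(i)
    overlap_any(joint_calls, shared[i, ]), logical(1))
  list(mother = cohort_metrics(pipeline$mother_fit, c("mother", "shared")),
       child = cohort_metrics(pipeline$child_fit, c("child", "shared")),
       shared_sensitivity = if (nrow(shared)) mean(shared_hit) else NA_real_,
       n_shared_called = nrow(joint_calls))
}
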