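#' Methylated/unmethylated intensity pair
#'
#' Container for probe-level methylated (`M`) and unmethylated (`U`)
#' intensity matrices (probes in rows, samples in columns) with companion
#' detection p-values, plus a provenance log of quality filters applied.
#'
#' @param M,U non-negative intensity matrices, probes x samples.
#' @param detection_p matrix of per-probe, per-sample detection p-values in
#'   \[0, 1\], same shape.
#' @return an object of class `intensity_pair`.
#' @export
intensity_pair <- function(M, U, detection_p) {
  stop_if_not(all(dim(M) == dim(U)) && all(dim(M) == dim(detection_p)),
              "M, U and detection_p must share dimensions")
  neg <- which(M < 0 | U < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative intensity at probe ", rownames(M)[neg[1, 1]] %||% neg[1, 1],
         ", sample ", colnames(M)[neg[1, 2]] %||% neg[1, 2], call. = FALSE)
  stop_if_not(all(detection_p >= 0 & detection_p <= 1),
              "detection p-values must lie in [0, 1]")
  structure(list(M = M, U = U, detection_p = detection_p,
                 probe_ids = rownames(M), sample_ids = colnames(M),
                 log = empty_filter_log()),
            class = "intensity_pair")
}

empty_filter_log <- function() {
  data.frame(step = character(), unit = character(), n_removed = integer(),
             reason = character(), stringsAsFactors = FALSE)
}

log_filter <- function(log, step, unit, n_removed, reason) {
  rbind(log, data.frame(step = step, unit = unit, n_removed = n_removed,
                        reason = reason, stringsAsFactors = FALSE))
}

#' @export
print.intensity_pair <- function(x, ...) {
  cat("intensity_pair:", nrow(x$M), "probes x", ncol(x$M), "samples\n")
  if (nrow(x$log)) {
    cat("filters applied:\n")
    print(x$log, row.names = FALSE)
  }
  invisible(x)
}

#' Quality-control thresholds
#'
#' @param probe_detection_max probes whose mean detection p across samples
#'   exceeds this are removed (default 0.05).
#' @param sample_detection_max samples whose mean detection p across probes
#'   exceeds this are removed (default 0.1).
#' @param beta_offset offset added to the denominator of the beta value
#'   (default 100).
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(probe_detection_max = 0.05,
                          sample_detection_max = 0.1,
                          beta_offset = 100) {
  stop_if_not(probe_detection_max > 0 && probe_detection_max < 1 &&
                sample_detection_max > 0 && sample_detection_max < 1,
              "detection thresholds must lie in (0, 1)")
  stop_if_not(beta_offset > 0, "beta_offset must be positive")
  structure(list(probe_detection_max = probe_detection_max,
                 sample_detection_max = sample_detection_max,
                 beta_offset = beta_offset), class = "qc_thresholds")
}

#' Compute beta methylation values
#'
#' Beta value per probe and sample: `M / (U + M + offset)`. The offset
#' stabilises the ratio at low total intensity and bounds values in
#' \[0, 1).
#'
#' @param intensities an [intensity_pair()].
#' @param offset non-negative denominator offset (default 100).
#' @return a `beta_matrix`: list with `values` (probes x samples),
#'   `probe_ids`, `sample_ids` and the inherited filter `log`.
#' @export
compute_beta <- function(intensities, offset = 100) {
  stop_if_not(inherits(intensities, "intensity_pair"),
              "intensities must be an intensity_pair")
  stop_if_not(offset >= 0, "offset must be >= 0")
  values <- intensities$M / (intensities$U + intensities$M + offset)
  values[intensities$M == 0 & intensities$U == 0] <- 0
  structure(list(values = values,
                 probe_ids = intensities$probe_ids,
                 sample_ids = intensities$sample_ids,
                 log = intensities$log),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples; range", sprintf("%.3f-%.3f", min(x$values), max(x$values)),
      "\n")
  invisible(x)
}

#' Remove probes failing detection
#'
#' Removes probes whose mean detection p-value across the current samples
#' strictly exceeds `probe_detection_max` (boundary values are retained).
#'
#' @param intensities an [intensity_pair()].
#' @param thresholds a [qc_thresholds()].
#' @return the filtered `intensity_pair` with an updated provenance log.
#' @export
filter_probes_by_detection <- function(intensities,
                                       thresholds = qc_thresholds()) {
  mp <- rowMeans(intensities$detection_p)
  keep <- mp <= thresholds$probe_detection_max
  if (!any(keep)) stop("all probes removed by detection filter", call. = FALSE)
  out <- subset_intensities(intensities, probes = keep)
  out$log <- log_filter(out$log, "probe_detection", "probe", sum(!keep),
                        paste0("mean detection p > ",
                               thresholds$probe_detection_max))
  out
}

#' Remove samples failing detection
#'
#' Removes samples whose mean detection p-value across the current probes
#' strictly exceeds `sample_detection_max`.
#'
#' @inheritParams filter_probes_by_detection
#' @return the filtered `intensity_pair` with an updated provenance log.
#' @export
filter_samples_by_detection <- function(intensities,
                                        thresholds = qc_thresholds()) {
  mp <- colMeans(intensities$detection_p)
  keep <- mp <= thresholds$sample_detection_max
  if (!any(keep)) stop("all samples removed by detection filter", call. = FALSE)
  out <- subset_intensities(intensities, samples = keep)
  out$log <- log_filter(out$log, "sample_detection", "sample", sum(!keep),
                        paste0("mean detection p > ",
                               thresholds$sample_detection_max))
  out
}

subset_intensities <- function(ip, probes = NULL, samples = NULL) {
  if (!is.null(probes)) {
    ip$M <- ip$M[probes, , drop = FALSE]
    ip$U <- ip$U[probes, , drop = FALSE]
    ip$detection_p <- ip$detection_p[probes, , drop = FALSE]
    ip$probe_ids <- rownames(ip$M)
  }
  if (!is.null(samples)) {
    ip$M <- ip$M[, samples, drop = FALSE]
    ip$U <- ip$U[, samples, drop = FALSE]
    ip$detection_p <- ip$detection_p[, samples, drop = FALSE]
    ip$sample_ids <- colnames(ip$M)
  }
  ip
}

#' Remove annotation-flagged probes
#'
#' Drops probes carrying any of the requested contamination flags
#' (`cross_reactive`, `snp_overlap`). Probes matching several flags are
#' removed once (set union).
#'
#' @param beta a `beta_matrix` from [compute_beta()].
#' @param annotation probe annotation with flag columns.
#' @param flags character vector of flag column names; empty means no-op.
#' @return the filtered `beta_matrix` with an updated log.
#' @export
remove_flagged_probes <- function(beta, annotation,
                                  flags = c("cross_reactive", "snp_overlap")) {
  known <- c("cross_reactive", "snp_overlap")
  bad <- setdiff(flags, known)
  if (length(bad)) stop("unknown flag name(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  idx <- match(beta$probe_ids, annotation$probe_id)
  stop_if_not(!anyNA(idx), "all probes must be annotated")
  drop <- rep(FALSE, length(idx))
  for (f in flags) drop <- drop | annotation[[f]][idx]
  out <- beta
  out$values <- beta$values[!drop, , drop = FALSE]
  out$probe_ids <- beta$probe_ids[!drop]
  out$log <- log_filter(beta$log, "flagged_probes", "probe", sum(drop),
                        paste0("flagged: ", paste(flags, collapse = "+")))
  out
}

#' Simplified per-channel dye-bias rescaling
#'
#' Two-colour arrays can show global intensity differences between the
#' methylated and unmethylated channels. This optional correction rescales
#' both channels of each sample to a common per-sample median (the
#' geometric mean of the two channel medians), which removes a
#' multiplicative channel imbalance while leaving balanced data nearly
#' unchanged.
#'
#' @param intensities an [intensity_pair()].
#' @return the rescaled `intensity_pair`.
#' @export
dye_bias_rescale <- function(intensities) {
  m_med <- apply(intensities$M, 2, stats::median)
  u_med <- apply(intensities$U, 2, stats::median)
  stop_if_not(all(m_med > 0) && all(u_med > 0),
              "channel medians must be positive to rescale")
  target <- sqrt(m_med * u_med)
  out <- intensities
  out$M <- sweep(intensities$M, 2, target / m_med, `*`)
  out$U <- sweep(intensities$U, 2, target / u_med, `*`)
  out$log <- log_filter(out$log, "dye_bias_rescale", "sample", 0L,
                        "per-channel median rescaling")
  out
}

#' Full preprocessing for one cohort
#'
#' Applies, in order: probe detection filter, sample detection filter, a
#' re-check pass (probe means change after sample removal, so both filters
#' are re-applied once so the final state is a fixed point), beta
#' computation, and contaminant probe removal.
#'
#' @param intensities an [intensity_pair()].
#' @param annotation probe annotation table.
#' @param thresholds a [qc_thresholds()].
#' @param flags contamination flags to drop (see [remove_flagged_probes()]).
#' @param dye_bias apply [dye_bias_rescale()] first.
#' @return a `beta_matrix` whose `log` records every removal.
#' @export
preprocess_cohort <- function(intensities, annotation,
                              thresholds = qc_thresholds(),
                              flags = c("cross_reactive", "snp_overlap"),
                              dye_bias = FALSE) {
  if (dye_bias) intensities <- dye_bias_rescale(intensities)
  ip <- filter_probes_by_detection(intensities, thresholds)
  ip <- filter_samples_by_detection(ip, thresholds)
  ip <- filter_probes_by_detection(ip, thresholds)   # re-check pass
  ip <- filter_samples_by_detection(ip, thresholds)
  beta <- compute_beta(ip, thresholds$beta_offset)
  remove_flagged_probes(beta, annotation, flags)
}

#' QC report from a filter log
#'
#' @param log the `log` element of a filtered object.
#' @return a list with per-step removal counts, suitable for
#'   [write_json_summary()].
#' @export
qc_report <- function(log) {
  list(steps = log,
       n_probes_removed = sum(log$n_removed[log$unit == "probe"]),
       n_samples_removed = sum(log$n_removed[log$unit == "sample"]))
}
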