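#' Joint-analysis configuration
#'
#' @param alpha per-cohort significance level (default 0.01). Requiring a
#'   matched region to pass `alpha` in both independent cohorts gives a
#'   joint chance level of `alpha^2`.
#' @param z_convention `"one_sided_magnitude"` (z = qnorm(1 - p), default)
#'   or `"signed_two_sided"` (z = sign * qnorm(1 - p/2)).
#' @param min_overlap_bp minimum genomic overlap (bp) for two candidate
#'   regions to be matched.
#' @return a list of class `joint_config`.
#' @export
joint_config <- function(alpha = 0.01,
                         z_convention = c("one_sided_magnitude",
                                          "signed_two_sided"),
                         min_overlap_bp = 1L) {
  z_convention <- match.arg(z_convention)
  stop_if_not(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  stop_if_not(min_overlap_bp >= 1, "min_overlap_bp must be >= 1")
  structure(list(alpha = alpha, z_convention = z_convention,
                 min_overlap_bp = as.integer(min_overlap_bp)),
            class = "joint_config")
}

#' Convert p-values to z-statistics
#'
#' Maps bump p-values to the z scale, which is better suited for
#' correlating region-level evidence across cohorts. Strictly decreasing
#' in p.
#'
#' @param p p-values in (0, 1\].
#' @param convention see [joint_config()].
#' @param effect_sign sign(s) of the effect, used by the signed convention.
#' @param n_null pooled null size; a p of exactly 0 (which the bootstrap
#'   plus-one rule never produces itself) is mapped to `1/(1 + n_null)`
#'   with a warning.
#' @return z-statistics.
#' @export
z_transform <- function(p, convention = c("one_sided_magnitude",
                                          "signed_two_sided"),
                        effect_sign = 1, n_null = NULL) {
  convention <- match.arg(convention)
  stop_if_not(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  if (any(p == 0)) {
    stop_if_not(!is.null(n_null),
                "p = 0 supplied without n_null to map it to a floor")
    warning("p = 0 mapped to 1/(1 + n_null)", call. = FALSE)
    p[p == 0] <- 1 / (1 + n_null)
  }
  switch(convention,
         one_sided_magnitude = stats::qnorm(1 - p),
         signed_two_sided = effect_sign * stats::qnorm(1 - p / 2))
}

#' Match candidate regions across cohorts by genomic overlap
#'
#' One-to-one greedy matching: overlapping pairs (same chromosome, at
#' least `min_overlap_bp` shared base pairs under the half-open
#' convention) are ranked by descending overlap, ties broken by leftmost
#' start; each bump participates in at most one pair. The result is
#' invariant to swapping the two input sets.
#'
#' @param mother_bumps,child_bumps bump `data.frame`s with `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param config a [joint_config()].
#' @return a `data.frame` with `mother_idx`, `child_idx` (row indices into
#'   the inputs), `chrom`, `overlap_bp`.
#' @export
match_regions <- function(mother_bumps, child_bumps,
                          config = joint_config()) {
  empty <- data.frame(mother_idx = integer(), child_idx = integer(),
                      chrom = character(), overlap_bp = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(mother_bumps) == 0 || nrow(child_bumps) == 0) return(empty)
  hits <- list()
  for (ch in intersect(unique(mother_bumps$chrom), unique(child_bumps$chrom))) {
    mi <- which(mother_bumps$chrom == ch)
    ci <- which(child_bumps$chrom == ch)
    ## half-open [start, end) -> closed 1-based [start+1, end]
    ir_m <- IRanges::IRanges(mother_bumps$start[mi] + 1L,
                             mother_bumps$end[mi])
    ir_c <- IRanges::IRanges(child_bumps$start[ci] + 1L,
                             child_bumps$end[ci])
    fo <- IRanges::findOverlaps(ir_m, ir_c,
                                minoverlap = config$min_overlap_bp)
    if (length(fo) == 0) next
    q <- S4Vectors::queryHits(fo); s <- S4Vectors::subjectHits(fo)
    ov <- IRanges::width(IRanges::pintersect(ir_m[q], ir_c[s]))
    hits[[ch]] <- data.frame(mother_idx = mi[q], child_idx = ci[s],
                             chrom = ch, overlap_bp = ov,
                             stringsAsFactors = FALSE)
  }
  if (length(hits) == 0) return(empty)
  hits <- do.call(rbind, hits)
  smin <- pmin(mother_bumps$start[hits$mother_idx],
               child_bumps$start[hits$child_idx])
  smax <- pmax(mother_bumps$start[hits$mother_idx],
               child_bumps$start[hits$child_idx])
  hits <- hits[order(-hits$overlap_bp, hits$chrom, smin, smax), , drop = FALSE]
  used_m <- logical(nrow(mother_bumps)); used_c <- logical(nrow(child_bumps))
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    m <- hits$mother_idx[i]; cc <- hits$child_idx[i]
    if (!used_m[m] && !used_c[cc]) {
      keep[i] <- TRUE; used_m[m] <- TRUE; used_c[cc] <- TRUE
    }
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlate cross-cohort z-statistics
#'
#' Pearson correlation of matched mother and child z-statistics, with a
#' two-sided p-value from the t distribution on n - 2 degrees of freedom.
#'
#' @param z_mother,z_child matched z vectors (length >= 3).
#' @return list with `r`, `p_value`, `n`.
#' @export
correlate_z <- function(z_mother, z_child) {
  stop_if_not(length(z_mother) == length(z_child),
              "z vectors must have equal length")
  stop_if_not(length(z_mother) >= 3, "at least 3 pairs required")
  if (stats::sd(z_mother) == 0 || stats::sd(z_child) == 0) {
    warning("zero variance in z-statistics; correlation undefined",
            call. = FALSE)
    return(list(r = NA_real_, p_value = NA_real_, n = length(z_mother)))
  }
  ct <- stats::cor.test(z_mother, z_child, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(z_mother))
}

#' Intersect marginally significant matched regions
#'
#' Keeps matched pairs significant at `alpha` in both cohorts. The implied
#' chance level of passing both independent tests is `alpha^2`.
#'
#' @param pairs matched-pair `data.frame` with `p_mother`, `p_child`.
#' @param alpha per-cohort significance level.
#' @return list with `shared` (the kept rows) and `joint_level`
#'   (`alpha^2`).
#' @export
intersect_significant <- function(pairs, alpha = 0.01) {
  keep <- pairs$p_mother < alpha & pairs$p_child < alpha
  list(shared = pairs[keep, , drop = FALSE], joint_level = alpha^2)
}

#' Joint mother-child DMR analysis
#'
#' Matches the candidate regions of two [bump_hunt()] fits by genomic
#' overlap, converts bump p-values to z-statistics, correlates the matched
#' z-statistics genome-wide (a threshold-free measure of cross-generation
#' similarity), and intersects the marginally significant regions at the
#' per-cohort level `alpha`, for a joint chance level of `alpha^2`.
#'
#' @param mother_fit,child_fit `bump_hunt` objects for the two cohorts.
#' @param config a [joint_config()].
#' @return an object of class `joint_dmr`: matched `pairs` (with z and p
#'   per cohort, sign pattern, gene), `correlation`, marginal and shared
#'   significant counts, the `shared` region table and `joint_level`.
#' @export
joint_dmr <- function(mother_fit, child_fit, config = joint_config()) {
  stop_if_not(inherits(mother_fit, "bump_hunt") &&
                inherits(child_fit, "bump_hunt"),
              "inputs must be bump_hunt fits")
  mb <- mother_fit$bumps; cb <- child_fit$bumps
  pairs <- match_regions(mb, cb, config)
  ## clip p away from 1 so qnorm stays finite (floor mirrors the
  ## bootstrap plus-one resolution)
  clip <- function(p, n_null) pmin(p, 1 - 0.5 / (1 + n_null))
  pairs$p_mother <- mb$p_value[pairs$mother_idx]
  pairs$p_child <- cb$p_value[pairs$child_idx]
  pairs$sign_mother <- mb$sign[pairs$mother_idx]
  pairs$sign_child <- cb$sign[pairs$child_idx]
  pairs$z_mother <- z_transform(clip(pairs$p_mother, mother_fit$n_null),
                                config$z_convention, pairs$sign_mother)
  pairs$z_child <- z_transform(clip(pairs$p_child, child_fit$n_null),
                               config$z_convention, pairs$sign_child)
  pairs$gene <- mb$gene[pairs$mother_idx]
  pairs$start <- pmin(mb$start[pairs$mother_idx], cb$start[pairs$child_idx])
  pairs$end <- pmax(mb$end[pairs$mother_idx], cb$end[pairs$child_idx])
  pairs$sign_pattern <- paste0(ifelse(pairs$sign_mother > 0, "+", "-"), "/",
                               ifelse(pairs$sign_child > 0, "+", "-"))

  correlation <- if (nrow(pairs) >= 3)
    correlate_z(pairs$z_mother, pairs$z_child)
  else list(r = NA_real_, p_value = NA_real_, n = nrow(pairs))

  inter <- intersect_significant(pairs, config$alpha)
  structure(list(pairs = pairs, correlation = correlation,
                 n_mother_candidates = nrow(mb),
                 n_child_candidates = nrow(cb),
                 n_matched = nrow(pairs),
                 n_mother_sig = sum(mb$p_value < config$alpha),
                 n_child_sig = sum(cb$p_value < config$alpha),
                 n_shared_sig = nrow(inter$shared),
                 shared = inter$shared, joint_level = inter$joint_level,
                 alpha = config$alpha, config = config),
            class = "joint_dmr")
}

#' @export
print.joint_dmr <- function(x, ...) {
  cat("Joint mother-child DMR analysis\n")
  cat(sprintf("  candidates: %d mother, %d child, %d matched\n",
              x$n_mother_candidates, x$n_child_candidates, x$n_matched))
  if (!is.na(x$correlation$r))
    cat(sprintf("  z correlation: r = %.3f (p = %.3g, n = %d)\n",
                x$correlation$r, x$correlation$p_value, x$correlation$n))
  cat(sprintf("  at alpha = %g: %d mother DMRs, %d child DMRs, %d shared (joint level %g)\n",
              x$alpha, x$n_mother_sig, x$n_child_sig, x$n_shared_sig,
              x$joint_level))
  if (nrow(x$shared)) {
    cat("  shared regions:\n")
    print(x$shared[c("chrom", "start", "end", "gene", "sign_pattern",
                     "p_mother", "p_child")], row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn joint_dmr z-z scatter of matched regions; the dashed lines
#'   mark the z value of the per-cohort significance level and jointly
#'   significant regions are drawn in red.
#' @param x a `joint_dmr` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.joint_dmr <- function(x, ...) {
  p <- x$pairs
  stop_if_not(nrow(p) > 0, "no matched pairs to plot")
  sig <- p$p_mother < x$alpha & p$p_child < x$alpha
  graphics::plot(p$z_mother, p$z_child,
                 col = ifelse(sig, "red", "grey40"),
                 pch = ifelse(sig, 16, 1),
                 xlab = "mother z", ylab = "child z", ...)
  zc <- stats::qnorm(1 - x$alpha)
  graphics::abline(v = zc, h = zc, col = "darkgreen", lty = 2)
  if (nrow(p) >= 3 && !is.na(x$correlation$r))
    graphics::abline(stats::lm(p$z_child ~ p$z_mother), col = "red")
  invisible(x)
}
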