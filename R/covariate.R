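#' Total SREI adversity score
#'
#' The Stressful and Risky Events Inventory comprises 16 adverse-event
#' items, each scored by emotional impact: 0 (no occurrence), 1 (little
#' impact) or 3 (very high impact). The total is the cumulative emotional
#' intensity, ranging 0 to 48.
#'
#' @param item_scores numeric vector of 16 item scores, or a matrix with 16
#'   columns (one row per respondent).
#' @return the total score (per row for matrix input).
#' @export
srei_total <- function(item_scores) {
  if (is.matrix(item_scores) || is.data.frame(item_scores)) {
    item_scores <- as.matrix(item_scores)
    stop_if_not(ncol(item_scores) == 16, "expected 16 SREI items")
    stop_if_not(all(item_scores %in% c(0, 1, 3)),
                "SREI item scores must be 0, 1 or 3")
    return(rowSums(item_scores))
  }
  stop_if_not(length(item_scores) == 16, "expected 16 SREI items")
  stop_if_not(all(item_scores %in% c(0, 1, 3)),
              "SREI item scores must be 0, 1 or 3")
  sum(item_scores)
}

#' Associate an adversity covariate with methylation in given regions
#'
#' Re-runs the bump-hunting engine with a continuous covariate (by default
#' the SREI total) as the tested variable — the group indicator and the
#' other nuisance covariates stay in the design — and reports, for each
#' supplied region, the sign of the average member-probe coefficient and
#' the p-value of the best-overlapping bump (p = 1 when no bump overlaps
#' the region). Region restriction is a filter on the genome-wide fit, not
#' a refit.
#'
#' @param beta a `beta_matrix` or probes x samples matrix for one cohort.
#' @param pheno phenotype rows for the same samples; the covariate must
#'   vary.
#' @param annotation probe annotation.
#' @param regions `data.frame` of regions to report on (`chrom`, `start`,
#'   `end`, half-open; typically the shared DMRs, with optional `gene` /
#'   `region_id` columns carried through).
#' @param covariate name of the tested phenotype column.
#' @param covariates nuisance covariates kept in the design.
#' @param keep_group keep the group indicator as a nuisance term (the
#'   covariate and group membership are correlated, so dropping it
#'   attributes group differences to the covariate).
#' @param config a [bump_config()].
#' @return a `data.frame`: one row per region with `sign`, `p_value`, the
#'   overlap found, and a `fit` attribute holding the underlying
#'   `bump_hunt` object.
#' @export
associate_covariate <- function(beta, pheno, annotation, regions,
                                covariate = "srei_total",
                                covariates = c("epithelial", "age"),
                                keep_group = TRUE,
                                config = bump_config()) {
  v <- pheno[[covariate]]
  stop_if_not(!is.null(v), "covariate '", covariate, "' not in pheno")
  stop_if_not(stats::sd(v, na.rm = TRUE) > 0,
              "covariate '", covariate, "' has no variance")
  nuisance <- c(if (keep_group) "group", covariates)
  design <- design_matrix(pheno, covariate, nuisance)
  fit <- bump_hunt(beta, design, annotation, config)

  out <- regions
  out$sign <- NA_integer_
  out$p_value <- 1
  out$overlap_bp <- 0L
  ann <- fit$annotation
  for (i in seq_len(nrow(regions))) {
    member <- which(ann$chrom == regions$chrom[i] &
                      ann$pos >= regions$start[i] &
                      ann$pos < regions$end[i])
    if (length(member))
      out$sign[i] <- sign(mean(fit$coefficients[member]))
    ## best-overlapping bump: maximal overlap, ties to smaller p
    b <- fit$bumps
    ov <- pmin(b$end, regions$end[i]) - pmax(b$start, regions$start[i])
    ov[b$chrom != regions$chrom[i]] <- 0L
    hit <- which(ov > 0)
    if (length(hit)) {
      best <- hit[order(-ov[hit], b$p_value[hit])][1]
      out$p_value[i] <- b$p_value[best]
      out$overlap_bp[i] <- ov[best]
    }
  }
  attr(out, "fit") <- fit
  out
}
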