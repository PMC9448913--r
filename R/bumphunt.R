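#' Bump-hunting configuration
#'
#' Hyperparameters of the DMR engine. Defaults follow common practice for
#' array DMR searches: clusters break at gaps above 1000 bp, the cutoff is
#' the 0.95 quantile of the absolute smoothed coefficient profile, the null
#' is a residual bootstrap with 1000 iterations, and smoothing is
#' cluster-wise local quadratic regression with a 1000 bp bandwidth applied
#' to clusters of at least 7 probes.
#'
#' @param max_gap maximum intra-cluster gap in bp.
#' @param pick_cutoff_q quantile in (0,1) of |smoothed coefficient| used as
#'   the bump cutoff.
#' @param n_bootstrap number of bootstrap iterations (B).
#' @param smoothing `"loess_by_cluster"` (local quadratic regression),
#'   `"running_mean"`, or `"none"`.
#' @param smooth_span_bp smoothing bandwidth in bp.
#' @param min_probes_smooth clusters below this size pass through
#'   unsmoothed.
#' @param seed integer seed for the bootstrap.
#' @return a list of class `bump_config`.
#' @export
bump_config <- function(max_gap = 1000, pick_cutoff_q = 0.95,
                        n_bootstrap = 1000L,
                        smoothing = c("loess_by_cluster", "running_mean",
                                      "none"),
                        smooth_span_bp = 1000, min_probes_smooth = 7L,
                        seed = 1L) {
  smoothing <- match.arg(smoothing)
  stop_if_not(max_gap > 0, "max_gap must be positive")
  stop_if_not(pick_cutoff_q > 0 && pick_cutoff_q < 1,
              "pick_cutoff_q must lie in (0, 1)")
  stop_if_not(n_bootstrap >= 1, "n_bootstrap must be >= 1")
  structure(list(max_gap = max_gap, pick_cutoff_q = pick_cutoff_q,
                 n_bootstrap = as.integer(n_bootstrap), smoothing = smoothing,
                 smooth_span_bp = smooth_span_bp,
                 min_probes_smooth = as.integer(min_probes_smooth),
                 seed = as.integer(seed)),
            class = "bump_config")
}

#' Cluster CpG probes by genomic proximity
#'
#' Single-linkage partition of the probe set: a new cluster starts whenever
#' the chromosome changes or the gap to the previous probe exceeds
#' `max_gap`.
#'
#' @param annotation probe annotation sorted by (chromosome, position).
#' @param max_gap maximum intra-cluster gap in bp.
#' @return a list of class `cpg_clusters` with `cluster_id` (integer per
#'   probe) and `clusters` (one row per cluster: chrom, start/end bp,
#'   probe index range, size).
#' @export
cluster_probes <- function(annotation, max_gap = 1000) {
  pos <- annotation$pos
  chrom <- annotation$chrom
  n <- length(pos)
  stop_if_not(n > 0, "empty annotation")
  same <- c(FALSE, chrom[-1] == chrom[-n])
  if (any(same & c(0, diff(pos)) <= 0))
    stop("annotation is not sorted by (chromosome, position)", call. = FALSE)
  new_cluster <- !same | c(Inf, diff(pos)) > max_gap
  cluster_id <- cumsum(new_cluster)
  idx_start <- which(new_cluster)
  idx_end <- c(idx_start[-1] - 1L, n)
  clusters <- data.frame(cluster_id = seq_along(idx_start),
                         chrom = chrom[idx_start],
                         start = pos[idx_start],
                         end = pos[idx_end] + 1L,
                         idx_start = idx_start, idx_end = idx_end,
                         n_probes = idx_end - idx_start + 1L,
                         stringsAsFactors = FALSE)
  structure(list(cluster_id = cluster_id, clusters = clusters),
            class = "cpg_clusters")
}

#' Per-probe covariate-adjusted linear models
#'
#' Fits, by ordinary least squares, the same design to every probe's
#' methylation values and extracts the coefficient (and standard error) of
#' the column of interest. A positive coefficient means the tested
#' condition (or a higher covariate score) has higher methylation.
#'
#' @param beta_values numeric matrix, probes x samples.
#' @param X design matrix, samples x covariates, full column rank.
#' @param interest_index column of `X` that is tested.
#' @return list with `coef` and `se`, one value per probe.
#' @export
fit_probe_models <- function(beta_values, X, interest_index) {
  n <- ncol(beta_values); k <- ncol(X)
  stop_if_not(nrow(X) == n, "design rows must match samples")
  qrX <- qr(X)
  if (qrX$rank < k) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):k]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  XtXi <- solve(crossprod(X))
  Yt <- t(beta_values)                       # samples x probes
  coefs <- XtXi %*% crossprod(X, Yt)         # k x probes
  res <- Yt - X %*% coefs
  df <- n - k
  sigma2 <- if (df > 0) colSums(res^2) / df else rep(NA_real_, ncol(Yt))
  list(coef = as.vector(coefs[interest_index, ]),
       se = unname(sqrt(sigma2 * XtXi[interest_index, interest_index])))
}

## tricube local polynomial smoother rows for one cluster; returns a dense
## hat matrix (n x n). Exact for polynomials up to `degree`.
local_poly_hat <- function(pos, span_bp, degree = 2L) {
  n <- length(pos)
  S <- matrix(0, n, n)
  need <- degree + 2L       # points with positive weight for a stable fit
  for (i in seq_len(n)) {
    d <- abs(pos - pos[i])
    h <- max(span_bp, sort(d)[min(need, n)] * 1.0001)
    w <- (1 - pmin(d / h, 1)^3)^3
    use <- w > 0
    t <- (pos[use] - pos[i]) / h
    deg <- degree
    row <- NULL
    while (is.null(row) && deg >= 0) {
      Z <- outer(t, 0:deg, `^`)
      ZtW <- t(Z * w[use])
      fit <- tryCatch(solve(ZtW %*% Z, ZtW), error = function(e) NULL)
      if (!is.null(fit)) row <- fit[1, ] else deg <- deg - 1L
    }
    if (is.null(row)) row <- w[use] / sum(w[use])
    S[i, use] <- row
  }
  S
}

running_mean_hat <- function(pos, span_bp) {
  n <- length(pos)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    use <- abs(pos - pos[i]) <= span_bp / 2
    S[i, use] <- 1 / sum(use)
  }
  S
}

#' Build the cluster-wise smoother matrix
#'
#' Smoothing of the coefficient profile is linear in the coefficients, so
#' it is materialised once as a sparse block-diagonal matrix `S` (probes x
#' probes): smoothed = S \%*\% coefficients. Clusters smaller than
#' `min_probes_smooth` (and all clusters when smoothing is `"none"`) get
#' identity rows; no block spans a cluster boundary.
#'
#' @param pos probe positions (bp), annotation order.
#' @param clusters a [cluster_probes()] result.
#' @param config a [bump_config()].
#' @return a `Matrix::sparseMatrix`.
#' @export
smoother_matrix <- function(pos, clusters, config) {
  n <- length(pos)
  ii <- seq_len(n); jj <- seq_len(n); xx <- rep(1, n)   # identity default
  if (config$smoothing != "none") {
    cl <- clusters$clusters
    big <- cl[cl$n_probes >= config$min_probes_smooth, , drop = FALSE]
    if (nrow(big)) {
      blocks <- lapply(seq_len(nrow(big)), function(r) {
        idx <- big$idx_start[r]:big$idx_end[r]
        H <- if (config$smoothing == "loess_by_cluster")
          local_poly_hat(pos[idx], config$smooth_span_bp)
        else running_mean_hat(pos[idx], config$smooth_span_bp)
        nz <- which(H != 0, arr.ind = TRUE)
        cbind(idx[nz[, 1]], idx[nz[, 2]], H[nz])
      })
      trip <- do.call(rbind, blocks)
      smoothed_rows <- unique(trip[, 1])
      keep <- !(ii %in% smoothed_rows)
      ii <- c(ii[keep], trip[, 1]); jj <- c(jj[keep], trip[, 2])
      xx <- c(xx[keep], trip[, 3])
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Smooth a coefficient profile within clusters
#'
#' @param coefficients per-probe values in annotation order.
#' @param pos probe positions.
#' @param clusters a [cluster_probes()] result.
#' @param config a [bump_config()].
#' @return smoothed per-probe values.
#' @export
smooth_by_cluster <- function(coefficients, pos, clusters, config) {
  S <- smoother_matrix(pos, clusters, config)
  as.vector(S %*% coefficients)
}

#' Pick the bump cutoff from the smoothed profile
#'
#' The cutoff is the `q` quantile (linear interpolation between order
#' statistics) of the absolute smoothed coefficients genome-wide.
#'
#' @param smoothed per-probe smoothed coefficients.
#' @param q quantile in (0,1).
#' @return the cutoff, in beta units.
#' @export
pick_cutoff <- function(smoothed, q = 0.95) {
  x <- abs(smoothed[is.finite(smoothed)])
  stop_if_not(length(x) > 0, "no finite values to pick a cutoff from")
  stats::quantile(x, q, names = FALSE, type = 7)
}

## areas (and run bounds) of same-sign excursions beyond the cutoff,
## never crossing cluster boundaries; vectorised via run-length encoding
run_segments <- function(values, cluster_id, cutoff) {
  cat <- (values > cutoff) - (values < -cutoff)
  r <- rle(cat + 3 * cluster_id)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- cat[starts] != 0L
  starts <- starts[keep]; ends <- ends[keep]
  cs <- c(0, cumsum(abs(values)))
  list(idx_start = starts, idx_end = ends,
       sign = cat[starts],
       area = cs[ends + 1L] - cs[starts])
}

#' Segment bumps from a smoothed profile
#'
#' Within each cluster, maximal runs of consecutive probes whose smoothed
#' coefficient exceeds `cutoff` (positive bumps) or falls below `-cutoff`
#' (negative bumps). Each bump is scored by its area, the sum of the
#' absolute smoothed coefficients over member probes. Intervals are
#' 0-based half-open, spanning the first to last member probe.
#'
#' @param smoothed per-probe smoothed coefficients.
#' @param annotation probe annotation (chrom, pos) in the same order.
#' @param clusters a [cluster_probes()] result.
#' @param cutoff non-negative cutoff in beta units.
#' @return a `data.frame` of bumps (possibly empty): chrom, start, end,
#'   cluster_id, probe index range, n_probes, sign, area.
#' @export
find_bumps <- function(smoothed, annotation, clusters, cutoff) {
  stop_if_not(cutoff >= 0, "cutoff must be >= 0")
  seg <- run_segments(smoothed, clusters$cluster_id, cutoff)
  data.frame(chrom = annotation$chrom[seg$idx_start],
             start = annotation$pos[seg$idx_start],
             end = annotation$pos[seg$idx_end] + 1L,
             cluster_id = clusters$cluster_id[seg$idx_start],
             idx_start = seg$idx_start, idx_end = seg$idx_end,
             n_probes = seg$idx_end - seg$idx_start + 1L,
             sign = seg$sign, area = seg$area,
             stringsAsFactors = FALSE)
}

#' Residual-bootstrap null distribution of bump areas
#'
#' Fits the null model (design without the column of interest), resamples
#' whole residual sample vectors with replacement (preserving cross-probe
#' correlation), forms null responses as null fit + resampled residuals,
#' re-estimates and re-smooths the coefficient profile, and segments bumps
#' at the fixed observed cutoff. Null areas are pooled across all
#' iterations and clusters into one empirical null.
#'
#' @param beta_values probes x samples matrix.
#' @param X design matrix.
#' @param interest_index tested column of `X`.
#' @param S smoother matrix from [smoother_matrix()].
#' @param cluster_id per-probe cluster ids.
#' @param cutoff observed cutoff (held fixed across iterations).
#' @param B number of bootstrap iterations.
#' @param seed integer seed.
#' @return numeric vector of pooled null areas.
#' @export
bootstrap_null <- function(beta_values, X, interest_index, S, cluster_id,
                           cutoff, B, seed = 1L) {
  set.seed(substream_seed(seed, 303L))
  n <- ncol(beta_values)
  X0 <- X[, -interest_index, drop = FALSE]
  Yt <- t(beta_values)                                  # n x p
  F0 <- X0 %*% solve(crossprod(X0), crossprod(X0, Yt))  # null fit
  ## rescale residuals so their variance matches the error variance
  ## (raw null-model residuals shrink it by (n - k0) / n)
  R <- (Yt - F0) * sqrt(n / (n - ncol(X0)))
  h <- X %*% solve(crossprod(X))[, interest_index]      # coef_j = h'Y_j
  c0 <- as.vector(crossprod(F0, h))
  areas <- vector("list", B)
  chunk <- 200L
  done <- 0L
  while (done < B) {
    nb <- min(chunk, B - done)
    A <- matrix(0, n, nb)
    for (b in seq_len(nb)) {
      idx <- sample.int(n, n, replace = TRUE)
      tab <- rowsum(as.vector(h), idx)
      A[as.integer(rownames(tab)), b] <- tab
    }
    null_coef <- crossprod(R, A) + c0                   # p x nb
    sm <- as.matrix(S %*% null_coef)
    for (b in seq_len(nb))
      areas[[done + b]] <- run_segments(sm[, b], cluster_id, cutoff)$area
    done <- done + nb
  }
  unlist(areas, use.names = FALSE)
}

## empirical p with plus-one rule: (1 + #{null >= area}) / (1 + N)
null_p_values <- function(areas, null_areas) {
  N <- length(null_areas)
  if (N == 0) {
    warning("empty bootstrap null; p-values set to 1", call. = FALSE)
    return(rep(1, length(areas)))
  }
  srt <- sort(null_areas)
  n_ge <- N - findInterval(areas, srt, left.open = TRUE)
  (1 + n_ge) / (1 + N)
}

#' Design matrix for the DMR engine
#'
#' Builds a model matrix from the phenotype table with the tested variable
#' first after the intercept. Character/factor variables are dummy coded;
#' for `group` the reference level is `control`, so positive coefficients
#' mean the neglect group is more methylated.
#'
#' @param pheno phenotype `data.frame` with a `sample_id` column.
#' @param interest name of the tested variable.
#' @param covariates names of nuisance covariates.
#' @return list of class `dmr_design`: `X`, `interest_index`, `sample_ids`.
#' @export
design_matrix <- function(pheno, interest, covariates = character()) {
  stop_if_not(interest %in% names(pheno),
              "interest variable '", interest, "' not in pheno")
  stop_if_not(all(covariates %in% names(pheno)),
              "covariate(s) missing from pheno")
  vars <- c(interest, covariates)
  dat <- pheno[vars]
  for (v in vars) {
    if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
    if (v == "group") dat[[v]] <- stats::relevel(factor(dat[[v]]), "control")
  }
  X <- stats::model.matrix(stats::reformulate(vars), dat)
  asn <- attr(X, "assign")
  int_cols <- which(asn == 1L)
  stop_if_not(length(int_cols) == 1L,
              "interest variable must map to exactly one design column")
  rownames(X) <- pheno$sample_id
  structure(list(X = X, interest_index = int_cols,
                 sample_ids = pheno$sample_id),
            class = "dmr_design")
}

#' Fit the bump-hunting DMR model
#'
#' The full engine for one cohort: cluster CpGs by proximity, fit a
#' covariate-adjusted linear model at every probe, smooth the coefficient
#' of interest within clusters, pick the cutoff as a genome-wide quantile
#' of the absolute smoothed profile, segment candidate bumps, and assign
#' each bump an empirical p-value against a residual-bootstrap null of
#' pooled areas.
#'
#' @param beta a `beta_matrix` from [compute_beta()] /
#'   [preprocess_cohort()], or a plain probes x samples matrix with probe
#'   ids as rownames and sample ids as colnames.
#' @param design a [design_matrix()] object (its samples must all be
#'   present among the beta columns; beta columns are aligned to it).
#' @param annotation probe annotation; it is subset to the probes present
#'   in `beta` and must then be sorted by (chromosome, position).
#' @param config a [bump_config()].
#' @return an object of class `bump_hunt`; see [print.bump_hunt()],
#'   [summary.bump_hunt()], [coef.bump_hunt()], [plot.bump_hunt()]. The
#'   `bumps` element is a `data.frame` ordered by p-value, then descending
#'   area, then genomic position.
#' @export
bump_hunt <- function(beta, design, annotation, config = bump_config()) {
  values <- if (inherits(beta, "beta_matrix")) beta$values else beta
  stop_if_not(inherits(design, "dmr_design"), "design must be a dmr_design")
  stop_if_not(all(design$sample_ids %in% colnames(values)),
              "design samples missing from beta matrix")
  values <- values[, design$sample_ids, drop = FALSE]
  keep <- annotation$probe_id %in% rownames(values)
  ann <- annotation[keep, , drop = FALSE]
  stop_if_not(nrow(ann) == nrow(values),
              "annotation does not cover all probes in beta")
  values <- values[ann$probe_id, , drop = FALSE]

  clusters <- cluster_probes(ann, config$max_gap)
  fit <- fit_probe_models(values, design$X, design$interest_index)
  S <- smoother_matrix(ann$pos, clusters, config)
  smoothed <- as.vector(S %*% fit$coef)
  cutoff <- pick_cutoff(smoothed, config$pick_cutoff_q)
  bumps <- find_bumps(smoothed, ann, clusters, cutoff)
  null_areas <- bootstrap_null(values, design$X, design$interest_index, S,
                               clusters$cluster_id, cutoff,
                               config$n_bootstrap, config$seed)
  bumps$p_value <- null_p_values(bumps$area, null_areas)
  ord <- order(bumps$p_value, -bumps$area, bumps$chrom, bumps$start)
  bumps <- bumps[ord, , drop = FALSE]
  rownames(bumps) <- NULL
  ## majority gene label across member probes
  bumps$gene <- vapply(seq_len(nrow(bumps)), function(i) {
    g <- ann$gene[bumps$idx_start[i]:bumps$idx_end[i]]
    names(sort(table(g), decreasing = TRUE))[1]
  }, character(1))

  structure(list(bumps = bumps, coefficients = fit$coef, se = fit$se,
                 smoothed = smoothed, cutoff = cutoff,
                 clusters = clusters, annotation = ann,
                 n_null = length(null_areas),
                 null_area_quantiles = stats::quantile(
                   null_areas, c(0.5, 0.9, 0.95, 0.99, 1),
                   names = TRUE),
                 config = config, n_samples = ncol(values),
                 interest = colnames(design$X)[design$interest_index]),
            class = "bump_hunt")
}

#' @describeIn bump_hunt print a short account of the fit.
#' @param x,object a `bump_hunt` object.
#' @param ... unused.
#' @export
print.bump_hunt <- function(x, ...) {
  cat("Bump-hunting DMR fit\n")
  cat("  tested variable:", x$interest, "on", x$n_samples, "samples,",
      nrow(x$annotation), "probes\n")
  cat(sprintf("  cutoff %.4g (q = %.2f), %d candidate bumps, %d pooled null areas\n",
              x$cutoff, x$config$pick_cutoff_q, nrow(x$bumps), x$n_null))
  if (nrow(x$bumps)) {
    cat("  top bumps:\n")
    print(utils::head(x$bumps[c("chrom", "start", "end", "n_probes", "sign",
                                "area", "p_value", "gene")], 5),
          row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn bump_hunt significant-bump counts at conventional levels.
#' @param alpha significance levels to tabulate.
#' @export
summary.bump_hunt <- function(object, alpha = c(0.001, 0.01, 0.05), ...) {
  out <- list(n_bumps = nrow(object$bumps),
              n_significant = stats::setNames(
                vapply(alpha, function(a) sum(object$bumps$p_value < a),
                       numeric(1)),
                paste0("alpha_", alpha)),
              cutoff = object$cutoff, n_null = object$n_null,
              interest = object$interest)
  class(out) <- "summary.bump_hunt"
  out
}

#' @export
print.summary.bump_hunt <- function(x, ...) {
  cat("bump_hunt summary -", x$n_bumps, "candidate bumps for", x$interest,
      "\n  cutoff:", format(x$cutoff, digits = 4), "\n")
  for (i in seq_along(x$n_significant))
    cat(" ", names(x$n_significant)[i], ":", x$n_significant[i],
        "significant\n")
  invisible(x)
}

#' @describeIn bump_hunt per-probe raw and smoothed coefficients.
#' @export
coef.bump_hunt <- function(object, ...) {
  data.frame(probe_id = object$annotation$probe_id,
             chrom = object$annotation$chrom, pos = object$annotation$pos,
             coef = object$coefficients, se = object$se,
             smoothed = object$smoothed, stringsAsFactors = FALSE)
}

#' @describeIn bump_hunt coefficient profile of one bump's cluster, with
#'   the cutoff band.
#' @param bump row index into `x$bumps` (default 1, the top bump).
#' @export
plot.bump_hunt <- function(x, bump = 1L, ...) {
  stop_if_not(nrow(x$bumps) >= bump, "no such bump")
  b <- x$bumps[bump, ]
  cl <- x$clusters$clusters
  cl <- cl[cl$cluster_id == b$cluster_id, ]
  idx <- cl$idx_start:cl$idx_end
  pos <- x$annotation$pos[idx]
  graphics::plot(pos, x$coefficients[idx], pch = 16, col = "grey50",
                 xlab = paste0("position on ", b$chrom, " (bp)"),
                 ylab = "group effect (beta units)",
                 main = sprintf("%s  p = %.3g", b$gene, b$p_value), ...)
  graphics::lines(pos, x$smoothed[idx], col = "red", lwd = 2)
  graphics::abline(h = c(-x$cutoff, 0, x$cutoff),
                   lty = c(2, 1, 2), col = "grey30")
  invisible(x)
}
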