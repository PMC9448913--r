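## small builders used across test files

tiny_config <- function(...) {
  defaults <- list(n_probes = 600L, chromosomes = c(chr1 = 300L, chr2 = 300L),
                   n_mother_neglect = 15L, n_mother_control = 18L,
                   n_child_neglect = 12L, n_child_control = 15L,
                   n_planted_shared = 2L, n_planted_mother_only = 1L,
                   n_planted_child_only = 1L, seed = 99L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

## intensity pair from explicit beta values at fixed total intensity
ip_from_beta <- function(beta, detection_p = NULL, total = 10000) {
  M <- beta * (total + 100)
  U <- total - M
  if (is.null(detection_p))
    detection_p <- matrix(0, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  dimnames(M) <- dimnames(U) <- dimnames(beta)
  intensity_pair(M, U, detection_p)
}

named_matrix <- function(values, n_probes, n_samples) {
  matrix(values, n_probes, n_samples,
         dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                         sprintf("S%03d", seq_len(n_samples))))
}

## minimal sorted annotation for hand-built probe sets
toy_annotation <- function(pos, chrom = rep("chr1", length(pos)),
                           gene = rep("LOC1", length(pos))) {
  data.frame(probe_id = sprintf("cg%05d", seq_along(pos)),
             chrom = chrom, pos = pos, gene = gene,
             cross_reactive = FALSE, snp_overlap = FALSE,
             stringsAsFactors = FALSE)
}

## brute-force oracles -------------------------------------------------

## pairwise-gap clustering oracle: probes i, j co-cluster iff a chain of
## consecutive gaps <= max_gap connects them on one chromosome
oracle_clusters <- function(chrom, pos, max_gap) {
  n <- length(pos)
  id <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (i == 1 || chrom[i] != chrom[i - 1] || pos[i] - pos[i - 1] > max_gap)
      cur <- cur + 1L
    id[i] <- cur
  }
  id
}

## exhaustive run enumeration oracle for bump segmentation
oracle_segments <- function(values, cluster_id, cutoff) {
  out <- list()
  i <- 1L
  n <- length(values)
  while (i <= n) {
    s <- if (values[i] > cutoff) 1L else if (values[i] < -cutoff) -1L else 0L
    if (s == 0L) { i <- i + 1L; next }
    j <- i
    while (j < n && cluster_id[j + 1] == cluster_id[i]) {
      s2 <- if (values[j + 1] > cutoff) 1L else if (values[j + 1] < -cutoff) -1L else 0L
      if (s2 != s) break
      j <- j + 1L
    }
    out[[length(out) + 1L]] <- list(start = i, end = j, sign = s,
                                    area = sum(abs(values[i:j])))
    i <- j + 1L
  }
  out
}
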