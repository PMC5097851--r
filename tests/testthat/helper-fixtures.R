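# Independent oracles and small fixture builders shared across tests.

# naive triple-loop matrix product (oracle for mr_multiply)
naive_multiply <- function(A, B) {
  C <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A))) {
    for (k in seq_len(ncol(B))) {
      acc <- 0
      for (j in seq_len(ncol(A))) acc <- acc + A[i, j] * B[j, k]
      C[i, k] <- acc
    }
  }
  C
}

# brute-force double loop over genes and records (oracle for
# mr_epigenetic_scores); outer loop per gene, inner sum vectorised
brute_force_scores <- function(signal, annotation, config = scoring_config()) {
  out <- stats::setNames(numeric(nrow(annotation)), annotation$gene_id)
  for (m in seq_len(nrow(annotation))) {
    raw <- signal$pos - annotation$tss[m]
    sel <- signal$chrom == annotation$chrom[m] & abs(raw) <= config$d_star
    if (!any(sel)) next
    d <- raw[sel]
    if (annotation$strand[m] == "-") d <- -d
    out[m] <- sum(signal$weight[sel] * phi(d, config))
  }
  out
}

# random annotation on a couple of chromosomes
rand_annotation <- function(n_genes, seed, chrom_length = 1e6L, n_chroms = 2L) {
  with_local_seed(seed, {
    data.frame(
      gene_id = sprintf("g%04d", seq_len(n_genes)),
      chrom = sample(paste0("chr", seq_len(n_chroms)), n_genes, replace = TRUE),
      tss = sample.int(chrom_length, n_genes),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

rand_signal <- function(n_reads, seed, chrom_length = 1e6L, n_chroms = 2L) {
  with_local_seed(seed, {
    data.frame(
      chrom = sample(paste0("chr", seq_len(n_chroms)), n_reads, replace = TRUE),
      pos = sample.int(chrom_length, n_reads, replace = TRUE),
      weight = sample(c(1, 1, 2), n_reads, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

# random design matrix with bias column, as a score_matrix
rand_design <- function(M, n_features, seed) {
  with_local_seed(seed, {
    v <- matrix(rnorm(M * n_features), M, n_features,
                dimnames = list(sprintf("g%05d", seq_len(M)),
                                paste0("f", seq_len(n_features))))
    score_matrix(cbind(v, bias = 1), has_bias = TRUE)
  })
}

# canonical multiset representation of engine output, for set comparisons
pair_signature <- function(pairs) {
  sort(vapply(pairs, function(p) {
    paste(epimapred:::encode_tuple(p$key), epimapred:::encode_value(p$value),
          sep = " -> ")
  }, character(1)), method = "radix")
}
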