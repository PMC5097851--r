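test_that("phi is constant for histones and decays symmetrically for TFs", {
  hist_cfg <- scoring_config(kind = "histone")
  expect_equal(phi(c(-1999, 0, 37, 2000), hist_cfg), rep(1, 4))

  tf_cfg <- scoring_config(kind = "tf", d0 = 5000)
  expect_equal(phi(0, tf_cfg), 1)
  expect_equal(phi(5000, tf_cfg), exp(-1))
  expect_equal(phi(-5000, tf_cfg), exp(-1))  # |d| in the exponent
})

test_that("genes_within matches a brute-force window scan", {
  ann <- rand_annotation(80, seed = 11, chrom_length = 2e5L)
  idx <- tss_index(ann)
  positions <- with_local_seed(12, sample.int(2e5L, 300))
  for (pos in positions) {
    got <- genes_within(idx, "chr1", pos, 2000)
    raw <- pos - ann$tss
    sel <- ann$chrom == "chr1" & abs(raw) <= 2000
    want_ids <- ann$gene_id[sel]
    expect_setequal(got$gene_id, want_ids)
    if (length(want_ids)) {
      d_want <- ifelse(ann$strand[sel] == "-", -raw[sel], raw[sel])
      expect_equal(got$distance[match(want_ids, got$gene_id)], d_want)
    }
  }
})

test_that("window is inclusive at both ends and strand flips distance sign", {
  ann <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                    tss = c(10000L, 50000L), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  idx <- tss_index(ann)
  expect_equal(genes_within(idx, "chr1", 12000, 2000)$gene_id, "gp")  # +d*
  expect_equal(genes_within(idx, "chr1", 8000, 2000)$gene_id, "gp")   # -d*
  expect_length(genes_within(idx, "chr1", 12001, 2000)$gene_id, 0)
  expect_equal(genes_within(idx, "chr1", 11500, 2000)$distance, 1500)
  # downstream of a minus-strand gene lies at smaller coordinates
  expect_equal(genes_within(idx, "chr1", 49000, 2000)$distance, 1000)
  expect_length(suppressMessages(genes_within(idx, "chrX", 100, 2000)$gene_id), 0)
})

test_that("hand-checked score examples: tag count and TF kernel", {
  ann <- data.frame(gene_id = "g1", chrom = "chr1", tss = 10000L,
                    strand = "+", stringsAsFactors = FALSE)
  idx <- tss_index(ann)
  sig <- data.frame(chrom = "chr1", pos = c(9000L, 11500L, 13000L),
                    weight = 1, stringsAsFactors = FALSE)
  expect_equal(unname(mr_epigenetic_scores(sig, idx)), 2)
  tf <- mr_epigenetic_scores(sig, idx, scoring_config(kind = "tf", d0 = 5000))
  expect_equal(unname(tf), exp(-0.2) + exp(-0.3), tolerance = 1e-12)
  empty <- data.frame(chrom = character(), pos = integer(), weight = double())
  expect_equal(unname(mr_epigenetic_scores(empty, idx)), 0)
})

test_that("a read equidistant from two TSSs contributes to both genes", {
  ann <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    tss = c(10000L, 13000L), strand = "+",
                    stringsAsFactors = FALSE)
  idx <- tss_index(ann)
  sig <- data.frame(chrom = "chr1", pos = 11500L, weight = 1,
                    stringsAsFactors = FALSE)
  sc <- mr_epigenetic_scores(sig, idx)
  expect_equal(unname(sc), c(1, 1))
})

test_that("MapReduce scores equal the brute-force double loop on random fixtures", {
  for (seed in 1:100) {
    n_genes <- 5L + seed %% 20L
    ann <- rand_annotation(n_genes, seed = seed, chrom_length = 60000L)
    sig <- rand_signal(150, seed = seed + 1000L, chrom_length = 60000L)
    idx <- tss_index(ann)
    hist_cfg <- scoring_config(kind = "histone")
    expect_identical(mr_epigenetic_scores(sig, idx, hist_cfg),
                     brute_force_scores(sig, ann, hist_cfg))
    tf_cfg <- scoring_config(kind = "tf")
    got <- mr_epigenetic_scores(sig, idx, tf_cfg)
    want <- brute_force_scores(sig, ann, tf_cfg)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("adding a read in a gene's window never decreases its score; other chromosomes unaffected", {
  ann <- rand_annotation(40, seed = 3, chrom_length = 1e5L)
  sig <- rand_signal(300, seed = 4, chrom_length = 1e5L)
  idx <- tss_index(ann)
  base <- mr_epigenetic_scores(sig, idx)
  g <- ann[7, ]
  extra <- rbind(sig, data.frame(chrom = g$chrom, pos = g$tss + 100L,
                                 weight = 2, stringsAsFactors = FALSE))
  bumped <- mr_epigenetic_scores(extra, idx)
  expect_true(all(bumped >= base))
  expect_gt(bumped[g$gene_id], base[g$gene_id])
  other <- ann$gene_id[ann$chrom != g$chrom]
  expect_identical(bumped[other], base[other])
})

test_that("scores are identical for 1 and 4 workers", {
  ann <- rand_annotation(60, seed = 21, chrom_length = 2e5L)
  sig <- rand_signal(2000, seed = 22, chrom_length = 2e5L)
  idx <- tss_index(ann)
  s1 <- mr_epigenetic_scores(sig, idx, engine = engine_config(1))
  s4 <- mr_epigenetic_scores(sig, idx, engine = engine_config(4))
  expect_identical(s1, s4)
})

test_that("assemble_score_matrix appends the bias column and checks gene order", {
  ids <- c("g1", "g2", "g3")
  cols <- list(f1 = stats::setNames(1:3 * 1.0, ids),
               f2 = stats::setNames(4:6 * 1.0, ids))
  x <- assemble_score_matrix(cols, add_bias = TRUE)
  expect_equal(dim(x), c(3L, 3L))
  expect_equal(unname(x$values[, "bias"]), rep(1, 3))
  expect_equal(colnames(x$values), c("f1", "f2", "bias"))

  only_bias <- assemble_score_matrix(list(), add_bias = TRUE, gene_ids = ids)
  expect_equal(dim(only_bias), c(3L, 1L))

  cols$f2 <- cols$f2[c(2, 1, 3)]
  expect_error(assemble_score_matrix(cols), "ordering differs")
  cols$f2 <- stats::setNames(4:6 * 1.0, c("g1", "g2", "g9"))
  expect_error(assemble_score_matrix(cols), "g9")
})

test_that("log and arsinh transforms behave at the anchor points", {
  v <- matrix(c(0, exp(1) - 1, 4, 0, 1, 1, 1, 1), 4,
              dimnames = list(paste0("g", 1:4), c("f1", "bias")))
  x <- score_matrix(v, has_bias = TRUE)
  lt <- transform_scores(x, "log", pseudocount = 1)
  expect_equal(unname(lt$values[, "f1"])[1:2], c(0, 1))
  expect_equal(unname(lt$values[, "bias"]), rep(1, 4))  # bias untouched

  at <- transform_scores(x, "arsinh")
  expect_equal(unname(at$values[1, "f1"]), 0)
  expect_equal(unname(at$values[3, "f1"]), asinh(4))

  v[1, 1] <- -5
  expect_error(transform_scores(score_matrix(v, has_bias = TRUE), "log"),
               "positive")
})

test_that("quantile normalisation maps columns onto the mean order statistics", {
  v <- matrix(c(1, 2, 3, 4, 5, 6, 1, 1, 1), 3,
              dimnames = list(paste0("g", 1:3), c("a", "b", "bias")))
  x <- quantile_normalise(score_matrix(v, has_bias = TRUE))
  expect_equal(unname(x$values[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(x$values[, "b"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(x$values[, "bias"]), rep(1, 3))

  # identical columns are a fixed point
  w <- matrix(c(5, 1, 9, 5, 1, 9), 3,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(quantile_normalise(score_matrix(w))$values, w)

  # after normalisation all columns share one sorted multiset,
  # and within-column rank order is preserved
  r <- with_local_seed(8, matrix(rnorm(60), 20,
                                 dimnames = list(sprintf("g%02d", 1:20),
                                                 c("a", "b", "c"))))
  q <- quantile_normalise(score_matrix(r))$values
  expect_equal(unname(sort(q[, 1])), unname(sort(q[, 2])))
  expect_equal(unname(sort(q[, 1])), unname(sort(q[, 3])))
  for (j in 1:3) expect_equal(order(q[, j]), order(r[, j]))

  expect_warning(quantile_normalise(score_matrix(w[, 1, drop = FALSE])),
                 ">= 2")
})

test_that("tied values receive the mean of their tied reference values", {
  v <- matrix(c(1, 1, 5, 2, 4, 6), 3,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  q <- quantile_normalise(score_matrix(v))$values
  ref <- unname(rowMeans(apply(v, 2, sort)))   # 1.5, 2.5, 5.5
  expect_equal(unname(q[, "a"]), c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))

  # cross-check against limma's implementation on tie-free data (for ties
  # limma interpolates the reference at the mean rank instead of averaging
  # the tied reference values, so agreement is exact only without ties)
  r <- with_local_seed(13, matrix(rnorm(80), 20, 4,
                                  dimnames = list(sprintf("g%02d", 1:20),
                                                  paste0("f", 1:4))))
  mine <- quantile_normalise(score_matrix(r))$values
  theirs <- limma::normalizeQuantiles(r, ties = TRUE)
  expect_equal(unname(mine), unname(theirs), tolerance = 1e-12)
})
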