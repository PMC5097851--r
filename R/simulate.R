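#' Synthetic study configuration
#'
#' Parameters of the seeded generator that emulates the statistical
#' structure the pipeline assumes: per-gene read pileups concentrated within
#' `d_star` of the TSS plus a uniform genomic background, and expression
#' linear in the log-transformed scores plus Gaussian noise.
#'
#' @param n_genes number of genes M.
#' @param n_features number of epigenetic features N (before the bias
#'   column).
#' @param n_chroms number of chromosomes.
#' @param chrom_length common chromosome length in bp (default sized so
#'   mean TSS spacing is 10 `d_star`, keeping pathological window crowding
#'   rare).
#' @param reads_per_gene mean target read count per gene-feature pileup.
#' @param background_rate uniform background read density, reads per bp per
#'   feature.
#' @param beta_true generative coefficients, length `n_features + 1` (bias
#'   last); default: alternating-sign unit effects with bias 2.
#' @param noise_sigma SD of the Gaussian expression noise.
#' @param d_star scoring window half-width in bp (pileup reads fall within
#'   it).
#' @param seed integer seed fixing the whole generator stream.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000L, n_features = 6L,
                              n_chroms = 2L, chrom_length = NULL,
                              reads_per_gene = 50, background_rate = 1e-4,
                              beta_true = NULL, noise_sigma = 0.5,
                              d_star = 2000, seed = 0L) {
  if (is.null(chrom_length)) {
    chrom_length <- ceiling(10 * d_star * n_genes / n_chroms) + 4L * d_star
  }
  if (is.null(beta_true)) {
    beta_true <- c(rep_len(c(1, -1), n_features) *
                     seq(1, 0.5, length.out = n_features), 2)
  }
  cfg <- list(n_genes = as.integer(n_genes), n_features = as.integer(n_features),
              n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              reads_per_gene = reads_per_gene,
              background_rate = background_rate, beta_true = beta_true,
              noise_sigma = noise_sigma, d_star = d_star,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes > 0, cfg$n_features > 0, cfg$n_chroms > 0,
            cfg$reads_per_gene >= 0, cfg$background_rate >= 0,
            cfg$noise_sigma >= 0,
            length(cfg$beta_true) == cfg$n_features + 1L)
  structure(cfg, class = "simulation_config")
}

#' Simulate a gene annotation
#'
#' M genes spread over the configured chromosomes with TSS positions
#' uniform within each chromosome (inset by `d_star` from both ends so a
#' pileup never leaves the chromosome) and Bernoulli(0.5) strands.
#' Deterministic under the configuration seed.
#'
#' @param config a [simulation_config()].
#' @return Annotation `data.frame` (`gene_id`, `chrom`, `tss`, `strand`).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$chrom_length < 10 * config$d_star * config$n_genes / config$n_chroms) {
    stop_("infeasible packing: chromosome length ", config$chrom_length,
          " < 10 * d_star * genes-per-chromosome")
  }
  with_local_seed(config$seed, {
    chrom <- sort(rep_len(paste0("chr", seq_len(config$n_chroms)),
                          config$n_genes), method = "radix")
    lo <- config$d_star + 1L
    hi <- config$chrom_length - config$d_star
    tss <- as.integer(floor(stats::runif(config$n_genes, lo, hi + 1)))
    strand <- ifelse(stats::runif(config$n_genes) < 0.5, "+", "-")
    data.frame(gene_id = sprintf("g%05d", seq_len(config$n_genes)),
               chrom = chrom, tss = pmin(tss, hi), strand = strand,
               stringsAsFactors = FALSE)
  })
}

#' Simulate ChIP-seq signal records for one feature
#'
#' For gene m, `Poisson(target_scores[m])` unit-weight read-equivalents at
#' offsets uniform in `[-d_star, d_star]` from its TSS, plus
#' `Poisson(background_rate * genome length)` background reads uniform over
#' the genome. Offsets are uniform (not peak-shaped) so the expected raw
#' histone score of gene m is exactly `target_scores[m]` plus the expected
#' background falling in its window.
#'
#' @param annotation annotation `data.frame` (from [simulate_annotation()]).
#' @param target_scores non-negative M-vector of expected pileup read
#'   counts.
#' @param config a [simulation_config()].
#' @param seed seed for this feature's reads (default the config seed).
#' @return Signal `data.frame` (`chrom`, `pos`, `weight = 1`).
#' @export
simulate_chipseq <- function(annotation, target_scores, config,
                             seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"),
            length(target_scores) == nrow(annotation),
            all(target_scores >= 0))
  with_local_seed(seed, {
    counts <- stats::rpois(nrow(annotation), target_scores)
    total <- sum(counts)
    gene_rows <- rep.int(seq_len(nrow(annotation)), counts)
    offsets <- sample.int(2L * config$d_star + 1L, total, replace = TRUE) -
      config$d_star - 1L
    pos <- annotation$tss[gene_rows] + offsets
    chrom <- annotation$chrom[gene_rows]
    n_bg <- stats::rpois(1L, config$background_rate * config$chrom_length *
                           config$n_chroms)
    if (n_bg > 0L) {
      bg_chrom <- paste0("chr", sample.int(config$n_chroms, n_bg, replace = TRUE))
      bg_pos <- sample.int(config$chrom_length, n_bg, replace = TRUE)
      chrom <- c(chrom, bg_chrom)
      pos <- c(pos, bg_pos)
    }
    o <- order(chrom, pos, method = "radix")
    data.frame(chrom = chrom[o], pos = as.integer(pos[o]),
               weight = rep(1, length(pos)), stringsAsFactors = FALSE)
  })
}

#' Simulate expression from a design matrix
#'
#' `Y = X beta_true + N(0, noise_sigma^2)` i.i.d.; `noise_sigma = 0` gives
#' exact linearity.
#'
#' @param X a [score_matrix()] or design matrix (typically log-transformed
#'   scores plus bias).
#' @param beta_true coefficient vector, `ncol(X)` long.
#' @param noise_sigma Gaussian noise SD (>= 0).
#' @param seed integer seed.
#' @return Named numeric expression vector.
#' @export
simulate_expression <- function(X, beta_true, noise_sigma, seed = 0L) {
  Xm <- as_design(X)
  if (ncol(Xm) != length(beta_true)) {
    stop_("X has ", ncol(Xm), " columns but beta_true has ", length(beta_true))
  }
  stopifnot(noise_sigma >= 0)
  y <- drop(Xm %*% beta_true)
  if (noise_sigma > 0) {
    y <- y + with_local_seed(seed, stats::rnorm(length(y), 0, noise_sigma))
  }
  stats::setNames(y, rownames(Xm))
}

#' Simulate cell-line datasets at the design-matrix level
#'
#' Generates score matrices directly in the (log-score) design space --
#' Gaussian feature columns with per-feature means, plus a bias column --
#' and expression `Y_c = X_c beta_c + eps_c`. By default every cell-line
#' shares `beta_true` (emulating cell-line-invariant regulatory function);
#' `beta_sd > 0` adds per-line coefficient divergence. Optionally a latent
#' gene-level residual factor of SD `residual_factor_sd` is shared by the
#' lines named in `factor_lines`, inducing correlated residuals.
#'
#' @param n_lines number of cell-lines.
#' @param n_genes genes per line (a common gene universe).
#' @param n_features epigenetic features (before bias).
#' @param beta_true shared coefficients, length `n_features + 1` (bias
#'   last).
#' @param noise_sigma per-gene expression noise SD.
#' @param beta_sd SD of per-line Gaussian perturbations of `beta_true` (0 =
#'   shared coefficients).
#' @param factor_lines indices of lines sharing the latent residual factor.
#' @param residual_factor_sd SD of the shared latent factor.
#' @param seed integer seed.
#' @return List of [cell_line_dataset()] objects; attribute `truth` records
#'   the per-line coefficients and noise parameters.
#' @export
simulate_cell_lines <- function(n_lines = 3L, n_genes = 1000L,
                                n_features = 6L,
                                beta_true = NULL, noise_sigma = 0.5,
                                beta_sd = 0, factor_lines = NULL,
                                residual_factor_sd = 0, seed = 0L) {
  if (is.null(beta_true)) {
    beta_true <- c(rep_len(c(1, -1), n_features) *
                     seq(1, 0.5, length.out = n_features), 2)
  }
  stopifnot(length(beta_true) == n_features + 1L)
  with_local_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    feat <- paste0("feat", seq_len(n_features))
    mu <- stats::rnorm(n_features, 0, 0.5)
    latent <- stats::rnorm(n_genes, 0, residual_factor_sd)
    betas <- vector("list", n_lines)
    datasets <- vector("list", n_lines)
    for (c_i in seq_len(n_lines)) {
      v <- vapply(seq_len(n_features),
                  function(f) stats::rnorm(n_genes, mu[f], 1),
                  numeric(n_genes))
      dimnames(v) <- list(genes, feat)
      v <- cbind(v, bias = 1)
      X <- score_matrix(v, has_bias = TRUE)
      beta_c <- beta_true + stats::rnorm(n_features + 1L, 0, beta_sd)
      eps <- stats::rnorm(n_genes, 0, noise_sigma)
      if (!is.null(factor_lines) && c_i %in% factor_lines) {
        eps <- eps + latent
      }
      y <- stats::setNames(drop(v %*% beta_c) + eps, genes)
      betas[[c_i]] <- beta_c
      datasets[[c_i]] <- cell_line_dataset(paste0("line", c_i), X, y)
    }
    attr(datasets, "truth") <- list(beta_true = beta_true, betas = betas,
                                    noise_sigma = noise_sigma,
                                    residual_factor_sd = residual_factor_sd,
                                    factor_lines = factor_lines, seed = seed)
    datasets
  })
}

#' Write a self-contained WIG/BED/TSV fixture suite
#'
#' Generates an annotation (BED6), per cell-line and per feature a
#' variableStep WIG of simulated reads, per cell-line an expression TSV,
#' and a `truth.json` recording the generative parameters. Per-feature
#' target intensities are log-normal with mean around `reads_per_gene`;
#' expression is a linear function of the log-transformed realized
#' gene-level scores (the generator's own window sums over the reads it
#' placed, including background and neighbouring-gene spillover) plus
#' Gaussian noise, so the scored design is exactly linear and the fit
#' recovers `beta_true` up to `noise_sigma`. The whole directory is
#' reproducible byte-for-byte under the configuration seed and parses
#' end-to-end through the package's readers.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @param n_cell_lines number of simulated cell-lines sharing `beta_true`.
#' @return Invisibly, a manifest list with file paths and the truth record.
#' @export
make_fixture_suite <- function(config, out_dir, n_cell_lines = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_annotation(config)
  bed <- file.path(out_dir, "genes.bed")
  write_gene_annotation(ann, bed)
  feat <- paste0("feat", seq_len(config$n_features))
  manifest <- list(bed = bed, cell_lines = list())
  for (c_i in seq_len(n_cell_lines)) {
    line <- paste0("line", c_i)
    targets <- with_local_seed(config$seed + 1000L * c_i, {
      vapply(seq_len(config$n_features), function(f) {
        stats::rlnorm(config$n_genes,
                      meanlog = log(config$reads_per_gene) - 0.5,
                      sdlog = 1)
      }, numeric(config$n_genes))
    })
    wigs <- character(config$n_features)
    realized <- matrix(0, config$n_genes, config$n_features,
                       dimnames = list(ann$gene_id, feat))
    for (f in seq_len(config$n_features)) {
      sig <- simulate_chipseq(ann, targets[, f], config,
                              seed = config$seed + 1000L * c_i + f)
      wigs[f] <- file.path(out_dir, paste0(line, "_", feat[f], ".wig"))
      write_wig(sig, wigs[f])
      realized[, f] <- window_sums(sig, ann, config$d_star)
    }
    X_real <- cbind(log1p(realized), bias = 1)
    y <- simulate_expression(X_real, config$beta_true, config$noise_sigma,
                             seed = config$seed + 1000L * c_i + 999L)
    expr <- file.path(out_dir, paste0(line, "_expression.tsv"))
    write_expression(y, expr)
    manifest$cell_lines[[line]] <- list(wigs = stats::setNames(wigs, feat),
                                        expression = expr)
  }
  truth <- list(beta_true = config$beta_true,
                noise_sigma = config$noise_sigma, seed = config$seed,
                n_genes = config$n_genes, n_features = config$n_features,
                n_cell_lines = n_cell_lines, d_star = config$d_star,
                reads_per_gene = config$reads_per_gene,
                background_rate = config$background_rate,
                transform = "log1p")
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$truth <- truth
  manifest$truth_path <- file.path(out_dir, "truth.json")
  invisible(manifest)
}

# Per-gene total read weight within [tss - d_star, tss + d_star]; the
# generator's own bookkeeping of what it placed (independent of the
# scoring module's engine path).
window_sums <- function(signal, annotation, d_star) {
  out <- numeric(nrow(annotation))
  for (m in seq_len(nrow(annotation))) {
    sel <- signal$chrom == annotation$chrom[m] &
      abs(signal$pos - annotation$tss[m]) <= d_star
    out[m] <- sum(signal$weight[sel])
  }
  out
}

#' Run the scoring pipeline over a fixture suite
#'
#' Reads a [make_fixture_suite()] directory back through the package's
#' readers, scores every cell-line's WIG tracks against the BED annotation,
#' log-transforms, and pairs the score matrices with the expression tables.
#'
#' @param manifest value of [make_fixture_suite()].
#' @param config the [simulation_config()] used to generate the suite (for
#'   `d_star`).
#' @param engine an [engine_config()].
#' @return List of [cell_line_dataset()] objects.
#' @export
load_fixture_suite <- function(manifest, config, engine = engine_config()) {
  ann <- read_gene_annotation(manifest$bed)
  idx <- tss_index(ann)
  scfg <- scoring_config(d_star = config$d_star, kind = "histone")
  lapply(names(manifest$cell_lines), function(line) {
    entry <- manifest$cell_lines[[line]]
    cols <- lapply(entry$wigs, function(w) {
      mr_epigenetic_scores(read_wig(w), idx, scfg, engine)
    })
    names(cols) <- names(entry$wigs)
    X <- transform_scores(assemble_score_matrix(cols, add_bias = TRUE),
                          method = "log", pseudocount = 1)
    cell_line_dataset(line, X, read_expression(entry$expression))
  })
}
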