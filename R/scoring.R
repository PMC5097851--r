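#' Scoring configuration
#'
#' Parameters of the TSS-proximal scoring kernel. `d_star` is the window
#' half-width in bp limiting which reads contribute to a gene (2000 bp,
#' approximating the average width of ChIP-seq binding regions); `d0` is the
#' decay constant in bp of the exponential transcription-factor kernel
#' (5000 bp). `kind` selects the kernel: constant sum-of-tags for histone
#' modifications, exponentially decaying affinity for transcription factors.
#'
#' @param d_star window half-width, bp (> 0).
#' @param d0 exponential decay constant, bp (> 0).
#' @param kind `"histone"` or `"tf"`.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(d_star = 2000, d0 = 5000, kind = c("histone", "tf")) {
  kind <- match.arg(kind)
  if (!is.numeric(d_star) || d_star <= 0) stop_("`d_star` must be > 0")
  if (!is.numeric(d0) || d0 <= 0) stop_("`d0` must be > 0")
  structure(list(d_star = d_star, d0 = d0, kind = kind),
            class = "scoring_config")
}

#' Read--gene association kernel
#'
#' Maps a signed read-to-TSS distance to a strength of association:
#' exactly 1 for histone modifications (tag counting) and
#' `exp(-|distance| / d0)` for transcription factors. The absolute distance
#' is used so affinity decays symmetrically on both sides of the TSS.
#' Callers enforce `|distance| <= d_star`.
#'
#' @param distance signed distance(s) in bp from the TSS (downstream
#'   positive).
#' @param config a [scoring_config()].
#' @return Numeric weight(s) in (0, 1].
#' @export
phi <- function(distance, config) {
  if (config$kind == "histone") return(rep(1, length(distance)))
  exp(-abs(distance) / config$d0)
}

#' Build a TSS range-query index
#'
#' Per-chromosome TSS coordinates sorted ascending, supporting O(log M)
#' window queries by binary search ([findInterval()]); the same contract as
#' a balanced search tree over TSS loci.
#'
#' @param annotation data.frame from [read_gene_annotation()].
#' @return An object of class `tss_index`; `gene_ids` preserves the
#'   annotation's gene order (the row order of score columns).
#' @export
tss_index <- function(annotation) {
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(annotation)))
  if (anyDuplicated(annotation$gene_id)) stop_("duplicate gene_id in annotation")
  chroms <- split(annotation[, c("gene_id", "tss", "strand")], annotation$chrom)
  chroms <- lapply(chroms, function(d) {
    o <- order(d$tss, method = "radix")
    list(tss = d$tss[o], gene_id = d$gene_id[o], strand = d$strand[o])
  })
  structure(list(chroms = chroms, gene_ids = annotation$gene_id,
                 warned = new.env(parent = emptyenv())),
            class = "tss_index")
}

#' Genes whose TSS window covers a position
#'
#' Returns exactly the genes with `|pos - tss| <= d_star` (inclusive at both
#' ends). The signed distance is `pos - tss` for `+` strand genes and its
#' negation for `-` strand genes, so downstream is always positive. An
#' unknown chromosome yields an empty result (noted once per chromosome).
#'
#' @param index a [tss_index()].
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @param d_star window half-width in bp.
#' @return `list(gene_id =, distance =)` of equal-length vectors.
#' @export
genes_within <- function(index, chrom, pos, d_star) {
  ch <- index$chroms[[chrom]]
  if (is.null(ch)) {
    if (!exists(chrom, envir = index$warned, inherits = FALSE)) {
      assign(chrom, TRUE, envir = index$warned)
      message("tss_index: no genes on chromosome '", chrom, "'")
    }
    return(list(gene_id = character(0), distance = numeric(0)))
  }
  i1 <- findInterval(pos - d_star - 0.5, ch$tss) + 1L
  i2 <- findInterval(pos + d_star + 0.5, ch$tss)
  if (i1 > i2) return(list(gene_id = character(0), distance = numeric(0)))
  sel <- i1:i2
  raw <- pos - ch$tss[sel]
  list(gene_id = ch$gene_id[sel],
       distance = ifelse(ch$strand[sel] == "-", -raw, raw))
}

signal_to_pairs <- function(signal) {
  chrom <- as.character(signal$chrom)
  pos <- signal$pos
  weight <- signal$weight
  lapply(seq_along(pos), function(i) {
    kv(i, list(chrom = chrom[i], pos = pos[i], weight = weight[i]))
  })
}

#' Gene-level epigenetic scores as a MapReduce program
#'
#' Computes one column of the epigenetic score matrix: for every gene m the
#' sum, over signal records r within `d_star` of its TSS, of
#' `weight(r) * phi(d(r, m))`. Expressed as a single map-shuffle-reduce
#' round: the mapper turns a record into one `(gene_id, phi-weight)` pair
#' per gene whose window covers it (a record near several TSSs contributes
#' to every such gene); the reducer sums the canonically ordered weights per
#' gene. Genes with no nearby signal score 0.
#'
#' @param signal data.frame of signal records (`chrom`, `pos`, `weight`),
#'   e.g. from [read_wig()].
#' @param index a [tss_index()] sharing the signal's chromosome namespace.
#' @param config a [scoring_config()].
#' @param engine an [engine_config()].
#' @return Named numeric vector over all indexed genes, in annotation order.
#' @export
mr_epigenetic_scores <- function(signal, index, config = scoring_config(),
                                 engine = engine_config()) {
  stopifnot(inherits(index, "tss_index"), inherits(config, "scoring_config"))
  scores <- stats::setNames(numeric(length(index$gene_ids)), index$gene_ids)
  if (nrow(signal) == 0L) return(scores)
  d_star <- config$d_star
  prog <- mr_program(mr_round(
    mapper = function(pair) {
      rec <- pair$value
      hits <- genes_within(index, rec$chrom, rec$pos, d_star)
      n <- length(hits$gene_id)
      if (n == 0L) return(list())
      w <- rec$weight * phi(hits$distance, config)
      out <- vector("list", n)
      for (i in seq_len(n)) out[[i]] <- kv(hits$gene_id[i], w[i])
      out
    },
    reducer = function(key, values) {
      list(kv(key, sum(unlist(values, use.names = FALSE))))
    }
  ))
  out <- execute_program(prog, signal_to_pairs(signal), engine)
  ids <- vapply(out, `[[`, character(1), "key")
  scores[ids] <- vapply(out, `[[`, numeric(1), "value")
  scores
}

#' Construct a score matrix
#'
#' The genes x features matrix X of gene-level epigenetic scores; the
#' optional bias column (all ones, named `bias`) is always last.
#'
#' @param values numeric matrix with gene ids as rownames and feature names
#'   as colnames.
#' @param has_bias whether the last column is the unity bias term.
#' @return An object of class `score_matrix` with fields `values` and
#'   `has_bias`.
#' @export
score_matrix <- function(values, has_bias = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_("score matrix needs gene rownames and feature colnames")
  }
  if (has_bias) {
    last <- values[, ncol(values)]
    if (!all(last == 1)) stop_("has_bias = TRUE but last column is not all ones")
  }
  structure(list(values = values, has_bias = isTRUE(has_bias)),
            class = "score_matrix")
}

#' @export
dim.score_matrix <- function(x) dim(x$values)

#' @export
print.score_matrix <- function(x, ...) {
  cat("score_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "features", if (x$has_bias) "(incl. bias)" else "", "\n")
  invisible(x)
}

# number of free predictors (bias excluded)
n_predictors_of <- function(x) ncol(x$values) - as.integer(x$has_bias)

#' Assemble score columns into a matrix
#'
#' @param columns named list of score columns (named numeric vectors sharing
#'   one gene ordering, e.g. from [mr_epigenetic_scores()]).
#' @param add_bias append a unity bias column (named `bias`) as the last
#'   column.
#' @param gene_ids gene ordering; required when `columns` is empty.
#' @return A [score_matrix()].
#' @export
assemble_score_matrix <- function(columns, add_bias = TRUE, gene_ids = NULL) {
  if (length(columns) == 0L) {
    if (is.null(gene_ids)) stop_("gene_ids required when no columns are given")
    if (!add_bias) stop_("nothing to assemble")
    v <- matrix(1, length(gene_ids), 1L,
                dimnames = list(gene_ids, "bias"))
    return(score_matrix(v, has_bias = TRUE))
  }
  if (is.null(names(columns)) || any(names(columns) == "")) {
    stop_("`columns` must be a named list")
  }
  ref <- names(columns[[1L]])
  for (nm in names(columns)) {
    ids <- names(columns[[nm]])
    if (!identical(ids, ref)) {
      extra <- c(setdiff(ids, ref), setdiff(ref, ids))
      stop_("column '", nm, "' gene ordering differs from column '",
            names(columns)[1L], "'",
            if (length(extra)) paste0("; symmetric difference: ",
                                      paste(extra, collapse = ", "))
            else " (same genes, different order)")
    }
  }
  v <- do.call(cbind, columns)
  rownames(v) <- ref
  if (add_bias) v <- cbind(v, bias = 1)
  score_matrix(v, has_bias = add_bias)
}

#' Transform raw scores
#'
#' `log` maps x to `ln(x + pseudocount)` (pseudocount 1 by default, so zero
#' scores stay zero); `arsinh` maps x to `asinh(x)` and takes no
#' pseudocount. The bias column, if present, is untouched.
#'
#' @param x a [score_matrix()] of raw (non-negative) scores.
#' @param method `"log"` or `"arsinh"`.
#' @param pseudocount added before the log transform.
#' @return A transformed [score_matrix()].
#' @export
transform_scores <- function(x, method = c("log", "arsinh"), pseudocount = 1) {
  stopifnot(inherits(x, "score_matrix"))
  method <- match.arg(method)
  v <- x$values
  cols <- seq_len(ncol(v) - as.integer(x$has_bias))
  if (length(cols) == 0L) return(x)
  if (method == "log") {
    if (any(v[, cols] + pseudocount <= 0)) {
      stop_("log transform undefined: scores + pseudocount must be positive")
    }
    v[, cols] <- log(v[, cols] + pseudocount)
  } else {
    v[, cols] <- asinh(v[, cols])
  }
  score_matrix(v, has_bias = x$has_bias)
}

#' Quantile-normalise score columns
#'
#' Forces every non-bias column onto the mean order-statistic reference
#' distribution: after normalisation all columns share the same sorted value
#' multiset, while each column's internal rank order is preserved. Tied
#' values within a column receive the mean of their tied reference values.
#'
#' @param x a [score_matrix()] with at least 2 non-bias columns (a single
#'   column is returned unchanged with a warning).
#' @return A quantile-normalised [score_matrix()].
#' @export
quantile_normalise <- function(x) {
  stopifnot(inherits(x, "score_matrix"))
  v <- x$values
  cols <- seq_len(ncol(v) - as.integer(x$has_bias))
  if (length(cols) < 2L) {
    warning("quantile normalisation needs >= 2 feature columns; returning input")
    return(x)
  }
  sub <- v[, cols, drop = FALSE]
  ref <- rowMeans(apply(sub, 2L, sort))
  v[, cols] <- apply(sub, 2L, function(col) {
    assigned <- ref[rank(col, ties.method = "first")]
    stats::ave(assigned, match(col, col))
  })
  score_matrix(v, has_bias = x$has_bias)
}
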