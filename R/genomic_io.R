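#' Read a UCSC wiggle (.WIG) signal track
#'
#' Parses the `variableStep` and `fixedStep` wiggle dialects (a `span`
#' attribute is accepted). Each declared data line yields one signal record:
#' a record with span s and value v contributes a single record of weight v
#' at the record's start coordinate -- span does not multiply weight, which
#' keeps histone tag counts exact integers when the WIG values are integral.
#' Positions are 1-based. `fixedStep` positions are `start + i * step` for
#' i = 0, 1, ....
#'
#' @param path path to a WIG file.
#' @return A `data.frame` with columns `chrom`, `pos` (1-based), `weight`
#'   (non-negative read-equivalents), one row per data line.
#' @export
read_wig <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  txt <- trimws(lines)
  skip <- txt == "" | startsWith(txt, "#") | startsWith(txt, "track") |
    startsWith(txt, "browser")
  is_var <- grepl("^variableStep\\b", txt)
  is_fix <- grepl("^fixedStep\\b", txt)
  is_decl <- is_var | is_fix
  # any non-data, non-declaration word-initial line is an unknown directive
  wordish <- grepl("^[A-Za-z]", txt) & !skip & !is_decl
  if (any(wordish)) {
    stop_("WIG parse error at line ", which(wordish)[1L],
          ": unknown directive '", sub("[ \t].*$", "", txt[which(wordish)[1L]]), "'")
  }
  data_idx <- which(!skip & !is_decl)
  if (length(data_idx) > 0L && (!any(is_decl) || data_idx[1L] < which(is_decl)[1L])) {
    stop_("WIG parse error at line ", data_idx[1L],
          ": data before any variableStep/fixedStep declaration")
  }
  decl_idx <- which(is_decl)
  if (length(decl_idx) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), weight = double(),
                      stringsAsFactors = FALSE))
  }
  block_of <- findInterval(data_idx, decl_idx)
  out <- vector("list", length(decl_idx))
  for (b in seq_along(decl_idx)) {
    di <- decl_idx[b]
    attrs <- parse_wig_attrs(txt[di], di)
    rows <- data_idx[block_of == b]
    if (length(rows) == 0L) {
      out[[b]] <- NULL
      next
    }
    fields <- strsplit(txt[rows], "[ \t]+")
    nf <- lengths(fields)
    if (is_var[di]) {
      bad <- which(nf != 2L)
      if (length(bad)) {
        stop_("WIG parse error at line ", rows[bad[1L]],
              ": expected '<position> <value>'")
      }
      fm <- matrix(unlist(fields), nrow = 2L)
      pos <- suppressWarnings(as.numeric(fm[1L, ]))
      val <- suppressWarnings(as.numeric(fm[2L, ]))
      bad <- which(is.na(pos) | is.na(val) | pos < 1)
      if (length(bad)) {
        stop_("WIG parse error at line ", rows[bad[1L]],
              ": invalid position/value '", txt[rows[bad[1L]]], "'")
      }
    } else {
      bad <- which(nf != 1L)
      if (length(bad)) {
        stop_("WIG parse error at line ", rows[bad[1L]],
              ": fixedStep data lines carry a single value")
      }
      val <- suppressWarnings(as.numeric(unlist(fields)))
      bad <- which(is.na(val))
      if (length(bad)) {
        stop_("WIG parse error at line ", rows[bad[1L]],
              ": non-numeric value '", txt[rows[bad[1L]]], "'")
      }
      pos <- attrs$start + (seq_along(val) - 1L) * attrs$step
    }
    bad <- which(val < 0)
    if (length(bad)) {
      stop_("WIG parse error at line ", rows[bad[1L]],
            ": negative value ", val[bad[1L]])
    }
    out[[b]] <- data.frame(chrom = attrs$chrom, pos = as.integer(pos),
                           weight = val, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), weight = double(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

parse_wig_attrs <- function(line, lineno) {
  type <- sub("[ \t].*$", "", line)
  toks <- strsplit(line, "[ \t]+")[[1L]][-1L]
  kv_ok <- grepl("^[A-Za-z]+=[^=]+$", toks)
  if (length(toks) && !all(kv_ok)) {
    stop_("WIG parse error at line ", lineno, ": malformed attribute '",
          toks[!kv_ok][1L], "'")
  }
  keys <- sub("=.*$", "", toks)
  vals <- sub("^[^=]*=", "", toks)
  allowed <- if (type == "fixedStep") c("chrom", "start", "step", "span") else c("chrom", "span")
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) {
    stop_("WIG parse error at line ", lineno, ": unknown ", type,
          " attribute '", unknown[1L], "'")
  }
  get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
  chrom <- get("chrom")
  if (is.na(chrom)) stop_("WIG parse error at line ", lineno, ": missing chrom=")
  res <- list(type = type, chrom = chrom, span = 1L, start = NA_integer_, step = 1L)
  if (!is.na(get("span"))) res$span <- as.integer(get("span"))
  if (type == "fixedStep") {
    start <- suppressWarnings(as.integer(get("start")))
    step <- suppressWarnings(as.integer(get("step")))
    if (is.na(start) || start < 1L) {
      stop_("WIG parse error at line ", lineno, ": fixedStep needs start= >= 1")
    }
    if (is.na(step) || step < 1L) {
      stop_("WIG parse error at line ", lineno, ": fixedStep needs step= >= 1")
    }
    res$start <- start
    res$step <- step
  }
  res
}

#' Write signal records as variableStep WIG
#'
#' Weights at identical (chrom, pos) coordinates are aggregated and positions
#' written in ascending order per chromosome, so output is a valid
#' variableStep track and byte-deterministic for a given record multiset.
#'
#' @param records data.frame with columns `chrom`, `pos`, `weight`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wig <- function(records, path) {
  stopifnot(all(c("chrom", "pos", "weight") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=wiggle_0", con)
  for (ch in sort(unique(records$chrom), method = "radix")) {
    sub <- records[records$chrom == ch, , drop = FALSE]
    w <- rowsum(sub$weight, group = sub$pos, reorder = TRUE)
    pos <- as.integer(rownames(w))
    writeLines(paste0("variableStep chrom=", ch), con)
    writeLines(paste(pos, format_full(drop(w))), con)
  }
  invisible(path)
}

#' Read gene annotations from BED6
#'
#' BED coordinates are 0-based half-open; internal coordinates are 1-based
#' inclusive, converted exactly once here. The TSS is `chromStart + 1` for
#' `+` strand genes and `chromEnd` for `-` strand genes.
#'
#' @param path path to a BED6 file (whitespace-delimited).
#' @return A `data.frame` with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_gene_annotation <- function(path) {
  empty <- data.frame(gene_id = character(), chrom = character(),
                      tss = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (length(readLines(path, n = 1L)) == 0L) return(empty)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 6L) stop_("BED6 required: missing strand column (got ",
                            ncol(tab), " columns)")
  strand <- as.character(tab[[6L]])
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) stop_("invalid strand '", strand[bad[1L]], "' for record ",
                         bad[1L])
  gene_id <- as.character(tab[[4L]])
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup)) stop_("duplicate gene_id in annotation: ",
                         paste(unique(dup), collapse = ", "))
  tss <- ifelse(strand == "+", tab[[2L]] + 1L, tab[[3L]])
  data.frame(gene_id = gene_id, chrom = as.character(tab[[1L]]),
             tss = as.integer(tss), strand = strand, stringsAsFactors = FALSE)
}

#' Read/write a two-column expression table
#'
#' Tab-separated `gene_id <TAB> abundance`; a header line is detected by a
#' non-numeric second field and skipped. Writing uses 17 significant digits
#' so a write/read round trip reproduces values exactly.
#'
#' @param path file path.
#' @return Named numeric vector of abundances (names are gene ids).
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0L) return(stats::setNames(numeric(0), character(0)))
  first <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  offset <- 0L
  if (length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2L])))) {
    lines <- lines[-1L]
    offset <- 1L
    if (length(lines) == 0L) return(stats::setNames(numeric(0), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) stop_("expression parse error at line ", bad[1L] + offset,
                         ": expected two tab-separated columns")
  fm <- matrix(unlist(fields), nrow = 2L)
  vals <- suppressWarnings(as.numeric(fm[2L, ]))
  bad <- which(is.na(vals))
  if (length(bad)) stop_("expression parse error at line ", bad[1L] + offset,
                         ": non-numeric abundance '", fm[2L, bad[1L]], "'")
  ids <- fm[1L, ]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop_("duplicate gene_id in expression table: ",
                         paste(unique(dup), collapse = ", "))
  stats::setNames(vals, ids)
}

#' @rdname read_expression
#' @param x named numeric vector of abundances.
#' @param header write a `gene_id\tabundance` header line.
#' @export
write_expression <- function(x, path, header = TRUE) {
  stopifnot(is.numeric(x), !is.null(names(x)))
  lines <- paste(names(x), format_full(unname(x)), sep = "\t")
  if (header) lines <- c("gene_id\tabundance", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read/write the score-matrix interchange format
#'
#' A TSV with two metadata lines (`#features:` and `#has_bias:`), a column
#' header, gene ids as row labels and one column per epigenetic feature.
#'
#' @param path file path.
#' @return A [score_matrix()].
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "#features:")) {
    stop_("score-matrix parse error: missing '#features:' header line")
  }
  features <- strsplit(sub("^#features:[ \t]*", "", lines[1L]), "\t",
                       fixed = TRUE)[[1L]]
  if (!startsWith(lines[2L], "#has_bias:")) {
    stop_("score-matrix parse error: missing '#has_bias:' header line")
  }
  has_bias <- toupper(trimws(sub("^#has_bias:", "", lines[2L]))) %in%
    c("TRUE", "1", "YES")
  body <- lines[-(1:2)]
  nf <- vapply(strsplit(body, "\t", fixed = TRUE), length, integer(1))
  if (any(nf != length(features) + 1L)) {
    stop_("score-matrix parse error at line ",
          which(nf != length(features) + 1L)[1L] + 2L, ": ragged row")
  }
  tab <- utils::read.table(text = body, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(vals) <- as.character(tab[[1L]])
  if (!identical(colnames(vals), features)) {
    stop_("score-matrix parse error: header row does not match #features: line")
  }
  score_matrix(vals, has_bias = has_bias)
}

#' @rdname read_score_matrix
#' @param x a [score_matrix()].
#' @export
write_score_matrix <- function(x, path) {
  stopifnot(inherits(x, "score_matrix"))
  v <- x$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#features:", paste(colnames(v), collapse = "\t")), con)
  writeLines(paste0("#has_bias:", if (x$has_bias) "TRUE" else "FALSE"), con)
  writeLines(paste(c("gene_id", colnames(v)), collapse = "\t"), con)
  body <- apply(v, 1L, function(row) paste(format_full(row), collapse = "\t"))
  writeLines(paste(rownames(v), body, sep = "\t"), con)
  invisible(path)
}

#' Write gene annotations as BED6
#'
#' Inverse of [read_gene_annotation()]: emits a 1 kb gene body anchored at
#' the TSS with the conventional strand-dependent coordinate conversion
#' (the TSS round-trips exactly; the body extent is nominal).
#'
#' @param annotation data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @param path output path.
#' @param body_length nominal gene-body length in bp.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path, body_length = 1000L) {
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(annotation)))
  plus <- annotation$strand == "+"
  start0 <- ifelse(plus, annotation$tss - 1L,
                   pmax(0L, annotation$tss - body_length))
  end0 <- ifelse(plus, annotation$tss - 1L + body_length, annotation$tss)
  lines <- paste(annotation$chrom, start0, end0, annotation$gene_id, 0L,
                 annotation$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
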