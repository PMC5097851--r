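#' Minimal deterministic map-shuffle-reduce engine
#'
#' The engine executes programs expressed as an ordered sequence of
#' (mapper, reducer) rounds over multisets of key--value pairs. Every mapper
#' instance is a pure function of a single pair; all mapper instances of a
#' round halt before any reducer of that round starts; reducers consume a
#' key together with the full (canonically ordered) list of values grouped
#' under it. Work is partitioned across `workers` slots by a stable hash of
#' the encoded key, and the final output multiset is canonically sorted, so
#' results are bit-identical for any worker count.
#'
#' @param workers positive integer, number of parallel worker slots.
#' @param backend `"serial"` evaluates every partition in the calling
#'   process; `"multicore"` forks one process per partition via
#'   [parallel::mclapply()] (unix only; falls back to serial elsewhere).
#' @return An object of class `engine_config`.
#' @seealso [mr_program()], [execute_program()]
#' @export
engine_config <- function(workers = 1L, backend = c("serial", "multicore")) {
  backend <- match.arg(backend)
  workers <- as.integer(workers)
  if (length(workers) != 1L || is.na(workers) || workers < 1L) {
    stop_("`workers` must be a single positive integer")
  }
  structure(list(workers = workers, backend = backend), class = "engine_config")
}

#' Construct a key--value pair
#'
#' Keys are tuples of orderable primitives (character, numeric, integer,
#' logical); values are primitives or flat (optionally named) records.
#'
#' @param key tuple of primitives (atomic scalar or vector).
#' @param value primitive or flat list record.
#' @return A pair suitable for engine input and mapper/reducer emission.
#' @export
kv <- function(key, value) list(key = key, value = value)

#' Define one mapper/reducer round
#'
#' @param mapper function of one key--value pair returning a list of pairs
#'   (possibly empty).
#' @param reducer function `(key, values)` returning a list of pairs, where
#'   `values` is the canonically ordered list of values grouped under `key`.
#' @return An object of class `mr_round`.
#' @export
mr_round <- function(mapper, reducer) {
  stopifnot(is.function(mapper), is.function(reducer))
  structure(list(mapper = mapper, reducer = reducer), class = "mr_round")
}

#' Assemble a MapReduce program
#'
#' @param ... one or more [mr_round()] objects (or a single list of them),
#'   executed in order.
#' @return An object of class `mr_program` with at least one round.
#' @export
mr_program <- function(...) {
  rounds <- list(...)
  if (length(rounds) == 1L && is.list(rounds[[1L]]) &&
      !inherits(rounds[[1L]], "mr_round")) {
    rounds <- rounds[[1L]]
  }
  if (length(rounds) < 1L) stop_("a program needs at least one round")
  ok <- vapply(rounds, inherits, logical(1), what = "mr_round")
  if (!all(ok)) stop_("all rounds must be created with mr_round()")
  structure(list(rounds = rounds), class = "mr_program")
}

# ---- canonical encodings ---------------------------------------------------

# Encode an orderable primitive as a type-tagged string. %.17g preserves
# doubles exactly, so equal encodings imply equal values.
encode_scalar <- function(x) {
  if (is.character(x)) return(paste0("s:", x))
  if (is.integer(x)) return(sprintf("i:%d", x))
  if (is.double(x)) return(paste0("n:", sprintf("%.17g", x)))
  if (is.logical(x)) return(paste0("b:", as.integer(x)))
  stop_("unorderable element of class '", class(x)[1L], "'")
}

encode_tuple <- function(x) {
  if (is.null(x)) return("")
  if (!is.atomic(x) && !is.list(x)) {
    stop_("unorderable element of class '", class(x)[1L], "'")
  }
  if (length(x) == 0L) return("")
  if (is.atomic(x) && length(x) == 1L) return(encode_scalar(x))
  paste(vapply(as.list(x), encode_scalar, character(1)), collapse = "\x1f")
}

encode_value <- function(v) {
  if (is.list(v)) {
    nm <- names(v) %||% rep("", length(v))
    parts <- vapply(seq_along(v), function(i) {
      paste0(nm[i], "=", encode_tuple(v[[i]]))
    }, character(1))
    return(paste(parts, collapse = "\x1e"))
  }
  encode_tuple(v)
}

# Stable (non-randomised) polynomial string hash, for key partitioning.
stable_hash <- function(s) {
  vapply(s, function(x) {
    h <- 0
    for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Canonical total order on a list of values: numeric scalars sort
# numerically, anything else by its type-tagged encoding (radix, so the
# order is locale-independent). Makes reducer-side summation order, and
# hence floating-point results, deterministic.
order_values <- function(values, key_label) {
  enc <- vapply(values, function(v) {
    tryCatch(encode_value(v), error = function(e) {
      stop_("unorderable value under key [", key_label, "]: ",
            conditionMessage(e))
    })
  }, character(1))
  numeric_scalar <- vapply(values, function(v) {
    is.numeric(v) && length(v) == 1L && !is.list(v)
  }, logical(1))
  if (all(numeric_scalar)) {
    order(unlist(values, use.names = FALSE), enc, method = "radix")
  } else {
    order(enc, method = "radix")
  }
}

# ---- phases ----------------------------------------------------------------

apply_phase <- function(items, fn, config, phase, keyof) {
  if (length(items) == 0L) return(list())
  run_chunk <- function(chunk) {
    out <- vector("list", length(chunk))
    for (i in seq_along(chunk)) {
      out[[i]] <- tryCatch(fn(chunk[[i]]), error = function(e) {
        stop_(phase, " failed on key [", encode_tuple(keyof(chunk[[i]])),
              "]: ", conditionMessage(e))
      })
    }
    unlist(out, recursive = FALSE) %||% list()
  }
  if (config$workers == 1L) return(run_chunk(items))
  part <- stable_hash(vapply(items, function(it) encode_tuple(keyof(it)),
                             character(1))) %% config$workers
  chunks <- unname(split(items, factor(part, levels = 0:(config$workers - 1L))))
  chunks <- chunks[lengths(chunks) > 0L]
  res <- if (config$backend == "multicore" && .Platform$OS.type == "unix") {
    parallel::mclapply(chunks, run_chunk, mc.cores = config$workers)
  } else {
    lapply(chunks, run_chunk)
  }
  for (r in res) {
    if (inherits(r, "try-error") || inherits(r, "condition")) {
      stop_(phase, " worker failed: ", conditionMessage(attr(r, "condition") %||% r))
    }
  }
  unlist(res, recursive = FALSE) %||% list()
}

#' Run a mapper over a multiset of pairs
#'
#' Applies a pure mapper to every pair and returns the multiset union of the
#' emissions. The result is identical (as a multiset) for any worker count.
#'
#' @param pairs list of pairs created with [kv()].
#' @param mapper function of one pair returning a list of pairs.
#' @param config an [engine_config()].
#' @return List of emitted pairs.
#' @export
run_mapper_phase <- function(pairs, mapper, config = engine_config()) {
  apply_phase(pairs, function(p) mapper(p), config, "mapper",
              keyof = function(p) p$key)
}

#' Group pairs by key
#'
#' The grouping step implicit between a round's mapper and reducer: each
#' input pair lands in exactly one group, group keys are unique and returned
#' in a canonical (radix) key order, and each group's value list is sorted by
#' a deterministic total order on values.
#'
#' @param pairs list of pairs.
#' @return List of `list(key =, values =)` groups.
#' @export
shuffle_pairs <- function(pairs) {
  if (length(pairs) == 0L) return(list())
  keys <- vapply(pairs, function(p) encode_tuple(p$key), character(1))
  lev <- sort(unique(keys), method = "radix")
  idx <- split(seq_along(pairs), factor(keys, levels = lev))
  lapply(idx, function(ii) {
    vals <- lapply(pairs[ii], `[[`, "value")
    key <- pairs[[ii[1L]]]$key
    list(key = key, values = vals[order_values(vals, encode_tuple(key))])
  })
}

#' Run a reducer over grouped pairs
#'
#' @param groups output of [shuffle_pairs()].
#' @param reducer function `(key, values)` returning a list of pairs.
#' @param config an [engine_config()].
#' @return List of emitted pairs.
#' @export
run_reducer_phase <- function(groups, reducer, config = engine_config()) {
  apply_phase(groups, function(g) reducer(g$key, g$values), config, "reducer",
              keyof = function(g) g$key)
}

canonical_pairs <- function(pairs) {
  if (length(pairs) == 0L) return(list())
  k <- vapply(pairs, function(p) encode_tuple(p$key), character(1))
  v <- vapply(pairs, function(p) encode_value(p$value), character(1))
  pairs[order(k, v, method = "radix")]
}

#' Execute a MapReduce program
#'
#' Runs the program's rounds in sequence on the input multiset: mapper phase,
#' shuffle, reducer phase, with the round-r mapper fully drained before the
#' round-r reducer starts. Exactly R rounds are executed. The returned
#' multiset is canonically sorted and bit-identical for any `workers` value
#' in the configuration.
#'
#' @param program an [mr_program()].
#' @param input list of pairs (the initial multiset U0).
#' @param config an [engine_config()].
#' @return Canonically ordered list of output pairs.
#' @export
execute_program <- function(program, input, config = engine_config()) {
  if (!inherits(program, "mr_program")) stop_("`program` must be an mr_program")
  if (!inherits(config, "engine_config")) stop_("`config` must be an engine_config")
  pairs <- input
  for (r in seq_along(program$rounds)) {
    round <- program$rounds[[r]]
    pairs <- tryCatch({
      mapped <- run_mapper_phase(pairs, round$mapper, config)
      grouped <- shuffle_pairs(mapped)
      run_reducer_phase(grouped, round$reducer, config)
    }, error = function(e) {
      stop_("round ", r, ": ", conditionMessage(e))
    })
  }
  canonical_pairs(pairs)
}
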