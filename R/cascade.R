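#' Cascade configuration
#'
#' The ordered alignment cascade assigns every retained read to the first
#' compartment whose reference it matches within that stage's mismatch
#' allowance: contaminant (k=2), structural RNAs (k=2), the GFP sensor (k=0),
#' the recoded trigger (k=0), miRNA hairpins (k=0), then the genome (k=0).
#' Reads failing all stages are `unmapped`; reads outside the length window
#' after trimming are `discarded_length`.
#'
#' @param adapter 3' adapter sequence removed before length filtering.
#'   The default is the TruSeq small RNA 3' adapter.
#' @param min_len,max_len Retained insert length window in nt.
#' @param stages Data frame with columns `stage` (reference slot of the
#'   bundle), `compartment` (label reads assigned at that stage receive) and
#'   `k` (mismatch allowance). The default reproduces the six-stage order
#'   above.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(adapter = "TGGAATTCTCGGGTGCCAAGG",
                           min_len = 21L, max_len = 34L,
                           stages = default_stages()) {
  stopifnot(is.character(adapter), length(adapter) == 1L)
  if (min_len > max_len) .stopf("min_len must be <= max_len")
  stopifnot(is.data.frame(stages),
            all(c("stage", "compartment", "k") %in% names(stages)),
            all(stages$k >= 0))
  structure(list(adapter = adapter, min_len = as.integer(min_len),
                 max_len = as.integer(max_len), stages = stages),
            class = "cascade_config")
}

#' @rdname cascade_config
#' @export
default_stages <- function() {
  data.frame(
    stage = c("contaminant", "structural", "sensor_gfp", "recoded_gfp",
              "hairpins", "genome"),
    compartment = c("contaminant", "structural", "sensor_gfp", "recoded_gfp",
                    "mirna", "genome"),
    k = c(2L, 2L, 0L, 0L, 0L, 0L))
}

COMPARTMENTS <- c("contaminant", "structural", "sensor_gfp", "recoded_gfp",
                  "mirna", "genome", "unmapped", "discarded_length")

.as_read_frame <- function(reads) {
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(reads))
    return(data.frame(read_id = ids, sequence = unname(reads)))
  }
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  reads
}

#' Trim 3' adapters and filter by insert length
#'
#' Removes the 3' adapter at its leftmost occurrence, using cutadapt-style
#' semantics: the adapter (or a prefix of it, when the read ends first) must
#' match from the trim point through the end of the read with an error rate
#' of at most `error_rate`, with a minimum overlap of `min_overlap` bases.
#' Reads without an adapter occurrence are kept untrimmed. Reads whose insert
#' falls outside `[min_len, max_len]` are moved to the discard log with
#' reason `"too_short"` or `"too_long"`.
#'
#' @param reads Character vector of read sequences (names used as ids) or a
#'   data frame with `read_id` and `sequence` columns.
#' @param config A [cascade_config()].
#' @param error_rate Maximum fraction of mismatches in the adapter overlap.
#' @param min_overlap Minimum adapter overlap considered.
#' @return List with `kept` (data frame `read_id`, `sequence`) and
#'   `discarded` (data frame `read_id`, `sequence`, `reason`).
#' @export
trim_and_filter <- function(reads, config = cascade_config(),
                            error_rate = 0.1, min_overlap = 3L) {
  stopifnot(inherits(config, "cascade_config"))
  if (!nzchar(config$adapter)) .stopf("adapter must be non-empty")
  rf <- .as_read_frame(reads)
  if (nrow(rf) == 0L) {
    return(list(kept = data.frame(read_id = character(0), sequence = character(0)),
                discarded = data.frame(read_id = character(0),
                                       sequence = character(0),
                                       reason = character(0))))
  }
  araw <- charToRaw(config$adapter)
  trimmed <- vapply(rf$sequence, function(s) {
    p <- .cpp_trim_point(charToRaw(s), araw, error_rate,
                         as.integer(min_overlap))
    if (p > 0L) substr(s, 1L, p - 1L) else s
  }, character(1), USE.NAMES = FALSE)
  len <- nchar(trimmed)
  reason <- rep(NA_character_, length(len))
  reason[len < config$min_len] <- "too_short"
  reason[len > config$max_len] <- "too_long"
  keep <- is.na(reason)
  list(kept = data.frame(read_id = rf$read_id[keep], sequence = trimmed[keep]),
       discarded = data.frame(read_id = rf$read_id[!keep],
                              sequence = trimmed[!keep],
                              reason = reason[!keep]))
}

# Precompute an exact-search engine for a set of references: a single
# concatenated string with a separator that can never match read characters.
# Leftmost match in the concatenation realizes the (reference order, offset)
# tie-break directly.
.concat_engine <- function(references) {
  lens <- nchar(references)
  concat <- paste(references, collapse = "#")
  starts <- cumsum(c(0L, utils::head(lens, -1L) + 1L))  # 0-based ref starts
  list(concat = concat, starts = starts, lens = lens,
       ids = names(references))
}

.concat_locate <- function(engine, query) {
  p <- regexpr(query, engine$concat, fixed = TRUE)[1]
  if (p < 0) return(NULL)
  idx <- findInterval(p - 1L, engine$starts)
  list(ref = idx, offset = (p - 1L) - engine$starts[idx])
}

#' Best k-mismatch alignment of a query against a reference set
#'
#' Scans every offset of every reference on both strands (the query as given
#' is `sense`; its reverse complement is `antisense`) and returns the hit
#' with the fewest mismatches, provided it does not exceed `k`. Ties are
#' broken deterministically by fewest mismatches, then reference declaration
#' order, then smallest offset, then sense before antisense. An `N` in the
#' query counts as a mismatch at every position.
#'
#' @param query Read sequence over `A,C,G,T,N`.
#' @param references Named character vector of reference sequences.
#' @param k Maximum mismatches allowed.
#' @param search_both_strands Search the reverse complement as well.
#' @return A one-row data frame (`reference_id`, `offset` 0-based, `strand`,
#'   `mismatches`) or `NULL` when no reference qualifies.
#' @export
align_k_mismatch <- function(query, references, k,
                             search_both_strands = TRUE) {
  stopifnot(is.character(query), length(query) == 1L, is.character(references))
  if (is.null(names(references)) || any(!nzchar(names(references))))
    .stopf("references must be named")
  .check_alphabet(query, allow_n = TRUE, what = "query")
  hit <- if (k == 0L) {
    .align_exact(query, .concat_engine(references), search_both_strands)
  } else {
    .align_scan(query, references, k, search_both_strands)
  }
  if (is.null(hit)) return(NULL)
  data.frame(reference_id = names(references)[hit$ref],
             offset = hit$offset, strand = hit$strand,
             mismatches = hit$mismatches)
}

.align_exact <- function(query, engine, both_strands = TRUE) {
  if (grepl("N", query, fixed = TRUE)) return(NULL)  # N never matches
  s <- .concat_locate(engine, query)
  a <- if (both_strands) .concat_locate(engine, reverse_complement(query)) else NULL
  if (is.null(s) && is.null(a)) return(NULL)
  pick_sense <- !is.null(s) &&
    (is.null(a) || s$ref < a$ref ||
       (s$ref == a$ref && s$offset <= a$offset))
  h <- if (pick_sense) s else a
  list(ref = h$ref, offset = h$offset,
       strand = if (pick_sense) "sense" else "antisense", mismatches = 0L)
}

.align_scan <- function(query, references, k, both_strands = TRUE,
                        raws = NULL) {
  if (is.null(raws)) raws <- lapply(references, .seq_raw)
  qs <- .seq_raw(query, query = TRUE)
  qa <- if (both_strands) .seq_raw(reverse_complement(query), query = TRUE) else NULL
  best <- NULL
  for (r in seq_along(raws)) {
    for (strand in c("sense", "antisense")) {
      q <- if (strand == "sense") qs else qa
      if (is.null(q)) next
      hit <- .cpp_best_offset(q, raws[[r]], as.integer(k))
      if (!length(hit)) next
      cand <- list(ref = r, offset = hit[1], strand = strand,
                   mismatches = hit[2])
      if (is.null(best) || .hit_before(cand, best)) best <- cand
    }
    # nothing in a later reference can beat a 0-mismatch hit already found
    if (!is.null(best) && best$mismatches == 0L) break
  }
  best
}

.hit_before <- function(a, b) {
  if (a$mismatches != b$mismatches) return(a$mismatches < b$mismatches)
  if (a$ref != b$ref) return(a$ref < b$ref)
  if (a$offset != b$offset) return(a$offset < b$offset)
  a$strand == "sense" && b$strand != "sense"
}

.stage_references <- function(bundle, stage) {
  refs <- switch(stage,
                 contaminant = bundle$contaminant,
                 structural = bundle$structural,
                 sensor_gfp = bundle$sensor_gfp,
                 recoded_gfp = bundle$recoded_gfp,
                 hairpins = bundle$hairpins,
                 genome = bundle$genome,
                 NULL)
  if (is.null(refs) || length(refs) == 0L)
    .stopf("cascade configuration error: no reference sequences for stage '%s'",
           stage)
  refs
}

#' Run the sequential alignment cascade
#'
#' Trims and length-filters the input, then walks every retained read through
#' the configured stages in order; the first stage producing a qualifying hit
#' claims the read. The per-compartment totals always partition the input
#' (asserted on every run).
#'
#' @param reads Character vector or data frame of raw reads (see
#'   [trim_and_filter()]); may carry a `truth_label` column which is passed
#'   through to the assignments.
#' @param bundle A `reference_bundle`.
#' @param config A [cascade_config()].
#' @return A list of class `cascade_result`: `assignments` (per retained
#'   read: compartment, reference, 0-based offset, length, strand, mismatch
#'   count), `discarded`, `totals`, `retained_total` and `n_input`.
#' @export
run_cascade <- function(reads, bundle, config = cascade_config()) {
  stopifnot(inherits(bundle, "reference_bundle"),
            inherits(config, "cascade_config"))
  rf <- .as_read_frame(reads)
  tf <- trim_and_filter(rf, config)
  kept <- tf$kept
  st <- config$stages
  engines <- lapply(seq_len(nrow(st)), function(i) {
    refs <- .stage_references(bundle, st$stage[i])
    if (st$k[i] == 0L) {
      list(k = 0L, refs = refs, engine = .concat_engine(refs))
    } else {
      list(k = st$k[i], refs = refs, raws = lapply(refs, .seq_raw))
    }
  })

  n <- nrow(kept)
  compartment <- rep("unmapped", n)
  reference_id <- rep(NA_character_, n)
  offset <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  mismatches <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    q <- kept$sequence[j]
    for (i in seq_len(nrow(st))) {
      e <- engines[[i]]
      hit <- if (e$k == 0L) .align_exact(q, e$engine)
             else .align_scan(q, e$refs, e$k, raws = e$raws)
      if (!is.null(hit)) {
        compartment[j] <- st$compartment[i]
        reference_id[j] <- names(e$refs)[hit$ref]
        offset[j] <- hit$offset
        strand[j] <- hit$strand
        mismatches[j] <- hit$mismatches
        break
      }
    }
  }

  assignments <- data.frame(read_id = kept$read_id, sequence = kept$sequence,
                            length = nchar(kept$sequence),
                            compartment = compartment,
                            reference_id = reference_id, offset = offset,
                            strand = strand, mismatches = mismatches)
  if ("truth_label" %in% names(rf)) {
    assignments$truth_label <-
      rf$truth_label[match(assignments$read_id, rf$read_id)]
  }
  comp_levels <- unique(c(st$compartment, "unmapped", "discarded_length"))
  totals <- table(factor(compartment, levels = setdiff(comp_levels,
                                                       "discarded_length")))
  totals <- c(as.integer(totals), nrow(tf$discarded))
  names(totals) <- comp_levels
  if (sum(totals) != nrow(rf))
    .stopf("internal error: compartment totals do not partition the input")
  structure(list(assignments = assignments, discarded = tf$discarded,
                 totals = totals, retained_total = n, n_input = nrow(rf)),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("Alignment cascade: %d reads in, %d retained after trim/length filter\n",
              x$n_input, x$retained_total))
  for (nm in names(x$totals)) {
    cat(sprintf("  %-18s %8d\n", nm, x$totals[[nm]]))
  }
  invisible(x)
}

#' Write per-read cascade assignments to TSV
#'
#' @param result A `cascade_result`.
#' @param path Output file.
#' @export
write_assignments_tsv <- function(result, path) {
  stopifnot(inherits(result, "cascade_result"))
  utils::write.table(result$assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
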