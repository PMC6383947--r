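READ_CLASSES <- c("mirna", "pirna_21u", "sirna_22g", "sirna_26g",
                  "sirna_other", "sense_degradation", "gfp_primary",
                  "gfp_secondary", "contaminant", "structural")

#' Read mixture for the simulator
#'
#' Target class fractions and per-class read-length rules for
#' [simulate_reads()]. The defaults emulate the composition of gonadal small
#' RNA libraries: secondary 22G siRNAs are the dominant antisense class
#' (27% of reads), with miRNAs, sense degradation fragments, other antisense
#' siRNAs, structural/contaminant carry-over, a modest piRNA fraction (the
#' 5'-independent cloning chemistry captures 5'-monophosphate piRNAs at
#' reduced efficiency), primary 26G siRNAs and a small GFP-sensor component
#' dominated by secondary over primary trigger-derived siRNAs.
#'
#' @param fractions Named numeric vector over the ten read classes;
#'   non-negative, summing to 1.
#' @param n_reads Number of reads to draw.
#' @param seed Integer seed.
#' @param lengths Named list of per-class insert length choices (nt).
#' @param adapter 3' adapter appended to every read (set to `""` for none).
#' @param ambiguous_primary If `TRUE`, trigger-derived (`gfp_primary`) reads
#'   are deliberately drawn from SNP-free windows of the recoded sequence so
#'   that they are indistinguishable from sensor-derived reads — the
#'   documented misclassification window of the SNP assay. Requires a bundle
#'   whose SNP phase leaves such windows.
#' @return A list of class `read_mixture`.
#' @export
read_mixture <- function(fractions = c(mirna = 0.15, pirna_21u = 0.05,
                                       sirna_22g = 0.27, sirna_26g = 0.05,
                                       sirna_other = 0.13,
                                       sense_degradation = 0.15,
                                       gfp_primary = 0.01,
                                       gfp_secondary = 0.04,
                                       contaminant = 0.05,
                                       structural = 0.10),
                         n_reads = 1000L, seed = 1L,
                         lengths = NULL, adapter = "TGGAATTCTCGGGTGCCAAGG",
                         ambiguous_primary = FALSE) {
  full <- stats::setNames(numeric(length(READ_CLASSES)), READ_CLASSES)
  if (length(fractions)) {
    bad <- setdiff(names(fractions), READ_CLASSES)
    if (length(bad)) .stopf("unknown read class: %s", bad[1])
    full[names(fractions)] <- fractions
  }
  if (any(full < 0) || abs(sum(full) - 1) > 1e-8)
    .stopf("class fractions must be non-negative and sum to 1 (got %.6f)",
           sum(full))
  default_lens <- list(mirna = 21:23, pirna_21u = 21L, sirna_22g = 22L,
                       sirna_26g = 26L, sirna_other = 21:30,
                       sense_degradation = 21:34, gfp_primary = 21:23,
                       gfp_secondary = 22L, contaminant = 21:34,
                       structural = 21:34)
  if (!is.null(lengths)) default_lens[names(lengths)] <- lengths
  structure(list(fractions = full, n_reads = as.integer(n_reads),
                 seed = as.integer(seed), lengths = default_lens,
                 adapter = adapter, ambiguous_primary = ambiguous_primary),
            class = "read_mixture")
}

# Does read (either strand) match any of the prepared raw references within
# k mismatches?
.scan_collides <- function(read, raws, k) {
  qs <- .seq_raw(read, query = TRUE)
  qa <- .seq_raw(reverse_complement(read), query = TRUE)
  for (rraw in raws) {
    if (length(.cpp_best_offset(qs, rraw, as.integer(k)))) return(TRUE)
    if (length(.cpp_best_offset(qa, rraw, as.integer(k)))) return(TRUE)
  }
  FALSE
}

#' Simulate small RNA reads with known ground truth
#'
#' Draws class counts from a multinomial at the mixture's target fractions
#' and generates each read from the matching reference compartment:
#' 22G/26G siRNAs are 22/26 nt, 5' G, reverse complements of coding-exon
#' subsequences; piRNAs are 21 nt, 5' T, sense over a piRNA locus; miRNAs
#' are sense hairpin fragments; secondary GFP siRNAs are 22 nt 5' G
#' antisense to the sensor; primary GFP siRNAs come from the recoded trigger
#' and span at least one SNP (unless `ambiguous_primary`). Candidate reads
#' that would also match an earlier cascade compartment (within that stage's
#' mismatch allowance) or map non-uniquely are rejection-sampled away, so
#' the truth label of every emitted read is unambiguous. The 3' adapter is
#' appended when configured.
#'
#' @param bundle A `reference_bundle`.
#' @param mixture A [read_mixture()].
#' @return Data frame with `read_id`, `sequence` (adapter included) and
#'   `truth_label`.
#' @export
simulate_reads <- function(bundle, mixture = read_mixture()) {
  stopifnot(inherits(bundle, "reference_bundle"),
            inherits(mixture, "read_mixture"))
  set.seed(mixture$seed)
  n <- mixture$n_reads
  if (n == 0L) {
    return(data.frame(read_id = character(0), sequence = character(0),
                      truth_label = character(0)))
  }
  counts <- stats::setNames(
    as.integer(stats::rmultinom(1, n, mixture$fractions)), READ_CLASSES)

  ann <- bundle$annotation
  exons <- ann[ann$kind == "gene_coding_exon", , drop = FALSE]
  pirna <- ann[ann$kind == "pirna_locus", , drop = FALSE]
  for (cl in READ_CLASSES) {
    if (counts[[cl]] == 0L) next
    ok <- switch(cl,
                 mirna = length(bundle$hairpins) > 0,
                 pirna_21u = nrow(pirna) > 0,
                 sirna_22g = , sirna_26g = , sirna_other = ,
                 sense_degradation = nrow(exons) > 0,
                 gfp_primary = nzchar(bundle$recoded_gfp),
                 gfp_secondary = nzchar(bundle$sensor_gfp),
                 contaminant = length(bundle$contaminant) > 0,
                 structural = length(bundle$structural) > 0)
    if (!ok) .stopf("mixture requests class '%s' but the bundle has no compatible feature", cl)
  }

  k2_raws <- lapply(c(bundle$contaminant, bundle$structural), .seq_raw)
  cont_raws <- lapply(bundle$contaminant, .seq_raw)
  exact_gfp <- .concat_engine(c(bundle$sensor_gfp, bundle$recoded_gfp))
  exact_hp <- if (length(bundle$hairpins)) .concat_engine(bundle$hairpins) else NULL
  genome_engine <- .concat_engine(bundle$genome)
  sensor <- unname(bundle$sensor_gfp)
  recoded <- unname(bundle$recoded_gfp)
  snps <- bundle$snp_positions
  ex <- list(chrom = exons$chrom, start = exons$start, end = exons$end,
             strand = exons$strand, n = nrow(exons))
  pir <- list(chrom = pirna$chrom, start = pirna$start, end = pirna$end,
              strand = pirna$strand, n = nrow(pirna))

  draw_sub <- function(seqs) {
    # (ref index, sequence) of one reference drawn uniformly
    i <- sample.int(length(seqs), 1L)
    list(i = i, s = seqs[[i]])
  }
  window <- function(s, len) {
    if (nchar(s) < len) return(NULL)
    p <- sample.int(nchar(s) - len + 1L, 1L)
    substr(s, p, p + len - 1L)
  }
  pick_len <- function(cl) {
    lens <- mixture$lengths[[cl]]
    if (length(lens) == 1L) lens else sample(lens, 1L)
  }

  # Checks applied before a candidate read for `cl` is accepted: it must not
  # match any stage that precedes its own compartment in the cascade, and
  # genome-derived reads must occur exactly once in the genome.
  accept <- function(read, cl) {
    if (cl == "structural") {
      if (.scan_collides(read, cont_raws, 2L)) return(FALSE)
    } else if (cl != "contaminant" && .scan_collides(read, k2_raws, 2L)) {
      return(FALSE)
    }
    if (cl %in% c("mirna", "pirna_21u", "sirna_22g", "sirna_26g",
                  "sirna_other", "sense_degradation")) {
      if (!is.null(.align_exact(read, exact_gfp))) return(FALSE)
    }
    if (cl %in% c("pirna_21u", "sirna_22g", "sirna_26g", "sirna_other",
                  "sense_degradation")) {
      if (!is.null(exact_hp) && !is.null(.align_exact(read, exact_hp)))
        return(FALSE)
      if (!.unique_in_genome(read, genome_engine)) return(FALSE)
    }
    TRUE
  }

  gen_one <- function(cl) {
    for (attempt in 1:200) {
      read <- switch(cl,
        contaminant = window(draw_sub(bundle$contaminant)$s, pick_len(cl)),
        structural = window(draw_sub(bundle$structural)$s, pick_len(cl)),
        mirna = window(draw_sub(bundle$hairpins)$s, pick_len(cl)),
        pirna_21u = {
          i <- sample.int(pir$n, 1L)
          s <- substr(bundle$genome[[pir$chrom[i]]], pir$start[i] + 1L,
                      pir$end[i])
          if (pir$strand[i] == "-") reverse_complement(s) else s
        },
        sirna_22g = .exon_antisense(bundle, ex, 22L, first_base = "G"),
        sirna_26g = .exon_antisense(bundle, ex, 26L, first_base = "G"),
        sirna_other = {
          len <- pick_len(cl)
          r <- .exon_antisense(bundle, ex, len, first_base = NULL)
          if (!is.null(r) && (len %in% c(22L, 26L)) &&
              startsWith(r, "G")) NULL else r
        },
        sense_degradation = {
          i <- sample.int(ex$n, 1L)
          len <- pick_len(cl)
          if (ex$end[i] - ex$start[i] < len) NULL else {
            p <- sample.int(ex$end[i] - ex$start[i] - len + 1L, 1L)
            s <- substr(bundle$genome[[ex$chrom[i]]], ex$start[i] + p,
                        ex$start[i] + p + len - 1L)
            # a degradation fragment is sense to the mRNA, i.e. to the gene
            if (ex$strand[i] == "-") reverse_complement(s) else s
          }
        },
        gfp_primary = .trigger_read(recoded, snps, pick_len(cl),
                                    mixture$ambiguous_primary),
        gfp_secondary = {
          len <- pick_len(cl)
          p <- sample.int(nchar(sensor) - len + 1L, 1L)
          w <- substr(sensor, p, p + len - 1L)
          r <- reverse_complement(w)
          if (startsWith(r, "G")) r else NULL
        })
      if (!is.null(read) && nzchar(read) && accept(read, cl)) {
        # strand randomization for double-stranded sources
        if (cl %in% c("contaminant", "structural") && stats::runif(1) < 0.5)
          read <- reverse_complement(read)
        return(read)
      }
    }
    .stopf("could not generate an unambiguous read of class '%s' after 200 attempts", cl)
  }

  classes <- rep(READ_CLASSES, times = counts)
  classes <- sample(classes)  # shuffle library order
  seqs <- vapply(classes, gen_one, character(1), USE.NAMES = FALSE)
  if (nzchar(mixture$adapter)) seqs <- paste0(seqs, mixture$adapter)
  data.frame(read_id = sprintf("read_%06d", seq_along(seqs)),
             sequence = seqs, truth_label = classes)
}

.unique_in_genome <- function(read, engine) {
  n_hits <- function(q) {
    h <- gregexpr(q, engine$concat, fixed = TRUE)[[1]]
    if (h[1] < 0) 0L else length(h)
  }
  n_fwd <- n_hits(read)
  rc <- reverse_complement(read)
  if (rc == read) return(n_fwd == 1L)
  (n_fwd + n_hits(rc)) == 1L
}

# Antisense read of `len` over a random coding exon; NULL on a failed draw.
# `ex` is the list-of-columns view of the exon annotation.
.exon_antisense <- function(bundle, ex, len, first_base = "G") {
  i <- sample.int(ex$n, 1L)
  if (ex$end[i] - ex$start[i] < len) return(NULL)
  p <- sample.int(ex$end[i] - ex$start[i] - len + 1L, 1L)  # 1-based in exon
  w <- substr(bundle$genome[[ex$chrom[i]]], ex$start[i] + p,
              ex$start[i] + p + len - 1L)
  read <- if (ex$strand[i] == "+") reverse_complement(w) else w
  if (!is.null(first_base) && substr(read, 1L, 1L) != first_base) return(NULL)
  read
}

# A read from the recoded trigger: spans >= 1 SNP (or deliberately none when
# `ambiguous` is set), drawn from either strand of the dsRNA. Start
# positions are sampled directly from the windows satisfying the SNP
# constraint.
.trigger_read <- function(recoded, snps, len, ambiguous = FALSE) {
  starts <- seq_len(nchar(recoded) - len + 1L)
  covered <- vapply(starts, function(p) any(snps >= p & snps <= p + len - 1L),
                    logical(1))
  ok <- if (ambiguous) starts[!covered] else starts[covered]
  if (!length(ok))
    .stopf("no %s window of %d nt exists in the recoded trigger",
           if (ambiguous) "SNP-free" else "SNP-spanning", len)
  p <- ok[sample.int(length(ok), 1L)]
  w <- substr(recoded, p, p + len - 1L)
  if (stats::runif(1) < 0.5) w else reverse_complement(w)
}

#' Write simulated reads as FASTQ (constant quality)
#'
#' @param reads Data frame from [simulate_reads()] (or any frame with
#'   `read_id` and `sequence`).
#' @param path Output FASTQ file.
#' @export
write_reads_fastq <- function(reads, path) {
  rf <- .as_read_frame(reads)
  x <- Biostrings::DNAStringSet(stats::setNames(rf$sequence, rf$read_id))
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Read a FASTQ file into the simulator's read-frame format
#'
#' @param path FASTQ file.
#' @return Data frame with `read_id` and `sequence`.
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(x), sequence = as.character(x))
}

#' Write / read ground-truth labels
#'
#' @param reads Data frame with `read_id` and `truth_label`.
#' @param path TSV file.
#' @export
write_truth_labels <- function(reads, path) {
  utils::write.table(reads[, c("read_id", "truth_label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_labels
#' @export
read_truth_labels <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
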