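#' Configuration for the synthetic reference bundle
#'
#' Describes a small reference world with the same compartments as a real
#' gonadal small RNA-seq analysis: a bacterial contaminant fragment,
#' structural RNA pools (tRNA/rRNA stand-ins), a germline GFP sensor, the
#' recoded RNAi trigger derived from it, miRNA hairpins and a toy genome with
#' annotated coding exons, piRNA loci, pseudogenes and transposons.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param n_genes,gene_len Number of protein-coding genes (one coding exon
#'   each) and the inclusive range their exon lengths are drawn from.
#' @param n_pirna piRNA loci; each locus is 21 nt and its sense sequence is
#'   forced to start with T (5' U in RNA space).
#' @param n_pseudogenes,pseudogene_len Pseudogene features and length range.
#' @param n_transposons,transposon_len Transposon features and length range.
#' @param n_hairpins,hairpin_len miRNA hairpin count and length.
#' @param sensor_len GFP sensor length (nt).
#' @param snp_spacing,snp_phase SNP placement for the recoded trigger; see
#'   [recode_sequence()].
#' @param contaminant_len Length of the contaminant reference fragment.
#' @param structural_lens Named lengths of the structural RNA pools.
#' @param min_gap Minimum distance (nt) between annotated features.
#' @return A list of class `reference_config`.
#' @export
reference_config <- function(chrom_lengths = c(chrI = 15000L, chrII = 15000L),
                             n_genes = 40L, gene_len = c(180L, 320L),
                             n_pirna = 30L,
                             n_pseudogenes = 8L, pseudogene_len = c(150L, 250L),
                             n_transposons = 8L, transposon_len = c(200L, 300L),
                             n_hairpins = 40L, hairpin_len = 90L,
                             sensor_len = 720L,
                             snp_spacing = 21L, snp_phase = 0L,
                             contaminant_len = 2000L,
                             structural_lens = c(trna_pool = 800L,
                                                 rrna_pool = 1500L),
                             min_gap = 40L) {
  cfg <- list(chrom_lengths = chrom_lengths, n_genes = n_genes,
              gene_len = gene_len, n_pirna = n_pirna,
              n_pseudogenes = n_pseudogenes, pseudogene_len = pseudogene_len,
              n_transposons = n_transposons, transposon_len = transposon_len,
              n_hairpins = n_hairpins, hairpin_len = hairpin_len,
              sensor_len = sensor_len, snp_spacing = snp_spacing,
              snp_phase = snp_phase, contaminant_len = contaminant_len,
              structural_lens = structural_lens, min_gap = min_gap)
  if (is.null(names(cfg$chrom_lengths)) || any(!nzchar(names(cfg$chrom_lengths))))
    .stopf("chromosome lengths must be named")
  structure(cfg, class = "reference_config")
}

FEATURE_KINDS <- c("gene_coding_exon", "pirna_locus", "pseudogene", "transposon")

# Place non-overlapping features on one chromosome, left to right, with at
# least min_gap between them; errors when demands exceed capacity.
.place_features <- function(chrom, chrom_len, lens, min_gap) {
  k <- length(lens)
  if (k == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  slack <- chrom_len - sum(lens) - (k + 1L) * min_gap
  if (slack < 0) {
    .stopf("feature demands exceed capacity of chromosome %s (%d nt needed, %d available)",
           chrom, sum(lens) + (k + 1L) * min_gap, chrom_len)
  }
  extra <- as.integer(floor(diff(c(0, sort(stats::runif(k)), 1)) * slack))
  lens <- as.integer(lens)
  starts <- integer(k)
  pos <- 0L
  for (i in seq_len(k)) {
    pos <- pos + min_gap + extra[i]
    starts[i] <- pos
    pos <- pos + lens[i]
  }
  data.frame(chrom = chrom, start = starts, end = starts + lens)
}

#' Build a synthetic reference bundle
#'
#' Generates all reference sequences and the genome annotation for the
#' simulated small RNA world described by a [reference_config()]. The recoded
#' GFP trigger is derived from the sensor with [recode_sequence()]; the
#' genome is patched so that each piRNA locus reads 5' T in sense
#' orientation. Deterministic for a fixed seed.
#'
#' @param config A [reference_config()].
#' @param seed Integer seed.
#' @return A list of class `reference_bundle` with elements `contaminant`,
#'   `structural`, `sensor_gfp`, `recoded_gfp`, `snp_positions`, `hairpins`,
#'   `genome` (all named character sequences) and `annotation`, a data frame
#'   with columns `feature_id`, `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `kind`.
#' @export
build_reference <- function(config = reference_config(), seed = 1L) {
  stopifnot(inherits(config, "reference_config"))
  set.seed(seed)
  cfg <- config

  contaminant <- c(ecoli_fragment = .random_seq(cfg$contaminant_len))
  structural <- vapply(cfg$structural_lens, .random_seq, character(1))
  sensor <- .random_seq(cfg$sensor_len)
  rec <- recode_sequence(sensor, cfg$snp_spacing, cfg$snp_phase)
  hairpins <- vapply(seq_len(cfg$n_hairpins), function(i) .random_seq(cfg$hairpin_len),
                     character(1))
  names(hairpins) <- sprintf("mir-%03d", seq_along(hairpins))

  genome <- vapply(cfg$chrom_lengths, .random_seq, character(1))

  draw_len <- function(n, rng) {
    if (n == 0L) return(integer(0))
    sample(seq.int(rng[1], rng[2]), n, replace = TRUE)
  }
  kinds <- rep(FEATURE_KINDS,
               times = c(cfg$n_genes, cfg$n_pirna, cfg$n_pseudogenes,
                         cfg$n_transposons))
  lens <- c(draw_len(cfg$n_genes, cfg$gene_len),
            rep(21L, cfg$n_pirna),
            draw_len(cfg$n_pseudogenes, cfg$pseudogene_len),
            draw_len(cfg$n_transposons, cfg$transposon_len))
  ord <- sample.int(length(kinds))   # interleave kinds along chromosomes
  kinds <- kinds[ord]; lens <- lens[ord]
  chrom_of <- sample(names(genome), length(kinds), replace = TRUE,
                     prob = cfg$chrom_lengths / sum(cfg$chrom_lengths))

  ann <- do.call(rbind, lapply(names(genome), function(ch) {
    sel <- chrom_of == ch
    placed <- .place_features(ch, cfg$chrom_lengths[[ch]], lens[sel],
                              cfg$min_gap)
    placed$kind <- kinds[sel]
    placed
  }))
  ann <- ann[order(match(ann$chrom, names(genome)), ann$start), , drop = FALSE]
  ann$strand <- sample(c("+", "-"), nrow(ann), replace = TRUE)
  counters <- c(gene_coding_exon = 0L, pirna_locus = 0L, pseudogene = 0L,
                transposon = 0L)
  prefix <- c(gene_coding_exon = "g", pirna_locus = "pir",
              pseudogene = "pseu", transposon = "tn")
  ids <- character(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    counters[ann$kind[i]] <- counters[ann$kind[i]] + 1L
    ids[i] <- sprintf("%s%03d", prefix[ann$kind[i]], counters[ann$kind[i]])
  }
  ann$gene_id <- ids
  ann$feature_id <- ifelse(ann$kind == "gene_coding_exon",
                           paste0(ids, "_e1"), ids)
  ann <- ann[, c("feature_id", "gene_id", "chrom", "start", "end", "strand",
                 "kind")]
  rownames(ann) <- NULL

  # Force piRNA loci to read 5' T in sense orientation.
  for (i in which(ann$kind == "pirna_locus")) {
    ch <- ann$chrom[i]
    if (ann$strand[i] == "+") {
      substr(genome[[ch]], ann$start[i] + 1L, ann$start[i] + 1L) <- "T"
    } else {
      substr(genome[[ch]], ann$end[i], ann$end[i]) <- "A"
    }
  }

  bundle <- structure(list(contaminant = contaminant,
                           structural = structural,
                           sensor_gfp = c(sensor_gfp = sensor),
                           recoded_gfp = c(recoded_gfp = rec$recoded),
                           snp_positions = rec$snp_positions,
                           snp_spacing = cfg$snp_spacing,
                           snp_phase = cfg$snp_phase,
                           hairpins = hairpins,
                           genome = genome,
                           annotation = ann,
                           config = cfg, seed = seed),
                      class = "reference_bundle")
  .validate_bundle(bundle)
  bundle
}

.validate_bundle <- function(b) {
  stopifnot(nchar(b$sensor_gfp) == nchar(b$recoded_gfp))
  s <- strsplit(unname(b$sensor_gfp), "")[[1]]
  r <- strsplit(unname(b$recoded_gfp), "")[[1]]
  diffs <- which(s != r)
  if (!identical(diffs, as.integer(b$snp_positions)))
    .stopf("sensor/recoded sequences do not differ exactly at snp_positions")
  if (length(diffs) > 1 && any(diff(diffs) != b$snp_spacing))
    .stopf("SNP positions are not evenly spaced")
  ann <- b$annotation
  if (nrow(ann)) {
    stopifnot(all(ann$start < ann$end), all(ann$strand %in% c("+", "-")),
              all(ann$kind %in% FEATURE_KINDS))
    lens <- nchar(b$genome)[ann$chrom]
    if (any(ann$end > lens)) .stopf("feature interval exceeds chromosome bounds")
  }
  invisible(b)
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("Synthetic small RNA reference bundle\n")
  cat(sprintf("  genome: %d chromosome(s), %d nt total\n",
              length(x$genome), sum(nchar(x$genome))))
  tab <- table(factor(x$annotation$kind, levels = FEATURE_KINDS))
  cat(sprintf("  annotation: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  sensor/recoded GFP: %d nt, %d SNPs (spacing %d, phase %d)\n",
              nchar(x$sensor_gfp), length(x$snp_positions), x$snp_spacing,
              x$snp_phase))
  cat(sprintf("  hairpins: %d; structural pools: %d; contaminant: %d nt\n",
              length(x$hairpins), length(x$structural),
              sum(nchar(x$contaminant))))
  invisible(x)
}

# Sense sequence of an annotated feature.
.feature_seq <- function(bundle, row) {
  s <- substr(bundle$genome[[row$chrom]], row$start + 1L, row$end)
  if (row$strand == "-") s <- reverse_complement(s)
  s
}

.annotation_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = annotation$strand,
    ID = annotation$feature_id,
    gene_id = annotation$gene_id,
    type = annotation$kind)
}

#' Write a reference bundle to disk
#'
#' Sequences go to FASTA files (one per compartment) and the annotation to a
#' GFF3 file (1-based inclusive coordinates, converted from the internal
#' 0-based half-open representation).
#'
#' @param bundle A `reference_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_reference_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "reference_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wfa <- function(seqs, file) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                                file.path(dir, file))
  }
  wfa(bundle$contaminant, "contaminant.fa")
  wfa(bundle$structural, "structural.fa")
  wfa(bundle$sensor_gfp, "sensor_gfp.fa")
  wfa(bundle$recoded_gfp, "recoded_gfp.fa")
  wfa(bundle$hairpins, "hairpins.fa")
  wfa(bundle$genome, "genome.fa")
  rtracklayer::export(.annotation_granges(bundle$annotation),
                      file.path(dir, "annotation.gff3"), format = "gff3")
  invisible(dir)
}

#' Read a reference bundle written by [write_reference_bundle()]
#'
#' SNP positions are recomputed by diffing the sensor against the recoded
#' trigger, so the FASTA/GFF3 files are the only source of truth.
#'
#' @param dir Directory containing the bundle files.
#' @return A `reference_bundle`.
#' @export
read_reference_bundle <- function(dir) {
  rfa <- function(file) {
    x <- Biostrings::readDNAStringSet(file.path(dir, file))
    stats::setNames(as.character(x), names(x))
  }
  sensor <- rfa("sensor_gfp.fa")
  recoded <- rfa("recoded_gfp.fa")
  s <- strsplit(unname(sensor), "")[[1]]
  r <- strsplit(unname(recoded), "")[[1]]
  snps <- which(s != r)
  spacing <- if (length(snps) > 1) unique(diff(snps)) else integer(0)
  if (length(spacing) > 1) .stopf("unevenly spaced SNPs in stored bundle")
  ann <- read_annotation_gff3(file.path(dir, "annotation.gff3"))
  structure(list(contaminant = rfa("contaminant.fa"),
                 structural = rfa("structural.fa"),
                 sensor_gfp = sensor, recoded_gfp = recoded,
                 snp_positions = snps,
                 snp_spacing = if (length(spacing)) spacing else NA_integer_,
                 snp_phase = if (length(snps)) snps[1] - (if (length(spacing)) spacing else 0L) else 0L,
                 hairpins = rfa("hairpins.fa"), genome = rfa("genome.fa"),
                 annotation = ann, config = NULL, seed = NA_integer_),
            class = "reference_bundle")
}

#' Read a feature annotation from GFF3
#'
#' @param path GFF3 file with `ID` and `gene_id` attributes and feature kinds
#'   in the `type` column.
#' @return Annotation data frame in the internal 0-based half-open convention.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(feature_id = as.character(gr$ID),
             gene_id = as.character(gr$gene_id),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             kind = as.character(gr$type))
}
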