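SMALL_RNA_CLASSES <- c("mirna", "pirna", "sirna_22g", "sirna_26g",
                       "sirna_other_antisense", "sense_read", "gfp_primary",
                       "gfp_secondary", "unclassified")

# GRanges of the genome-compartment assignments (read strand on the genome:
# a sense hit lies on the + strand, an antisense hit on the - strand).
.assignment_granges <- function(assignments) {
  GenomicRanges::GRanges(
    seqnames = assignments$reference_id,
    ranges = IRanges::IRanges(start = assignments$offset + 1L,
                              width = assignments$length),
    strand = ifelse(assignments$strand == "sense", "+", "-"))
}

#' Classify reads into small RNA classes
#'
#' Pure function of the cascade compartment, read length, first (5')
#' nucleotide and orientation relative to the annotation: the miRNA-hairpin
#' compartment maps to `mirna`, the sensor compartment to `gfp_secondary`
#' and the recoded-trigger compartment to `gfp_primary`. Genome-compartment
#' reads overlapping a piRNA locus in sense orientation are `pirna`; reads
#' antisense to a coding exon are `sirna_22g` (22 nt, 5' G), `sirna_26g`
#' (26 nt, 5' G) or `sirna_other_antisense`; reads sense to a coding exon
#' are `sense_read`; everything else is `unclassified`.
#'
#' @param assignments Assignment table from [run_cascade()] (the
#'   `assignments` element, or a compatible data frame).
#' @param annotation Annotation data frame (see [build_reference()]).
#' @return Factor of classes, one per assignment row.
#' @export
classify_small_rna <- function(assignments, annotation) {
  stopifnot(is.data.frame(assignments),
            all(c("compartment", "sequence", "length", "strand") %in%
                  names(assignments)))
  n <- nrow(assignments)
  cls <- rep("unclassified", n)
  cls[assignments$compartment == "mirna"] <- "mirna"
  cls[assignments$compartment == "sensor_gfp"] <- "gfp_secondary"
  cls[assignments$compartment == "recoded_gfp"] <- "gfp_primary"

  gi <- which(assignments$compartment == "genome")
  if (length(gi)) {
    ga <- assignments[gi, , drop = FALSE]
    reads <- .assignment_granges(ga)
    feats <- .annotation_granges(annotation)
    ov <- GenomicRanges::findOverlaps(reads, feats, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    same <- as.character(GenomicRanges::strand(reads))[q] ==
      as.character(GenomicRanges::strand(feats))[s]
    kind <- annotation$kind[s]
    first <- substr(ga$sequence, 1L, 1L)

    pir <- unique(q[kind == "pirna_locus" & same])
    anti <- unique(q[kind == "gene_coding_exon" & !same])
    sens <- unique(q[kind == "gene_coding_exon" & same])

    sub <- rep("unclassified", nrow(ga))
    sub[sens] <- "sense_read"
    sub[anti] <- ifelse(ga$length[anti] == 22L & first[anti] == "G",
                        "sirna_22g",
                 ifelse(ga$length[anti] == 26L & first[anti] == "G",
                        "sirna_26g", "sirna_other_antisense"))
    sub[pir] <- "pirna"
    cls[gi] <- sub
  }
  factor(cls, levels = SMALL_RNA_CLASSES)
}

#' Strand-separated per-gene read counting
#'
#' Counts genome-compartment reads against the coding-exon union of each
#' gene. A read increments a gene iff its genomic interval overlaps one of
#' the gene's coding exons by at least 1 bp and its strand relation to the
#' gene matches the requested orientation; reads overlapping exons of more
#' than one gene are dropped as ambiguous (union-mode analog).
#'
#' @param assignments A single assignment table, a `cascade_result`, or a
#'   named list of either (one element per library/sample).
#' @param annotation Annotation data frame.
#' @param orientation `"antisense"` (endo-siRNA convention) or `"sense"`.
#' @return Integer matrix (genes x samples) of class `count_matrix` with
#'   attributes `orientation` and `ambiguous` (dropped multi-gene reads per
#'   sample). Genes without coding exons are absent.
#' @export
count_by_feature <- function(assignments, annotation,
                             orientation = c("antisense", "sense")) {
  orientation <- match.arg(orientation)
  if (inherits(assignments, "cascade_result"))
    assignments <- assignments$assignments
  if (is.data.frame(assignments)) assignments <- list(sample = assignments)
  assignments <- lapply(assignments, function(a) {
    if (inherits(a, "cascade_result")) a$assignments else a
  })
  if (is.null(names(assignments)))
    names(assignments) <- sprintf("sample_%d", seq_along(assignments))

  exons <- annotation[annotation$kind == "gene_coding_exon", , drop = FALSE]
  genes <- unique(exons$gene_id)
  feats <- .annotation_granges(exons)
  counts <- matrix(0L, nrow = length(genes), ncol = length(assignments),
                   dimnames = list(genes, names(assignments)))
  ambiguous <- stats::setNames(integer(length(assignments)),
                               names(assignments))
  for (j in seq_along(assignments)) {
    a <- assignments[[j]]
    a <- a[a$compartment == "genome", , drop = FALSE]
    if (!nrow(a)) next
    reads <- .assignment_granges(a)
    ov <- GenomicRanges::findOverlaps(reads, feats, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    same <- as.character(GenomicRanges::strand(reads))[q] ==
      as.character(GenomicRanges::strand(feats))[s]
    want <- if (orientation == "sense") same else !same
    gene_of <- exons$gene_id[s]
    # ambiguity is judged on all overlapped genes, before the orientation cut
    genes_per_read <- tapply(gene_of, q, function(g) length(unique(g)))
    ambig_reads <- as.integer(names(genes_per_read)[genes_per_read > 1])
    ambiguous[j] <- length(ambig_reads)
    keep <- want & !(q %in% ambig_reads)
    if (any(keep)) {
      # one increment per read even when it overlaps two exons of one gene
      tab <- table(factor(tapply(gene_of[keep], q[keep], function(g) g[1]),
                          levels = genes))
      counts[, j] <- as.integer(tab)
    }
  }
  structure(counts, orientation = orientation, ambiguous = ambiguous,
            class = c("count_matrix", class(counts)))
}

#' Keep features with at least a minimum mean normalized count
#'
#' @param matrix Numeric matrix of normalized counts (features x samples).
#' @param threshold Minimum mean; the boundary is kept (`>=`).
#' @param groups Optional factor over columns; a feature is retained when
#'   its mean reaches the threshold in at least one group.
#' @return Character vector of retained feature ids.
#' @export
filter_min_mean <- function(matrix, threshold = 5, groups = NULL) {
  stopifnot(is.matrix(matrix))
  if (is.null(groups)) {
    keep <- rowMeans(matrix) >= threshold
  } else {
    groups <- as.factor(groups)
    stopifnot(length(groups) == ncol(matrix))
    gm <- vapply(levels(groups), function(g) {
      rowMeans(matrix[, groups == g, drop = FALSE])
    }, numeric(nrow(matrix)))
    keep <- apply(gm >= threshold, 1L, any)
  }
  rownames(matrix)[keep]
}

#' Overlap between two detected-feature sets
#'
#' @param set_a,set_b Character vectors (duplicates ignored).
#' @return Named integer vector `only_a`, `shared`, `only_b`.
#' @export
overlap_sets <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  c(only_a = length(setdiff(a, b)), shared = length(intersect(a, b)),
    only_b = length(setdiff(b, a)))
}

#' Write / read a count matrix as TSV (feature ids in the first column)
#'
#' @param matrix Count matrix.
#' @param path TSV file.
#' @export
write_count_matrix <- function(matrix, path) {
  df <- data.frame(feature_id = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
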