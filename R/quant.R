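#' Construct an aligned-read table
#'
#' Reads are strand-aware 1-based closed intervals tagged with the cell
#' they came from. `chrom` is either a genome chromosome present in the
#' annotation layout or a spike-in identifier (recognised by prefix,
#' default `"ERCC-"`).
#'
#' @param chrom,strand,start,end,cell_id vectors of equal length.
#' @return data.frame of class `sc3_reads`.
#' @export
aligned_reads <- function(chrom, strand, start, end, cell_id) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start > end)) stop_user("aligned_reads: start > end")
  if (!all(strand %in% c("+", "-"))) stop_user("aligned_reads: strand must be + or -")
  structure(data.frame(chrom = as.character(chrom), strand = strand,
                       start = start, end = end,
                       cell_id = as.character(cell_id),
                       stringsAsFactors = FALSE),
            class = c("sc3_reads", "data.frame"))
}

#' Read aligned reads from a BED6 file
#'
#' BED columns: chrom, start (0-based half-open), end, name (used as the
#' cell id), score, strand. Coordinates are converted to 1-based closed.
#'
#' @param path BED6 file path.
#' @return data.frame of class `sc3_reads`.
#' @export
read_bed_reads <- function(path) {
  if (!file.exists(path)) stop_user("read file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 6L) stop_user("BED6 file needs 6 columns: ", path)
  aligned_reads(tab[[1L]], tab[[6L]], tab[[2L]] + 1L, tab[[3L]], tab[[4L]])
}

#' Write aligned reads as BED6
#' @param reads an `sc3_reads` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_reads <- function(reads, path) {
  bed <- data.frame(reads$chrom, reads$start - 1L, reads$end,
                    reads$cell_id, 0L, reads$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assign reads to genes
#'
#' The library chemistry is strand-preserving (read strand equals
#' transcript strand), so a read is assigned to a gene only when at least
#' one base of the read intersects the gene's (extended) exonic span on
#' the same strand. Reads hitting more than one such gene are `AMBIGUOUS`,
#' reads hitting none are `UNASSIGNED`, and reads on spike-in
#' chromosomes are `SPIKE_IN`. Reads on chromosomes that are neither in
#' the layout nor spike-ins are an error.
#'
#' @param reads an `sc3_reads` table (or anything [aligned_reads()] accepts
#'   as a data.frame with those columns).
#' @param ann the extended `sc3_annotation`.
#' @param spike_prefix chromosome-name prefix marking spike-ins.
#' @param use_gene_span if `TRUE`, overlap the whole gene span instead of
#'   the exonic span.
#' @return character vector, per read: a `gene_id`, `"AMBIGUOUS"`,
#'   `"UNASSIGNED"` or `"SPIKE_IN"`.
#' @export
assign_reads <- function(reads, ann, spike_prefix = "ERCC-",
                         use_gene_span = FALSE) {
  n <- nrow(reads)
  out <- rep("UNASSIGNED", n)
  spike <- startsWith(reads$chrom, spike_prefix)
  out[spike] <- "SPIKE_IN"
  unknown <- !spike & !(reads$chrom %in% ann$layout$chrom)
  if (any(unknown)) {
    stop_user("read on unknown chromosome: ", reads$chrom[unknown][1L])
  }
  gi <- which(!spike)
  if (!length(gi) || n_genes(ann) == 0L) return(out)

  g <- ann$genes
  if (use_gene_span) {
    ex_chrom <- g$chrom; ex_strand <- g$strand
    ex_start <- g$start; ex_end <- g$end
    ex_gene <- seq_len(nrow(g))
  } else {
    nex <- vapply(g$exons, nrow, 0L)
    ex_gene <- rep(seq_len(nrow(g)), nex)
    exm <- do.call(rbind, g$exons)
    ex_chrom <- g$chrom[ex_gene]; ex_strand <- g$strand[ex_gene]
    ex_start <- exm[, 1L]; ex_end <- exm[, 2L]
  }
  subj <- GenomicRanges::GRanges(ex_chrom, IRanges::IRanges(ex_start, ex_end),
                                 strand = ex_strand)
  qry <- GenomicRanges::GRanges(reads$chrom[gi],
                                IRanges::IRanges(reads$start[gi], reads$end[gi]),
                                strand = reads$strand[gi])
  suppressWarnings({
    hits <- GenomicRanges::findOverlaps(qry, subj, ignore.strand = FALSE)
  })
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    gene_hit <- ex_gene[S4Vectors::subjectHits(hits)]
    per_read <- lapply(split(gene_hit, qh), unique)
    hit_reads <- as.integer(names(per_read))
    n_hit <- lengths(per_read)
    one <- n_hit == 1L
    out[gi[hit_reads[one]]] <- g$gene_id[unlist(per_read[one])]
    out[gi[hit_reads[!one]]] <- "AMBIGUOUS"
  }
  out
}

#' Assign a single read
#' @param r one-row `sc3_reads` table (or data.frame).
#' @inheritParams assign_reads
#' @return length-1 character: gene id or category.
#' @export
assign_read <- function(r, ann, spike_prefix = "ERCC-",
                        use_gene_span = FALSE) {
  assign_reads(r[1L, , drop = FALSE], ann, spike_prefix, use_gene_span)
}

#' Count reads per gene and cell
#'
#' Builds the integer gene-by-cell count matrix together with the per-cell
#' read-category tallies (`assigned`, `ambiguous`, `unassigned`,
#' `spike_in`). The categories are mutually exclusive and complete:
#' their sum equals the number of input reads per cell, and `assigned`
#' equals the column sum of the count matrix.
#'
#' @inheritParams assign_reads
#' @param cells optional character vector fixing the cell (column) order;
#'   defaults to sorted unique cell ids in `reads`.
#' @return Object of class `sc3_counts`: list with `counts` (matrix) and
#'   `tallies` (data.frame).
#' @export
count_cells <- function(reads, ann, spike_prefix = "ERCC-",
                        use_gene_span = FALSE, cells = NULL) {
  cells <- cells %||% sort(unique(reads$cell_id))
  gene_ids <- ann$genes$gene_id
  counts <- matrix(0L, nrow = length(gene_ids), ncol = length(cells),
                   dimnames = list(gene_ids, cells))
  asn <- if (nrow(reads)) {
    assign_reads(reads, ann, spike_prefix, use_gene_span)
  } else {
    character(0)
  }
  cell <- factor(reads$cell_id, levels = cells)
  is_gene <- !(asn %in% c("AMBIGUOUS", "UNASSIGNED", "SPIKE_IN"))
  if (any(is_gene)) {
    tab <- table(factor(asn[is_gene], levels = gene_ids), cell[is_gene])
    counts <- counts + unclass(tab)
  }
  tallies <- data.frame(
    cell_id = cells,
    assigned = as.integer(colSums(counts)),
    ambiguous = as.integer(table(cell[asn == "AMBIGUOUS"])),
    unassigned = as.integer(table(cell[asn == "UNASSIGNED"])),
    spike_in = as.integer(table(cell[asn == "SPIKE_IN"])),
    stringsAsFactors = FALSE
  )
  structure(list(counts = counts, tallies = tallies), class = "sc3_counts")
}

#' @export
print.sc3_counts <- function(x, ...) {
  cat("sc3_counts:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      sum(x$tallies$assigned), "assigned reads\n")
  invisible(x)
}

#' Convert counts to reads per million (RPM)
#'
#' `rpm[g, c] = counts[g, c] / denominator_c * 1e6`. With the default
#' denominator (reads assigned to genes) every column with at least one
#' assigned read sums exactly to 1e6; cells with zero assigned reads
#' yield an all-zero column and a warning. `denominator =
#' "genome_mapped"` uses assigned + ambiguous + unassigned instead (the
#' total reads mapped to the genome), in which case columns sum to less
#' than 1e6 whenever reads were ambiguous or unassigned.
#'
#' @param m an `sc3_counts` object.
#' @param denominator `"assigned"` (default) or `"genome_mapped"`.
#' @return numeric matrix of RPM values (genes x cells).
#' @export
to_rpm <- function(m, denominator = c("assigned", "genome_mapped")) {
  denominator <- match.arg(denominator)
  denom <- if (denominator == "assigned") {
    m$tallies$assigned
  } else {
    m$tallies$assigned + m$tallies$ambiguous + m$tallies$unassigned
  }
  zero <- denom == 0
  if (any(zero)) {
    warning("cell(s) with zero ", denominator, " reads: ",
            paste(m$tallies$cell_id[zero], collapse = ", "), call. = FALSE)
    denom[zero] <- 1
  }
  sweep(m$counts, 2L, denom, "/") * 1e6
}

#' log2(RPM + 1) transform
#' @param rpm an RPM matrix from [to_rpm()], or an `sc3_counts` object
#'   (converted with the default denominator first).
#' @return numeric matrix of log2(RPM+1) values.
#' @export
log2_rpm1 <- function(rpm) {
  if (inherits(rpm, "sc3_counts")) rpm <- to_rpm(rpm)
  log2(rpm + 1)
}

#' Expressed genes
#'
#' A gene is called expressed when its log2(RPM+1) value exceeds
#' `threshold` (strictly) in at least `min_cells` cells. The default,
#' > 4 in at least one cell, is the expressed-gene definition used for
#' clustering and the expression-percentile QC.
#'
#' @param logm log2(RPM+1) matrix (genes x cells).
#' @param threshold strict lower bound on log2(RPM+1).
#' @param min_cells minimum number of cells exceeding the bound.
#' @return character vector of expressed gene ids.
#' @export
expressed_genes <- function(logm, threshold = 4, min_cells = 1) {
  hits <- rowSums(logm > threshold)
  rownames(logm)[hits >= min_cells]
}

#' Write a genes-x-cells matrix as TSV
#' @param m numeric matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes-x-cells matrix from TSV
#' @param path TSV written by [write_matrix_tsv()].
#' @return numeric matrix with gene ids as rownames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop_user("matrix file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
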