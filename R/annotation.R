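#' Genome layout: chromosome names and lengths
#'
#' A minimal container describing the coordinate space an annotation lives
#' in. Chromosome names must be unique and lengths positive; all gene and
#' read coordinates are validated against it.
#'
#' @param chrom character vector of chromosome names.
#' @param length integer vector of chromosome lengths (base pairs, >= 1).
#' @return An object of class `sc3_layout`: a data.frame with columns
#'   `chrom` and `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length)) {
    stop_user("genome_layout: 'chrom' and 'length' differ in length")
  }
  if (anyDuplicated(chrom)) {
    stop_user("genome_layout: duplicated chromosome name: ",
              chrom[duplicated(chrom)][1L])
  }
  if (any(is.na(length)) || any(length < 1) || any(length != floor(length))) {
    stop_user("genome_layout: chromosome lengths must be positive integers")
  }
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("sc3_layout", "data.frame"))
}

#' Read a chromosome-length table
#'
#' Two-column TSV (name, length), no header required; a header line is
#' detected and skipped when the second field is non-numeric.
#'
#' @param path file path.
#' @return A [genome_layout()] object.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop_user("chromosome-size file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2L) stop_user("chromosome-size file needs 2 columns: ", path)
  if (is.na(suppressWarnings(as.numeric(tab[1L, 2L])))) tab <- tab[-1L, , drop = FALSE]
  genome_layout(tab[[1L]], as.numeric(tab[[2L]]))
}

#' Write a chromosome-length table
#' @param layout a [genome_layout()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(layout, path) {
  utils::write.table(layout, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

BIOTYPES <- c("protein_coding", "pseudogene", "tRNA", "ncRNA", "other")

#' Construct a single gene model
#'
#' Strand-dependent termini are derived, not supplied: the transcription
#' start site (TSS) is `start` on `+` and `end` on `-`; the transcription
#' termination site (TTS) is the opposite terminus. Exons must be sorted,
#' non-overlapping and contained in `[start, end]`.
#'
#' @param gene_id,gene_name identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive span.
#' @param exons two-column matrix (start, end) of exon intervals; defaults
#'   to the single-exon full span.
#' @param biotype one of `r paste(BIOTYPES, collapse = ", ")`.
#' @return One-row data.frame with an `exons` list-column.
#' @export
gene_model <- function(gene_id, gene_name = gene_id, chrom, strand,
                       start, end, exons = NULL,
                       biotype = "protein_coding") {
  strand <- match.arg(strand, c("+", "-"))
  biotype <- match.arg(biotype, BIOTYPES)
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start > end || start < 1) {
    stop_user("gene_model(", gene_id, "): invalid span [", start, ", ", end, "]")
  }
  if (is.null(exons)) exons <- cbind(start, end)
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 1L] > exons[, 2L]) ||
      exons[1L, 1L] < start || exons[nrow(exons), 2L] > end) {
    stop_user("gene_model(", gene_id, "): exons outside gene span")
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
    stop_user("gene_model(", gene_id, "): overlapping exons")
  }
  out <- data.frame(gene_id = as.character(gene_id),
                    gene_name = as.character(gene_name),
                    chrom = as.character(chrom), strand = strand,
                    start = start, end = end, biotype = biotype,
                    tss = if (strand == "+") start else end,
                    tts = if (strand == "+") end else start,
                    stringsAsFactors = FALSE)
  out$exons <- list(exons)
  out
}

#' Build an annotation set from gene models
#'
#' An annotation set couples a table of gene models to a [genome_layout()]
#' and maintains per-chromosome, per-strand indices sorted by start
#' coordinate. Every gene must lie on a chromosome of the layout and within
#' its bounds.
#'
#' @param genes data.frame of gene models (rows as produced by
#'   [gene_model()], possibly `rbind`-ed).
#' @param layout a [genome_layout()].
#' @return Object of class `sc3_annotation`: list with elements `layout`,
#'   `genes` and `index`.
#' @export
annotation_set <- function(genes, layout) {
  stopifnot(inherits(layout, "sc3_layout"))
  if (is.null(genes) || nrow(genes) == 0L) {
    genes <- gene_model("x", chrom = layout$chrom[1L] %||% "chr1",
                        strand = "+", start = 1, end = 1)[0L, ]
  }
  unknown <- setdiff(unique(genes$chrom), layout$chrom)
  if (length(unknown)) {
    stop_user("gene on unknown chromosome: ", unknown[1L])
  }
  if (anyDuplicated(genes$gene_id)) {
    stop_user("duplicated gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1L])
  }
  clen <- stats::setNames(layout$length, layout$chrom)
  bad <- genes$end > clen[genes$chrom] | genes$start < 1
  if (any(bad)) {
    stop_user("gene outside chromosome bounds: ", genes$gene_id[bad][1L])
  }
  rownames(genes) <- NULL
  key <- paste(genes$chrom, genes$strand)
  idx <- split(seq_len(nrow(genes)), key)
  idx <- lapply(idx, function(i) i[order(genes$start[i])])
  structure(list(layout = layout, genes = genes, index = idx),
            class = "sc3_annotation")
}

#' @export
print.sc3_annotation <- function(x, ...) {
  cat("sc3_annotation:", nrow(x$genes), "genes on",
      nrow(x$layout), "chromosomes\n")
  if (nrow(x$genes)) {
    cat("  biotypes:",
        paste(names(table(x$genes$biotype)), table(x$genes$biotype),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of genes in an annotation set
#' @param ann an `sc3_annotation`.
#' @return integer count.
#' @export
n_genes <- function(ann) nrow(ann$genes)

#' Remove genes of unwanted biotypes
#'
#' Drops every gene whose biotype is in `removed_biotypes` (by default
#' pseudogenes, tRNAs and ncRNAs, the classes the annotation rewrite
#' discards). The input is not modified.
#'
#' @param ann an `sc3_annotation`.
#' @param cfg an [extension_config()]; only `removed_biotypes` is used.
#' @return A new `sc3_annotation`.
#' @export
filter_biotypes <- function(ann, cfg = extension_config()) {
  keep <- !(ann$genes$biotype %in% cfg$removed_biotypes)
  annotation_set(ann$genes[keep, , drop = FALSE], ann$layout)
}

#' Collapse genes sharing an identical TTS
#'
#' Genes on the same chromosome and strand whose transcription termination
#' sites coincide would double-count the same 3'-end tag pile-up, so all
#' but one are removed. The survivor is the gene with the longest span;
#' ties break to the lexicographically smallest `gene_id`, making the
#' result independent of input order.
#'
#' @param ann an `sc3_annotation`.
#' @return A new `sc3_annotation` with one gene per (chrom, strand, TTS).
#' @export
dedupe_identical_tts <- function(ann) {
  g <- ann$genes
  if (nrow(g) < 2L) return(ann)
  key <- paste(g$chrom, g$strand, g$tts)
  span <- g$end - g$start + 1
  ord <- order(key, -span, g$gene_id)
  keep_sorted <- !duplicated(key[ord])
  keep <- sort(ord[keep_sorted])
  annotation_set(g[keep, , drop = FALSE], ann$layout)
}

#' Rename genes via a two-column mapping table
#'
#' Applies an old-name to new-name mapping (for example, matching genome
#' assembly gene symbols to their human counterparts, supplied as a
#' precomputed table). Unmatched names are left untouched; unused mapping
#' keys trigger a warning.
#'
#' @param ann an `sc3_annotation`.
#' @param mapping data.frame whose first two columns are old and new name.
#' @return A new `sc3_annotation` with `gene_name` rewritten.
#' @export
apply_name_mapping <- function(ann, mapping) {
  if (is.null(mapping) || nrow(mapping) == 0L) return(ann)
  old <- as.character(mapping[[1L]]); new <- as.character(mapping[[2L]])
  if (anyDuplicated(old)) {
    stop_user("duplicate mapping key: ", old[duplicated(old)][1L])
  }
  g <- ann$genes
  hit <- match(g$gene_name, old)
  g$gene_name[!is.na(hit)] <- new[hit[!is.na(hit)]]
  unused <- setdiff(old, ann$genes$gene_name)
  if (length(unused)) {
    warning(length(unused), " mapping key(s) not present in annotation, e.g. ",
            unused[1L], call. = FALSE)
  }
  annotation_set(g, ann$layout)
}

#' Read a two-column name-mapping table
#' @param path TSV path (old name, new name; optional header).
#' @return data.frame with columns `old` and `new`.
#' @export
read_name_mapping <- function(path) {
  if (!file.exists(path)) stop_user("name-mapping file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_user("name-mapping file needs 2 columns: ", path)
  stats::setNames(tab[, 1:2], c("old", "new"))
}
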