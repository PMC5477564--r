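#' Read a GFF3 transcript definition file into an annotation set
#'
#' Parses `gene`, `mRNA`/`transcript` and `exon` features. One gene model
#' is built per gene row; exons of all transcripts of a gene are unioned
#' into a sorted, non-overlapping exon set. A gene carrying the attribute
#' `pseudo=True` (or a `pseudogene` feature type, or
#' `gene_biotype=pseudogene`) is typed as a pseudogene; `gene_biotype`
#' values `tRNA` and `ncRNA` are honoured likewise, anything else
#' unrecognised becomes `other` and absent means `protein_coding`.
#' Coordinates are preserved verbatim (1-based, closed).
#'
#' @param path GFF3 file path.
#' @param layout a [genome_layout()]; genes on chromosomes absent from it
#'   are an error naming the chromosome.
#' @return An `sc3_annotation`.
#' @export
read_gff3 <- function(path, layout) {
  if (!file.exists(path)) stop_user("GFF3 file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1L]]
    stop_user("malformed GFF3 line ", bad, " in ", path,
              " (expected 9 tab-separated fields, got ", nf[nf != 9L][1L], ")")
  }
  if (!any(body)) {
    return(annotation_set(NULL, layout))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop_user("GFF3 parse error in ", path, ": ",
                                  conditionMessage(e))
  )
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)
  df$ID <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_
  parents <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) if (length(p)) as.character(p)[1L] else NA_character_, "")
  } else {
    rep(NA_character_, nrow(df))
  }

  is_gene <- df$type %in% c("gene", "pseudogene")
  is_exon <- df$type == "exon"
  is_tx <- !is_gene & !is_exon & !is.na(parents) & parents %in% df$ID[is_gene]

  tx2gene <- stats::setNames(parents[is_tx], df$ID[is_tx])
  exon_owner <- parents[is_exon]
  ## exons may point at a transcript or directly at a gene
  via_tx <- exon_owner %in% names(tx2gene)
  exon_gene <- ifelse(via_tx, tx2gene[exon_owner], exon_owner)

  gidx <- which(is_gene)
  models <- vector("list", length(gidx))
  for (k in seq_along(gidx)) {
    i <- gidx[k]
    gid <- df$ID[i] %||% NA_character_
    if (is.na(gid)) stop_user("gene row without ID attribute in ", path)
    biotype <- "protein_coding"
    bt <- if ("gene_biotype" %in% names(df)) as.character(df$gene_biotype[i]) else NA
    if (!is.na(bt)) biotype <- if (bt %in% BIOTYPES) bt else "other"
    if (df$type[i] == "pseudogene") biotype <- "pseudogene"
    ps <- if ("pseudo" %in% names(df)) as.character(df$pseudo[i]) else NA
    if (!is.na(ps) && tolower(ps) == "true") biotype <- "pseudogene"
    nm <- if ("Name" %in% names(df)) as.character(df$Name[i]) else NA
    ex_rows <- which(is_exon)[which(exon_gene[seq_len(sum(is_exon))] == gid)]
    exons <- NULL
    if (length(ex_rows)) {
      red <- IRanges::reduce(IRanges::IRanges(df$start[ex_rows], df$end[ex_rows]))
      exons <- cbind(IRanges::start(red), IRanges::end(red))
    }
    models[[k]] <- gene_model(
      gene_id = gid, gene_name = if (is.na(nm)) gid else nm,
      chrom = as.character(df$seqnames[i]),
      strand = as.character(df$strand[i]),
      start = df$start[i], end = df$end[i],
      exons = exons, biotype = biotype
    )
  }
  annotation_set(do.call(rbind, models), layout)
}

#' Write an annotation set as GFF3
#'
#' Emits, per gene, one `gene` row, one `mRNA` row and one `exon` row per
#' exon, all sharing the gene's coordinates and strand, so that a
#' coordinate change (e.g. a TTS extension) is visible in all three
#' feature types. The output round-trips through [read_gff3()]
#' coordinate-exactly.
#'
#' @param ann an `sc3_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  g <- ann$genes
  if (nrow(g) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rows <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    ex <- g$exons[[i]]
    tx_id <- paste0(g$gene_id[i], ".t1")
    n <- 2L + nrow(ex)
    rows[[i]] <- data.frame(
      seqnames = g$chrom[i],
      start = c(g$start[i], g$start[i], ex[, 1L]),
      end = c(g$end[i], g$end[i], ex[, 2L]),
      strand = g$strand[i],
      type = c("gene", "mRNA", rep("exon", nrow(ex))),
      ID = c(g$gene_id[i], tx_id, paste0(tx_id, ".exon", seq_len(nrow(ex)))),
      Name = c(g$gene_name[i], rep(NA_character_, n - 1L)),
      parent = c(NA_character_, g$gene_id[i], rep(tx_id, nrow(ex))),
      gene_biotype = c(g$biotype[i], rep(NA_character_, n - 1L)),
      pseudo = c(if (g$biotype[i] == "pseudogene") "True" else NA_character_,
                 rep(NA_character_, n - 1L)),
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr)$source <- "sc3kit"
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Name <- df$Name
  plist <- as.list(df$parent)
  plist[is.na(df$parent)] <- list(character(0))
  S4Vectors::mcols(gr)$Parent <- unname(IRanges::CharacterList(plist))
  S4Vectors::mcols(gr)$gene_biotype <- df$gene_biotype
  S4Vectors::mcols(gr)$pseudo <- df$pseudo
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
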