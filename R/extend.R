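#' Configuration for the 3'-end extension rewrite
#'
#' 3'-end tag counting concentrates reads within a few hundred bp of the
#' transcription termination site (TTS); an annotation whose TTS falls
#' short of the true 3' end loses those reads. The rewrite therefore
#' extends every retained gene's TTS downstream by up to `max_extension`
#' bp, stopping early at strand-aware collisions with neighbouring genes
#' (see [compute_extended_tts()]).
#'
#' @param max_extension maximum extension in bp (default 10,000).
#' @param removed_biotypes biotypes removed from the annotation (default
#'   pseudogene, tRNA, ncRNA).
#' @param biotype_filter_order `"before_extension"` (default; removed
#'   genes do not block extension) or `"after_extension"` (they do, and
#'   are dropped afterwards).
#' @param feature_types_to_extend GFF3 feature types rewritten to the new
#'   coordinate (informational; [write_gff3()] always emits gene, mRNA and
#'   exon rows at the extended coordinates).
#' @return list of class `sc3_extension_config`.
#' @export
extension_config <- function(max_extension = 10000,
                             removed_biotypes = c("pseudogene", "tRNA", "ncRNA"),
                             biotype_filter_order = c("before_extension",
                                                      "after_extension"),
                             feature_types_to_extend = c("gene", "transcript",
                                                         "exon")) {
  if (!is_count1(max_extension)) {
    stop_user("max_extension must be a single non-negative integer")
  }
  structure(list(max_extension = as.numeric(max_extension),
                 removed_biotypes = removed_biotypes,
                 biotype_filter_order = match.arg(biotype_filter_order),
                 feature_types_to_extend = feature_types_to_extend),
            class = "sc3_extension_config")
}

## Extended TTS for gene row i of `genes`, against the ORIGINAL
## coordinates of all other rows. Collision caps, all evaluated in the
## gene's 3' direction within the window W of max_extension bp past the
## TTS t:
##   (a) t +/- E                       (full extension)
##   (b) same-strand TSS s in W        -> 1 bp short of s
##   (c) opposite-strand TTS u in W    -> floor((t+u)/2) on '+',
##                                        floor((t+u)/2)+1 on '-'
##                                        (the two halves never overlap)
##   (d) any other gene body overlapping W -> 1 bp short of its first
##       intruding base (covers bodies that span the window without
##       presenting a terminus inside it; for TSS/TTS hits this cap is
##       never more restrictive than (b)/(c))
##   (e) chromosome end
## The result is clamped to [t, window end]: extension length 0 is legal.
ext_tts_idx <- function(i, genes, clen, E) {
  t <- genes$tts[i]
  str_i <- genes$strand[i]
  chrom_i <- genes$chrom[i]
  L <- clen[[chrom_i]]
  if (E == 0) return(t)

  j <- which(genes$chrom == chrom_i)
  j <- j[j != i]

  if (str_i == "+") {
    win_lo <- t + 1; win_hi <- min(t + E, L)
    if (win_lo > win_hi) return(t)
    cap <- win_hi
    for (k in j) {
      if (genes$strand[k] == "+") {
        s <- genes$tss[k]
        if (s >= win_lo && s <= win_hi) cap <- min(cap, s - 1)
      } else {
        u <- genes$tts[k]
        if (u >= win_lo && u <= win_hi) cap <- min(cap, floor((t + u) / 2))
      }
      if (genes$start[k] <= win_hi && genes$end[k] >= win_lo) {
        cap <- min(cap, max(genes$start[k], win_lo) - 1)
      }
    }
    max(t, cap)
  } else {
    win_hi <- t - 1; win_lo <- max(t - E, 1)
    if (win_lo > win_hi) return(t)
    cap <- win_lo
    for (k in j) {
      if (genes$strand[k] == "-") {
        s <- genes$tss[k]
        if (s >= win_lo && s <= win_hi) cap <- max(cap, s + 1)
      } else {
        u <- genes$tts[k]
        if (u >= win_lo && u <= win_hi) cap <- max(cap, floor((t + u) / 2) + 1)
      }
      if (genes$start[k] <= win_hi && genes$end[k] >= win_lo) {
        cap <- max(cap, min(genes$end[k], win_hi) + 1)
      }
    }
    min(t, cap)
  }
}

#' Extended TTS for one gene
#'
#' Computes the new transcription termination site for gene `g` against
#' the original (pre-extension) coordinates of every other gene in `ann`,
#' which must already be deduplicated (see [dedupe_identical_tts()]) and,
#' under the default filter order, biotype-filtered. The extension runs in
#' the gene's 3' direction for at most `cfg$max_extension` bp and stops
#' early at: a same-strand downstream TSS (1 bp upstream of it), an
#' opposite-strand downstream TTS (the midpoint of the two TTSs, split so
#' the two extensions stay disjoint), any other gene body intruding into
#' the window (1 bp short of the intrusion), and the chromosome end.
#'
#' @param g a gene id present in `ann`, or a one-row gene-model
#'   data.frame whose `gene_id` is present in `ann`.
#' @param ann an `sc3_annotation` (deduplicated).
#' @param cfg an [extension_config()].
#' @return The new TTS coordinate (base pair).
#' @export
compute_extended_tts <- function(g, ann, cfg = extension_config()) {
  gid <- if (is.character(g)) g else g$gene_id[1L]
  i <- match(gid, ann$genes$gene_id)
  if (is.na(i)) stop_user("gene not in annotation set: ", gid)
  clen <- stats::setNames(as.list(ann$layout$length), ann$layout$chrom)
  ext_tts_idx(i, ann$genes, clen, cfg$max_extension)
}

#' Extend all TTSs of an annotation set
#'
#' Applies the full annotation rewrite: biotype removal and identical-TTS
#' deduplication, then per-gene TTS extension with all collision tests
#' evaluated against the original coordinate set (so the result does not
#' depend on gene processing order). Each retained gene's span and its
#' 3'-most exon are extended to the new TTS. With
#' `biotype_filter_order = "after_extension"` removed biotypes still block
#' extension and are dropped only at the end.
#'
#' @param ann an `sc3_annotation`.
#' @param cfg an [extension_config()].
#' @return A new `sc3_annotation` with extended coordinates.
#' @export
extend_all <- function(ann, cfg = extension_config()) {
  before <- cfg$biotype_filter_order == "before_extension"
  if (before) ann <- filter_biotypes(ann, cfg)
  ann <- dedupe_identical_tts(ann)

  g <- ann$genes
  clen <- stats::setNames(as.list(ann$layout$length), ann$layout$chrom)
  if (nrow(g)) {
    new_tts <- vapply(seq_len(nrow(g)), ext_tts_idx, numeric(1L),
                      genes = g, clen = clen, E = cfg$max_extension)
    for (i in seq_len(nrow(g))) {
      if (new_tts[i] == g$tts[i]) next
      ex <- g$exons[[i]]
      if (g$strand[i] == "+") {
        g$end[i] <- new_tts[i]
        ex[nrow(ex), 2L] <- new_tts[i]
      } else {
        g$start[i] <- new_tts[i]
        ex[1L, 1L] <- new_tts[i]
      }
      g$tts[i] <- new_tts[i]
      g$exons[[i]] <- ex
    }
  }
  out <- annotation_set(g, ann$layout)
  if (!before) out <- filter_biotypes(out, cfg)
  out
}
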