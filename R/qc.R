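#' Read a read-category tally table
#'
#' TSV with one row per sample, mirroring the mapping-statistics layout of
#' the cohort metadata tables: `sample_id`, `total_reads`, and the five
#' category columns `sc3seq_mapped`, `mapped_others`, `control_rna`,
#' `low_quality_adaptor_polyA`, `unmapped`. Extra columns are kept.
#'
#' @param path TSV path (header required).
#' @return data.frame.
#' @export
read_tally <- function(path) {
  if (!file.exists(path)) stop_user("tally file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "total_reads", TALLY_CATEGORIES)
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_user("tally file missing column(s): ", paste(miss, collapse = ", "))
  }
  tab
}

TALLY_CATEGORIES <- c("sc3seq_mapped", "mapped_others", "control_rna",
                      "low_quality_adaptor_polyA", "unmapped")

#' Check read-category accounting
#'
#' A tally row passes when its five read categories (mapped to genes,
#' mapped elsewhere, spike-in control RNA, low-quality/adaptor/poly-A,
#' unmapped) sum exactly to `total_reads`.
#'
#' @param tally data.frame as returned by [read_tally()].
#' @return logical vector, one element per row (`TRUE` = pass).
#' @export
check_tally <- function(tally) {
  cats <- as.matrix(tally[, TALLY_CATEGORIES, drop = FALSE])
  rowSums(cats) == tally$total_reads
}

#' Read a qPCR Ct table
#' @param path TSV with columns `sample_id`, `gene_name`, `ct`.
#' @return data.frame; Ct values must be positive.
#' @export
read_ct <- function(path) {
  if (!file.exists(path)) stop_user("Ct file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "gene_name", "ct"), names(tab))
  if (length(miss)) {
    stop_user("Ct file missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(tab$ct)) || any(tab$ct <= 0)) {
    stop_user("Ct values must be positive finite numbers")
  }
  tab
}

#' Prescreen amplified cDNAs by housekeeping-gene Ct values
#'
#' A sample passes the quality prescreen when its qPCR cycle thresholds
#' for the housekeeping genes satisfy Ct(GAPDH) < `gapdh_max` and
#' Ct(PPIA) < `ppia_max`, both strictly (lower Ct means more cDNA).
#' Samples missing either marker are flagged `"indeterminate"`. When a
#' sample has replicate measurements of a marker, their mean is used.
#'
#' @param records data.frame with `sample_id`, `gene_name`, `ct`.
#' @param gapdh_max strict upper bound for GAPDH Ct (default 19).
#' @param ppia_max strict upper bound for PPIA Ct (default 20).
#' @return data.frame with `sample_id`, `status` (`"pass"`, `"fail"` or
#'   `"indeterminate"`), and the per-marker Ct means.
#' @export
prescreen_ct <- function(records, gapdh_max = 19, ppia_max = 20) {
  samples <- unique(records$sample_id)
  gct <- vapply(samples, function(s) {
    v <- records$ct[records$sample_id == s & records$gene_name == "GAPDH"]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1L))
  pct <- vapply(samples, function(s) {
    v <- records$ct[records$sample_id == s & records$gene_name == "PPIA"]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1L))
  status <- ifelse(is.na(gct) | is.na(pct), "indeterminate",
                   ifelse(gct < gapdh_max & pct < ppia_max, "pass", "fail"))
  data.frame(sample_id = samples, status = status,
             ct_gapdh = gct, ct_ppia = pct,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' TTS meta-profile of read positions
#'
#' For every assigned read, the offset of its 5' position from the
#' annotated TTS of its gene is computed along the gene's 3' direction
#' (negative = inside the gene body, positive = downstream of the TTS).
#' Offsets are histogrammed in `bin_width`-bp bins over `window`, and the
#' per-cell histograms are scaled to kilo-RPM (bin count / assigned reads
#' x 1e3). In a 3'-end tag library the mass concentrates within a few
#' hundred bp upstream of the TTS.
#'
#' `ann` must carry the ORIGINAL (pre-extension) TTSs, which are the
#' biologically annotated 3' ends; reads are assigned against the
#' extended annotation (`assign_ann`, computed from `ann` by default) so
#' that tags downstream of an under-annotated TTS are still captured.
#'
#' @param reads an `sc3_reads` table.
#' @param ann pre-extension `sc3_annotation` (offset origin).
#' @param window signed offset range in bp, default `c(-3000, 1000)`.
#' @param bin_width bin width in bp, default 50.
#' @param assign_ann annotation used for read assignment; defaults to
#'   `extend_all(ann, cfg)`.
#' @param cfg extension config used for the default `assign_ann`.
#' @param spike_prefix spike-in chromosome prefix.
#' @return list of class `sc3_metaprofile`: `breaks` (bin edges),
#'   `offsets` (bin midpoints), `density` (bins x cells, kilo-RPM) and
#'   `mean` (cross-cell mean profile).
#' @export
tts_metaprofile <- function(reads, ann, window = c(-3000, 1000),
                            bin_width = 50, assign_ann = NULL,
                            cfg = extension_config(),
                            spike_prefix = "ERCC-") {
  assign_ann <- assign_ann %||% extend_all(ann, cfg)
  breaks <- seq(window[1L], window[2L], by = bin_width)
  nb <- length(breaks) - 1L
  cells <- sort(unique(reads$cell_id))
  dens <- matrix(0, nrow = nb, ncol = length(cells),
                 dimnames = list(NULL, cells))
  if (nrow(reads)) {
    asn <- assign_reads(reads, assign_ann, spike_prefix = spike_prefix)
    is_gene <- !(asn %in% c("AMBIGUOUS", "UNASSIGNED", "SPIKE_IN"))
    if (any(is_gene)) {
      gi <- match(asn[is_gene], ann$genes$gene_id)
      if (anyNA(gi)) {
        stop_user("assigned gene absent from the offset-origin annotation")
      }
      plus <- ann$genes$strand[gi] == "+"
      p5 <- ifelse(reads$strand[is_gene] == "+", reads$start[is_gene],
                   reads$end[is_gene])
      off <- ifelse(plus, p5 - ann$genes$tts[gi], ann$genes$tts[gi] - p5)
      cell <- reads$cell_id[is_gene]
      assigned_per_cell <- table(factor(reads$cell_id[is_gene], levels = cells))
      inw <- off >= window[1L] & off <= window[2L]
      if (any(inw)) {
        bin <- pmin(pmax(findInterval(off[inw], breaks,
                                      rightmost.closed = TRUE), 1L), nb)
        tab <- table(factor(bin, levels = seq_len(nb)),
                     factor(cell[inw], levels = cells))
        denom <- pmax(as.numeric(assigned_per_cell), 1)
        dens <- sweep(unclass(tab), 2L, denom, "/") * 1e3
      }
    }
  }
  structure(list(breaks = breaks,
                 offsets = (breaks[-1L] + breaks[-length(breaks)]) / 2,
                 density = dens,
                 mean = if (ncol(dens)) rowMeans(dens) else rep(0, nb)),
            class = "sc3_metaprofile")
}

#' qPCR concordance with sequencing expression values
#'
#' Per sample, the delta-Ct of a gene is the mean housekeeping Ct
#' (default GAPDH and PPIA) minus the gene's Ct, so that higher expression
#' gives a larger delta-Ct. Over all (gene, sample) pairs shared between
#' the Ct table and the expression matrix (housekeeping genes excluded),
#' a least-squares line of log2(RPM+1) on delta-Ct and the Pearson
#' correlation are returned.
#'
#' @param ct data.frame with `sample_id`, `gene_name`, `ct`.
#' @param logm log2(RPM+1) matrix, rownames = gene names, colnames =
#'   sample ids.
#' @param housekeeping housekeeping gene names (mean Ct reference).
#' @return list with `slope`, `intercept`, `pearson_r`, `n` and the
#'   paired data in `data`.
#' @export
qpcr_concordance <- function(ct, logm, housekeeping = c("GAPDH", "PPIA")) {
  samples <- intersect(unique(ct$sample_id), colnames(logm))
  pairs <- NULL
  for (s in samples) {
    sub <- ct[ct$sample_id == s, , drop = FALSE]
    hk <- sub$ct[sub$gene_name %in% housekeeping]
    if (!length(hk)) next
    sub <- sub[!(sub$gene_name %in% housekeeping) &
                 sub$gene_name %in% rownames(logm), , drop = FALSE]
    if (!nrow(sub)) next
    pairs <- rbind(pairs, data.frame(
      sample_id = s, gene_name = sub$gene_name,
      delta_ct = mean(hk) - sub$ct,
      log_expr = logm[sub$gene_name, s],
      stringsAsFactors = FALSE
    ))
  }
  if (is.null(pairs) || nrow(pairs) < 3L) {
    stop_user("qpcr_concordance: fewer than 3 shared (gene, sample) pairs")
  }
  fit <- stats::lm(log_expr ~ delta_ct, data = pairs)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       pearson_r = stats::cor(pairs$delta_ct, pairs$log_expr),
       n = nrow(pairs),
       data = pairs)
}

#' Per-cell expression percentiles of expressed genes
#'
#' Restricted to the expressed-gene subset, computes per cell the 25th,
#' 50th and 75th percentile of log2(RPM+1) (linear interpolation between
#' order statistics) and a whisker at median + 2 standard deviations.
#' Uniform 75th-percentile values across a cohort indicate uniform
#' library quality.
#'
#' @param logm log2(RPM+1) matrix.
#' @param expressed gene subset; default [expressed_genes()] of `logm`.
#' @return data.frame with `cell_id`, `p25`, `p50`, `p75`, `whisker`.
#' @export
expression_percentiles <- function(logm, expressed = NULL) {
  expressed <- expressed %||% expressed_genes(logm)
  sub <- logm[expressed, , drop = FALSE]
  if (nrow(sub) == 0L) stop_user("no expressed genes to summarise")
  qs <- apply(sub, 2L, stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE)
  sds <- apply(sub, 2L, stats::sd)
  data.frame(cell_id = colnames(logm),
             p25 = qs[1L, ], p50 = qs[2L, ], p75 = qs[3L, ],
             whisker = qs[2L, ] + 2 * sds,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag cells with outlying 75th-percentile expression
#'
#' Uniformity screen over a cohort: a cell is flagged when its p75
#' deviates from the cohort median p75 by more than `k` median absolute
#' deviations.
#'
#' @param pct data.frame from [expression_percentiles()].
#' @param k MAD multiplier (default 5).
#' @return logical vector, `TRUE` = outlier, named by cell.
#' @export
flag_percentile_outliers <- function(pct, k = 5) {
  med <- stats::median(pct$p75)
  m <- stats::mad(pct$p75)
  if (m == 0) m <- .Machine$double.eps
  stats::setNames(abs(pct$p75 - med) > k * m, pct$cell_id)
}
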