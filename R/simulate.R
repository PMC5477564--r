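SCENARIOS <- c("isolated", "shared_tts", "tandem_same_strand", "convergent",
               "body_intrusion", "pseudogene_neighbor")

SLOT_WIDTH <- 60000

## One slot's gene models at base coordinate s (all offsets fixed; a
## per-slot jitter is added to s by the caller). Returns list(genes=list
## of gene_model rows, truth=data.frame). expected_tts is the extended
## TTS under the default config (10 kb, filter before extension);
## retained says whether the gene survives dedupe + biotype filtering.
scenario_slot <- function(scenario, tag, chrom, s) {
  gm <- function(id, strand, lo, hi, biotype = "protein_coding") {
    gene_model(paste0(tag, "_", id), chrom = chrom, strand = strand,
               start = s + lo, end = s + hi, biotype = biotype)
  }
  tr <- function(id, expected, retained = TRUE) {
    data.frame(gene_id = paste0(tag, "_", id), scenario = scenario,
               expected_tts = if (is.na(expected)) NA_real_ else s + expected,
               retained = retained, stringsAsFactors = FALSE)
  }
  switch(scenario,
    isolated = list(
      genes = list(gm("G", "+", 2000, 7000)),
      truth = tr("G", 17000)
    ),
    shared_tts = list(
      genes = list(gm("A", "+", 2000, 12000), gm("B", "+", 8000, 12000)),
      truth = rbind(tr("A", 22000), tr("B", NA, retained = FALSE))
    ),
    tandem_same_strand = list(
      genes = list(gm("A", "+", 2000, 8000), gm("B", "+", 11000, 20000)),
      truth = rbind(tr("A", 10999), tr("B", 30000))
    ),
    convergent = list(
      genes = list(gm("A", "+", 2000, 10000), gm("B", "-", 16000, 26000)),
      truth = rbind(tr("A", 13000), tr("B", 13001))
    ),
    body_intrusion = list(
      genes = list(gm("G", "+", 2000, 8000), gm("B", "-", 6000, 26000)),
      truth = rbind(tr("G", 8000), tr("B", 6000))
    ),
    pseudogene_neighbor = list(
      genes = list(gm("G", "+", 2000, 8000),
                   gm("P", "+", 11000, 20000, biotype = "pseudogene")),
      truth = rbind(tr("G", 18000), tr("P", NA, retained = FALSE))
    ),
    stop_user("unknown scenario: ", scenario)
  )
}

#' Generate a toy annotation with planted gene-adjacency scenarios
#'
#' Places the requested number of each adjacency scenario in
#' non-interfering 60 kb slots along the genome and records, per gene,
#' the scenario it instantiates and its expected extended TTS under the
#' default [extension_config()]. Scenarios: `isolated` (full 10 kb
#' extension), `shared_tts` (two genes, one survivor),
#' `tandem_same_strand` downstream TSS stop, `convergent`
#' opposite-strand TTS midpoint split, `body_intrusion` (zero-length
#' extension against a spanning body) and `pseudogene_neighbor`
#' (blocker removed by the biotype filter). Deterministic per seed
#' (slot order and a small positional jitter are randomised).
#'
#' @param layout a [genome_layout()]; default one 4 Mb chromosome.
#' @param scenario_counts named integer vector over
#'   `r paste(SCENARIOS, collapse = ", ")`.
#' @param seed RNG seed.
#' @return list with `ann` (an `sc3_annotation`) and `truth`
#'   (data.frame: `gene_id`, `scenario`, `expected_tts`, `retained`).
#' @export
make_annotation <- function(layout = genome_layout("chr1", 4e6),
                            scenario_counts = c(isolated = 2, shared_tts = 2,
                                                tandem_same_strand = 2,
                                                convergent = 2,
                                                body_intrusion = 2,
                                                pseudogene_neighbor = 2),
                            seed = 1) {
  bad <- setdiff(names(scenario_counts), SCENARIOS)
  if (length(bad)) stop_user("unknown scenario: ", bad[1L])
  slots <- rep(names(scenario_counts), scenario_counts)
  ## slots fit wholly on one chromosome; greedy fill in layout order
  capacity <- floor((layout$length - 10000) / SLOT_WIDTH)
  capacity[capacity < 0] <- 0
  if (sum(capacity) < length(slots)) {
    stop_user("genome too small for ", length(slots), " scenario slots (fits ",
              sum(capacity), ")")
  }
  with_seed(seed, {
    slots <- sample(slots)
    genes <- list()
    truth <- list()
    ci <- 1L; slot_in_chrom <- 0L
    for (k in seq_along(slots)) {
      while (slot_in_chrom >= capacity[ci]) {
        ci <- ci + 1L; slot_in_chrom <- 0L
      }
      s <- slot_in_chrom * SLOT_WIDTH + sample.int(2000L, 1L)
      out <- scenario_slot(slots[k], sprintf("%s%03d", slots[k], k),
                           layout$chrom[ci], s)
      genes <- c(genes, out$genes)
      truth[[k]] <- out$truth
      slot_in_chrom <- slot_in_chrom + 1L
    }
    list(ann = annotation_set(do.call(rbind, genes), layout),
         truth = do.call(rbind, truth))
  })
}

#' Generate a random annotation (for property testing)
#'
#' Genes with random strand and length are scattered uniformly over the
#' layout, overlaps allowed; a fraction of same-strand gene pairs is
#' forced to share an identical TTS to exercise deduplication.
#'
#' @param n_genes number of genes.
#' @param layout a [genome_layout()].
#' @param seed RNG seed.
#' @param shared_tts_frac fraction of genes duplicated at an existing TTS.
#' @param pseudo_frac fraction of genes typed pseudogene.
#' @return An `sc3_annotation`.
#' @export
random_annotation <- function(n_genes = 100,
                              layout = genome_layout("chr1", 2e6),
                              seed = 1, shared_tts_frac = 0.1,
                              pseudo_frac = 0.1) {
  with_seed(seed, {
    chrom <- sample(layout$chrom, n_genes, replace = TRUE,
                    prob = layout$length / sum(layout$length))
    clen <- stats::setNames(layout$length, layout$chrom)
    len <- sample(500:20000, n_genes, replace = TRUE)
    len <- pmin(len, clen[chrom])
    start <- floor(stats::runif(n_genes, 1, clen[chrom] - len + 1))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    biotype <- ifelse(stats::runif(n_genes) < pseudo_frac, "pseudogene",
                      "protein_coding")
    models <- lapply(seq_len(n_genes), function(i) {
      gene_model(sprintf("RG%04d", i), chrom = chrom[i], strand = strand[i],
                 start = start[i], end = start[i] + len[i] - 1,
                 biotype = biotype[i])
    })
    ## force some identical-TTS pairs (same chrom+strand, shifted start)
    n_dup <- floor(n_genes * shared_tts_frac)
    if (n_dup > 0) {
      src <- sample(n_genes, n_dup, replace = TRUE)
      for (k in seq_len(n_dup)) {
        g <- models[[src[k]]]
        delta <- sample(100:3000, 1L)
        if (g$strand == "+") {
          ns <- max(1, g$start + delta); ne <- g$end
        } else {
          ns <- g$start; ne <- min(clen[g$chrom], g$end - delta)
        }
        if (ns > ne) next
        models[[length(models) + 1L]] <- gene_model(
          sprintf("RGD%04d", k), chrom = g$chrom, strand = g$strand,
          start = ns, end = ne, biotype = g$biotype)
      }
    }
    annotation_set(do.call(rbind, models), layout)
  })
}

#' Simulate 3'-biased reads over an annotation
#'
#' Each cell receives `reads_per_cell` reads. A fraction `spike_frac`
#' (binomially drawn) lands uniformly on synthetic ERCC-like spike-in
#' chromosomes; the rest are drawn from genes (uniformly, or by
#' `weights`), with the read 5' position a truncated-exponential distance
#' upstream of the gene's TTS (scale `bias_scale`, truncated at
#' `tts_window`), emulating 3'-end tag enrichment within ~300 bp of the
#' TTS. Read strand equals gene strand. Provenance of every read is
#' recorded.
#'
#' @param ann an `sc3_annotation` (original, pre-extension coordinates;
#'   offsets are measured from its TTSs).
#' @param cells character vector of cell ids (or a count).
#' @param reads_per_cell reads per cell.
#' @param tts_window bias truncation window in bp (default 300).
#' @param bias_scale exponential scale in bp (default 100).
#' @param spike_frac expected spike-in read fraction (default 0.05).
#' @param read_length read length in bp (default 40).
#' @param weights optional per-gene sampling weights (named by gene_id).
#' @param seed RNG seed.
#' @return list with `reads` (an `sc3_reads` table), `truth` (data.frame:
#'   `read_id`, `cell_id`, `source`) and `spike_layout` (the ERCC-like
#'   chromosome table).
#' @export
simulate_reads <- function(ann, cells = 4, reads_per_cell = 1000,
                           tts_window = 300, bias_scale = 100,
                           spike_frac = 0.05, read_length = 40,
                           weights = NULL, seed = 1) {
  if (!is_count1(reads_per_cell)) stop_user("reads_per_cell must be >= 0")
  if (is.numeric(cells) && length(cells) == 1L) {
    cells <- sprintf("cell%03d", seq_len(cells))
  }
  g <- ann$genes
  if (nrow(g) == 0L && spike_frac < 1) stop_user("annotation has no genes")
  clen <- stats::setNames(ann$layout$length, ann$layout$chrom)
  spike_ids <- sprintf("ERCC-%05d", c(2, 3, 4, 43, 85, 92, 108, 130))
  spike_len <- 1000L
  w <- if (is.null(weights)) rep(1, nrow(g)) else weights[g$gene_id]
  with_seed(seed, {
    all <- vector("list", length(cells))
    for (ci in seq_along(cells)) {
      n_spike <- if (reads_per_cell > 0) {
        stats::rbinom(1L, reads_per_cell, spike_frac)
      } else {
        0L
      }
      n_gene <- reads_per_cell - n_spike
      rows <- NULL
      if (n_gene > 0) {
        gi <- sample.int(nrow(g), n_gene, replace = TRUE, prob = w)
        u <- stats::runif(n_gene)
        d <- floor(-bias_scale * log(1 - u * (1 - exp(-tts_window / bias_scale))))
        plus <- g$strand[gi] == "+"
        p5 <- ifelse(plus, g$tts[gi] - d, g$tts[gi] + d)
        start <- ifelse(plus, p5, p5 - read_length + 1)
        end <- ifelse(plus, p5 + read_length - 1, p5)
        start <- pmax(1, start)
        end <- pmin(clen[g$chrom[gi]], end)
        rows <- data.frame(chrom = g$chrom[gi], strand = g$strand[gi],
                           start = start, end = end,
                           source = g$gene_id[gi], stringsAsFactors = FALSE)
      }
      if (n_spike > 0) {
        sc <- sample(spike_ids, n_spike, replace = TRUE)
        sp <- sample.int(spike_len - read_length, n_spike, replace = TRUE)
        rows <- rbind(rows, data.frame(
          chrom = sc, strand = "+", start = sp, end = sp + read_length - 1,
          source = sc, stringsAsFactors = FALSE))
      }
      rows$cell_id <- cells[ci]
      all[[ci]] <- rows
    }
    df <- do.call(rbind, all)
    if (is.null(df)) {
      df <- data.frame(chrom = character(0), strand = character(0),
                       start = numeric(0), end = numeric(0),
                       source = character(0), cell_id = character(0))
    }
    reads <- aligned_reads(df$chrom, df$strand, df$start, df$end, df$cell_id)
    truth <- data.frame(read_id = seq_len(nrow(df)), cell_id = df$cell_id,
                        source = df$source, stringsAsFactors = FALSE)
    list(reads = reads, truth = truth,
         spike_layout = data.frame(chrom = spike_ids, length = spike_len))
  })
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower | out > upper)
  tries <- 0L
  while (length(bad) && tries < 1000L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out <= lower | out > upper)
    tries <- tries + 1L
  }
  if (length(bad)) out[bad] <- pmin(pmax(mean, lower + sd / 100), upper)
  out
}

#' Simulate a cell-type-structured log-expression matrix
#'
#' Each cell is planted into a lineage and its marker genes are set
#' according to that lineage's rule: "on" genes draw from a normal
#' (`on_mean`, `on_sd`) truncated above `th$theta_on`, "low" genes from
#' (`low_mean`, `low_sd`) truncated into `(theta_off, theta_on]`, one
#' random member of each `any_on` set is turned on, and all other marker
#' genes sit at `off_level`. The truncation encodes that a planted state
#' genuinely is that state (the draw's spread models biological
#' variability within the state). Background genes are log-normal noise
#' around `bg_mean` with spread `noise_sd`. Technical dropout is
#' expression-dependent, as in shallow 3'-end tag data: a nonzero value
#' `v` is zeroed with probability `dropout_p * 2^(-v)`, so weakly
#' expressed ("low") genes drop out an order of magnitude more often
#' than strongly expressed ones.
#'
#' @param n_cells_per_type cells per lineage: a single count or a named
#'   vector over rule labels.
#' @param rules list of [marker_rule()]s.
#' @param on_mean,on_sd "on" level distribution (log2(RPM+1) scale).
#' @param low_mean,low_sd "low" level distribution.
#' @param off_level "off" level (default 0).
#' @param dropout_p dropout probability scale (default 0.1).
#' @param noise_sd background noise sd (default 0.5).
#' @param n_background number of background genes.
#' @param bg_mean background mean level (default 1).
#' @param th an `sc3_thresholds` object.
#' @param seed RNG seed.
#' @return list with `logm` (genes x cells matrix), `truth` (data.frame:
#'   `cell_id`, `label`, and `profile` — the label refined by the any-on
#'   pick; the number of distinct profiles is the planted cluster count,
#'   since cells of one lineage with different any-on genes are planted
#'   with genuinely different expression patterns) and `states`
#'   (character matrix of planted per-(gene, cell) states:
#'   on/low/off/any_on/background).
#' @export
simulate_expression <- function(n_cells_per_type = 20,
                                rules = default_rules(),
                                on_mean = 6, on_sd = 1,
                                low_mean = 3, low_sd = 0.5,
                                off_level = 0, dropout_p = 0.1,
                                noise_sd = 0.5, n_background = 200,
                                bg_mean = 1, th = thresholds(), seed = 1) {
  labels <- vapply(rules, `[[`, "", "label")
  if (length(n_cells_per_type) == 1L && is.null(names(n_cells_per_type))) {
    n_cells_per_type <- stats::setNames(rep(n_cells_per_type, length(labels)),
                                        labels)
  }
  marker_genes <- sort(unique(unlist(lapply(rules, rule_genes))))
  bg_genes <- sprintf("BG%04d", seq_len(n_background))
  genes <- c(marker_genes, bg_genes)
  cell_label <- rep(names(n_cells_per_type), n_cells_per_type)
  n_cells <- length(cell_label)
  cells <- sprintf("cell%04d", seq_len(n_cells))
  with_seed(seed, {
    cell_label <- sample(cell_label)
    logm <- matrix(0, nrow = length(genes), ncol = n_cells,
                   dimnames = list(genes, cells))
    states <- matrix("off", nrow = length(genes), ncol = n_cells,
                     dimnames = list(genes, cells))
    states[bg_genes, ] <- "background"
    logm[bg_genes, ] <- pmax(0, stats::rnorm(n_background * n_cells,
                                             bg_mean, noise_sd))
    by_label <- stats::setNames(rules[match(cell_label, labels)], NULL)
    profile <- cell_label
    for (ci in seq_len(n_cells)) {
      r <- by_label[[ci]]
      if (is.null(r)) stop_user("no rule for planted label: ", cell_label[ci])
      logm[marker_genes, ci] <- off_level
      if (length(r$on)) {
        logm[r$on, ci] <- rtrunc_norm(length(r$on), on_mean, on_sd,
                                      lower = th$theta_on)
        states[r$on, ci] <- "on"
      }
      if (length(r$low)) {
        logm[r$low, ci] <- rtrunc_norm(length(r$low), low_mean, low_sd,
                                       lower = th$theta_off,
                                       upper = th$theta_on)
        states[r$low, ci] <- "low"
      }
      if (length(r$any_on)) {
        pick <- sample(r$any_on, 1L)
        logm[pick, ci] <- rtrunc_norm(1L, on_mean, on_sd, lower = th$theta_on)
        states[pick, ci] <- "any_on"
        profile[ci] <- paste0(cell_label[ci], "/", pick)
      }
      mentioned <- rule_genes(r)
      silent <- setdiff(marker_genes, mentioned)
      logm[silent, ci] <- off_level
    }
    if (dropout_p > 0) {
      nz <- logm > 0
      p <- dropout_p * 2^(-logm)
      drop <- nz & matrix(stats::runif(length(logm)) < p, nrow = nrow(logm))
      logm[drop] <- 0
    }
    list(logm = logm,
         truth = data.frame(cell_id = cells, label = cell_label,
                            profile = profile, stringsAsFactors = FALSE),
         states = states)
  })
}
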