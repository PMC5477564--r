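## Independent oracles, written from the rule statements, not from the
## package internals. All operate on plain data.frames.

## Naive all-pairs extended-TTS oracle. For gene i (row of `genes`,
## columns gene_id/chrom/strand/start/end/tss/tts), scan every other
## gene and accumulate the most restrictive stopping position.
oracle_extended_tts <- function(i, genes, chrom_len, E) {
  g <- genes[i, ]
  L <- chrom_len[[g$chrom]]
  dir <- if (g$strand == "+") +1 else -1
  t <- g$tts
  ## candidate extension length, shrunk pair by pair
  allowed <- E
  ## clamp at chromosome ends
  if (dir > 0) allowed <- min(allowed, L - t) else allowed <- min(allowed, t - 1)
  if (allowed < 0) allowed <- 0
  win_a <- t + dir           # first base of the window
  win_b <- t + dir * E       # last base (unclamped)
  for (j in seq_len(nrow(genes))) {
    if (j == i) next
    o <- genes[j, ]
    if (o$chrom != g$chrom) next
    in_win <- function(p) {
      if (dir > 0) p >= win_a && p <= win_b else p <= win_a && p >= win_b
    }
    ## same-strand TSS in window: stop 1 bp before it
    if (o$strand == g$strand && in_win(o$tss)) {
      allowed <- min(allowed, abs(o$tss - t) - 1)
    }
    ## opposite-strand TTS in window: stop at the split midpoint
    if (o$strand != g$strand && in_win(o$tts)) {
      mid <- if (dir > 0) floor((t + o$tts) / 2) else floor((t + o$tts) / 2) + 1
      allowed <- min(allowed, abs(mid - t))
    }
    ## any body intruding into the window: stop 1 bp before its first base
    lo <- min(win_a, win_b); hi <- max(win_a, win_b)
    if (o$start <= hi && o$end >= lo) {
      first <- if (dir > 0) max(o$start, win_a) else min(o$end, win_a)
      allowed <- min(allowed, abs(first - t) - 1)
    }
  }
  t + dir * max(0, allowed)
}

## Apply the oracle to every gene of an (already filtered + deduped)
## annotation, returning the expected TTS vector in gene order.
oracle_extend_all <- function(ann, E = 10000) {
  genes <- ann$genes
  chrom_len <- stats::setNames(as.list(ann$layout$length), ann$layout$chrom)
  vapply(seq_len(nrow(genes)), oracle_extended_tts, numeric(1L),
         genes = genes, chrom_len = chrom_len, E = E)
}

## Base-by-base walking oracle (second independent route, only feasible
## for small windows): extend one base at a time while no rule fires.
walk_extended_tts <- function(i, genes, chrom_len, E) {
  g <- genes[i, ]
  L <- chrom_len[[g$chrom]]
  dir <- if (g$strand == "+") +1 else -1
  t <- g$tts
  others <- genes[-i, , drop = FALSE]
  others <- others[others$chrom == g$chrom, , drop = FALSE]
  win_b <- t + dir * E
  mids <- numeric(0)
  if (nrow(others)) {
    opp <- others[others$strand != g$strand, , drop = FALSE]
    if (nrow(opp)) {
      inw <- if (dir > 0) {
        opp$tts > t & opp$tts <= win_b
      } else {
        opp$tts < t & opp$tts >= win_b
      }
      u <- opp$tts[inw]
      mids <- if (dir > 0) floor((t + u) / 2) else floor((t + u) / 2) + 1
    }
  }
  pos <- t
  for (e in seq_len(E)) {
    p <- t + dir * e
    if (p < 1 || p > L) break
    if (nrow(others) && any(others$start <= p & p <= others$end)) break
    if (length(mids) && ((dir > 0 && any(p > mids)) ||
                         (dir < 0 && any(p < mids)))) break
    pos <- p
  }
  pos
}

## Naive ward.D2 agglomeration via the Lance-Williams update on squared
## dissimilarities, recomputed with explicit loops. Returns merge
## heights in merge order.
oracle_ward_heights <- function(d) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  size <- rep(1, n)
  alive <- rep(TRUE, n)
  heights <- numeric(n - 1L)
  for (m in seq_len(n - 1L)) {
    best_i <- NA; best_j <- NA; best <- Inf
    for (i in seq_len(n - 1L)) {
      if (!alive[i]) next
      for (j in seq((i + 1L), n)) {
        if (!alive[j]) next
        if (D2[i, j] < best - 1e-12) {
          best <- D2[i, j]; best_i <- i; best_j <- j
        }
      }
    }
    heights[m] <- sqrt(best)
    ## merge j into i
    for (k in seq_len(n)) {
      if (!alive[k] || k == best_i || k == best_j) next
      D2[best_i, k] <- D2[k, best_i] <-
        ((size[best_i] + size[k]) * D2[k, best_i] +
         (size[best_j] + size[k]) * D2[k, best_j] -
         size[k] * D2[best_i, best_j]) /
        (size[best_i] + size[best_j] + size[k])
    }
    size[best_i] <- size[best_i] + size[best_j]
    alive[best_j] <- FALSE
  }
  heights
}

## Brute-force read assignment: loop over all genes, count strand-matched
## exonic overlaps.
oracle_assign <- function(read, ann, spike_prefix = "ERCC-") {
  if (startsWith(read$chrom, spike_prefix)) return("SPIKE_IN")
  hits <- character(0)
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    if (g$chrom != read$chrom || g$strand != read$strand) next
    ex <- g$exons[[1L]]
    if (any(ex[, 1L] <= read$end & ex[, 2L] >= read$start)) {
      hits <- c(hits, g$gene_id)
    }
  }
  if (length(hits) == 0L) "UNASSIGNED"
  else if (length(hits) == 1L) hits
  else "AMBIGUOUS"
}

## Tiny deterministic fixture: three genes on one chromosome.
toy_annotation <- function() {
  layout <- genome_layout("chr1", 1e6)
  genes <- rbind(
    gene_model("g1", "GENE1", chrom = "chr1", strand = "+",
               start = 10000, end = 15000,
               exons = cbind(c(10000, 13000), c(11000, 15000))),
    gene_model("g2", "GENE2", chrom = "chr1", strand = "-",
               start = 40000, end = 48000),
    gene_model("g3", "GENE3", chrom = "chr1", strand = "+",
               start = 100000, end = 120000, biotype = "pseudogene")
  )
  annotation_set(genes, layout)
}
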