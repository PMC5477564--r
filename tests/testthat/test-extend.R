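make_ann <- function(..., chrom_len = 1e6) {
  annotation_set(rbind(...), genome_layout("chr1", chrom_len))
}

test_that("isolated gene extends by the full 10 kb", {
  ann <- make_ann(gene_model("g", chrom = "chr1", strand = "+",
                             start = 45000, end = 50000))
  expect_equal(compute_extended_tts("g", ann), 60000)
})

test_that("same-strand downstream TSS stops extension 1 bp upstream", {
  ann <- make_ann(
    gene_model("g", chrom = "chr1", strand = "+", start = 45000, end = 50000),
    gene_model("dn", chrom = "chr1", strand = "+", start = 53000, end = 58000)
  )
  expect_equal(compute_extended_tts("g", ann), 52999)
  ## mirrored on the minus strand
  ann2 <- make_ann(
    gene_model("g", chrom = "chr1", strand = "-", start = 50000, end = 55000),
    gene_model("up", chrom = "chr1", strand = "-", start = 42000, end = 47000)
  )
  expect_equal(compute_extended_tts("g", ann2), 47001)
})

test_that("convergent TTSs meet at disjoint midpoints", {
  ann <- make_ann(
    gene_model("p", chrom = "chr1", strand = "+", start = 45000, end = 50000),
    gene_model("m", chrom = "chr1", strand = "-", start = 56000, end = 62000)
  )
  expect_equal(compute_extended_tts("p", ann), 53000)
  expect_equal(compute_extended_tts("m", ann), 53001)
  ## extensions [50001, 53000] and [53001, 55999] are disjoint
  ext <- extend_all(ann)
  p <- ext$genes[ext$genes$gene_id == "p", ]
  m <- ext$genes[ext$genes$gene_id == "m", ]
  expect_true(p$end < m$start)
})

test_that("extension clamps at the chromosome end", {
  ann <- make_ann(gene_model("g", chrom = "chr1", strand = "+",
                             start = 990000, end = 995000))
  expect_equal(compute_extended_tts("g", ann), 1000000)
  ## minus strand clamps at base 1
  ann2 <- make_ann(gene_model("g", chrom = "chr1", strand = "-",
                              start = 4000, end = 9000))
  expect_equal(compute_extended_tts("g", ann2), 1)
})

test_that("a body starting 1 bp after the TTS gives a zero-length extension", {
  ann <- make_ann(
    gene_model("g", chrom = "chr1", strand = "+", start = 45000, end = 50000),
    gene_model("blk", chrom = "chr1", strand = "-", start = 48000,
               end = 70000)
  )
  ## blocker body spans the whole window with no terminus inside it
  expect_equal(compute_extended_tts("g", ann), 50000)
})

test_that("compute_extended_tts rejects genes not in the set", {
  ann <- toy_annotation()
  expect_error(compute_extended_tts("nope", ann), "nope")
})

test_that("max_extension = 0 is the identity on coordinates", {
  ann <- random_annotation(n_genes = 30, seed = 7)
  out <- extend_all(ann, extension_config(max_extension = 0))
  keep <- match(out$genes$gene_id, ann$genes$gene_id)
  expect_equal(out$genes$tts, ann$genes$tts[keep])
  expect_equal(out$genes$start, ann$genes$start[keep])
  expect_equal(out$genes$end, ann$genes$end[keep])
})

test_that("extend_all updates gene span, 3'-most exon and written GFF3", {
  g <- gene_model("g", chrom = "chr1", strand = "+", start = 45000,
                  end = 50000, exons = cbind(c(45000, 48000), c(46000, 50000)))
  ann <- make_ann(g)
  ext <- extend_all(ann)
  row <- ext$genes[1L, ]
  expect_equal(row$end, 60000)
  expect_equal(row$tts, 60000)
  expect_equal(unname(row$exons[[1L]][2L, 2L]), 60000)
  expect_equal(row$exons[[1L]][1L, ], c(start = 45000, end = 46000))
  ## extended coordinate appears in gene, mRNA and exon rows
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ext, f)
  body <- readLines(f)
  body <- body[!startsWith(body, "#")]
  fields <- strsplit(body, "\t")
  types <- vapply(fields, `[[`, "", 3L)
  ends <- as.numeric(vapply(fields, `[[`, "", 5L))
  expect_equal(max(ends[types == "gene"]), 60000)
  expect_equal(max(ends[types == "mRNA"]), 60000)
  expect_equal(max(ends[types == "exon"]), 60000)
})

test_that("pseudogene blocking depends on the filter order", {
  ann <- make_ann(
    gene_model("g", chrom = "chr1", strand = "+", start = 45000, end = 50000),
    gene_model("ps", chrom = "chr1", strand = "+", start = 53000, end = 58000,
               biotype = "pseudogene")
  )
  before <- extend_all(ann, extension_config())
  expect_equal(before$genes$tts, 60000)
  after <- extend_all(
    ann, extension_config(biotype_filter_order = "after_extension"))
  expect_equal(after$genes$tts, 52999)
  expect_false("ps" %in% after$genes$gene_id)
})

test_that("extend_all matches the all-pairs oracle on planted scenarios", {
  ma <- make_annotation(seed = 11)
  ext <- extend_all(ma$ann)
  pre <- dedupe_identical_tts(filter_biotypes(ma$ann))
  expected <- oracle_extend_all(pre)
  m <- match(pre$genes$gene_id, ext$genes$gene_id)
  expect_false(anyNA(m))
  expect_equal(ext$genes$tts[m], expected)
  ## and the planted per-scenario expectations hold
  tr <- ma$truth
  expect_setequal(ext$genes$gene_id, tr$gene_id[tr$retained])
  m2 <- match(ext$genes$gene_id, tr$gene_id)
  expect_equal(ext$genes$tts, tr$expected_tts[m2])
})

test_that("extend_all agrees with the base-walk oracle on small windows", {
  for (seed in 1:10) {
    ann <- random_annotation(n_genes = 25,
                             layout = genome_layout("chr1", 3e5),
                             seed = seed)
    cfg <- extension_config(max_extension = 2000)
    pre <- dedupe_identical_tts(filter_biotypes(ann, cfg))
    ext <- extend_all(ann, cfg)
    clen <- list(chr1 = 3e5)
    walked <- vapply(seq_len(n_genes(pre)), walk_extended_tts, numeric(1L),
                     genes = pre$genes, chrom_len = clen, E = 2000)
    m <- match(pre$genes$gene_id, ext$genes$gene_id)
    expect_equal(ext$genes$tts[m], walked,
                 info = paste("seed", seed))
  }
})

test_that("extension is order-independent and bounded", {
  for (seed in 1:10) {
    ann <- random_annotation(n_genes = 60, seed = seed)
    ext <- extend_all(ann)
    perm <- with_seed(seed + 500, sample(n_genes(ann)))
    ext2 <- extend_all(annotation_set(ann$genes[perm, ], ann$layout))
    m <- match(ext$genes$gene_id, ext2$genes$gene_id)
    expect_equal(ext$genes$tts, ext2$genes$tts[m])
    ## bounded by [0, 10 kb] in the 3' direction
    pre <- dedupe_identical_tts(filter_biotypes(ann))
    m3 <- match(ext$genes$gene_id, pre$genes$gene_id)
    delta <- ifelse(ext$genes$strand == "+",
                    ext$genes$tts - pre$genes$tts[m3],
                    pre$genes$tts[m3] - ext$genes$tts)
    expect_true(all(delta >= 0 & delta <= 10000))
  }
})

test_that("extension regions never overlap retained original bodies", {
  for (seed in 1:10) {
    ann <- random_annotation(n_genes = 60, seed = seed + 100)
    pre <- dedupe_identical_tts(filter_biotypes(ann))
    ext <- extend_all(ann)
    m <- match(ext$genes$gene_id, pre$genes$gene_id)
    for (i in seq_len(n_genes(ext))) {
      g <- ext$genes[i, ]
      old_tts <- pre$genes$tts[m[i]]
      if (g$tts == old_tts) next
      reg <- sort(c(old_tts + if (g$strand == "+") 1 else -1, g$tts))
      others <- pre$genes[-m[i], , drop = FALSE]
      others <- others[others$chrom == g$chrom, , drop = FALSE]
      ovl <- others$start <= reg[2L] & others$end >= reg[1L]
      expect_false(any(ovl),
                   info = paste("seed", seed, "gene", g$gene_id))
    }
  }
})

test_that("re-running extension is documented non-idempotent but oracle-consistent", {
  ma <- make_annotation(seed = 13)
  ext1 <- extend_all(ma$ann)
  ext2 <- extend_all(ext1)
  ## second pass obeys the oracle computed on the extended coordinates
  pre2 <- dedupe_identical_tts(filter_biotypes(ext1))
  expected <- oracle_extend_all(pre2)
  m <- match(pre2$genes$gene_id, ext2$genes$gene_id)
  expect_equal(ext2$genes$tts[m], expected)
})
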