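ext_toy <- function() extend_all(toy_annotation())

test_that("assign_read honours strand, spike-ins and extended 3' regions", {
  ext <- ext_toy()
  ## inside g1's extended 3' region (original end 15000, extended 25000)
  r <- aligned_reads("chr1", "+", 20000, 20039, "c1")
  expect_identical(assign_read(r, ext), "g1")
  ## wrong strand over the same span -> unassigned
  r2 <- aligned_reads("chr1", "-", 12000, 12039, "c1")
  expect_identical(assign_read(r2, ext), "UNASSIGNED")
  ## spike-in chromosome
  r3 <- aligned_reads("ERCC-00002", "+", 10, 49, "c1")
  expect_identical(assign_read(r3, ext), "SPIKE_IN")
  ## unknown chromosome errors with its name
  r4 <- aligned_reads("chrZ", "+", 10, 49, "c1")
  expect_error(assign_read(r4, ext), "chrZ")
})

test_that("reads overlapping two same-strand genes are ambiguous", {
  layout <- genome_layout("chr1", 1e5)
  ann <- annotation_set(rbind(
    gene_model("a", chrom = "chr1", strand = "+", start = 1000, end = 5000),
    gene_model("b", chrom = "chr1", strand = "+", start = 4500, end = 9000)
  ), layout)
  r <- aligned_reads("chr1", "+", 4600, 4700, "c1")
  expect_identical(assign_read(r, ann), "AMBIGUOUS")
})

test_that("assignment matches the brute-force all-genes oracle", {
  ann <- extend_all(random_annotation(n_genes = 30,
                                      layout = genome_layout("chr1", 5e5),
                                      seed = 21))
  sim <- simulate_reads(ann, cells = 2, reads_per_cell = 300, seed = 22)
  got <- assign_reads(sim$reads, ann)
  want <- vapply(seq_len(nrow(sim$reads)), function(i) {
    oracle_assign(sim$reads[i, ], ann)
  }, "")
  expect_identical(got, want)
})

test_that("exonic-span vs gene-span overlap is configurable", {
  layout <- genome_layout("chr1", 1e5)
  ann <- annotation_set(
    gene_model("g", chrom = "chr1", strand = "+", start = 1000, end = 9000,
               exons = cbind(c(1000, 8000), c(2000, 9000))),
    layout)
  intronic <- aligned_reads("chr1", "+", 4000, 4050, "c1")
  expect_identical(assign_read(intronic, ann), "UNASSIGNED")
  expect_identical(assign_read(intronic, ann, use_gene_span = TRUE), "g")
})

test_that("count_cells tallies partition the reads", {
  ext <- ext_toy()
  sim <- simulate_reads(toy_annotation(), cells = 5, reads_per_cell = 400,
                        spike_frac = 0.1, seed = 3)
  cm <- count_cells(sim$reads, ext)
  per_cell <- table(factor(sim$reads$cell_id, levels = cm$tallies$cell_id))
  expect_equal(cm$tallies$assigned + cm$tallies$ambiguous +
                 cm$tallies$unassigned + cm$tallies$spike_in,
               as.integer(per_cell))
  expect_equal(cm$tallies$assigned, unname(as.integer(colSums(cm$counts))))
  ## spike-ins never enter gene counts
  expect_false(any(startsWith(rownames(cm$counts), "ERCC-")))
  expect_true(all(cm$tallies$spike_in > 0))
})

test_that("zero reads give an all-zero matrix", {
  ext <- ext_toy()
  empty <- aligned_reads(character(0), character(0), numeric(0), numeric(0),
                         character(0))
  ## the toy pseudogene is filtered by extend_all, leaving 2 genes
  cm <- count_cells(empty, ext, cells = c("c1", "c2"))
  expect_equal(dim(cm$counts), c(2L, 2L))
  expect_true(all(cm$counts == 0L))
  expect_true(all(cm$tallies$assigned == 0L))
})

test_that("recovered counts equal planted truth for isolated genes", {
  ma <- make_annotation(scenario_counts = c(isolated = 6), seed = 9)
  ext <- extend_all(ma$ann)
  sim <- simulate_reads(ma$ann, cells = 3, reads_per_cell = 500,
                        spike_frac = 0.05, seed = 10)
  cm <- count_cells(sim$reads, ext)
  truth_counts <- table(factor(sim$truth$source,
                               levels = rownames(cm$counts)),
                        factor(sim$truth$cell_id,
                               levels = colnames(cm$counts)))
  expect_equal(unclass(cm$counts), unclass(truth_counts),
               ignore_attr = TRUE)
})

test_that("to_rpm normalises each cell to one million", {
  ## single gene, 100 reads -> RPM 1e6; 30/70 -> 3e5/7e5
  cm <- structure(list(
    counts = matrix(c(100L, 0L, 30L, 70L), nrow = 2,
                    dimnames = list(c("g1", "g2"), c("c1", "c2"))),
    tallies = data.frame(cell_id = c("c1", "c2"), assigned = c(100L, 100L),
                         ambiguous = 0L, unassigned = 0L, spike_in = 0L)
  ), class = "sc3_counts")
  rpm <- to_rpm(cm)
  expect_equal(rpm[, "c1"], c(g1 = 1e6, g2 = 0))
  expect_equal(rpm[, "c2"], c(g1 = 3e5, g2 = 7e5))
  ## zero-assigned cell -> zero column with a warning
  cm$tallies$assigned[2L] <- 0L
  cm$counts[, 2L] <- 0L
  expect_warning(rpm0 <- to_rpm(cm), "c2")
  expect_equal(unname(rpm0[, 2L]), c(0, 0))
})

test_that("RPM columns sum to 1e6 on random count matrices", {
  for (seed in 1:100) {
    cm <- with_seed(seed, {
      counts <- matrix(rpois(20 * 5, 3), nrow = 20,
                       dimnames = list(sprintf("g%02d", 1:20),
                                       sprintf("c%d", 1:5)))
      structure(list(
        counts = counts,
        tallies = data.frame(cell_id = colnames(counts),
                             assigned = colSums(counts),
                             ambiguous = 0L, unassigned = 0L, spike_in = 0L)
      ), class = "sc3_counts")
    })
    if (any(cm$tallies$assigned == 0)) next
    expect_equal(unname(colSums(to_rpm(cm))), rep(1e6, 5))
  }
})

test_that("log transform preserves within-cell count ordering", {
  cm <- with_seed(42, {
    counts <- matrix(rpois(50 * 3, 10), nrow = 50,
                     dimnames = list(sprintf("g%02d", 1:50), c("a", "b", "c")))
    structure(list(counts = counts,
                   tallies = data.frame(cell_id = colnames(counts),
                                        assigned = colSums(counts),
                                        ambiguous = 0L, unassigned = 0L,
                                        spike_in = 0L)),
              class = "sc3_counts")
  })
  logm <- log2_rpm1(cm)
  for (j in 1:3) {
    expect_equal(order(logm[, j], cm$counts[, j]),
                 order(cm$counts[, j], cm$counts[, j]))
  }
})

test_that("expressed_genes applies a strict threshold", {
  logm <- matrix(c(4, 0, 4.01, 0, 6, 0), nrow = 3, byrow = FALSE,
                 dimnames = list(c("at4", "mid", "hi"), c("c1", "c2")))
  logm["at4", ] <- c(4, 4)       # exactly 4 everywhere -> excluded
  logm["mid", ] <- c(0, 4.01)
  logm["hi", ] <- c(6, 0)
  expect_setequal(expressed_genes(logm), c("mid", "hi"))
  ## all-zero matrix -> empty
  z <- matrix(0, 3, 2, dimnames = list(c("a", "b", "c"), c("x", "y")))
  expect_length(expressed_genes(z), 0L)
  ## min_cells raises the bar
  expect_setequal(expressed_genes(logm, min_cells = 2), character(0))
})

test_that("planted on-genes are exactly the expressed set", {
  n_bg <- 450
  logm <- with_seed(31, {
    m <- matrix(abs(rnorm(500 * 10, 0.5, 0.5)),
                nrow = 500,
                dimnames = list(sprintf("G%03d", 1:500),
                                sprintf("c%02d", 1:10)))
    on <- sample(500, 50)
    m[on, 3] <- 6
    attr(m, "on") <- rownames(m)[sort(on)]
    m
  })
  expect_setequal(expressed_genes(logm), attr(logm, "on"))
})

test_that("matrix TSV round trip", {
  m <- matrix(c(1.5, 0, 2.25, 7), nrow = 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, f)
  expect_equal(read_matrix_tsv(f), m)
})

test_that("BED6 round trip converts coordinates correctly", {
  r <- aligned_reads(c("chr1", "ERCC-00002"), c("+", "-"),
                     c(100, 7), c(149, 56), c("a", "b"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed_reads(r, f)
  back <- read_bed_reads(f)
  expect_equal(back$start, r$start)
  expect_equal(back$end, r$end)
  expect_identical(back$cell_id, r$cell_id)
})
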