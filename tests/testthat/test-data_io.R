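test_that("10x Matrix-Market triplets are transposed to cells x genes on load", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 2", "2 2 5"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("AAAC", "TTTG"), file.path(dir, "barcodes.tsv"))
  writeLines(c("ENSG1\tGENE1\tGene Expression",
               "ENSG2\tGENE2\tGene Expression",
               "ENSG3\tGENE3\tGene Expression"),
             file.path(dir, "features.tsv"))
  cm <- read_counts(dir, "mtx10x")
  expect_equal(dim(cm), c(2L, 3L))
  expect_equal(cm$cell_ids, c("AAAC", "TTTG"))
  expect_equal(cm$gene_names, c("GENE1", "GENE2", "GENE3"))
  m <- as.matrix(cm$values)
  expect_equal(unname(m), rbind(c(2, 0, 0), c(0, 5, 0)))
})

test_that("an all-zero CSV round-trips with its identifiers", {
  f <- withr::local_tempfile(fileext = ".csv")
  cm <- count_matrix(matrix(0, 4, 3), cell_ids = paste0("c", 1:4),
                     gene_names = paste0("g", 1:3))
  write_counts(cm, f, "csv")
  back <- read_counts(f, "csv")
  expect_equal(as.matrix(back$values), as.matrix(cm$values))
  expect_equal(back$cell_ids, cm$cell_ids)
  expect_equal(back$gene_names, cm$gene_names)
})

test_that("read/write round trip is lossless in every supported format", {
  cm <- random_counts(50, 80, seed = 11)
  for (fmt in c("mtx10x", "csv", "h5")) {
    path <- if (fmt == "mtx10x") withr::local_tempdir() else {
      withr::local_tempfile(fileext = paste0(".", fmt))
    }
    write_counts(cm, path, fmt)
    back <- read_counts(path, fmt)
    expect_equal(as.matrix(back$values), as.matrix(cm$values),
                 info = fmt, ignore_attr = TRUE)
    expect_equal(back$cell_ids, cm$cell_ids, info = fmt)
    expect_equal(back$gene_names, cm$gene_names, info = fmt)
  }
})

test_that("writing an empty post-QC matrix still yields a readable file", {
  cm <- count_matrix(matrix(0, 0, 3), cell_ids = character(0),
                     gene_names = paste0("g", 1:3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_counts(cm, f, "csv")
  back <- read_counts(f, "csv")
  expect_equal(dim(back), c(0L, 3L))
})

test_that("identifier collisions are rejected with the duplicates named", {
  expect_error(count_matrix(matrix(0, 2, 2), cell_ids = c("a", "a")),
               "identifier collision.*a")
  expect_error(count_matrix(matrix(0, 2, 2), gene_names = c("g", "g")),
               "identifier collision")
  expect_error(count_matrix(matrix(-1, 2, 2)), "nonnegative")
  expect_error(count_matrix(matrix(0.5, 2, 2)), "integral")
})

test_that("duplicated 10x gene symbols are de-duplicated by suffixing", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 1 1", "1 1 3"), file.path(dir, "matrix.mtx"))
  writeLines("AAAC", file.path(dir, "barcodes.tsv"))
  writeLines(c("ENSG1\tDUP", "ENSG2\tDUP"), file.path(dir, "features.tsv"))
  expect_message(cm <- read_counts(dir, "mtx10x"), "de-duplicated")
  expect_equal(cm$gene_names, c("DUP", "DUP-1"))
})

test_that("cells at the expressed-gene boundary are filtered, not those above", {
  # cell 1: 199 expressed genes (removed); cells 2-3: 250 (kept)
  m <- matrix(0, 3, 500)
  m[1, 1:199] <- 1
  m[2, 1:250] <- 1
  m[3, 251:500] <- 1
  cm <- count_matrix(m)
  out <- qc_filter(cm, min_cells_per_gene = 1)
  expect_equal(out$cell_ids, c("cell_2", "cell_3"))
  expect_equal(out$meta$qc$cells_removed_low_coverage, 1)
})

test_that("high-mitochondrial-fraction cells are removed on raw counts", {
  m <- matrix(1, 3, 300) # every cell expresses 300 genes
  m[1, 1] <- 20          # cell 1: 21/319 mito = 6.6%
  cm <- count_matrix(m, gene_names = c("MT-ND1", "mt-co1",
                                       sprintf("G%03d", 3:300)))
  out <- qc_filter(cm, min_genes_per_cell = 10, min_cells_per_gene = 1)
  expect_equal(nrow(out$values), 2L)
  expect_equal(out$meta$qc$cells_removed_mito, 1)
})

test_that("QC matches a brute-force recount and is idempotent", {
  base <- random_counts(300, 500, density = 0.6, seed = 21)
  m <- as.matrix(base$values)
  withr::with_seed(22, {
    low <- sample(300, 20)    # planted low-coverage cells
    rare <- sample(500, 30)   # planted rare genes
    for (i in low) {
      keep <- sample(500, 150)
      row <- numeric(500); row[keep] <- pmax(m[i, keep], 1)
      m[i, ] <- row
    }
    for (j in rare) {
      cells <- sample(setdiff(1:300, low), 5)
      col <- numeric(300); col[cells] <- 1
      m[, j] <- col
    }
  })
  cm <- count_matrix(m, cell_ids = base$cell_ids, gene_names = base$gene_names)
  out <- qc_filter(cm, min_genes_per_cell = 200, min_cells_per_gene = 15)
  # independent brute-force pass
  keep_cells <- rowSums(m > 0) >= 200
  mm <- m[keep_cells, ]
  keep_genes <- colSums(mm > 0) >= 15
  expect_equal(nrow(out$values), sum(keep_cells))
  expect_equal(sum(keep_cells), 280L)
  expect_equal(ncol(out$values), sum(keep_genes))
  expect_equal(as.matrix(out$values), mm[, keep_genes], ignore_attr = TRUE)
  # idempotence and value preservation
  again <- qc_filter(out, min_genes_per_cell = 200, min_cells_per_gene = 15)
  expect_equal(as.matrix(again$values), as.matrix(out$values))
  expect_error(qc_filter(cm, min_genes_per_cell = 1000), "all cells")
})

test_that("two-column label files align to a cell ordering", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(cell_id = c("b", "a"), label = c("T", "B")),
                   f, row.names = FALSE)
  expect_equal(read_labels(f, cell_ids = c("a", "b")), c("B", "T"))
  expect_error(read_labels(f, cell_ids = c("a", "z")), "missing")
})
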