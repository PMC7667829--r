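test_that("a single aligned read produces unit depth in its bin", {
  sam <- write_test_sam(tempfile(fileext = ".sam"), c(c1 = 1000),
                        data.frame(contig = "c1", pos = 1, len = 100))
  tr <- load_depth(sam, bin_size = 100)
  expect_length(tr, 1)
  expect_equal(tr$c1$depths, c(1, rep(0, 9)))
  expect_equal(tr$c1$total_mapped, 1)
})

test_that("alignment coverage conserves mass and includes zero contigs", {
  set.seed(41)
  n <- 10000
  reads <- data.frame(contig = "big", pos = sample.int(100000 - 149, n,
                                                       replace = TRUE),
                      len = 150)
  sam <- write_test_sam(tempfile(fileext = ".sam"),
                        c(big = 100000, empty = 50000), reads)
  tr <- load_depth(sam, bin_size = 100)
  expect_equal(sum(tr$big$depths) * 100, n * 150)
  expect_true(all(tr$empty$depths == 0))
  expect_length(tr$empty$depths, 500)
})

test_that("per-base depth TSV is binned with a true-width partial last bin", {
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame("c", 1:250, 2), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tr <- load_depth(tsv, bin_size = 100, lengths = c(c = 250))
  expect_equal(tr$c$depths, c(2, 2, 2))
  expect_equal(length(tr$c$depths), 3)
})

test_that("unknown formats and unsorted alignments are rejected clearly", {
  bad <- tempfile()
  writeLines(c("only one field", "another"), bad)
  expect_error(load_depth(bad), "unknown format")
  sam <- write_test_sam(tempfile(fileext = ".sam"), c(c1 = 1000),
                        data.frame(contig = "c1", pos = 1, len = 100))
  txt <- sub("SO:coordinate", "SO:queryname", readLines(sam))
  sam2 <- tempfile(fileext = ".sam")
  writeLines(txt, sam2)
  bam <- Rsamtools::asBam(sam2, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE, sort = FALSE)
  expect_error(load_depth(bam, format = "bam"), "sort")
})

test_that("contig length filter keeps the 40 kbp boundary inclusive", {
  mk <- function(len) quick_track(numeric(ceiling(len / 100)),
                                  contig_length = len, contig_id = as.character(len))
  tr <- lapply(c(39999, 40000, 813000), mk)
  kept <- filter_contigs(tr)
  expect_equal(vapply(kept, `[[`, numeric(1), "contig_length"),
               c(40000, 813000))
  expect_equal(filter_contigs(list()), list())
})

test_that("contig filter matches brute force, is idempotent and monotone", {
  set.seed(7)
  lens <- round(runif(100, 10e3, 100e3))
  tr <- lapply(lens, function(L) quick_track(numeric(ceiling(L / 100)),
                                             contig_length = L,
                                             contig_id = paste0("c", L)))
  kept <- filter_contigs(tr)
  expect_length(kept, sum(lens >= 40000))
  expect_identical(filter_contigs(kept), kept)
  for (ml in c(20e3, 50e3, 80e3))
    expect_lte(length(filter_contigs(tr, ml + 10e3)),
               length(filter_contigs(tr, ml)))
})

test_that("normalization is per-million and preserves raw depths", {
  t1 <- quick_track(c(10, 20), total_mapped = 1e6)
  expect_equal(normalize_track(t1)$norm_depths, c(10, 20))
  t2 <- quick_track(c(10, 20), total_mapped = 2e6)
  n2 <- normalize_track(t2)
  expect_equal(n2$norm_depths, c(5, 10))
  expect_equal(n2$depths, c(10, 20))
  set.seed(1)
  t3 <- quick_track(runif(50, 1, 10), total_mapped = 3.7e5)
  n3 <- normalize_track(t3)
  expect_equal(length(unique(round(n3$norm_depths / n3$depths, 12))), 1)
  t0 <- quick_track(c(1, 2), total_mapped = 0)
  expect_error(normalize_track(t0), "total_mapped")
})

test_that("track pairing matches on contig id and reports strays", {
  mk <- function(id, src) quick_track(rep(1, 500), contig_id = id,
                                      source = src)
  expect_warning(p <- pair_tracks(list(mk("A", "whole"), mk("B", "whole")),
                                  list(mk("A", "vlp"))), "B")
  expect_named(p, "A")
  expect_warning(p2 <- pair_tracks(list(mk("A", "whole")),
                                   list(mk("C", "vlp"))), "A|C")
  expect_length(p2, 0)
  set.seed(2)
  ids <- paste0("n", 1:200)
  w <- lapply(ids, mk, src = "whole"); v <- lapply(ids, mk, src = "vlp")
  expect_length(pair_tracks(w, v), 200)
  vbad <- mk("A", "vlp"); vbad$bin_size <- 50L
  vbad$depths <- rep(1, 1000)
  expect_error(pair_tracks(list(mk("A", "whole")), list(vbad)), "bin_size")
})

test_that("bedGraph export merges runs and round-trips through load_depth", {
  tr <- quick_track(c(1, 1, 2))
  path <- tempfile(fileext = ".bedgraph")
  write_track(tr, path)
  expect_equal(readLines(path), c("t\t0\t200\t1", "t\t200\t300\t2"))
  z <- quick_track(rep(0, 10))
  write_track(z, path)
  expect_equal(readLines(path), "t\t0\t1000\t0")
  set.seed(3)
  r <- quick_track(round(runif(400, 0, 50)), contig_length = 39950)
  write_track(r, path)
  back <- load_depth(path, bin_size = 100, lengths = c(t = 39950))
  expect_equal(back$t$depths, r$depths, tolerance = 1e-9)
})

test_that("re-binning 25 bp tracks to 100 bp equals direct computation", {
  m <- genome_model(50e3, gta = gta_params(5000, n_fragments = 500))
  fr <- simulate_fragments(m, 500, seed = 5)
  t25 <- fragments_to_coverage(fr, bin_size = 25)
  t100 <- fragments_to_coverage(fr, bin_size = 100)
  expect_equal(rebin_track(t25, 100)$depths, t100$depths)
})
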