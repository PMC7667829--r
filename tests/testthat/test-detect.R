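test_that("contig baseline is the lower coverage envelope", {
  expect_equal(contig_baseline(quick_track(rep(10, 1000))), 10)
  mix <- quick_track(c(rep(1, 950), rep(10000, 50)))
  expect_equal(contig_baseline(mix), 1)
  expect_equal(contig_baseline(quick_track(rep(0, 500))), 0)
})

test_that("whole-community evenness flags chimera-like coverage", {
  even <- wgs_evenness(quick_track(rep(100, 2000), source = "whole"))
  expect_equal(even$cv, 0)
  expect_true(even$pass)
  chim <- wgs_evenness(quick_track(c(rep(10, 1000), rep(1000, 1000)),
                                   source = "whole"))
  expect_false(chim$pass)
  set.seed(10)
  pois <- wgs_evenness(quick_track(rpois(2000, 100), source = "whole"))
  expect_true(pois$pass)
})

test_that("change-point segmentation recovers piecewise-constant structure", {
  y <- c(rep(1, 1000), rep(100, 200), rep(1, 1000))
  segs <- segment_log_coverage(quick_track(y))
  expect_equal(nrow(segs), 3)
  expect_lte(abs(segs$start_bin[2] - 1001), 2)
  expect_lte(abs(segs$end_bin[2] - 1200), 2)
  expect_equal(nrow(segment_log_coverage(quick_track(rep(5, 800)))), 1)
})

test_that("segments always tile the contig", {
  set.seed(11)
  for (i in 1:5) {
    d <- rpois(1500, sample(c(1, 20, 400), 1)) *
      rep(sample(c(1, 1, 50), 5, replace = TRUE), each = 300)
    tr <- quick_track(d, contig_length = 150000 - sample(0:99, 1))
    segs <- segment_log_coverage(tr)
    expect_equal(segs$start[1], 0)
    expect_equal(segs$end[nrow(segs)], tr$contig_length)
    if (nrow(segs) > 1)
      expect_equal(segs$start[-1], segs$end[-nrow(segs)])
  }
})

test_that("edge sharpness measures the fold across a boundary", {
  step <- quick_track(c(rep(1, 500), rep(100, 500)))
  expect_equal(as.numeric(edge_sharpness(step, 50000, 500)), 100)
  expect_equal(as.numeric(edge_sharpness(step, 50000 - 2000, 500)), 1)
  ramp <- quick_track(seq(100, 200, length.out = 500))
  expect_lt(as.numeric(edge_sharpness(ramp, 25000, 500)), 1.1)
  at_end <- edge_sharpness(step, 99900, 500)
  expect_true(attr(at_end, "truncated"))
  expect_true(is.finite(as.numeric(at_end)))
})

test_that("decay slopes match the geometric staircase analytically", {
  d <- seq(0, 399999, by = 100)
  stair <- quick_track(1000 * 0.5^floor(d / 40000))
  fit <- fit_decay_slope(stair, c(0, 400000))
  expect_equal(fit$slope, -0.25, tolerance = 0.05)  # log2(0.5) per 40 kbp
  expect_gt(fit$r2, 0.9)
  flat <- fit_decay_slope(quick_track(rep(50, 500)), c(0, 50000))
  expect_equal(flat$slope, 0, tolerance = 1e-9)
  expo <- quick_track(100 * 2^(-(seq_len(1000) - 0.5) / 100))
  fe <- fit_decay_slope(expo, c(0, 100000))
  expect_gt(fe$r2, 0.999)
  expect_equal(fit_decay_slope(quick_track(rep(0, 100)), c(0, 10000))$flag,
               "all_zero")
})

test_that("pac sites are called on staircases but not flat tracks", {
  expect_length(call_pac_sites(quick_track(rep(7, 3000))), 0)
  m <- genome_model(3e5, pac_sites = list(
    pac_site(120e3, rate = 1000, headful = 44000, q = 0.6)))
  ec <- expected_coverage(m)
  ec$total_mapped <- 1e6
  pacs <- call_pac_sites(ec)
  expect_length(pacs, 1)
  expect_lte(abs(pacs - 120e3), 100)
})

test_that("headful size is recovered from staircases and flagged otherwise", {
  d <- seq(0, 399999, by = 100)
  stair <- quick_track(1000 * 0.5^floor(d / 40000))
  H <- estimate_headful_size(stair, c(0, 400000))
  expect_lte(abs(H - 40000), 100)
  flat <- estimate_headful_size(quick_track(rep(10, 2000)))
  expect_true(is.na(flat))
  expect_equal(attr(flat, "flag"), "no_periodicity")
})

test_that("transduction frequency is the plateau:flank coverage ratio", {
  expect_equal(estimate_transduction_frequency(10000, 1), 10000)
  expect_equal(estimate_transduction_frequency(55, 55), 1)
  expect_warning(n <- estimate_transduction_frequency(100, 0), "undefined")
  expect_true(is.na(n))
})

test_that("unevenness is 1 for flat tracks and ordered across fixtures", {
  expect_equal(unevenness_ratio(quick_track(rep(9, 2000))), 1)
  p1 <- make_fixture("p1_like", seed = 31)
  p22 <- make_fixture("p22_like", seed = 31)
  u1 <- unevenness_ratio(p1$pairs[[1]]$vlp)
  u22 <- unevenness_ratio(p22$pairs[[1]]$vlp)
  expect_lte(u1, 10)
  expect_lt(u1, u22)
})

test_that("a lambda-like contig is classified specialized with ~25 kbp flanks", {
  fx <- make_fixture("lambda_like", seed = 13)
  cl <- call_patterns(fx$pairs[[1]])
  expect_equal(cl$mode, "specialized")
  expect_lte(abs(cl$primary[1] - 125000), 200)
  expect_lte(abs(cl$primary[2] - 173500), 200)
  expect_length(cl$flanks, 2)
  for (fl in cl$flanks)
    expect_true(fl$extent > 15000 && fl$extent < 30000)
  expect_gt(cl$frequency_ratio, 5000)
  expect_lt(cl$frequency_ratio, 20000)
})

test_that("flat low VLP coverage over even WGS is standard", {
  set.seed(14)
  pr <- quick_pair(rpois(2000, 100), rpois(2000, 0.3))
  cl <- call_patterns(pr)
  expect_equal(cl$mode, "standard")
  expect_false("wgs_uneven" %in% cl$qc)
})

test_that("classification is invariant to joint rescaling of a sample", {
  fx <- make_fixture("lambda_like", seed = 15)
  p <- fx$pairs[[1]]
  base <- call_patterns(p)
  for (c0 in c(5, 0.9)) {
    p2 <- p
    for (side in c("wgs", "vlp")) {
      p2[[side]]$depths <- p[[side]]$depths * c0
      p2[[side]]$total_mapped <- p[[side]]$total_mapped * c0
    }
    cl <- call_patterns(p2)
    expect_equal(cl$mode, base$mode)
    expect_equal(cl$primary, base$primary)
    expect_equal(cl$frequency_ratio, base$frequency_ratio, tolerance = 0.01)
  }
})

test_that("lateral transduction is called with the truncation flag", {
  fx <- make_fixture("faecalis_like", seed = 16)
  cl <- call_patterns(fx$pairs[[1]])
  expect_equal(cl$mode, "lateral")
  expect_equal(cl$frequency_ratio, 240, tolerance = 0.5)
  expect_gte(cl$flanks$right$extent, 1e5)
  expect_true("truncated_at_end" %in% cl$qc)
  expect_true(is.null(cl$flanks$left))
})

test_that("call intervals always lie within the contig", {
  fx <- make_fixture("community_like", seed = 17)
  calls <- call_patterns_all(fx$pairs)
  for (cl in calls) {
    L <- fx$pairs[[cl$contig_id]]$wgs$contig_length
    if (!is.null(cl$primary))
      expect_true(cl$primary[1] >= 0 && cl$primary[2] <= L)
    if (length(cl$pac_positions))
      expect_true(all(cl$pac_positions >= 0 & cl$pac_positions <= L))
    for (fl in cl$flanks)
      expect_true(fl$interval[1] >= 0 && fl$interval[2] <= L)
  }
})
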