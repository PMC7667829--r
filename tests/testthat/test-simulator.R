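test_that("GTA-only packaging emits fixed-size fragments with full mass", {
  m <- genome_model(1e5, circular = TRUE,
                    gta = gta_params(13000, n_fragments = 1000))
  fr <- simulate_fragments(m, 1000, seed = 1)
  expect_equal(nrow(fr), 1000)
  expect_true(all(fr$end - fr$start == 13000))
  expect_equal(sum(fr$end - fr$start), 13e6)
  cov <- fragments_to_coverage(fr)
  expect_equal(sum(cov$depths) * 100, 13e6)   # mass conservation, wrapped
})

test_that("headful indices follow the geometric continuation law", {
  q <- 0.5; H <- 40000
  m <- genome_model(2e6, circular = TRUE,
                    pac_sites = list(pac_site(0, rate = 1, headful = H,
                                              q = q)))
  n <- 10000
  fr <- simulate_fragments(m, n, seed = 2)
  k <- fr$start / H + 1
  for (j in 1:5) {
    p <- q^(j - 1) * (1 - q)
    expect_lt(abs(sum(k == j) - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
  }
})

test_that("a prophage without imprecise excision packages only itself", {
  m <- genome_model(2e5, prophages = list(
    prophage_element(50e3, 90e3, induction_rate = 1, f_spec = 0)))
  fr <- simulate_fragments(m, 500, seed = 3)
  expect_true(all(fr$start == 50e3 & fr$end == 90e3))
  expect_true(all(fr$mode == "induction"))
})

test_that("fragment coverage handles simple, wrapped and random cases", {
  one <- data.frame(start = 0, end = 1000, mode = "x", element = "e")
  cov <- fragments_to_coverage(one, bin_size = 100, genome_length = 2000,
                               circular = FALSE)
  expect_equal(cov$depths, c(rep(1, 10), rep(0, 10)))

  wrap <- data.frame(start = 9500, end = 10500, mode = "x", element = "e")
  cw <- fragments_to_coverage(wrap, bin_size = 100, genome_length = 10000,
                              circular = TRUE)
  expect_equal(cw$depths, c(rep(1, 5), rep(0, 90), rep(1, 5)))

  ## brute-force per-base overlap oracle
  set.seed(4)
  L <- 10000
  s <- sample.int(L, 200, replace = TRUE) - 1
  len <- sample(50:400, 200, replace = TRUE)
  fr <- data.frame(start = s, end = pmin(s + len, L), mode = "x",
                   element = "e")
  per_base <- numeric(L)
  for (i in seq_len(nrow(fr)))
    per_base[(fr$start[i] + 1):fr$end[i]] <-
      per_base[(fr$start[i] + 1):fr$end[i]] + 1
  oracle <- colMeans(matrix(per_base, nrow = 100))
  got <- fragments_to_coverage(fr, bin_size = 100, genome_length = L,
                               circular = FALSE)
  expect_equal(got$depths, oracle)
})

test_that("closed-form expected coverage reproduces the headful decay", {
  m <- genome_model(2e5, pac_sites = list(
    pac_site(0, rate = 1000, headful = 40000, q = 0.5)))
  ec <- expected_coverage(m)          # natural scale: rate = initiations
  expect_equal(ec$depths[1001], 1000 * 0.5^2)   # position 100 kbp
  expect_equal(ec$depths[1], 1000)
  ## non-increasing, constant within each headful window
  expect_true(all(diff(ec$depths) <= 1e-9))
  expect_equal(length(unique(round(ec$depths[1:400], 6))), 1)
})

test_that("specialized plateau:flank ratio follows the configured side split", {
  base <- function(side) genome_model(3e5, prophages = list(
    prophage_element(125e3, 173500, induction_rate = 1, f_spec = 1e-4,
                     capsid = 48500, min_retained = 23500,
                     side_bias = side)))
  two <- expected_coverage(base(0.5), bin_size = 100)
  plateau <- two$depths[1500]                 # mid-prophage
  flank <- two$depths[1736]                   # first bin right of the edge
  expect_equal(plateau / flank, 20000, tolerance = 0.01)
  one <- expected_coverage(base(0), bin_size = 100)   # right-side only
  expect_equal(one$depths[1500] / one$depths[1736], 10000,
               tolerance = 0.01)
})

test_that("an empty model yields an all-zero expected track", {
  m <- genome_model(5e4)
  ec <- expected_coverage(m)
  expect_true(all(ec$depths == 0))
  expect_error(simulate_fragments(m, 10), "emitters")
})

test_that("whole-community tracks honour gradient and noise settings", {
  t1 <- simulate_wgs_track(1e5, mean_depth = 50, ori_gradient = 1,
                           noise = FALSE)
  expect_true(all(t1$depths == 50))
  m <- genome_model(1e6, circular = TRUE, ori_position = 50)
  t2 <- simulate_wgs_track(m, mean_depth = 100, ori_gradient = 2,
                           noise = FALSE)
  expect_equal(max(t2$depths) / min(t2$depths), 2, tolerance = 1e-3)
  t3 <- simulate_wgs_track(5e5, mean_depth = 100, noise = TRUE, seed = 6)
  expect_equal(var(t3$depths) / mean(t3$depths), 1, tolerance = 0.15)
})

test_that("identical model, n and seed give identical fragment sets", {
  m <- all_modes_model()
  a <- simulate_fragments(m, 5000, seed = 99)
  b <- simulate_fragments(m, 5000, seed = 99)
  expect_identical(a, b)
  c <- simulate_fragments(m, 5000, seed = 100)
  expect_false(identical(a, c))
})

test_that("sampled coverage converges to the closed form (all modes)", {
  ## smoke-scale version of the acceptance check
  m <- all_modes_model(circular = FALSE)
  n <- 30000
  mc <- fragments_to_coverage(simulate_fragments(m, n, seed = 8))
  ec <- expected_coverage(m, n_particles = n)
  sel <- ec$depths >= 10
  z <- (mc$depths[sel] - ec$depths[sel]) / sqrt(ec$depths[sel])
  expect_lt(max(abs(z)), 5)
})

test_that("GTA coverage with a flat bias is uniform in expectation", {
  m <- genome_model(4e5, circular = TRUE,
                    gta = gta_params(13000, n_fragments = 1))
  ec <- expected_coverage(m, n_particles = 50000)
  expect_equal(max(ec$depths) / min(ec$depths), 1, tolerance = 1e-9)
  mc <- fragments_to_coverage(simulate_fragments(m, 50000, seed = 9))
  sm <- with(mc, stats::filter(depths, rep(1 / 100, 100), circular = TRUE))
  expect_lt(max(sm, na.rm = TRUE) / min(sm, na.rm = TRUE), 1.25)
})

test_that("preset fixtures carry their configured truths", {
  p22 <- make_fixture("p22_like", seed = 1)
  expect_true(length(strsplit(p22$truth$pac_positions, ";")[[1]]) %in% 5:6)
  expect_equal(p22$truth$headful_bp, 44000)
  lam <- make_fixture("lambda_like", seed = 1)
  expect_equal(lam$truth$frequency_ratio, 10000)
  null_comm <- make_fixture("community_like", seed = 1,
                            overrides = list(rate_scale = 0))
  expect_true(all(null_comm$truth$mode == "standard"))
  expect_gte(length(null_comm$pairs), 50)
  expect_error(make_fixture("nope"), "unknown fixture")
})
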