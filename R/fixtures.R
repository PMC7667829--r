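#' Ground-truthed synthetic fixtures
#'
#' Builds paired whole-community/VLP coverage for one of the preset packaging
#' systems, together with truth labels for detector validation. Presets
#' (parameterized in `inst/extdata/fixtures.yaml`):
#' \describe{
#'   \item{lambda_like}{one contig with an induced prophage and two ~25 kbp
#'     specialized-transduction flanks at a 1:10,000 frequency per side.}
#'   \item{p22_like}{a generalized transducer: six pac-like sites, 44 kbp
#'     headful, processive staircases.}
#'   \item{p1_like}{quasi-random packaging with low (<10x) unevenness.}
#'   \item{pbsx_like}{GTA-like packaging of 13 kbp fragments with a bias
#'     field calibrated to a 30-fold smoothed max/min coverage ratio.}
#'   \item{faecalis_like}{an induced prophage with one-sided lateral
#'     transduction at 1:240.}
#'   \item{community_like}{>= 50 contigs (40-800 kbp) mixing all modes with
#'     standard contigs and seeded cellular-contamination contigs.}
#' }
#'
#' @param name Fixture name.
#' @param seed RNG seed: identical name/seed give identical fixtures.
#' @param bin_size Bin width in bp (default from the YAML config).
#' @param overrides Named list merged over the preset's YAML parameters.
#' @return A list with `pairs` (named list of `paired_coverage`), `truth`
#'   (data.frame: contig, mode, frequency_ratio, pac_positions, headful_bp,
#'   contaminant, seed), and `models` (the `genome_model` objects used).
#' @export
make_fixture <- function(name, seed = 1, bin_size = NULL,
                         overrides = list()) {
  cfg_all <- yaml::read_yaml(system.file("extdata", "fixtures.yaml",
                                         package = "transductr",
                                         mustWork = TRUE))
  if (!name %in% names(cfg_all$fixtures))
    stop("make_fixture: unknown fixture '", name, "' (have: ",
         paste(names(cfg_all$fixtures), collapse = ", "), ")")
  cfg <- utils::modifyList(cfg_all$fixtures[[name]], overrides)
  bs <- bin_size %||% cfg_all$bin_size
  rl <- cfg_all$read_length
  out <- switch(name,
    lambda_like = fixture_lambda(cfg, seed, bs),
    p22_like = fixture_p22(cfg, seed, bs),
    p1_like = fixture_gta(cfg, seed, bs, calibrate = FALSE,
                          mode = "gta_like"),
    pbsx_like = fixture_gta(cfg, seed, bs, calibrate = TRUE,
                            mode = "gta_like"),
    faecalis_like = fixture_faecalis(cfg, seed, bs),
    community_like = fixture_community(cfg, seed, bs))
  out$truth$seed <- seed
  out$pairs <- finalize_sample(out$pairs, rl)
  out
}

## Set each sample's total_mapped to the whole-sample read count implied by
## its coverage mass, identical across the sample's tracks.
finalize_sample <- function(pairs, read_length) {
  mass <- function(tr) mean(tr$depths) * tr$contig_length
  tw <- max(1, round(sum(vapply(pairs, function(p) mass(p$wgs),
                                numeric(1))) / read_length))
  tv <- max(1, round(sum(vapply(pairs, function(p) mass(p$vlp),
                                numeric(1))) / read_length))
  for (i in seq_along(pairs)) {
    pairs[[i]]$wgs$total_mapped <- tw
    pairs[[i]]$vlp$total_mapped <- tv
  }
  pairs
}

pair_of <- function(id, wgs, vlp) {
  wgs$contig_id <- id; vlp$contig_id <- id
  structure(list(contig_id = id, wgs = wgs, vlp = vlp),
            class = "paired_coverage")
}

truth_row <- function(contig, mode, frequency_ratio = NA_real_,
                      pac_positions = "", headful_bp = NA_real_,
                      contaminant = FALSE) {
  data.frame(contig = contig, mode = mode,
             frequency_ratio = frequency_ratio,
             pac_positions = pac_positions, headful_bp = headful_bp,
             contaminant = contaminant, stringsAsFactors = FALSE)
}

fixture_lambda <- function(cfg, seed, bs) {
  pr <- cfg$prophage
  model <- genome_model(cfg$contig_length, circular = cfg$circular,
    prophages = list(prophage_element(pr$start, pr$end,
      induction_rate = pr$induction_rate, f_spec = pr$f_spec,
      capsid = pr$capsid, min_retained = pr$min_retained,
      side_bias = pr$side_bias)))
  id <- "lambda_contig"
  fr <- simulate_fragments(model, cfg$n_particles, seed = seed)
  vlp <- fragments_to_coverage(fr, bin_size = bs, contig_id = id)
  wgs <- simulate_wgs_track(model, mean_depth = cfg$wgs_mean_depth,
                            seed = seed + 1, bin_size = bs, contig_id = id)
  ## per-side frequency: plateau / (f_spec * side share)
  n_ratio <- 1 / (pr$f_spec * max(pr$side_bias, 1 - pr$side_bias))
  list(pairs = setNames(list(pair_of(id, wgs, vlp)), id),
       truth = truth_row(id, "specialized", frequency_ratio = n_ratio),
       models = list(model))
}

fixture_p22 <- function(cfg, seed, bs) {
  sites <- lapply(cfg$pac_positions, function(p)
    pac_site(p, rate = 1, headful = cfg$headful, q = cfg$q))
  model <- genome_model(cfg$genome_length, circular = cfg$circular,
                        pac_sites = sites)
  id <- "p22_host_contig"
  fr <- simulate_fragments(model, cfg$n_particles, seed = seed)
  vlp <- fragments_to_coverage(fr, bin_size = bs, contig_id = id)
  wgs <- simulate_wgs_track(model, mean_depth = cfg$wgs_mean_depth,
                            seed = seed + 1, bin_size = bs, contig_id = id)
  list(pairs = setNames(list(pair_of(id, wgs, vlp)), id),
       truth = truth_row(id, "generalized",
                         pac_positions = paste(cfg$pac_positions,
                                               collapse = ";"),
                         headful_bp = cfg$headful),
       models = list(model))
}

## GTA-like fixtures; for pbsx_like the bias field is calibrated so the
## 10 kbp-smoothed expected coverage has exactly the configured max/min fold.
fixture_gta <- function(cfg, seed, bs, calibrate, mode) {
  L <- cfg$genome_length
  build <- function(fold) {
    field <- make_bias_field(L, fold = fold, corr_length = cfg$bias_corr,
                             seed = seed + 7)
    genome_model(L, circular = cfg$circular,
                 gta = gta_params(fragment_size = cfg$fragment_size,
                                  n_fragments = cfg$n_fragments,
                                  bias_field = field))
  }
  target <- cfg$bias_fold
  fold <- target
  model <- build(fold)
  if (calibrate) {
    for (it in 1:3) {
      ec <- expected_coverage(model, bin_size = bs)
      sm <- runmean(ec$depths, 10000 / bs)
      r <- max(sm) / min(sm)
      fold <- fold^(log(target) / log(r))
      model <- build(fold)
    }
  }
  id <- paste0(mode, "_contig")
  fr <- simulate_fragments(model, cfg$n_fragments, seed = seed)
  vlp <- fragments_to_coverage(fr, bin_size = bs, contig_id = id)
  wgs <- simulate_wgs_track(model, mean_depth = cfg$wgs_mean_depth,
                            ori_gradient = cfg$ori_gradient %||% 1,
                            seed = seed + 1, bin_size = bs, contig_id = id)
  list(pairs = setNames(list(pair_of(id, wgs, vlp)), id),
       truth = truth_row(id, mode), models = list(model))
}

fixture_faecalis <- function(cfg, seed, bs) {
  pr <- cfg$prophage
  model <- genome_model(cfg$contig_length, circular = cfg$circular,
    prophages = list(prophage_element(pr$start, pr$end,
      induction_rate = pr$induction_rate, f_spec = pr$f_spec,
      lateral_rate = pr$induction_rate / pr$lateral_ratio, q = pr$q,
      lateral_direction = pr$lateral_direction)))
  id <- "faecalis_contig"
  fr <- simulate_fragments(model, cfg$n_particles, seed = seed)
  vlp <- fragments_to_coverage(fr, bin_size = bs, contig_id = id)
  wgs <- simulate_wgs_track(model, mean_depth = cfg$wgs_mean_depth,
                            seed = seed + 1, bin_size = bs, contig_id = id)
  list(pairs = setNames(list(pair_of(id, wgs, vlp)), id),
       truth = truth_row(id, "lateral", frequency_ratio = pr$lateral_ratio),
       models = list(model))
}

fixture_community <- function(cfg, seed, bs) {
  with_seed(seed, {
    specs <- community_specs(cfg)
    built <- lapply(seq_len(nrow(specs)), function(i)
      build_community_contig(specs[i, ], cfg, bs))
    pairs <- setNames(lapply(built, `[[`, "pair"),
                      vapply(built, function(b) b$pair$contig_id, ""))
    truth <- do.call(rbind, lapply(built, `[[`, "truth"))
    models <- lapply(built, `[[`, "model")
  })
  list(pairs = pairs, truth = truth, models = models)
}

community_specs <- function(cfg) {
  kinds <- c(rep("standard", cfg$n_standard),
             rep("dominant", cfg$n_dominant),
             rep("contamination", cfg$n_contamination),
             rep("induction", cfg$n_induction),
             rep("island", cfg$n_island),
             rep("specialized", cfg$n_specialized),
             rep("lateral", cfg$n_lateral),
             rep("generalized", cfg$n_generalized),
             rep("gta", cfg$n_gta))
  n <- length(kinds)
  len_range <- list(standard = c(40e3, 500e3), dominant = c(100e3, 400e3),
                    contamination = c(150e3, 400e3),
                    induction = c(150e3, 400e3), island = c(150e3, 300e3),
                    specialized = c(250e3, 450e3), lateral = c(400e3, 600e3),
                    generalized = c(450e3, 800e3), gta = c(250e3, 400e3))
  L <- vapply(kinds, function(k) {
    r <- len_range[[k]]; round(runif(1, r[1], r[2]) / 100) * 100
  }, numeric(1))
  wgs_mean <- ifelse(kinds %in% c("dominant", "contamination"),
                     rlnorm(n, log(cfg$dominant_wgs_mean), 0.25),
                     rlnorm(n, log(cfg$wgs_mean), cfg$wgs_sdlog))
  data.frame(contig = sprintf("NODE_%03d", seq_len(n)), kind = kinds,
             length = L, wgs_mean = wgs_mean, stringsAsFactors = FALSE)
}

build_community_contig <- function(sp, cfg, bs) {
  L <- sp$length
  id <- sp$contig
  rs <- cfg$rate_scale
  model <- NULL
  truth <- truth_row(id, "standard")
  if (sp$kind %in% c("induction", "island") && rs > 0) {
    depth <- cfg$induction_depth * runif(1, 0.7, 1.5) * rs
    if (sp$kind == "island") {
      ilen <- round(runif(1, 10e3, 18e3) / 100) * 100
      s <- round(runif(1, 50e3, L - 50e3 - ilen) / 100) * 100
      model <- genome_model(L, islands = list(
        island_element(s, s + ilen, hijack_rate = depth)))
    } else {
      plen <- round(runif(1, 35e3, 45e3) / 100) * 100
      s <- round(runif(1, 50e3, L - 50e3 - plen) / 100) * 100
      model <- genome_model(L, prophages = list(
        prophage_element(s, s + plen, induction_rate = depth)))
    }
    truth <- truth_row(id, "induction")
  } else if (sp$kind == "specialized" && rs > 0) {
    depth <- cfg$element_depth * runif(1, 0.7, 1.3) * rs
    plen <- 40e3
    s <- round(runif(1, 60e3, L - 60e3 - plen) / 100) * 100
    model <- genome_model(L, prophages = list(
      prophage_element(s, s + plen, induction_rate = depth,
                       f_spec = 2 / cfg$spec_ratio, capsid = plen,
                       min_retained = 15e3, side_bias = 0.5)))
    truth <- truth_row(id, "specialized", frequency_ratio = cfg$spec_ratio)
  } else if (sp$kind == "lateral" && rs > 0) {
    depth <- cfg$element_depth * runif(1, 0.7, 1.3) * rs
    plen <- 40e3
    s <- round(runif(1, 60e3, 100e3) / 100) * 100
    model <- genome_model(L, prophages = list(
      prophage_element(s, s + plen, induction_rate = depth,
                       lateral_rate = depth / cfg$lateral_ratio,
                       q = cfg$q_lateral, lateral_direction = "right")))
    truth <- truth_row(id, "lateral", frequency_ratio = cfg$lateral_ratio)
  } else if (sp$kind == "generalized" && rs > 0) {
    npac <- if (L >= 640e3) 3L else 2L   # keep sites >= ~190 kbp apart
    pos <- round(seq(100e3, L - 150e3, length.out = npac) / 100) * 100
    sites <- lapply(pos, function(p)
      pac_site(p, rate = cfg$pac_depth * rs, headful = cfg$headful,
               q = cfg$q_pac))
    model <- genome_model(L, pac_sites = sites)
    truth <- truth_row(id, "generalized",
                       pac_positions = paste(pos, collapse = ";"),
                       headful_bp = cfg$headful)
  } else if (sp$kind == "gta" && rs > 0) {
    nfr <- round(cfg$gta_depth * rs * L / 13000)
    field <- make_bias_field(L, fold = cfg$gta_bias_fold,
                             corr_length = 80e3)
    ## circular: GTA packaging acts on the whole replicon, so the contig
    ## sees no artificial coverage falloff at its ends
    model <- genome_model(L, circular = TRUE,
                          gta = gta_params(fragment_size = 13000,
                                           n_fragments = nfr,
                                           bias_field = field))
    truth <- truth_row(id, "gta_like")
  }

  nb <- n_bins_for(L, bs)
  if (!is.null(model)) {
    totw <- sum(vapply(emitters_of(model), `[[`, numeric(1), "weight"))
    fr <- simulate_fragments(model, max(1, round(totw)))
    vdep <- fragments_to_coverage(fr, bin_size = bs, contig_id = id)$depths
  } else vdep <- numeric(nb)
  if (sp$kind == "contamination") {
    vdep <- vdep + rpois(nb, cfg$contam_fraction * sp$wgs_mean)
    truth <- truth_row(id, "standard", contaminant = TRUE)
  } else {
    vdep <- vdep + rpois(nb, cfg$noise_rate)
  }
  vlp <- coverage_track(id, L, vdep, bin_size = bs, source = "vlp")
  wgs <- coverage_track(id, L, rpois(nb, sp$wgs_mean), bin_size = bs,
                        source = "whole")
  list(pair = pair_of(id, wgs, vlp), truth = truth, model = model)
}
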