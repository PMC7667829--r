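## Mechanistic simulator of DNA packaging into VLPs.
##
## Every packaging mechanism is an "emitter" with a weight proportional to
## the expected number of particles it produces. Headful emitters (pac sites,
## lateral packaging) are weighted by rate/(1-q): `rate` is the expected
## number of packaging initiations and each initiation yields 1/(1-q)
## particles on average (first headful always packaged, each next with
## probability q). With that weighting the closed-form expected coverage at
## distance d downstream of a site is rate * q^floor(d/H).

emitters_of <- function(model) {
  em <- list()
  for (i in seq_along(model$prophages)) {
    p <- model$prophages[[i]]
    if (p$induction_rate > 0)
      em[[length(em) + 1]] <- list(type = "induced", weight = p$induction_rate,
                                   el = p, id = paste0("prophage_", i))
    if (p$lateral_rate > 0)
      em[[length(em) + 1]] <- list(type = "lateral",
                                   weight = p$lateral_rate / (1 - p$q),
                                   el = p, id = paste0("prophage_", i))
  }
  for (i in seq_along(model$pac_sites)) {
    s <- model$pac_sites[[i]]
    if (s$rate > 0)
      em[[length(em) + 1]] <- list(type = "pac", weight = s$rate / (1 - s$q),
                                   el = s, id = paste0("pac_", i))
  }
  for (i in seq_along(model$islands)) {
    isl <- model$islands[[i]]
    if (isl$hijack_rate > 0)
      em[[length(em) + 1]] <- list(type = "island", weight = isl$hijack_rate,
                                   el = isl, id = paste0("island_", i))
  }
  if (!is.null(model$gta) && model$gta$n_fragments > 0)
    em[[length(em) + 1]] <- list(type = "gta",
                                 weight = model$gta$n_fragments,
                                 el = model$gta, id = "gta")
  em
}

## Per-base GTA start probabilities (sums to 1 over the genome).
gta_start_prob <- function(gta, L) {
  if (is.null(gta$bias_field)) b <- rep(1, L)
  else b <- rep(gta$bias_field, each = gta$bias_bin, length.out = L)
  if (!is.null(gta$self_exclusion)) {
    se <- gta$self_exclusion
    idx <- seq.int(se[1] + 1, se[2])
    b[idx] <- b[idx] * gta$self_exclusion_factor
  }
  b / sum(b)
}

#' Simulate packaged DNA fragments
#'
#' Draws `n_particles` packaged-DNA intervals from a [genome_model()]. Each
#' particle is one of: an induced-prophage particle (the exact prophage
#' interval), an imprecise-excision (specialized) particle spanning one
#' prophage edge, a lateral or generalized headful (the k-th headful downwind
#' of an initiation site, with k-1 geometric), an island-hijack particle, or
#' a GTA fragment of fixed size. On circular genomes fragments wrap the
#' origin (represented with `end > genome_length`); on linear genomes they
#' truncate at the ends.
#'
#' @param model A [genome_model()].
#' @param n_particles Number of particles to draw.
#' @param seed Optional RNG seed (identical inputs and seed give identical
#'   output).
#' @return A `fragment_set`: data.frame with columns `start`, `end` (0-based
#'   half-open bp; `end` may exceed `genome_length` when wrapping), `mode`
#'   (provenance: induction/specialized/lateral/generalized/island/gta) and
#'   `element`; attributes `genome_length` and `circular`.
#' @export
simulate_fragments <- function(model, n_particles, seed = NULL) {
  stopifnot(inherits(model, "genome_model"), n_particles > 0)
  validate_genome_model(model)
  em <- emitters_of(model)
  if (!length(em)) stop("simulate_fragments: model has no active emitters")
  w <- vapply(em, `[[`, numeric(1), "weight")
  with_seed(seed, {
    counts <- as.vector(rmultinom(1, n_particles, prob = w))
    parts <- vector("list", length(em))
    for (j in seq_along(em)) {
      if (counts[j] == 0) next
      parts[[j]] <- emit_fragments(em[[j]], counts[j], model)
    }
    frags <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  })
  rownames(frags) <- NULL
  structure(frags, genome_length = model$genome_length,
            circular = model$circular,
            class = c("fragment_set", class(frags)))
}

emit_fragments <- function(emitter, n, model) {
  L <- model$genome_length
  circ <- model$circular
  el <- emitter$el
  out <- switch(emitter$type,
    induced = {
      spec <- rbinom(1, n, el$f_spec)
      base <- data.frame(start = rep(el$start, n - spec),
                         end = rep(el$end, n - spec),
                         mode = rep("induction", n - spec))
      if (spec > 0) {
        emax <- el$capsid - el$min_retained
        e <- ceiling(runif(spec) * emax)   # flank extent in {1..emax}
        left <- runif(spec) < el$side_bias
        s <- ifelse(left, el$start - e, el$end - (el$capsid - e))
        en <- ifelse(left, el$start + (el$capsid - e), el$end + e)
        base <- rbind(base, data.frame(start = s, end = en,
                                       mode = "specialized"))
      }
      base
    },
    lateral = {
      k <- rgeom(n, prob = 1 - el$q) + 1   # headful index, >= 1
      H <- el$capsid
      if (el$lateral_direction == "right") {
        s <- el$end + (k - 1) * H; en <- el$end + k * H
      } else {
        s <- el$start - k * H; en <- el$start - (k - 1) * H
      }
      data.frame(start = s, end = en, mode = "lateral")
    },
    pac = {
      k <- rgeom(n, prob = 1 - el$q) + 1
      H <- el$headful
      if (el$strand == "+") {
        s <- el$position + (k - 1) * H; en <- el$position + k * H
      } else {
        s <- el$position - k * H; en <- el$position - (k - 1) * H
      }
      data.frame(start = s, end = en, mode = "generalized")
    },
    island = data.frame(start = rep(el$start, n), end = rep(el$end, n),
                        mode = "island"),
    gta = {
      p <- gta_start_prob(el, L)
      s <- sample.int(L, n, replace = TRUE, prob = p) - 1
      data.frame(start = s, end = s + el$fragment_size, mode = "gta")
    })
  out$element <- emitter$id
  clip_fragments(out, L, circ)
}

## Linear genomes: truncate at the ends and drop empty fragments.
## Circular genomes: map start into [0, L); end may exceed L (wrap).
clip_fragments <- function(f, L, circular) {
  f$start <- round(f$start); f$end <- round(f$end)
  if (circular) {
    len <- f$end - f$start
    len <- pmin(len, L)
    f$start <- f$start %% L
    f$end <- f$start + len
  } else {
    f$start <- pmax(f$start, 0)
    f$end <- pmin(f$end, L)
    f <- f[f$end > f$start, , drop = FALSE]
  }
  f
}

#' Binned coverage of a set of packaged fragments
#'
#' Depth at a base is the number of fragments overlapping it; bins average
#' per-base depth, so mass conservation (sum of depth x width == total
#' packaged bases) holds exactly.
#'
#' @param fragments A `fragment_set` from [simulate_fragments()], or a
#'   data.frame with `start`/`end` columns.
#' @param genome_length,circular Genome geometry; defaults from the
#'   `fragment_set` attributes.
#' @param bin_size Bin width in bp.
#' @param total_mapped Value recorded in the track (default: number of
#'   fragments).
#' @return A [coverage_track()] with `source = "vlp"`.
#' @export
fragments_to_coverage <- function(fragments, bin_size = 100,
                                  genome_length = NULL, circular = NULL,
                                  contig_id = "sim", total_mapped = NULL) {
  genome_length <- genome_length %||% attr(fragments, "genome_length")
  circular <- circular %||% (attr(fragments, "circular") %||% FALSE)
  L <- as.integer(genome_length)
  s <- fragments$start; e <- fragments$end
  if (any(e > L)) {
    if (!circular) stop("fragments_to_coverage: fragment beyond linear end")
    wrap <- e > L
    s <- c(s, rep(0, sum(wrap)))
    e <- c(pmin(e, L), e[wrap] - L)
  }
  d <- tabulate(s + 1, nbins = L + 1) - tabulate(e + 1, nbins = L + 1)
  per_base <- cumsum(d)[seq_len(L)]
  coverage_track(contig_id, L, bin_means(per_base, bin_size),
                 bin_size = bin_size,
                 total_mapped = total_mapped %||% nrow(fragments),
                 source = "vlp")
}

#' Closed-form expected VLP coverage of a genome model
#'
#' Deterministic per-base expectation of the depth produced by
#' [simulate_fragments()], aggregated into bins. Contributions: induced
#' prophages give a plateau of height `induction_rate`; specialized flanks
#' decline linearly with the survival function of the uniform flank-extent
#' law; lateral and generalized headfuls give `rate * q^floor(d/H)` at
#' distance d downwind of the initiation site; islands give a plateau; GTA
#' packaging is the convolution of the start-rate field with a box of the
#' fragment size.
#'
#' @param model A [genome_model()].
#' @param n_particles Particle pool size the expectation is scaled to, or
#'   NULL (default) for the model's natural scale (total emitter weight), in
#'   which case each rate is in particles/initiations directly.
#' @param bin_size Bin width in bp.
#' @return A [coverage_track()] of expected depths (`source = "vlp"`).
#' @export
expected_coverage <- function(model, n_particles = NULL, bin_size = 100,
                              contig_id = "expected") {
  stopifnot(inherits(model, "genome_model"))
  validate_genome_model(model)
  L <- as.integer(model$genome_length)
  circ <- model$circular
  em <- emitters_of(model)
  if (!length(em))     # empty model: nothing is packaged
    return(coverage_track(contig_id, L,
                          numeric(n_bins_for(L, bin_size)),
                          bin_size = bin_size, total_mapped = 0,
                          source = "vlp"))
  totw <- sum(vapply(em, `[[`, numeric(1), "weight"))
  scale <- if (is.null(n_particles)) 1 else n_particles / totw
  ev <- numeric(L)
  ## pos0: 0-based positions (unique within one call), possibly outside [0, L)
  add <- function(pos0, val) {
    if (circ) pos0 <- pos0 %% L
    keep <- pos0 >= 0 & pos0 < L
    idx <- pos0[keep] + 1
    ev[idx] <<- ev[idx] + val[keep]
  }
  for (e in em) {
    el <- e$el
    w <- e$weight * scale
    if (e$type == "induced") {
      r_ind <- el$induction_rate * scale
      add(seq.int(el$start, el$end - 1), rep(r_ind * (1 - el$f_spec),
                                             el$end - el$start))
      if (el$f_spec > 0) {
        emax <- el$capsid - el$min_retained
        G <- el$capsid
        for (side in c("left", "right")) {
          sw <- if (side == "left") el$side_bias else 1 - el$side_bias
          if (sw == 0) next
          wgt <- r_ind * el$f_spec * sw
          d <- seq.int(0, min(emax, L) - 1)
          p_flank <- (emax - d) / emax
          dint <- seq.int(0, min(G, L) - 1)
          p_int <- pmin(1, pmax(0, (G - dint - 1) / emax))
          if (side == "right") {
            add(el$end + d, wgt * p_flank)
            add(el$end - 1 - dint, wgt * p_int)
          } else {
            add(el$start - 1 - d, wgt * p_flank)
            add(el$start + dint, wgt * p_int)
          }
        }
      }
    } else if (e$type %in% c("lateral", "pac")) {
      if (e$type == "lateral") {
        rate <- el$lateral_rate * scale
        H <- el$capsid
        origin <- if (el$lateral_direction == "right") el$end else el$start
        dirn <- if (el$lateral_direction == "right") 1 else -1
      } else {
        rate <- el$rate * scale
        H <- el$headful
        origin <- el$position
        dirn <- if (el$strand == "+") 1 else -1
      }
      q <- el$q
      ## span until the per-particle contribution is negligible
      kmax <- ceiling(log(1e-12) / log(q))
      span <- kmax * H
      if (circ) {
        ## fold wrapped laps onto the genome, one lap at a time
        d <- seq.int(0, L - 1)
        pos <- ((origin + dirn * d) %% L) + 1
        lap <- 0
        while (lap * L < span) {
          ev[pos] <- ev[pos] + rate * q^floor((d + lap * L) / H)
          lap <- lap + 1
        }
      } else {
        dmax <- if (dirn > 0) min(span, L - origin) else min(span, origin + 1)
        if (dmax >= 1) {
          d <- seq.int(0, dmax - 1)
          add(origin + dirn * d, rate * q^floor(d / H))
        }
      }
    } else if (e$type == "island") {
      add(seq.int(el$start, el$end - 1),
          rep(el$hijack_rate * scale, el$end - el$start))
    } else if (e$type == "gta") {
      p <- gta_start_prob(el, L)
      lam <- el$n_fragments * scale * p
      F_ <- as.integer(el$fragment_size)
      if (circ) {
        lam3 <- c(lam, lam)  # one wrap is enough when F <= L
        cs <- cumsum(lam3)
        y <- seq_len(L)
        hi <- cs[y + L]
        lo <- cs[y + L - min(F_, L)]
        ev <- ev + (hi - lo)
      } else {
        cs <- cumsum(lam)
        y <- seq_len(L)
        lo_idx <- pmax(y - F_, 0)
        ev <- ev + cs[y] - c(0, cs)[lo_idx + 1]
      }
    }
  }
  coverage_track(contig_id, L, bin_means(ev, bin_size), bin_size = bin_size,
                 total_mapped = n_particles %||% totw, source = "vlp")
}

#' Simulate a whole-community (WGS) coverage track
#'
#' Whole-metagenome coverage of a correctly assembled contig is even, with an
#' optional replication gradient (log-linear ramp spanning `ori_gradient`
#' fold from the origin to the terminus) and optional Poisson noise per bin.
#'
#' @param model A [genome_model()] or a genome length in bp.
#' @param mean_depth Mean depth of the track.
#' @param ori_gradient Fold coverage increase at the origin relative to the
#'   terminus (>= 1; 1 = flat).
#' @param noise If TRUE, each bin is Poisson-sampled around its expectation.
#' @param seed Optional RNG seed.
#' @param bin_size Bin width in bp.
#' @return A [coverage_track()] with `source = "whole"`.
#' @export
simulate_wgs_track <- function(model, mean_depth = 100, ori_gradient = 1,
                               noise = TRUE, seed = NULL, bin_size = 100,
                               contig_id = "sim") {
  if (inherits(model, "genome_model")) {
    L <- model$genome_length
    circ <- model$circular
    ori <- model$ori_position %||% 0
  } else {
    L <- as.numeric(model); circ <- FALSE; ori <- 0
  }
  stopifnot(mean_depth > 0, ori_gradient >= 1)
  n <- n_bins_for(L, bin_size)
  mid <- (seq_len(n) - 0.5) * bin_size
  if (ori_gradient > 1) {
    d <- abs(mid - ori)
    if (circ) d <- pmin(d, L - d)
    D <- max(d)
    shape <- ori_gradient^(-d / D)
    mu <- mean_depth * shape / mean(shape)
  } else mu <- rep(mean_depth, n)
  depths <- if (noise) with_seed(seed, rpois(n, mu)) else mu
  coverage_track(contig_id, L, depths, bin_size = bin_size,
                 total_mapped = round(mean_depth * L / 100),
                 source = "whole")
}

#' Deterministically downsample a coverage track
#'
#' Scales both depths and `total_mapped` by `fraction`, emulating random read
#' subsampling in expectation: normalized depths are unchanged while raw
#' coverage (and hence the detector's coverage gates) drops.
#'
#' @param track A [coverage_track()].
#' @param fraction Retained fraction in (0, 1].
#' @return The downsampled track.
#' @export
downsample_track <- function(track, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  track$depths <- track$depths * fraction
  track$total_mapped <- track$total_mapped * fraction
  if (inherits(track, "normalized_track"))
    track$norm_depths <- track$depths * 1e6 / track$total_mapped
  track
}
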