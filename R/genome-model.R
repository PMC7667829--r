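#' Mobile-element layout of a simulated genome
#'
#' A `genome_model` describes one (circular or linear) replicon and the
#' packaging machinery acting on it: inducible prophages with optional
#' imprecise-excision (specialized) and lateral packaging, chromosomal
#' islands that hijack helper capsids, *pac*-site driven generalized headful
#' packaging, and GTA-like random fragment packaging. All coordinates are
#' 0-based half-open.
#'
#' @param genome_length Replicon length in bp.
#' @param circular Whether the replicon is circular (fragments may wrap).
#' @param prophages List of [prophage_element()] objects.
#' @param pac_sites List of [pac_site()] objects.
#' @param islands List of [island_element()] objects.
#' @param gta Optional [gta_params()].
#' @param ori_position Optional origin-of-replication position in bp (used by
#'   [simulate_wgs_track()] for the replication gradient).
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(genome_length, circular = FALSE, prophages = list(),
                         pac_sites = list(), islands = list(), gta = NULL,
                         ori_position = NULL) {
  genome_length <- as.numeric(genome_length)
  stopifnot(genome_length >= 1)
  m <- structure(
    list(genome_length = genome_length, circular = isTRUE(circular),
         prophages = prophages, pac_sites = pac_sites, islands = islands,
         gta = gta, ori_position = ori_position),
    class = "genome_model")
  validate_genome_model(m)
  m
}

validate_genome_model <- function(m) {
  L <- m$genome_length
  chk <- function(s, e, what) {
    if (s < 0 || e > L || e <= s)
      stop("genome_model: ", what, " interval [", s, ", ", e,
           ") outside [0, ", L, ")")
  }
  for (p in m$prophages) {
    chk(p$start, p$end, "prophage")
    if (p$lateral_rate > 0 && (p$q <= 0 || p$q >= 1))
      stop("genome_model: continuation probability q must be in (0, 1)")
  }
  for (i in m$islands) chk(i$start, i$end, "island")
  for (s in m$pac_sites) {
    if (s$position < 0 || s$position >= L)
      stop("genome_model: pac site at ", s$position, " outside [0, ", L, ")")
    if (s$q <= 0 || s$q >= 1)
      stop("genome_model: continuation probability q must be in (0, 1)")
    if (s$headful <= 0) stop("genome_model: headful must be > 0")
  }
  if (!is.null(m$gta) && m$gta$fragment_size <= 0)
    stop("genome_model: GTA fragment size must be > 0")
  invisible(m)
}

#' Prophage element
#'
#' @param start,end Prophage interval in bp (0-based half-open).
#' @param induction_rate Expected number of induced particles carrying phage
#'   DNA, relative to the other rates in the model.
#' @param f_spec Probability that an induced particle is an imprecise-excision
#'   (specialized transducing) particle.
#' @param capsid Capsid capacity G in bp (default: prophage length). A
#'   specialized particle packages G bp in total: part of the prophage plus a
#'   host flank.
#' @param min_retained Minimum phage DNA retained in a specialized particle
#'   (bp); the host flank extent is Uniform on (0, capsid - min_retained].
#'   Default capsid/2.
#' @param side_bias Probability that a specialized particle extends across
#'   the left prophage edge (0.5 = symmetric, 0 = right-only).
#' @param lateral_rate Expected number of lateral-transduction initiation
#'   events (in-situ headful packaging starting at a prophage edge).
#' @param lateral_direction `"right"` or `"left"`: direction in which lateral
#'   headfuls proceed into the host genome.
#' @param q Per-headful continuation probability for lateral packaging.
#' @return An object of class `prophage_element`.
#' @export
prophage_element <- function(start, end, induction_rate = 1, f_spec = 0,
                             capsid = NULL, min_retained = NULL,
                             side_bias = 0.5, lateral_rate = 0,
                             lateral_direction = c("right", "left"),
                             q = 0.5) {
  capsid <- capsid %||% (end - start)
  min_retained <- min_retained %||% (capsid / 2)
  stopifnot(f_spec >= 0, f_spec <= 1, capsid > 0, side_bias >= 0,
            side_bias <= 1, min_retained >= 0, min_retained < capsid)
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 induction_rate = induction_rate, f_spec = f_spec,
                 capsid = capsid, min_retained = min_retained,
                 side_bias = side_bias, lateral_rate = lateral_rate,
                 lateral_direction = match.arg(lateral_direction), q = q),
            class = "prophage_element")
}

#' Chromosomal island hijacking helper capsids
#'
#' @param start,end Island interval in bp.
#' @param hijack_rate Expected number of particles packaging the island.
#' @return An object of class `island_element`.
#' @export
island_element <- function(start, end, hijack_rate = 1) {
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 hijack_rate = hijack_rate), class = "island_element")
}

#' Packaging-initiation (pac) site for generalized headful packaging
#'
#' @param position Site position in bp.
#' @param rate Expected number of packaging initiations r at this site.
#' @param headful Headful size H in bp (one capsid's worth of DNA).
#' @param q Per-headful continuation probability; the k-th headful downstream
#'   of the site is packaged with probability `q^(k-1)`.
#' @param strand `"+"` (headfuls proceed to increasing coordinates) or
#'   `"-"`.
#' @return An object of class `pac_site`.
#' @export
pac_site <- function(position, rate = 1, headful = 44000, q = 0.5,
                     strand = c("+", "-")) {
  structure(list(position = as.numeric(position), rate = rate,
                 headful = as.numeric(headful), q = q,
                 strand = match.arg(strand)),
            class = "pac_site")
}

#' GTA-like random packaging parameters
#'
#' Gene-transfer-agent-like particles package fixed-size quasi-random
#' fragments of the host genome. An optional smooth positive bias field
#' modulates the per-position packaging rate; the region encoding the element
#' itself may be packaged at a reduced rate (self exclusion).
#'
#' @param fragment_size Packaged fragment size F in bp (e.g. 13000).
#' @param n_fragments Expected number of GTA particles.
#' @param bias_field Optional positive per-window rate multiplier with mean
#'   1: a numeric vector interpreted over windows of `bias_bin` bp, or NULL
#'   for a flat field. See [make_bias_field()].
#' @param bias_bin Window width of `bias_field` in bp (default 1000).
#' @param self_exclusion Optional `c(start, end)` interval packaged at
#'   `self_exclusion_factor` times the local rate.
#' @param self_exclusion_factor Rate multiplier inside `self_exclusion`.
#' @return An object of class `gta_params`.
#' @export
gta_params <- function(fragment_size = 13000, n_fragments = 1,
                       bias_field = NULL, bias_bin = 1000,
                       self_exclusion = NULL, self_exclusion_factor = 0.2) {
  if (!is.null(bias_field)) {
    stopifnot(all(bias_field > 0))
    bias_field <- bias_field / mean(bias_field)
  }
  structure(list(fragment_size = as.numeric(fragment_size),
                 n_fragments = n_fragments, bias_field = bias_field,
                 bias_bin = as.numeric(bias_bin),
                 self_exclusion = self_exclusion,
                 self_exclusion_factor = self_exclusion_factor),
            class = "gta_params")
}

#' Smooth positive bias field for GTA packaging
#'
#' Generates a log-scale smooth random field (Gaussian noise smoothed over
#' `corr_length`) rescaled so its max/min ratio is exactly `fold` and its
#' mean is 1.
#'
#' @param genome_length Genome length in bp.
#' @param fold Target max/min ratio of the field (>= 1).
#' @param corr_length Autocorrelation length in bp.
#' @param bias_bin Window width in bp.
#' @param seed Optional RNG seed.
#' @return Numeric vector of per-window multipliers, mean 1.
#' @export
make_bias_field <- function(genome_length, fold = 2, corr_length = 50000,
                            bias_bin = 1000, seed = NULL) {
  n <- n_bins_for(genome_length, bias_bin)
  z <- with_seed(seed, {
    raw <- rnorm(n)
    ## circular smoothing keeps the field seamless on circular genomes
    k <- max(1L, round(corr_length / bias_bin))
    sm <- stats::filter(rep(raw, 3), rep(1 / k, k), sides = 2,
                        circular = FALSE)
    as.numeric(sm[(n + 1):(2 * n)])
  })
  if (fold <= 1 || diff(range(z)) == 0) return(rep(1, n))
  z <- (z - min(z)) / diff(range(z))      # in [0, 1]
  f <- fold^z                             # max/min exactly `fold`
  f / mean(f)
}

## Evaluate set.seed(seed) locally, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}
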