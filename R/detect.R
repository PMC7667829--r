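#' Detector parameters
#'
#' All classification thresholds of the pattern detector, exposed as explicit
#' parameters. Fold thresholds act on normalized (per-million) depth;
#' coverage gates (`min_induction_cov`, `min_flank_cov`) act on raw read
#' depth, so that downsampling a sample degrades calls the way subsampled
#' reads do while jointly rescaled samples classify identically.
#'
#' @param pseudocount Depth floor used in all log transforms and ratios.
#' @param min_plateau,max_plateau Admissible induced-prophage/island plateau
#'   lengths in bp.
#' @param induction_fold Minimum plateau fold over the contig baseline.
#' @param edge_window Window w_e (bp) over which edge sharpness is measured.
#' @param edge_fold Minimum fold across a boundary to call it sharp.
#' @param flank_fold Minimum flank fold over baseline (specialized/lateral).
#' @param lateral_min_extent Minimum one-sided flank extent (bp) for a
#'   lateral call; shorter flanks are specialized.
#' @param unevenness_fold Minimum smoothed max/min ratio for a generalized
#'   call.
#' @param gta_min_unevenness Lower unevenness bound of the GTA-like band
#'   `[gta_min_unevenness, unevenness_fold)`.
#' @param smooth_window Smoothing window (bp) for evenness/unevenness.
#' @param min_induction_cov Minimum raw plateau depth for a confident
#'   induction call (downsampling gate).
#' @param min_flank_cov Minimum raw smoothed flank depth for a confident
#'   specialized/lateral call (downsampling gate).
#' @param min_signal_cov Minimum smoothed raw VLP depth for the track to
#'   count as carrying signal at all; below it shot noise dominates any
#'   max/min ratio and the contig is standard.
#' @param wgs_cv_max Maximum CV of smoothed whole-community coverage before
#'   a contig is flagged as unevenly assembled.
#' @param seg_penalty Change-point penalty on the log2 scale; NULL selects
#'   `4 * sigma^2 * log(n)` with sigma estimated from successive differences.
#' @param headful_scale Characteristic headful size (bp) used to size decay
#'   windows and deduplicate pac calls.
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(pseudocount = 0.01, min_plateau = 5000,
                            max_plateau = 200000, induction_fold = 10,
                            edge_window = 500, edge_fold = 5,
                            flank_fold = 3, lateral_min_extent = 1e5,
                            unevenness_fold = 5, gta_min_unevenness = 2,
                            smooth_window = 10000, min_induction_cov = 20,
                            min_flank_cov = 150, min_signal_cov = 5,
                            wgs_cv_max = 0.5,
                            seg_penalty = NULL, headful_scale = 44000) {
  p <- as.list(environment())
  stopifnot(p$induction_fold > 1, p$edge_fold > 1, p$flank_fold > 1,
            p$unevenness_fold > 1, p$min_plateau < p$max_plateau)
  structure(p, class = "detector_params")
}

#' Robust baseline VLP coverage of a contig
#'
#' The reference level against which plateaus and flanks are measured:
#' median of the normalized bins at or below the 25th percentile, i.e. the
#' lower coverage envelope. Neither a large induced prophage nor a lateral
#' flank spanning most of the contig (several hundred kbp is typical) can
#' inflate its own baseline. Zero is allowed.
#'
#' @param vlp A VLP [coverage_track()] (normalized on the fly if needed).
#' @param params [detector_params()].
#' @return Baseline depth (per-million units).
#' @export
contig_baseline <- function(vlp, params = detector_params()) {
  x <- norm_depths_of(vlp)
  thr <- quantile(x, 0.25, names = FALSE)
  median(x[x <= thr])
}

#' Whole-community coverage evenness check
#'
#' Even whole-metagenome coverage is evidence of correct assembly; a chimeric
#' contig shows strongly uneven coverage that could mimic transduction
#' signals. Reports the CV of the smoothed normalized depth; contigs failing
#' the threshold are still processed but flagged.
#'
#' @param wgs A whole-community [coverage_track()].
#' @param params [detector_params()].
#' @return A list with `contig_id`, `cv` and logical `pass`.
#' @export
wgs_evenness <- function(wgs, params = detector_params()) {
  x <- norm_depths_of(wgs)
  sm <- runmean(x, params$smooth_window / wgs$bin_size)
  cv <- if (mean(sm) == 0) 0 else sd(sm) / mean(sm)
  list(contig_id = wgs$contig_id, cv = cv, pass = cv <= params$wgs_cv_max)
}

## Binary segmentation on a numeric vector: returns sorted breakpoints
## (last index of each left part). A split is accepted when it reduces the
## residual sum of squares by more than `penalty`; ties resolve toward
## fewer segments.
binseg <- function(y, penalty, min_size = 3L, max_segments = 60L) {
  n <- length(y)
  breaks <- integer(0)
  rss_of <- function(lo, hi) {
    v <- y[lo:hi]
    sum(v^2) - sum(v)^2 / length(v)
  }
  best_split <- function(lo, hi) {
    m <- hi - lo + 1L
    if (m < 2L * min_size) return(NULL)
    v <- y[lo:hi]
    cs <- cumsum(v); cs2 <- cumsum(v^2)
    k <- seq.int(min_size, m - min_size)   # size of left part
    rss_l <- cs2[k] - cs[k]^2 / k
    rss_r <- (cs2[m] - cs2[k]) - (cs[m] - cs[k])^2 / (m - k)
    tot <- cs2[m] - cs[m]^2 / m
    gain <- tot - (rss_l + rss_r)
    i <- which.max(gain)
    list(gain = gain[i], at = lo + k[i] - 1L)
  }
  queue <- list(c(1L, n))
  while (length(queue) && length(breaks) + 1L < max_segments) {
    seg <- queue[[1]]; queue <- queue[-1]
    sp <- best_split(seg[1], seg[2])
    if (is.null(sp) || sp$gain <= penalty) next
    breaks <- c(breaks, sp$at)
    queue <- c(queue, list(c(seg[1], sp$at)), list(c(sp$at + 1L, seg[2])))
  }
  sort(breaks)
}

## The noise term adapts to per-bin scatter; the absolute floor of 1 log2
## unit keeps zero-inflated tracks (where mad(diff) collapses to 0) from
## being shredded, while every biologically meaningful step (>= the
## flank_fold of 3, i.e. 1.6 log2 units) still clears it.
auto_penalty <- function(y) {
  s <- mad(diff(y)) / sqrt(2)
  max(4 * s^2 * log(length(y)), 1)
}

#' Change-point segmentation of log VLP coverage
#'
#' Segments `log2(normalized depth + pseudocount)` with penalized binary
#' segmentation. Segments tile the contig; each is annotated with its mean
#' normalized depth, fold over the contig baseline, edge sharpness at both
#' boundaries, and a log-linear decay fit.
#'
#' @param vlp A VLP [coverage_track()].
#' @param params [detector_params()].
#' @return A data.frame of segments with columns `start`, `end` (bp, 0-based
#'   half-open), `start_bin`, `end_bin`, `length`, `mean_vlp_norm`,
#'   `fold_over_baseline`, `left_edge_fold`, `right_edge_fold`,
#'   `decay_slope`, `decay_r2`.
#' @export
segment_log_coverage <- function(vlp, params = detector_params()) {
  x <- norm_depths_of(vlp)
  pc <- params$pseudocount
  y <- log2(x + pc)
  pen <- params$seg_penalty %||% auto_penalty(y)
  br <- binseg(y, pen)
  b0 <- c(0L, br); b1 <- c(br, length(x))
  base <- contig_baseline(vlp, params)
  segs <- data.frame(
    start_bin = b0 + 1L, end_bin = b1,
    start = b0 * vlp$bin_size,
    end = pmin(b1 * vlp$bin_size, vlp$contig_length))
  segs$length <- segs$end - segs$start
  segs$mean_vlp_norm <- vapply(seq_len(nrow(segs)), function(i)
    mean(x[segs$start_bin[i]:segs$end_bin[i]]), numeric(1))
  segs$fold_over_baseline <- (segs$mean_vlp_norm + pc) / (base + pc)
  segs$left_edge_fold <- vapply(segs$start, function(b)
    as.numeric(edge_sharpness(vlp, b, params$edge_window, pc, gap = 1L)),
    numeric(1))
  segs$right_edge_fold <- vapply(segs$end, function(b)
    as.numeric(edge_sharpness(vlp, b, params$edge_window, pc, gap = 1L)),
    numeric(1))
  dec <- lapply(seq_len(nrow(segs)), function(i)
    fit_decay_slope(vlp, c(segs$start[i], segs$end[i]), pc))
  segs$decay_slope <- vapply(dec, function(d) d$slope, numeric(1))
  segs$decay_r2 <- vapply(dec, function(d) d$r2, numeric(1))
  segs
}

#' Edge sharpness at a boundary
#'
#' Ratio of mean normalized depth over `w_e` bp after versus before the
#' boundary, each floored at the pseudocount. Values > 1 are rising edges,
#' < 1 falling. A `gap` of bins directly at the boundary can be excluded so
#' that a change-point placed one bin off (leaving a mixed bin) does not
#' dilute the measurement. Boundaries within `w_e` of a contig end are
#' evaluated over the available bins and carry a `truncated` attribute.
#'
#' @param track A [coverage_track()].
#' @param boundary Boundary position in bp (0-based).
#' @param w_e Window in bp.
#' @param pseudocount Depth floor.
#' @param gap Guard band in bins excluded on each side of the boundary.
#' @return Fold (numeric) with attribute `truncated`.
#' @export
edge_sharpness <- function(track, boundary, w_e = 500, pseudocount = 0.01,
                           gap = 0L) {
  x <- norm_depths_of(track)
  n <- length(x)
  wb <- max(1L, round(w_e / track$bin_size))
  b <- floor(boundary / track$bin_size)       # bins before: ..b ; after: b+1..
  hi <- b + gap
  lo <- b - gap
  after <- seq.int(hi + 1L, min(hi + wb, n))
  before <- seq.int(max(1L, lo - wb + 1L), lo)
  truncated <- (hi + wb > n) || (lo - wb + 1L < 1L) || lo < 1L || hi >= n
  after <- after[after >= 1L & after <= n]
  before <- before[before >= 1L & before <= n]
  ma <- if (length(after)) mean(x[after]) else 0
  mb <- if (length(before)) mean(x[before]) else 0
  structure(max(ma, pseudocount) / max(mb, pseudocount),
            truncated = truncated)
}

#' Log-linear decay fit over an interval
#'
#' Least-squares fit of `log2(normalized depth + pseudocount)` against
#' position. Negative slopes decay with increasing coordinate; the slope is
#' reported per 10 kbp.
#'
#' @param track A [coverage_track()].
#' @param interval `c(start, end)` in bp.
#' @param pseudocount Depth floor.
#' @return List with `slope` (log2-fold per 10 kbp), `r2`, and `flag`
#'   (`"ok"`, `"too_short"` or `"all_zero"`).
#' @export
fit_decay_slope <- function(track, interval, pseudocount = 0.01) {
  x <- norm_depths_of(track)
  b0 <- floor(interval[1] / track$bin_size) + 1L
  b1 <- min(ceiling(interval[2] / track$bin_size), length(x))
  if (b1 - b0 + 1L < 10L)
    return(list(slope = NA_real_, r2 = NA_real_, flag = "too_short"))
  xs <- x[b0:b1]
  if (all(xs == 0))
    return(list(slope = NA_real_, r2 = NA_real_, flag = "all_zero"))
  pos <- (seq.int(b0, b1) - 0.5) * track$bin_size
  y <- log2(xs + pseudocount)
  f <- lm(y ~ pos)
  r2 <- suppressWarnings(summary(f)$r.squared)  # exact fits warn harmlessly
  list(slope = unname(coef(f)[2]) * 1e4, r2 = r2, flag = "ok")
}

#' Smoothed coverage unevenness (max/min fold)
#'
#' Max/min ratio of the smoothed, pseudocount-floored normalized track; 1
#' for a flat track. Generalized transduction gives strong unevenness,
#' GTA-like packaging mild unevenness.
#'
#' @param track A [coverage_track()].
#' @param smooth_window Smoothing window in bp.
#' @param pseudocount Depth floor.
#' @return Fold (numeric, >= 1).
#' @export
unevenness_ratio <- function(track, smooth_window = 10000,
                             pseudocount = 0.01) {
  x <- norm_depths_of(track)
  sm <- pmax(runmean(x, smooth_window / track$bin_size), pseudocount)
  max(sm) / min(sm)
}

#' Call pac sites on a VLP track
#'
#' A pac site is a packaging-initiation position: a sharp rising coverage
#' edge followed by a sustained log-linear decay (the headful staircase).
#' Candidate boundaries come from change-point segmentation; calls within
#' one headful of a stronger call are deduplicated. Mirrored (minus-strand)
#' staircases - a sharp drop preceded by a leftward decay - are also called.
#'
#' @param track A VLP [coverage_track()].
#' @param params [detector_params()].
#' @param segments Optional precomputed output of [segment_log_coverage()].
#' @return Numeric vector of pac positions in bp (0-based).
#' @export
call_pac_sites <- function(track, params = detector_params(),
                           segments = NULL) {
  if (track$contig_length < params$lateral_min_extent) return(numeric(0))
  segs <- segments %||% segment_log_coverage(track, params)
  if (nrow(segs) < 2) return(numeric(0))
  bnd <- segs$end[-nrow(segs)]
  Hs <- params$headful_scale
  pc <- params$pseudocount
  folds <- vapply(bnd, function(b)
    as.numeric(edge_sharpness(track, b, params$edge_window, pc, gap = 1L)),
    numeric(1))
  sharpness <- pmax(folds, 1 / folds)
  ## a genuine headful staircase declines through gentle 1/q steps only: a
  ## second sharp edge inside the decay window marks a plateau, not a pac
  other_sharp <- function(b, win)
    any(bnd != b & bnd > win[1] & bnd < win[2] &
          sharpness >= params$edge_fold)
  cand <- data.frame(pos = numeric(0), strength = numeric(0))
  for (i in seq_along(bnd)) {
    b <- bnd[i]
    f <- edge_sharpness(track, b, params$edge_window, pc, gap = 1L)
    if (isTRUE(attr(f, "truncated"))) next
    fold <- as.numeric(f)
    if (fold >= params$edge_fold) {          # rising edge, decay rightward
      win <- c(b, min(b + 2 * Hs, track$contig_length))
      dec <- fit_decay_slope(track, win, pc)
      if (!other_sharp(b, win) && !is.na(dec$slope) && dec$slope < 0 &&
          -dec$slope * diff(win) / 1e4 >= 0.5)
        cand <- rbind(cand, data.frame(pos = b, strength = fold))
    } else if (fold <= 1 / params$edge_fold) { # falling edge, decay leftward
      win <- c(max(b - 2 * Hs, 0), b)
      dec <- fit_decay_slope(track, win, pc)
      if (!other_sharp(b, win) && !is.na(dec$slope) && dec$slope > 0 &&
          dec$slope * diff(win) / 1e4 >= 0.5)
        cand <- rbind(cand, data.frame(pos = b, strength = 1 / fold))
    }
  }
  if (!nrow(cand)) return(numeric(0))
  cand <- cand[order(-cand$strength), ]
  keep <- numeric(0)
  for (i in seq_len(nrow(cand)))
    if (!length(keep) || all(abs(cand$pos[i] - keep) >= Hs))
      keep <- c(keep, cand$pos[i])
  sort(keep)
}

#' Estimate the headful size from a staircase region
#'
#' The staircase period is recovered from the strong negative steps of the
#' smoothed log2 depth: lagged differences are thresholded into a step
#' impulse train whose dominant autocorrelation lag gives the period,
#' refined by the median consecutive step spacing. Undefined (flagged NA)
#' when fewer than two steps rise above the noise floor.
#'
#' @param track A VLP [coverage_track()].
#' @param interval `c(start, end)` bp region containing the staircase.
#' @param params [detector_params()].
#' @return Headful size in bp, or NA with attribute `flag = "no_periodicity"`.
#' @export
estimate_headful_size <- function(track, interval = NULL,
                                  params = detector_params()) {
  x <- norm_depths_of(track)
  bs <- track$bin_size
  if (!is.null(interval)) {
    b0 <- floor(interval[1] / bs) + 1L
    b1 <- min(ceiling(interval[2] / bs), length(x))
    x <- x[b0:b1]
  }
  pc <- params$pseudocount
  w <- max(3L, round(500 / bs))
  y <- log2(runmean(x, w) + pc)
  n <- length(y)
  if (n <= 3L * w) return(no_period())
  D <- y[(w + 1L):n] - y[seq_len(n - w)]     # lag-w difference spans a step
  thr <- -max(4 * mad(D), 0.3)
  hit <- which(D < thr)
  if (length(hit) < 2L) return(no_period())
  ## cluster consecutive hits into one step each, keep the steepest position
  cl <- cumsum(c(1L, diff(hit) > w))
  steps <- vapply(split(hit, cl), function(ii) ii[which.min(D[ii])],
                  numeric(1)) + w / 2
  if (length(steps) < 2L) return(no_period())
  spacing <- diff(sort(steps))
  H <- median(spacing) * bs
  ## cross-check the period on the impulse-train autocorrelation
  z <- numeric(length(D)); z[round(steps - w / 2)] <- 1
  lag_max <- min(length(z) - 1L, ceiling(2.5 * H / bs))
  a <- acf(z, lag.max = lag_max, plot = FALSE)$acf[-1]
  if (length(a) > 3) {
    peaks <- which(diff(sign(diff(a))) == -2) + 1L
    if (length(peaks)) {
      lag <- peaks[which.max(a[peaks])] * bs
      if (abs(lag - H) / H > 0.5 && length(spacing) < 3)
        attr(H, "flag") <- "weak_periodicity"
    }
  }
  H
}

no_period <- function() structure(NA_real_, flag = "no_periodicity")

#' Transducing-particle frequency from plateau and flank coverage
#'
#' The frequency of transducing particles among particles produced by an
#' element is estimated as the ratio of prophage-plateau coverage to the
#' maximal coverage of the transduced flank, reported as "1:N".
#'
#' @param plateau_mean Mean (normalized) depth of the prophage plateau.
#' @param flank_max Maximal (normalized) depth of the transduced flank.
#' @return N (numeric, 2 significant figures): the frequency is 1:N. NA with
#'   a warning when `flank_max` is 0 (only a lower bound is then defined).
#' @export
estimate_transduction_frequency <- function(plateau_mean, flank_max) {
  if (flank_max <= 0) {
    warning("flank coverage is 0: frequency undefined; 1:N exceeds the ",
            "detection floor ", fmt_sig2(plateau_mean))
    return(structure(NA_real_, lower_bound = fmt_sig2(plateau_mean)))
  }
  fmt_sig2(plateau_mean / flank_max)
}
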