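#' Classify the transduction pattern of one contig
#'
#' The automated replacement for visual inspection of paired coverage
#' tracks. The decision cascade: (1) whole-community evenness is computed
#' and flagged only; (2) induction: a 5-200 kbp plateau at least
#' `induction_fold` over baseline with sharp edges on both sides and raw
#' depth above the induction gate; (3) specialized: induction plus adjacent
#' flank(s) above `flank_fold` over baseline, below a tenth of the plateau,
#' shorter than `lateral_min_extent` and above the flank coverage gate;
#' (4) lateral: as specialized but with a one-sided, log-linearly decaying
#' flank of at least `lateral_min_extent`; (5) generalized: no dominant
#' plateau, at least one pac call, unevenness at least `unevenness_fold`;
#' (6) GTA-like: mild unevenness without sharp edges; (7) standard:
#' flat VLP coverage; anything else is unknown.
#'
#' @param paired A `paired_coverage` object from [pair_tracks()] (or a list
#'   with `wgs` and `vlp` tracks).
#' @param params [detector_params()].
#' @return A `pattern_call`: list with `contig_id`, `mode` (one of standard,
#'   induction, specialized, lateral, generalized, gta_like, unknown),
#'   `primary` interval, `flanks` (left/right interval + extent),
#'   `frequency_ratio` (N meaning 1:N), `pac_positions`,
#'   `headful_estimate`, `qc` flags, and a `features` list (baseline,
#'   unevenness, wgs_cv, plateau/flank depths, segments).
#' @export
call_patterns <- function(paired, params = detector_params()) {
  wgs <- normalize_track(paired$wgs)
  vlp <- normalize_track(paired$vlp)
  pc <- params$pseudocount
  bs <- vlp$bin_size
  L <- vlp$contig_length

  ev <- wgs_evenness(wgs, params)
  base <- contig_baseline(vlp, params)
  segs <- segment_log_coverage(vlp, params)
  unev <- unevenness_ratio(vlp, params$smooth_window, pc)
  qc <- character(0)
  if (!ev$pass) qc <- c(qc, "wgs_uneven")

  raw_mean <- function(b0, b1)         # raw depth over a bin range
    mean(vlp$depths[b0:b1])
  sharp <- function(fold) pmax(fold, 1 / fold)

  ## --- induction plateau candidates -------------------------------------
  is_cand <- segs$length >= params$min_plateau &
    segs$length <= params$max_plateau &
    segs$fold_over_baseline >= params$induction_fold &
    sharp(segs$left_edge_fold) >= params$edge_fold &
    sharp(segs$right_edge_fold) >= params$edge_fold &
    segs$left_edge_fold > 1 & segs$right_edge_fold < 1
  cand <- which(is_cand)
  plateau <- NULL
  if (length(cand)) {
    gated <- cand[vapply(cand, function(i)
      raw_mean(segs$start_bin[i], segs$end_bin[i]), numeric(1)) >=
        params$min_induction_cov]
    if (length(gated) < length(cand)) qc <- c(qc, "low_coverage")
    if (length(gated))
      plateau <- gated[which.max(segs$mean_vlp_norm[gated])]
  }

  ## --- flanks around the dominant plateau -------------------------------
  flanks <- list()
  flank_max_norm <- NA_real_
  if (!is.null(plateau)) {
    pl_mean <- segs$mean_vlp_norm[plateau]
    norm <- vlp$norm_depths
    sm5 <- runmean(norm, max(1, round(params$edge_window / bs)))
    chain <- function(idx_seq) {
      picked <- integer(0)
      for (i in idx_seq) {
        ok <- segs$fold_over_baseline[i] >= params$flank_fold &&
          segs$mean_vlp_norm[i] <= pl_mean / 10
        if (!ok) break
        picked <- c(picked, i)
      }
      picked
    }
    for (side in c("left", "right")) {
      idx <- if (side == "left") rev(seq_len(plateau - 1))
             else seq.int(plateau + 1, length.out = nrow(segs) - plateau)
      picked <- chain(idx)
      if (!length(picked)) next
      b0 <- min(segs$start_bin[picked]); b1 <- max(segs$end_bin[picked])
      ## skip the 2 bins adjacent to the plateau: a mid-bin plateau edge
      ## would bleed plateau depth into the flank maximum
      if (side == "left") b1 <- max(b0, b1 - 2L) else b0 <- min(b1, b0 + 2L)
      fmax <- max(sm5[b0:b1])
      fmax_raw <- fmax * vlp$total_mapped / 1e6
      confident <- fmax_raw >= params$min_flank_cov
      if (!confident) { qc <- c(qc, "low_coverage"); next }
      iv <- c(min(segs$start[picked]), max(segs$end[picked]))
      dec <- fit_decay_slope(vlp, iv, pc)
      flanks[[side]] <- list(interval = iv, extent = iv[2] - iv[1],
                             max_norm = fmax, slope = dec$slope)
      flank_max_norm <- max(flank_max_norm, fmax, na.rm = TRUE)
    }
  }

  pacs <- call_pac_sites(vlp, params, segments = segs)

  ## --- cascade ------------------------------------------------------------
  mode <- NULL
  lateral_side <- NULL
  for (side in names(flanks)) {
    fl <- flanks[[side]]
    decaying <- !is.na(fl$slope) &&
      (if (side == "right") fl$slope < 0 else fl$slope > 0)
    if (fl$extent >= params$lateral_min_extent && decaying)
      lateral_side <- side
  }
  if (!is.null(plateau) && length(flanks) && !is.null(lateral_side)) {
    mode <- "lateral"
  } else if (!is.null(plateau) && length(flanks)) {
    mode <- "specialized"
  } else if (!is.null(plateau)) {
    mode <- "induction"
  } else {
    ## below the signal floor any max/min ratio is shot noise
    no_signal <- max(runmean(vlp$depths,
                             params$smooth_window / bs)) <
      params$min_signal_cov
    if (length(pacs) && unev >= params$unevenness_fold) {
      mode <- "generalized"
    } else if (no_signal || (!length(pacs) &&
                             unev < params$gta_min_unevenness)) {
      mode <- "standard"
    } else if (!length(pacs) && unev >= params$gta_min_unevenness &&
               unev < params$unevenness_fold &&
               all(sharp(segs$left_edge_fold[-1]) < params$edge_fold)) {
      mode <- "gta_like"
    } else {
      mode <- "unknown"
    }
  }

  ## --- call assembly ------------------------------------------------------
  primary <- if (!is.null(plateau))
    c(segs$start[plateau], segs$end[plateau]) else NULL
  freq <- NA_real_
  if (mode %in% c("specialized", "lateral") && is.finite(flank_max_norm) &&
      flank_max_norm > 0)
    freq <- estimate_transduction_frequency(segs$mean_vlp_norm[plateau],
                                            flank_max_norm)
  headful <- NA_real_
  if (mode == "generalized" && length(pacs)) {
    nxt <- c(pacs[-1], L)
    iv <- c(pacs[1], nxt[1])
    if (diff(iv) >= 3 * params$headful_scale)
      headful <- as.numeric(estimate_headful_size(vlp, iv, params))
  }
  touches_end <- function(iv)
    !is.null(iv) && (iv[1] <= params$edge_window ||
                     iv[2] >= L - params$edge_window)
  if (touches_end(primary) ||
      any(vapply(flanks, function(f) touches_end(f$interval), logical(1))))
    qc <- c(qc, "truncated_at_end")

  structure(
    list(contig_id = vlp$contig_id, mode = mode, primary = primary,
         flanks = flanks, frequency_ratio = freq,
         pac_positions = pacs,
         headful_estimate = headful,
         qc = unique(qc),
         features = list(baseline = base, unevenness = unev, wgs_cv = ev$cv,
                         plateau_mean = if (!is.null(plateau))
                           segs$mean_vlp_norm[plateau] else NA_real_,
                         flank_max = flank_max_norm,
                         segments = segs)),
    class = "pattern_call")
}

#' @export
print.pattern_call <- function(x, ...) {
  cat(sprintf("<pattern_call> %s  mode=%s", x$contig_id, x$mode))
  if (!is.null(x$primary))
    cat(sprintf("  primary=[%d,%d)", x$primary[1], x$primary[2]))
  if (!is.na(x$frequency_ratio))
    cat(sprintf("  freq=1:%g", x$frequency_ratio))
  if (length(x$pac_positions))
    cat(sprintf("  pac=%s", paste(x$pac_positions, collapse = ",")))
  if (!is.na(x$headful_estimate))
    cat(sprintf("  headful=%g bp", x$headful_estimate))
  if (length(x$qc)) cat("  [", paste(x$qc, collapse = ","), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Classify every contig of a paired coverage set
#'
#' @param pairs Named list of `paired_coverage` objects.
#' @param params [detector_params()].
#' @return Named list of `pattern_call` objects.
#' @export
call_patterns_all <- function(pairs, params = detector_params()) {
  lapply(pairs, call_patterns, params = params)
}

#' Tabulate pattern calls
#'
#' @param calls List of `pattern_call` objects.
#' @return A data.frame, one row per contig: mode, primary interval, flank
#'   extents, frequency ratio, pac count, headful estimate, unevenness,
#'   baseline, whole-community CV and qc flags.
#' @export
calls_table <- function(calls) {
  row <- function(cl) {
    data.frame(
      contig = cl$contig_id, mode = cl$mode,
      primary_start = cl$primary[1] %||% NA_real_,
      primary_end = cl$primary[2] %||% NA_real_,
      flank_left_extent = cl$flanks$left$extent %||% NA_real_,
      flank_right_extent = cl$flanks$right$extent %||% NA_real_,
      frequency_ratio = cl$frequency_ratio,
      n_pac = length(cl$pac_positions),
      pac_positions = paste(cl$pac_positions, collapse = ";"),
      headful_bp = cl$headful_estimate,
      unevenness = cl$features$unevenness,
      baseline = cl$features$baseline,
      plateau_mean = cl$features$plateau_mean,
      flank_max = cl$features$flank_max,
      wgs_cv = cl$features$wgs_cv,
      qc = paste(cl$qc, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(calls, row))
  rownames(out) <- NULL
  out
}
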