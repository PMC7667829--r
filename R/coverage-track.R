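#' Coverage track for one contig
#'
#' A `coverage_track` holds the binned mean read depth of one contig from one
#' read set (whole-community metagenome or VLP fraction). Depths are mean
#' per-base depth within each bin; the last bin may be partial and is averaged
#' over its true width.
#'
#' @param contig_id Contig identifier (string).
#' @param contig_length Contig length in bp.
#' @param bin_size Bin width in bp (default 100).
#' @param depths Numeric vector of mean depth per bin, length
#'   `ceiling(contig_length / bin_size)`, all values >= 0.
#' @param total_mapped Total mapped read count for the whole sample the track
#'   came from (used for per-million normalization).
#' @param source Read-set label, `"whole"` or `"vlp"`.
#'
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(contig_id, contig_length, depths, bin_size = 100,
                           total_mapped = NA_real_,
                           source = c("whole", "vlp")) {
  source <- match.arg(source)
  contig_length <- as.numeric(contig_length)
  bin_size <- as.integer(bin_size)
  stopifnot(contig_length >= 1, bin_size >= 1)
  expected <- n_bins_for(contig_length, bin_size)
  if (length(depths) != expected)
    stop("coverage_track: expected ", expected, " bins for contig '",
         contig_id, "' (length ", contig_length, ", bin ", bin_size,
         "), got ", length(depths))
  if (any(depths < 0)) stop("coverage_track: negative depths")
  structure(
    list(contig_id = as.character(contig_id),
         contig_length = contig_length,
         bin_size = bin_size,
         depths = as.numeric(depths),
         total_mapped = as.numeric(total_mapped),
         source = source),
    class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s  %s bp  bin %d  %d bins  mean depth %.3g%s\n",
              x$contig_id, format(x$contig_length, big.mark = ","),
              x$bin_size, length(x$depths), mean(x$depths),
              if (inherits(x, "normalized_track")) "  [normalized]" else ""))
  invisible(x)
}

#' Normalize a coverage track to depth per million mapped reads
#'
#' Adds `norm_depths = depths * 1e6 / total_mapped`, enabling comparison of
#' samples sequenced to different depths. Raw depths are preserved.
#'
#' @param track A `coverage_track` with a positive `total_mapped`.
#' @return The track with class `normalized_track` prepended and a
#'   `norm_depths` field.
#' @export
normalize_track <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (is.na(track$total_mapped) || track$total_mapped <= 0)
    stop("normalize_track: total_mapped must be > 0 (contig '",
         track$contig_id, "')")
  if (inherits(track, "normalized_track")) return(track)
  track$norm_depths <- track$depths * 1e6 / track$total_mapped
  class(track) <- c("normalized_track", class(track))
  track
}

## Normalized depths, normalizing on the fly if needed.
norm_depths_of <- function(track) {
  if (inherits(track, "normalized_track")) track$norm_depths
  else normalize_track(track)$norm_depths
}

#' Pair whole-community and VLP tracks per contig
#'
#' Tracks are matched on `contig_id`; contigs present in only one read set are
#' reported in a warning and excluded.
#'
#' @param wgs,vlp Lists of `coverage_track` objects binned identically.
#' @return A named list of `paired_coverage` objects (fields `contig_id`,
#'   `wgs`, `vlp`), one per contig present in both sets.
#' @export
pair_tracks <- function(wgs, vlp) {
  wid <- vapply(wgs, `[[`, "", "contig_id")
  vid <- vapply(vlp, `[[`, "", "contig_id")
  names(wgs) <- wid; names(vlp) <- vid
  shared <- intersect(wid, vid)
  only <- c(setdiff(wid, vid), setdiff(vid, wid))
  if (length(only))
    warning("pair_tracks: contigs present in only one read set excluded: ",
            paste(only, collapse = ", "))
  pairs <- lapply(shared, function(id) {
    w <- wgs[[id]]; v <- vlp[[id]]
    if (w$bin_size != v$bin_size)
      stop("pair_tracks: bin_size mismatch for contig '", id, "' (",
           w$bin_size, " vs ", v$bin_size, ")")
    if (w$contig_length != v$contig_length)
      stop("pair_tracks: contig_length mismatch for contig '", id, "'")
    structure(list(contig_id = id, wgs = w, vlp = v),
              class = "paired_coverage")
  })
  names(pairs) <- shared
  pairs
}

#' Discard contigs below a minimum length
#'
#' The workflow analyses only contigs long enough to expose transduction
#' patterns; the boundary is inclusive (a contig exactly `min_length` long is
#' kept). Order is preserved.
#'
#' @param tracks List of `coverage_track` (or `paired_coverage`) objects.
#' @param min_length Minimum contig length in bp (default 40000).
#' @return The filtered list, original order retained.
#' @export
filter_contigs <- function(tracks, min_length = 40000) {
  if (!length(tracks)) return(tracks)
  len <- vapply(tracks, function(t)
    if (inherits(t, "paired_coverage")) t$wgs$contig_length
    else t$contig_length, numeric(1))
  tracks[len >= min_length]
}

#' Re-bin a coverage track to a coarser bin size
#'
#' The new bin size must be a multiple of the old one; depths are averaged
#' with weights equal to the true base width of each constituent bin, so
#' re-binning agrees exactly with direct computation at the coarser size.
#'
#' @param track A `coverage_track`.
#' @param bin_size New (coarser) bin size, a multiple of `track$bin_size`.
#' @return A `coverage_track` at the new bin size.
#' @export
rebin_track <- function(track, bin_size) {
  stopifnot(inherits(track, "coverage_track"))
  old <- track$bin_size
  if (bin_size == old) return(track)
  if (bin_size %% old != 0)
    stop("rebin_track: new bin size must be a multiple of ", old)
  n_old <- length(track$depths)
  widths <- rep(old, n_old)
  widths[n_old] <- track$contig_length - (n_old - 1) * old
  ratio <- bin_size %/% old
  grp <- rep(seq_len(ceiling(n_old / ratio)), each = ratio,
             length.out = n_old)
  sums <- as.numeric(rowsum(track$depths * widths, grp))
  w <- as.numeric(rowsum(widths, grp))
  coverage_track(track$contig_id, track$contig_length, sums / w,
                 bin_size = bin_size, total_mapped = track$total_mapped,
                 source = track$source)
}
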