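#' Read contig lengths from FASTA, .fai or chrom.sizes
#'
#' Accepts a named numeric vector (returned unchanged), a samtools `.fai`
#' index (5 columns), a two-column chrom.sizes file, or a FASTA file.
#'
#' @param x Named numeric vector or a file path.
#' @return Named numeric vector of contig lengths in bp.
#' @export
read_contig_lengths <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x))) stop("contig lengths must be named")
    return(x)
  }
  stopifnot(is.character(x), length(x) == 1, file.exists(x))
  if (grepl("\\.(fa|fasta|fna)$", x, ignore.case = TRUE)) {
    seqs <- Biostrings::readDNAStringSet(x)
    len <- as.numeric(Biostrings::width(seqs))
    names(len) <- sub("\\s.*$", "", names(seqs))
    return(len)
  }
  tab <- read.table(x, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("cannot parse contig lengths from '", x, "'")
  setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

detect_depth_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bam") return("bam")
  if (ext == "sam") return("sam")
  if (ext %in% c("bedgraph", "bg")) return("bedGraph")
  if (ext %in% c("tsv", "txt", "depth")) return("depth")
  ## sniff: skip track/browser/comment lines
  lines <- readLines(path, n = 50L)
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (!length(lines)) stop("load_depth: cannot detect format of '", path,
                           "': no data lines")
  f <- strsplit(lines[1], "\t| +")[[1]]
  if (length(f) >= 4 && !is.na(suppressWarnings(as.numeric(f[2]))) &&
      !is.na(suppressWarnings(as.numeric(f[3]))))
    return("bedGraph")
  if (length(f) == 3 && !is.na(suppressWarnings(as.numeric(f[2]))))
    return("depth")
  stop("load_depth: unknown format for '", path, "': first data line has ",
       length(f), " fields (expected SAM/BAM, 4-column bedGraph, or ",
       "3-column per-base depth TSV)")
}

#' Load binned coverage tracks from alignments or depth files
#'
#' Reads a coordinate-sorted SAM/BAM alignment, a 3-column per-base depth TSV
#' (contig, 1-based position, depth; zero positions may be omitted) or a
#' 0-based half-open bedGraph, and returns one binned [coverage_track] per
#' contig, including all-zero tracks for covered-nowhere contigs. Depth is the
#' mean per-base depth within each bin; the last partial bin is averaged over
#' its true width.
#'
#' For alignments, contig identities and lengths come from the header and
#' `total_mapped` is the number of mapped alignment records in the file.
#' Multi-mapped reads placed once by the aligner (e.g. `ambiguous=random`)
#' carry mapping quality 0 and are counted by default; raise `min_mapq` to
#' exclude them. For depth files, supply `lengths` (FASTA/.fai/chrom.sizes or
#' named vector) as the contig-length authority; otherwise lengths are
#' inferred from the rightmost covered position with a warning.
#'
#' @param path Input file (SAM, BAM, depth TSV, or bedGraph).
#' @param bin_size Bin width in bp (default 100).
#' @param lengths Optional contig lengths (see [read_contig_lengths()]).
#' @param source Read-set label for the resulting tracks.
#' @param format Override format auto-detection
#'   (`"bam"`, `"sam"`, `"depth"`, `"bedGraph"`).
#' @param min_mapq Minimum mapping quality for alignment records
#'   (default 0: multi-mappers retained once).
#' @param read_length Assumed read length used only to derive `total_mapped`
#'   from depth-file inputs (aligned bases / `read_length`).
#' @return Named list of [coverage_track] objects, one per contig.
#' @export
load_depth <- function(path, bin_size = 100, lengths = NULL,
                       source = c("whole", "vlp"), format = NULL,
                       min_mapq = 0, read_length = 100) {
  source <- match.arg(source)
  stopifnot(file.exists(path), bin_size >= 1)
  format <- format %||% detect_depth_format(path)
  switch(format,
    bam = load_depth_bam(path, bin_size, source, min_mapq),
    sam = load_depth_bam(sam_to_bam(path), bin_size, source, min_mapq),
    depth = load_depth_tsv(path, bin_size, lengths, source, read_length),
    bedGraph = load_depth_bedgraph(path, bin_size, lengths, source,
                                   read_length),
    stop("load_depth: unsupported format '", format, "'"))
}

sam_to_bam <- function(path) {
  dest <- tempfile(fileext = "")
  ## asBam coordinate-sorts and indexes the converted file
  Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
}

load_depth_bam <- function(path, bin_size, source, min_mapq) {
  hdr <- Rsamtools::scanBamHeader(path)[[1]]
  hd <- names(hdr$text)
  if ("@HD" %in% hd) {
    tags <- unlist(hdr$text[hd == "@HD"])
    if (any(grepl("^SO:", tags)) && !any(tags == "SO:coordinate"))
      stop("load_depth: alignment '", path, "' is not coordinate-sorted; ",
           "sort it first (samtools sort) and index it (samtools index)")
  }
  lens <- hdr$targets
  if (!length(lens))
    stop("load_depth: alignment '", path, "' has no reference sequences ",
         "in its header")
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    mapqFilter = if (min_mapq > 0) min_mapq else NA_integer_)
  gal <- GenomicAlignments::readGAlignments(path, param = param)
  cov <- GenomicAlignments::coverage(gal)
  total <- length(gal)
  tracks <- lapply(names(lens), function(id) {
    rle_to_track(cov[[id]], id, lens[[id]], bin_size, total, source)
  })
  names(tracks) <- names(lens)
  tracks
}

rle_to_track <- function(rle, contig_id, contig_length, bin_size, total,
                         source) {
  starts <- seq(1, contig_length, by = bin_size)
  ends <- pmin(starts + bin_size - 1, contig_length)
  d <- IRanges::viewMeans(IRanges::Views(rle, start = starts, end = ends))
  coverage_track(contig_id, contig_length, as.numeric(d),
                 bin_size = bin_size, total_mapped = total, source = source)
}

load_depth_tsv <- function(path, bin_size, lengths, source, read_length) {
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("contig", "pos", "depth"))
  if (is.null(lengths)) {
    warning("load_depth: no contig lengths given; inferring from the ",
            "rightmost covered position")
    lengths <- tapply(tab$pos, tab$contig, max)
    lengths <- setNames(as.numeric(lengths), names(lengths))
  } else lengths <- read_contig_lengths(lengths)
  aligned <- sum(tab$depth)
  total <- max(1, round(aligned / read_length))
  tracks <- lapply(names(lengths), function(id) {
    L <- lengths[[id]]
    v <- numeric(L)
    sub <- tab[tab$contig == id, ]
    if (nrow(sub)) {
      if (any(sub$pos < 1 | sub$pos > L))
        stop("load_depth: position outside contig '", id, "'")
      v[sub$pos] <- sub$depth
    }
    coverage_track(id, L, bin_means(v, bin_size), bin_size = bin_size,
                   total_mapped = total, source = source)
  })
  names(tracks) <- names(lengths)
  tracks
}

load_depth_bedgraph <- function(path, bin_size, lengths, source,
                                read_length) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (is.null(lengths)) {
    lengths <- tapply(GenomicRanges::end(gr),
                      as.character(GenomicRanges::seqnames(gr)), max)
    lengths <- setNames(as.numeric(lengths), names(lengths))
  } else lengths <- read_contig_lengths(lengths)
  aligned <- sum(as.numeric(GenomicRanges::width(gr)) * gr$score)
  total <- max(1, round(aligned / read_length))
  tracks <- lapply(names(lengths), function(id) {
    L <- lengths[[id]]
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == id]
    rle <- S4Vectors::Rle(0, L)
    if (length(sub)) {
      if (max(GenomicRanges::end(sub)) > L)
        stop("load_depth: bedGraph interval beyond contig '", id, "'")
      rle <- IRanges::coverage(GenomicRanges::ranges(sub),
                               weight = sub$score, width = L)
    }
    rle_to_track(rle, id, L, bin_size, total, source)
  })
  names(tracks) <- names(lengths)
  tracks
}

#' Write a coverage track as bedGraph
#'
#' Emits 0-based half-open bedGraph covering the full contig; adjacent bins
#' with equal value are merged into one line (an all-zero track becomes a
#' single line of value 0). A written track round-trips through
#' [load_depth()] within floating-point tolerance.
#'
#' @param track A [coverage_track], or a list of them (written consecutively).
#' @param path Output file path.
#' @param append Append instead of overwrite (used for multi-contig files).
#' @return The path, invisibly.
#' @export
write_track <- function(track, path, append = FALSE) {
  if (inherits(track, "coverage_track")) track <- list(track)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  for (t in track) {
    r <- rle(t$depths)
    ends_bin <- cumsum(r$lengths)
    starts_bp <- c(0, head(ends_bin, -1)) * t$bin_size
    ends_bp <- pmin(ends_bin * t$bin_size, t$contig_length)
    writeLines(sprintf("%s\t%d\t%d\t%.10g", t$contig_id,
                       as.integer(starts_bp), as.integer(ends_bp),
                       r$values), con)
  }
  invisible(path)
}
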