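#' @keywords internal
"_PACKAGE"

#' @importFrom stats acf coef lm mad median quantile rbinom rgeom rlnorm
#'   rmultinom rnorm rpois runif sd setNames
#' @importFrom utils read.table write.table head tail
NULL

## Running mean with shrinking windows at the edges, so a length-n input
## returns a length-n output and no NA padding is introduced.
runmean <- function(x, k) {
  n <- length(x)
  k <- max(1L, as.integer(k))
  if (k == 1L || n <= 1L) return(x)
  if (k > n) k <- n
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (k - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Mean depth per bin from a per-base numeric vector; the last partial bin
## is averaged over its true width.
bin_means <- function(per_base, bin_size) {
  L <- length(per_base)
  n_bins <- ceiling(L / bin_size)
  idx <- rep(seq_len(n_bins), each = bin_size, length.out = L)
  sums <- as.numeric(rowsum(per_base, idx, reorder = TRUE))
  widths <- tabulate(idx, nbins = n_bins)
  sums / widths
}

## Number of bins a contig of length L has at a given bin size.
n_bins_for <- function(contig_length, bin_size) {
  as.integer(ceiling(contig_length / bin_size))
}

## Bin start coordinates (0-based) for a track.
bin_starts <- function(track) {
  (seq_len(length(track$depths)) - 1L) * track$bin_size
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_sig2 <- function(x) signif(x, 2)
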