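#' Normalized-coverage rank table across contigs
#'
#' For each sample (whole community and VLP) every contig's share of the
#' sample's summed mean coverage is computed
#' (mean coverage / sum of mean coverages), and contigs are ranked by share
#' with rank 1 for the highest. DNA genuinely carried in VLPs keeps the same
#' or a better (lower) rank in the VLP sample; cellular contamination is
#' depleted by VLP purification and slips to a worse rank.
#'
#' @param pairs Named list of `paired_coverage` objects (>= 2 contigs).
#' @return A `rank_table` data.frame with columns `contig`, `mean_cov_wgs`,
#'   `mean_cov_vlp`, `share_wgs`, `share_vlp`, `rank_wgs`, `rank_vlp`,
#'   `rank_delta` (`rank_vlp - rank_wgs`). Ranks are a permutation of
#'   1..n; ties in share are broken lexicographically by contig id, and
#'   zero-coverage contigs therefore sort last deterministically.
#' @export
build_rank_table <- function(pairs) {
  if (length(pairs) < 2)
    stop("build_rank_table: need >= 2 contigs (ranks are meaningless ",
         "for a single contig)")
  id <- vapply(pairs, `[[`, "", "contig_id")
  mw <- vapply(pairs, function(p) mean(p$wgs$depths), numeric(1))
  mv <- vapply(pairs, function(p) mean(p$vlp$depths), numeric(1))
  if (sum(mw) == 0 || sum(mv) == 0)
    stop("build_rank_table: a sample has zero total coverage")
  sw <- mw / sum(mw)
  sv <- mv / sum(mv)
  rank_of <- function(share) {
    ord <- order(-share, id)
    r <- integer(length(share)); r[ord] <- seq_along(share)
    r
  }
  out <- data.frame(contig = id, mean_cov_wgs = mw, mean_cov_vlp = mv,
                    share_wgs = sw, share_vlp = sv,
                    rank_wgs = rank_of(sw), rank_vlp = rank_of(sv),
                    stringsAsFactors = FALSE)
  out$rank_delta <- out$rank_vlp - out$rank_wgs
  rownames(out) <- NULL
  class(out) <- c("rank_table", "data.frame")
  out
}

#' Flag candidate contigs for cellular-DNA contamination
#'
#' A candidate whose VLP-sample rank is numerically higher (less abundant)
#' than its whole-community rank is flagged `contamination_suspect`:
#' genuinely packaged DNA is enriched by VLP purification while randomly
#' contaminating cellular DNA is depleted. Equal or better VLP ranks are
#' `consistent`. The screen is advisory: it annotates calls, it does not
#' remove them.
#'
#' @param table A `rank_table` from [build_rank_table()].
#' @param candidates Character vector of contig ids to screen (default: all).
#' @return The table restricted to the candidates, with a `flag` column
#'   (`"consistent"` or `"contamination_suspect"`).
#' @export
flag_contamination <- function(table, candidates = table$contig) {
  missing_ids <- setdiff(candidates, table$contig)
  if (length(missing_ids))
    stop("flag_contamination: unknown contig id(s): ",
         paste(missing_ids, collapse = ", "))
  ## compare on shares first: equal shares (equal rank before tiebreak)
  ## are consistent by definition
  sub <- table[match(candidates, table$contig), ]
  worse <- sub$rank_vlp > sub$rank_wgs & sub$share_vlp != sub$share_wgs
  sub$flag <- ifelse(worse, "contamination_suspect", "consistent")
  rownames(sub) <- NULL
  sub
}
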