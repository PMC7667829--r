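## Shared fixtures built in code: tiny SAM alignments, quick tracks and
## paired-coverage objects used across the test files.

## A coverage track whose normalized depths equal its raw depths
## (total_mapped = 1e6), convenient for feature tests.
quick_track <- function(depths, bin_size = 100, contig_id = "t",
                        source = "vlp", total_mapped = 1e6,
                        contig_length = length(depths) * bin_size) {
  coverage_track(contig_id, contig_length, depths, bin_size = bin_size,
                 total_mapped = total_mapped, source = source)
}

quick_pair <- function(wgs_depths, vlp_depths, bin_size = 100,
                       contig_id = "t", total_wgs = 1e6, total_vlp = 1e6) {
  w <- quick_track(wgs_depths, bin_size, contig_id, "whole", total_wgs)
  v <- quick_track(vlp_depths, bin_size, contig_id, "vlp", total_vlp)
  structure(list(contig_id = contig_id, wgs = w, vlp = v),
            class = "paired_coverage")
}

## Write a coordinate-sorted SAM file: `reads` is a data.frame with columns
## contig, pos (1-based) and len; all reads are simple full-length matches.
write_test_sam <- function(path, contig_lengths, reads) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  reads <- reads[order(match(reads$contig, names(contig_lengths)),
                       reads$pos), ]
  body <- sprintf("r%04d\t0\t%s\t%d\t30\t%dM\t*\t0\t0\t*\t*",
                  seq_len(nrow(reads)), reads$contig,
                  as.integer(reads$pos), as.integer(reads$len))
  writeLines(c(hdr, body), path)
  path
}

## Model used by the Monte-Carlo vs closed-form equivalence checks:
## every packaging mode active on one replicon.
all_modes_model <- function(circular = TRUE) {
  field <- make_bias_field(6e5, fold = 3, corr_length = 60e3, seed = 2)
  genome_model(6e5, circular = circular,
    prophages = list(prophage_element(50e3, 90e3, induction_rate = 5,
      f_spec = 0.2, capsid = 40e3, min_retained = 15e3, side_bias = 0.4,
      lateral_rate = 2, q = 0.6, lateral_direction = "right")),
    islands = list(island_element(450e3, 465e3, hijack_rate = 3)),
    pac_sites = list(pac_site(250e3, rate = 4, headful = 44e3, q = 0.5),
                     pac_site(520e3, rate = 2, headful = 30e3, q = 0.7,
                              strand = "-")),
    gta = gta_params(13e3, n_fragments = 6, bias_field = field))
}
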