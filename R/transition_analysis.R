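# Non-satellite transition analysis: the complement of the monomer hit
# intervals on each read, with any contiguous uncovered stretch of at least
# min_nonsat_length (default 1 kb) flagging the read as containing a
# transition into non-satellite sequence.  Qualifying intervals are exported
# as FASTA + BED for external repeat-library annotation.

#' Uncovered (non-satellite) regions of a read
#'
#' Overlapping hits are unioned before complementation, so the hit intervals
#' and the uncovered intervals exactly partition [0, read length).
#'
#' @param read_length length of the read in bases
#' @param hits monomer hit data.frame for the read (may be empty)
#' @param read_id read identifier
#' @param min_nonsat_length a single uncovered interval at least this long
#'   sets \code{transition_flag} (default 1000)
#' @return a "transition_summary" list: read_id, uncovered_intervals
#'   (data.frame start/end, 0-based half-open, sorted, disjoint),
#'   n_nonsat_bases, transition_flag, min_nonsat_length
#' @export
uncovered_regions <- function(read_length, hits, read_id = NA,
                              min_nonsat_length = 1000L) {
  stopifnot(read_length >= 1)
  if (nrow(hits) > 0) {
    stopifnot(all(hits$start >= 0), all(hits$end <= read_length))
    cov <- IRanges::reduce(IRanges::IRanges(hits$start + 1L, hits$end))
    unc <- IRanges::setdiff(IRanges::IRanges(1L, read_length), cov)
  } else {
    unc <- IRanges::IRanges(1L, read_length)
  }
  iv <- data.frame(start = IRanges::start(unc) - 1L,
                   end = IRanges::end(unc))
  widths <- iv$end - iv$start
  structure(list(
    read_id = read_id,
    uncovered_intervals = iv,
    n_nonsat_bases = as.integer(sum(widths)),
    transition_flag = any(widths >= min_nonsat_length),
    min_nonsat_length = as.integer(min_nonsat_length)),
    class = "transition_summary")
}

#' Export qualifying non-satellite intervals as FASTA and BED
#'
#' Writes every uncovered interval of at least \code{min_nonsat_length}
#' bases as a FASTA record named \code{read_id:start-end} and as a BED row
#' (0-based half-open), ready for external repeat-library masking.
#'
#' @param read_seq the read's nucleotide string
#' @param summary a transition summary with \code{transition_flag} TRUE
#' @param fasta_path,bed_path output paths; existing files are appended to
#'   when \code{append = TRUE}
#' @param append whether to append (default FALSE)
#' @return invisibly, the exported interval data.frame
#' @export
export_nonsatellite <- function(read_seq, summary, fasta_path, bed_path,
                                append = FALSE) {
  if (!isTRUE(summary$transition_flag)) {
    stop("export_nonsatellite: read has no qualifying transition interval")
  }
  iv <- summary$uncovered_intervals
  iv <- iv[iv$end - iv$start >= summary$min_nonsat_length, , drop = FALSE]
  ids <- sprintf("%s:%d-%d", summary$read_id, iv$start, iv$end)
  seqs <- substring(read_seq, iv$start + 1L, iv$end)
  fa <- paste0(">", ids, "\n", seqs)
  if (append) cat(fa, file = fasta_path, sep = "\n", append = TRUE)
  else writeLines(fa, fasta_path)
  bed <- data.frame(summary$read_id, iv$start, iv$end, ids)
  write.table(bed, bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = append)
  invisible(data.frame(read_id = summary$read_id, start = iv$start,
                       end = iv$end, name = ids,
                       stringsAsFactors = FALSE))
}
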