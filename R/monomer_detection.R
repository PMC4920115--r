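# Built-in monomer detector: semi-global alignment of each training monomer
# against the read (model global, read end-gaps free), both strands, tiled
# greedily by score with bounded overlap.  An external profile-HMM hit table
# (parse_external_hits) is an interchangeable front end; everything
# downstream is front-end agnostic.

#' Detection configuration
#'
#' @param min_length minimum emitted monomer length in bases (default 150)
#' @param min_model_identity minimum identity of a hit against its best
#'   model, in [0,1] (default 0.70).  This is the package's stand-in for the
#'   unstated score cutoff of an external profile search.
#' @param max_overlap_fraction two emitted hits may overlap by at most this
#'   fraction of the shorter hit (default 0.1)
#' @return a list of class "detection_config"
#' @export
detection_config <- function(min_length = 150L, min_model_identity = 0.70,
                             max_overlap_fraction = 0.1) {
  stopifnot(min_length > 0,
            min_model_identity >= 0, min_model_identity <= 1,
            max_overlap_fraction >= 0, max_overlap_fraction <= 1)
  structure(list(min_length = as.integer(min_length),
                 min_model_identity = min_model_identity,
                 max_overlap_fraction = max_overlap_fraction),
            class = "detection_config")
}

# Candidate hit ends for one model on one target strand: positions of the
# end-anchored semi-global distance scan that fall under the distance budget,
# grouped into valleys (runs closer than a third of the model length); the
# leftmost minimum of each valley is kept.
scan_candidates <- function(model, target, max_dist) {
  sc <- semiglobal_end_scores(model, target)
  cand <- which(sc <= max_dist)
  if (length(cand) == 0) return(NULL)
  mlen <- nchar(model)
  grp <- cumsum(c(1L, diff(cand) > mlen %/% 3L))
  ends <- vapply(split(cand, grp),
                 function(j) j[which.min(sc[j])], integer(1))
  data.frame(end = unname(ends), dist = sc[unname(ends)])
}

#' Detect monomers on a read
#'
#' Each model is aligned semi-globally against the read and its reverse
#' complement; candidate occurrences are end positions where the full-model
#' edit distance falls under the identity budget.  Hit boundaries come from
#' the alignment; identity is the edit-distance identity
#' \code{1 - D / max(|model|, span)} (the same normalization used for
#' monomer-monomer comparisons).  Candidates from all models and strands are
#' resolved greedily by score (edits under the model length), ties broken by
#' leftmost start then model id, accepting a hit only if it overlaps every
#' accepted hit by at most \code{max_overlap_fraction} of the shorter one.
#'
#' @param read_seq nucleotide string of the read
#' @param read_id read identifier carried into the hit table
#' @param models named character vector of training monomer sequences
#' @param config a \code{\link{detection_config}}
#' @return data.frame of hits sorted by start: read_id, start, end
#'   (0-based half-open, forward strand), strand, model_id, score, identity.
#'   Empty (zero rows) when nothing is detectable.
#' @export
detect_monomers <- function(read_seq, read_id, models,
                            config = detection_config()) {
  stopifnot(nchar(read_seq) >= 1, length(models) >= 1,
            !is.null(names(models)))
  n <- nchar(read_seq)
  targets <- c("+" = read_seq, "-" = revcomp(read_seq))
  cands <- list()
  for (strand in c("+", "-")) {
    target <- targets[[strand]]
    for (mi in seq_along(models)) {
      model <- models[[mi]]
      mlen <- nchar(model)
      max_dist <- floor(mlen * (1 - config$min_model_identity))
      cc <- scan_candidates(model, target, max_dist)
      if (is.null(cc)) next
      for (r in seq_len(nrow(cc))) {
        e <- cc$end[r]
        s <- semiglobal_hit_start(model, target, e, 30L)
        span <- e - s
        if (span < config$min_length) next
        d <- ond_edit_distance(model, substr(target, s + 1L, e))
        identity <- 1 - d / max(mlen, span)
        if (identity < config$min_model_identity) next
        if (strand == "+") {
          fs <- s; fe <- e
        } else {
          fs <- n - e; fe <- n - s
        }
        cands[[length(cands) + 1L]] <- data.frame(
          read_id = read_id, start = fs, end = fe, strand = strand,
          model_id = names(models)[mi], score = mlen - d,
          identity = identity, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cands) == 0) return(empty_hits())
  hits <- do.call(rbind, cands)
  hits <- hits[order(-hits$score, hits$start, hits$model_id), , drop = FALSE]
  acc <- integer(0)
  for (i in seq_len(nrow(hits))) {
    if (length(acc) > 0) {
      ov <- pmin(hits$end[i], hits$end[acc]) -
        pmax(hits$start[i], hits$start[acc])
      shorter <- pmin(hits$end[i] - hits$start[i],
                      hits$end[acc] - hits$start[acc])
      if (any(ov > config$max_overlap_fraction * shorter)) next
    }
    acc <- c(acc, i)
  }
  hits <- hits[acc, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Ordered monomer start index for one read
#'
#' @param hits monomer hit data.frame from a single read
#' @return strictly increasing integer vector of start positions
#' @export
monomer_index <- function(hits) {
  if (nrow(hits) == 0) return(integer(0))
  if (length(unique(hits$read_id)) > 1) {
    stop("monomer_index: hits span multiple reads")
  }
  sort(hits$start)
}

#' Extract strand-normalized monomer sequences for a read's hits
#'
#' Minus-strand hits are reverse-complemented into the forward (model)
#' orientation, so sequences can be compared irrespective of the strand
#' each monomer was found on; orientation stays available in
#' \code{hits$strand} for the inversion check.
#'
#' @param read_seq the read's nucleotide string
#' @param hits hit data.frame sorted by start
#' @return character vector of monomer sequences, one per hit
#' @export
monomer_sequences <- function(read_seq, hits) {
  if (nrow(hits) == 0) return(character(0))
  seqs <- substring(read_seq, hits$start + 1L, hits$end)
  flip <- hits$strand == "-"
  if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
  seqs
}
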