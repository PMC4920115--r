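# Regularity evaluation over the clustered monomer index, read
# classification, HOR period estimation and consensus calling.
#
# For cluster X with ordered start positions X_1 < X_2 < ..., the distance
# set is d_X,i = X_{i+1} - X_i, and d pools these over all clusters.  The
# four regularity conditions are:
#   1. every monomer belongs to a cluster with more than one member;
#   2. 0.95 <= d_X,i / median(d) <= 1.05 for every cluster and i (closed
#      interval);
#   3. the head-to-tail gap between adjacent monomers is <= 5 bases;
#   4. all monomers within a cluster share one orientation (no inversions).

#' Evaluate the four regularity conditions for one read
#'
#' @param hits monomer hit data.frame sorted by start (>= 2 rows)
#' @param assignment the cluster assignment covering exactly these hits
#' @param max_gap condition-3 gap bound in bases (default 5)
#' @param band condition-2 closed ratio band (default c(0.95, 1.05))
#' @return a "regularity_report" list: condition1..condition4, regular,
#'   failing_monomers (ordinals implicated in any failure), d_sets (per
#'   multi-member cluster), median_d
#' @export
evaluate_regularity <- function(hits, assignment, max_gap = 5L,
                                band = c(0.95, 1.05)) {
  n <- nrow(hits)
  if (n < 2) stop("evaluate_regularity: need >= 2 hits")
  stopifnot(length(assignment$labels) == n, !is.unsorted(hits$start))
  labels <- assignment$labels
  failing <- integer(0)

  sizes <- assignment$cluster_sizes
  condition1 <- all(sizes >= 2L)
  if (!condition1) {
    failing <- c(failing, which(labels %in% names(sizes)[sizes < 2L]))
  }

  d_sets <- list()
  for (lab in names(sizes)[sizes >= 2L]) {
    pos <- hits$start[labels == lab]
    d_sets[[lab]] <- diff(sort(pos))
  }
  d <- unlist(d_sets, use.names = FALSE)
  median_d <- if (length(d) > 0) median(d) else NA_real_

  condition2 <- TRUE
  if (length(d) > 0) {
    for (lab in names(d_sets)) {
      ratio <- d_sets[[lab]] / median_d
      bad <- ratio < band[1] - .eps | ratio > band[2] + .eps
      if (any(bad)) {
        condition2 <- FALSE
        idx <- which(labels == lab)
        failing <- c(failing, idx[c(which(bad), which(bad) + 1L)])
      }
    }
  }

  gaps <- hits$start[-1] - hits$end[-n]
  bad_gap <- gaps > max_gap
  condition3 <- !any(bad_gap)
  if (!condition3) {
    failing <- c(failing, which(bad_gap), which(bad_gap) + 1L)
  }

  condition4 <- TRUE
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    st <- hits$strand[idx]
    if (length(unique(st)) > 1) {
      condition4 <- FALSE
      # the minority orientation is the implicated one
      minority <- names(which.min(table(st)))
      failing <- c(failing, idx[st == minority])
    }
  }

  structure(list(
    condition1 = condition1, condition2 = condition2,
    condition3 = condition3, condition4 = condition4,
    regular = condition1 && condition2 && condition3 && condition4,
    failing_monomers = sort(unique(failing)),
    d_sets = d_sets, median_d = median_d),
    class = "regularity_report")
}

#' Estimate the HOR period in monomers
#'
#' \code{round(median(d) / median monomer span)}: with gaps bounded by 5
#' bases the pooled inter-occurrence distance divided by the typical monomer
#' span counts the monomers per HOR unit.
#'
#' @param report a regularity report (supplies median(d))
#' @param hits the read's monomer hits (supply the spans)
#' @return integer period
#' @export
estimate_period <- function(report, hits) {
  if (is.na(report$median_d)) {
    stop("estimate_period: no multi-member cluster")
  }
  span <- median(hits$end - hits$start)
  as.integer(round(report$median_d / span))
}

#' Classify one read
#'
#' Combines the threshold scan, the regularity report and the transition
#' summary into the final taxonomy:
#' \itemize{
#'   \item \strong{regular}: a grid threshold satisfied condition 1, all
#'     four conditions hold, and the estimated period is >= 2 (a single
#'     merged cluster with uniform spacing is plain monomeric tandem, not a
#'     higher-order unit, and falls to no-HOR);
#'   \item \strong{irregular}: condition 1 was satisfiable but conditions
#'     2-4 fail, or condition 1 is unsatisfiable on the whole grid yet at
#'     least two multi-member clusters exist at 0.88 (a disrupted array);
#'     condition-4 failures additionally set \code{inversion_flag};
#'   \item \strong{no-HOR}: fewer than two monomers, all mutual identities
#'     below 0.88 (\code{monomeric_flag}), all-singleton clustering at 0.88,
#'     or a single HOR copy / no higher-order structure.
#' }
#'
#' @param read_id,read_length identity and length of the read
#' @param hits monomer hit data.frame (may be empty)
#' @param scan result of \code{\link{select_threshold}} or NULL when < 2
#'   monomers
#' @param report regularity report at the selected threshold, or NULL
#' @param transition transition summary from
#'   \code{\link{uncovered_regions}}, or NULL
#' @param monomeric_floor identity below which satellite is monomeric
#'   (default 0.88, the low end of the scan grid)
#' @return a "read_classification" list
#' @export
classify_read <- function(read_id, read_length, hits, scan = NULL,
                          report = NULL, transition = NULL,
                          monomeric_floor = 0.88) {
  n <- nrow(hits)
  cl <- list(read_id = read_id, read_length = read_length,
             n_monomers = n, n_clusters = NA_integer_,
             selected_threshold = NA_real_, label = "no-HOR",
             inversion_flag = FALSE, monomeric_flag = FALSE,
             transition_flag = FALSE, hor_period = NA_integer_,
             approx_period = NA_integer_,
             median_monomer_identity = if (n > 0)
               median(hits$identity) else NA_real_,
             n_nonsat_bases = if (is.null(transition))
               NA_integer_ else transition$n_nonsat_bases,
             nonsat_intervals = if (is.null(transition)) NULL else
               transition$uncovered_intervals[
                 transition$uncovered_intervals$end -
                   transition$uncovered_intervals$start >=
                   transition$min_nonsat_length, , drop = FALSE],
             note = NA_character_)
  if (!is.null(transition)) cl$transition_flag <- transition$transition_flag

  if (n < 2) {
    cl$note <- "insufficient-monomers"
    return(structure(cl, class = "read_classification"))
  }
  stopifnot(!is.null(scan))
  idm <- scan$idm
  off <- idm[upper.tri(idm)]
  cl$n_clusters <- length(scan$assignment$cluster_sizes)
  cl$selected_threshold <- scan$threshold

  if (all(off < monomeric_floor - .eps)) {
    cl$monomeric_flag <- TRUE
    cl$note <- "monomeric"
    return(structure(cl, class = "read_classification"))
  }

  if (scan$assignment$supports_hor) {
    stopifnot(!is.null(report))
    period <- estimate_period(report, hits)
    if (report$regular && period >= 2L) {
      cl$label <- "regular"
      cl$hor_period <- period
    } else if (report$regular) {
      cl$note <- "no-higher-order-structure"
    } else {
      cl$label <- "irregular"
      cl$inversion_flag <- !report$condition4
      cl$approx_period <- if (!is.na(report$median_d)) period else
        NA_integer_
    }
  } else {
    # condition 1 unattainable anywhere on the grid: a disrupted array is
    # still irregular if at least two clusters repeat at the 0.88 floor
    multi <- sum(scan$assignment$cluster_sizes >= 2L)
    if (multi >= 2L) {
      cl$label <- "irregular"
      if (!is.null(report)) cl$inversion_flag <- !report$condition4
    } else {
      cl$note <- "single-copy-or-incomplete"
    }
  }
  structure(cl, class = "read_classification")
}

#' Per-cluster and full-unit consensus sequences for a regular read
#'
#' Each cluster's members (strand-normalized) are aligned globally to the
#' cluster medoid (the member with minimal summed edit distance to the
#' others; ties broken by read order) and a column-wise majority is taken
#' over medoid positions; majority deletions drop the column, insertions
#' relative to the medoid are ignored, and ties keep the medoid base.  The
#' full-unit consensus concatenates the cluster consensi in within-unit
#' order (order of first appearance along the read).
#'
#' @param read_seq the read's nucleotide string
#' @param hits monomer hit data.frame sorted by start
#' @param assignment cluster assignment for these hits
#' @param read_id id used to name output records
#' @return named character vector: one consensus per cluster
#'   ("<id>/cluster_<label>") plus "<id>/unit"
#' @export
hor_consensus <- function(read_seq, hits, assignment, read_id = "read") {
  seqs <- monomer_sequences(read_seq, hits)
  labels <- assignment$labels
  out <- character(0)
  unit <- character(0)
  for (lab in unique(labels)) {
    members <- seqs[labels == lab]
    cons <- majority_consensus(members)
    out[sprintf("%s/cluster_%s", read_id, lab)] <- cons
    unit <- c(unit, cons)
  }
  out[sprintf("%s/unit", read_id)] <- paste(unit, collapse = "")
  out
}

majority_consensus <- function(members) {
  if (length(members) == 1) return(members[[1]])
  dm <- matrix(0, length(members), length(members))
  for (i in seq_along(members)) {
    for (j in seq_along(members)) {
      if (i < j) {
        dm[i, j] <- dm[j, i] <- ond_edit_distance(members[i], members[j])
      }
    }
  }
  medoid <- which.min(rowSums(dm))
  ref <- members[[medoid]]
  cols <- matrix("-", nrow = length(members), ncol = nchar(ref))
  for (i in seq_along(members)) {
    if (i == medoid) {
      cols[i, ] <- strsplit(ref, "")[[1]]
      next
    }
    al <- global_align(members[[i]], ref)
    p <- strsplit(al[1], "")[[1]]
    s <- strsplit(al[2], "")[[1]]
    keep <- s != "-"  # columns that exist in the medoid
    cols[i, ] <- p[keep]
  }
  ref_chars <- strsplit(ref, "")[[1]]
  cons <- vapply(seq_len(ncol(cols)), function(j) {
    tab <- table(cols[, j])
    top <- names(tab)[tab == max(tab)]
    if (ref_chars[j] %in% top) ref_chars[j] else top[1]
  }, character(1))
  paste(cons[cons != "-"], collapse = "")
}
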