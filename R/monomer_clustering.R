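# Clustering of a read's monomers by pairwise identity: single-linkage
# connected components of the >=-threshold similarity graph, with the
# threshold scanned from 98% down to 88% in 1% decrements.

# Closed-interval comparisons on ratios/thresholds use a small epsilon so
# that values sitting exactly on a boundary (e.g. a ratio of 0.95 stored in
# binary floating point) are treated as inside.
.eps <- 1e-9

#' Pairwise sequence identity
#'
#' \code{1 - D / max(|a|, |b|)} where D is the unit-cost edit distance
#' (substitutions, insertions, deletions) computed by the O(ND)
#' band-doubling algorithm.  The max-length denominator makes the measure
#' symmetric and conservative; the 88% monomeric boundary inherits this
#' normalization.
#'
#' @param a,b non-empty nucleotide strings
#' @return identity in [0, 1]
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) {
    stop("pairwise_identity: empty sequence")
  }
  1 - ond_edit_distance(a, b) / max(nchar(a), nchar(b))
}

#' All-against-all identity matrix for a set of monomer sequences
#'
#' @param seqs character vector of (strand-normalized) monomer sequences
#' @return symmetric numeric matrix with unit diagonal
#' @export
identity_matrix <- function(seqs) {
  n <- length(seqs)
  m <- diag(1, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        m[i, j] <- m[j, i] <- pairwise_identity(seqs[i], seqs[j])
      }
    }
  }
  m
}

# Connected components of the graph with an edge wherever idm >= threshold;
# component labels numbered by first appearance (lowest member ordinal).
components_at <- function(idm, threshold) {
  n <- nrow(idm)
  comp <- integer(n)
  next_label <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    next_label <- next_label + 1L
    queue <- i
    comp[i] <- next_label
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(idm[v, ] >= threshold - .eps & comp == 0L)
      comp[nb] <- next_label
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Cluster a read's monomers at one identity threshold
#'
#' Clusters are the connected components (single linkage) of the graph with
#' an edge (i, j) whenever \code{pairwise_identity(seq_i, seq_j) >=
#' threshold}.  Sequences must already be strand-normalized
#' (\code{\link{monomer_sequences}}).  Labels are letters A, B, C, ... in
#' order of first appearance along the read.
#'
#' @param monomer_seqs character vector of monomer sequences in read order
#' @param threshold identity threshold in [0, 1]
#' @param read_id optional read id carried on the assignment
#' @param idm optional precomputed identity matrix (avoids recomputation
#'   during the threshold scan)
#' @return a "cluster_assignment" list: read_id, threshold, labels (one per
#'   monomer), cluster_sizes (named by label), supports_hor (all clusters
#'   multi-member)
#' @export
cluster_at_threshold <- function(monomer_seqs, threshold, read_id = NA,
                                 idm = NULL) {
  stopifnot(length(monomer_seqs) >= 1, threshold >= 0, threshold <= 1)
  if (is.null(idm)) idm <- identity_matrix(monomer_seqs)
  comp <- components_at(idm, threshold)
  labels <- cluster_label(comp)
  sizes <- table(factor(labels, levels = unique(labels)))
  sizes <- stats::setNames(as.integer(sizes), names(sizes))
  structure(list(read_id = read_id, threshold = threshold, labels = labels,
                 cluster_sizes = sizes,
                 supports_hor = all(sizes >= 2L)),
            class = "cluster_assignment")
}

#' Identity threshold grid
#'
#' @param high,low,step grid bounds and decrement; defaults 0.98, 0.88, 0.01
#'   (11 points, both ends inclusive)
#' @return decreasing numeric vector of thresholds
#' @export
threshold_grid <- function(high = 0.98, low = 0.88, step = 0.01) {
  stopifnot(high >= low, step > 0)
  seq(high, low - .eps, by = -step)
}

#' Select the clustering threshold for a read
#'
#' Thresholds 0.98, 0.97, ..., 0.88 are evaluated in order and the FIRST
#' (highest) one whose clustering assigns every monomer to a multi-member
#' cluster (regularity condition 1) is returned.  If no grid point
#' qualifies, the 0.88 assignment is returned with
#' \code{supports_hor = FALSE}: such reads cannot support HOR inference and
#' fall to the no-HOR taxonomy downstream.
#'
#' @param monomer_seqs >= 2 strand-normalized monomer sequences in read
#'   order
#' @param grid decreasing threshold vector (default
#'   \code{\link{threshold_grid}()})
#' @param read_id optional read id
#' @param idm optional precomputed identity matrix
#' @return list(threshold, assignment, idm)
#' @export
select_threshold <- function(monomer_seqs, grid = threshold_grid(),
                             read_id = NA, idm = NULL) {
  if (length(monomer_seqs) < 2) {
    stop("select_threshold: need >= 2 monomers")
  }
  if (is.null(idm)) idm <- identity_matrix(monomer_seqs)
  for (th in grid) {
    a <- cluster_at_threshold(monomer_seqs, th, read_id, idm)
    if (a$supports_hor) {
      return(list(threshold = th, assignment = a, idm = idm))
    }
  }
  a <- cluster_at_threshold(monomer_seqs, grid[length(grid)], read_id, idm)
  list(threshold = grid[length(grid)], assignment = a, idm = idm)
}
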