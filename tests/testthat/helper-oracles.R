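# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: edit distance comes from utils::adist (full
# O(nm) dynamic programming), single-linkage clustering from
# stats::hclust + cutree on the oracle distance matrix.

dp_edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

dp_identity <- function(a, b) {
  1 - dp_edit_distance(a, b) / max(nchar(a), nchar(b))
}

# Single-linkage clusters at an identity threshold, as integer component
# ids numbered by first appearance.
oracle_clusters <- function(seqs, threshold) {
  n <- length(seqs)
  if (n == 1) return(1L)
  idm <- matrix(1, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      idm[i, j] <- idm[j, i] <- dp_identity(seqs[i], seqs[j])
    }
  }
  hc <- stats::hclust(stats::as.dist(1 - idm), method = "single")
  memb <- stats::cutree(hc, h = 1 - threshold + 1e-9)
  # renumber by first appearance
  as.integer(factor(memb, levels = unique(memb)))
}

oracle_select_threshold <- function(seqs, grid = seq(0.98, 0.88, -0.01)) {
  for (th in grid) {
    cl <- oracle_clusters(seqs, th)
    if (all(table(cl) >= 2)) return(th)
  }
  NA_real_
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly n random positions (test-local, independent of the
# package's mutator)
sub_n <- function(seq, n) {
  ch <- strsplit(seq, "")[[1]]
  n <- min(n, length(ch))
  pos <- sample(length(ch), n)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# Hand-built hit table for condition tests: k-monomer unit repeated
# n_units times, monomer length ml, zero gaps.
tandem_hits <- function(k, n_units, ml = 171L, read_id = "r1") {
  n <- k * n_units
  starts <- (seq_len(n) - 1L) * ml
  data.frame(read_id = read_id, start = starts, end = starts + ml,
             strand = "+",
             model_id = "m1", score = ml, identity = 1,
             stringsAsFactors = FALSE)
}

tandem_assignment <- function(k, n_units, read_id = "r1") {
  labels <- rep(LETTERS[seq_len(k)], n_units)
  sizes <- stats::setNames(rep(as.integer(n_units), k), LETTERS[seq_len(k)])
  structure(list(read_id = read_id, threshold = 0.98, labels = labels,
                 cluster_sizes = sizes, supports_hor = all(sizes >= 2)),
            class = "cluster_assignment")
}

# One analyze_read round trip for a synthetic spec, using the family
# ancestor as the single training model.
classify_spec <- function(sp, config = pipeline_config(min_read_length = 500)) {
  r <- synthesize_read(sp)
  h <- detect_monomers(r$sequence, r$id, c(anc = r$family$ancestor),
                       config$detection)
  list(read = r,
       result = analyze_read(r$sequence, r$id, h, config),
       hits = h)
}
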