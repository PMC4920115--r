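# Ground-truth generator: satellite reads built as flank + n_units tandem
# copies of a k-monomer HOR unit + flank, with controlled within-cluster and
# between-cluster divergence, per-base read error, and planted anomalies
# (inversion, monomer deletion/insertion, non-satellite insertion,
# whole-read reverse complement, monomeric mode).  Every planted feature is
# recorded with exact final coordinates: mutations are applied per segment,
# so segment boundaries remain known even when read error introduces indels.

DNA <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(DNA, n, replace = TRUE),
                                collapse = "")

# Substitute exactly n_mut positions (sampled without replacement) with a
# different base.  Divergence scales that must respect identity bands
# (between-cluster, monomeric) use this deterministic-count form so the
# planted identity structure is a stated property of the world, not a noise
# outcome; placement stays random.
mutate_exact <- function(seq, n_mut) {
  if (n_mut == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), n_mut)
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA, b), 1),
                    character(1))
  paste(ch, collapse = "")
}

# Per-base binomial substitutions (small-scale, non-critical divergence).
mutate_binomial <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(DNA, b), 1),
                      character(1))
  }
  paste(ch, collapse = "")
}

# Post-correction long-read error: per base, with probability `rate`, a
# substitution (1/2), a single-base insertion after the base (1/4) or a
# deletion of the base (1/4).
apply_read_error <- function(seq, rate) {
  if (rate == 0 || nchar(seq) == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) {
    op <- sample(c("sub", "ins", "del"), 1, prob = c(0.5, 0.25, 0.25))
    ch[i] <- switch(op,
      sub = sample(setdiff(DNA, substr(ch[i], 1, 1)), 1),
      ins = paste0(ch[i], sample(DNA, 1)),
      del = "")
  }
  paste(ch, collapse = "")
}

#' Specification of one synthetic satellite read
#'
#' @param seed integer RNG seed; all randomness in the read derives from it
#' @param monomer_length monomer size in bases (default 171, alpha
#'   satellite)
#' @param period_k monomers per HOR unit (default 4)
#' @param n_units tandem copies of the unit (default 3)
#' @param within_cluster_divergence expected pairwise substitution rate
#'   among copies of the same monomer (default 0.005)
#' @param between_cluster_divergence expected pairwise substitution rate
#'   between distinct monomers of the unit (default 0.08, i.e. ~92%
#'   identity, inside the 88-98% scan window)
#' @param read_error_rate residual per-base error of the quality-assessed
#'   read (default 0.01; substitutions and single-base indels)
#' @param anomalies list of planted events, each a list with a \code{type}
#'   of "inversion", "deletion" or "insertion" (fields \code{unit},
#'   \code{monomer}), "nonsat" (fields \code{after_unit}, \code{length}),
#'   or "revcomp" (whole read)
#' @param flanks two non-satellite flank lengths in bases (default c(0, 0))
#' @param monomeric generate divergent monomeric satellite instead of an
#'   HOR array (no unit structure; see \code{monomeric_divergence})
#' @param monomeric_divergence pairwise substitution rate among monomeric
#'   copies (default 0.20, i.e. ~80% identity, below the 88% floor)
#' @return a "synthetic_read_spec" list
#' @export
synthetic_read_spec <- function(seed, monomer_length = 171L, period_k = 4L,
                                n_units = 3L,
                                within_cluster_divergence = 0.005,
                                between_cluster_divergence = 0.08,
                                read_error_rate = 0.01,
                                anomalies = list(), flanks = c(0L, 0L),
                                monomeric = FALSE,
                                monomeric_divergence = 0.20) {
  stopifnot(period_k >= 1, n_units >= 1, monomer_length >= 20,
            between_cluster_divergence > within_cluster_divergence,
            within_cluster_divergence >= 0,
            between_cluster_divergence <= 0.3, read_error_rate >= 0,
            read_error_rate <= 0.3, length(flanks) == 2)
  for (a in anomalies) {
    if (!a$type %in% c("inversion", "deletion", "insertion", "nonsat",
                       "revcomp")) {
      stop("unknown anomaly type: ", a$type)
    }
    if (a$type %in% c("inversion", "deletion", "insertion")) {
      if (a$unit < 1 || a$unit > n_units || a$monomer < 1 ||
          a$monomer > period_k) {
        stop("anomaly coordinates out of range")
      }
    }
  }
  structure(list(seed = as.integer(seed),
                 monomer_length = as.integer(monomer_length),
                 period_k = as.integer(period_k),
                 n_units = as.integer(n_units),
                 within_cluster_divergence = within_cluster_divergence,
                 between_cluster_divergence = between_cluster_divergence,
                 read_error_rate = read_error_rate,
                 anomalies = anomalies, flanks = as.integer(flanks),
                 monomeric = monomeric,
                 monomeric_divergence = monomeric_divergence),
            class = "synthetic_read_spec")
}

#' Generate a k-monomer family from one random ancestor
#'
#' Each family member carries exactly
#' \code{round(between_cluster_divergence / 2 * monomer_length)}
#' substitutions relative to the ancestor, so any two members differ at
#' close to \code{between_cluster_divergence} of their positions
#' (identity ~0.92 at the default).  Deterministic given the spec seed.
#'
#' @param spec a \code{\link{synthetic_read_spec}}
#' @return list(monomers = character vector of length period_k,
#'   ancestor = character scalar)
#' @export
make_monomer_family <- function(spec) {
  n_mut <- round(spec$between_cluster_divergence / 2 * spec$monomer_length)
  if (spec$period_k > 1 && n_mut < 1) {
    stop("between_cluster_divergence too small to separate ",
         spec$period_k, " monomers")
  }
  set.seed(spec$seed %% 2147483647L)
  ancestor <- random_dna(spec$monomer_length)
  monomers <- if (spec$period_k == 1) ancestor else
    vapply(seq_len(spec$period_k),
           function(i) mutate_exact(ancestor, n_mut), character(1))
  list(monomers = monomers, ancestor = ancestor)
}

#' Synthesize one satellite read with ground truth
#'
#' @param spec a \code{\link{synthetic_read_spec}}
#' @return list(id, sequence, truth, family) where truth is a list with
#'   \code{intervals} (data.frame: start, end, kind, cluster, strand, unit),
#'   \code{expected_label}, \code{expected_period},
#'   \code{expected_inversion}, \code{expected_monomeric},
#'   \code{expected_transition}, \code{anomalies}
#' @export
synthesize_read <- function(spec) {
  fam <- make_monomer_family(spec)  # also seeds the RNG
  k <- spec$period_k

  segs <- list()
  add <- function(seq, kind, cluster = NA, strand = "+", unit = NA) {
    segs[[length(segs) + 1L]] <<- list(seq = seq, kind = kind,
                                       cluster = cluster, strand = strand,
                                       unit = unit)
  }
  if (spec$flanks[1] > 0) add(random_dna(spec$flanks[1]), "flank")

  if (spec$monomeric) {
    n_mut <- round(spec$monomeric_divergence / 2 * spec$monomer_length)
    for (i in seq_len(k * spec$n_units)) {
      add(mutate_exact(fam$ancestor, n_mut), "monomer",
          cluster = cluster_label(i), unit = 1L)
    }
  } else {
    within_copy_rate <- spec$within_cluster_divergence / 2
    for (u in seq_len(spec$n_units)) {
      for (m in seq_len(k)) {
        anns <- Filter(function(a)
          a$type %in% c("inversion", "deletion", "insertion") &&
            a$unit == u && a$monomer == m, spec$anomalies)
        deleted <- any(vapply(anns, function(a) a$type == "deletion",
                              logical(1)))
        if (!deleted) {
          s <- mutate_binomial(fam$monomers[m], within_copy_rate)
          inv <- any(vapply(anns, function(a) a$type == "inversion",
                            logical(1)))
          if (inv) add(revcomp(s), "monomer", cluster_label(m), "-", u)
          else add(s, "monomer", cluster_label(m), "+", u)
        }
        if (any(vapply(anns, function(a) a$type == "insertion",
                       logical(1)))) {
          add(mutate_binomial(fam$monomers[m], within_copy_rate),
              "monomer", cluster_label(m), "+", u)
        }
      }
      nonsats <- Filter(function(a) a$type == "nonsat" &&
                          a$after_unit == u, spec$anomalies)
      for (a in nonsats) add(random_dna(a$length), "nonsat")
    }
  }
  if (spec$flanks[2] > 0) add(random_dna(spec$flanks[2]), "flank")

  for (i in seq_along(segs)) {
    segs[[i]]$seq <- apply_read_error(segs[[i]]$seq, spec$read_error_rate)
  }
  if (any(vapply(spec$anomalies, function(a) a$type == "revcomp",
                 logical(1)))) {
    segs <- rev(segs)
    for (i in seq_along(segs)) {
      segs[[i]]$seq <- revcomp(segs[[i]]$seq)
      if (segs[[i]]$kind == "monomer") {
        segs[[i]]$strand <- if (segs[[i]]$strand == "+") "-" else "+"
      }
    }
  }

  lens <- vapply(segs, function(s) nchar(s$seq), integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens
  truth_iv <- data.frame(
    start = starts, end = ends,
    kind = vapply(segs, function(s) s$kind, character(1)),
    cluster = vapply(segs, function(s) as.character(s$cluster),
                     character(1)),
    strand = vapply(segs, function(s) s$strand, character(1)),
    unit = vapply(segs, function(s) as.integer(s$unit), integer(1)),
    stringsAsFactors = FALSE)

  types <- vapply(spec$anomalies, function(a) a$type, character(1))
  has_nonsat_1kb <- any(types == "nonsat" &
    vapply(spec$anomalies,
           function(a) a$type == "nonsat" && a$length >= 1000, logical(1)))
  structural <- any(types %in% c("inversion", "deletion", "insertion",
                                 "nonsat"))
  expected_label <-
    if (spec$monomeric) "no-HOR"
    else if (structural) "irregular"
    else if (spec$n_units < 2 || spec$period_k < 2) "no-HOR"
    else "regular"

  truth <- list(
    intervals = truth_iv,
    expected_label = expected_label,
    expected_period = if (expected_label == "regular") spec$period_k else
      NA_integer_,
    expected_inversion = any(types == "inversion"),
    expected_monomeric = spec$monomeric,
    expected_transition = has_nonsat_1kb,
    anomalies = spec$anomalies)
  list(id = sprintf("synth_seed%d", spec$seed),
       sequence = paste(vapply(segs, function(s) s$seq, character(1)),
                        collapse = ""),
       truth = truth, family = fam)
}

#' Generate a set of synthetic reads with a shared monomer family style
#'
#' Each read gets its own spec with a seed derived from the master seed by a
#' fixed counter scheme (kept below 2^31), so the whole set is reproducible
#' from one integer and individual reads can be regenerated independently.
#'
#' @param n number of reads
#' @param seed master seed
#' @param ... forwarded to \code{\link{synthetic_read_spec}}
#' @return list(reads = named character vector, truth = list per read,
#'   specs = list per read)
#' @export
simulate_reads <- function(n, seed, ...) {
  stopifnot(n >= 1)
  reads <- character(0)
  truth <- list()
  specs <- list()
  for (i in seq_len(n)) {
    sp <- synthetic_read_spec(seed = (seed * 7919L + i) %% 2147483629L, ...)
    r <- synthesize_read(sp)
    id <- sprintf("synth_%03d_seed%d", i, sp$seed)
    reads[[id]] <- r$sequence
    truth[[id]] <- r$truth
    specs[[id]] <- sp
  }
  list(reads = reads, truth = truth, specs = specs)
}

#' Write a simulated read set as FASTA plus ground-truth tables
#'
#' Emits the reads, a per-read truth TSV (expected label, period, flags)
#' and a BED of planted monomer intervals.
#'
#' @param sim result of \code{\link{simulate_reads}}
#' @param fasta_path,truth_path,bed_path output paths
#' @return invisibly, the truth data.frame
#' @export
write_simulation <- function(sim, fasta_path, truth_path, bed_path) {
  write_fasta(sim$reads, fasta_path)
  tr <- do.call(rbind, lapply(names(sim$truth), function(id) {
    t <- sim$truth[[id]]
    data.frame(read_id = id, expected_label = t$expected_label,
               expected_period = t$expected_period,
               expected_inversion = t$expected_inversion,
               expected_monomeric = t$expected_monomeric,
               expected_transition = t$expected_transition,
               stringsAsFactors = FALSE)
  }))
  write.table(tr, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  iv <- do.call(rbind, lapply(names(sim$truth), function(id) {
    x <- sim$truth[[id]]$intervals
    x <- x[x$kind == "monomer", , drop = FALSE]
    if (nrow(x) == 0) return(NULL)
    data.frame(read_id = id, start = x$start, end = x$end,
               name = sprintf("%s:%s", x$cluster, x$strand),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(iv)) write_bed(iv, bed_path) else file.create(bed_path)
  invisible(tr)
}
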