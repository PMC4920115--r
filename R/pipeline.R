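# End-to-end orchestration: detect (or ingest) monomers per read, select
# the clustering threshold, evaluate regularity, classify, analyze
# transitions, and write the summary TSV, consensus FASTA, non-satellite
# BED/FASTA and a run manifest.

#' Pipeline configuration
#'
#' Houses every tunable of the workflow: the detector settings, the 98-88%
#' threshold scan grid, the closed [0.95, 1.05] spacing band of condition 2,
#' the 5-base gap bound of condition 3, the 1 kb non-satellite transition
#' rule and the minimum read length admitted to analysis.
#'
#' @param detection a \code{\link{detection_config}}
#' @param grid_high,grid_low,grid_step threshold scan grid (defaults 0.98,
#'   0.88, 0.01)
#' @param band_low,band_high condition-2 ratio band (defaults 0.95, 1.05)
#' @param max_gap condition-3 bound in bases (default 5)
#' @param min_nonsat_length transition rule in bases (default 1000)
#' @param min_read_length reads shorter than this are skipped (default
#'   2000)
#' @return a list of class "pipeline_config"
#' @export
pipeline_config <- function(detection = detection_config(),
                            grid_high = 0.98, grid_low = 0.88,
                            grid_step = 0.01, band_low = 0.95,
                            band_high = 1.05, max_gap = 5L,
                            min_nonsat_length = 1000L,
                            min_read_length = 2000L) {
  stopifnot(grid_high >= grid_low, band_low < 1, band_high > 1)
  structure(list(detection = detection,
                 grid = threshold_grid(grid_high, grid_low, grid_step),
                 grid_low = grid_low,
                 band = c(band_low, band_high),
                 max_gap = as.integer(max_gap),
                 min_nonsat_length = as.integer(min_nonsat_length),
                 min_read_length = as.integer(min_read_length)),
            class = "pipeline_config")
}

#' Analyze a single read from its monomer hits
#'
#' The front-end-agnostic core: given a read and its hit table (built-in
#' detector or external profile search), runs threshold selection,
#' regularity evaluation, transition analysis and classification.
#'
#' @param read_seq nucleotide string
#' @param read_id read identifier
#' @param hits monomer hit data.frame for this read
#' @param config a \code{\link{pipeline_config}}
#' @return list(classification, hits, scan, report, transition, consensus)
#'   where consensus is a named character vector for regular reads and NULL
#'   otherwise
#' @export
analyze_read <- function(read_seq, read_id, hits,
                         config = pipeline_config()) {
  n <- nchar(read_seq)
  transition <- uncovered_regions(n, hits, read_id,
                                  config$min_nonsat_length)
  if (nrow(hits) < 2) {
    cl <- classify_read(read_id, n, hits, transition = transition,
                        monomeric_floor = config$grid_low)
    return(list(classification = cl, hits = hits, scan = NULL,
                report = NULL, transition = transition, consensus = NULL))
  }
  seqs <- monomer_sequences(read_seq, hits)
  scan <- select_threshold(seqs, config$grid, read_id)
  report <- evaluate_regularity(hits, scan$assignment, config$max_gap,
                                config$band)
  cl <- classify_read(read_id, n, hits, scan, report, transition,
                      monomeric_floor = config$grid_low)
  consensus <- if (cl$label == "regular") {
    hor_consensus(read_seq, hits, scan$assignment, read_id)
  } else NULL
  list(classification = cl, hits = hits, scan = scan, report = report,
       transition = transition, consensus = consensus)
}

#' Run the full workflow over a read set
#'
#' For every read passing the length filter: detect (or ingest) monomers,
#' select the clustering threshold, evaluate regularity, classify, analyze
#' transitions; then write \code{summary.tsv}, \code{consensus.fasta},
#' \code{nonsatellite.bed} + \code{nonsatellite.fasta} and
#' \code{manifest.json} under \code{out_dir}.  Output files are written to
#' temporary names and atomically renamed.  Fully deterministic: same
#' inputs and config give byte-identical outputs.
#'
#' @param reads named character vector of read sequences, or a path to a
#'   FASTA file
#' @param monomers named character vector of training monomers, or a FASTA
#'   path (exactly one of \code{monomers}/\code{hits} must be given)
#' @param hits precomputed monomer hit data.frame (e.g. from
#'   \code{\link{parse_external_hits}})
#' @param out_dir output directory, created if needed
#' @param config a \code{\link{pipeline_config}}
#' @param quiet suppress progress messages
#' @return invisibly, a list with the classification list, the summary
#'   data.frame and the output paths
#' @export
run_pipeline <- function(reads, monomers = NULL, hits = NULL,
                         out_dir = ".", config = pipeline_config(),
                         quiet = FALSE) {
  if (is.character(reads) && length(reads) == 1 && is.null(names(reads))) {
    reads <- read_fasta(reads)
  }
  if (!is.null(monomers) && !is.null(hits)) {
    stop("give exactly one of monomers / hits")
  }
  if (is.null(monomers) && is.null(hits)) {
    stop("give exactly one of monomers / hits")
  }
  if (is.character(monomers) && length(monomers) == 1 &&
      is.null(names(monomers))) {
    monomers <- read_fasta(monomers)
  }
  keep <- nchar(reads) >= config$min_read_length
  if (!any(keep)) {
    stop("no read passes the minimum length filter (",
         config$min_read_length, " bp)")
  }
  reads <- reads[keep]
  if (!quiet) message("analyzing ", length(reads), " reads")

  results <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    id <- names(reads)[i]
    h <- if (is.null(hits)) {
      detect_monomers(reads[[i]], id, monomers, config$detection)
    } else {
      hh <- hits[hits$read_id == id, , drop = FALSE]
      hh <- hh[order(hh$start), , drop = FALSE]
      rownames(hh) <- NULL
      hh
    }
    results[[i]] <- analyze_read(reads[[i]], id, h, config)
  }
  names(results) <- names(reads)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(summary = file.path(out_dir, "summary.tsv"),
                consensus = file.path(out_dir, "consensus.fasta"),
                nonsat_bed = file.path(out_dir, "nonsatellite.bed"),
                nonsat_fasta = file.path(out_dir, "nonsatellite.fasta"),
                manifest = file.path(out_dir, "manifest.json"))
  tmp <- lapply(paths, function(p) paste0(p, ".tmp"))

  classifications <- lapply(results, function(r) r$classification)
  write_read_summary(classifications, tmp$summary)

  cons <- do.call(c, unname(lapply(results, function(r) r$consensus)))
  if (length(cons) > 0) write_fasta(cons, tmp$consensus)
  else file.create(tmp$consensus)

  file.create(tmp$nonsat_bed)
  file.create(tmp$nonsat_fasta)
  first <- TRUE
  for (r in results) {
    if (isTRUE(r$transition$transition_flag)) {
      export_nonsatellite(reads[[r$classification$read_id]], r$transition,
                          tmp$nonsat_fasta, tmp$nonsat_bed,
                          append = !first)
      first <- FALSE
    }
  }

  manifest <- list(
    package = "horscan",
    version = as.character(utils::packageVersion("horscan")),
    n_reads = length(reads),
    config = list(
      min_length = config$detection$min_length,
      min_model_identity = config$detection$min_model_identity,
      max_overlap_fraction = config$detection$max_overlap_fraction,
      grid = config$grid, band = config$band, max_gap = config$max_gap,
      min_nonsat_length = config$min_nonsat_length,
      min_read_length = config$min_read_length),
    input_digest = digest_strings(reads))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             tmp$manifest)

  for (nm in names(paths)) file.rename(tmp[[nm]], paths[[nm]])
  summary_df <- do.call(rbind, lapply(classifications, classification_row))
  rownames(summary_df) <- NULL
  if (!quiet) {
    tab <- table(summary_df$classification)
    message("classification: ",
            paste(sprintf("%s=%d", names(tab), tab), collapse = " "))
  }
  invisible(list(results = results, classifications = classifications,
                 summary = summary_df, paths = paths))
}

# Order-sensitive content digest of the input reads for the run manifest
# (no external digest dependency; a simple polynomial hash is enough for a
# provenance fingerprint).
digest_strings <- function(x) {
  h <- 0
  for (s in c(names(x), unname(x))) {
    for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  }
  sprintf("%010d", as.integer(h))
}

#' Aggregate a per-read summary into category counts
#'
#' Reproduces the shape of a repeat-structure prediction table: counts and
#' frequencies for regular / irregular / no-HOR, plus the inversion
#' sub-count (a subset of irregular), the monomeric sub-count and the
#' number of reads with a >= 1 kb non-satellite transition.
#'
#' @param summary a summary data.frame (from \code{run_pipeline()} or
#'   \code{\link{read_read_summary}})
#' @return data.frame with columns category, reads, frequency
#' @export
hor_report <- function(summary) {
  n <- nrow(summary)
  cls <- summary$classification
  inv <- sum(summary$inversion_flag %in% c(TRUE, "true"))
  mono <- sum(summary$monomeric_flag %in% c(TRUE, "true"))
  trans <- sum(!is.na(summary$nonsat_intervals) &
                 summary$nonsat_intervals != ".")
  data.frame(
    category = c("regular", "irregular", "inversions", "no-HOR",
                 "monomeric", "transition"),
    reads = c(sum(cls == "regular"), sum(cls == "irregular"), inv,
              sum(cls == "no-HOR"), mono, trans),
    frequency = round(c(sum(cls == "regular"), sum(cls == "irregular"),
                        inv, sum(cls == "no-HOR"), mono, trans) / n, 2),
    stringsAsFactors = FALSE)
}
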