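# Readers/writers for every external representation the pipeline touches:
# FASTA in/out, profile-search tabular hit files in, per-read summary tables
# and BED interval files out.

#' Read long reads from a FASTA file
#'
#' Sequences are upper-cased and every character outside A,C,G,T,N is mapped
#' to N (ambiguity codes never count as matches in identity computations
#' downstream).  Record order is preserved.
#'
#' @param path path to a (possibly gzipped) FASTA file
#' @return a named character vector of sequences; names are record ids
#'   (first whitespace-delimited token of each header)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(x))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  ids <- sub("\\s.*$", "", names(x))
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate read id in ", path, ": ", ids[duplicated(ids)][1])
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of nucleotide sequences
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(seqs)), path)
  invisible(path)
}

#' Parse an external profile-HMM hit table
#'
#' Ingests the one-row-per-hit tabular output of a nucleotide profile search
#' (the \code{nhmmer --tblout} dialect: target name, target accession, query
#' name, query accession, hmm from/to, alignment from/to, envelope from/to,
#' target length, strand, E-value, score, bias).  Alignment coordinates are
#' 1-based inclusive on the target read; on the minus strand the "from"
#' coordinate exceeds the "to" coordinate.  Both are converted here, exactly
#' once, to 0-based half-open forward-strand coordinates.
#'
#' @param path path to the tabular hits file; lines starting with '#' are
#'   ignored
#' @param min_length hits whose alignment span is shorter than this many
#'   bases are discarded (default 150, the minimum monomer length)
#' @return a monomer hit data.frame with columns read_id, start, end, strand,
#'   model_id, score, identity (identity is NA: the tabular format does not
#'   carry it)
#' @export
parse_external_hits <- function(path, min_length = 150L) {
  if (!file.exists(path)) stop("hits file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  out <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    ln <- rows[k]
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) < 12) {
      stop("unparsable hits row at line ", ln, ": expected >= 12 fields")
    }
    afrom <- suppressWarnings(as.integer(f[7]))
    ato <- suppressWarnings(as.integer(f[8]))
    if (is.na(afrom) || is.na(ato)) {
      stop("unparsable alignment coordinates at line ", ln)
    }
    strand <- f[12]
    if (!strand %in% c("+", "-")) {
      # some dialects put strand after the target-length column
      strand <- if (afrom <= ato) "+" else "-"
    }
    if (afrom <= ato) {
      start <- afrom - 1L; end <- ato; strand <- "+"
    } else {
      start <- ato - 1L; end <- afrom; strand <- "-"
    }
    score <- suppressWarnings(as.numeric(f[14]))
    if (is.na(score)) score <- suppressWarnings(as.numeric(f[13]))
    out[[k]] <- data.frame(
      read_id = f[1], start = start, end = end, strand = strand,
      model_id = f[3], score = if (is.na(score)) 0 else score,
      identity = NA_real_, stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(hits)) {
    hits <- empty_hits()
  }
  hits <- hits[hits$end - hits$start >= min_length, , drop = FALSE]
  hits <- hits[order(hits$read_id, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(read_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), model_id = character(0),
             score = numeric(0), identity = numeric(0),
             stringsAsFactors = FALSE)
}

summary_columns <- c(
  "read_id", "read_length", "n_monomers", "n_clusters",
  "selected_threshold", "classification", "inversion_flag",
  "monomeric_flag", "hor_period", "median_monomer_identity",
  "n_nonsat_bases", "nonsat_intervals")

#' Write the per-read summary table
#'
#' Tab-delimited, one row per read, fixed column order: read_id, read_length,
#' n_monomers, n_clusters, selected_threshold, classification,
#' inversion_flag, monomeric_flag, hor_period, median_monomer_identity,
#' n_nonsat_bases, nonsat_intervals.  Missing values are written as ".".
#' Row order is input order.
#'
#' @param classifications a list of read classification objects (see
#'   \code{\link{classify_read}})
#' @param path output path
#' @export
write_read_summary <- function(classifications, path) {
  stopifnot(length(classifications) > 0)
  df <- do.call(rbind, lapply(classifications, classification_row))
  for (col in names(df)) {
    v <- df[[col]]
    if (is.logical(v)) v <- ifelse(v, "true", "false")
    v <- as.character(v)
    v[is.na(v)] <- "."
    df[[col]] <- v
  }
  write.table(df[, summary_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a per-read summary table back into a data.frame
#'
#' @param path path to a summary TSV written by
#'   \code{\link{write_read_summary}}
#' @return data.frame with "." restored to NA and numeric/logical columns
#'   retyped
#' @export
read_read_summary <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   na.strings = ".", stringsAsFactors = FALSE,
                   colClasses = "character")
  for (col in c("read_length", "n_monomers", "n_clusters", "hor_period",
                "n_nonsat_bases")) {
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in c("selected_threshold", "median_monomer_identity")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("inversion_flag", "monomeric_flag")) {
    df[[col]] <- df[[col]] == "true"
  }
  df
}

classification_row <- function(cl) {
  iv <- cl$nonsat_intervals
  iv_str <- if (is.null(iv) || nrow(iv) == 0) NA_character_ else {
    paste(sprintf("%d-%d", iv$start, iv$end), collapse = ",")
  }
  data.frame(
    read_id = cl$read_id,
    read_length = cl$read_length,
    n_monomers = cl$n_monomers,
    n_clusters = if (is.null(cl$n_clusters)) NA_integer_ else cl$n_clusters,
    selected_threshold = if (is.null(cl$selected_threshold))
      NA_real_ else cl$selected_threshold,
    classification = cl$label,
    inversion_flag = isTRUE(cl$inversion_flag),
    monomeric_flag = isTRUE(cl$monomeric_flag),
    hor_period = if (is.null(cl$hor_period)) NA_integer_ else cl$hor_period,
    median_monomer_identity = if (is.null(cl$median_monomer_identity))
      NA_real_ else cl$median_monomer_identity,
    n_nonsat_bases = cl$n_nonsat_bases,
    nonsat_intervals = iv_str,
    stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' BED3+ (0-based half-open) with an optional name column.
#'
#' @param intervals data.frame with columns read_id, start, end and
#'   optionally name
#' @param path output path
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("read_id", "start", "end") %in% names(intervals)))
  nm <- if ("name" %in% names(intervals)) intervals$name else
    sprintf("%s:%d-%d", intervals$read_id, intervals$start, intervals$end)
  bed <- data.frame(intervals$read_id, intervals$start, intervals$end, nm)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
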