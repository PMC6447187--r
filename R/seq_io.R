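# Sequence containers and file-format boundaries.
#
# All internal coordinates in this package are 0-based half-open; 1-based
# inclusive coordinates (BLAST tabular) are converted at import and the
# convention is recorded in every report this package writes.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

normalize_residues <- function(x, id = "<sequence>") {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- regexpr(sprintf("[^%s]", paste(DNA_ALPHABET, collapse = "")), x)
  if (bad != -1L) {
    stop(sprintf(
      "sequence '%s' contains non-nucleotide residue '%s' at position %d",
      id, substr(x, bad, bad), as.integer(bad)
    ), call. = FALSE)
  }
  x
}

#' Construct a transcriptome container
#'
#' A `transcriptome` is the package's core sequence collection: a named
#' character vector of upper-case nucleotide sequences over `{A,C,G,T,N}`
#' plus the set of ids designated as the design target gene. Hits against
#' target ids ("self hits") are never counted as off-targets.
#'
#' @param sequences named character vector of nucleotide sequences; names are
#'   unique transcript ids. `U` is rewritten to `T` and case is normalized.
#' @param target_ids character vector of ids to treat as the design target.
#'   Ids need not be present in `sequences` (the target cDNA itself is often
#'   kept in a separate FASTA), but when absent they are recorded as external.
#' @return an object of class `transcriptome` with elements `sequences`
#'   (named character) and `target_ids`.
#' @examples
#' tx <- transcriptome(c(tx1 = "ACGTACGT", tx2 = "GGGTTTAA"), target_ids = "tx1")
#' length(tx$sequences)
#' @export
transcriptome <- function(sequences, target_ids = character(0)) {
  if (length(sequences) == 0L) {
    stop("a transcriptome needs at least one sequence", call. = FALSE)
  }
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every sequence must have a non-empty id", call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate sequence id: '%s'", dup[[1L]]), call. = FALSE)
  }
  if (any(!nzchar(sequences))) {
    stop("empty sequence not allowed", call. = FALSE)
  }
  seqs <- vapply(ids, function(i) normalize_residues(sequences[[i]], i), character(1))
  structure(
    list(sequences = seqs, target_ids = unique(as.character(target_ids))),
    class = "transcriptome"
  )
}

#' @export
print.transcriptome <- function(x, ...) {
  lens <- nchar(x$sequences)
  cat(sprintf(
    "transcriptome: %d sequences (%d nt total), %d target id(s)\n",
    length(x$sequences), sum(lens), length(x$target_ids)
  ))
  invisible(x)
}

#' @export
length.transcriptome <- function(x) length(x$sequences)

#' Read a FASTA file into a transcriptome
#'
#' Headers are parsed to the first whitespace as the transcript id. Residues
#' are upper-cased and `U` is rewritten to `T`; any residue outside
#' `{A,C,G,T,N}` is an error reporting its position. Duplicate ids are an
#' error naming the id.
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @param target_ids ids to mark as the design target (see [transcriptome()]).
#' @return a [transcriptome()].
#' @export
read_fasta <- function(path, target_ids = character(0)) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  }
  # BStringSet accepts arbitrary letters so that alphabet validation (with
  # position reporting) stays in one place, in normalize_residues().
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop(sprintf("no FASTA records in %s", path), call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  names(seqs) <- ids
  transcriptome(seqs, target_ids = target_ids)
}

#' Write a transcriptome to FASTA
#'
#' @param x a [transcriptome()].
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "transcriptome"))
  set <- Biostrings::BStringSet(x$sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Import homology hits from BLAST tabular output
#'
#' Reads the standard 12-column tabular format (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`), one hit per
#' row. Subject coordinates are converted to 0-based half-open on the forward
#' strand; minus-strand hits (those with `sstart > send`) are flagged with
#' `strand == "-"`. The 12-column format carries gap *openings*, not total
#' gap length; `gap_count` therefore holds the `gapopen` column (a lower
#' bound on gapped columns) and `gap_unverifiable` marks rows where it
#' disagrees with the gap total recomputed from the span arithmetic
#' `2*length - qspan - sspan`.
#'
#' @param path tab-separated file; lines starting with `#` are ignored.
#' @return a data.frame with one row per hit: `query_id`, `subject_id`,
#'   `identity_pct`, `aligned_len`, `mismatches`, `gap_count`,
#'   `gap_unverifiable`, `query_start`, `query_end`, `subject_start`,
#'   `subject_end` (0-based half-open, forward strand), `strand`, `e_value`,
#'   `bit_score`.
#' @export
import_blast_tab <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("hit table not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col != 12L)) {
    bad <- which(n_col != 12L)[[1L]]
    stop(sprintf(
      "line %d: expected 12 tab-separated columns, found %d",
      lineno[[bad]], n_col[[bad]]
    ), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  num_cols <- 3:12
  suppressWarnings(vals <- apply(m[, num_cols, drop = FALSE], 2L, as.numeric))
  vals <- matrix(vals, nrow = nrow(m))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "line %d: non-numeric value '%s' in column %d",
      lineno[[bad[[1L]]]], m[bad[[1L]], num_cols[[bad[[2L]]]]], num_cols[[bad[[2L]]]]
    ), call. = FALSE)
  }
  qstart <- vals[, 5L]
  qend <- vals[, 6L]
  sstart <- vals[, 7L]
  send <- vals[, 8L]
  minus <- sstart > send
  s_lo <- pmin(sstart, send)
  s_hi <- pmax(sstart, send)
  len <- vals[, 2L]
  qspan <- abs(qend - qstart) + 1
  sspan <- s_hi - s_lo + 1
  gap_total <- 2 * len - qspan - sspan
  gapopen <- vals[, 4L]
  out <- data.frame(
    query_id = m[, 1L],
    subject_id = m[, 2L],
    identity_pct = vals[, 1L],
    aligned_len = as.integer(len),
    mismatches = as.integer(vals[, 3L]),
    gap_count = as.integer(gapopen),
    gap_unverifiable = gapopen != gap_total,
    query_start = as.integer(pmin(qstart, qend)) - 1L,
    query_end = as.integer(pmax(qstart, qend)),
    subject_start = as.integer(s_lo) - 1L,
    subject_end = as.integer(s_hi),
    strand = ifelse(minus, "-", "+"),
    e_value = vals[, 9L],
    bit_score = vals[, 10L],
    stringsAsFactors = FALSE
  )
  bad <- out$identity_pct < 0 | out$identity_pct > 100 | out$aligned_len < 1
  if (any(bad)) {
    stop(sprintf("line %d: hit fails invariants (identity in [0,100], length >= 1)",
                 lineno[[which(bad)[[1L]]]]), call. = FALSE)
  }
  out
}

#' Write a dsRNA design report
#'
#' Emits a machine-readable JSON report (window, counts, subjects, resolved
#' parameters) plus a TSV of per-fragment off-target risk. All coordinates
#' are 0-based half-open, and the JSON says so in its `coordinate_system`
#' field.
#'
#' @param result a design result from [design_dsrna()].
#' @param path output path prefix; writes `<path>.json` and `<path>.risk.tsv`.
#' @return named character vector of the two file paths, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "dsrna_design"))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop(sprintf("output directory does not exist: %s", dir), call. = FALSE)
  }
  json_path <- paste0(path, ".json")
  tsv_path <- paste0(path, ".risk.tsv")
  payload <- list(
    tool = "dstile",
    version = as.character(packageVersion("dstile")),
    coordinate_system = "0-based, half-open",
    target_id = result$target_id,
    params = unclass(result$params),
    window = list(
      start = result$window$start,
      end = result$window$end,
      length = result$window$length,
      offtarget_fragment_count = result$window$offtarget_fragment_count,
      distinct_subjects = result$window$distinct_subjects
    ),
    window_counts = result$window$rank_context,
    amplicon = result$amplicon,
    t7 = if (!is.null(result$t7)) unclass(result$t7) else NULL,
    n_fragments = length(result$profile$fragment_starts),
    n_flagged_fragments = sum(result$profile$flagged),
    n_hits = if (is.null(result$hits)) 0L else nrow(result$hits)
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  risk <- data.frame(
    fragment_index = seq_along(result$profile$fragment_starts) - 1L,
    fragment_start = result$profile$fragment_starts,
    fragment_end = result$profile$fragment_starts + result$profile$k,
    offtarget_count = result$profile$counts,
    flagged = result$profile$flagged,
    subjects = vapply(result$profile$subjects, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  write.table(risk, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(json = json_path, risk_tsv = tsv_path))
}

#' Read a design report back from JSON
#'
#' @param path path to a `.json` file written by [write_report()].
#' @return the report as a list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
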