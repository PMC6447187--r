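# Fragment tiling and off-target screening.
#
# A dsRNA trigger is processed by Dicer into short siRNAs, any of which can
# silence a transcript it matches closely enough. The screen therefore tiles
# the target cDNA into k-mers (k = 19 by default) and asks, for each tile,
# whether any non-target transcript carries an approximate match passing the
# acceptance rule: alignment length > 17 nt, identity > 90%, gaps < 3.

#' Parameters for the off-target scan
#'
#' Thresholds are stored in ready-to-compare form: `min_match_len` is the
#' smallest acceptable alignment length (18, i.e. "longer than 17 nt"),
#' `min_identity_pct` is a strict lower bound (90 means identity must exceed
#' 90%), and `max_gaps` is the largest acceptable number of gapped columns
#' (2, i.e. "fewer than 3 gaps").
#'
#' @param k tile length in nt. Default 19, the classic siRNA core length.
#' @param min_match_len minimum alignment columns for an off-target call
#'   (inclusive).
#' @param min_identity_pct identity percentage a hit must strictly exceed.
#'   Identity counts gap columns in the denominator (BLAST `pident`).
#' @param max_gaps maximum gapped columns allowed (inclusive); gap count is
#'   total gap length, not openings.
#' @param stride tiling step; 1 tiles every register (any Dicer product),
#'   `k` reproduces non-overlapping tiling.
#' @param both_strands scan the reverse complement of each transcript too
#'   (dsRNA silences via both strands; BLASTn also searches both).
#' @param seed_len exact-match seed for the built-in matcher. Any acceptable
#'   alignment at the default thresholds contains an exact co-diagonal run of
#'   at least 7 bases (at most 2 non-match columns split at worst 17 matches
#'   into thirds), so the default of 7 loses nothing; larger values are
#'   faster but may miss heavily-gapped hits.
#' @return a `scan_params` object (validated list).
#' @export
scan_params <- function(k = 19L, min_match_len = 18L, min_identity_pct = 90,
                        max_gaps = 2L, stride = 1L, both_strands = TRUE,
                        seed_len = 7L) {
  k <- as.integer(k)
  min_match_len <- as.integer(min_match_len)
  max_gaps <- as.integer(max_gaps)
  stride <- as.integer(stride)
  seed_len <- as.integer(seed_len)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (seed_len < 1L || seed_len > min_match_len || min_match_len > k) {
    stop("need 1 <= seed_len <= min_match_len <= k", call. = FALSE)
  }
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  if (min_identity_pct < 0 || min_identity_pct > 100) {
    stop("min_identity_pct must be in [0, 100]", call. = FALSE)
  }
  if (max_gaps < 0L) stop("max_gaps must be >= 0", call. = FALSE)
  structure(
    list(k = k, min_match_len = min_match_len,
         min_identity_pct = min_identity_pct, max_gaps = max_gaps,
         stride = stride, both_strands = isTRUE(both_strands),
         seed_len = seed_len),
    class = "scan_params"
  )
}

#' Tile a target sequence into k-mer fragments
#'
#' With stride 1 this produces every k-mer: `L - k + 1` fragments for a
#' target of length `L`. With a larger stride, starts are `0, s, 2s, ...`
#' plus a final fragment ending exactly at `L` when the last regular tile
#' does not already reach it, so the 3' end is always covered.
#'
#' @param target nucleotide string (or single-sequence [transcriptome()]).
#' @param params a [scan_params()].
#' @return data.frame with columns `index` (1-based ordinal), `id`
#'   (`frag_<start>`), `start` (0-based offset on the target), `kmer`.
#' @export
tile_target <- function(target, params = scan_params()) {
  seq <- as_target_sequence(target)
  L <- nchar(seq)
  k <- params$k
  if (L < k) {
    stop(sprintf("target length %d is shorter than k = %d", L, k), call. = FALSE)
  }
  starts <- seq.int(0L, L - k, by = params$stride)
  if (starts[length(starts)] != L - k) starts <- c(starts, L - k)
  data.frame(
    index = seq_along(starts),
    id = sprintf("frag_%d", starts),
    start = as.integer(starts),
    kmer = substring(seq, starts + 1L, starts + k),
    stringsAsFactors = FALSE
  )
}

as_target_sequence <- function(target) {
  if (inherits(target, "transcriptome")) {
    if (length(target$sequences) != 1L) {
      stop("give a single-sequence transcriptome (or a string) as the target",
           call. = FALSE)
    }
    return(unname(target$sequences[[1L]]))
  }
  normalize_residues(as.character(target))
}

#' Write fragments to FASTA for an external BLAST search
#'
#' Record ids are `frag_<start>` so that [offtargets_from_blast()] can map
#' hits back to fragment coordinates.
#'
#' @param fragments output of [tile_target()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fragments_fasta <- function(fragments, path) {
  seqs <- fragments$kmer
  names(seqs) <- fragments$id
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Apply the off-target acceptance rule to one homology hit
#'
#' A hit is a potential off-target silencing fragment iff its subject is not
#' the target gene itself, the alignment spans at least `min_match_len`
#' columns, identity strictly exceeds `min_identity_pct`, and it has at most
#' `max_gaps` gapped columns. Rejections carry the first failed criterion in
#' the order self, length, identity, gaps.
#'
#' @param hit list or one-row data.frame with `subject_id`, `aligned_len`,
#'   `identity_pct`, `gap_count`.
#' @param params a [scan_params()].
#' @param target_ids ids counted as the target gene (self hits).
#' @return list with `accept` (logical) and `reason` (`NA` when accepted,
#'   otherwise one of `"self"`, `"length"`, `"identity"`, `"gaps"`).
#' @export
evaluate_hit <- function(hit, params = scan_params(), target_ids = character(0)) {
  reason <- NA_character_
  if (hit$subject_id %in% target_ids) {
    reason <- "self"
  } else if (hit$aligned_len < params$min_match_len) {
    reason <- "length"
  } else if (!(hit$identity_pct > params$min_identity_pct)) {
    reason <- "identity"
  } else if (hit$gap_count > params$max_gaps) {
    reason <- "gaps"
  }
  list(accept = is.na(reason), reason = reason)
}

#' Scan fragments for off-target matches in a transcriptome
#'
#' The default route (`method = "seeded"`) indexes exact `seed_len`-mers of
#' both strands of every non-target transcript and extends each seed by a
#' banded dynamic program that enumerates all match-bounded alignments
#' passing the acceptance rule. `method = "bruteforce"` runs an unseeded,
#' unbanded dynamic program over every fragment x transcript x strand triple;
#' it is quadratic and exists as the independent oracle the seeded route is
#' tested against. Alignments are match-bounded (they start and end with an
#' identical column), mirroring how local-alignment tools trim HSPs; `N`
#' never counts as a match.
#'
#' Overlapping alignments of the same fragment to the same subject and
#' strand are collapsed to one reported hit: highest identity, then longest,
#' then leftmost on the subject.
#'
#' @param fragments output of [tile_target()].
#' @param transcriptome a [transcriptome()]; entries whose id is in
#'   `target_ids` are excluded from the scan.
#' @param params a [scan_params()].
#' @param method `"seeded"` (default) or `"bruteforce"`.
#' @return data.frame of accepted hits: `fragment_index`, `fragment_start`,
#'   `subject_id`, `subject_start`, `subject_end` (0-based half-open, forward
#'   strand), `strand`, `aligned_len`, `matches`, `mismatches`, `gap_count`,
#'   `identity_pct`.
#' @export
scan_offtargets <- function(fragments, transcriptome, params = scan_params(),
                            method = c("seeded", "bruteforce")) {
  method <- match.arg(method)
  stopifnot(inherits(transcriptome, "transcriptome"))
  subj_ids <- setdiff(names(transcriptome$sequences), transcriptome$target_ids)
  if (nrow(fragments) == 0L || length(subj_ids) == 0L) {
    return(empty_hits())
  }
  subjects <- transcriptome$sequences[subj_ids]
  raw <- if (method == "seeded") {
    cpp_scan_seeded(fragments$kmer, unname(subjects), params$min_match_len,
                    params$min_identity_pct, params$max_gaps, params$seed_len,
                    params$both_strands)
  } else {
    cpp_scan_brute(fragments$kmer, unname(subjects), params$min_match_len,
                   params$min_identity_pct, params$max_gaps,
                   params$both_strands)
  }
  collapse_candidates(raw, fragments, subj_ids)
}

#' @rdname scan_offtargets
#' @export
scan_offtargets_bruteforce <- function(fragments, transcriptome,
                                       params = scan_params()) {
  scan_offtargets(fragments, transcriptome, params, method = "bruteforce")
}

empty_hits <- function() {
  data.frame(
    fragment_index = integer(0), fragment_start = integer(0),
    subject_id = character(0), subject_start = integer(0),
    subject_end = integer(0), strand = character(0),
    aligned_len = integer(0), matches = integer(0), mismatches = integer(0),
    gap_count = integer(0), identity_pct = numeric(0),
    stringsAsFactors = FALSE
  )
}

# Collapse raw alignment candidates into reported hits. Candidates for the
# same (fragment, subject, strand) whose subject spans overlap (transitively)
# form one locus; its representative is the candidate with highest identity,
# then greatest aligned length, then leftmost, then shortest span.
collapse_candidates <- function(raw, fragments, subj_ids) {
  if (nrow(raw) == 0L) return(empty_hits())
  aligned_len <- raw$matches + raw$mismatches + raw$gap_count
  identity_pct <- 100 * raw$matches / aligned_len
  cand <- data.frame(
    fragment_index = fragments$index[raw$frag],
    fragment_start = fragments$start[raw$frag],
    subject_id = subj_ids[raw$subj],
    subject_start = raw$subject_start,
    subject_end = raw$subject_end,
    strand = raw$strand,
    aligned_len = as.integer(aligned_len),
    matches = raw$matches,
    mismatches = raw$mismatches,
    gap_count = raw$gap_count,
    identity_pct = identity_pct,
    stringsAsFactors = FALSE
  )
  key <- paste(cand$fragment_start, cand$subject_id, cand$strand, sep = "\r")
  pieces <- lapply(split(cand, key), function(g) {
    g <- g[order(g$subject_start, g$subject_end), , drop = FALSE]
    cummax_end <- cummax(c(-1L, g$subject_end[-nrow(g)]))
    locus <- cumsum(g$subject_start >= cummax_end)
    reps <- lapply(split(g, locus), function(l) {
      l[order(-l$identity_pct, -l$aligned_len, l$subject_start,
              l$subject_end), , drop = FALSE][1L, , drop = FALSE]
    })
    do.call(rbind, reps)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$fragment_start, out$subject_id, out$strand,
                   out$subject_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert imported BLAST hits of tiled fragments into accepted off-targets
#'
#' For users who ran the fragment FASTA from [write_fragments_fasta()]
#' through an external BLASTn: applies the acceptance rule of
#' [evaluate_hit()] to each row and maps query ids (`frag_<start>`) back to
#' fragment coordinates.
#'
#' @param hits data.frame from [import_blast_tab()].
#' @param fragments output of [tile_target()].
#' @param params a [scan_params()].
#' @param target_ids subject ids counted as the target gene.
#' @return data.frame in the same shape as [scan_offtargets()] (without
#'   `matches`/`mismatches` recomputation; identity and gaps come from the
#'   imported table).
#' @export
offtargets_from_blast <- function(hits, fragments, params = scan_params(),
                                  target_ids = character(0)) {
  idx <- match(hits$query_id, fragments$id)
  if (anyNA(idx)) {
    stop(sprintf("query id '%s' does not match any fragment id",
                 hits$query_id[which(is.na(idx))[1L]]), call. = FALSE)
  }
  keep <- !(hits$subject_id %in% target_ids) &
    hits$aligned_len >= params$min_match_len &
    hits$identity_pct > params$min_identity_pct &
    hits$gap_count <= params$max_gaps
  h <- hits[keep, , drop = FALSE]
  idx <- idx[keep]
  out <- data.frame(
    fragment_index = fragments$index[idx],
    fragment_start = fragments$start[idx],
    subject_id = h$subject_id,
    subject_start = h$subject_start,
    subject_end = h$subject_end,
    strand = h$strand,
    aligned_len = h$aligned_len,
    matches = NA_integer_,
    mismatches = h$mismatches,
    gap_count = h$gap_count,
    identity_pct = h$identity_pct,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$fragment_start, out$subject_id, out$strand,
                   out$subject_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter candidate homology hits by e-value, identity and query coverage
#'
#' Screening rule for candidate homologs from a similarity search: keep a
#' hit iff its e-value is below `1e-5`, identity exceeds 20%, and query
#' coverage (aligned query span / query length, as a percentage) exceeds
#' 50%. All three bounds are strict.
#'
#' @param hits data.frame with `e_value`, `identity_pct`, `query_start`,
#'   `query_end` (0-based half-open, as from [import_blast_tab()]).
#' @param query_len query sequence length in residues.
#' @param max_evalue,min_identity_pct,min_coverage_pct strict thresholds.
#' @return the retained rows, with a `query_coverage_pct` column added.
#' @export
filter_candidate_hits <- function(hits, query_len, max_evalue = 1e-5,
                                  min_identity_pct = 20,
                                  min_coverage_pct = 50) {
  if (query_len <= 0) stop("query_len must be positive", call. = FALSE)
  if (is.null(hits$e_value) || anyNA(hits$e_value)) {
    stop("every hit needs an e-value for candidate filtering", call. = FALSE)
  }
  cov <- 100 * (hits$query_end - hits$query_start) / query_len
  keep <- hits$e_value < max_evalue &
    hits$identity_pct > min_identity_pct &
    cov > min_coverage_pct
  out <- hits[keep, , drop = FALSE]
  out$query_coverage_pct <- cov[keep]
  rownames(out) <- NULL
  out
}
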