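# Risk mapping and amplicon window selection.
#
# Accepted off-target hits are mapped back onto the target as a per-fragment
# risk profile; the amplicon (the dsRNA synthesis template) is then the
# window of the requested length containing the fewest flagged fragments.

#' Canonical T7 RNA polymerase promoter (binding site)
#'
#' The minimal class III T7 promoter appended 5' of each PCR primer so the
#' amplicon can be transcribed in vitro from both ends. Configurable in
#' [make_t7_templates()]; some protocols append extra G residues for
#' efficient initiation.
#' @export
T7_PROMOTER <- "TAATACGACTCACTATAG"

#' Build a per-fragment off-target risk profile
#'
#' @param fragments output of [tile_target()].
#' @param hits accepted hits from [scan_offtargets()] or
#'   [offtargets_from_blast()].
#' @param target_id id recorded for reporting.
#' @param target_len target length in nt; inferred from the last fragment
#'   when omitted (exact for stride-1 tiling).
#' @return a `risk_profile`: `target_id`, `target_len`, `k`,
#'   `fragment_starts`, `counts` (accepted hits per fragment), `flagged`
#'   (`count > 0`), `subjects` (list of subject-id sets per fragment).
#' @export
build_risk_profile <- function(fragments, hits, target_id = "target",
                               target_len = NULL) {
  k <- nchar(fragments$kmer[[1L]])
  if (is.null(target_len)) target_len <- max(fragments$start) + k
  unknown <- setdiff(unique(hits$fragment_start), fragments$start)
  if (length(unknown) > 0L) {
    stop(sprintf("hit references unknown fragment start %d", unknown[[1L]]),
         call. = FALSE)
  }
  idx <- match(hits$fragment_start, fragments$start)
  counts <- tabulate(idx, nbins = nrow(fragments))
  subjects <- rep(list(character(0)), nrow(fragments))
  if (nrow(hits) > 0L) {
    by_frag <- split(hits$subject_id, idx)
    subjects[as.integer(names(by_frag))] <- lapply(by_frag,
                                                   function(s) sort(unique(s)))
  }
  structure(
    list(target_id = target_id, target_len = as.integer(target_len),
         k = as.integer(k), fragment_starts = fragments$start,
         counts = as.integer(counts), flagged = counts > 0L,
         subjects = subjects),
    class = "risk_profile"
  )
}

#' @export
print.risk_profile <- function(x, ...) {
  cat(sprintf(
    "risk profile for '%s': %d fragments (k = %d), %d flagged (%d hits)\n",
    x$target_id, length(x$fragment_starts), x$k, sum(x$flagged),
    sum(x$counts)
  ))
  invisible(x)
}

#' Select the amplicon window with the least off-target load
#'
#' Evaluates every candidate start `0 .. L - amplicon_len` and returns the
#' window minimizing the number of flagged fragments it contains. A fragment
#' counts as inside a window only when fully contained (`start >= window
#' start` and `start + k <= window end`): a dsRNA can only give rise to
#' siRNAs lying wholly within itself. Ties are broken by fewest distinct
#' off-target subjects, then leftmost start.
#'
#' @param profile a `risk_profile` from [build_risk_profile()].
#' @param amplicon_len requested amplicon length in nt (must be in
#'   `[k, target length]`).
#' @param containment `"full"` (default, see above) or `"partial"` (count a
#'   flagged fragment if it overlaps the window at all).
#' @return an `amplicon_window`: `start`, `end` (0-based half-open),
#'   `length`, `offtarget_fragment_count`, `distinct_subjects`,
#'   `rank_context` (data.frame of every window start and its count).
#' @export
select_window <- function(profile, amplicon_len,
                          containment = c("full", "partial")) {
  stopifnot(inherits(profile, "risk_profile"))
  containment <- match.arg(containment)
  amplicon_len <- as.integer(amplicon_len)
  L <- profile$target_len
  k <- profile$k
  if (amplicon_len > L) {
    stop(sprintf("amplicon length %d exceeds target length %d",
                 amplicon_len, L), call. = FALSE)
  }
  if (amplicon_len < k) {
    stop(sprintf("amplicon length %d is shorter than fragment length k = %d",
                 amplicon_len, k), call. = FALSE)
  }
  starts <- 0:(L - amplicon_len)
  flagged_starts <- profile$fragment_starts[profile$flagged]
  counts <- vapply(starts, function(w) {
    if (containment == "full") {
      sum(flagged_starts >= w & flagged_starts + k <= w + amplicon_len)
    } else {
      sum(flagged_starts < w + amplicon_len & flagged_starts + k > w)
    }
  }, integer(1))
  best <- which(counts == min(counts))
  if (length(best) > 1L) {
    n_subj <- vapply(best, function(i) {
      length(window_subjects(profile, starts[[i]], amplicon_len, containment))
    }, integer(1))
    best <- best[n_subj == min(n_subj)]
  }
  w <- starts[[best[[1L]]]]  # leftmost among remaining ties
  structure(
    list(start = w, end = w + amplicon_len, length = amplicon_len,
         offtarget_fragment_count = counts[[best[[1L]]]],
         distinct_subjects = window_subjects(profile, w, amplicon_len,
                                             containment),
         rank_context = data.frame(window_start = starts, count = counts)),
    class = "amplicon_window"
  )
}

window_subjects <- function(profile, w, amplicon_len, containment = "full") {
  s <- profile$fragment_starts
  inside <- if (containment == "full") {
    s >= w & s + profile$k <= w + amplicon_len
  } else {
    s < w + amplicon_len & s + profile$k > w
  }
  sort(unique(unlist(profile$subjects[inside & profile$flagged])))
}

#' @export
print.amplicon_window <- function(x, ...) {
  cat(sprintf(
    "amplicon window [%d,%d) (%d nt): %d off-target fragment(s), %d subject(s)\n",
    x$start, x$end, x$length, x$offtarget_fragment_count,
    length(x$distinct_subjects)
  ))
  invisible(x)
}

#' Tag synthesis primers with a T7 promoter
#'
#' Prepends the promoter to each primer, giving the tagged primer pair used
#' to amplify the in vitro transcription template. When `window` and
#' `target` are supplied the amplicon sequence is extracted at the window
#' coordinates and included.
#'
#' @param forward_primer,reverse_primer primer sequences (nucleotides only).
#' @param promoter promoter to prepend; `""` leaves primers untagged.
#' @param window optional `amplicon_window`.
#' @param target optional target sequence (string or single-sequence
#'   [transcriptome()]) for amplicon extraction.
#' @return a `t7_template`: `promoter`, `forward_primer`, `reverse_primer`,
#'   `tagged_forward`, `tagged_reverse`, and `amplicon` when extractable.
#' @export
make_t7_templates <- function(forward_primer, reverse_primer,
                              promoter = T7_PROMOTER, window = NULL,
                              target = NULL) {
  for (p in list(forward_primer, reverse_primer)) {
    if (!nzchar(p)) stop("primers must be non-empty", call. = FALSE)
    normalize_residues(p, "primer")
  }
  if (nzchar(promoter)) normalize_residues(promoter, "promoter")
  amplicon <- NULL
  if (!is.null(window) && !is.null(target)) {
    seq <- as_target_sequence(target)
    amplicon <- substring(seq, window$start + 1L, window$end)
  }
  structure(
    list(promoter = promoter,
         forward_primer = forward_primer, reverse_primer = reverse_primer,
         tagged_forward = paste0(promoter, forward_primer),
         tagged_reverse = paste0(promoter, reverse_primer),
         amplicon = amplicon),
    class = "t7_template"
  )
}

#' End-to-end dsRNA design
#'
#' Tiles the target, screens every fragment against the transcriptome (or
#' filters externally computed BLAST hits), maps accepted hits into a risk
#' profile, and selects the amplicon window with the least off-target load.
#' Optionally tags user-designed primers with a T7 promoter. Primer design
#' itself (melting temperature, GC clamp) is left to dedicated tools.
#'
#' @param target target cDNA (string or single-sequence [transcriptome()]).
#' @param transcriptome a [transcriptome()] to screen against.
#' @param amplicon_len requested amplicon length in nt. There is no
#'   principled default - it is dictated by the primers and construct.
#' @param params a [scan_params()].
#' @param target_id id used in reports and for self-hit exclusion (combined
#'   with `transcriptome$target_ids`).
#' @param blast_hits optional data.frame from [import_blast_tab()] to use
#'   instead of the built-in matcher.
#' @param forward_primer,reverse_primer,promoter optional primer tagging
#'   (see [make_t7_templates()]).
#' @return a `dsrna_design`: `target_id`, `params`, `hits`, `profile`,
#'   `window`, `amplicon`, `t7`.
#' @export
design_dsrna <- function(target, transcriptome, amplicon_len,
                         params = scan_params(), target_id = "target",
                         blast_hits = NULL, forward_primer = NULL,
                         reverse_primer = NULL, promoter = T7_PROMOTER) {
  seq <- as_target_sequence(target)
  txome <- transcriptome
  txome$target_ids <- unique(c(txome$target_ids, target_id))
  fragments <- tile_target(seq, params)
  hits <- if (is.null(blast_hits)) {
    scan_offtargets(fragments, txome, params)
  } else {
    offtargets_from_blast(blast_hits, fragments, params, txome$target_ids)
  }
  profile <- build_risk_profile(fragments, hits, target_id = target_id,
                                target_len = nchar(seq))
  window <- select_window(profile, amplicon_len)
  amplicon <- substring(seq, window$start + 1L, window$end)
  t7 <- NULL
  if (!is.null(forward_primer) && !is.null(reverse_primer)) {
    t7 <- make_t7_templates(forward_primer, reverse_primer, promoter,
                            window = window, target = seq)
  }
  structure(
    list(target_id = target_id, params = params, hits = hits,
         profile = profile, window = window, amplicon = amplicon, t7 = t7),
    class = "dsrna_design"
  )
}

#' @export
print.dsrna_design <- function(x, ...) {
  cat(sprintf("dsRNA design for '%s'\n", x$target_id))
  print(x$profile)
  print(x$window)
  if (length(x$window$distinct_subjects) > 0L) {
    cat("  subjects:", paste(x$window$distinct_subjects, collapse = ", "), "\n")
  }
  invisible(x)
}
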