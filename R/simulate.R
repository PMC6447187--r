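# Synthetic fixtures with known ground truth: random transcriptomes,
# planted paralogous blocks, and Cq tables with known knockdown fractions.
# Every generator takes an explicit seed and is byte-reproducible.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_sequence <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' Generate a random transcriptome
#'
#' Independent uniform-composition transcripts (GC fraction tunable);
#' reproducible for a given seed.
#'
#' @param n_transcripts number of transcripts (>= 1).
#' @param length_range c(min, max) transcript length in nt.
#' @param gc target GC fraction in (0, 1).
#' @param seed RNG seed.
#' @param prefix transcript id prefix (`<prefix>1 ...`).
#' @return a [transcriptome()].
#' @export
make_transcriptome <- function(n_transcripts, length_range = c(500L, 1500L),
                               gc = 0.5, seed = NULL, prefix = "tx") {
  if (n_transcripts < 1L) stop("need at least one transcript", call. = FALSE)
  if (length(length_range) != 2L || length_range[[1L]] > length_range[[2L]] ||
      length_range[[1L]] < 1L) {
    stop("length_range must be c(min, max) with 1 <= min <= max", call. = FALSE)
  }
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)", call. = FALSE)
  with_seed(seed, {
    lens <- sample(seq.int(length_range[[1L]], length_range[[2L]]),
                   n_transcripts, replace = TRUE)
    seqs <- vapply(lens, random_sequence, character(1), gc = gc)
    names(seqs) <- paste0(prefix, seq_len(n_transcripts))
    transcriptome(seqs)
  })
}

#' Plant a mutated copy of a target block into a transcriptome
#'
#' Emulates the paralogy that creates off-target silencing risk: a
#' `block_len`-nt block of the target is copied, mutated (per-base
#' substitutions to a different base; length-1 insertions/deletions), and
#' spliced into a host transcript. The returned truth record lists the
#' target fragment starts guaranteed to be flagged at zero mutation: every
#' k-mer sharing at least `min_match_len` nt with the source block (an
#' ungapped exact alignment of that length passes the acceptance rule),
#' clamped to valid fragment starts; `contained_starts` is the subset of
#' k-mers lying fully inside the block. Neighbouring fragments can pick up
#' extra flags when flanking host bases happen to extend an alignment, so
#' the truth set is a guaranteed subset, not an exact equality.
#'
#' @param transcriptome a [transcriptome()].
#' @param target target sequence (string or single-sequence transcriptome).
#' @param block_len nt copied from the target (>= k to create any flaggable
#'   fragment).
#' @param source_start 0-based block start on the target; random if `NULL`.
#' @param substitution_rate,indel_rate per-base probabilities in `[0, 1)`.
#' @param host_id host transcript; random if `NULL`.
#' @param insert_pos 0-based insertion point in the host; random if `NULL`.
#' @param k fragment length used for the truth record.
#' @param min_match_len acceptance length threshold used for the truth
#'   record (see [scan_params()]).
#' @param seed RNG seed.
#' @return list with `transcriptome` (host modified) and `truth`
#'   (`host_id`, `insert_pos`, `source_start`, `block_len`, `block`,
#'   `n_substitutions`, `n_indels`, `expected_flagged_starts`).
#' @export
plant_offtarget <- function(transcriptome, target, block_len,
                            source_start = NULL, substitution_rate = 0,
                            indel_rate = 0, host_id = NULL,
                            insert_pos = NULL, k = 19L, min_match_len = 18L,
                            seed = NULL) {
  stopifnot(inherits(transcriptome, "transcriptome"))
  seq <- as_target_sequence(target)
  L <- nchar(seq)
  if (block_len < k) stop("block_len must be at least k", call. = FALSE)
  if (block_len > L) stop("block_len exceeds target length", call. = FALSE)
  if (substitution_rate < 0 || substitution_rate >= 1 ||
      indel_rate < 0 || indel_rate >= 1) {
    stop("mutation rates must be in [0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    if (is.null(source_start)) {
      source_start <- sample.int(L - block_len + 1L, 1L) - 1L
    }
    if (source_start + block_len > L) {
      stop("block extends past the end of the target", call. = FALSE)
    }
    if (is.null(host_id)) host_id <- sample(names(transcriptome$sequences), 1L)
    if (!host_id %in% names(transcriptome$sequences)) {
      stop(sprintf("host transcript '%s' not found", host_id), call. = FALSE)
    }
    host <- transcriptome$sequences[[host_id]]
    if (nchar(host) <= block_len) {
      stop("host transcript must be longer than the planted block", call. = FALSE)
    }
    block <- substring(seq, source_start + 1L, source_start + block_len)
    mut <- mutate_block(block, substitution_rate, indel_rate)
    if (is.null(insert_pos)) insert_pos <- sample.int(nchar(host) + 1L, 1L) - 1L
    new_host <- paste0(substring(host, 1L, insert_pos), mut$block,
                       substring(host, insert_pos + 1L, nchar(host)))
    transcriptome$sequences[[host_id]] <- new_host
    list(
      transcriptome = transcriptome,
      truth = list(
        host_id = host_id, insert_pos = as.integer(insert_pos),
        source_start = as.integer(source_start),
        block_len = as.integer(block_len), block = mut$block,
        n_substitutions = mut$n_sub, n_indels = mut$n_indel,
        contained_starts = seq.int(source_start, source_start + block_len - k),
        expected_flagged_starts = seq.int(
          max(0L, source_start - (k - min_match_len)),
          min(L - k, source_start + block_len - min_match_len)
        )
      )
    )
  })
}

mutate_block <- function(block, substitution_rate, indel_rate) {
  bases <- strsplit(block, "", fixed = TRUE)[[1L]]
  alphabet <- c("A", "C", "G", "T")
  n_sub <- 0L
  if (substitution_rate > 0) {
    hit <- runif(length(bases)) < substitution_rate
    n_sub <- sum(hit)
    if (n_sub > 0L) {
      bases[hit] <- vapply(bases[hit], function(b) {
        sample(setdiff(alphabet, b), 1L)
      }, character(1))
    }
  }
  n_indel <- 0L
  if (indel_rate > 0) {
    out <- character(0)
    for (b in bases) {
      if (runif(1L) < indel_rate) {
        n_indel <- n_indel + 1L
        if (runif(1L) < 0.5) {
          out <- c(out, sample(alphabet, 1L), b)  # length-1 insertion
        }
        # else: length-1 deletion (drop the base)
      } else {
        out <- c(out, b)
      }
    }
    bases <- out
  }
  list(block = paste(bases, collapse = ""), n_sub = as.integer(n_sub),
       n_indel = as.integer(n_indel))
}

#' Default simulated knockdown design
#'
#' Fold-change table mirroring a typical silencing experiment: two dsRNA
#' arms (gene-specific and heterologous control) crossed with two bacterial
#' challenges plus a buffer-injected calibrator, n = 5 biological
#' replicates. The gene-specific arm knocks the target down to 12% of
#' control; antimicrobial-peptide readouts drop to roughly half.
#'
#' @return data.frame with columns `group`, `gene`, `fold`.
#' @export
default_cq_design <- function() {
  rbind(
    data.frame(group = "PBS", gene = c("target", "amp1"), fold = 1),
    data.frame(group = "dsControl_Gneg", gene = c("target", "amp1"),
               fold = 1),
    data.frame(group = "dsTarget_Gneg", gene = c("target", "amp1"),
               fold = c(0.12, 0.47)),
    data.frame(group = "dsControl_Gpos", gene = c("target", "amp1"),
               fold = 1),
    data.frame(group = "dsTarget_Gpos", gene = c("target", "amp1"),
               fold = c(0.12, 0.55))
  )
}

#' Simulate replicate Cq measurements with known fold changes
#'
#' For every group and gene, `Cq = baseline_cq[gene] - log_E(fold) +
#' Normal(0, sigma)`; the reference gene has fold 1 everywhere. The
#' calibrator group must have fold 1 for every gene so recovered fold
#' changes have a defined truth.
#'
#' @param fold_changes data.frame with columns `group`, `gene`, `fold`
#'   (true fold vs the calibrator), e.g. [default_cq_design()].
#' @param calibrator_group group with all folds 1.
#' @param reference_gene name of the simulated reference gene.
#' @param n_replicates biological replicates per group.
#' @param sigma Gaussian cycle noise (cycles).
#' @param efficiency amplification factor `E` (> 1); scalar or named
#'   per-gene vector.
#' @param baseline_cq named per-gene baseline cycles; genes missing from it
#'   default to 22 (16 for the reference gene).
#' @param seed RNG seed.
#' @return data.frame `sample`, `group`, `gene`, `replicate`, `cq`.
#' @export
simulate_cq <- function(fold_changes, calibrator_group = "PBS",
                        reference_gene = "reference", n_replicates = 5L,
                        sigma = 0.2, efficiency = 2,
                        baseline_cq = NULL, seed = NULL) {
  stopifnot(all(c("group", "gene", "fold") %in% names(fold_changes)))
  if (any(fold_changes$fold <= 0)) stop("true folds must be positive", call. = FALSE)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  e_of <- function(g) {
    e <- if (length(efficiency) > 1L || !is.null(names(efficiency))) {
      if (g %in% names(efficiency)) efficiency[[g]] else 2
    } else efficiency
    if (e <= 1) stop("efficiency must exceed 1", call. = FALSE)
    e
  }
  cal <- fold_changes[fold_changes$group == calibrator_group, , drop = FALSE]
  if (nrow(cal) == 0L) {
    stop(sprintf("calibrator group '%s' missing from fold_changes",
                 calibrator_group), call. = FALSE)
  }
  if (any(cal$fold != 1)) {
    stop("the calibrator group must have true fold 1 for every gene",
         call. = FALSE)
  }
  base_of <- function(g) {
    if (!is.null(baseline_cq) && g %in% names(baseline_cq)) baseline_cq[[g]]
    else if (g == reference_gene) 16 else 22
  }
  groups <- unique(fold_changes$group)
  genes <- unique(c(fold_changes$gene, reference_gene))
  with_seed(seed, {
    rows <- list()
    for (grp in groups) {
      for (g in genes) {
        fold <- if (g == reference_gene) 1 else {
          row <- fold_changes[fold_changes$group == grp & fold_changes$gene == g, ]
          if (nrow(row) == 0L) 1 else row$fold[[1L]]
        }
        cq <- base_of(g) - log(fold, base = e_of(g)) +
          rnorm(n_replicates, 0, sigma)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sprintf("%s_r%d", grp, seq_len(n_replicates)),
          group = grp, gene = g, replicate = seq_len(n_replicates),
          cq = cq, stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Write a Cq table to delimited text
#'
#' @param records data.frame from [simulate_cq()] or compatible.
#' @param path output path (`.csv` for comma, anything else tab).
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(records, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  write.table(records, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
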