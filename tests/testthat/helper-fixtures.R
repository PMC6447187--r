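# Shared fixtures and independent mini-oracles. Everything is generated in
# code; no binary fixtures.

rand_seq <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# A planted-block scan instance: random transcriptome plus a mutated copy of
# a random target block spliced into one transcript.
planted_instance <- function(seed, target_len = 80, n_tx = 3,
                             len_range = c(300, 700), block_len = 40,
                             sub_rate = 0.03, indel_rate = 0.02) {
  tx <- make_transcriptome(n_tx, len_range, seed = seed)
  set.seed(seed + 100000L)
  target <- rand_seq(target_len)
  planted <- plant_offtarget(tx, target, block_len = block_len,
                             substitution_rate = sub_rate,
                             indel_rate = indel_rate, seed = seed + 200000L)
  list(target = target, db = planted$transcriptome, truth = planted$truth,
       fragments = tile_target(target))
}

# Naive recount of flagged fragments per candidate window (the window
# optimizer is cross-checked against this).
naive_window_counts <- function(flagged_starts, k, target_len, amplicon_len) {
  vapply(0:(target_len - amplicon_len), function(w) {
    sum(flagged_starts >= w & flagged_starts + k <= w + amplicon_len)
  }, integer(1))
}

# Pooled-variance two-sample t-test p-value from the textbook formula,
# independent of stats::t.test.
manual_t_pvalue <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(tstat), df = na + nb - 2)
}

# Cq fixture with two groups and one gene pair, written by hand (not via
# simulate_cq) so the ddct path is exercised on independent numbers.
manual_cq_records <- function(delta = 1, n = 4, base_t = 24, base_r = 18) {
  rows <- list()
  for (grp in c("ctrl", "treated")) {
    off <- if (grp == "treated") delta else 0
    for (r in seq_len(n)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("%s_%d", grp, r), group = grp,
        gene = c("goi", "ref"), replicate = r,
        cq = c(base_t + off, base_r), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

hit_key <- function(hits) {
  paste(hits$fragment_start, hits$subject_id, hits$strand,
        hits$subject_start, hits$subject_end, hits$aligned_len,
        hits$gap_count, sep = "|")
}
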