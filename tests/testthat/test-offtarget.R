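test_that("tile_target produces L - k + 1 stride-1 fragments", {
  for (L in c(19L, 25L, 100L)) {
    fr <- tile_target(rand_seq(L, seed = L))
    expect_equal(nrow(fr), L - 19L + 1L)
    expect_equal(fr$start, 0:(L - 19L))
    expect_true(all(nchar(fr$kmer) == 19L))
  }
  expect_error(tile_target(rand_seq(10, seed = 1)), "shorter than k")
})

test_that("tile_target stride covers the 3' end", {
  seq <- rand_seq(50, seed = 3)
  fr <- tile_target(seq, scan_params(stride = 19))
  expect_equal(fr$start, c(0L, 19L, 31L))  # final tile forced to end at L
  expect_equal(fr$kmer[3], substr(seq, 32, 50))
  # stride landing exactly on L - k adds nothing
  fr2 <- tile_target(rand_seq(57, seed = 4), scan_params(stride = 19))
  expect_equal(fr2$start, c(0L, 19L, 38L))
})

test_that("evaluate_hit applies the printed thresholds with exact strictness", {
  p <- scan_params()
  hit <- function(len, id, gaps, subject = "tx7") {
    list(subject_id = subject, aligned_len = len, identity_pct = id,
         gap_count = gaps)
  }
  expect_true(evaluate_hit(hit(19, 100, 0), p)$accept)
  expect_true(evaluate_hit(hit(18, 94.7, 2), p)$accept)
  # 'larger than 17 nucleotides' is strict
  r <- evaluate_hit(hit(17, 100, 0), p)
  expect_false(r$accept); expect_equal(r$reason, "length")
  # identity must strictly exceed 90
  r <- evaluate_hit(hit(19, 90.0, 0), p)
  expect_false(r$accept); expect_equal(r$reason, "identity")
  # 'fewer than 3 gaps' is strict
  r <- evaluate_hit(hit(19, 100, 3), p)
  expect_false(r$accept); expect_equal(r$reason, "gaps")
  # self hits excluded before anything else
  r <- evaluate_hit(hit(17, 100, 0, subject = "me"), p, target_ids = "me")
  expect_equal(r$reason, "self")
})

test_that("exact planted 19-mer is found by exactly the overlapping fragments", {
  set.seed(11)
  target <- rand_seq(60)
  kmer <- substr(target, 21, 39)  # the fragment starting at 20 (0-based)
  db <- transcriptome(c(host = paste0(rand_seq(40), kmer, rand_seq(40))))
  hits <- scan_offtargets(tile_target(target), db)
  full <- hits[hits$identity_pct == 100 & hits$aligned_len == 19, ]
  expect_equal(full$fragment_start, 20L)
  expect_equal(full$subject_start, 40L)
  expect_equal(full$subject_end, 59L)
  # 18-nt exact overlaps flag the two neighbouring fragments as well
  expect_true(all(c(19L, 20L, 21L) %in% hits$fragment_start))
})

test_that("single substitution in a planted block keeps 18/19 hits", {
  set.seed(12)
  target <- rand_seq(80)
  block <- substr(target, 21, 50)  # 30 nt, fragments 20..31 fully inside
  mid <- 15L
  mutated <- block
  old <- substr(mutated, mid, mid)
  substr(mutated, mid, mid) <- setdiff(c("A", "C", "G", "T"), old)[1]
  db <- transcriptome(c(host = paste0(rand_seq(50), mutated, rand_seq(50))))
  hits <- scan_offtargets(tile_target(target), db)
  oracle <- scan_offtargets_bruteforce(tile_target(target), db)
  expect_identical(hits, oracle)
  # fragments spanning the mutated column still reach 18/19 ~ 94.7%
  spanning <- hits$fragment_start <= 34L & hits$fragment_start + 19L > 34L &
    hits$gap_count == 0L & hits$aligned_len == 19L
  expect_true(any(spanning))
  expect_true(all(hits$identity_pct[spanning] >= 100 * 18 / 19 - 1e-9))
  # every fully-contained fragment of the block is flagged
  expect_true(all(20:31 %in% hits$fragment_start))
})

test_that("random unrelated transcriptome yields no accepted hits", {
  set.seed(13)
  target <- rand_seq(120)
  db <- make_transcriptome(4, c(400, 800), seed = 99)
  hits <- scan_offtargets(tile_target(target), db)
  expect_equal(nrow(hits), 0L)
  expect_identical(hits, scan_offtargets_bruteforce(tile_target(target), db))
})

test_that("self hits are excluded and empty inputs give empty results", {
  set.seed(14)
  target <- rand_seq(60)
  fr <- tile_target(target)
  self_db <- transcriptome(c(me = target), target_ids = "me")
  expect_equal(nrow(scan_offtargets(fr, self_db)), 0L)
  expect_equal(nrow(scan_offtargets(fr[0, ], self_db)), 0L)
})

test_that("strand symmetry: reverse-complementing the database flips strands", {
  for (seed in 1:5) {
    inst <- planted_instance(seed)
    h_fwd <- scan_offtargets(inst$fragments, inst$db)
    rc <- inst$db
    rc$sequences[] <- vapply(rc$sequences, revcomp_chr, character(1))
    h_rc <- scan_offtargets(inst$fragments, rc)
    key <- function(h) sort(paste(h$fragment_start, h$subject_id))
    expect_equal(key(h_rc), key(h_fwd))
    flip <- c("+" = "-", "-" = "+")
    key2 <- function(h, s) sort(paste(h$fragment_start, h$subject_id, s))
    expect_equal(key2(h_rc, h_rc$strand), key2(h_fwd, flip[h_fwd$strand]))
  }
})

test_that("relaxing any threshold never removes an accepted hit", {
  inst <- planted_instance(21, sub_rate = 0.06, indel_rate = 0.03)
  # Relaxation can merge loci (newly-accepted alignments bridge spans), so
  # monotonicity is asserted on the (fragment, subject, strand) level: no
  # flagged locus disappears.
  trip <- function(h) unique(paste(h$fragment_start, h$subject_id, h$strand))
  h0 <- trip(scan_offtargets(inst$fragments, inst$db, scan_params()))
  relaxed <- list(
    scan_params(min_match_len = 16L),
    scan_params(min_identity_pct = 80),
    scan_params(max_gaps = 3L)
  )
  for (p in relaxed) {
    h1 <- trip(scan_offtargets(inst$fragments, inst$db, p))
    expect_true(all(h0 %in% h1))
  }
})

test_that("offtargets_from_blast applies the acceptance rule to imported hits", {
  fr <- tile_target(rand_seq(40, seed = 31))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    sprintf("frag_0\ttx7\t94.737\t19\t1\t0\t1\t19\t101\t119\t1e-3\t30"),
    sprintf("frag_2\ttx7\t88.000\t19\t2\t0\t1\t19\t101\t119\t1e-3\t30"),  # identity
    sprintf("frag_5\ttx8\t100.000\t17\t0\t0\t1\t17\t50\t66\t1e-3\t30"),   # length
    sprintf("frag_7\tself\t100.000\t19\t0\t0\t1\t19\t10\t28\t1e-9\t38")   # self
  ), tsv)
  hits <- import_blast_tab(tsv)
  acc <- offtargets_from_blast(hits, fr, target_ids = "self")
  expect_equal(acc$fragment_start, 0L)
  expect_equal(acc$subject_id, "tx7")
  bad <- hits; bad$query_id[1] <- "frag_99"
  expect_error(offtargets_from_blast(bad, fr), "frag_99")
})

test_that("filter_candidate_hits enforces strict e-value/identity/coverage", {
  mk <- function(e, id, qs, qe) {
    data.frame(query_id = "q", subject_id = "s", e_value = e,
               identity_pct = id, query_start = qs, query_end = qe)
  }
  # coverage computed on a 100-residue query
  expect_equal(nrow(filter_candidate_hits(mk(1e-6, 25, 0, 60), 100)), 1L)
  expect_equal(nrow(filter_candidate_hits(mk(1e-4, 80, 0, 90), 100)), 0L)  # e-value
  expect_equal(nrow(filter_candidate_hits(mk(1e-6, 20.0, 0, 90), 100)), 0L) # identity
  expect_equal(nrow(filter_candidate_hits(mk(1e-6, 80, 0, 50), 100)), 0L)   # coverage
  expect_equal(nrow(filter_candidate_hits(mk(1e-5, 80, 0, 90), 100)), 0L)   # e strict
  hits <- mk(NA, 50, 0, 90)
  expect_error(filter_candidate_hits(hits, 100), "e-value")
  expect_error(filter_candidate_hits(mk(1e-6, 50, 0, 90), 0), "query_len")
})
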