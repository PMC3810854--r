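# Filter HMM derivation, HMM scoring against the path-enumeration
# oracle, window scanning, envelopes and the staged cascade.

test_that("the derived HMM mirrors the CM's marginal emissions", {
  # no pairs: match emissions equal the CM's ML emissions
  cm <- cm_build(fix_aln(c("ACGU", "AGGU"), "____"))
  hmm <- cm_to_hmm(cm)
  expect_equal(hmm$M, cm$clen)
  ml <- which(vapply(cm$states, function(s) s$type, "") == "ML")
  for (k in seq_len(hmm$M)) {
    expect_equal(hmm$mesc[k, ], cm$states[[ml[k]]]$esc, tolerance = 1e-4)
  }
  validate_profile_hmm(hmm)

  # paired columns marginalize the 16-vector over the partner base
  cmh <- cm_build(fix_aln(c("GGAACC", "GGUUCC", "GCAAGC"), "<<..>>"))
  hmmh <- cm_to_hmm(cmh)
  mp <- which(vapply(cmh$states, function(s) s$type, "") == "MP")[1]
  p16 <- covmod:::implied_probs(cmh$states[[mp]]$esc,
                                as.numeric(outer(cmh$null, cmh$null)))
  # brute-force marginal of the left partner
  left_marg <- vapply(1:4, function(a) sum(p16[(a - 1) * 4 + 1:4]), 0)
  expect_equal(hmmh$mesc[1, ], round(log2(left_marg / 0.25), 5),
               tolerance = 1e-4)
  validate_profile_hmm(hmmh)
})

test_that("Viterbi and Forward match path enumeration on toy HMMs", {
  cms <- list(cm_build(fix_aln(c("ACG", "AGG"), "___")),
              cm_build(fix_aln(c("ACGUA", "AGGUA", "ACGCA"), "_____")))
  set.seed(13)
  for (cm in cms) {
    hmm <- cm_to_hmm(cm)
    seqs <- c(all_seqs(1), all_seqs(2),
              vapply(1:25, function(q) random_rna(sample(3:6, 1)), ""))
    for (s in seqs) {
      for (mode in c("local", "glocal")) {
        o <- oracle_hmm_scores(hmm, s, mode)
        expect_equal(hmm_viterbi(hmm, s, mode), o$viterbi,
                     tolerance = 1e-9)
        expect_equal(hmm_forward(hmm, s, mode, exact = TRUE), o$forward,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("Forward dominates Viterbi; empty sequences score as defined", {
  cm <- cm_build(fix_aln(c("GGAAACC", "GGUUUCC"), "<<...>>"))
  hmm <- cm_to_hmm(cm)
  set.seed(2)
  for (q in 1:20) {
    s <- random_rna(sample(1:40, 1))
    expect_gte(hmm_forward(hmm, s) + 1e-9, hmm_viterbi(hmm, s))
  }
  # glocal empty = all-delete path score; local empty = -inf sentinel
  tr <- hmm$trans
  alldel <- unname(tr[1, "MD"] + sum(tr[2:hmm$M, "DD"]))
  expect_equal(hmm_viterbi(hmm, "", mode = "glocal"), alldel,
               tolerance = 1e-9)
  expect_lt(hmm_viterbi(hmm, "", mode = "local"),
            covmod:::NEG_INF_SCORE / 2)
})

test_that("an uninformative HMM with forced match transitions scores only transitions", {
  M <- 4L
  trans <- matrix(covmod:::NEG_INF_SCORE, M + 1, 9,
                  dimnames = list(NULL, covmod:::TRANS_COLS))
  trans[, "MM"] <- 0  # deterministic M->M, probability one
  hmm <- structure(list(name = "flat", M = M,
                        mesc = matrix(0, M, 4), trans = trans,
                        calibration = list()),
                   class = "profile_hmm")
  expect_equal(hmm_viterbi(hmm, "ACGUAC", mode = "glocal"), 0,
               tolerance = 1e-12)
})

test_that("window tiling follows the stated rule and maps strands back", {
  cm <- cm_build(fix_aln(c("ACGU", "AGGU"), "____"))
  hmm <- cm_to_hmm(cm)
  target <- "GGAAUUCCGG"  # length 10
  sw <- scan_windows(hmm, target, window_len = 5, overlap = 2)
  expect_identical(sw$start, c(1L, 4L, 6L))
  expect_identical(sw$end, c(5L, 8L, 10L))
  # window score equals scoring the subsequence directly
  expect_equal(sw$score[2], hmm_viterbi(hmm, substr(target, 4, 8)),
               tolerance = 1e-9)
  # reverse strand: forward coordinates, monotone mapping
  swm <- scan_windows(hmm, target, window_len = 5, overlap = 2,
                      strand = "-")
  expect_identical(sort(swm$start), c(1L, 3L, 6L))
  expect_equal(swm$score[1], hmm_viterbi(hmm, substr(revcomp(target), 1, 5)),
               tolerance = 1e-9)
  # short target: one full-length window
  expect_equal(nrow(scan_windows(hmm, "ACGU", 10, 3)), 1)
})

test_that("envelope definition finds planted copies and never overlaps", {
  fam <- accepted_family(151)
  cm <- cm_build(covmod:::subset_alignment(fam$aln, fam$split$train))
  hmm <- cm_to_hmm(cm)
  set.seed(31)
  # weak-model window: empty result is a value, not an error
  blank <- define_envelopes(hmm, random_rna(120), p_in = 0.999)
  expect_true(is.matrix(blank))
  # two well-separated copies in one window -> two envelopes on target
  win <- paste0(random_rna(25), fam$consensus, random_rna(60),
                fam$consensus, random_rna(25))
  envs <- define_envelopes(hmm, win)
  expect_gte(nrow(envs), 2)
  if (nrow(envs) > 1) {
    expect_true(all(envs[-1, "start"] > envs[-nrow(envs), "end"]))
  }
  expect_true(all(envs[, "start"] >= 1 & envs[, "end"] <= nchar(win)))
  # each planted copy is overlapped by an envelope
  for (s0 in c(26, 25 + cm$clen + 60 + 1)) {
    expect_true(any(envs[, "start"] <= s0 + cm$clen - 1 &
                      envs[, "end"] >= s0))
  }
})

test_that("the cascade is monotone, respects ceilings, and finds plants", {
  fam <- accepted_family(161)
  cm <- cm_build(covmod:::subset_alignment(fam$aln, fam$split$train))
  cm <- calibrate_model(cm, n = 300L, L = 150L, seed = 5L)
  hmm <- cm_to_hmm(cm)
  W <- 2L * cm$clen + 20L
  set.seed(41)
  target <- paste0(random_rna(2000), fam$consensus, random_rna(2000))
  expect_error(run_filter_cascade(hmm, target, thresholds = c(0.1, 0.2, 0.3),
                                  window_len = W, overlap = cm$clen),
               "non-increasing")
  # ceilings of 1 keep everything; ceilings of 0 keep nothing
  all_in <- run_filter_cascade(hmm, target, thresholds = c(1, 1, 1),
                               window_len = W, overlap = cm$clen)
  expect_equal(unname(all_in$stats["stage3_pass"]),
               unname(all_in$stats["windows"]))
  none <- run_filter_cascade(hmm, target, thresholds = c(0, 0, 0),
                             window_len = W, overlap = cm$clen)
  expect_equal(unname(none$stats["stage1_pass"]), 0)
  # survivor counts never grow from stage to stage (defaults)
  fc <- run_filter_cascade(hmm, target, window_len = W,
                           overlap = cm$clen)
  expect_true(all(diff(fc$stats) <= 0))
  # the planted copy survives to an envelope
  expect_true(any(fc$envelopes$start <= 2000 + cm$clen &
                    fc$envelopes$end >= 2001))
  # uncalibrated models are refused
  cm0 <- cm_build(covmod:::subset_alignment(fam$aln, fam$split$train))
  expect_error(run_filter_cascade(cm_to_hmm(cm0), target, window_len = W,
                                  overlap = cm$clen), "not calibrated")
})
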