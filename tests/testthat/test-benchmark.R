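# Synthetic families, train/test splitting, pseudo-genome construction
# and ROC scoring.

test_that("family generation is seed-deterministic and honors its knobs", {
  cfg <- family_config(len = 60, n_seq = 5)
  f1 <- generate_family(cfg, seed = 7)
  f2 <- generate_family(cfg, seed = 7)
  expect_identical(f1, f2)
  f3 <- generate_family(cfg, seed = 8)
  expect_false(identical(f1$aln$rows, f3$aln$rows))
  # zero mutation: descendants identical to the consensus
  f0 <- generate_family(family_config(len = 50, n_seq = 4, sub_rate = 0,
                                      indel_rate = 0), seed = 3)
  expect_true(all(f0$seqs == f0$consensus))
  # fully compensatory: every paired column remains a canonical pair
  fc <- generate_family(family_config(len = 60, n_seq = 8,
                                      p_compensatory = 1,
                                      indel_rate = 0), seed = 5)
  pt <- parse_wuss(fc$structure)
  canonical <- c("AU", "UA", "CG", "GC", "GU", "UG")
  m <- covmod:::aln_char_matrix(fc$aln$rows)
  keep <- !grepl("[a-z.]", substr(fc$aln$rows[1], 1, 1))  # no inserts anyway
  for (i in which(pt$partner > seq_len(pt$length))) {
    pairs <- paste0(m[, i], m[, pt$partner[i]])
    expect_true(all(pairs %in% canonical))
  }
  expect_error(family_config(pair_frac = 1.4), "infeasible")
})

test_that("the greedy split honors both identity ceilings and matches brute force", {
  # hand-built toy: 6 sequences with controlled pairwise identities over
  # 20 columns
  base <- "ACGUACGUACGUACGUACGU"
  mut <- function(s, pos) {
    for (p in pos) substr(s, p, p) <- chartr("ACGU", "CAUG",
                                             substr(s, p, p))
    s
  }
  rows <- c(base,                 # s1
            mut(base, 1:2),      # s2: 90% to s1 (test-incompatible)
            mut(base, 1:12),     # s3: 40% to s1
            mut(base, 9:20),     # s4: 40% to s1, 20% to s3
            mut(base, 5:16),     # s5: 60% to s3 and s4 (train material)
            mut(base, 1:20))     # s6: 0% to s1 (train material)
  aln <- fix_aln(rows, strrep("_", 20))
  sp <- split_train_test(aln, test_test_max_id = 0.70,
                         train_test_max_id = 0.60, min_train = 2,
                         min_test = 1, max_test = 3)
  expect_true(sp$accepted)
  idm <- outer(seq_along(rows), seq_along(rows),
               Vectorize(function(a, b)
                 pairwise_identity(rows[a], rows[b])))
  # returned split satisfies the ceilings
  expect_true(all(idm[sp$test, sp$test][upper.tri(diag(length(sp$test)))]
                  <= 0.70))
  expect_true(all(idm[sp$train, sp$test] <= 0.60))
  # brute force over all assignments: the returned test set is maximal
  # among valid splits with >= 2 training sequences
  best <- 0
  n <- length(rows)
  for (mask in 0:(2^n - 1)) {
    test <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(test) < 1 || length(test) > 3) next
    if (length(test) > 1 &&
        any(idm[test, test][upper.tri(diag(length(test)))] > 0.70)) next
    train <- setdiff(seq_len(n), test)
    train <- train[apply(idm[train, test, drop = FALSE], 1,
                         function(r) all(r <= 0.60))]
    if (length(train) >= 2) best <- max(best, length(test))
  }
  expect_equal(length(sp$test), best)
  # forced rules: identical candidates cannot share the test set
  dup <- fix_aln(c(base, base, mut(base, 1:12), mut(base, 5:16)),
                 strrep("_", 20))
  spd <- split_train_test(dup, min_train = 1, min_test = 1)
  expect_lte(sum(c(1, 2) %in% spd$test), 1)
})

test_that("pseudo-genome construction embeds disjoint truths deterministically", {
  test_seqs <- data.frame(
    family = rep(c("fa", "fb"), each = 3),
    name = sprintf("t%d", 1:6),
    seq = vapply(1:6, function(q) random_rna(60 + q), ""),
    stringsAsFactors = FALSE)
  bs <- build_pseudo_genome(test_seqs, n_chunks = 2, chunk_len = 10000,
                            seed = 5)
  expect_equal(sum(nchar(bs$genome)), 20000 + sum(nchar(test_seqs$seq)))
  expect_equal(nrow(bs$truth), 6)
  # disjoint truth intervals per target
  for (t in unique(bs$truth$target)) {
    tr <- bs$truth[bs$truth$target == t, ]
    tr <- tr[order(tr$start), ]
    if (nrow(tr) > 1) expect_true(all(tr$start[-1] > tr$end[-nrow(tr)]))
    expect_true(all(tr$end <= nchar(bs$genome[t])))
  }
  # embedded residues match the (strand-adjusted) test sequences
  for (q in seq_len(nrow(bs$truth))) {
    tr <- bs$truth[q, ]
    got <- unname(substr(bs$genome[tr$target], tr$start, tr$end))
    want <- test_seqs$seq[test_seqs$name == tr$name]
    if (tr$strand == "-") want <- revcomp(want)
    expect_identical(got, want)
  }
  expect_identical(build_pseudo_genome(test_seqs, n_chunks = 2,
                                       chunk_len = 10000, seed = 5), bs)
  expect_error(build_pseudo_genome(test_seqs, n_chunks = 1,
                                   chunk_len = 100, seed = 1),
               "larger chunks")
})

test_that("markov decoys reproduce the training trinucleotide composition", {
  covmod:::with_seed(11, {
    train <- paste(sample(c("A", "C", "G", "U"), 30000, replace = TRUE,
                          prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    dec <- covmod:::sample_decoy(50000,
                                 list(type = "markov", k = 3,
                                      train_seq = train))
    tri_freq <- function(s) {
      tri <- substring(s, 1:(nchar(s) - 2), 3:nchar(s))
      table(factor(tri)) / length(tri)
    }
    ft <- tri_freq(train)
    fd <- tri_freq(dec)
    shared <- intersect(names(ft), names(fd))
    expect_gt(length(shared), 40)
    expect_lt(max(abs(ft[shared] - fd[shared])), 0.01)
  })
})

test_that("ROC scoring reproduces a hand-enumerated curve", {
  truth <- data.frame(
    family = c("fa", "fa", "fb"), target = "chr",
    strand = c("+", "+", "-"), start = c(100, 500, 900),
    end = c(160, 560, 960), name = c("t1", "t2", "t3"),
    stringsAsFactors = FALSE)
  hits <- data.frame(
    model  = c("fa",  "fa",  "fa",  "fb",  "fa"),
    target = "chr",
    strand = c("+",   "+",   "+",   "-",   "+"),
    start  = c(101,   102,   540,   2000,  130),
    end    = c(158,   159,   600,   2060,  190),
    bits   = c(50,    45,    40,    35,    30),
    evalue = c(1e-9,  1e-8,  1e-7,  1e-6,  1e-5),
    stringsAsFactors = FALSE)
  # manual walk: hit1 claims t1 (TP); hit2 overlaps claimed t1 -> FP;
  # hit3 covers only 21/61 < 50% of t2 -> FP; hit4 decoy -> FP;
  # hit5 overlaps claimed t1 by 31/61 >= 50% -> still FP (claimed once)
  roc <- score_roc(hits, truth, genome_mb = 1, n_queries = 2)
  expect_equal(roc$tp, c(1, 1, 1, 1, 1))
  expect_equal(roc$fp, c(0, 1, 2, 3, 4))
  expect_equal(roc$sensitivity, rep(1 / 3, 5))
  # 3 FPs over 1 Mb and 2 queries -> 1.5 FP/Mb/query at the 4th hit
  expect_equal(roc$fp_per_mb_query[4], 1.5)
  # perfect list: sensitivity 1 at zero false positives
  perfect <- data.frame(
    model = truth$family, target = truth$target, strand = truth$strand,
    start = truth$start, end = truth$end, bits = 99,
    evalue = c(1e-12, 1e-11, 1e-10), stringsAsFactors = FALSE)
  proc <- score_roc(perfect, truth, 1, 2)
  expect_equal(proc$sensitivity[3], 1)
  expect_equal(proc$fp[3], 0)
  # monotone curve
  expect_true(all(diff(roc$tp) >= 0) && all(diff(roc$fp) >= 0))
  bad <- perfect
  bad$target <- "nowhere"
  expect_error(score_roc(bad, truth, 1, 2), "unknown")
})
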