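# CM dynamic programming: CYK/Inside against the enumeration oracle,
# parse trees, bands, and alignment reconstruction.

test_that("CYK and Inside agree with parse enumeration on a toy model", {
  cm <- toy_zoo()$hairpin
  attr(cm, "pack_glocal") <- covmod:::cm_pack(cm, local = FALSE)
  for (L in 1:4) {
    seqs <- all_seqs(L)
    oracle <- oracle_cm_scores(cm, seqs)
    got_cyk <- vapply(seqs, function(s) cyk(cm, s, mode = "glocal")$score, 0)
    got_ins <- vapply(seqs, function(s)
      inside(cm, s, mode = "glocal", exact = TRUE)$score, 0)
    expect_equal(unname(got_cyk), oracle$cyk, tolerance = 1e-9)
    expect_equal(unname(got_ins), oracle$inside, tolerance = 1e-9)
  }
})

test_that("Inside dominates CYK and a training sequence beats its point mutants", {
  zoo <- toy_zoo()
  set.seed(11)
  for (cm in zoo) {
    for (q in 1:5) {
      s <- random_rna(sample(3:8, 1))
      expect_gte(inside(cm, s)$score + 1e-9, cyk(cm, s)$score)
    }
  }
  # single-sequence model scores its training sequence at least as well
  # as any single-point mutant
  train <- "GGAAACC"
  cm1 <- cm_build(fix_aln(train, "<<...>>"))
  s0 <- cyk(cm1, train)$score
  for (pos in 1:7) for (b in setdiff(c("A", "C", "G", "U"),
                                     substr(train, pos, pos))) {
    mut <- train
    substr(mut, pos, pos) <- b
    expect_gte(s0 + 1e-9, cyk(cm1, mut)$score)
  }
})

test_that("parse trees re-score exactly and account for every residue", {
  zoo <- toy_zoo()
  set.seed(5)
  for (cm in zoo) {
    for (mode in c("glocal", "local")) {
      for (q in 1:4) {
        s <- random_rna(sample(4:9, 1))
        ck <- cyk(cm, s, mode = mode, scan = (mode == "local"))
        if (ck$score <= covmod:::NEG_INF_SCORE / 2) next
        # tree coordinates index the scanned sequence itself
        expect_equal(parse_tree_score(cm, ck$tree, s, mode = mode),
                     ck$score, tolerance = 1e-9)
        nres <- if (mode == "local") ck$j - ck$i + 1L else nchar(s)
        expect_equal(covmod:::parse_tree_residues(cm, ck$tree), nres)
      }
    }
  }
})

test_that("a single-parse model makes Inside equal CYK exactly", {
  cm <- cm_build(fix_aln("ACGU", "____"))
  # force determinism: each split state goes to the next ML only, inserts
  # are unreachable
  stype <- vapply(cm$states, function(s) s$type, "")
  for (v in seq_along(cm$states)) {
    s <- cm$states[[v]]
    if (!length(s$children)) next
    keep <- which(stype[s$children] %in% c("ML", "E"))[1]
    tsc <- rep(covmod:::NEG_INF_SCORE, length(s$children))
    if (!is.na(keep)) tsc[keep] <- 0
    cm$states[[v]]$tsc <- tsc
  }
  s <- "ACGU"
  expect_equal(inside(cm, s, exact = TRUE)$score, cyk(cm, s)$score,
               tolerance = 1e-12)
})

test_that("local mode contains glocal mode under zero-cost begins and ends", {
  zoo <- toy_zoo()
  set.seed(3)
  for (cm in zoo) {
    packL <- covmod:::cm_pack(cm, local = TRUE, begin_sc = 0, end_sc = 0)
    for (q in 1:6) {
      s <- random_rna(sample(3:8, 1))
      codes <- covmod:::encode_seq(s)
      L <- length(codes)
      fb <- covmod:::full_bands(length(cm$states), L)
      loc <- covmod:::cm_engine_cpp(codes, packL, inside = FALSE,
                                    scan = FALSE, exact = TRUE,
                                    ilo = fb$imin, ihi = fb$imax,
                                    jlo = fb$jmin, jhi = fb$jmax,
                                    traceback = FALSE)
      glo <- cyk(cm, s, mode = "glocal")
      expect_gte(loc$score + 1e-9, glo$score)
    }
  }
})

test_that("full bands reproduce unbanded scores and degenerate bands signal -inf", {
  fam <- accepted_family(131)
  cm <- cm_build(covmod:::subset_alignment(fam$aln, fam$split$train))
  s <- unname(fam$seqs[fam$split$test])[1]
  L <- nchar(s)
  fb <- covmod:::full_bands(length(cm$states), L)
  fb$column_bands <- NULL
  class(fb) <- "band_set"
  for (mode in c("glocal", "local")) {
    expect_identical(banded_cyk(cm, s, fb, mode = mode)$score,
                     cyk(cm, s, mode = mode)$score)
    expect_identical(banded_inside(cm, s, fb, mode = mode,
                                   exact = TRUE)$score,
                     inside(cm, s, mode = mode, exact = TRUE)$score)
  }
  # zero-width bands exclude every parse: -inf sentinel, no exception
  nb <- list(imin = rep(2L, length(cm$states)),
             imax = rep(1L, length(cm$states)),
             jmin = rep(1L, length(cm$states)),
             jmax = rep(0L, length(cm$states)))
  res <- banded_cyk(cm, s, nb, mode = "glocal")
  expect_lt(res$score, covmod:::NEG_INF_SCORE / 2)
  expect_null(res$tree)
})

test_that("HMM-derived bands behave: full at tiny tail_p, nested in tail_p, cover the truth", {
  fam <- accepted_family(141)
  cm <- cm_build(covmod:::subset_alignment(fam$aln, fam$split$train))
  hmm <- cm_to_hmm(cm)
  set.seed(21)
  s <- paste0(random_rna(30), fam$consensus, random_rna(30))
  b0 <- derive_bands(hmm, cm, s, tail_p = 1e-13)
  expect_identical(banded_cyk(cm, s, b0, mode = "glocal")$score,
                   cyk(cm, s, mode = "glocal")$score)
  # widths monotone non-increasing in tail_p
  widths <- vapply(c(1e-9, 1e-7, 1e-5, 1e-3), function(tp) {
    b <- derive_bands(hmm, cm, s, tail_p = tp, mode = "glocal")
    mean(b$imax - b$imin)
  }, 0)
  expect_true(all(diff(widths) <= 1e-9))
  # planted consensus: each column's band contains its true position
  b <- derive_bands(hmm, cm, s, tail_p = 1e-7, mode = "glocal")
  truth_pos <- 30 + seq_len(cm$clen)
  expect_true(all(b$column_bands["lo", ] <= truth_pos &
                    b$column_bands["hi", ] >= truth_pos))
})

test_that("aligning training sequences reproduces their match columns", {
  aln <- fix_aln(c("GGAAUACCU", "GGCAUGCCU", "GGAUUACCU"), "<<<..>>>.",
                 id = "self")
  # no gaps anywhere: the alignment is its own match-column pattern
  cm <- cm_build(aln)
  res <- cmalign(cm, stats::setNames(aln$rows, aln$names))
  expect_identical(res$alignment$rows, aln$rows)
  # same pairing (the writer uses canonical <>/: characters)
  expect_identical(parse_wuss(res$alignment$ss_cons)$partner,
                   parse_wuss(aln$ss_cons)$partner)
  # output round-trips through stockholm
  f <- tempfile(fileext = ".sto")
  write_stockholm(res$alignment, f)
  expect_identical(read_stockholm(f)[[1]]$rows, res$alignment$rows)
  # single sequence: ungapped residues equal the input
  one <- cmalign(cm, c(x = "GGAAUACCU"))
  expect_identical(gsub("[-.]", "", one$alignment$rows), "GGAAUACCU")
})
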