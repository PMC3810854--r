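# Model construction: consensus columns, guide tree, state layout,
# parameterization and the model file format.

test_that("consensus column selection follows the occupancy rule", {
  aln <- fix_aln(c("A-CA", "A-C-", "A---"), "____")
  mask <- select_consensus_columns(aln, 0.5)
  expect_identical(mask, c(TRUE, FALSE, TRUE, FALSE))
  # an all-gap column is never consensus
  expect_false(select_consensus_columns(aln, 1e-9)[2])
  # a paired column whose partner is dropped stays, unpaired
  aln2 <- fix_aln(c("GAC", "G--", "G--"), "<.>")
  mask2 <- select_consensus_columns(aln2, 0.5)
  expect_identical(mask2, c(TRUE, FALSE, FALSE))
  cm <- cm_build(aln2)
  expect_equal(cm$clen, 1L)
  expect_equal(sum(vapply(cm$nodes, function(n) n$type == "MATP", TRUE)), 0)
})

test_that("guide trees have the hand-derived node multisets", {
  counts <- function(ss) {
    tr <- build_guide_tree(parse_wuss(ss))
    table(vapply(tr$nodes, `[[`, "", "type"))
  }
  c1 <- counts("<<__>>")
  expect_equal(as.integer(c1[c("ROOT", "MATP", "MATL", "END")]), c(1L, 2L, 2L, 1L))
  c2 <- counts("<_><_>")
  expect_equal(as.integer(c2[c("ROOT", "BIF", "BEGL", "BEGR", "MATP",
                             "MATL", "END")]), rep(c(1L, 2L), c(4, 3)))
  c3 <- counts("____")
  expect_equal(as.integer(c3[c("ROOT", "MATL", "END")]), c(1L, 4L, 1L))
})

test_that("every consensus column is consumed exactly once (random structures)", {
  set.seed(7)
  for (q in 1:25) {
    len <- sample(10:60, 1)
    pt <- covmod:::sample_structure(len, runif(1, 0, 0.6))
    tr <- build_guide_tree(pt)
    consumed <- integer(0)
    for (nd in tr$nodes) {
      consumed <- c(consumed, nd$left, nd$right)
    }
    consumed <- sort(consumed[!is.na(consumed)])
    expect_identical(consumed, seq_len(len))
  }
})

test_that("state layout matches the node expansion table", {
  n_states <- function(ss) {
    length(layout_states(build_guide_tree(parse_wuss(ss)))$states)
  }
  expect_equal(n_states("____"), 16)    # 3 + 4*3 + 1
  expect_equal(n_states("<<__>>"), 22)  # 3 + 2*6 + 2*3 + 1
  # emission dimensionality: 16 per MP, 4 per single-emitter, 0 otherwise
  cm <- cm_build(fix_aln(c("GGAACC", "GGUUCC"), "<<..>>"))
  for (s in cm$states) {
    expect_length(s$esc, covmod:::state_emit_dim(s$type))
  }
})

test_that("parameterization reproduces the closed-form pseudocount arithmetic", {
  # single sequence, Laplace +1, uniform null: P(A) = (1+1)/(1+4)
  cm <- cm_build(fix_aln("ACGU", "____"), pseudocount = 1)
  ml <- which(vapply(cm$states, function(s) s$type, "") == "ML")
  expect_equal(cm$states[[ml[1]]]$esc[1], round(log2(1.6), 5))
  expect_equal(cm$states[[ml[2]]]$esc[2], round(log2(1.6), 5))
  # all transition/emission distributions implied by the scores normalize
  for (s in cm$states) {
    if (s$type %in% c("B", "E") || length(s$children) == 0) next
    p <- 2^s$tsc
    expect_equal(sum(p), 1, tolerance = 1e-4)
  }
  for (s in cm$states) {
    if (covmod:::state_emit_dim(s$type) == 4 && s$type %in% c("ML", "MR")) {
      expect_equal(sum(0.25 * 2^s$esc), 1, tolerance = 1e-4)
    }
  }
})

test_that("emission scores shrink to the null as pseudocounts grow", {
  aln <- fix_aln(c("GGAACC", "GGAACC", "GGAACC"), "<<..>>")
  sizes <- c(0.5, 5, 50, 5000)
  worst <- vapply(sizes, function(a) {
    cm <- cm_build(aln, pseudocount = a)
    max(vapply(cm$states, function(s)
      if (length(s$esc)) max(abs(s$esc)) else 0, 0))
  }, 0)
  expect_true(all(diff(worst) < 0))
  expect_lt(worst[length(worst)], 0.01)
})

test_that("model files round-trip field-for-field and support multi-model files", {
  zoo <- toy_zoo()
  f <- tempfile(fileext = ".cm")
  write_cm(zoo, f)
  back <- read_cm(f)
  expect_length(back, length(zoo))
  for (q in seq_along(zoo)) {
    expect_identical(back[[q]], zoo[[q]])
  }
  # calibration block round-trips too
  cal <- zoo$chain
  cal$calibration$cm_inside_glocal <-
    gumbel_params(3.21, 0.71, calib_len = 2e5, calib_n = 1000L,
                  seed = 7L)
  write_cm(cal, f)
  expect_identical(read_cm(f)[[1]], cal)

  expect_error(read_cm(tempfile()), "no such file")
  writeLines("NONSENSE 9", f)
  expect_error(read_cm(f), "version")
  writeLines(c("COVMOD 1", "NAME x"), f)
  expect_error(read_cm(f), "truncated")
})

test_that("identical alignments build bit-identical model files", {
  aln <- fix_aln(c("GGAAACCU", "GGUUUCCU", "GGAUACCU"), "<<...>>.")
  f1 <- tempfile(); f2 <- tempfile()
  write_cm(cm_build(aln), f1)
  write_cm(cm_build(aln), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("an uncalibrated model refuses E-value-thresholded search", {
  cm <- cm_build(fix_aln(c("GGAAACCU", "GGUUUCCU"), "<<...>>."))
  expect_error(cmsearch(cm, c(t1 = random_rna(300))), "not calibrated")
})
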