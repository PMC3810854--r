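# Structure parsing and alignment/sequence file input-output.

test_that("bracket structures parse to the forced pair tables", {
  pt <- parse_wuss("<<<___>>>")
  expect_identical(pt$partner, c(9L, 8L, 7L, 0L, 0L, 0L, 3L, 2L, 1L))
  expect_identical(parse_wuss(":::::")$partner, integer(5))
  expect_error(parse_wuss("<<>"), "unbalanced")
  expect_error(parse_wuss("<x!"), "illegal")
  expect_error(parse_wuss("(<)>"), "mismatched|unbalanced")
  # pseudoknot layers are dropped with a warning
  expect_warning(pt2 <- parse_wuss("<<AA>>aa"), "pseudoknot")
  expect_identical(pt2$partner, c(6L, 5L, 0L, 0L, 2L, 1L, 0L, 0L))
})

test_that("parsed structures are always nested and involutive", {
  set.seed(42)
  rand_balanced <- function(n) {
    # random balanced bracket string mixed with unpaired characters
    out <- character(0)
    open <- 0
    for (q in seq_len(n)) {
      r <- runif(1)
      if (r < 0.35 && open > 0) {
        out <- c(out, ">")
        open <- open - 1
      } else if (r < 0.7) {
        out <- c(out, "<")
        open <- open + 1
      } else {
        out <- c(out, sample(c(".", ",", ":", "_", "-", "~"), 1))
      }
    }
    paste(c(out, rep(">", open)), collapse = "")
  }
  for (q in 1:40) {
    pt <- parse_wuss(rand_balanced(sample(5:60, 1)))
    expect_true(validate_pair_table(pt))
  }
})

test_that("stockholm files round-trip, concatenate interleaved blocks, and reject broken input", {
  aln <- fix_aln(c("GGAAcC", "GG--CC"), "<<..>>", id = "toyfam")
  f <- tempfile(fileext = ".sto")
  write_stockholm(aln, f)
  back <- read_stockholm(f)
  expect_length(back, 1)
  expect_identical(back[[1]]$rows, toupper(aln$rows))
  expect_identical(back[[1]]$ss_cons, aln$ss_cons)
  expect_identical(back[[1]]$id, "toyfam")
  # re-writing what was read is a fixed point
  f2 <- tempfile(fileext = ".sto")
  write_stockholm(back, f2)
  expect_identical(read_stockholm(f2), back)

  # interleaved (multi-block) records concatenate per sequence
  writeLines(c("# STOCKHOLM 1.0",
               "s1 GGGGAAAACCCC",
               "s2 GGGGAAAACCCC",
               "#=GC SS_cons <<<<....>>>>",
               "",
               "s1 AAAA",
               "s2 AAUU",
               "#=GC SS_cons ....",
               "//"), f)
  multi <- read_stockholm(f)[[1]]
  expect_equal(nchar(multi$rows), c(16, 16))
  expect_equal(nchar(multi$ss_cons), 16)

  writeLines(c("# STOCKHOLM 1.0", "s1 ACGU", "//"), f)
  expect_error(read_stockholm(f), "SS_cons")
  writeLines(c("# STOCKHOLM 1.0", "s1 ACGU", "s2 AC",
               "#=GC SS_cons ....", "//"), f)
  expect_error(read_stockholm(f), "s2")

  # two models per file
  write_stockholm(list(aln, fix_aln("ACGU", "____", id = "b")), f)
  expect_length(read_stockholm(f), 2)
})

test_that("fasta reading streams, normalizes and round-trips", {
  f <- tempfile(fileext = ".fa")
  seqs <- c(one = random_rna(100), two = random_rna(250))
  write_fasta(seqs, f)
  it <- read_fasta(f, chunk_size = 1L)
  r1 <- it()
  r2 <- it()
  expect_null(it())
  expect_equal(nchar(c(r1$seq, r2$seq)), c(100, 250))
  expect_identical(r1$name, "one")

  # lowercase DNA input is normalized to uppercase RNA
  writeLines(c(">x", "acgt", ">y", "GGTT"), f)
  got <- read_fasta_all(f)
  expect_identical(unname(got), c("ACGU", "GGUU"))

  writeLines(character(0), f)
  expect_null(read_fasta(f)())

  expect_error(write_fasta(c(a = "AC", a = "GG"), f), "duplicate")
  writeLines(c(">x", "AC", ">x", "GG"), f)
  it2 <- read_fasta(f)
  it2()
  expect_error(it2(), "duplicate")
})

test_that("reverse complement handles degenerate codes set-wise", {
  expect_identical(revcomp("ACGU"), "ACGU")
  expect_identical(revcomp("GGAU"), "AUCC")
  expect_identical(revcomp("RYN"), "NRY")
  expect_identical(revcomp(revcomp("GGAUCGN")), "GGAUCGN")
})
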