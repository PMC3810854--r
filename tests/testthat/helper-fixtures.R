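# Shared fixtures: tiny structure-annotated alignments and the toy-model
# zoo (unpaired chain, hairpin, interior loop, one bifurcation) used by
# the oracle-equivalence tests.

fix_aln <- function(rows, ss, names = sprintf("s%d", seq_along(rows)),
                    id = "fix") {
  structured_alignment(names, rows, ss, id = id)
}

# zoo of toy models, <= 6 consensus columns each
toy_zoo <- function(pseudocount = 0.5) {
  alns <- list(
    chain = fix_aln(c("ACGU", "AGGU", "ACGA"), "____", id = "chain"),
    hairpin = fix_aln(c("GGAACC", "GCUUGC", "GGAUCC"), "<<__>>",
                      id = "hairpin"),
    iloop = fix_aln(c("GAGCUC", "GUGCAC", "GAGCUC"), "<_<>_>",
                    id = "iloop"),
    bif = fix_aln(c("GACGUC", "GGCGCC", "GACGCC"), "<_><_>", id = "bif")
  )
  lapply(alns, cm_build, pseudocount = pseudocount)
}

# all RNA strings of length n (4^n)
all_seqs <- function(n) {
  if (n == 0) return("")
  grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "U")), n))
  apply(grid, 1, paste, collapse = "")
}

random_rna <- function(n, freqs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = freqs),
        collapse = "")
}

# a small benchmark-regime family (accepted split guaranteed by seed scan)
accepted_family <- function(seed0 = 101L, len = 65L) {
  for (sd in seed0:(seed0 + 120L)) {
    fam <- generate_family(family_config(len = len), seed = sd, id = "fam")
    sp <- split_train_test(fam$aln, max_test = 4)
    if (sp$accepted) {
      fam$split <- sp
      return(fam)
    }
  }
  stop("no accepted family in seed range")
}
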