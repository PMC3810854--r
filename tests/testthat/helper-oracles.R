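# Independent oracles: exhaustive parse-tree enumeration for CMs and
# path enumeration for profile HMMs. Deliberately naive - these recompute
# scores by brute force and never share code with the DP engines.

# ---- CM: enumerate all glocal parse trees of subsequence [i, j] ----
# A parse skeleton records the emitting states and their positions; its
# score against a concrete sequence is the transition total plus emission
# lookups, so one enumeration serves all sequences of a given length.
enum_cm_parses <- function(cm, pack, L) {
  states <- cm$states
  memo <- new.env(parent = emptyenv())
  rec <- function(v, i, j) {
    key <- paste(v, i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    ty <- states[[v]]$type
    out <- list()
    if (ty == "E") {
      if (i > j) out <- list(list(tsc = 0, em = list()))
    } else if (ty == "B") {
      l <- states[[v]]$children[1]
      r <- states[[v]]$children[2]
      for (k in (i - 1):j) {
        lefts <- rec(l, i, k)
        if (length(lefts) == 0) next
        rights <- rec(r, k + 1, j)
        for (pl in lefts) for (pr in rights) {
          out[[length(out) + 1]] <- list(tsc = pl$tsc + pr$tsc,
                                         em = c(pl$em, pr$em))
        }
      }
    } else {
      kids <- states[[v]]$children
      tsc <- states[[v]]$tsc
      if (ty %in% c("S", "D")) {
        for (q in seq_along(kids)) {
          for (p in rec(kids[q], i, j)) {
            out[[length(out) + 1]] <- list(tsc = p$tsc + tsc[q], em = p$em)
          }
        }
      } else if (ty %in% c("ML", "IL") && i <= j) {
        for (q in seq_along(kids)) {
          for (p in rec(kids[q], i + 1, j)) {
            out[[length(out) + 1]] <- list(
              tsc = p$tsc + tsc[q],
              em = c(list(c(v, i, NA)), p$em))
          }
        }
      } else if (ty %in% c("MR", "IR") && i <= j) {
        for (q in seq_along(kids)) {
          for (p in rec(kids[q], i, j - 1)) {
            out[[length(out) + 1]] <- list(
              tsc = p$tsc + tsc[q],
              em = c(list(c(v, NA, j)), p$em))
          }
        }
      } else if (ty == "MP" && i < j) {
        for (q in seq_along(kids)) {
          for (p in rec(kids[q], i + 1, j - 1)) {
            out[[length(out) + 1]] <- list(
              tsc = p$tsc + tsc[q],
              em = c(list(c(v, i, j)), p$em))
          }
        }
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, 1L, L)
}

# score every parse against every sequence: returns list(cyk=, inside=)
# vectors over the sequences (glocal, full-length parses)
oracle_cm_scores <- function(cm, seqs) {
  pack <- covmod:::cm_pack(cm, local = FALSE)
  L <- nchar(seqs[1])
  stopifnot(all(nchar(seqs) == L))
  X <- do.call(rbind, lapply(seqs, covmod:::encode_seq))
  parses <- enum_cm_parses(cm, pack, L)
  if (length(parses) == 0) {
    return(list(cyk = rep(covmod:::NEG_INF_SCORE, length(seqs)),
                inside = rep(covmod:::NEG_INF_SCORE, length(seqs))))
  }
  score_parse <- function(p) {
    s <- rep(p$tsc, nrow(X))
    for (em in p$em) {
      v <- em[1]
      if (is.na(em[3])) {
        s <- s + pack$esc1[v, X[, em[2]]]
      } else if (is.na(em[2])) {
        s <- s + pack$esc1[v, X[, em[3]]]
      } else {
        s <- s + pack$esc2[v, (X[, em[2]] - 1L) * 15L + X[, em[3]]]
      }
    }
    s
  }
  mx <- rep(covmod:::NEG_INF_SCORE, nrow(X))
  for (p in parses) mx <- pmax(mx, score_parse(p))
  acc <- rep(0, nrow(X))
  for (p in parses) acc <- acc + 2^(score_parse(p) - mx)
  list(cyk = mx, inside = mx + log2(acc))
}

# ---- HMM: enumerate all alignment paths of one sequence ----
# Mirrors the engine's semantics: free flanks; uniform local begin over
# match states; local Viterbi is the single best alignment while local
# Forward sums over multi-hit path sets (a hit may end and the model
# re-enter downstream); glocal enters at M1/D1 and exits at M_M/D_M.
oracle_hmm_paths <- function(hmm, seq, mode = "local",
                             multihit = FALSE) {
  codes <- covmod:::encode_seq(seq)
  L <- length(codes)
  M <- hmm$M
  mesc <- covmod:::mesc_codes(hmm)
  tr <- hmm$trans
  local <- mode == "local"
  lbsc <- -log2(M)
  memo <- new.env(parent = emptyenv())
  hits_memo <- new.env(parent = emptyenv())
  rec <- function(k, typ, i) {
    key <- paste(k, typ, i)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- numeric(0)
    if (typ == "M" && local) {
      # end of this hit (uniform exit cost); in multihit mode further
      # hits may follow
      out <- c(out, lbsc + if (multihit) c(0, hits_after(i)) else 0)
    }
    if (!local && k == M && typ %in% c("M", "D")) out <- c(out, 0)
    if (k < M) {
      row <- tr[k + 1, ]
      tM <- switch(typ, M = row[["MM"]], I = row[["IM"]], D = row[["DM"]])
      tI <- switch(typ, M = row[["MI"]], I = row[["II"]], D = row[["DI"]])
      tD <- switch(typ, M = row[["MD"]], I = row[["ID"]], D = row[["DD"]])
      if (i < L && tM > covmod:::NEG_INF_SCORE / 2) {
        out <- c(out, tM + mesc[k + 1, codes[i + 1]] + rec(k + 1, "M", i + 1))
      }
      if (i < L && tI > covmod:::NEG_INF_SCORE / 2) {
        out <- c(out, tI + rec(k, "I", i + 1))
      }
      if (tD > covmod:::NEG_INF_SCORE / 2) {
        out <- c(out, tD + rec(k + 1, "D", i))
      }
    }
    memo[[key]] <- out
    out
  }
  # all path sets with >= 1 further hit starting strictly after boundary i
  hits_after <- function(i) {
    key <- as.character(i)
    got <- hits_memo[[key]]
    if (!is.null(got)) return(got)
    out <- numeric(0)
    if (i < L) {
      for (i0 in i:(L - 1)) {
        for (k in 1:M) {
          out <- c(out,
                   lbsc + mesc[k, codes[i0 + 1]] + rec(k, "M", i0 + 1))
        }
      }
    }
    hits_memo[[key]] <- out
    out
  }
  if (local) {
    if (L == 0) return(numeric(0))
    hits_after(0)
  } else {
    scores <- numeric(0)
    for (i0 in 0:L) {
      if (i0 < L) {
        scores <- c(scores,
                    tr[1, "MM"] + mesc[1, codes[i0 + 1]] +
                      rec(1, "M", i0 + 1))
      }
      scores <- c(scores, tr[1, "MD"] + rec(1, "D", i0))
    }
    scores
  }
}

oracle_hmm_scores <- function(hmm, seq, mode = "local") {
  vit <- oracle_hmm_paths(hmm, seq, mode, multihit = FALSE)
  fwd <- if (mode == "local") {
    oracle_hmm_paths(hmm, seq, mode, multihit = TRUE)
  } else {
    vit
  }
  neg <- covmod:::NEG_INF_SCORE
  list(viterbi = if (length(vit)) max(vit) else neg,
       forward = if (length(fwd)) covmod:::log2sumexp(fwd) else neg)
}
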