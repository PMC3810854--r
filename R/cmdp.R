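# CM dynamic programming: CYK and Inside scoring, HMM-derived bands,
# parse trees and their conversion to structural alignments.

STATE_CODE <- c(S = 0L, MP = 1L, ML = 2L, MR = 3L, D = 4L,
                IL = 5L, IR = 6L, B = 7L, E = 8L)

# 15 x 4 membership weight matrix for IUPAC codes (uniform over the set).
iupac_weights <- function() {
  w <- matrix(0, nrow = length(IUPAC_CODES), ncol = 4,
              dimnames = list(IUPAC_CODES, RNA_BASES))
  for (k in seq_along(IUPAC_CODES)) {
    set <- IUPAC_SETS[[k]]
    w[k, match(set, RNA_BASES)] <- 1 / length(set)
  }
  w
}

# Flatten a covariance model into the arrays the C++ engine consumes.
# Degenerate-code emission scores are the log2 of the mean likelihood
# ratio over the code's compatible bases (marginal scoring).
#
# Local begins are uniform over the begin-target states, so the default
# begin penalty is log2(1/n_targets); local ends pay log2(p_end) with
# p_end = 0.05. (Zero-cost begins/ends remain available for property
# checks, but as defaults they let the summed local score of random
# sequence swamp genuine hits.)
cm_pack <- function(cm, local = FALSE, begin_sc = NULL, end_sc = NULL) {
  default_pens <- is.null(begin_sc) && is.null(end_sc)
  key <- if (local) "pack_local" else "pack_glocal"
  cached <- attr(cm, key)
  if (default_pens && !is.null(cached)) return(cached)
  states <- cm$states
  ns <- length(states)
  stype <- unname(STATE_CODE[vapply(states, `[[`, "", "type")])
  child <- unlist(lapply(states, `[[`, "children"), use.names = FALSE)
  nchild <- vapply(states, function(s) length(s$children), 0L)
  child_off <- c(0L, cumsum(nchild))
  tsc <- unlist(lapply(states, `[[`, "tsc"), use.names = FALSE)
  stopifnot(length(tsc) == length(child))

  W15 <- iupac_weights()
  esc1 <- matrix(NEG_INF_SCORE, ns, 15)
  esc2 <- matrix(NEG_INF_SCORE, ns, 225)
  for (v in seq_len(ns)) {
    ty <- states[[v]]$type
    if (ty %in% c("ML", "MR", "IL", "IR")) {
      esc1[v, ] <- log2(as.numeric(W15 %*% 2^states[[v]]$esc))
    } else if (ty == "MP") {
      P <- matrix(2^states[[v]]$esc, 4, 4, byrow = TRUE)  # rows = left base
      M15 <- W15 %*% P %*% t(W15)
      esc2[v, ] <- log2(as.numeric(t(M15)))  # row-major: (c1, c2)
    }
  }
  begin_states <- which(stype %in% STATE_CODE[c("MP", "ML", "MR", "B")]) - 1L
  begin_sc <- begin_sc %||% log2(1 / max(1L, length(begin_states)))
  end_sc <- end_sc %||% log2(0.05)
  pack <- list(stype = as.integer(stype), child = as.integer(child - 1L),
               child_off = as.integer(child_off), tsc = as.numeric(tsc),
               esc1 = esc1, esc2 = esc2,
               begin_states = as.integer(begin_states),
               begin_sc = begin_sc, end_sc = end_sc, local = local)
  if (default_pens) attr(cm, key) <- pack  # caches only in this copy
  pack
}

full_bands <- function(ns, L) {
  list(imin = rep(1L, ns), imax = rep(L + 1L, ns),
       jmin = rep(0L, ns), jmax = rep(L, ns))
}

cm_engine <- function(cm, seq, mode, inside, scan, bands = NULL,
                      exact = TRUE, traceback = FALSE) {
  local <- match.arg(mode, c("glocal", "local")) == "local"
  pack <- cm_pack(cm, local = local)
  codes <- if (is.character(seq)) encode_seq(seq) else as.integer(seq)
  L <- length(codes)
  if (L == 0L) stop("empty sequence cannot be scored against a CM")
  b <- bands %||% full_bands(length(cm$states), L)
  cm_engine_cpp(codes, pack, inside = inside, scan = scan, exact = exact,
                ilo = as.integer(b$imin), ihi = as.integer(b$imax),
                jlo = as.integer(b$jmin), jhi = as.integer(b$jmax),
                traceback = traceback)
}

#' Optimal (CYK) parse of a sequence against a covariance model
#'
#' Computes the maximum log-odds parse. In `scan` mode the best-scoring
#' subsequence is reported (used by the search pipeline); otherwise the
#' whole sequence must be parsed (used by alignment).
#'
#' @param cm a `covariance_model`.
#' @param seq RNA string (IUPAC degeneracy allowed).
#' @param mode `"glocal"` (full model) or `"local"` (internal entry/exit).
#' @param bands optional `band_set` from [derive_bands()].
#' @param scan report the best subsequence instead of parsing all of `seq`.
#' @return list: `score` (bits), `tree` (a `parse_tree`), `i`, `j` (best
#'   interval in scan mode), `cells` (DP cells evaluated).
#' @export
cyk <- function(cm, seq, mode = "glocal", bands = NULL, scan = FALSE) {
  res <- cm_engine(cm, seq, mode, inside = FALSE, scan = scan,
                   bands = bands, traceback = TRUE)
  tree <- NULL
  if (!is.null(res$tree)) {
    tree <- structure(res$tree, class = "parse_tree",
                      dimnames = list(NULL, c("state", "i", "j")))
  }
  list(score = res$score, tree = tree, i = res$i, j = res$j,
       cells = res$cells)
}

#' Inside (summed) score of a sequence against a covariance model
#'
#' Log-sum of all parse scores; always at least the CYK score.
#'
#' @inheritParams cyk
#' @param exact use exact log-sum arithmetic (default); `FALSE` selects the
#'   table-driven approximation used by the scanning pipeline.
#' @return list: `score` (bits), `cells`.
#' @export
inside <- function(cm, seq, mode = "glocal", bands = NULL, scan = FALSE,
                   exact = TRUE) {
  res <- cm_engine(cm, seq, mode, inside = TRUE, scan = scan,
                   bands = bands, exact = exact)
  list(score = res$score, cells = res$cells)
}

#' Banded CYK
#'
#' Same recurrences as [cyk()] restricted to the banded cells. With bands
#' that exclude every complete parse the score is the -inf sentinel
#' (-1e30) and the tree is `NULL`.
#'
#' @inheritParams cyk
#' @param bands a `band_set` from [derive_bands()].
#' @export
banded_cyk <- function(cm, seq, bands, mode = "glocal", scan = FALSE) {
  cyk(cm, seq, mode = mode, bands = bands, scan = scan)
}

#' Banded Inside
#' @inheritParams inside
#' @param bands a `band_set` from [derive_bands()].
#' @export
banded_inside <- function(cm, seq, bands, mode = "glocal", scan = FALSE,
                          exact = TRUE) {
  inside(cm, seq, mode = mode, bands = bands, scan = scan, exact = exact)
}

# Consensus-column span [lcol, rcol] of the subtree rooted at each node.
node_column_spans <- function(cm) {
  n <- length(cm$nodes)
  lcol <- rep(NA_integer_, n)
  rcol <- rep(NA_integer_, n)
  # children always have larger node index: sweep bottom-up
  for (ni in rev(seq_len(n))) {
    nd <- cm$nodes[[ni]]
    cols <- c(nd$left, nd$right)
    for (ci in nd$children) cols <- c(cols, lcol[ci], rcol[ci])
    cols <- cols[!is.na(cols)]
    if (length(cols)) {
      lcol[ni] <- min(cols)
      rcol[ni] <- max(cols)
    }
  }
  list(lcol = lcol, rcol = rcol)
}

#' Derive position bands for CM states from an HMM posterior alignment
#'
#' Runs Forward-Backward on the filter HMM, finds for each consensus
#' column the smallest position interval holding all but `tail_p` of that
#' column's match posterior mass, and maps column intervals to start/end
#' position bounds for every CM state via the consensus columns its node
#' subtree spans. A column with (numerically) no posterior mass yields an
#' unconstrained band; `tail_p <= 1e-12` yields full bands for all states.
#'
#' @param hmm the CM's derived filter HMM (see [cm_to_hmm()]).
#' @param cm the covariance model.
#' @param seq target sequence (string).
#' @param tail_p posterior tail probability excluded per column side.
#' @param mode HMM alignment mode; match the downstream CM mode.
#' @param pad extra positions added on each side of every bound.
#' @return a `band_set`: integer vectors `imin`, `imax`, `jmin`, `jmax`
#'   (one entry per state), plus `column_bands` (2 x clen).
#' @export
derive_bands <- function(hmm, cm, seq, tail_p = 1e-7, mode = "local",
                         pad = 4L) {
  codes <- if (is.character(seq)) encode_seq(seq) else as.integer(seq)
  L <- length(codes)
  ns <- length(cm$states)
  clen <- cm$clen
  if (tail_p <= 1e-12) {
    fb <- full_bands(ns, L)
    fb$column_bands <- rbind(lo = rep(1L, clen), hi = rep(L, clen))
    return(structure(fb, class = "band_set"))
  }
  post <- hmm_posterior(hmm, codes, mode = mode)
  pm <- post$match_posterior  # M x L
  lo <- integer(clen)
  hi <- integer(clen)
  for (k in seq_len(clen)) {
    m <- pm[k, ]
    tot <- sum(m)
    if (tot < 1e-12) {
      lo[k] <- 1L
      hi[k] <- L
    } else {
      cum <- cumsum(m) / tot
      lo[k] <- which(cum > tail_p / 2)[1]
      hi[k] <- L + 1L - which(rev(cumsum(rev(m)) / tot) > tail_p / 2)[1]
      if (hi[k] < lo[k]) hi[k] <- lo[k]
    }
  }
  spans <- node_column_spans(cm)
  imin <- rep(1L, ns); imax <- rep(L + 1L, ns)
  jmin <- rep(0L, ns); jmax <- rep(L, ns)
  for (v in seq_len(ns)) {
    ni <- cm$states[[v]]$node
    if (cm$nodes[[ni]]$type %in% c("ROOT", "END")) next  # unconstrained
    lc <- spans$lcol[ni]; rc <- spans$rcol[ni]
    if (is.na(lc)) next
    # union of adjacent column bands guards single deleted columns
    lc2 <- min(lc + 1L, clen); rc2 <- max(rc - 1L, 1L)
    imin[v] <- max(1L, min(lo[lc], lo[lc2]) - pad)
    imax[v] <- min(L + 1L, max(hi[lc], hi[lc2]) + pad + 1L)
    jmin[v] <- max(0L, min(lo[rc], lo[rc2]) - pad - 1L)
    jmax[v] <- min(L, max(hi[rc], hi[rc2]) + pad)
  }
  structure(list(imin = imin, imax = imax, jmin = jmin, jmax = jmax,
                 column_bands = rbind(lo = lo, hi = hi)),
            class = "band_set")
}

# ---------------------------------------------------------------- parse trees

#' Re-score a parse tree
#'
#' Sums the emission and transition scores along the tree; must reproduce
#' the CYK score that produced it.
#'
#' @param cm the model.
#' @param tree a `parse_tree` (matrix of state/i/j triples, preorder;
#'   state 0 denotes the local-end EL sink).
#' @param seq the parsed sequence.
#' @param mode scoring mode the tree was produced under.
#' @return score in bits.
#' @export
parse_tree_score <- function(cm, tree, seq, mode = "glocal") {
  local <- match.arg(mode, c("glocal", "local")) == "local"
  pack <- cm_pack(cm, local = local)
  codes <- if (is.character(seq)) encode_seq(seq) else as.integer(seq)
  states <- cm$states
  n <- nrow(tree)
  total <- 0
  # parse the preorder list recursively; returns next row index
  walk <- function(pos) {
    v <- tree[pos, "state"]; i <- tree[pos, "i"]; j <- tree[pos, "j"]
    if (v == 0L) return(pos + 1L)  # EL emits its run at the null
    ty <- states[[v]]$type
    if (ty == "E") return(pos + 1L)
    if (ty == "MP") {
      total <<- total + pack$esc2[v, (codes[i] - 1L) * 15L + codes[j]]
    } else if (ty %in% c("ML", "IL")) {
      total <<- total + pack$esc1[v, codes[i]]
    } else if (ty %in% c("MR", "IR")) {
      total <<- total + pack$esc1[v, codes[j]]
    }
    if (ty == "B") {
      pos <- walk(pos + 1L)  # B -> children carry no transition cost
      return(walk(pos))
    }
    nxt_v <- tree[pos + 1L, "state"]
    if (nxt_v == 0L) {
      total <<- total + pack$end_sc
    } else {
      k <- match(nxt_v, states[[v]]$children)
      if (is.na(k)) {
        if (v == 1L && local && (nxt_v - 1L) %in% pack$begin_states) {
          total <<- total + pack$begin_sc
        } else {
          stop("tree/model mismatch at row ", pos)
        }
      } else {
        total <<- total + states[[v]]$tsc[k]
      }
    }
    walk(pos + 1L)
  }
  end <- walk(1L)
  stopifnot(end == n + 1L)
  total
}

# residue count of a parse tree (emission accounting invariant)
parse_tree_residues <- function(cm, tree) {
  states <- cm$states
  n <- 0L
  for (r in seq_len(nrow(tree))) {
    v <- tree[r, "state"]
    if (v == 0L) {  # EL run
      n <- n + max(0L, tree[r, "j"] - tree[r, "i"] + 1L)
    } else {
      ty <- states[[v]]$type
      n <- n + switch(ty, MP = 2L, ML = 1L, MR = 1L, IL = 1L, IR = 1L, 0L)
    }
  }
  n
}

#' Merge parse trees into a structure-annotated multiple alignment
#'
#' Match states map to shared consensus columns; insert-state emissions go
#' into per-state insert blocks (lowercase, left-flushed, `.`-padded),
#' placed at the inter-column slot where the state emits. The consensus
#' structure line is rebuilt from the model's MATP columns.
#'
#' @param cm the model.
#' @param trees list of `parse_tree`s (glocal; no local ends).
#' @param seqs character vector of the parsed sequences, same order.
#' @param names sequence identifiers.
#' @return a [structured_alignment()].
#' @export
parsetree_to_alignment <- function(cm, trees, seqs, names = NULL) {
  stopifnot(length(trees) == length(seqs))
  names <- names %||% sprintf("seq%d", seq_along(seqs))
  states <- cm$states
  stype_v <- vapply(states, `[[`, "", "type")
  clen <- cm$clen
  nseq <- length(seqs)

  # column of each match emission; insert residues keyed by state
  match_res <- matrix(NA_character_, nseq, clen)
  ins_res <- vector("list", nseq)
  for (s in seq_len(nseq)) {
    chars <- strsplit(normalize_rna(seqs[[s]]), "")[[1]]
    if (parse_tree_residues(cm, trees[[s]]) != length(chars)) {
      stop("tree/sequence length mismatch for '", names[s], "'")
    }
    ins_res[[s]] <- list()
    tr <- trees[[s]]
    for (r in seq_len(nrow(tr))) {
      v <- tr[r, "state"]
      if (v == 0L) stop("local-end parses cannot be merged into an MSA")
      ty <- stype_v[v]
      nd <- cm$nodes[[states[[v]]$node]]
      i <- tr[r, "i"]; j <- tr[r, "j"]
      if (ty == "MP") {
        match_res[s, nd$left] <- chars[i]
        match_res[s, nd$right] <- chars[j]
      } else if (ty == "ML") {
        match_res[s, nd$left %||% nd$right] <- chars[i]
      } else if (ty == "MR") {
        match_res[s, nd$right] <- chars[j]
      } else if (ty %in% c("IL", "IR")) {
        key <- as.character(v)
        ch <- if (ty == "IL") chars[i] else chars[j]
        ins_res[[s]][[key]] <- c(ins_res[[s]][[key]], ch)
      }
    }
  }

  # insert block layout: slot (inter-column gap) per insert state, ordered
  # inner-node-first within a slot (emission order), IL before IR
  ins_states <- which(stype_v %in% c("IL", "IR"))
  slot_of <- integer(0)
  for (v in ins_states) {
    nd <- cm$nodes[[states[[v]]$node]]
    spans <- node_column_spans(cm)
    g <- switch(nd$type,
      ROOT = if (stype_v[v] == "IL") 0L else clen,
      MATP = if (stype_v[v] == "IL") nd$left else nd$right - 1L,
      MATL = nd$left,
      MATR = nd$right - 1L,
      BEGR = {
        ci <- nd$children[1]
        lf <- spans$lcol[ci]
        if (is.na(lf)) 0L else lf - 1L
      },
      0L)
    slot_of[as.character(v)] <- g
  }
  used <- ins_states[vapply(ins_states, function(v) {
    any(vapply(ins_res, function(x) !is.null(x[[as.character(v)]]), TRUE))
  }, TRUE)]
  node_of <- vapply(used, function(v) states[[v]]$node, 0L)
  ord <- used[order(slot_of[as.character(used)], -node_of, used)]

  widths <- vapply(ord, function(v) {
    max(vapply(ins_res, function(x) length(x[[as.character(v)]] %||%
                                             character(0)), 0L))
  }, 0L)

  build_row <- function(s) {
    out <- character(0)
    ss <- character(0)
    cons_pt <- parse_wuss(cm$cons_ss)
    for (k in 0:clen) {
      for (q in seq_along(ord)) {
        if (slot_of[as.character(ord[q])] != k) next
        resid <- tolower(ins_res[[s]][[as.character(ord[q])]] %||%
                           character(0))
        block <- c(resid, rep(".", widths[q] - length(resid)))
        out <- c(out, block)
        ss <- c(ss, rep(".", widths[q]))
      }
      if (k < clen) {
        ch <- match_res[s, k + 1L]
        out <- c(out, if (is.na(ch)) "-" else ch)
        ss <- c(ss, substr(cm$cons_ss, k + 1L, k + 1L))
      }
    }
    list(row = paste(out, collapse = ""), ss = paste(ss, collapse = ""))
  }
  built <- lapply(seq_len(nseq), build_row)
  structured_alignment(names = names,
                       rows = vapply(built, `[[`, "", "row"),
                       ss_cons = built[[1]]$ss,
                       id = cm$name)
}
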