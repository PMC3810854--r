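# Covariance-model construction from structure-annotated alignments.
#
# A CM is a profile SCFG laid out along a guide tree derived from the
# consensus secondary structure: MATP nodes model base-paired column pairs,
# MATL/MATR model unpaired columns, BIF/BEGL/BEGR model multiloop
# branching. Nodes expand into states (MP/ML/MR emit, D deletes, IL/IR
# insert, S/B/E are structural) whose emission and transition log-odds
# parameters are estimated from the alignment.

NODE_TYPES  <- c("ROOT", "MATP", "MATL", "MATR", "BIF", "BEGL", "BEGR", "END")
STATE_TYPES <- c("S", "MP", "ML", "MR", "D", "IL", "IR", "B", "E")

# node type -> states, in fixed within-node order
NODE_STATE_MAP <- list(
  ROOT = c("S", "IL", "IR"),
  MATP = c("MP", "ML", "MR", "D", "IL", "IR"),
  MATL = c("ML", "D", "IL"),
  MATR = c("MR", "D", "IR"),
  BIF  = "B",
  BEGL = "S",
  BEGR = c("S", "IL"),
  END  = "E"
)

SPLIT_STATES <- c("S", "MP", "ML", "MR", "D", "B", "E")

#' Select consensus (match) columns of an alignment
#'
#' A column is consensus iff its fraction of non-gap residues is at least
#' `gap_threshold`. A paired column whose partner is dropped is retained as
#' an unpaired consensus column (the pairing is severed downstream).
#'
#' @param aln a [structured_alignment()].
#' @param gap_threshold occupancy fraction in (0, 1].
#' @return logical vector, one entry per alignment column.
#' @export
select_consensus_columns <- function(aln, gap_threshold = 0.5) {
  stopifnot(gap_threshold > 0, gap_threshold <= 1)
  m <- aln_char_matrix(aln$rows)
  occ <- colMeans(!is_gap_char(m))
  occ >= gap_threshold
}

#' Build the guide tree for a nested consensus structure
#'
#' Deterministic construction, walking each interval inward from the
#' outside: a base pair spanning the interval gives MATP; an unpaired left
#' end gives MATL (preferred over MATR when both ends are unpaired); an
#' unpaired right end under a paired left end gives MATR; a left end paired
#' inside the interval gives BIF with BEGL/BEGR children. Every branch
#' terminates in END.
#'
#' @param pt a `pair_table` over consensus columns (nested).
#' @return a `guide_tree`: list of nodes with fields `type`, `left`,
#'   `right` (consensus-column ordinals or NA), `children`, `parent`.
#' @export
build_guide_tree <- function(pt) {
  validate_pair_table(pt)
  p <- pt$partner
  nodes <- list()
  add_node <- function(type, left = NA_integer_, right = NA_integer_, parent = NA_integer_) {
    nodes[[length(nodes) + 1L]] <<- list(
      type = type, left = left, right = right,
      children = integer(0), parent = parent
    )
    idx <- length(nodes)
    if (!is.na(parent)) {
      nodes[[parent]]$children <<- c(nodes[[parent]]$children, idx)
    }
    idx
  }
  recurse <- function(i, j, parent) {
    if (i > j) {
      add_node("END", parent = parent)
      return(invisible(NULL))
    }
    if (p[i] == 0L) {
      idx <- add_node("MATL", left = i, parent = parent)
      recurse(i + 1L, j, idx)
    } else if (p[j] == 0L) {
      idx <- add_node("MATR", right = j, parent = parent)
      recurse(i, j - 1L, idx)
    } else if (p[i] == j) {
      idx <- add_node("MATP", left = i, right = j, parent = parent)
      recurse(i + 1L, j - 1L, idx)
    } else {
      # i pairs inside [i, j]: bifurcate at its partner
      k <- p[i]
      stopifnot(k > i, k < j)
      b <- add_node("BIF", parent = parent)
      bl <- add_node("BEGL", parent = b)
      recurse(i, k, bl)
      br <- add_node("BEGR", parent = b)
      recurse(k + 1L, j, br)
    }
    invisible(NULL)
  }
  root <- add_node("ROOT")
  recurse(1L, pt$length, root)
  structure(list(nodes = nodes, clen = pt$length), class = "guide_tree")
}

#' @export
print.guide_tree <- function(x, ...) {
  tab <- table(vapply(x$nodes, `[[`, "", "type"))
  cat("guide_tree:", length(x$nodes), "nodes over", x$clen, "columns (",
      paste(names(tab), tab, sep = ":", collapse = " "), ")\n")
  invisible(x)
}

# Emission dimension per state type.
state_emit_dim <- function(type) {
  switch(type, MP = 16L, ML = 4L, MR = 4L, IL = 4L, IR = 4L, 0L)
}

#' Expand a guide tree into the CM state layout
#'
#' Each node contributes a fixed set of states; transitions connect a
#' node's split and insert states to its own later inserts and to the next
#' node's split states. BIF's B state connects to its BEGL and BEGR start
#' states (probability one each, not free parameters).
#'
#' @param tree a `guide_tree`.
#' @return list with `states` (type, node, children state indices) and
#'   `node_states` (state indices per node).
#' @export
layout_states <- function(tree) {
  nodes <- tree$nodes
  states <- list()
  node_states <- vector("list", length(nodes))
  for (ni in seq_along(nodes)) {
    for (st in NODE_STATE_MAP[[nodes[[ni]]$type]]) {
      states[[length(states) + 1L]] <- list(type = st, node = ni,
                                            children = integer(0))
      node_states[[ni]] <- c(node_states[[ni]], length(states))
    }
  }
  stype <- vapply(states, `[[`, "", "type")
  # split states (including S) of each node, and its insert states
  splits_of <- function(ni) node_states[[ni]][stype[node_states[[ni]]] %in% SPLIT_STATES]
  inserts_of <- function(ni) node_states[[ni]][stype[node_states[[ni]]] %in% c("IL", "IR")]
  for (ni in seq_along(nodes)) {
    nd <- nodes[[ni]]
    if (nd$type == "END") next
    if (nd$type == "BIF") {
      b <- node_states[[ni]][1]
      kids <- vapply(nd$children, function(ci) node_states[[ci]][1], 0L)
      states[[b]]$children <- kids
      next
    }
    nxt <- nd$children[1]
    nxt_splits <- splits_of(nxt)
    ins <- inserts_of(ni)
    for (si in node_states[[ni]]) {
      ty <- stype[si]
      if (ty %in% c("S", "MP", "ML", "MR", "D")) {
        states[[si]]$children <- c(ins, nxt_splits)
      } else if (ty == "IL") {
        states[[si]]$children <- c(ins[ins >= si], nxt_splits)
      } else if (ty == "IR") {
        states[[si]]$children <- c(si, nxt_splits)
      }
    }
  }
  list(states = states, node_states = node_states)
}

# Maps every non-consensus alignment-column "gap slot" to the insert state
# that emits there. Gap slot g (0..clen) is the run of non-consensus
# columns between consensus ordinals g and g+1. Nodes claim slots in
# preorder (outer nodes win ties); an insert state whose slot is already
# claimed simply receives no observed counts.
insert_slot_map <- function(tree, layout) {
  nodes <- tree$nodes
  stype <- vapply(layout$states, `[[`, "", "type")
  clen <- tree$clen
  claim <- rep(NA_integer_, clen + 1L)  # slot g stored at index g+1
  claim_slot <- function(g, state) {
    if (g >= 0 && g <= clen && is.na(claim[g + 1L])) claim[g + 1L] <<- state
  }
  state_of <- function(ni, ty) {
    cand <- layout$node_states[[ni]]
    cand[stype[cand] == ty][1]
  }
  subtree_left <- function(ni) {
    # leftmost consensus ordinal covered by the subtree rooted at ni
    repeat {
      nd <- nodes[[ni]]
      if (!is.na(nd$left)) return(nd$left)
      if (!is.na(nd$right)) return(nd$right)  # MATR-only chain
      if (length(nd$children) == 0L) return(NA_integer_)
      ni <- nd$children[1]
    }
  }
  for (ni in seq_along(nodes)) {
    nd <- nodes[[ni]]
    switch(nd$type,
      ROOT = {
        claim_slot(0L, state_of(ni, "IL"))
        claim_slot(clen, state_of(ni, "IR"))
      },
      MATP = {
        claim_slot(nd$left, state_of(ni, "IL"))
        claim_slot(nd$right - 1L, state_of(ni, "IR"))
      },
      MATL = claim_slot(nd$left, state_of(ni, "IL")),
      MATR = claim_slot(nd$right - 1L, state_of(ni, "IR")),
      BEGR = {
        lft <- subtree_left(nd$children[1])
        if (!is.na(lft)) claim_slot(lft - 1L, state_of(ni, "IL"))
      }
    )
  }
  claim
}

# Fractional count increment for a possibly-degenerate residue.
residue_count_vec <- function(ch) {
  set <- IUPAC_SETS[[ch]]
  if (is.null(set)) stop("illegal residue '", ch, "' in alignment")
  v <- numeric(4)
  v[match(set, RNA_BASES)] <- 1 / length(set)
  v
}

#' Estimate CM probabilities from an alignment and convert to log-odds
#'
#' Each alignment row is traced through the guide tree: residues in match
#' columns feed match-state emission counts, gaps feed delete states,
#' residues in non-consensus columns feed the owning insert state, and the
#' induced state path feeds transition counts. Symmetric Laplace
#' pseudocounts are added, distributions normalized, and scores computed in
#' bits against the null model (rounded to 5 decimals, the model-file
#' precision). Insert emissions are fixed at the null (score 0), so inserts
#' are penalized through transitions only.
#'
#' @param aln a [structured_alignment()].
#' @param tree guide tree over the consensus columns.
#' @param layout state layout from [layout_states()].
#' @param cons_mask logical consensus-column mask over alignment columns.
#' @param pseudocount Laplace pseudocount per cell (default 0.5).
#' @param null background base frequencies (default uniform).
#' @param name model name.
#' @return a `covariance_model`.
#' @export
parameterize <- function(aln, tree, layout, cons_mask,
                         pseudocount = 0.5, null = rep(0.25, 4),
                         name = aln$id %||% "query") {
  states <- layout$states
  stype <- vapply(states, `[[`, "", "type")
  nodes <- tree$nodes
  clen <- tree$clen
  cons_idx <- which(cons_mask)
  stopifnot(length(cons_idx) == clen)
  stopifnot(abs(sum(null) - 1) < 1e-9)

  # alignment columns per gap slot
  slot_cols <- vector("list", clen + 1L)
  bounds <- c(0L, cons_idx, nchar(aln$ss_cons) + 1L)
  noncons <- which(!cons_mask)
  for (g in 0:clen) {
    slot_cols[[g + 1L]] <- noncons[noncons > bounds[g + 1L] & noncons < bounds[g + 2L]]
  }
  slot_state <- insert_slot_map(tree, layout)

  ns <- length(states)
  ecounts <- lapply(states, function(s) numeric(state_emit_dim(s$type)))
  tcounts <- lapply(states, function(s) numeric(length(s$children)))

  mat <- aln_char_matrix(aln$rows)
  keep_rows <- rowSums(!is_gap_char(mat)) > 0
  if (!all(keep_rows)) {
    warning("excluding ", sum(!keep_rows), " all-gap sequence(s)")
  }

  add_trans <- function(from, to) {
    k <- match(to, states[[from]]$children)
    stopifnot(!is.na(k))
    tcounts[[from]][k] <<- tcounts[[from]][k] + 1
  }

  for (r in which(keep_rows)) {
    row <- mat[r, ]
    res <- !is_gap_char(row)
    # state visited per node for this row, then insert visits; recursion
    # carries the current source state down each branch
    trace <- function(ni, src) {
      nd <- nodes[[ni]]
      sts <- layout$node_states[[ni]]
      get_state <- function(ty) sts[stype[sts] == ty][1]
      cur <- src
      if (nd$type == "BIF") {
        b <- sts[1]
        if (!is.na(cur)) add_trans(cur, b)
        trace(nd$children[1], NA_integer_)  # B -> BEGL S is fixed
        trace(nd$children[2], NA_integer_)
        return(invisible(NULL))
      }
      if (nd$type == "END") {
        if (!is.na(cur)) add_trans(cur, sts[1])
        return(invisible(NULL))
      }
      split <- switch(nd$type,
        ROOT = , BEGL = , BEGR = get_state("S"),
        MATL = {
          c1 <- cons_idx[nd$left]
          if (res[c1]) {
            s <- get_state("ML")
            ecounts[[s]] <<- ecounts[[s]] + residue_count_vec(row[c1])
            s
          } else get_state("D")
        },
        MATR = {
          c2 <- cons_idx[nd$right]
          if (res[c2]) {
            s <- get_state("MR")
            ecounts[[s]] <<- ecounts[[s]] + residue_count_vec(row[c2])
            s
          } else get_state("D")
        },
        MATP = {
          c1 <- cons_idx[nd$left]; c2 <- cons_idx[nd$right]
          if (res[c1] && res[c2]) {
            s <- get_state("MP")
            vl <- residue_count_vec(row[c1]); vr <- residue_count_vec(row[c2])
            # 16-vector layout: left base major, (a-1)*4 + b
            ecounts[[s]] <<- ecounts[[s]] + as.numeric(t(outer(vl, vr)))
            s
          } else if (res[c1]) {
            s <- get_state("ML")
            ecounts[[s]] <<- ecounts[[s]] + residue_count_vec(row[c1])
            s
          } else if (res[c2]) {
            s <- get_state("MR")
            ecounts[[s]] <<- ecounts[[s]] + residue_count_vec(row[c2])
            s
          } else get_state("D")
        }
      )
      if (!is.na(cur) && nd$type != "ROOT") add_trans(cur, split)
      cur <- split
      for (ty in c("IL", "IR")) {
        ist <- sts[stype[sts] == ty]
        if (length(ist) == 0L) next
        owned <- which(slot_state == ist) - 1L  # slots owned by this insert
        k <- 0L
        for (g in owned) k <- k + sum(res[slot_cols[[g + 1L]]])
        if (k > 0L) {
          add_trans(cur, ist)
          if (k > 1L) for (q in seq_len(k - 1L)) add_trans(ist, ist)
          cur <- ist
        }
      }
      if (length(nd$children) > 0L) trace(nd$children[1], cur)
      invisible(NULL)
    }
    trace(1L, NA_integer_)
  }

  # counts -> probabilities -> bits
  null16 <- as.numeric(outer(null, null))
  final_states <- vector("list", ns)
  for (si in seq_len(ns)) {
    s <- states[[si]]
    tsc <- numeric(length(s$children))
    if (s$type == "B") {
      tsc <- c(0, 0)  # both branches taken with probability 1
    } else if (length(s$children) > 0L) {
      p <- tcounts[[si]] + pseudocount
      p <- p / sum(p)
      stopifnot(abs(sum(p) - 1) < 1e-9)
      tsc <- round(log2(p), 5)
    }
    ed <- state_emit_dim(s$type)
    esc <- numeric(ed)
    if (ed > 0L) {
      if (s$type %in% c("IL", "IR")) {
        esc <- rep(0, 4)  # insert emissions fixed to the null
      } else {
        p <- ecounts[[si]] + pseudocount
        p <- p / sum(p)
        stopifnot(abs(sum(p) - 1) < 1e-9)
        bg <- if (ed == 16L) null16 else null
        esc <- round(log2(p / bg), 5)
      }
    }
    final_states[[si]] <- list(type = s$type, node = s$node,
                               children = s$children, tsc = tsc, esc = esc)
  }

  cons_pt <- structure(
    list(length = clen,
         partner = consensus_partner_from_tree(tree)),
    class = "pair_table"
  )
  structure(
    list(name = name, clen = clen, nodes = nodes,
         node_states = layout$node_states, states = final_states,
         null = null, cons_ss = pair_table_to_wuss(cons_pt),
         calibration = list()),
    class = "covariance_model"
  )
}

# Reconstructs the consensus pairing actually modeled (MATP columns).
consensus_partner_from_tree <- function(tree) {
  partner <- integer(tree$clen)
  for (nd in tree$nodes) {
    if (nd$type == "MATP") {
      partner[nd$left] <- nd$right
      partner[nd$right] <- nd$left
    }
  }
  partner
}

#' Build a covariance model from a structure-annotated alignment
#'
#' Convenience front-end: consensus-column selection, guide-tree
#' construction, state layout and parameterization in one call.
#'
#' @param aln a [structured_alignment()].
#' @param gap_threshold consensus-column occupancy threshold.
#' @param pseudocount Laplace pseudocount.
#' @param null background base frequencies.
#' @param name model name.
#' @return a `covariance_model`.
#' @examples
#' aln <- structured_alignment(c("s1", "s2"),
#'                             c("GGAAACC", "GGUUUCC"),
#'                             "<<...>>")
#' cm <- cm_build(aln, name = "toy")
#' cm
#' @export
cm_build <- function(aln, gap_threshold = 0.5, pseudocount = 0.5,
                     null = rep(0.25, 4), name = aln$id %||% "query") {
  validate_structured_alignment(aln)
  mask <- select_consensus_columns(aln, gap_threshold)
  if (!any(mask)) stop("no consensus columns at this gap threshold")
  pt <- parse_wuss(aln$ss_cons)
  cons_pt <- subset_pair_table(pt, mask)
  tree <- build_guide_tree(cons_pt)
  layout <- layout_states(tree)
  parameterize(aln, tree, layout, mask, pseudocount = pseudocount,
               null = null, name = name)
}

#' @export
print.covariance_model <- function(x, ...) {
  cat("covariance_model '", x$name, "': ", x$clen, " consensus columns, ",
      length(x$states), " states, ", length(x$nodes), " nodes; ",
      if (length(x$calibration)) "calibrated" else "not calibrated",
      "\n", sep = "")
  invisible(x)
}
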