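# Sequence-only profile HMM derived from a CM: the filter stages of the
# search pipeline and the source of alignment bands.

# Declared default transition probabilities used where no direct CM
# correspondence exists (see cm_to_hmm).
HMM_DEFAULT_TRANS <- list(
  M = c(MM = 0.94, MI = 0.04, MD = 0.02),
  I = c(IM = 0.50, II = 0.45, ID = 0.05),
  D = c(DM = 0.70, DI = 0.05, DD = 0.25),
  B = c(MM = 0.97, MI = 0.00, MD = 0.03)
)

TRANS_COLS <- c("MM", "MI", "MD", "IM", "II", "ID", "DM", "DI", "DD")

# implied emission probabilities of a state from its stored bit scores
implied_probs <- function(esc, null) {
  p <- null * 2^esc
  p / sum(p)
}

#' Derive the filter profile HMM from a covariance model
#'
#' Match state k emits with the CM's marginal emission distribution at
#' consensus column k (pair emissions marginalized over the partner).
#' Transitions are projected from the CM node's split/insert transitions
#' where the node consuming column k also leads directly to the node
#' consuming column k+1; elsewhere declared defaults apply. Any HMM-stage
#' calibrations stored on the CM are carried over.
#'
#' @param cm a `covariance_model`.
#' @return a `profile_hmm` with `M == cm$clen`.
#' @export
cm_to_hmm <- function(cm) {
  clen <- cm$clen
  states <- cm$states
  stype_v <- vapply(states, `[[`, "", "type")
  null <- cm$null
  null16 <- as.numeric(outer(null, null))

  # which node/state consumes each consensus column, and on which side
  col_node <- integer(clen)
  col_side <- character(clen)
  for (ni in seq_along(cm$nodes)) {
    nd <- cm$nodes[[ni]]
    if (!is.na(nd$left)) { col_node[nd$left] <- ni; col_side[nd$left] <- "L" }
    if (!is.na(nd$right) && nd$type %in% c("MATP", "MATR")) {
      col_node[nd$right] <- ni
      col_side[nd$right] <- "R"
    }
  }
  state_of <- function(ni, ty) {
    cand <- cm$node_states[[ni]]
    cand[stype_v[cand] == ty][1]
  }

  mesc <- matrix(0, clen, 4)
  for (k in seq_len(clen)) {
    ni <- col_node[k]
    nd <- cm$nodes[[ni]]
    if (nd$type == "MATP") {
      p16 <- implied_probs(states[[state_of(ni, "MP")]]$esc, null16)
      pm <- matrix(p16, 4, 4, byrow = TRUE)
      p <- if (col_side[k] == "L") rowSums(pm) else colSums(pm)
    } else {
      ty <- if (nd$type == "MATL") "ML" else "MR"
      p <- implied_probs(states[[state_of(ni, ty)]]$esc, null)
    }
    mesc[k, ] <- round(log2(p / null), 5)
  }

  # transitions: rows 0..M (row k = out of position k; row 0 = begin)
  trans <- matrix(NA_real_, clen + 1, 9, dimnames = list(NULL, TRANS_COLS))
  dflt <- function() c(HMM_DEFAULT_TRANS$M, HMM_DEFAULT_TRANS$I,
                       HMM_DEFAULT_TRANS$D)
  trans_probs_of <- function(v) {
    # implied transition probabilities out of state v
    implied <- 2^states[[v]]$tsc
    implied / sum(implied)
  }
  classify_next <- function(src_v, k) {
    # project transitions of src_v onto {emit k+1, delete k+1, insert}
    ni <- states[[src_v]]$node
    kids <- states[[src_v]]$children
    p <- trans_probs_of(src_v)
    out <- c(M = 0, I = 0, D = 0)
    dropped <- 0
    for (q in seq_along(kids)) {
      y <- kids[q]
      yty <- stype_v[y]
      ynode <- states[[y]]$node
      if (ynode == ni) {
        if (yty == "IL") out["I"] <- out["I"] + p[q] else dropped <- dropped + p[q]
      } else {
        ynd <- cm$nodes[[ynode]]
        consumes <- switch(ynd$type,
          MATL = , MATP = identical(ynd$left, k + 1L),
          FALSE)
        if (!consumes) return(NULL)  # no direct correspondence
        emits <- switch(yty, MP = TRUE, ML = TRUE, MR = FALSE, D = FALSE,
                        NULL)
        if (is.null(emits)) return(NULL)
        if (emits) out["M"] <- out["M"] + p[q] else out["D"] <- out["D"] + p[q]
      }
    }
    if (sum(out) <= 0) return(NULL)
    out / sum(out)
  }
  for (k in 0:clen) {
    if (k == clen) {
      trans[k + 1, ] <- c(1, 0, 0, 1, 0, 0, 1, 0, 0)  # forced exit to end
      next
    }
    proj <- NULL
    if (k >= 1) {
      ni <- col_node[k]
      nd <- cm$nodes[[ni]]
      if (col_side[k] == "L" && nd$type %in% c("MATL", "MATP")) {
        prim <- if (nd$type == "MATL") "ML" else "MP"
        pm <- classify_next(state_of(ni, prim), k)
        if (!is.null(pm)) {
          pd <- classify_next(state_of(ni, "D"), k)
          il <- state_of(ni, "IL")
          pins <- if (!is.na(il)) classify_next(il, k) else NULL
          proj <- unname(c(pm, pins %||% HMM_DEFAULT_TRANS$I,
                           pd %||% HMM_DEFAULT_TRANS$D))
        }
      }
      trans[k + 1, ] <- proj %||% unname(dflt())
    } else {
      trans[1, ] <- unname(c(HMM_DEFAULT_TRANS$B["MM"], 0,
                             HMM_DEFAULT_TRANS$B["MD"], 1, 0, 0, 1, 0, 0))
    }
  }
  # positions without an insert (k = 0 and k = M): I-row entries unused
  tsc <- ifelse(trans > 0, round(log2(trans), 5), NEG_INF_SCORE)
  # no insert state after the last match position
  tsc[clen + 1, c("MI", "II", "ID")] <- NEG_INF_SCORE
  tsc[1, c("MI", "IM", "II", "ID", "DM", "DI", "DD")] <-
    c(NEG_INF_SCORE, 0, NEG_INF_SCORE, NEG_INF_SCORE, 0, NEG_INF_SCORE,
      NEG_INF_SCORE)

  cal_keys <- grep("^hmm_", names(cm$calibration), value = TRUE)
  W15 <- iupac_weights()
  mesc15 <- t(apply(mesc, 1, function(e) log2(as.numeric(W15 %*% 2^e))))
  structure(list(name = cm$name, M = clen, mesc = mesc, trans = tsc,
                 mesc15 = mesc15, calibration = cm$calibration[cal_keys]),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm '", x$name, "': M = ", x$M,
      if (length(x$calibration)) " (calibrated)" else "", "\n", sep = "")
  invisible(x)
}

validate_profile_hmm <- function(hmm, tol = 1e-9) {
  stopifnot(hmm$M >= 1, nrow(hmm$mesc) == hmm$M)
  # emission rows: implied probabilities must renormalize
  for (k in seq_len(hmm$M)) {
    p <- 0.25 * 2^hmm$mesc[k, ]
    if (abs(sum(p) - 1) > 1e-4) stop("match emission row ", k,
                                     " does not normalize")
  }
  invisible(TRUE)
}

# expands 4-letter emission bit scores to the 15 IUPAC codes
mesc_codes <- function(hmm) {
  if (!is.null(hmm$mesc15)) return(hmm$mesc15)
  W15 <- iupac_weights()
  t(apply(hmm$mesc, 1, function(e) log2(as.numeric(W15 %*% 2^e))))
}

hmm_engine <- function(hmm, seq, mode, forward, posterior = FALSE,
                       exact = TRUE) {
  local <- match.arg(mode, c("local", "glocal")) == "local"
  codes <- if (is.character(seq)) encode_seq(seq) else as.integer(seq)
  hmm_engine_cpp(codes, hmm$M, mesc_codes(hmm), hmm$trans, local = local,
                 forward = forward, posterior = posterior, exact = exact)
}

#' Viterbi score of a sequence under the filter HMM
#'
#' Maximum log-odds alignment score in bits. Local mode allows entry at
#' any match position (uniform begin) and exit after any match; glocal
#' requires traversing the full model. Flanking residues are free (scored
#' by the null). An empty sequence scores the all-delete path in glocal
#' mode and -inf (the -1e30 sentinel) in local mode.
#'
#' @param hmm a `profile_hmm`.
#' @param seq RNA string or integer codes.
#' @param mode `"local"` or `"glocal"`.
#' @return score in bits.
#' @export
hmm_viterbi <- function(hmm, seq, mode = "local") {
  hmm_engine(hmm, seq, mode, forward = FALSE)$score
}

#' Forward score of a sequence under the filter HMM
#'
#' Log-sum over all alignments; always at least the Viterbi score.
#'
#' @inheritParams hmm_viterbi
#' @param exact exact log-sum (default) or the fast table approximation.
#' @export
hmm_forward <- function(hmm, seq, mode = "local", exact = TRUE) {
  hmm_engine(hmm, seq, mode, forward = TRUE, exact = exact)$score
}

# Forward-Backward posteriors: match_posterior (M x L) and per-position
# in-model probability (emitted by any match or insert state).
hmm_posterior <- function(hmm, seq, mode = "local") {
  hmm_engine(hmm, seq, mode, forward = TRUE, posterior = TRUE,
             exact = TRUE)
}

#' Tile a target sequence into windows and score each with the HMM
#'
#' Deterministic tiling: windows of `window_len` advancing by
#' `window_len - overlap`, with a final window snapped to the target end;
#' a target shorter than `window_len` gives one full-length window. On the
#' minus strand the reverse complement is scored and window coordinates
#' are reported in the forward coordinate system.
#'
#' @param hmm a `profile_hmm`.
#' @param target target sequence string.
#' @param window_len window length (> overlap).
#' @param overlap overlap between successive windows (>= 0).
#' @param strand `"+"` or `"-"`.
#' @param algo `"viterbi"` or `"forward"`; `mode` as in [hmm_viterbi()].
#' @param mode alignment mode.
#' @return data.frame: `start`, `end` (forward coordinates, 1-based
#'   inclusive), `score`.
#' @export
scan_windows <- function(hmm, target, window_len, overlap,
                         strand = "+", algo = "viterbi", mode = "local") {
  stopifnot(window_len > overlap, overlap >= 0)
  seq <- if (strand == "-") revcomp(target) else target
  codes <- encode_seq(seq)
  L <- length(codes)
  fwd <- match.arg(algo, c("viterbi", "forward")) == "forward"
  local <- match.arg(mode, c("local", "glocal")) == "local"
  m <- hmm_scan_cpp(codes, hmm$M, mesc_codes(hmm), hmm$trans,
                    local = local, forward = fwd,
                    window_len = window_len,
                    stride = window_len - overlap)
  starts <- as.integer(m[, 1])
  ends <- as.integer(m[, 2])
  sc <- m[, 3]
  if (strand == "-") {
    tmp <- L - ends + 1L
    ends <- L - starts + 1L
    starts <- tmp
  }
  data.frame(start = starts, end = ends, score = sc)
}

# Shared tiling rule (identical to the C++ scanner): fixed stride, final
# window snapped to the target end; short targets give one window.
tile_starts <- function(L, window_len, stride) {
  if (L <= window_len) return(1L)
  starts <- seq.int(1L, L - window_len + 1L, by = stride)
  if (starts[length(starts)] + window_len - 1L < L) {
    starts <- c(starts, L - window_len + 1L)
  }
  starts
}

#' Define hit envelopes from HMM posterior decoding
#'
#' Positions whose in-model posterior probability is at least `p_in` are
#' grouped into maximal runs; runs are padded by `pad` positions, merged
#' when separated by fewer than `merge_gap` positions, and clipped to the
#' window.
#'
#' @param hmm a `profile_hmm`.
#' @param window window sequence (string or codes).
#' @param p_in posterior threshold for "in model".
#' @param pad positions added to each envelope side.
#' @param merge_gap runs closer than this are merged.
#' @param mode HMM mode for posterior decoding.
#' @return matrix with columns `start`, `end` (window-local, 1-based
#'   inclusive); zero rows when no position passes.
#' @export
define_envelopes <- function(hmm, window, p_in = 0.7, pad = 5L,
                             merge_gap = 10L, mode = "local") {
  post <- hmm_posterior(hmm, window, mode = mode)
  pin <- post$in_model_posterior
  L <- length(pin)
  hot <- pin >= p_in
  if (!any(hot)) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  runs[, 1] <- pmax(1L, runs[, 1] - pad)
  runs[, 2] <- pmin(L, runs[, 2] + pad)
  # merge padded runs separated by < merge_gap
  out <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (q in 2:nrow(runs)) {
      if (runs[q, 1] - out[nrow(out), 2] - 1L < merge_gap) {
        out[nrow(out), 2] <- max(out[nrow(out), 2], runs[q, 2])
      } else {
        out <- rbind(out, runs[q, , drop = FALSE])
      }
    }
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' Run the staged HMM filter cascade over one target strand
#'
#' Stage 1 scores every window with local Viterbi, stage 2 rescores
#' survivors with local Forward, stage 3 with glocal Forward, and stage 4
#' defines envelopes by posterior decoding. Each stage keeps a window iff
#' its score's P-value is at most the stage ceiling; ceilings must be
#' non-increasing.
#'
#' @param hmm calibrated `profile_hmm` (keys `hmm_vit_local`,
#'   `hmm_fwd_local`, `hmm_fwd_glocal`).
#' @param target target strand sequence (already reverse-complemented for
#'   the minus strand).
#' @param thresholds numeric length-3 vector of per-stage P-value
#'   ceilings.
#' @param window_len,overlap tiling parameters.
#' @param p_in,pad,merge_gap envelope-definition parameters.
#' @return list: `envelopes` (data.frame with window/envelope coordinates
#'   and stage scores, strand-local), `stats` (windows evaluated per
#'   stage).
#' @export
run_filter_cascade <- function(hmm, target, thresholds = c(0.35, 0.15, 0.02),
                               window_len, overlap, p_in = 0.7, pad = 5L,
                               merge_gap = 10L) {
  if (any(diff(thresholds) > 0)) {
    stop("stage P-value ceilings must be non-increasing")
  }
  for (key in c("hmm_vit_local", "hmm_fwd_local", "hmm_fwd_glocal")) {
    if (is.null(hmm$calibration[[key]])) {
      stop("model not calibrated for stage '", key, "'")
    }
  }
  stopifnot(window_len > overlap)
  codes <- encode_seq(target)
  L <- length(codes)
  m1 <- hmm_scan_cpp(codes, hmm$M, mesc_codes(hmm), hmm$trans,
                     local = TRUE, forward = FALSE,
                     window_len = window_len,
                     stride = window_len - overlap)
  starts <- as.integer(m1[, 1])
  ends <- as.integer(m1[, 2])
  n1 <- length(starts)
  p1 <- score_to_pvalue(m1[, 3], hmm$calibration$hmm_vit_local)
  keep <- which(p1 <= thresholds[1])
  n2 <- length(keep)
  s2 <- vapply(keep, function(q) {
    hmm_engine(hmm, codes[starts[q]:ends[q]], "local",
               forward = TRUE, exact = FALSE)$score
  }, 0)
  p2 <- score_to_pvalue(s2, hmm$calibration$hmm_fwd_local)
  keep <- keep[p2 <= thresholds[2]]
  s2 <- s2[p2 <= thresholds[2]]
  n3 <- length(keep)
  s3 <- vapply(keep, function(q) {
    hmm_engine(hmm, codes[starts[q]:ends[q]], "glocal",
               forward = TRUE, exact = FALSE)$score
  }, 0)
  p3 <- score_to_pvalue(s3, hmm$calibration$hmm_fwd_glocal)
  sel <- p3 <= thresholds[3]
  keep <- keep[sel]
  s2 <- s2[sel]
  s3 <- s3[sel]
  n4 <- length(keep)

  env_rows <- list()
  for (qq in seq_along(keep)) {
    q <- keep[qq]
    envs <- define_envelopes(hmm, codes[starts[q]:ends[q]], p_in = p_in,
                             pad = pad, merge_gap = merge_gap)
    if (nrow(envs) == 0L) next
    for (e in seq_len(nrow(envs))) {
      env_rows[[length(env_rows) + 1L]] <- data.frame(
        win_start = starts[q], win_end = ends[q],
        start = starts[q] + envs[e, "start"] - 1L,
        end = starts[q] + envs[e, "end"] - 1L,
        vit_p = p1[q], fwd_sc = s2[qq], glocal_sc = s3[qq]
      )
    }
  }
  envelopes <- if (length(env_rows)) do.call(rbind, env_rows) else
    data.frame(win_start = integer(0), win_end = integer(0),
               start = integer(0), end = integer(0), vit_p = numeric(0),
               fwd_sc = numeric(0), glocal_sc = numeric(0))
  # merge envelopes from overlapping windows
  if (nrow(envelopes) > 1) {
    envelopes <- envelopes[order(envelopes$start, envelopes$end), ]
    keep_rows <- rep(TRUE, nrow(envelopes))
    for (q in 2:nrow(envelopes)) {
      prev <- max(which(keep_rows[1:(q - 1)]))
      if (envelopes$start[q] <= envelopes$end[prev]) {
        envelopes$end[prev] <- max(envelopes$end[prev], envelopes$end[q])
        keep_rows[q] <- FALSE
      }
    }
    envelopes <- envelopes[keep_rows, , drop = FALSE]
  }
  list(envelopes = envelopes,
       stats = c(windows = n1, stage1_pass = n2, stage2_pass = n3,
                 stage3_pass = n4))
}
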