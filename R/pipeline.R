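# Search orchestration: filter cascade -> envelopes -> banded CM scoring,
# hit ranking and overlap resolution; model-library scanning; alignment
# front-end.

#' Search a covariance model against a nucleotide database
#'
#' Default pipeline per target and strand: staged HMM filtering
#' ([run_filter_cascade()]), envelope definition, HMM-banded CYK (best
#' subsequence and parse) and banded Inside (reported bit score and
#' E-value). The CM stages score glocally - a hit is a complete
#' structure; truncated-hit alignment is out of scope - while the filter
#' stages remain local/glocal as described in [run_filter_cascade()]. `mode = "max"` bypasses all filters and bands and scores
#' every window with unbanded Inside; `mode = "hmm"` scores every window
#' with the filter HMM's local Forward only (a sequence-only baseline).
#'
#' Hits are sorted by increasing E-value (ties: decreasing bit score,
#' then target id, then start); overlapping hits on the same target and
#' strand are resolved by keeping the best E-value.
#'
#' @param cm a calibrated `covariance_model` (calibration required
#'   whenever an E-value cutoff is used).
#' @param db named character vector of target sequences, or a FASTA path.
#' @param e_cutoff report hits with E-value at most this (default 10).
#' @param thresholds length-3 non-increasing vector of filter-stage
#'   P-value ceilings.
#' @param mode `"default"`, `"max"`, or `"hmm"`.
#' @param tail_p band tail probability for the CM stages.
#' @param p_in,pad,merge_gap envelope-definition parameters.
#' @param z0 database size (Mb) above which filter ceilings tighten
#'   proportionally (`ceilings * min(1, z0 / Z_Mb)`).
#' @return data.frame of hits (1-based inclusive coordinates): `model`,
#'   `target`, `strand`, `start`, `end`, `bits` (Inside), `cyk_bits`,
#'   `evalue`, `pvalue`, plus filter-stage scores. Attribute `stats`
#'   holds window/envelope counts (`n_windows`, `n_final`).
#' @export
cmsearch <- function(cm, db, e_cutoff = 10, thresholds = c(0.35, 0.15, 0.02),
                     mode = c("default", "max", "hmm"), tail_p = 1e-7,
                     p_in = 0.7, pad = 5L, merge_gap = 10L, z0 = 10) {
  mode <- match.arg(mode)
  if (is.character(db) && length(db) == 1L && file.exists(db) &&
      is.null(names(db))) {
    db <- read_fasta_all(db)
  }
  if (length(db) == 0L) {
    return(empty_hits())
  }
  db <- normalize_rna(db)
  need_cal <- if (mode == "hmm") "hmm_fwd_local" else "cm_inside_glocal"
  if (is.finite(e_cutoff) && is.null(cm$calibration[[need_cal]])) {
    stop("model not calibrated: E-value thresholds unavailable ",
         "(run calibrate_model first)")
  }
  attr(cm, "pack_glocal") <- cm_pack(cm, local = FALSE)
  hmm <- cm_to_hmm(cm)
  W <- 2L * cm$clen + 20L
  overlap <- cm$clen
  stride <- W - overlap
  Z <- 2 * sum(nchar(db))
  fac <- min(1, z0 / (Z / 1e6))
  thr <- thresholds * fac

  rows <- list()
  n_windows <- 0L
  n_final <- 0L
  for (t in names(db)) {
    tl <- nchar(db[[t]])
    for (strand in c("+", "-")) {
      sseq <- if (strand == "-") revcomp(db[[t]]) else db[[t]]
      if (mode == "max") {
        res <- cm_scan_cpp(encode_seq(sseq), cm_pack(cm, local = FALSE),
                           W, stride, inside = TRUE)
        n_windows <- n_windows + length(res$start)
        n_final <- n_final + length(res$start)
        P <- score_to_pvalue(res$score, cm$calibration$cm_inside_glocal)
        E <- pvalue_to_evalue(P, Z, cm$calibration$cm_inside_glocal)
        sel <- which(E <= e_cutoff)
        for (q in sel) {
          rows[[length(rows) + 1L]] <- hit_row(
            cm$name, t, strand, res$start[q], res$end[q], tl,
            bits = res$score[q], cyk_bits = NA_real_, evalue = E[q],
            pvalue = P[q])
        }
      } else if (mode == "hmm") {
        sw <- scan_windows(hmm, sseq, W, overlap, strand = "+",
                           algo = "forward", mode = "local")
        n_windows <- n_windows + nrow(sw)
        n_final <- n_final + nrow(sw)
        P <- score_to_pvalue(sw$score, hmm$calibration$hmm_fwd_local)
        E <- pvalue_to_evalue(P, Z, hmm$calibration$hmm_fwd_local)
        for (q in which(E <= e_cutoff)) {
          rows[[length(rows) + 1L]] <- hit_row(
            cm$name, t, strand, sw$start[q], sw$end[q], tl,
            bits = sw$score[q], cyk_bits = NA_real_, evalue = E[q],
            pvalue = P[q])
        }
      } else {
        fc <- run_filter_cascade(hmm, sseq, thresholds = thr,
                                 window_len = W, overlap = overlap,
                                 p_in = p_in, pad = pad,
                                 merge_gap = merge_gap)
        n_windows <- n_windows + fc$stats[["windows"]]
        envs <- fc$envelopes
        n_final <- n_final + nrow(envs)
        if (nrow(envs) == 0L) next
        for (e in seq_len(nrow(envs))) {
          # score the envelope in window-sized context so the final-stage
          # score geometry matches the calibration null (and --max)
          mid <- (envs$start[e] + envs$end[e]) %/% 2L
          es <- max(1L, min(mid - W %/% 2L, nchar(sseq) - W + 1L))
          ee <- min(nchar(sseq), es + W - 1L)
          env_seq <- substr(sseq, es, ee)
          bands <- derive_bands(hmm, cm, env_seq, tail_p = tail_p,
                                mode = "glocal")
          ck <- banded_cyk(cm, env_seq, bands, mode = "glocal",
                           scan = TRUE)
          if (ck$score <= NEG_INF_SCORE / 2) next
          ins <- banded_inside(cm, env_seq, bands, mode = "glocal",
                               scan = TRUE, exact = FALSE)
          P <- score_to_pvalue(ins$score, cm$calibration$cm_inside_glocal)
          E <- pvalue_to_evalue(P, Z, cm$calibration$cm_inside_glocal)
          if (E > e_cutoff) next
          rows[[length(rows) + 1L]] <- hit_row(
            cm$name, t, strand, es + ck$i - 1L, es + ck$j - 1L, tl,
            bits = ins$score, cyk_bits = ck$score, evalue = E, pvalue = P,
            fwd_bits = envs$fwd_sc[e], glocal_bits = envs$glocal_sc[e])
        }
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty_hits()
  hits <- resolve_overlaps(hits)
  hits <- rank_hits(hits)
  attr(hits, "stats") <- c(n_windows = n_windows, n_final = n_final)
  hits
}

# strand-local [s, e] on the reverse complement -> forward coordinates
hit_row <- function(model, target, strand, s, e, target_len, bits,
                    cyk_bits, evalue, pvalue, fwd_bits = NA_real_,
                    glocal_bits = NA_real_) {
  if (strand == "-") {
    tmp <- target_len - e + 1L
    e <- target_len - s + 1L
    s <- tmp
  }
  data.frame(model = model, target = target, strand = strand,
             start = as.integer(s), end = as.integer(e), bits = bits,
             cyk_bits = cyk_bits, evalue = evalue, pvalue = pvalue,
             fwd_bits = fwd_bits, glocal_bits = glocal_bits,
             stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(model = character(0), target = character(0),
             strand = character(0), start = integer(0), end = integer(0),
             bits = numeric(0), cyk_bits = numeric(0),
             evalue = numeric(0), pvalue = numeric(0),
             fwd_bits = numeric(0), glocal_bits = numeric(0),
             stringsAsFactors = FALSE)
}

# keep the best hit (lowest E, then highest bits) in every overlapping
# cluster on the same target and strand
resolve_overlaps <- function(hits) {
  if (nrow(hits) < 2L) return(hits)
  ord <- order(hits$evalue, -hits$bits, hits$target, hits$start)
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  for (q in seq_len(nrow(hits))) {
    kept <- which(keep)
    clash <- FALSE
    for (p in kept) {
      if (hits$target[p] == hits$target[q] &&
          hits$strand[p] == hits$strand[q] &&
          hits$model[p] == hits$model[q] &&
          hits$start[q] <= hits$end[p] && hits$end[q] >= hits$start[p]) {
        clash <- TRUE
        break
      }
    }
    keep[q] <- !clash
  }
  hits[keep, , drop = FALSE]
}

rank_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$evalue, -hits$bits, hits$target, hits$start)
  out <- hits[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a sequence against a library of covariance models
#'
#' Equivalent to running [cmsearch()] for each model and merging the
#' ranked outputs.
#'
#' @param models list of calibrated `covariance_model`s (or a model file
#'   path).
#' @param db target sequence(s), as in [cmsearch()].
#' @param cross_model_overlap if `TRUE`, overlapping hits from different
#'   models are also resolved to the best E-value.
#' @param ... passed to [cmsearch()].
#' @return ranked hit data.frame as in [cmsearch()].
#' @export
cmscan <- function(models, db, cross_model_overlap = FALSE, ...) {
  if (is.character(models)) models <- read_cm(models)
  if (inherits(models, "covariance_model")) models <- list(models)
  if (length(models) == 0L) stop("no models in library")
  parts <- lapply(models, function(m) cmsearch(m, db, ...))
  hits <- do.call(rbind, parts)
  if (cross_model_overlap && nrow(hits) > 1L) {
    save_model <- hits$model
    hits$model <- "*"
    hits <- resolve_overlaps(hits)
    hits$model <- save_model[as.integer(rownames(hits))]
  }
  hits <- rank_hits(hits)
  stats <- Reduce(`+`, lapply(parts, attr, "stats"))
  attr(hits, "stats") <- stats
  hits
}

#' Align sequences to a covariance model
#'
#' Each sequence is parsed with glocal CYK (HMM-banded unless
#' `nonbanded`); parse trees are merged into a structure-annotated MSA.
#' Sequences longer than `max_len` are skipped with a warning. A sequence
#' whose bands exclude every parse is realigned without bands.
#'
#' @param cm a `covariance_model` (calibration not required).
#' @param seqs named character vector of RNA sequences, or a FASTA path.
#' @param nonbanded disable HMM bands.
#' @param tail_p band tail probability.
#' @param max_len per-sequence length guard.
#' @return list: `alignment` (a [structured_alignment()]), `scores`
#'   (per-sequence CYK bits), `skipped` (names of skipped sequences).
#' @export
cmalign <- function(cm, seqs, nonbanded = FALSE, tail_p = 1e-7,
                    max_len = 10000L) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs) &&
      is.null(names(seqs))) {
    seqs <- read_fasta_all(seqs)
  }
  seqs <- normalize_rna(seqs)
  attr(cm, "pack_glocal") <- cm_pack(cm, local = FALSE)
  hmm <- cm_to_hmm(cm)
  skipped <- character(0)
  trees <- list()
  scores <- numeric(0)
  kept <- character(0)
  for (nm in names(seqs)) {
    if (nchar(seqs[[nm]]) > max_len) {
      warning("sequence '", nm, "' exceeds the length guard; skipped")
      skipped <- c(skipped, nm)
      next
    }
    bands <- NULL
    if (!nonbanded) {
      bands <- derive_bands(hmm, cm, seqs[[nm]], tail_p = tail_p,
                            mode = "glocal")
    }
    ck <- cyk(cm, seqs[[nm]], mode = "glocal", bands = bands, scan = FALSE)
    if (ck$score <= NEG_INF_SCORE / 2 && !nonbanded) {
      ck <- cyk(cm, seqs[[nm]], mode = "glocal", scan = FALSE)
    }
    trees[[length(trees) + 1L]] <- ck$tree
    scores <- c(scores, ck$score)
    kept <- c(kept, nm)
  }
  if (length(trees) == 0L) stop("no alignable sequences")
  aln <- parsetree_to_alignment(cm, trees, unname(seqs[kept]), names = kept)
  list(alignment = aln, scores = stats::setNames(scores, kept),
       skipped = skipped)
}

#' Write a ranked hit table
#'
#' Tab-separated with `#`-prefixed header lines; coordinates 1-based
#' inclusive.
#'
#' @param hits data.frame from [cmsearch()]/[cmscan()].
#' @param path output path (or an open connection).
#' @export
write_hits <- function(hits, path) {
  if (inherits(path, "connection")) {
    con <- path
  } else {
    con <- file(path, "w")
    on.exit(close(con))
  }
  writeLines(c("# covmod hit table",
               paste0("# ", paste(names(hits), collapse = "\t"))), con)
  if (nrow(hits) > 0L) {
    lines <- apply(hits, 1, function(r) paste(trimws(r), collapse = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}
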