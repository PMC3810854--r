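# Synthetic RNA families and benchmark construction: train/test splits
# under identity ceilings, pseudo-genome embedding with recorded truth,
# and ROC-style scoring of ranked hit lists. Doubles as the package's
# fixture generator.

with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# canonical pair sampling weights (Watson-Crick heavy, rare wobble)
PAIR_TYPES <- c("CG", "GC", "AU", "UA", "GU", "UG")
PAIR_WEIGHTS <- c(0.30, 0.30, 0.17, 0.17, 0.03, 0.03)

#' Family generation configuration
#'
#' @param len consensus length (nt).
#' @param pair_frac fraction of consensus columns that are base-paired.
#' @param n_seq number of descendant sequences to evolve.
#' @param sub_rate mean per-column substitution probability per
#'   descendant. Column rates are Gamma-distributed around this mean
#'   (`rate_shape`), giving the conserved-core / variable-loop structure
#'   real families show; a base pair shares one rate.
#' @param p_compensatory probability that a substitution at a paired
#'   column replaces the pair with another canonical pair.
#' @param indel_rate mean per-unpaired-column deletion (and insertion)
#'   probability per descendant (scaled by the column rate).
#' @param rate_shape shape of the Gamma(shape, shape) column-rate
#'   distribution (mean 1; smaller = more heterogeneous).
#' @param seq_rate_range range of the per-sequence rate multiplier
#'   (lineage rate variation: some descendants sit closer to the
#'   consensus than others, as in real phylogenies).
#' @return config list.
#' @export
family_config <- function(len = 60L, pair_frac = 0.4, n_seq = 24L,
                          sub_rate = 0.25, p_compensatory = 0.9,
                          indel_rate = 0.02, rate_shape = 0.6,
                          seq_rate_range = c(0.5, 1.5)) {
  if (pair_frac < 0 || pair_frac > 1) stop("infeasible pairing fraction")
  if (len < 10L) stop("consensus too short")
  list(len = as.integer(len), pair_frac = pair_frac,
       n_seq = as.integer(n_seq), sub_rate = sub_rate,
       p_compensatory = p_compensatory, indel_rate = indel_rate,
       rate_shape = rate_shape, seq_rate_range = seq_rate_range)
}

# Random nested structure built from contiguous helices (as real RNA
# secondary structures are): stems of 3-7 bp are placed at random
# non-crossing locations with a minimum hairpin loop of 3 until the
# target pairing fraction is reached.
sample_structure <- function(len, pair_frac) {
  target <- round(pair_frac * len / 2)
  partner <- integer(len)
  placed <- 0L
  tries <- 0L
  while (placed < target && tries < 200L * max(1L, target)) {
    tries <- tries + 1L
    s <- min(sample(3:7, 1L), target - placed)
    span_min <- 2L * s + 3L
    if (span_min > len) next
    i <- sample.int(len - span_min + 1L, 1L)
    js <- seq.int(i + span_min - 1L, len)
    j <- js[sample.int(length(js), 1L)]
    idx <- c(i:(i + s - 1L), (j - s + 1L):j)
    if (any(partner[idx] > 0L)) next
    crossing <- FALSE
    for (a in which(partner > 0L)) {
      b <- partner[a]
      if (a < b) {
        inside_a <- a > i && a < j
        inside_b <- b > i && b < j
        if (inside_a != inside_b) { crossing <- TRUE; break }
      }
    }
    if (crossing) next
    # interior of the new outermost pair must not contain only part of an
    # existing pair (checked above); place the whole helix
    for (q in 0:(s - 1L)) {
      partner[i + q] <- j - q
      partner[j - q] <- i + q
    }
    placed <- placed + s
  }
  structure(list(length = len, partner = partner), class = "pair_table")
}

#' Generate a synthetic RNA family
#'
#' Samples a nested consensus structure and sequence, then evolves
#' descendants by per-column substitution (pair-aware: substitutions at
#' paired columns are compensatory with probability `p_compensatory`) and
#' indels in unpaired columns. Returns both the known alignment of all
#' descendants and their ungapped sequences. Bit-reproducible under the
#' seed.
#'
#' @param config from [family_config()].
#' @param seed RNG seed.
#' @param id family name.
#' @return list: `aln` (a [structured_alignment()] of all descendants),
#'   `seqs` (named ungapped strings), `consensus`, `structure` (WUSS
#'   string over consensus columns), `config`.
#' @export
generate_family <- function(config = family_config(), seed = 1L,
                            id = "fam") {
  with_seed(seed, {
    len <- config$len
    pt <- sample_structure(len, config$pair_frac)
    cons <- character(len)
    for (i in seq_len(len)) {
      p <- pt$partner[i]
      if (p == 0L) {
        cons[i] <- sample(RNA_BASES, 1L)
      } else if (p > i) {
        pr <- strsplit(sample(PAIR_TYPES, 1L, prob = PAIR_WEIGHTS),
                       "")[[1]]
        cons[i] <- pr[1]
        cons[p] <- pr[2]
      }
    }
    ss <- pair_table_to_wuss(pt)

    # per-column substitution rates (Gamma, mean 1; a pair shares the
    # left partner's rate): the conserved core real families show
    shape <- config$rate_shape %||% 0.6
    rates <- stats::rgamma(len, shape = shape, rate = shape)
    for (i in seq_len(len)) {
      if (pt$partner[i] > 0L && pt$partner[i] < i) {
        rates[i] <- rates[pt$partner[i]]
      }
    }
    n <- config$n_seq
    # per-sequence lineage rate multiplier (lineage rate variation)
    srr <- config$seq_rate_range %||% c(1, 1)
    seq_rate <- stats::runif(n, srr[1], srr[2])
    res_mat <- matrix(rep(cons, n), nrow = n, byrow = TRUE)
    ins_list <- vector("list", n)  # per seq: list(gap -> residues)
    for (s in seq_len(n)) {
      psub <- pmin(0.9, config$sub_rate * rates * seq_rate[s])
      pindel <- pmin(0.5, config$indel_rate * rates * seq_rate[s])
      ins_list[[s]] <- list()
      for (i in seq_len(len)) {
        p <- pt$partner[i]
        if (p > 0L && p < i) next  # pair handled at its left partner
        if (p == 0L) {
          if (stats::runif(1) < psub[i]) {
            res_mat[s, i] <- sample(setdiff(RNA_BASES, res_mat[s, i]), 1L)
          }
          if (stats::runif(1) < pindel[i]) {
            res_mat[s, i] <- "-"
          }
          if (stats::runif(1) < pindel[i]) {
            k <- 1L + stats::rgeom(1L, 0.5)
            ins_list[[s]][[as.character(i)]] <-
              paste(sample(RNA_BASES, k, replace = TRUE), collapse = "")
          }
        } else {
          if (stats::runif(1) < psub[i]) {
            if (stats::runif(1) < config$p_compensatory) {
              cur <- paste0(res_mat[s, i], res_mat[s, p])
              alt <- setdiff(PAIR_TYPES, cur)
              pr <- strsplit(sample(alt, 1L), "")[[1]]
              res_mat[s, i] <- pr[1]
              res_mat[s, p] <- pr[2]
            } else {
              side <- sample(c(i, p), 1L)
              res_mat[s, side] <- sample(setdiff(RNA_BASES,
                                                 res_mat[s, side]), 1L)
            }
          }
        }
      }
    }
    # assemble the alignment: consensus columns + insert blocks
    ins_width <- integer(len)
    for (i in seq_len(len)) {
      ins_width[i] <- max(0L, vapply(ins_list, function(x)
        nchar(x[[as.character(i)]] %||% ""), 0L))
    }
    rows <- character(n)
    ss_full <- character(0)
    for (i in seq_len(len)) {
      ss_full <- c(ss_full, substr(ss, i, i),
                   rep(".", ins_width[i]))
    }
    for (s in seq_len(n)) {
      parts <- character(0)
      for (i in seq_len(len)) {
        parts <- c(parts, res_mat[s, i])
        if (ins_width[i] > 0L) {
          resid <- tolower(ins_list[[s]][[as.character(i)]] %||% "")
          parts <- c(parts, strsplit(resid, "")[[1]],
                     rep(".", ins_width[i] - nchar(resid)))
        }
      }
      rows[s] <- paste(parts, collapse = "")
    }
    nms <- sprintf("%s_%02d", id, seq_len(n))
    aln <- structured_alignment(nms, rows, paste(ss_full, collapse = ""),
                                id = id)
    seqs <- vapply(rows, function(r) {
      gsub("[-._~]", "", toupper(r))
    }, "")
    names(seqs) <- nms
    list(aln = aln, seqs = seqs, consensus = paste(cons, collapse = ""),
         structure = ss, config = config)
  })
}

#' Pairwise percent identity between two aligned rows
#'
#' Identities divided by the number of columns in which both rows carry a
#' residue.
#'
#' @param a,b aligned strings of equal length.
#' @return fraction in `[0, 1]` (`NA` if no shared columns).
#' @export
pairwise_identity <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  both <- !is_gap_char(ca) & !is_gap_char(cb)
  if (!any(both)) return(NA_real_)
  sum(ca[both] == cb[both]) / sum(both)
}

#' Split family sequences into training and test sets under identity
#' ceilings
#'
#' Greedy assignment with a shrinking test quota: the test set is filled
#' first-come with sequences mutually at most `test_test_max_id`
#' identical; the training set then takes every remaining sequence
#' within `train_test_max_id` of all test members. If the training
#' minimum fails, the test quota shrinks and assignment retries.
#' Families that cannot meet the minimum sizes are rejected (a value,
#' not an error).
#'
#' @param aln a [structured_alignment()] of all candidate sequences.
#' @param test_test_max_id maximum pairwise identity within the test set.
#' @param train_test_max_id maximum identity between any train/test pair.
#' @param min_train,min_test minimum accepted sizes.
#' @param max_test cap on the test-set size.
#' @return list: `accepted` (logical), `train`, `test` (row indices),
#'   `reason` (when rejected).
#' @export
split_train_test <- function(aln, test_test_max_id = 0.70,
                             train_test_max_id = 0.60, min_train = 5L,
                             min_test = 1L, max_test = Inf) {
  n <- length(aln$rows)
  idm <- matrix(1, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a < b) {
      idm[a, b] <- idm[b, a] <- pairwise_identity(aln$rows[a], aln$rows[b])
    }
  }
  # greedy with a shrinking test quota
  for (tt in seq(min(max_test, n), min_test)) {
    test <- integer(0)
    for (s in seq_len(n)) {
      if (length(test) >= tt) break
      if (all(idm[s, test] <= test_test_max_id)) test <- c(test, s)
    }
    if (length(test) < min_test) next
    rest <- setdiff(seq_len(n), test)
    train <- rest[vapply(rest, function(s)
      all(idm[s, test] <= train_test_max_id), TRUE)]
    if (length(train) >= min_train) {
      return(list(accepted = TRUE, train = train, test = test,
                  reason = NULL))
    }
  }
  list(accepted = FALSE, train = integer(0), test = integer(0),
       reason = "identity ceilings leave too few train/test sequences")
}

# subset an alignment's rows (columns are kept as-is)
subset_alignment <- function(aln, rows) {
  structured_alignment(aln$names[rows], aln$rows[rows], aln$ss_cons,
                       id = aln$id)
}

# order-k Markov (or i.i.d.) decoy sequence sampler
sample_decoy <- function(L, decoy_model) {
  if (is.null(decoy_model) || decoy_model$type == "iid") {
    freqs <- decoy_model$freqs %||% rep(0.25, 4)
    return(paste(sample(RNA_BASES, L, replace = TRUE, prob = freqs),
                 collapse = ""))
  }
  stopifnot(decoy_model$type == "markov")
  k <- decoy_model$k
  train <- encode_seq(decoy_model$train_seq)
  stopifnot(all(train <= 4L), length(train) > k + 1L)
  nctx <- 4L^k
  counts <- matrix(1e-3, nctx, 4L)  # tiny smoothing
  ctx <- 0L
  pow <- 4L^((k - 1L):0L)
  for (i in seq_along(train)) {
    if (i > k) {
      counts[ctx + 1L, train[i]] <- counts[ctx + 1L, train[i]] + 1
    }
    if (i >= k) {
      ctx <- sum((train[(i - k + 1L):i] - 1L) * pow)
    }
  }
  out <- integer(L)
  out[1:k] <- sample.int(4L, k, replace = TRUE)
  for (i in (k + 1L):L) {
    ctx <- sum((out[(i - k):(i - 1L)] - 1L) * pow)
    p <- counts[ctx + 1L, ]
    out[i] <- sample.int(4L, 1L, prob = p / sum(p))
  }
  paste(RNA_BASES[out], collapse = "")
}

#' Build a pseudo-genome with embedded test sequences
#'
#' Decoy chunks are sampled from the decoy model; each test sequence is
#' inserted at a uniformly random position of a uniformly random chunk on
#' a uniformly random strand, and its final coordinates recorded as
#' truth. Insertion (rather than overwriting) guarantees disjoint truth
#' intervals.
#'
#' @param test_seqs data.frame with columns `family`, `name`, `seq`.
#' @param decoy_model `list(type = "iid", freqs = ...)` (default uniform)
#'   or `list(type = "markov", k = , train_seq = )`.
#' @param n_chunks,chunk_len decoy chunks and their pre-insertion length.
#' @param seed RNG seed.
#' @return a `benchmark_set`: list with `genome` (named character),
#'   `truth` (data.frame: family, target, strand, start, end; 1-based
#'   inclusive), `seed`.
#' @export
build_pseudo_genome <- function(test_seqs, decoy_model = NULL,
                                n_chunks = 2L, chunk_len = 50000L,
                                seed = 1L) {
  stopifnot(nrow(test_seqs) >= 1L)
  if (sum(nchar(test_seqs$seq)) >= n_chunks * chunk_len) {
    stop("total test length exceeds decoy length; use larger chunks")
  }
  with_seed(seed, {
    chunks <- vapply(seq_len(n_chunks), function(i)
      sample_decoy(chunk_len, decoy_model), "")
    placement <- data.frame(
      chunk = sample.int(n_chunks, nrow(test_seqs), replace = TRUE),
      offset = stats::runif(nrow(test_seqs)),
      strand = sample(c("+", "-"), nrow(test_seqs), replace = TRUE)
    )
    truth <- list()
    for (ci in seq_len(n_chunks)) {
      sel <- which(placement$chunk == ci)
      # insertion points in the decoy chunk, processed left to right
      pts <- 1L + floor(placement$offset[sel] * (chunk_len - 1L))
      ord <- sel[order(pts)]
      pts <- sort(pts)
      pieces <- character(0)
      cursor <- 1L
      grown <- 0L
      for (q in seq_along(ord)) {
        s <- ord[q]
        emb <- test_seqs$seq[s]
        if (placement$strand[s] == "-") emb <- revcomp(emb)
        pieces <- c(pieces, substr(chunks[ci], cursor, pts[q]), emb)
        start <- pts[q] + grown + 1L
        truth[[length(truth) + 1L]] <- data.frame(
          family = test_seqs$family[s], target = sprintf("chunk%d", ci),
          strand = placement$strand[s], start = start,
          end = start + nchar(emb) - 1L, name = test_seqs$name[s],
          stringsAsFactors = FALSE)
        grown <- grown + nchar(emb)
        cursor <- pts[q] + 1L
      }
      pieces <- c(pieces, substr(chunks[ci], cursor, chunk_len))
      chunks[ci] <- paste(pieces, collapse = "")
    }
    names(chunks) <- sprintf("chunk%d", seq_len(n_chunks))
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(family = character(0), target = character(0),
                 strand = character(0), start = integer(0),
                 end = integer(0), name = character(0))
    structure(list(genome = chunks, truth = truth, seed = seed),
              class = "benchmark_set")
  })
}

#' Score a ranked hit list against benchmark truth (ROC-like curve)
#'
#' Walking down the E-value-ranked list, a hit is a true positive when it
#' overlaps a not-yet-claimed truth interval of the same family on the
#' same strand by at least `overlap_frac` of the truth length (the first
#' such hit claims it). A hit overlapping a different family's truth is
#' ignored; every other hit is a false positive. The curve reports
#' sensitivity against false positives per Mb of genome per query family.
#'
#' @param hits ranked hit data.frame (needs `model`, `target`, `strand`,
#'   `start`, `end`, `evalue`).
#' @param truth truth table from [build_pseudo_genome()].
#' @param genome_mb single-strand genome size in Mb.
#' @param n_queries number of query families searched.
#' @param overlap_frac minimum overlap as a fraction of truth length.
#' @param targets valid target names (defaults to the truth's targets).
#' @return data.frame, one row per hit: `evalue`, `tp`, `fp`,
#'   `sensitivity`, `fp_per_mb_query`.
#' @export
score_roc <- function(hits, truth, genome_mb, n_queries,
                      overlap_frac = 0.5,
                      targets = unique(truth$target)) {
  if (nrow(hits) > 0L && length(setdiff(hits$target, targets)) > 0L) {
    stop("hits reference unknown targets")
  }
  hits <- rank_hits(hits)
  claimed <- rep(FALSE, nrow(truth))
  tp <- 0L
  fp <- 0L
  out <- vector("list", nrow(hits))
  for (q in seq_len(nrow(hits))) {
    h <- hits[q, ]
    ov_len <- pmax(0L, pmin(h$end, truth$end) - pmax(h$start, truth$start) + 1L)
    same_place <- truth$target == h$target & truth$strand == h$strand
    anyfam <- same_place & ov_len > 0L
    mine <- which(same_place & truth$family == h$model & !claimed &
                    ov_len >= overlap_frac * (truth$end - truth$start + 1L))
    if (length(mine) > 0L) {
      claimed[mine[1]] <- TRUE
      tp <- tp + 1L
    } else if (any(anyfam & truth$family != h$model)) {
      # overlaps another family's truth: ignored
    } else {
      fp <- fp + 1L
    }
    out[[q]] <- data.frame(evalue = h$evalue, tp = tp, fp = fp,
                           sensitivity = tp / nrow(truth),
                           fp_per_mb_query = fp / (genome_mb * n_queries))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(evalue = numeric(0), tp = integer(0), fp = integer(0),
               sensitivity = numeric(0), fp_per_mb_query = numeric(0))
}

#' Assemble the package's end-to-end synthetic benchmark
#'
#' Generates synthetic families, applies the train/test split under the
#' standard identity ceilings (70% test/test, 60% train/test), builds and
#' calibrates one model per accepted family, embeds the test sequences in
#' a pseudo-genome, and returns everything needed to run and score
#' searches.
#'
#' @param seed master seed; every stage derives its own seed from it.
#' @param n_families accepted families to collect.
#' @param len_range consensus-length range sampled per family.
#' @param n_chunks,chunk_len pseudo-genome dimensions.
#' @param calib_n,calib_L calibration sample size and length per stage
#'   (length defaults to each model's own window length).
#' @param quiet suppress progress messages.
#' @return list: `models` (calibrated), `train` (alignments), `genome`,
#'   `truth`, `families`.
#' @export
build_benchmark <- function(seed = 101L, n_families = 10L,
                            len_range = c(50L, 80L), n_chunks = 2L,
                            chunk_len = 50000L, calib_n = 1000L,
                            calib_L = NULL, quiet = TRUE) {
  fams <- list()
  attempt <- 0L
  while (length(fams) < n_families && attempt < 40L * n_families) {
    attempt <- attempt + 1L
    fseed <- seed * 1000L + attempt
    len <- with_seed(fseed, sample(len_range[1]:len_range[2], 1L))
    fam <- generate_family(family_config(len = len), seed = fseed,
                           id = sprintf("fam%02d", length(fams) + 1L))
    sp <- split_train_test(fam$aln, max_test = 8L)
    if (!sp$accepted) next
    fam$train_aln <- subset_alignment(fam$aln, sp$train)
    fam$test <- data.frame(
      family = fam$aln$id, name = fam$aln$names[sp$test],
      seq = unname(fam$seqs[sp$test]), stringsAsFactors = FALSE)
    fams[[length(fams) + 1L]] <- fam
  }
  if (length(fams) < n_families) {
    stop("could not assemble ", n_families, " families under the ",
         "identity ceilings")
  }
  test_seqs <- do.call(rbind, lapply(fams, `[[`, "test"))
  bs <- build_pseudo_genome(test_seqs, n_chunks = n_chunks,
                            chunk_len = chunk_len, seed = seed + 7L)
  models <- vector("list", length(fams))
  for (q in seq_along(fams)) {
    if (!quiet) message("building/calibrating model ", q)
    cm <- cm_build(fams[[q]]$train_aln)
    models[[q]] <- calibrate_model(cm, n = calib_n, L = calib_L,
                                   seed = seed + 100L * q)
  }
  list(models = models,
       train = lapply(fams, `[[`, "train_aln"),
       genome = bs$genome, truth = bs$truth, families = fams,
       seed = seed)
}

#' Run searches over a benchmark and score them
#'
#' @param bench from [build_benchmark()].
#' @param mode search mode passed to [cmsearch()].
#' @param e_cutoff reporting threshold.
#' @param quiet suppress progress messages.
#' @return list: `hits` (merged ranked), `roc`, `stats` (summed window
#'   counts).
#' @export
run_benchmark <- function(bench, mode = "default", e_cutoff = 10,
                          quiet = TRUE) {
  parts <- lapply(seq_along(bench$models), function(q) {
    if (!quiet) message("searching model ", q, " (", mode, ")")
    cmsearch(bench$models[[q]], bench$genome, e_cutoff = e_cutoff,
             mode = mode)
  })
  hits <- rank_hits(do.call(rbind, parts))
  stats <- Reduce(`+`, lapply(parts, attr, "stats"))
  genome_mb <- sum(nchar(bench$genome)) / 1e6
  roc <- score_roc(hits, bench$truth, genome_mb, length(bench$models),
                   targets = names(bench$genome))
  list(hits = hits, roc = roc, stats = stats)
}

#' Write benchmark artifacts (FASTA genome, Stockholm training files,
#' truth and ROC tables)
#'
#' @param bench from [build_benchmark()].
#' @param dir output directory (created if needed).
#' @param roc optional ROC table to write alongside.
#' @export
write_benchmark <- function(bench, dir, roc = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bench$genome, file.path(dir, "pseudo_genome.fa"))
  write_stockholm(bench$train, file.path(dir, "train.sto"))
  utils::write.table(bench$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(roc)) {
    utils::write.table(roc, file.path(dir, "roc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
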