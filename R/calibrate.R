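# E-value statistics: simulated null-score samples, maximum-likelihood
# Gumbel fits, and score -> P-value -> E-value conversion.

#' Gumbel (type-I extreme value) parameter container
#'
#' @param mu location in bits.
#' @param lambda scale, 1/bits (> 0).
#' @param calib_len total random-sequence length used in calibration.
#' @param calib_n number of simulated sequences (>= 100).
#' @param seed RNG seed used for the simulation.
#' @return a `gumbel_params` object.
#' @export
gumbel_params <- function(mu, lambda, calib_len = NA_real_,
                          calib_n = NA_integer_, seed = NA_integer_) {
  stopifnot(lambda > 0)
  structure(list(mu = mu, lambda = lambda, calib_len = calib_len,
                 calib_n = calib_n, seed = seed), class = "gumbel_params")
}

#' @export
print.gumbel_params <- function(x, ...) {
  cat(sprintf("gumbel_params: mu = %.4f bits, lambda = %.4f (n = %s)\n",
              x$mu, x$lambda, x$calib_n))
  invisible(x)
}

#' Sample null scores by simulated search against random sequence
#'
#' Draws `n` i.i.d. sequences of length `L` from the background base
#' distribution and scores each with the supplied scorer (one score per
#' sequence). Bit-reproducible under a fixed seed.
#'
#' @param scorer function taking one sequence string, returning bits.
#' @param null background base frequencies (length 4, sums to 1).
#' @param n number of sequences (>= 100).
#' @param L sequence length.
#' @param seed RNG seed.
#' @return numeric vector of `n` scores.
#' @export
simulate_null_scores <- function(scorer, null = rep(0.25, 4), n = 1000L,
                                 L = 200L, seed = 1L) {
  stopifnot(n >= 100L, abs(sum(null) - 1) < 1e-9)
  seqs <- sample_null_seqs(n, L, null, seed)
  vapply(seqs, scorer, 0)
}

sample_null_seqs <- function(n, L, null = rep(0.25, 4), seed = 1L) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(RNA_BASES, L, replace = TRUE, prob = null), collapse = "")
  }, "")
}

#' Maximum-likelihood Gumbel fit
#'
#' Solves the profile-likelihood equation for lambda (1-D root find) and
#' recovers mu in closed form. Deterministic given the sample.
#'
#' @param scores at least 100 finite scores with positive variance.
#' @param calib_len,calib_n,seed provenance stored in the result.
#' @return a [gumbel_params()] object.
#' @export
fit_gumbel <- function(scores, calib_len = NA_real_, calib_n = NA_integer_,
                       seed = NA_integer_) {
  x <- scores[is.finite(scores) & scores > NEG_INF_SCORE / 2]
  if (length(x) < 100L) stop("need at least 100 finite scores")
  if (stats::sd(x) < 1e-12) stop("degenerate score sample (zero variance)")
  xbar <- mean(x)
  # ML condition: 1/lambda = xbar - sum(x*exp(-lambda*x))/sum(exp(-lambda*x))
  g <- function(lambda) {
    z <- -lambda * x
    z <- z - max(z)
    w <- exp(z)
    1 / lambda - xbar + sum(x * w) / sum(w)
  }
  lo <- 1e-4 / stats::sd(x)
  hi <- 1e4 / stats::sd(x)
  lambda <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  z <- -lambda * x
  m <- max(z)
  mu <- -(m + log(mean(exp(z - m)))) / lambda
  gumbel_params(mu = mu, lambda = lambda, calib_len = calib_len,
                calib_n = calib_n, seed = seed)
}

#' Convert a bit score to a Gumbel tail P-value
#'
#' `P(S' >= S) = 1 - exp(-exp(-lambda (S - mu)))`, strictly decreasing
#' in S.
#'
#' @param S score(s) in bits.
#' @param params a [gumbel_params()].
#' @return P-value(s) in (0, 1).
#' @export
score_to_pvalue <- function(S, params) {
  if (is.null(params)) stop("model not calibrated")
  -expm1(-exp(-params$lambda * (S - params$mu)))
}

#' Convert a P-value to an E-value for a database of size Z
#'
#' `E = P * Z / L_cal`, where `L_cal` is the per-sample calibration
#' sequence length and `Z` the searched length in the same units (both
#' strands counted by the caller).
#'
#' @param P P-value(s).
#' @param Z searched length in residues.
#' @param params the calibration used (supplies the per-sample length).
#' @return expected hit count(s).
#' @export
pvalue_to_evalue <- function(P, Z, params) {
  if (is.null(params)) stop("model not calibrated")
  Lcal <- params$calib_len / params$calib_n
  P * Z / Lcal
}

#' Calibrate a covariance model by simulated search
#'
#' Fits Gumbel parameters for each filter-stage scorer (local Viterbi,
#' local Forward, glocal Forward of the derived HMM) and for the final CM
#' scorer (glocal Inside in scan mode - hits are scored as complete
#' structures, truncated-hit alignment being out of scope - and unbanded:
#' with the default band tail probability the bands are designed to leave
#' scores unchanged, so the null distribution is calibrated without
#' them). Results are stored in the model's calibration block and written
#' with the model file.
#'
#' Null sequences default to the pipeline's window length
#' (`2 * clen + 20`): the summed multi-hit local score grows with
#' sequence length, so the calibration geometry must match the scored
#' windows for its P-values to transfer.
#'
#' @param cm a built `covariance_model`.
#' @param n simulated sequences per stage.
#' @param L their length (default: the model's search window length).
#' @param seed base RNG seed (stage s uses `seed + s`).
#' @param tail_p retained for configuration compatibility (unused by the
#'   default scorers).
#' @return the model with a populated `calibration` list.
#' @export
calibrate_model <- function(cm, n = 1000L, L = NULL, seed = 1L,
                            tail_p = 1e-7) {
  L <- as.integer(L %||% (2L * cm$clen + 20L))
  attr(cm, "pack_glocal") <- cm_pack(cm, local = FALSE)
  hmm <- cm_to_hmm(cm)
  scorers <- list(
    hmm_vit_local = function(s)
      hmm_engine(hmm, s, "local", forward = FALSE, exact = FALSE)$score,
    hmm_fwd_local = function(s)
      hmm_engine(hmm, s, "local", forward = TRUE, exact = FALSE)$score,
    hmm_fwd_glocal = function(s)
      hmm_engine(hmm, s, "glocal", forward = TRUE, exact = FALSE)$score,
    cm_inside_glocal = function(s)
      inside(cm, s, mode = "glocal", scan = TRUE, exact = FALSE)$score
  )
  for (q in seq_along(scorers)) {
    sc <- simulate_null_scores(scorers[[q]], null = cm$null, n = n, L = L,
                               seed = seed + q)
    cm$calibration[[names(scorers)[q]]] <-
      fit_gumbel(sc, calib_len = as.numeric(n) * L, calib_n = n,
                 seed = seed + q)
  }
  attr(cm, "pack_glocal") <- NULL
  cm
}
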