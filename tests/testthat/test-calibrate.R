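# E-value statistics: null-score simulation, Gumbel fitting and the
# score -> P-value -> E-value chain.

# inverse-CDF Gumbel sampler, independent of the fitting code
rgumbel_ref <- function(n, mu, lambda) {
  mu - log(-log(runif(n))) / lambda
}

test_that("null-score simulation is seed-deterministic", {
  cm <- cm_build(fix_aln(c("GGAAACC", "GGUUUCC"), "<<...>>"))
  hmm <- cm_to_hmm(cm)
  scorer <- function(s) hmm_viterbi(hmm, s)
  a <- simulate_null_scores(scorer, n = 120, L = 50, seed = 9)
  b <- simulate_null_scores(scorer, n = 120, L = 50, seed = 9)
  d <- simulate_null_scores(scorer, n = 120, L = 50, seed = 10)
  expect_identical(a, b)
  expect_false(all(a == d))
  expect_error(simulate_null_scores(scorer, n = 50, L = 50, seed = 1),
               "n >= 100")
})

test_that("the ML fit recovers known Gumbel parameters and respects affine maps", {
  set.seed(77)
  x <- rgumbel_ref(5000, mu = 3.0, lambda = 0.69)
  g <- fit_gumbel(x)
  expect_lt(abs(g$mu - 3.0), 0.1)
  expect_lt(abs(g$lambda - 0.69) / 0.69, 0.05)
  # Gumbel family closure under affine transforms
  g2 <- fit_gumbel(2 + 1.5 * x)
  expect_equal(g2$mu, 2 + 1.5 * g$mu, tolerance = 1e-6)
  expect_equal(g2$lambda, g$lambda / 1.5, tolerance = 1e-6)
  # minimal sample size still yields finite parameters
  g3 <- fit_gumbel(x[1:100])
  expect_true(is.finite(g3$mu) && is.finite(g3$lambda))
  expect_error(fit_gumbel(rep(1, 200)), "degenerate")
})

test_that("the P-value closed form and E-value scaling behave", {
  g <- gumbel_params(mu = 4, lambda = 0.8, calib_len = 2e5,
                     calib_n = 1000L)
  expect_equal(score_to_pvalue(4, g), 1 - exp(-1), tolerance = 1e-12)
  expect_lt(score_to_pvalue(100, g), 1e-30)
  expect_gt(score_to_pvalue(-100, g), 1 - 1e-12)
  s <- seq(-5, 20, by = 0.5)
  P <- score_to_pvalue(s, g)
  expect_true(all(diff(P) <= 0))
  expect_true(all(diff(P[s >= g$mu]) < 0))  # strict where P < 1
  # E linear in Z, decreasing in S
  p <- score_to_pvalue(8, g)
  expect_equal(pvalue_to_evalue(p, 2e6, g) / pvalue_to_evalue(p, 1e6, g), 2)
  expect_error(score_to_pvalue(1, NULL), "not calibrated")
})

test_that("E-values are self-consistent on the calibration null", {
  cm <- cm_build(fix_aln(c("GGCAAACGCC", "GGCUUUCGCC", "GGGAAACGCC"),
                         "<<<....>>>"))
  hmm <- cm_to_hmm(cm)
  scorer <- function(s) hmm_viterbi(hmm, s)
  cal <- fit_gumbel(simulate_null_scores(scorer, n = 1000, L = 100,
                                         seed = 3),
                    calib_len = 1000 * 100, calib_n = 1000L)
  fresh <- simulate_null_scores(scorer, n = 2000, L = 100, seed = 4)
  # expected counts at E <= t over the fresh sample (Z = total length)
  E <- pvalue_to_evalue(score_to_pvalue(fresh, cal), 2000 * 100, cal)
  for (t in c(20, 100)) {
    expect_gt(sum(E <= t), t / 2)
    expect_lt(sum(E <= t), t * 2)
  }
})

test_that("model calibration is reproducible and round-trips through files", {
  fam <- accepted_family(171)
  cm <- cm_build(covmod:::subset_alignment(fam$aln, fam$split$train))
  c1 <- calibrate_model(cm, n = 150L, L = 80L, seed = 12L)
  c2 <- calibrate_model(cm, n = 150L, L = 80L, seed = 12L)
  expect_identical(c1$calibration, c2$calibration)
  expect_setequal(names(c1$calibration),
                  c("hmm_vit_local", "hmm_fwd_local", "hmm_fwd_glocal",
                    "cm_inside_glocal"))
  f <- tempfile(fileext = ".cm")
  write_cm(c1, f)
  back <- read_cm(f)[[1]]
  expect_identical(back, c1)
  # a calibrated file supports E-values immediately
  g <- back$calibration$cm_inside_glocal
  P <- score_to_pvalue(g$mu + 1, g)
  expect_true(P > 0 && P < 1)
})
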