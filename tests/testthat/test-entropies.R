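cfg <- entropy_config()

test_that("entropy_config enforces its invariants", {
  expect_error(entropy_config(m = 0))
  expect_error(entropy_config(r_frac = 0))
  expect_error(entropy_config(pe_order = 1))
  expect_error(entropy_config(sse_window = 1))
  expect_error(entropy_config(welch_overlap_frac = 1))
})

test_that("shannon helper hits the analytic limits", {
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0, tolerance = 1e-9)
  for (N in c(4, 32, 129)) {
    expect_equal(shannon_entropy(rep(1 / N, N)), log(N), tolerance = 1e-6)
  }
})

test_that("spectral entropy: degenerate, ordering and range", {
  expect_identical(spectral_entropy(rep(0, 512), 128, cfg), 0)
  set.seed(5)
  noise <- rnorm(640)
  expect_gt(spectral_entropy(noise, 128, cfg),
            spectral_entropy(sin_wave(10), 128, cfg))
  psde <- spectral_entropy(noise, 128, cfg)
  expect_gte(psde, 0)
  expect_lte(psde, log(129))  # 256-sample segments -> 129 one-sided bins
})

test_that("singular spectrum entropy: rank-1, sinusoid vs noise, uniform limit", {
  expect_lt(abs(singular_spectrum_entropy(rep(5, 100), cfg)), 1e-9)
  set.seed(6)
  sse_sin <- singular_spectrum_entropy(sin_wave(10), cfg)
  sse_noise <- singular_spectrum_entropy(rnorm(640), cfg)
  expect_lt(sse_sin, log(2) + 0.3)  # two dominant singular values
  expect_gt(sse_noise, sse_sin)
  # oracle: same trajectory matrix, independent svd route
  x <- rnorm(80)
  L <- 10; K <- 80 - 10 + 1
  tr <- sapply(1:K, function(j) x[j:(j + L - 1)])
  sv <- svd(tr)$d
  p <- sv / sum(sv)
  expect_equal(singular_spectrum_entropy(x, cfg),
               -sum(p * log(p + cfg$eps)), tolerance = 1e-12)
})

test_that("sample entropy matches the brute-force oracle and conventions", {
  expect_identical(sample_entropy(rep(5, 100), cfg), 0)
  # the ramp 1:10 has no template matches at r = 0.2*SD: the bounded
  # convention (0, with a warning) must agree with the oracle's
  x <- as.numeric(1:10)
  expect_warning(se_ramp <- sample_entropy(x, cfg), "no template matches")
  expect_equal(se_ramp, oracle_sampen(x, 2, 0.2 * sd(x)), tolerance = 1e-12)
  set.seed(11)
  noise <- rnorm(200)
  periodic <- rep(c(0.1, 0.9, 0.4, 0.6), 50)
  expect_gt(sample_entropy(noise, cfg), sample_entropy(periodic, cfg))
  expect_error(sample_entropy(c(1, 2, 3), cfg), "too short")
})

test_that("fuzzy entropy matches the brute-force oracle", {
  expect_identical(fuzzy_entropy(rep(2, 50), cfg), 0)
  x <- as.numeric(1:10)
  expect_equal(fuzzy_entropy(x, cfg), oracle_fuzzyen(x, 2, 0.2 * sd(x), 2),
               tolerance = 1e-10)
  set.seed(12)
  ramp <- as.numeric(1:100)
  shuffled <- sample(ramp)
  expect_lt(fuzzy_entropy(ramp, cfg), fuzzy_entropy(shuffled, cfg))
})

test_that("approximate entropy matches the brute-force oracle", {
  expect_identical(approximate_entropy(rep(1, 50), cfg), 0)
  x <- as.numeric(1:10)
  expect_equal(approximate_entropy(x, cfg), oracle_apen(x, 2, 0.2 * sd(x)),
               tolerance = 1e-10)
  set.seed(13)
  expect_gt(approximate_entropy(rnorm(512), cfg),
            approximate_entropy(sin_wave(10, secs = 4), cfg))
})

test_that("permutation entropy: analytic limits and hand example", {
  expect_equal(permutation_entropy(as.numeric(1:50), cfg), 0)
  # alternating series visits both order-2 patterns equally
  cfg2 <- entropy_config(pe_order = 2)
  expect_equal(permutation_entropy(c(0, 1, 0, 1, 0), cfg2), log(2),
               tolerance = 1e-12)
  x <- c(4, 7, 9, 10, 6, 11, 3)
  expect_equal(permutation_entropy(x, cfg), oracle_pe(x, 3, 1),
               tolerance = 1e-12)
  set.seed(14)
  expect_lte(permutation_entropy(rnorm(5000), cfg), log(factorial(3)))
  expect_error(permutation_entropy(c(1, 2, 3), cfg), "too short")
})

test_that("embedding entropies equal their oracles on random sequences", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- c(60, 120, 200)[seed]
    x <- rnorm(n)
    r <- 0.2 * sd(x)
    expect_equal(sample_entropy(x, cfg), oracle_sampen(x, 2, r),
                 tolerance = 1e-10)
    expect_equal(fuzzy_entropy(x, cfg), oracle_fuzzyen(x, 2, r, 2),
                 tolerance = 1e-10)
    expect_equal(approximate_entropy(x, cfg), oracle_apen(x, 2, r),
                 tolerance = 1e-10)
    expect_equal(permutation_entropy(x, cfg), oracle_pe(x, 3, 1),
                 tolerance = 1e-10)
  }
})

test_that("scale behavior: monotone invariance (PE), affine invariance (SE/FE/AE)", {
  set.seed(21)
  x <- rnorm(150)
  expect_equal(permutation_entropy(exp(x), cfg), permutation_entropy(x, cfg),
               tolerance = 1e-9)
  expect_equal(permutation_entropy(x^3 + 2, cfg), permutation_entropy(x, cfg),
               tolerance = 1e-9)
  y <- 3.7 * x - 11
  expect_equal(sample_entropy(y, cfg), sample_entropy(x, cfg),
               tolerance = 1e-9)
  expect_equal(fuzzy_entropy(y, cfg), fuzzy_entropy(x, cfg),
               tolerance = 1e-9)
  expect_equal(approximate_entropy(y, cfg), approximate_entropy(x, cfg),
               tolerance = 1e-9)
})

test_that("all six entropies are finite, nonnegative, and rank noise over a tone", {
  set.seed(22)
  noise <- rnorm(640)
  tone <- sin_wave(10)
  pn <- entropy_profile(noise, fs = 128, cfg)
  pt <- entropy_profile(tone, fs = 128, cfg)
  expect_true(all(is.finite(pn)) && all(is.finite(pt)))
  expect_true(all(pn >= -1e-9) && all(pt >= -1e-9))
  expect_true(all(pn > pt))
  expect_named(pn, c("AE", "FE", "SE", "PE", "SSE", "PSDE"))
})
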