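# trapezoidal numerical oracle for the filtered squared difference
vr_oracle <- function(ta, tb, tau, dt = NULL) {
  if (is.null(dt)) dt <- 0.001 * tau
  t_end <- max(c(ta, tb, 0)) + 30 * tau
  grid <- seq(0, t_end, by = dt)
  filt <- function(tt) {
    f <- numeric(length(grid))
    for (ti in tt) f <- f + ifelse(grid >= ti, exp(-(grid - ti) / tau), 0)
    f
  }
  d2 <- (filt(ta) - filt(tb))^2
  sum((d2[-1] + d2[-length(d2)]) / 2) * dt / tau
}

test_that("binning maps spike trains to the digital code", {
  tr <- spike_train(c(0, 1, 2), 200)
  b <- bin_train(tr, 5)
  expect_equal(length(b$bits), 40)
  expect_equal(b$bits[1], 1L)
  expect_equal(sum(b$bits), 1L)  # all three spikes share bin 0

  expect_equal(sum(bin_train(spike_train(integer(), 200), 5)$bits), 0L)

  # half-open windows: spike at 5 ms belongs to bin 2, not bin 1
  b2 <- bin_train(spike_train(c(4, 5), 20), 5)
  expect_equal(b2$bits, c(1L, 1L, 0L, 0L))

  expect_error(bin_train(spike_train(1, 200), 7), "not divisible")
})

test_that("re-binning a 1-ms-coded train with W = 1 is the identity", {
  set.seed(3)
  tr <- generate_poisson_train(80, 100)
  expect_equal(bin_train(tr, 1)$bits, as_binary(tr))
})

test_that("van Rossum distance reproduces closed-form single-spike values", {
  empty <- spike_train(integer(), 100)
  one <- spike_train(10, 100)
  expect_equal(van_rossum_distance(one, one, tau_c = 15), 0)
  expect_equal(van_rossum_distance(one, empty, tau_c = 15), 0.5, tolerance = 1e-9)
  # far-separated spikes contribute two independent halves
  far <- van_rossum_distance(spike_train(5, 2000), spike_train(1900, 2000),
                             tau_c = 15)
  expect_equal(far, 1, tolerance = 1e-4)
})

test_that("closed-form distance agrees with trapezoidal numerical integration", {
  set.seed(9)
  for (rep in 1:5) {
    ta <- sort(sample(0:199, sample(3:12, 1)))
    tb <- sort(sample(0:199, sample(3:12, 1)))
    tau <- sample(c(3, 15, 25), 1)
    expect_equal(
      van_rossum_distance(ta, tb, tau_c = tau),
      vr_oracle(ta, tb, tau),
      tolerance = 1e-3
    )
  }
})

test_that("distance is a pseudometric with the displacement property", {
  set.seed(4)
  for (rep in 1:10) {
    a <- sort(sample(0:199, 8)); b <- sort(sample(0:199, 8))
    c_ <- sort(sample(0:199, 8))
    dab <- van_rossum_distance(a, b, tau_c = 15)
    expect_gte(dab, 0)
    expect_equal(dab, van_rossum_distance(b, a, tau_c = 15))
    # triangle inequality on the induced norm (sqrt of the quadratic form)
    expect_lte(sqrt(dab),
               sqrt(van_rossum_distance(a, c_, tau_c = 15)) +
                 sqrt(van_rossum_distance(c_, b, tau_c = 15)) + 1e-9)
  }
  # a spurious spike moved toward its counterpart shrinks the distance
  d_seq <- sapply(c(80, 60, 40, 20, 5), function(pos) {
    van_rossum_distance(c(100), c(100 + pos), tau_c = 15)
  })
  expect_true(all(diff(d_seq) < 0))
})

test_that("distance sensitivity to spike timing falls with tau_c", {
  # a displaced spike costs 1 - exp(-dt/tau_c): larger tau_c, smaller cost
  a <- c(20, 60, 100)
  b <- c(20, 60, 105)
  d5 <- van_rossum_distance(a, b, tau_c = 5)
  d25 <- van_rossum_distance(a, b, tau_c = 25)
  expect_gt(d5, d25)
  expect_equal(d5, 1 - exp(-1), tolerance = 1e-6)
  expect_equal(d25, 1 - exp(-5 / 25), tolerance = 1e-6)
  # an inserted spike far from all others always costs 1/2, at any tau_c
  expect_equal(van_rossum_distance(c(20), c(20, 150), tau_c = 5), 0.5,
               tolerance = 1e-6)
  expect_equal(van_rossum_distance(c(20), c(20, 150), tau_c = 25), 0.5,
               tolerance = 1e-3)
})

test_that("binned-train distances use the bin-index grid with tau_c in bins", {
  F <- binned_train(c(1, rep(0, 39)), 5)
  G <- binned_train(rep(0, 40), 5)
  # single unmatched high bin contributes 1/2 regardless of the grid units
  expect_equal(van_rossum_distance(F, G, tau_c = 15), 0.5, tolerance = 1e-9)
  # one bin of displacement costs 1 - exp(-W / tau_c): tau_c = 15 ms over
  # W = 5 ms bins is 3 bin units
  F2 <- binned_train(tabulate(c(1, 4), 40), 5)
  G2 <- binned_train(tabulate(c(1, 5), 40), 5)
  expect_equal(van_rossum_distance(F2, G2, tau_c = 15), 1 - exp(-1 / 3),
               tolerance = 1e-9)
})

test_that("grid evaluation of the distance approaches the exact value", {
  a <- c(10, 50); b <- c(30)
  exact <- van_rossum_distance(a, b, tau_c = 15)
  expect_equal(van_rossum_distance(a, b, tau_c = 15, dt_eval = 0.01), exact,
               tolerance = 1e-2)
})

test_that("max cross-correlation detects identity, shifts, and anticorrelation", {
  set.seed(14)
  bits <- c(rep(0, 6), rbinom(26, 1, 0.4), rep(0, 8))
  F <- binned_train(bits, 5)
  expect_equal(max_crosscorr(F, F), 1, tolerance = 1e-9)

  shifted <- binned_train(c(rep(0L, 2), bits[1:38]), 5)
  expect_equal(max_crosscorr(F, shifted), 1, tolerance = 1e-9)
  expect_equal(max_crosscorr(F, shifted, method = "pearson"), 1,
               tolerance = 1e-9)

  # complement is anticorrelated at lag 0 under the Pearson reading
  comp <- binned_train(1L - bits, 5)
  sm <- function(v) {
    k <- dnorm(-4:4); k <- k / sum(k)
    as.numeric(stats::filter(c(numeric(4), v, numeric(4)), k, sides = 2)[4 + seq_along(v)])
  }
  expect_lt(cor(sm(bits), sm(1 - bits)), 0)

  expect_warning(z <- max_crosscorr(binned_train(rep(0, 40), 5), F),
                 "zero-variance")
  expect_equal(z, 0)
})

test_that("cross-correlation maximum lies in the admissible range", {
  set.seed(15)
  for (rep in 1:10) {
    F <- binned_train(rbinom(40, 1, 0.3), 5)
    G <- binned_train(rbinom(40, 1, 0.3), 5)
    x <- suppressWarnings(max_crosscorr(F, G))
    expect_true(x >= -1 && x <= 1)
    xp <- suppressWarnings(max_crosscorr(F, G, method = "pearson"))
    expect_true(xp >= -1 && xp <= 1)
  }
})

test_that("hit rate counts agreeing ones and zeros", {
  F <- binned_train(rep(c(1L, 0L), 20), 5)
  expect_equal(hit_rate(F, F), 100)
  expect_equal(hit_rate(binned_train(rep(1, 40), 5),
                        binned_train(rep(0, 40), 5)), 0)
  G <- F
  G$bits[1:6] <- 1L - G$bits[1:6]
  expect_equal(hit_rate(F, G), 100 * 34 / 40)
  expect_error(hit_rate(F, binned_train(rep(1, 20), 5)), "equal length")
})
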