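test_that("noise-free power-law data are recovered exactly", {
  x <- c(0.01, 1, 100, 1e4)
  fit <- fitPowerLaw(x, 2 * x^0.5)
  expect_equal(exponent(fit), 0.5, tolerance = 1e-10)
  expect_equal(normConst(fit), 2, tolerance = 1e-10)
  expect_equal(rSquared(fit), 1, tolerance = 1e-10)
  expect_lt(fit@exponentSE, 1e-7)
  expect_equal(fit@df, 2L)
  # two-column data.frame input
  fit2 <- fitPowerLaw(data.frame(x = x, y = 2 * x^0.5))
  expect_equal(exponent(fit2), exponent(fit))
})

test_that("degenerate fitting inputs are rejected", {
  expect_error(fitPowerLaw(c(1, 2, -3), c(1, 2, 3)), "positive")
  expect_error(fitPowerLaw(c(1, 2, 3), c(1, 0, 3)), "positive")
  expect_error(fitPowerLaw(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fitPowerLaw(c(5, 5, 5), c(1, 2, 3)), "zero variance")
})

test_that("fits are scale-equivariant: x -> kx leaves b, divides a by k^b", {
  set.seed(11)
  x <- exp(runif(40, -3, 8))
  y <- 3.2 * x^0.71 * exp(rnorm(40, sd = 0.4))
  base <- fitPowerLaw(x, y)
  for (k in c(1e-3, 0.5, 7, 1e4)) {
    scaled <- fitPowerLaw(k * x, y)
    expect_equal(exponent(scaled), exponent(base), tolerance = 1e-9)
    expect_equal(normConst(scaled), normConst(base) / k^exponent(base),
                 tolerance = 1e-9)
    expect_equal(rSquared(scaled), rSquared(base), tolerance = 1e-9)
  }
})

test_that("slope and intercept agree with exact-arithmetic normal equations", {
  # small integer datasets in ln space; the package path goes through
  # exp() / log() and lm(), the oracle through integer sums
  cases <- list(list(u = c(0L, 1L, 2L), v = c(1L, 3L, 4L)),
                list(u = c(-2L, 0L, 1L, 5L), v = c(7L, 2L, 0L, -4L)),
                list(u = c(1L, 2L, 3L, 4L, 5L), v = c(2L, 2L, 5L, 4L, 9L)),
                list(u = c(-3L, -1L, 0L, 2L, 4L, 6L),
                     v = c(10L, 4L, 5L, 1L, -2L, -5L)))
  for (cs in cases) {
    exact <- oracleIntegerLine(cs$u, cs$v)
    fit <- fitPowerLaw(exp(cs$u), exp(cs$v))
    expect_equal(exponent(fit), exact$slope, tolerance = 1e-9)
    expect_equal(fit@lnIntercept, exact$intercept, tolerance = 1e-9)
  }
})

test_that("delta-method SE of the constant matches a * se(intercept)", {
  set.seed(4)
  x <- exp(runif(30, 0, 10))
  fit <- fitPowerLaw(x, 9.58 * x^(2 / 3) * exp(rnorm(30, sd = 0.5)))
  expect_equal(fit@normConstSE, fit@normConst * fit@lnInterceptSE)
  expect_true(fit@exponentSE > 0 && fit@lnInterceptSE > 0)
})

test_that("parameter recovery: simulated scatter around the scaling law", {
  set.seed(107)
  n <- 107
  x <- exp(runif(n, log(1e-2), log(1e7)))
  y <- 9.58 * x^(2 / 3) * exp(rnorm(n, sd = 1.61))
  fit <- fitPowerLaw(x, y)
  expect_lt(abs(exponent(fit) - 2 / 3), 3 * fit@exponentSE)
})

test_that("comparing a fit with itself gives t = 0, p = 1", {
  set.seed(2)
  x <- exp(runif(25, 0, 6))
  fit <- fitPowerLaw(x, 2 * x^0.8 * exp(rnorm(25, sd = 0.3)))
  cmp <- compareSlopes(fit, fit)
  expect_equal(cmp@statistic, 0)
  expect_equal(cmp@pValue, 1)
  expect_equal(cmp@df, 2L * 25L - 4L)
})

test_that("slope comparison is symmetric: swapping fits negates t", {
  set.seed(3)
  x <- exp(runif(30, 0, 6))
  f1 <- fitPowerLaw(x, 2 * x^0.5 * exp(rnorm(30, sd = 0.3)))
  f2 <- fitPowerLaw(x, 2 * x^0.9 * exp(rnorm(30, sd = 0.3)))
  a <- compareSlopes(f1, f2)
  b <- compareSlopes(f2, f1)
  expect_equal(a@statistic, -b@statistic)
  expect_equal(a@pValue, b@pValue)
})

test_that("slope test agrees with the lm interaction parameterization", {
  # independent route: one pooled regression with a group x slope
  # interaction reproduces the pooled-variance two-slope t test
  set.seed(8)
  x1 <- exp(runif(22, 0, 7)); y1 <- 3 * x1^0.6 * exp(rnorm(22, sd = 0.4))
  x2 <- exp(runif(31, -2, 5)); y2 <- 5 * x2^0.8 * exp(rnorm(31, sd = 0.3))
  cmp <- compareSlopes(fitPowerLaw(x1, y1), fitPowerLaw(x2, y2))
  dat <- data.frame(lx = log(c(x1, x2)), ly = log(c(y1, y2)),
                    g = rep(c(0, 1), c(22, 31)))
  sm <- summary(lm(ly ~ lx * g, data = dat))$coefficients
  expect_equal(abs(cmp@statistic), abs(sm["lx:g", "t value"]),
               tolerance = 1e-9)
  expect_equal(cmp@pValue, sm["lx:g", "Pr(>|t|)"], tolerance = 1e-9)
  expect_equal(cmp@df, 22L + 31L - 4L)
})

test_that("the slope test reliably separates exponents 0.5 and 1.0", {
  # power check: 6 decades of x, ln-noise 0.3, n = 50 per group
  set.seed(500)
  rejected <- vapply(seq_len(200), function(r) {
    x1 <- exp(runif(50, 0, log(1e6)))
    x2 <- exp(runif(50, 0, log(1e6)))
    f1 <- fitPowerLaw(x1, 2 * x1^0.5 * exp(rnorm(50, sd = 0.3)))
    f2 <- fitPowerLaw(x2, 2 * x2^1.0 * exp(rnorm(50, sd = 0.3)))
    compareSlopes(f1, f2)@pValue < 0.001
  }, logical(1))
  expect_equal(mean(rejected), 1)
})

test_that("dataset filters reproduce the standard exclusion rules", {
  tab <- data.frame(taxon_id = c("a", "b", "c", "d", "e"),
                    domain = c("bacteria", "archaea", "eukaryote",
                               "eukaryote", NA),
                    volume_um3 = c(1, 5, 19, 3000, 2),
                    rrn_per_cell = c(1, 2, 3, 800, NA))
  # boundary inclusive of removal: rc <= 2 goes
  f1 <- filterTraits(tab, "exclude_rc_leq")
  expect_setequal(f1$taxon_id, c("c", "d", "e"))
  # rule applies to eukaryotes only
  f2 <- filterTraits(tab, "exclude_euk_below_v")
  expect_setequal(f2$taxon_id, c("a", "b", "d", "e"))
  f3 <- filterTraits(tab, "domain_only", label = "eukaryote")
  expect_setequal(f3$taxon_id, c("c", "d"))
  f4 <- filterTraits(tab, "domain_only", label = "prokaryote")
  expect_setequal(f4$taxon_id, c("a", "b"))
  expect_error(filterTraits(tab, "keep_everything"))
  expect_error(filterTraits(tab, "domain_only"), "label")
  # input is not mutated
  expect_equal(nrow(tab), 5)
})
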