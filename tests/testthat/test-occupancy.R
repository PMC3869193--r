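# Poisson occupancy statistics: forward pmf, tails, inverse design,
# sampling. Expected values come from closed forms evaluated directly and
# from a Monte-Carlo oracle, never from the functions under test.

test_that("pmf matches the direct closed form and a Monte-Carlo oracle", {
  # closed form e^-lambda lambda^k / k! evaluated by hand
  for (lambda in c(0.25, 1, 4)) {
    for (k in 0:5) {
      expect_equal(occupancy_pmf(k, occupancy_model(lambda)),
                   exp(-lambda) * lambda^k / factorial(k), tolerance = 1e-12)
    }
  }
  expect_equal(occupancy_pmf(0, occupancy_model(0)), 1)
  # Monte-Carlo oracle at the marine dilution: 1e7 draws, 3 standard errors
  set.seed(42)
  draws <- rpois(1e7, 0.25)
  p2_mc <- mean(draws == 2)
  se <- sqrt(p2_mc * (1 - p2_mc) / 1e7)
  expect_lt(abs(occupancy_pmf(2, 0.25) - p2_mc), 3 * se)
  # large-lambda loading must not overflow
  expect_true(is.finite(occupancy_pmf(1000, occupancy_model(1000))))
  expect_gt(occupancy_pmf(1000, occupancy_model(1000)), 0.01)
})

test_that("pmf rejects invalid counts and negative parameters", {
  expect_error(occupancy_pmf(-1, 1), "non-negative")
  expect_error(occupancy_pmf(1.5, 1), "integer")
  expect_error(occupancy_model(-0.1), ">= 0")
  expect_error(lambda_from_loading(-1, 1), ">= 0")
  expect_error(lambda_from_loading(1, 0), "> 0")
})

test_that("lambda is concentration times volume", {
  expect_identical(lambda_from_loading(1, 1), 1)
  expect_identical(lambda_from_loading(0, 1), 0)
  expect_identical(lambda_from_loading(1e3, 1), 1000)
  expect_equal(lambda_from_loading(0.5, 2), 1)
})

test_that("multicell tail equals its closed form and increases with lambda", {
  expect_identical(multicell_probability(occupancy_model(0)), 0)
  expect_equal(multicell_probability(0.25), 1 - exp(-0.25) * 1.25,
               tolerance = 1e-12)
  expect_equal(multicell_probability(1), 1 - 2 * exp(-1), tolerance = 1e-12)
  lams <- seq(0.05, 5, by = 0.05)
  expect_true(all(diff(vapply(lams, multicell_probability, 0)) > 0))
})

test_that("occupancy table sums to one under adaptive truncation", {
  for (lambda in c(0, 0.25, 1, 10, 1000)) {
    tab <- occupancy_table(occupancy_model(lambda))
    expect_lt(abs(sum(tab$probability) - 1), 1e-9)
    expect_equal(tab$percent, 100 * tab$probability)
  }
})

test_that("single-fraction solver inverts the pmf on both branches", {
  # maximizer: the fraction e^-1 is attained only at lambda = 1
  expect_equal(solve_lambda_for_single_fraction(exp(-1), "low"), 1)
  expect_equal(solve_lambda_for_single_fraction(exp(-1), "high"), 1)
  # forward-evaluate then invert
  expect_equal(solve_lambda_for_single_fraction(0.25 * exp(-0.25), "low"),
               0.25, tolerance = 1e-9)
  # independent root for 20% single-cell occupancy (uniroot oracle)
  oracle <- stats::uniroot(function(l) l * exp(-l) - 0.2,
                           c(1e-9, 1), tol = 1e-12)$root
  expect_equal(solve_lambda_for_single_fraction(0.2, "low"), oracle,
               tolerance = 1e-8)
  # inverse consistency across the feasible range, both branches
  for (p in c(0.01, 0.05, 0.1, 0.2, 0.3, exp(-1) - 1e-6)) {
    for (br in c("low", "high")) {
      lam <- solve_lambda_for_single_fraction(p, br)
      expect_lt(abs(occupancy_pmf(1, lam) - p), 1e-9)
      if (br == "low") expect_lte(lam, 1) else expect_gte(lam, 1)
    }
  }
  expect_error(solve_lambda_for_single_fraction(0.4), "infeasible")
  expect_error(solve_lambda_for_single_fraction(0), "> 0")
})

test_that("sampled counts reproduce the model moments and tail", {
  model <- occupancy_model(1)
  x <- sample_counts(model, 1e5, seed = 7)
  expect_identical(x, sample_counts(model, 1e5, seed = 7))  # reproducible
  expect_lt(abs(mean(x) - 1), 3 * sqrt(1 / 1e5))
  expect_lt(abs(var(x) - 1), 3 * sqrt(2 / 1e5))  # var of Poisson variance est ~ 2 lambda^2/n
  expect_true(all(sample_counts(occupancy_model(0), 100, seed = 1) == 0L))
  # multicell fraction at the marine dilution
  y <- sample_counts(occupancy_model(0.25), 1e5, seed = 11)
  p <- multicell_probability(0.25)
  expect_lt(abs(mean(y >= 2) - p), 3 * sqrt(p * (1 - p) / 1e5))
})
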