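test_that("psychometric evaluation matches quadrature of its integrand", {
  expect_equal(psychometric_eval(1.3, 0.15, 0), 0)
  # symmetry: r = a gives one Gaussian half (minus the negligible r<0 mass)
  expect_lt(abs(psychometric_eval(1.3, 0.13, 1.3) - 0.5), 1e-12)
  # saturation: the asymptote is 1 - Phi(-a/b), within 1e-12 of 1 for a/b = 10
  expect_lt(abs(psychometric_eval(1.5, 0.15, 1e6) - 1), 1e-12)
  expect_error(psychometric_eval(1.3, 0, 1), "`b` must be > 0")

  set.seed(4)
  for (i in 1:50) {
    a <- runif(1, 0.8, 2); b <- runif(1, 0.05, 0.6); r <- runif(1, 0, 3)
    expect_equal(psychometric_eval(a, b, r), quad_psy(a, b, r),
                 tolerance = 1e-9)
  }
})

test_that("psychometric function is nondecreasing in r and decreasing in a", {
  set.seed(6)
  for (i in 1:20) {
    a <- runif(1, 0.8, 2); b <- runif(1, 0.05, 0.6)
    r <- sort(runif(8, 0, 3))
    expect_true(all(diff(psychometric_eval(a, b, r)) >= 0))
    expect_gte(psychometric_eval(a, b, 1.5), psychometric_eval(a + 0.3, b, 1.5))
  }
})

test_that("binomial ML fit recovers generating parameters and is exchangeable", {
  r <- 1.19^(0:4)
  set.seed(11)
  n <- rep(2000L, 5)
  k <- rbinom(5, n, psychometric_eval(1.3, 0.15, r))
  d <- tibble::tibble(r = r, k = k, n = n)
  fit <- fit_psychometric(d)
  expect_true(fit$converged)
  expect_lt(abs(fit$a - 1.3) / 1.3, 0.05)
  expect_lt(abs(fit$b - 0.15) / 0.15, 0.10)

  # permuting the level rows changes nothing
  fit2 <- fit_psychometric(d[c(3, 1, 5, 2, 4), ])
  expect_equal(fit2$a, fit$a)
  expect_equal(fit2$b, fit$b)

  # the optimum is at least as good as the moment-based start
  ll <- function(a, b) {
    p <- pmin(pmax(psychometric_eval(a, b, d$r), 1e-12), 1 - 1e-12)
    sum(d$k * log(p) + (d$n - d$k) * log(1 - p))
  }
  expect_gte(fit$loglik, ll(mean(range(r)), diff(range(r)) / 4))

  td <- tidy(fit)
  expect_identical(td$term, c("a", "b"))
  expect_equal(glance(fit)$n_trials, 10000)
})

test_that("recovery error shrinks as trials per level grow", {
  r <- 1.19^(0:4)
  err <- vapply(c(20, 200, 2000), function(n_per) {
    set.seed(n_per)
    mean(vapply(1:8, function(i) {
      k <- rbinom(5, n_per, psychometric_eval(1.3, 0.15, r))
      f <- suppressWarnings(fit_psychometric(tibble::tibble(r = r, k = k, n = n_per)))
      abs(f$a - 1.3)
    }, numeric(1)))
  }, numeric(1))
  expect_true(err[3] < err[1])
  expect_lt(err[3], 0.02)
})

test_that("flat data are flagged non-identifiable", {
  d <- tibble::tibble(r = 1.19^(0:4), k = c(5, 5, 5, 5, 5), n = 10)
  expect_warning(fit <- fit_psychometric(d), "not identifiable")
  expect_false(fit$converged)
  expect_error(fit_psychometric(tibble::tibble(r = c(1, 1.19), k = 1, n = 2)),
               "3 distinct levels")
})

test_that("least-squares option agrees with ML on clean data", {
  r <- 1.19^(0:4)
  set.seed(21)
  k <- rbinom(5, 5000, psychometric_eval(1.3, 0.15, r))
  d <- tibble::tibble(r = r, k = k, n = 5000)
  f_ml <- fit_psychometric(d)
  f_ls <- fit_psychometric(d, least_squares = TRUE)
  expect_lt(abs(f_ml$a - f_ls$a), 0.02)
  expect_lt(abs(f_ml$b - f_ls$b), 0.02)
})

test_that("session QC applies both press-ratio criteria strictly", {
  ok <- tibble::tibble(level_n = 0:4, ratio = c(0.05, 0.2, 0.5, 0.9, 0.95))
  expect_true(session_qc(ok)$keep)

  bad0 <- ok; bad0$ratio[1] <- 0.12
  q0 <- session_qc(bad0)
  expect_false(q0$keep)
  expect_match(q0$reasons, "correct-rejection")

  # boundary: exactly 0.85 fails the strict 'greater than' criterion
  bad4 <- ok; bad4$ratio[5] <- 0.85
  expect_false(session_qc(bad4)$keep)
  expect_match(session_qc(bad4)$reasons, "hit criterion")

  expect_error(session_qc(tibble::tibble(level_n = 1:4, ratio = 0.5)),
               "control level")

  # a well-trained simulated subject passes QC
  s <- tiny_oddball(seed = 2, n_blocks_per_level = 12)
  expect_true(session_qc(s)$keep)
})
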