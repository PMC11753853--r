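test_that("OLS fit recovers exact lines and matches direct summation", {
  f <- linear_fit_r2(1:5, 2 * (1:5) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  # constant response: R^2 = 0 by convention
  expect_equal(linear_fit_r2(1:4, rep(3, 4))$r_squared, 0)

  # independent arithmetic oracle: direct sums
  x <- c(1, 2, 3, 4); y <- c(1.1, 1.9, 3.2, 3.8)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta <- sxy / sxx
  alpha <- mean(y) - beta * mean(x)
  ss_res <- sum((y - alpha - beta * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  f2 <- linear_fit_r2(x, y)
  expect_equal(f2$slope, beta)
  expect_equal(f2$intercept, alpha)
  expect_equal(f2$r_squared, 1 - ss_res / ss_tot)

  # R^2 invariant to affine rescaling of x
  f3 <- linear_fit_r2(10 * x + 7, y)
  expect_equal(f3$r_squared, f2$r_squared)

  expect_error(linear_fit_r2(1:2, 1:2), "at least 3")
  expect_error(linear_fit_r2(rep(1, 4), 1:4), "degenerate")
})

test_that("percent change follows 100 (ref - value)/ref", {
  expect_equal(percent_change(14, 10), 100 * 4 / 14)
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(10, 0), 100)
  expect_error(percent_change(0, 1), "reference")
  expect_error(percent_change(-3, 1), "reference")
})

test_that("sweep configs are validated", {
  base <- scenario("b", gap_geometry(1500, 1000, 100, large_groove()),
                   pressure_bc(300))
  expect_error(sweep_config("delta_p", 100, base), "at least 2")
  expect_error(sweep_config("delta_p", c(100, 100), base), "distinct")
  expect_error(sweep_config("gap_height", c(-1, 100), base), "positive")
  nocrack <- scenario("n", gap_geometry(1500, 1000, 100), pressure_bc(300))
  expect_error(sweep_config("crack_depth", c(10, 20), nocrack), "crack")
})

test_that("a pressure sweep returns ordered rows with increasing peaks", {
  base <- scenario("b", gap_geometry(1500, 100, 100, large_groove()),
                   pressure_bc(300))
  sw <- run_sweep(sweep_config("delta_p", c(50, 200), base),
                  mesh_size_um = 50, n_samples = 64)
  expect_s3_class(sw, "sweep_result")
  expect_equal(sw$value, c(50, 200))
  expect_true(all(sw$converged))
  expect_gt(sw$peak_fss_pa[2], sw$peak_fss_pa[1])
  expect_length(attr(sw, "profiles"), 2L)
})

test_that("crack invariance check passes identical peaks and fails outliers", {
  mk <- function(peaks) {
    out <- data.frame(value = seq_along(peaks), peak_fss_pa = peaks,
                      reynolds = 1, converged = TRUE)
    class(out) <- c("sweep_result", "data.frame")
    out
  }
  same <- crack_invariance_check(mk(c(10, 10, 10)), mk(c(10, 10, 10)))
  expect_true(same$pass)
  expect_equal(same$max_spread_pct, 0)
  bad <- crack_invariance_check(mk(c(10, 10, 20)), mk(c(10, 10, 10)))
  expect_false(bad$pass)
  uncv <- mk(c(10, 10)); uncv$converged[2] <- FALSE
  expect_error(crack_invariance_check(uncv, mk(c(10, 10))), "converged")
})

test_that("the reproduction driver is complete and deterministic", {
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  r1 <- reproduce_paper(d1, mesh_size_um = 50, widths = c(800, 100),
                        n_samples = 64, quiet = TRUE)
  r2 <- reproduce_paper(d2, mesh_size_um = 50, widths = c(800, 100),
                        n_samples = 64, quiet = TRUE)
  # every reported quantity of the study is present
  expect_true(is.finite(r1$pressure$fit$r_squared))
  expect_true(is.finite(r1$height$fit$r_squared))
  expect_true(is.finite(r1$height$peak_at_1000))
  expect_true(is.finite(r1$width$percent_drop_800_to_100))
  expect_true(is.logical(r1$crack$invariance$pass))
  expect_length(r1$gradients, 3L)
  # identical config -> bitwise-identical result tables
  for (study in c("pressure", "height", "width", "crack_depth",
                  "crack_width", "gradients")) {
    p1 <- file.path(d1, study, "peaks.tsv")
    if (file.exists(p1))
      expect_identical(readLines(p1),
                       readLines(file.path(d2, study, "peaks.tsv")))
    g1 <- file.path(d1, study, "profiles.tsv")
    expect_identical(readLines(g1),
                     readLines(file.path(d2, study, "profiles.tsv")))
  }
})
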