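test_that("standardize centers and scales with the sample-sd convention", {
  expect_equal(as.numeric(standardize(c(1, 2, 3))), c(-1, 0, 1))
  z <- standardize(rnorm(50, 10, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  # idempotent on already-standardized input
  expect_equal(as.numeric(standardize(as.numeric(z))), as.numeric(z),
               tolerance = 1e-8)
  expect_error(standardize(c(5, 5, 5)), "constant")
})

test_that("inverse normal transform maps ranks to normal quantiles", {
  expect_equal(inverse_normal_transform(c(3, 1, 2)),
               qnorm(c(5, 1, 3) / 6))
  x <- c(0.3, 2.5, 0.01, 7, 1)
  # rank invariance under strictly monotone transforms
  expect_equal(inverse_normal_transform(x), inverse_normal_transform(log(x)))
  expect_equal(inverse_normal_transform(x), inverse_normal_transform(rank(x)))
  # reversal symmetry of the normal quantile function
  expect_equal(inverse_normal_transform(rev(x)),
               rev(inverse_normal_transform(x)))
  expect_equal(inverse_normal_transform(-x), -inverse_normal_transform(x))
  # average ranks for ties
  t3 <- inverse_normal_transform(c(1, 1, 2))
  expect_equal(t3[1], t3[2])
  expect_error(inverse_normal_transform(c(1, 1, 1)), "all-tied")
  expect_error(inverse_normal_transform(c(1, 2)), "at least 3")
})

test_that("association fit matches lm() and flags singular designs", {
  set.seed(101)
  n <- 96
  d <- tibble::tibble(
    sex = rep(0:1, n / 2), age = runif(n, 20, 80),
    ev = runif(n), bmi = rnorm(n)
  )
  f <- fit_association(d, "bmi", "ev")
  x <- inverse_normal_transform(d$ev)
  y <- as.numeric(standardize(d$bmi))
  ref <- lm(y ~ x + sex + age + x:sex, data = d)
  expect_equal(unname(f$coefficients[, 1]), unname(coef(ref)[c(1, 2, 3, 4, 5)]),
               tolerance = 1e-12)
  expect_equal(f$n, n)
  td <- tidy(f)
  expect_equal(td$term[2], "beta_EV")
  expect_true(all(td$p.value >= 0 & td$p.value <= 1))
  gl <- glance(f)
  expect_true(gl$partial.r2 >= 0 && gl$partial.r2 <= 1)
  expect_true(gl$r.squared >= gl$partial.r2)
  # constant sex -> singular design naming the column
  d2 <- dplyr::mutate(d, sex = 1)
  expect_error(fit_association(d2, "bmi", "ev"), "sex")
})

test_that("regression is invariant to affine rescaling of age", {
  set.seed(55)
  n <- 80
  d <- tibble::tibble(sex = rep(0:1, n / 2), age = runif(n, 20, 80),
                      ev = runif(n), wc = rnorm(n) + 0.3 * runif(n))
  f1 <- fit_association(d, "wc", "ev")
  d2 <- dplyr::mutate(d, age = (age - 50) / 10)
  f2 <- fit_association(d2, "wc", "ev")
  expect_equal(f1$coefficients["beta_EV", ], f2$coefficients["beta_EV", ],
               tolerance = 1e-10)
  expect_equal(f1$coefficients["beta_Age", 4], f2$coefficients["beta_Age", 4],
               tolerance = 1e-10)
  expect_equal(f1$coefficients["beta_Age", 1] * 10,
               f2$coefficients["beta_Age", 1], tolerance = 1e-10)
})

test_that("null interaction coefficient is centered at zero", {
  set.seed(202)
  n <- 96
  reps <- 1000
  est <- replicate(reps, {
    d <- tibble::tibble(sex = rep(0:1, n / 2), age = runif(n, 20, 80),
                        ev = runif(n), y = 0.5 * inverse_normal_transform(ev) + rnorm(n))
    fit_association(d, "y", "ev",
                    standardize_trait = FALSE)$coefficients["beta_EV_by_sex", 1]
  })
  expect_lt(abs(mean(est)), 2 * sd(est) / sqrt(reps))
})

test_that("pair exposures with larger true effects give smaller median P", {
  set.seed(404)
  n <- 96
  med_p <- function(beta) {
    median(replicate(120, {
      d <- tibble::tibble(sex = rep(0:1, n / 2), age = runif(n, 20, 80),
                          ev = runif(n))
      d$y <- beta * inverse_normal_transform(d$ev) + rnorm(n, 0, 2.26)
      fit_association(d, "y", "ev",
                      standardize_trait = FALSE)$coefficients["beta_EV", 4]
    }))
  }
  # single-type effect magnitude vs the stronger pair-type magnitude
  expect_lt(med_p(-2.31), med_p(-1.62))
})

test_that("BH adjustment matches hand-computed and oracle step-up values", {
  res <- tibble::tibble(trait = "BMI", p = c(0.01, 0.02, 0.03))
  expect_equal(fdr_adjust(res)$q, c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(tibble::tibble(trait = "t", p = 0.4))$q, 0.4)
  expect_equal(fdr_adjust(tibble::tibble(trait = "t", p = rep(0.2, 4)))$q,
               rep(0.2, 4))
  expect_error(fdr_adjust(tibble::tibble(trait = "t", p = c(0.5, 1.2))),
               "\\[0, 1\\]")
  set.seed(88)
  for (rep in 1:100) {
    p <- runif(sample(3:40, 1))
    q <- fdr_adjust(tibble::tibble(trait = "t", p = p))$q
    expect_equal(q, bh_stepup_oracle(p))
  }
})

test_that("per-analysis FDR adjusts within trait families", {
  res <- tibble::tibble(
    trait = rep(c("BMI", "WC"), each = 3),
    p = c(0.01, 0.02, 0.03, 0.2, 0.4, 0.6)
  )
  out <- fdr_adjust(res, family = "per_analysis")
  expect_equal(out$q[out$trait == "BMI"], rep(0.03, 3))
  expect_equal(out$q[out$trait == "WC"], c(0.6, 0.6, 0.6))
})

test_that("positive interaction with male=1 coding weakens the effect in men", {
  set.seed(777)
  n <- 2000
  sex <- rep(0:1, n / 2)
  x <- rnorm(n)
  y <- -1 * x + 0.8 * x * sex + rnorm(n, 0, 0.5)
  d <- tibble::tibble(sex = sex, age = runif(n, 20, 80), ev = x, y = y)
  f <- fit_association(d, "y", "ev", standardize_trait = FALSE,
                       transform_exposure = FALSE)
  b_ev <- f$coefficients["beta_EV", 1]
  b_int <- f$coefficients["beta_EV_by_sex", 1]
  expect_gt(b_int, 0)
  # total effect in men (b_ev + b_int) is weaker in magnitude than in women
  expect_lt(abs(b_ev + b_int), abs(b_ev))
})

test_that("associate_all crosses exposures and traits with pooled FDR", {
  set.seed(99)
  n <- 40
  d <- tibble::tibble(
    sex = rep(0:1, n / 2), age = runif(n, 20, 80),
    evA = runif(n), evB = runif(n),
    BMI = rnorm(n), WC = rnorm(n)
  )
  res <- associate_all(d, c("BMI", "WC"), c("evA", "evB"))
  expect_equal(nrow(res), 4L)
  expect_true(all(c("beta_ev", "p", "beta_int", "p_int", "partial_r2", "q",
                    "q_int") %in% names(res)))
  expect_true(all(res$q >= res$p))
})
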