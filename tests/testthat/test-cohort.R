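test_that("Mann-Whitney handles complete separation and perfect ties", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 9)
  expect_equal(res$r, 1.0)
  expect_equal(res$p, naive_mann_whitney(c(1, 2, 3), c(4, 5, 6))$p)
  res2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res2$r, 0.0)
  res3 <- mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(res3$r, -1.0)
  expect_error(mann_whitney(numeric(0), 1:3), class = "dyadsync_domain_error")
})

test_that("exact p-values agree with the enumeration oracle (with ties)", {
  set.seed(60)
  for (i in 1:12) {
    na <- sample(2:7, 1); nb <- sample(2:7, 1)
    a <- round(runif(na, 0, 5))       # rounding induces ties
    b <- round(runif(nb, 1, 6))
    for (alt in c("two.sided", "greater", "less")) {
      mine <- mann_whitney(a, b, alt)
      oracle <- naive_mann_whitney(a, b, alt)
      expect_equal(mine$U, oracle$U)
      expect_equal(mine$p, oracle$p, tolerance = 1e-12)
      expect_equal(mine$r, oracle$r)
    }
  }
})

test_that("exact p-values agree with wilcox.test in tie-free cases", {
  set.seed(61)
  a <- rnorm(6); b <- rnorm(7) + 0.5
  mine <- mann_whitney(a, b)
  ref <- stats::wilcox.test(b, a, exact = TRUE)   # W = our U for group b
  expect_equal(mine$U, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(62)
  a <- round(rnorm(20), 1); b <- round(rnorm(20, 0.4), 1)
  mine <- mann_whitney(a, b)
  ref <- suppressWarnings(stats::wilcox.test(b, a, exact = FALSE, correct = TRUE))
  expect_equal(mine$method, "normal approximation")
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
})

test_that("the probability function matches its closed form", {
  m <- structure(list(a = 1, b = 0, c = 0), class = "dyad_classifier")
  expect_equal(predict(m, data.frame(x = c(-5, 0, 7), y = c(2, 0, -1))),
               rep(0.5, 3))
  # printed-parameter regime: exponent zero at x = ln(a)/(-b), y = 0
  m2 <- structure(list(a = 5, b = -23, c = 0.6), class = "dyad_classifier")
  expect_equal(predict(m2, data.frame(x = log(5) / 23, y = 0)), 0.5)
  p_hi <- predict(m2, data.frame(x = 0.33, y = 0))
  p_lo <- predict(m2, data.frame(x = 0.14, y = 0))
  expect_gt(p_hi, p_lo)
  # overflow guard: extreme inputs stay inside (0, 1)
  p_ext <- predict(m2, data.frame(x = c(-1e6, 1e6), y = c(0, 0)))
  expect_true(all(p_ext >= 0 & p_ext <= 1) && !anyNA(p_ext))
})

sim_cohort_xy <- function(n, a = 5, b = -23, c = 0.6, seed = 1) {
  withr::with_seed(seed, {
    x <- runif(n, -0.15, 0.45)
    y <- runif(n, -3, 3)
    p <- 1 / (1 + a * exp(b * x + c * y))
    lab <- ifelse(runif(n) < p, "B", "A")
    data.frame(x = x, y = y, label = lab)
  })
}

test_that("the classifier recovers generating parameters and symmetry", {
  df <- sim_cohort_xy(400, seed = 70)
  m <- fit_classifier(df)
  expect_gt(m$a, 0)
  expect_lt(m$b, 0)
  expect_equal(m$b, -23, tolerance = 0.35)
  expect_equal(m$c, 0.6, tolerance = 0.5)
  # relabelling complements probabilities and keeps the boundary
  m_sw <- fit_classifier(df, positive = "A")
  p <- predict(m, df); p_sw <- predict(m_sw, df)
  expect_equal(p, 1 - p_sw, tolerance = 1e-6)
  expect_error(fit_classifier(df[df$label == "B", ]), class = "dyadsync_domain_error")
  expect_error(fit_classifier(df[1:3, ]), class = "dyadsync_domain_error")
})

test_that("perfect separation is flagged", {
  df <- data.frame(x = c(rep(0, 10), rep(1, 10)), y = 0,
                   label = rep(c("A", "B"), each = 10))
  expect_warning(m <- fit_classifier(df), "separat")
  expect_true(m$separation)
})

test_that("bootstrap is seed-deterministic and sane on separable data", {
  df <- data.frame(x = c(rnorm(10, 0, 0.01), rnorm(10, 1, 0.01)), y = 0,
                   label = rep(c("A", "B"), each = 10))
  m1 <- suppressWarnings(bootstrap_classifier(df, n_boot = 50, seed = 7))
  m2 <- suppressWarnings(bootstrap_classifier(df, n_boot = 50, seed = 7))
  expect_identical(m1$boot, m2$boot)
  expect_equal(mean(m1$boot$accuracy), 1.0)
  m3 <- suppressWarnings(bootstrap_classifier(df, n_boot = 50, seed = 8))
  expect_false(identical(m1$boot, m3$boot))
})

test_that("uninformative features yield chance-level out-of-bag accuracy", {
  withr::with_seed(80, {
    df <- data.frame(x = rnorm(120), y = rnorm(120),
                     label = sample(c("A", "B"), 120, replace = TRUE))
  })
  m <- bootstrap_classifier(df, n_boot = 100, seed = 3)
  expect_lt(mean(m$boot$accuracy), 0.62)
  expect_gt(mean(m$boot$accuracy), 0.38)
})

test_that("tidy and glance summarise the bootstrap", {
  df <- sim_cohort_xy(80, seed = 71)
  m <- bootstrap_classifier(df, n_boot = 40, seed = 2)
  td <- tidy(m)
  expect_equal(td$term, c("a", "b", "c"))
  expect_true(all(c("estimate", "std.error", "boot.mean") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$n, 80)
  expect_equal(gl$n_boot, 40)
  expect_true(gl$accuracy_mean > 0 && gl$accuracy_mean <= 1)
})
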