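test_that("group summaries return mean and SEM with the n-1 convention", {
  s <- summarize_groups(c(1, 2, 3, 10, 20), c("a", "a", "a", "b", "b"))
  a <- s[s$group == "a", ]
  expect_equal(a$mean, 2)
  expect_equal(a$sem, 1 / sqrt(3))  # sd({1,2,3}) = 1
  expect_equal(s[s$group == "b", ]$sem, sqrt(50) / sqrt(2))  # sd({10,20}) = sqrt(50)
  expect_warning(s1 <- summarize_groups(c(1, 5), c("a", "b")), "size 1")
  expect_equal(s1$sem, c(0, 0))
  expect_equal(summarize_groups(c(4, 4, 4), rep("a", 3))$sem, 0)
})

test_that("2-SD abnormality flag uses a strict inequality", {
  expect_false(flag_abnormal(10, 10, 2))
  expect_true(flag_abnormal(10 + 2.0001 * 2, 10, 2))
  expect_false(flag_abnormal(10 - 2 * 2, 10, 2))  # exactly 2 SD is normal
  expect_error(flag_abnormal(1, 0, 0), "invalid reference")
})

test_that("Kruskal-Wallis H matches explicit rank arithmetic", {
  # {1,2,3} vs {4,5,6}: ranks 1..6, rank sums 6 and 15,
  # H = 12/(6*7) * (6^2/3 + 15^2/3) - 3*7 = 27/7
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21,
               tolerance = 1e-12)
  expect_equal(kw$statistic, 27 / 7, tolerance = 1e-12)

  ident <- kruskal_wallis(c(2, 2, 2, 2), c("a", "a", "b", "b"))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
})

test_that("Kruskal-Wallis p is close to a permutation oracle on small samples", {
  set.seed(33)
  x <- c(0.3, 1.2, 0.8, 2.5, 1.9, 3.1, 2.2, 0.5)
  g <- rep(c("a", "b"), each = 4)
  kw <- kruskal_wallis(x, g)
  h_stat <- function(values, groups) {
    r <- rank(values)
    n <- length(values)
    sums <- tapply(r, groups, sum)
    ns <- tapply(r, groups, length)
    12 / (n * (n + 1)) * sum(sums^2 / ns) - 3 * (n + 1)
  }
  n_perm <- 20000
  perm <- replicate(n_perm, h_stat(x, sample(g)))
  p_mc <- mean(perm >= kw$statistic - 1e-12)
  mc_sigma <- sqrt(p_mc * (1 - p_mc) / n_perm)
  expect_lt(abs(kw$p_value - p_mc), 4 * mc_sigma)
})

test_that("Fisher's exact p equals hypergeometric enumeration", {
  enum_fisher <- function(tab) {
    m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
    a_range <- max(0, k - n2):min(m, k)
    probs <- stats::dhyper(a_range, m, n2, k)
    p_obs <- stats::dhyper(tab[1, 1], m, n2, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2))$p_value, 1)
  # statin counts reconstructed from the cohort percentages: 60% of 50
  # cases, 36.5% of 74 controls
  statin <- matrix(c(30, 20, 27, 47), 2, byrow = TRUE)
  expect_equal(fisher_exact(statin)$p_value, enum_fisher(statin),
               tolerance = 1e-9)
  set.seed(44)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact(tab)$p_value
    expect_equal(p, enum_fisher(tab), tolerance = 1e-9)
    expect_gt(p, 0); expect_lte(p, 1)
  }
  expect_warning(z <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "zero margin")
  expect_equal(z$p_value, 1)
})

test_that("the linear model recovers programmed coefficients exactly without noise", {
  set.seed(55)
  n <- 80
  df <- data.frame(
    group = rep(c("control", "dm_ifg"), each = n / 2),
    age = rnorm(n, 57, 10), height = rnorm(n, 1.7, 0.1),
    statin = runif(n) < 0.4
  )
  df$y <- 0.44 - 0.36 * (df$group == "dm_ifg")
  fit <- suppressWarnings(
    fit_linear_model(df, "y", covariates = c("group", "age", "height",
                                             "statin")))
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "groupdm_ifg"], -0.36,
               tolerance = 1e-10)
  expect_equal(cf$estimate[cf$term == "age"], 0, tolerance = 1e-10)
  expect_equal(cf$estimate[cf$term == "statin"], 0, tolerance = 1e-10)
})

test_that("duplicated covariates raise a collinearity error naming the column", {
  df <- data.frame(y = rnorm(20), a = rnorm(20))
  df$b <- df$a
  expect_error(fit_linear_model(df, "y", covariates = c("a", "b")),
               "collinear covariates.*b")
})

test_that("BMI is dropped from the default covariate set with a message", {
  set.seed(56)
  n <- 40
  df <- data.frame(
    group = rep(c("control", "dm_ifg"), each = n / 2),
    age = rnorm(n, 57, 10), sex = sample(c("M", "F"), n, TRUE),
    height = rnorm(n, 1.7, 0.1), weight = rnorm(n, 80, 10)
  )
  df$bmi <- df$weight / df$height^2
  df$y <- rnorm(n)
  expect_message(fit <- fit_linear_model(df, "y"), "bmi")
  expect_false(any(grepl("bmi", fit$coefficients$term)))
})

test_that("pure-noise outcomes rarely produce extreme coefficients", {
  # type-I control: with 15 covariates and white-noise outcome, |t| should
  # stay below the 99.9% quantile in the overwhelming majority of fits
  set.seed(57)
  n <- 124
  n_rep <- 100
  exceed <- 0
  total <- 0
  for (r in seq_len(n_rep)) {
    df <- data.frame(
      group = rep(c("control", "dm_ifg"), c(74, 50)),
      age = rnorm(n, 57, 12), sex = sample(c("M", "F"), n, TRUE),
      height = rnorm(n, 1.7, 0.1), weight = rnorm(n, 80, 15),
      dyslipidemia = runif(n) < 0.7, hypertension = runif(n) < 0.5,
      fhx_ihd = runif(n) < 0.38, aspirin = runif(n) < 0.4,
      acei_arb = runif(n) < 0.42, ccb = runif(n) < 0.24,
      beta_blocker = runif(n) < 0.31, statin = runif(n) < 0.46,
      thiazide = runif(n) < 0.2
    )
    df$y <- rnorm(n)
    fit <- fit_linear_model(df, "y")
    cf <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    tcrit <- stats::qt(0.9995, df = n - nrow(fit$coefficients))
    exceed <- exceed + sum(abs(cf$estimate / cf$se) > tcrit)
    total <- total + nrow(cf)
  }
  expect_lte(exceed / total, 0.01)
})

test_that("coefficient recovery is unbiased with near-nominal CI coverage", {
  set.seed(58)
  n_rep <- 300
  beta <- -0.36
  est <- numeric(n_rep)
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    n <- 124
    df <- data.frame(group = rep(c("control", "dm_ifg"), c(74, 50)),
                     age = rnorm(n, 57, 12))
    df$y <- 0.44 + beta * (df$group == "dm_ifg") + rnorm(n, sd = 0.4)
    fit <- fit_linear_model(df, "y", covariates = c("group", "age"))
    cf <- fit$coefficients[fit$coefficients$term == "groupdm_ifg", ]
    est[r] <- cf$estimate
    half <- stats::qt(0.975, n - 3) * cf$se
    covered[r] <- abs(cf$estimate - beta) <= half
  }
  expect_lt(abs(mean(est) - beta), 0.01)
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("p-values render as clinical tables print them", {
  expect_identical(format_p(c(0.5, 0.049, 0.009, 0.03)),
                   c("NS", "0.05", "<0.01", "0.03"))
})

test_that("the summary table formats counts, percents and significance", {
  set.seed(59)
  n <- 60
  df <- data.frame(
    group = rep(c("control", "dm_ifg"), each = n / 2),
    marker = c(rnorm(n / 2, 0.44, 0.2), rnorm(n / 2, 0.08, 0.2)),
    flat = rnorm(n, 5, 1),
    statin = rep(c(FALSE, TRUE), each = n / 2)  # extreme group difference
  )
  tab <- build_summary_table(df)
  expect_s3_class(tab, "summary_table")
  m <- tab[tab$variable == "marker", ]
  expect_identical(m$test, "kruskal_wallis")
  expect_lt(m$p_value, 0.01)
  expect_identical(m$p_label, "<0.01")
  s <- tab[tab$variable == "statin", ]
  expect_identical(s$test, "fisher_exact")
  expect_identical(s$control, "0.0")
  expect_identical(s$dm_ifg, "100.0")
  # percent formatting mirrors count arithmetic: 27 of 74 -> 36.5
  df2 <- data.frame(group = rep(c("control", "dm_ifg"), c(74, 50)),
                    statin = c(rep(c(TRUE, FALSE), c(27, 47)),
                               rep(c(TRUE, FALSE), c(30, 20))))
  tab2 <- build_summary_table(df2)
  expect_identical(tab2$control, "36.5")
  expect_identical(tab2$dm_ifg, "60.0")
})

test_that("identical groups come out non-significant across the board", {
  set.seed(60)
  n <- 124
  df <- data.frame(
    group = rep(c("control", "dm_ifg"), c(74, 50)),
    m1 = rnorm(n), m2 = rnorm(n), m3 = rnorm(n),
    b1 = runif(n) < 0.4, b2 = runif(n) < 0.6
  )
  tab <- build_summary_table(df)
  expect_true(all(tab$p_label == "NS"))
})
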