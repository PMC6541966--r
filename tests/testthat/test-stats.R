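rand_oneway <- function(n, k, seed) {
  set.seed(seed)
  df <- expand.grid(subject = paste0("s", 1:n),
                    condition = paste0("c", 1:k),
                    stringsAsFactors = FALSE)
  df$value <- rnorm(nrow(df))
  df
}

rand_mixed <- function(a, n, t_, seed) {
  set.seed(seed)
  df <- expand.grid(subject = 1:(a * n), time = paste0("t", 1:t_),
                    stringsAsFactors = FALSE)
  df$group <- paste0("g", rep(rep(1:a, each = n), t_))
  df$subject <- paste0("s", df$subject)
  df$value <- rnorm(nrow(df))
  df
}

test_that("values identical across conditions give F = 0, p = 1", {
  df <- data.frame(subject = rep(c("a", "b", "c"), 2),
                   condition = rep(c("x", "y"), each = 3),
                   value = rep(c(1, 5, 9), 2))
  r <- rm_anova_oneway(df)
  expect_equal(r$effects$F, 0)
  expect_equal(r$effects$p, 1)
})

test_that("one-way rm F matches the explicit-loop oracle on random designs", {
  for (i in 1:50) {
    n <- sample(3:8, 1); k <- sample(2:5, 1)
    df <- rand_oneway(n, k, seed = 100 + i)
    r <- rm_anova_oneway(df)
    f_loop <- loop_oneway_F(df)
    expect_lt(abs(r$effects$F - f_loop) / f_loop, 1e-8)
    expect_equal(r$effects$df_num, k - 1)
    expect_equal(r$effects$df_den, (k - 1) * (n - 1))
  }
})

test_that("two-condition one-way rm F equals the squared paired t", {
  for (i in 1:20) {
    df <- rand_oneway(sample(3:10, 1), 2, seed = 200 + i)
    r <- rm_anova_oneway(df)
    wide <- tapply(df$value, list(df$subject, df$condition), identity)
    tt <- t.test(wide[, 1], wide[, 2], paired = TRUE)
    expect_lt(abs(r$effects$F - tt$statistic^2) / r$effects$F, 1e-8)
    expect_equal(r$effects$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("mixed-design sums of squares match the loop oracle and aov", {
  for (i in 1:30) {
    a <- sample(2:3, 1); n <- sample(3:7, 1); t_ <- sample(2:6, 1)
    df <- rand_mixed(a, n, t_, seed = 300 + i)
    r <- rm_anova_mixed(df)
    f_loop <- loop_mixed_F(df)
    expect_equal(unname(r$effects$F), unname(f_loop), tolerance = 1e-8)
  }
  # independent cross-check against stats::aov on one fixture
  df <- rand_mixed(3, 7, 6, seed = 999)
  r <- rm_anova_mixed(df)
  df$subject <- factor(df$subject)
  sm <- summary(aov(value ~ group * time + Error(subject/time), data = df))
  f_aov <- c(sm[["Error: subject"]][[1]]["group", "F value"],
             sm[["Error: subject:time"]][[1]][c("time", "group:time"),
                                              "F value"])
  expect_equal(unname(r$effects$F), unname(f_aov), tolerance = 1e-10)
})

test_that("F statistics are invariant to shifting and scaling the data", {
  df <- rand_mixed(3, 4, 5, seed = 400)
  base <- rm_anova_mixed(df)$effects$F
  df2 <- df; df2$value <- df$value * 7.3 - 11
  expect_equal(rm_anova_mixed(df2)$effects$F, base, tolerance = 1e-10)
  dfo <- rand_oneway(5, 3, seed = 401)
  b1 <- rm_anova_oneway(dfo)$effects$F
  dfo$value <- dfo$value * -2.5 + 4
  expect_equal(rm_anova_oneway(dfo)$effects$F, b1, tolerance = 1e-10)
})

test_that("mixed-design type-I error is calibrated at the nominal level", {
  # null Gaussian data, sphericity satisfied by construction
  rej <- matrix(FALSE, 1000, 3)
  for (i in 1:1000) {
    df <- rand_mixed(3, 7, 6, seed = 5000 + i)
    rej[i, ] <- rm_anova_mixed(df)$effects$p < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(rates >= 0.03 & rates <= 0.07))
})

test_that("design violations are reported as design errors", {
  df <- rand_oneway(4, 3, seed = 500)
  expect_error(rm_anova_oneway(df[-1, ]), "incomplete design")
  dm <- rand_mixed(2, 3, 3, seed = 501)
  dm$group[dm$subject == "s1"][1] <- "g2"
  expect_error(rm_anova_mixed(dm), "more than one group")
  du <- rand_mixed(2, 3, 3, seed = 502)
  du <- du[du$subject != "s1", ]
  expect_error(rm_anova_mixed(du), "unbalanced")
})

test_that("Greenhouse-Geisser correction shrinks df but not F", {
  df <- rand_oneway(8, 4, seed = 600)
  plain <- rm_anova_oneway(df)
  gg <- rm_anova_oneway(df, correction = "gg")
  expect_equal(gg$effects$F, plain$effects$F)
  expect_lte(gg$effects$epsilon, 1)
  expect_gte(gg$effects$epsilon, 1 / 3)  # lower bound 1/(k-1)
  expect_equal(gg$effects$df_num, plain$effects$df_num * gg$effects$epsilon)
})

test_that("bonferroni multiplies and clamps", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_identical(bonferroni(0.5, 3), 1)
  expect_error(bonferroni(0.5, 0), "m")
  expect_error(bonferroni(1.5, 2), "\\[0, 1\\]")
  set.seed(61)
  p <- runif(20)
  expect_equal(bonferroni(p, 20), pmin(1, 20 * p))
})

test_that("significance uses a strict p < alpha threshold", {
  fake <- structure(list(
    effects = data.frame(effect = c("e1", "e2"), F = c(5, 4),
                         df_num = 1, df_den = 10,
                         p = c(0.049, 0.05), epsilon = 1),
    posthoc = data.frame(contrast = "a - b", mean_diff = 1,
                         p_raw = 0.02, p_adjusted = 0.06)),
    class = "anova_result")
  rep <- significance_report(fake, alpha = 0.05)
  expect_identical(rep$significant, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(significance_report(list())), 0)
})
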