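test_that("significance codes follow the standard thresholds", {
  expect_equal(signif_code(c(5e-4, 0.005, 0.03, 0.07, 0.2)),
               c("***", "**", "*", ".", "n.s."))
  expect_equal(signif_code(0.001), "**")  # strict '<' at each threshold
  expect_equal(signif_code(0.05), ".")
})

test_that("response-specific exclusions drop the right sites", {
  d <- data.frame(site_id = as.character(1:54), tau_i = 10, tau_14c = 100)
  expect_equal(nrow(suppressMessages(apply_exclusions(d, "log_taui"))), 51L)
  expect_equal(nrow(suppressMessages(apply_exclusions(d, "log_tau14c"))),
               53L)
  expect_setequal(attr(suppressMessages(apply_exclusions(d, "log_taui")),
                       "excluded"), c("6", "12", "24"))
  # saturated sites are added for incubation-derived responses
  d$saturated <- d$site_id == "9"
  expect_true("9" %in% attr(suppressMessages(apply_exclusions(d, "doc")),
                            "excluded"))
  # empty exclusion list is the identity
  none <- apply_exclusions(d[, 1:3], "log_taui", exclusions = list())
  expect_equal(nrow(none), 54L)
})

test_that("orthogonal predictors have order-invariant sequential SS", {
  set.seed(15)
  n <- 32
  x1 <- scale(rnorm(n))[, 1]
  x2 <- scale(residuals(lm(rnorm(n) ~ x1)))[, 1]  # exactly orthogonal
  d <- data.frame(y = rnorm(n), x1 = x1, x2 = x2)
  a <- sequential_anova(d, "y", c("x1", "x2"))
  b <- sequential_anova(d, "y", c("x2", "x1"))
  expect_equal(a$ss[a$term == "x1"], b$ss[b$term == "x1"], tolerance = 1e-8)
  expect_equal(a$ss[a$term == "x2"], b$ss[b$term == "x2"], tolerance = 1e-8)
})

test_that("sequential ANOVA matches a nested-RSS brute force", {
  set.seed(16)
  n <- 20
  x1 <- rnorm(n)
  x2 <- 0.6 * x1 + rnorm(n)           # deliberately correlated
  g <- factor(rep(c("a", "b"), each = n / 2))
  y <- 1 + 0.8 * x1 + 0.3 * (g == "b") + rnorm(n)
  d <- data.frame(y = y, x1 = x1, x2 = x2, g = g)
  tab <- sequential_anova(d, "y", c("g", "x1", "x2"))
  # brute force: residual sums of squares of successively larger fits
  rss <- c(sum((y - mean(y))^2),
           sum(resid(lm(y ~ g))^2),
           sum(resid(lm(y ~ g + x1))^2),
           sum(resid(lm(y ~ g + x1 + x2))^2))
  ss_brute <- -diff(rss)
  df_res <- n - 4
  ms_res <- rss[4] / df_res
  f_brute <- (ss_brute / c(1, 1, 1)) / ms_res
  p_brute <- pf(f_brute, 1, df_res, lower.tail = FALSE)
  expect_equal(tab$ss[1:3], ss_brute, tolerance = 1e-8)
  expect_equal(tab$f[1:3], f_brute, tolerance = 1e-8)
  expect_equal(tab$p[1:3], p_brute, tolerance = 1e-8)
  # exact decomposition: term SS + residual SS = total SS about the mean
  expect_equal(sum(tab$ss), rss[1], tolerance = 1e-8)
})

test_that("design-term names map to data columns, orientation gets 2 df", {
  st <- quiet_study(synth_config(seed = 2))
  d <- quiet_analysis(st)$estimates
  d <- d[!is.na(d$tau_i), ]
  tab <- sequential_anova(d, "log_taui",
                          c("BGR", "MI", "TI", "MI:TI", "PCo1", "PCo2"))
  expect_equal(tab$term[1:6], c("BGR", "MI", "TI", "MI:TI", "PCo1", "PCo2"))
  expect_equal(tab$df[tab$term == "MI:TI"], 1)
  tab2 <- sequential_anova(d, "log_taui", c("BGR", "Orientation"))
  expect_equal(tab2$df[tab2$term == "Orientation"], 2)
  # term order is honoured even when a main effect follows the interaction
  tab3 <- sequential_anova(d, "log_taui",
                           c("BGR", "MI", "TI", "MI:TI", "pH"))
  expect_equal(tab3$term[5], "pH")
})

test_that("rank deficiency names the collinear term", {
  d <- data.frame(y = rnorm(10), x1 = 1:10)
  d$x2 <- d$x1 * 2
  expect_error(sequential_anova(d, "y", c("x1", "x2")), "collinear")
})

test_that("interaction cannot precede both of its main effects", {
  d <- data.frame(y = rnorm(12), mi = factor(rep(c("MI-", "MI+"), 6)),
                  ti = factor(rep(c("TT-", "TT+"), each = 6)))
  expect_error(sequential_anova(d, "y", c("MI:TI", "MI", "TI")),
               "precedes")
})

test_that("consistency screening needs comparable orderings", {
  d <- data.frame(y = rnorm(20), x1 = rnorm(20), x2 = rnorm(20))
  expect_error(order_consistency(d, "y", list(c("x1", "x2"))), "at least two")
  expect_error(order_consistency(d, "y", list(c("x1", "x2"), c("x1", "y2"))),
               "same term set")
})

test_that("an effect on an orthogonalised predictor is order-consistent", {
  set.seed(18)
  n <- 60
  x1 <- scale(rnorm(n))[, 1]
  x2 <- scale(residuals(lm(rnorm(n) ~ x1)))[, 1]
  d <- data.frame(y = 1.2 * x1 + rnorm(n), x1 = x1, x2 = x2)
  rep <- order_consistency(d, "y", list(c("x1", "x2"), c("x2", "x1")))
  v <- rep$drivers
  expect_equal(v$verdict[v$driver == "x1"], "significant")
  expect_false("crossed_out" %in% v$verdict)
})

test_that("collinearity produces crossed-out verdicts for the idle twin", {
  set.seed(19)
  n <- 40
  crossed <- replicate(200, {
    x1 <- rnorm(n)
    x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)  # r ~ 0.9
    y <- 1.0 * x1 + rnorm(n)                    # effect on x1 only
    d <- data.frame(y = y, x1 = x1, x2 = x2)
    rep <- order_consistency(d, "y", list(c("x1", "x2"), c("x2", "x1")))
    rep$drivers$verdict[rep$drivers$driver == "x2"] == "crossed_out"
  })
  expect_gte(mean(crossed), 0.80)
})

test_that("Pearson summaries match the closed-form covariance formula", {
  d <- data.frame(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 6))
  out <- pearson_summary(d, list(c("x", "y")))
  r_hand <- sum((d$x - 3) * (d$y - mean(d$y))) /
    sqrt(sum((d$x - 3)^2) * sum((d$y - mean(d$y))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_equal(out$n, 5L)
  ident <- pearson_summary(data.frame(x = 1:10, y = 1:10), list(c("x", "y")))
  expect_equal(ident$r, 1)
  expect_error(pearson_summary(data.frame(x = rep(1, 5), y = 1:5),
                               list(c("x", "y"))), "variance")
  expect_error(pearson_summary(data.frame(x = 1:2, y = 2:1),
                               list(c("x", "y"))), "fewer than 3")
})
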