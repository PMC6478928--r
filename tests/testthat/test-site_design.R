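test_that("slope filter is strict and exempts long-term monitoring sites", {
  pop <- data.frame(site_id = 1:3, slope = c(50, 60, 60),
                    is_lwf = c(FALSE, TRUE, FALSE))
  kept <- filter_population(pop)
  expect_equal(kept$site_id, c(1, 2))  # 50% kept (strictly larger excluded)
})

test_that("dryness index counts strict P < PET months", {
  expect_equal(dryness_index(rep(50, 12), rep(50, 12)), 0)
  expect_equal(dryness_index(rep(49, 360), rep(50, 360)), 360)
  set.seed(9)
  p <- runif(120, 0, 150); pet <- runif(120, 0, 150)
  brute <- sum(vapply(seq_along(p), function(i) p[i] < pet[i], logical(1)))
  expect_equal(dryness_index(p, pet), brute)
  expect_error(dryness_index(1:12, 1:11), "equal length")
})

test_that("median split yields balanced margins with ties in the lower bins", {
  s <- data.frame(temp = 1:4, dryness = c(1, 4, 2, 3))
  cc <- climate_categories(s)
  expect_equal(sort(as.character(unique(cc$climate_cat))),
               sort(c("MI-:TT-", "MI-:TT+", "MI+:TT-", "MI+:TT+")))
  expect_equal(as.vector(table(cc$climate_cat)), rep(1L, 4))
  # site exactly at both medians falls in the low-temperature, low-dryness
  # (i.e. moist) bins
  s <- data.frame(temp = c(1, 2, 3), dryness = c(1, 2, 3))
  cc <- climate_categories(s)
  expect_equal(as.character(cc$ti[2]), "TT-")
  expect_equal(as.character(cc$mi[2]), "MI+")
  # margins near-balanced for continuous covariates; the diagonal cells are
  # forced equal by the fixed margins
  set.seed(4)
  for (i in 1:10) {
    n <- sample(30:101, 1)
    s <- data.frame(temp = rnorm(n), dryness = rnorm(n))
    cc <- climate_categories(s)
    expect_lte(abs(sum(cc$ti == "TT+") - sum(cc$ti == "TT-")), 1)
    expect_lte(abs(sum(cc$mi == "MI+") - sum(cc$mi == "MI-")), 1)
    tab <- table(cc$mi, cc$ti)
    expect_lte(abs(tab["MI+", "TT+"] - tab["MI-", "TT-"]), 1)
  }
  expect_error(climate_categories(data.frame(temp = c(1, 1),
                                             dryness = 1:2)), "constant")
})

test_that("climate categories are invariant to monotone rescaling", {
  set.seed(12)
  s <- data.frame(temp = rnorm(40), dryness = runif(40, 0, 30))
  a <- climate_categories(s)
  s2 <- transform(s, temp = exp(temp), dryness = dryness^3)
  b <- climate_categories(s2)
  expect_equal(as.character(a$climate_cat), as.character(b$climate_cat))
})

test_that("identical sites coincide in the principal-coordinate plane", {
  s <- data.frame(ph = c(5, 5, 7), clay = c(20, 20, 40),
                  slope = c(10, 10, 30),
                  orientation = factor(c("N", "N", "S")))
  pc <- pcoa_soil_landform(s)
  expect_equal(pc$pco1[1], pc$pco1[2], tolerance = 1e-10)
  expect_equal(pc$pco2[1], pc$pco2[2], tolerance = 1e-10)
})

test_that("a one-dimensional configuration embeds on the first axis", {
  s <- data.frame(ph = c(4, 5, 6), clay = 20, slope = 10,
                  orientation = factor(rep("N", 3)))
  pc <- pcoa_soil_landform(s)
  expect_equal(pc$pco2, rep(0, 3), tolerance = 1e-8)
  expect_equal(order(pc$pco1), if (pc$pco1[1] < pc$pco1[3]) 1:3 else 3:1)
  expect_equal(diff(sort(pc$pco1))[1], diff(sort(pc$pco1))[2],
               tolerance = 1e-8)
})

test_that("PCoA eigenvalue sum matches the total dispersion", {
  set.seed(8)
  x <- data.frame(matrix(rnorm(60), 15, 4))
  names(x) <- c("ph", "clay", "slope", "extra")
  pc <- pcoa_soil_landform(x, vars = names(x),
                           distance = "euclidean_standardized")
  a <- as.matrix(dist(scale(as.matrix(x))))^2
  n <- nrow(a)
  j <- diag(n) - 1 / n
  b <- -0.5 * j %*% a %*% j
  expect_equal(sum(pc$eigenvalues), sum(diag(b)), tolerance = 1e-8)
})

test_that("PCoA on standardized Euclidean distances equals PCA up to sign", {
  set.seed(31)
  x <- data.frame(matrix(rnorm(80), 20, 4))
  names(x) <- paste0("v", 1:4)
  pc <- pcoa_soil_landform(x, vars = names(x),
                           distance = "euclidean_standardized")
  scores <- prcomp(scale(as.matrix(x)))$x
  expect_equal(abs(pc$pco1), abs(scores[, 1]), tolerance = 1e-8)
  expect_equal(abs(pc$pco2), abs(scores[, 2]), tolerance = 1e-8)
})

test_that("selection is deterministic, stratified and flags empty cells", {
  pop <- generate_population(synth_config(seed = 13))
  pf <- filter_population(pop)
  expect_warning(a <- select_orthogonal(pf, 54), "not sampled")
  b <- suppressWarnings(select_orthogonal(pf, 54))
  expect_identical(a$selected, b$selected)
  expect_equal(length(a$selected), 54L)
  expect_gt(length(a$cell_gaps), 0)
  # near-balanced climate categories among the selected
  sel <- a$sites[a$sites$selected, ]
  expect_true(all(table(sel$climate_cat) >= 12))
  expect_error(select_orthogonal(pf[1:10, ], 54), "exceeds")
})

test_that("an orthogonal balanced population reports near-zero correlation", {
  cell <- expand.grid(ti = c("TT-", "TT+"), mi = c("MI-", "MI+"),
                      region = c("A", "B"), rep = 1:2)
  t_pm <- ifelse(cell$ti == "TT+", 1, -1)
  m_pm <- ifelse(cell$mi == "MI+", 1, -1)
  r_pm <- ifelse(cell$region == "B", 1, -1)
  pop <- data.frame(site_id = as.character(seq_len(nrow(cell))),
                    region = cell$region,
                    ti = factor(cell$ti), mi = factor(cell$mi),
                    pco1 = t_pm * m_pm,    # contrast interactions are
                    pco2 = t_pm * r_pm)    # orthogonal to every main effect
  expect_lt(design_orthogonality(pop), 1e-10)
})

test_that("the selected design is more orthogonal than random subsets", {
  pop <- generate_population(synth_config(seed = 3))
  pf <- filter_population(pop)
  sel <- suppressWarnings(select_orthogonal(pf, 54))
  ann <- sel$sites
  set.seed(99)
  wins <- replicate(100, {
    idx <- sample(nrow(ann), length(sel$selected))
    design_orthogonality(ann[idx, , drop = FALSE]) >
      sel$orthogonality_report
  })
  expect_gte(mean(wins), 0.95)
})
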