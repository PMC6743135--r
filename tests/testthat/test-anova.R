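# Brute-force balanced two-way sum-of-squares decomposition, written
# directly from the definitional formulas as an independent oracle.
ss_oracle <- function(y, A, B) {
  N <- length(y); gm <- mean(y)
  mA <- tapply(y, A, mean); nA <- tapply(y, A, length)
  mB <- tapply(y, B, mean); nB <- tapply(y, B, length)
  mAB <- tapply(y, interaction(A, B), mean)
  nAB <- tapply(y, interaction(A, B), length)
  ss_a <- sum(nA * (mA - gm)^2)
  ss_b <- sum(nB * (mB - gm)^2)
  ss_cells <- sum(nAB * (mAB - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_e <- sum((y - mAB[interaction(A, B)])^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab, ss_e = ss_e,
       ss_tot = sum((y - gm)^2))
}

anova_fixture <- function(jitter = 0.1) {
  base <- c(1, 1, 1, 1, 3, 3, 3, 3)
  withr::with_seed(3, {
    tibble::tibble(
      radius_mm = rep(c(35, 35, 55, 55), each = 2),
      tip = rep(rep(c("blunt", "sharp"), each = 2), 2),
      peak_N = base + runif(8, -jitter, jitter))
  })
}

test_that("balanced two-way ANOVA matches the sum-of-squares oracle", {
  df <- anova_fixture()
  fit <- two_way_anova(df)
  tab <- tidy(fit)
  oracle <- ss_oracle(df$peak_N, factor(df$radius_mm), factor(df$tip))
  expect_equal(tab$sumsq[tab$term == "radius"], oracle$ss_a,
               tolerance = 1e-9)
  expect_equal(tab$sumsq[tab$term == "tip"], oracle$ss_b, tolerance = 1e-9)
  expect_equal(tab$sumsq[tab$term == "radius:tip"], oracle$ss_ab,
               tolerance = 1e-9)
  expect_equal(tab$sumsq[tab$term == "Residuals"], oracle$ss_e,
               tolerance = 1e-9)
  # F for the radius factor from the oracle decomposition
  f_oracle <- (oracle$ss_a / 1) / (oracle$ss_e / 4)
  expect_equal(tab$statistic[tab$term == "radius"], f_oracle,
               tolerance = 1e-9)
})

test_that("the balanced decomposition is exact and permutation-invariant", {
  df <- anova_fixture()
  tab <- tidy(two_way_anova(df))
  expect_equal(sum(tab$sumsq),
               ss_oracle(df$peak_N, factor(df$radius_mm),
                         factor(df$tip))$ss_tot,
               tolerance = 1e-9)
  expect_equal(sum(tab$df), nrow(df) - 1)
  perm <- withr::with_seed(9, df[sample(nrow(df)), ])
  expect_equal(tidy(two_way_anova(perm)), tab, tolerance = 1e-12)
})

test_that("identical observations give zero effect sums of squares", {
  df <- tibble::tibble(radius_mm = rep(c(35, 55), each = 4),
                       tip = rep(c("blunt", "sharp"), 4),
                       peak_N = 5)
  tab <- tidy(two_way_anova(df))
  expect_equal(tab$sumsq[tab$term != "Residuals"], rep(0, 3),
               tolerance = 1e-12)
})

test_that("empty and deficient cells are reported by name", {
  df <- anova_fixture()
  df <- df[!(df$radius_mm == 55 & df$tip == "sharp"), ]
  expect_error(two_way_anova(df), "radius=55.*tip=sharp")
  one_level <- df[df$tip == "blunt", ]
  expect_error(two_way_anova(one_level), "2 levels")
})

test_that("unbalanced data fall back to a type II analysis", {
  df <- anova_fixture()
  extra <- df[df$radius_mm == 35 & df$tip == "blunt", ][1, ]
  extra$peak_N <- extra$peak_N + 0.05
  fit <- two_way_anova(dplyr::bind_rows(df, extra))
  expect_false(fit$balanced)
  expect_match(fit$ss_type, "II")
  expect_equal(sum(tidy(fit)$df), 8)
})

test_that("Monte-Carlo null type-I rate is close to the nominal 0.05", {
  n_rep <- 1000
  withr::with_seed(104729, {
    hits <- matrix(FALSE, n_rep, 2)
    grid <- tidyr::expand_grid(radius_mm = c(35, 55), tip = c("b", "s"),
                               rep = 1:3)
    for (i in seq_len(n_rep)) {
      grid$peak_N <- rnorm(nrow(grid))
      g <- glance(two_way_anova(grid))
      hits[i, ] <- c(g$p_radius < 0.05, g$p_tip < 0.05)
    }
    rates <- colMeans(hits)
    expect_gte(min(rates), 0.03)
    expect_lte(max(rates), 0.07)
  })
})
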