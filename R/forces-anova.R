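#' Two-way fixed-effects ANOVA on insertion force peaks
#'
#' Tests peak insertion force against channel radius and needle tip
#' type with their interaction. Balanced designs use the classical
#' sequential sums of squares; unbalanced designs (e.g. after excluding
#' buckled insertions) use Type II sums of squares, the conventional
#' choice when main effects are the interest and the interaction is
#' still reported. By default, buckled insertions are excluded, since
#' their aborted traces carry no valid peak.
#'
#' @param summaries Tibble of per-insertion summaries (see
#'   [summarize_insertions()]) with columns `radius_mm`, `tip`, and the
#'   response.
#' @param response Name of the response column (default `"peak_N"`).
#' @param alpha Significance level (default 0.05).
#' @param exclude_buckled Drop rows with `buckled == TRUE` (default
#'   TRUE) when that column is present.
#' @return A `force_anova` object; see [tidy()] and [glance()] methods.
#' @export
two_way_anova <- function(summaries, response = "peak_N", alpha = 0.05,
                          exclude_buckled = TRUE) {
  stopifnot(all(c("radius_mm", "tip") %in% names(summaries)))
  if (!response %in% names(summaries))
    abort(paste0("no response column '", response, "'"))
  df <- summaries
  if (exclude_buckled && "buckled" %in% names(df))
    df <- df[!df$buckled, , drop = FALSE]
  dat <- data.frame(y = df[[response]],
                    radius = factor(df$radius_mm),
                    tip = factor(df$tip))
  if (nlevels(dat$radius) < 2 || nlevels(dat$tip) < 2)
    abort("both factors need at least 2 levels")
  counts <- table(dat$radius, dat$tip)
  if (any(counts < 2)) {
    bad <- which(counts < 2, arr.ind = TRUE)[1, ]
    abort(paste0("cell radius=", rownames(counts)[bad[1]], ", tip=",
                 colnames(counts)[bad[2]], " has fewer than 2 observations"))
  }
  balanced <- length(unique(as.vector(counts))) == 1
  fit <- aov(y ~ radius * tip, data = dat)
  if (balanced) {
    tab <- summary(fit)[[1]]
    terms <- trimws(rownames(tab))
    table <- tibble::tibble(
      term = c("radius", "tip", "radius:tip", "Residuals")[
        match(terms, c("radius", "tip", "radius:tip", "Residuals"))],
      df = tab$Df, sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`,
      statistic = tab$`F value`, p_value = tab$`Pr(>F)`)
    type <- "I (balanced)"
  } else {
    a2 <- car::Anova(lm(y ~ radius * tip, data = dat), type = 2)
    terms <- trimws(rownames(a2))
    table <- tibble::tibble(
      term = terms, df = a2$Df, sumsq = a2$`Sum Sq`,
      meansq = a2$`Sum Sq` / a2$Df,
      statistic = a2$`F value`, p_value = a2$`Pr(>F)`)
    type <- "II (unbalanced)"
  }
  structure(
    list(table = table, fit = fit, data = dat, alpha = alpha,
         balanced = balanced, ss_type = type, n = nrow(dat)),
    class = "force_anova")
}

#' @export
print.force_anova <- function(x, ...) {
  cat("<force_anova> two-way fixed effects, type ", x$ss_type, ", n = ",
      x$n, ", alpha = ", x$alpha, "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @describeIn two_way_anova One row per ANOVA source with SS, df, MS, F
#'   and p.
#' @param x A `force_anova`.
#' @param ... Unused.
#' @export
tidy.force_anova <- function(x, ...) x$table

#' @describeIn two_way_anova One-row model overview with the three test
#'   p-values.
#' @export
glance.force_anova <- function(x, ...) {
  p <- function(term) {
    x$table$p_value[match(term, x$table$term)]
  }
  tibble::tibble(n = x$n, alpha = x$alpha, balanced = x$balanced,
                 p_radius = p("radius"), p_tip = p("tip"),
                 p_interaction = p("radius:tip"))
}

#' Tukey-Kramer all-pairs comparisons
#'
#' For each pair of levels of one ANOVA factor, computes the
#' studentized-range statistic
#' `q = |m_i - m_j| / sqrt((MS_E / 2) (1/n_i + 1/n_j))` against the
#' critical value of the studentized range distribution at the ANOVA's
#' error degrees of freedom; the Kramer form is valid for unequal group
#' sizes and reduces to the classical Tukey HSD when sizes are equal.
#' Critical values and p-values come from the studentized range
#' distribution computed numerically ([stats::qtukey()]).
#'
#' @param anova A `force_anova` from [two_way_anova()].
#' @param factor Factor to compare: `"radius"` or `"tip"`.
#' @param alpha Significance level (defaults to the ANOVA's).
#' @return A `tukey_kramer` tibble with one row per level pair:
#'   `level_a`, `level_b`, `diff`, `se`, `q`, `q_crit`, `p_adj`,
#'   `significant`.
#' @export
tukey_kramer <- function(anova, factor = "radius", alpha = NULL) {
  stopifnot(inherits(anova, "force_anova"))
  alpha <- alpha %||% anova$alpha
  if (!factor %in% c("radius", "tip"))
    abort("factor must be 'radius' or 'tip'")
  f <- anova$data[[factor]]
  y <- anova$data$y
  means <- tapply(y, f, mean)
  ns <- tapply(y, f, length)
  res_row <- anova$table[anova$table$term == "Residuals", ]
  mse <- res_row$meansq
  df_err <- res_row$df
  k <- nlevels(f)
  combos <- utils::combn(levels(f), 2)
  level_a <- combos[1, ]; level_b <- combos[2, ]
  diff <- means[level_b] - means[level_a]
  se <- sqrt((mse / 2) * (1 / ns[level_a] + 1 / ns[level_b]))
  q <- abs(diff) / se
  q_crit <- qtukey(1 - alpha, k, df_err)
  p_adj <- ptukey(q, k, df_err, lower.tail = FALSE)
  out <- tibble::tibble(
    level_a = level_a, level_b = level_b,
    diff = as.numeric(diff), se = as.numeric(se), q = as.numeric(q),
    q_crit = q_crit, p_adj = as.numeric(p_adj),
    significant = as.numeric(q) > q_crit)
  structure(out, factor = factor, alpha = alpha, k = k, df_err = df_err,
            class = c("tukey_kramer", class(out)))
}

#' @describeIn tukey_kramer Mean-difference plot with significance
#'   colouring.
#' @param object A `tukey_kramer` tibble.
#' @param ... Unused.
#' @export
autoplot.tukey_kramer <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$pair <- paste(df$level_a, "vs", df$level_b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diff, y = .data$pair,
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$diff - .data$q_crit * .data$se,
      xmax = .data$diff + .data$q_crit * .data$se), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "mean difference (N)", y = NULL,
                  colour = "significant")
}
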