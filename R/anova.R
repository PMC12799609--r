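#' One-way analysis of variance from sums of squares
#'
#' Classical fixed-effects decomposition computed directly from group sums of
#' squares: `SS_between = sum n_i (ybar_i - ybar)^2`,
#' `SS_within = sum (y_ij - ybar_i)^2`, `F = MS_between / MS_within`, with the
#' p-value from the upper tail of the F distribution. Degenerate layouts are
#' reported rather than erroring: zero within-group variance with non-zero
#' between-group variance gives `F = Inf` (flagged), and identical values
#' everywhere give `F = 0`.
#'
#' @param data A data frame in long format.
#' @param response Column of measurements (tidy-eval).
#' @param group Column of group labels (tidy-eval).
#' @return An `ss_anova` object; see [tidy.ss_anova()] / [glance.ss_anova()].
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 2, 3, 4))
#' one_way_anova(d, y, g)
#' @export
one_way_anova <- function(data, response, group) {
  y <- rlang::eval_tidy(rlang::enquo(response), data)
  g <- as.factor(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- stats::complete.cases(y, g)
  y <- y[keep]; g <- droplevels(g[keep])
  a <- nlevels(g)
  n <- length(y)
  if (a < 2) stop("need at least 2 groups", call. = FALSE)
  if (n <= a) stop("need more observations than groups", call. = FALSE)

  grand <- mean(y)
  means <- tapply(y, g, mean)
  sizes <- tapply(y, g, length)
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum((y - means[g])^2)
  df_between <- a - 1
  df_within <- n - a

  terms <- tibble::tibble(
    term = c("group", "residuals"),
    df = c(df_between, df_within),
    sumsq = c(ss_between, ss_within)
  )
  new_ss_anova(terms, design = "one_way",
               levels = list(group = levels(g)), n = n)
}

#' Two-way analysis of variance (balanced, with interaction)
#'
#' Standard balanced two-factor decomposition with `r >= 2` replicates per
#' cell: main-effect sums of squares from marginal means, interaction from
#' cell means, residual within cells; df `(a-1)`, `(b-1)`, `(a-1)(b-1)`,
#' `ab(r-1)`. Unbalanced layouts are refused (the orthogonal decomposition
#' does not apply) with a pointer to [one_way_anova()] on cell means.
#'
#' @param data A data frame in long format.
#' @param response Measurement column (tidy-eval).
#' @param factor_a,factor_b Factor columns (tidy-eval).
#' @return An `ss_anova` object.
#' @examples
#' d <- expand.grid(culture = c("AC", "CF", "RF"),
#'                  enriched = c("yes", "no"), rep = 1:3)
#' d$y <- rnorm(nrow(d))
#' two_way_anova(d, y, culture, enriched)
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  y <- rlang::eval_tidy(rlang::enquo(response), data)
  fa <- as.factor(rlang::eval_tidy(rlang::enquo(factor_a), data))
  fb <- as.factor(rlang::eval_tidy(rlang::enquo(factor_b), data))
  keep <- stats::complete.cases(y, fa, fb)
  y <- y[keep]; fa <- droplevels(fa[keep]); fb <- droplevels(fb[keep])
  a <- nlevels(fa); b <- nlevels(fb)
  if (a < 2 || b < 2) stop("each factor needs at least 2 levels", call. = FALSE)
  counts <- table(fa, fb)
  r <- counts[1, 1]
  if (any(counts != r)) {
    stop("unbalanced design: cell sizes differ; use one_way_anova() on the ",
         "cell means instead", call. = FALSE)
  }
  if (r < 2) stop("need >= 2 replicates per cell for a residual term",
                  call. = FALSE)

  grand <- mean(y)
  m_a <- tapply(y, fa, mean)
  m_b <- tapply(y, fb, mean)
  m_ab <- tapply(y, list(fa, fb), mean)
  ss_a <- b * r * sum((m_a - grand)^2)
  ss_b <- a * r * sum((m_b - grand)^2)
  ss_ab <- r * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + grand)^2)
  ss_resid <- sum((y - m_ab[cbind(fa, fb)])^2)

  terms <- tibble::tibble(
    term = c("factor_a", "factor_b", "interaction", "residuals"),
    df = c(a - 1, b - 1, (a - 1) * (b - 1), a * b * (r - 1)),
    sumsq = c(ss_a, ss_b, ss_ab, ss_resid)
  )
  new_ss_anova(terms, design = "two_way",
               levels = list(factor_a = levels(fa), factor_b = levels(fb)),
               n = length(y))
}

# shared finishing: mean squares, F with degenerate-variance flags, p values
new_ss_anova <- function(terms, design, levels, n) {
  terms$meansq <- terms$sumsq / terms$df
  ms_resid <- terms$meansq[terms$term == "residuals"]
  eff <- terms$term != "residuals"
  f <- rep(NA_real_, nrow(terms))
  p <- rep(NA_real_, nrow(terms))
  flags <- character(0)
  for (i in which(eff)) {
    if (ms_resid > 0) {
      f[i] <- terms$meansq[i] / ms_resid
      p[i] <- stats::pf(f[i], terms$df[i],
                        terms$df[terms$term == "residuals"],
                        lower.tail = FALSE)
    } else if (terms$sumsq[i] > 0) {
      f[i] <- Inf
      p[i] <- 0
      flags <- c(flags, paste0(terms$term[i],
                               ": zero residual variance, F reported as Inf"))
    } else {
      f[i] <- 0
      p[i] <- 1
    }
  }
  terms$statistic <- f
  terms$p.value <- p
  structure(list(terms = terms, design = design, levels = levels,
                 n = n, flags = flags),
            class = "ss_anova")
}

#' @export
print.ss_anova <- function(x, ...) {
  cat("<ss_anova> ", x$design, " design, n = ", x$n, "\n", sep = "")
  print(x$terms)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Tidy an ANOVA table
#'
#' @param x An `ss_anova`.
#' @param ... Unused.
#' @return Tibble with `term`, `df`, `sumsq`, `meansq`, `statistic`,
#'   `p.value` (statistic/p are `NA` for the residual row).
#' @method tidy ss_anova
#' @export
tidy.ss_anova <- function(x, ...) x$terms

#' One-row ANOVA summary
#'
#' @param x An `ss_anova`.
#' @param ... Unused.
#' @return One-row tibble with total SS, residual df, n and flags.
#' @method glance ss_anova
#' @export
glance.ss_anova <- function(x, ...) {
  tibble::tibble(
    design = x$design,
    n = x$n,
    sumsq_total = sum(x$terms$sumsq),
    df_residual = x$terms$df[x$terms$term == "residuals"],
    flags = paste(x$flags, collapse = "; ")
  )
}
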