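## Group-comparison statistics: pooled two-sample t (the printed df of
## n1+n2-2 in the motivating analysis rules out Welch, which stays behind a
## flag) and the Mann-Whitney U with midranks, exact p for tie-free samples
## and a tie-corrected normal approximation otherwise.

new_test_result <- function(statistic, df, p_value, method, extra = list()) {
  structure(c(list(statistic = statistic, df = df,
                   p_value = p_value, method = method), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic %.4f%s, p = %.4g\n",
              x$method, x$statistic,
              if (!is.null(x$df)) sprintf(" (df=%d)", x$df) else "",
              x$p_value))
  invisible(x)
}

as_summary3 <- function(x, arg) {
  if (is.numeric(x) && !is.null(names(x)) &&
      all(c("mean", "sd", "n") %in% names(x)))
    return(list(mean = unname(x[["mean"]]), sd = unname(x[["sd"]]),
                n = unname(x[["n"]])))
  if (is.list(x) && all(c("mean", "sd", "n") %in% names(x)))
    return(x[c("mean", "sd", "n")])
  if (is.numeric(x))
    return(list(mean = mean(x), sd = stats::sd(x), n = length(x)))
  stop("`", arg, "` must be a numeric sample or a (mean, sd, n) summary",
       call. = FALSE)
}

#' Pooled two-sample t test
#'
#' Student's pooled-variance t with df = n1 + n2 - 2, accepting either raw
#' samples or `(mean, sd, n)` summary cells (named vector or list), so
#' printed table cells can be tested directly. Sign convention: the
#' statistic is (second group - first group) / SE, matching a table that
#' lists the first group's column first. Two-sided p from the t
#' distribution. `welch = TRUE` switches to the Welch-Satterthwaite df.
#'
#' @param x,y numeric samples, or summaries `c(mean=, sd=, n=)`.
#' @param welch use Welch's unequal-variance form.
#' @return a `test_result` (`statistic`, `df`, `p_value`, `method`).
#' @export
pooled_t_test <- function(x, y, welch = FALSE) {
  a <- as_summary3(x, "x"); b <- as_summary3(y, "y")
  if (a$n < 2 || b$n < 2) stop("both groups need n >= 2", call. = FALSE)
  if (!is.finite(a$sd) || !is.finite(b$sd))
    stop("group SDs must be finite", call. = FALSE)
  if (welch) {
    se2a <- a$sd^2 / a$n; se2b <- b$sd^2 / b$n
    se <- sqrt(se2a + se2b)
    if (se == 0) {
      if (a$mean == b$mean)
        return(new_test_result(0, NA_integer_, 1, "welch_t"))
      stop("zero variance with unequal means", call. = FALSE)
    }
    df <- (se2a + se2b)^2 / (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
    tv <- (b$mean - a$mean) / se
    return(new_test_result(tv, df, 2 * stats::pt(-abs(tv), df), "welch_t"))
  }
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  if (sp2 == 0) {
    if (a$mean == b$mean) return(new_test_result(0, df, 1, "pooled_t"))
    stop("zero pooled variance with unequal means", call. = FALSE)
  }
  tv <- (b$mean - a$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  new_test_result(tv, as.integer(df), 2 * stats::pt(-abs(tv), df), "pooled_t")
}

#' Mann-Whitney U test
#'
#' Rank-sum form with midranks: U for the first-listed sample is
#' `R_x - n_x(n_x+1)/2`, which counts pairs with `x_i > y_j` plus half the
#' ties — so "every x below every y" gives U = 0, and element-wise equal
#' samples give U = n_x n_y / 2. The complementary statistic
#' `U' = n_x n_y - U` is returned alongside. The two-sided p is exact (from
#' the exact null distribution of U) when there are no ties and
#' `n_x * n_y <= 400`, otherwise a normal approximation with tie-corrected
#' variance and no continuity correction.
#'
#' @param x,y numeric samples (both nonempty).
#' @param exact force or forbid the exact p; default decides as above.
#' @return a `test_result` with `statistic` (U of `x`), `u_other`, `p_value`.
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both samples must be nonempty", call. = FALSE)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (is.null(exact)) exact <- !ties && nx * ny <= 400
  if (exact && ties)
    stop("exact p is not defined in the presence of ties", call. = FALSE)
  if (exact) {
    p <- min(1, 2 * min(stats::pwilcox(u, nx, ny),
                        1 - stats::pwilcox(u - 1, nx, ny)))
  } else {
    N <- nx + ny
    tj <- table(c(x, y))
    sigma2 <- nx * ny / 12 * ((N + 1) - sum(tj^3 - tj) / (N * (N - 1)))
    if (sigma2 == 0) {
      p <- 1
    } else {
      z <- (u - nx * ny / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  new_test_result(u, NULL, p, "mann_whitney_u",
                  extra = list(u_other = nx * ny - u, exact = exact))
}

#' Summarize acceptability items by group
#'
#' Sample mean and SD (n-1 denominator) per item and group. An item absent
#' for every member of a group (the sleep-disturbance item in the acute
#' groups) yields an `assessed = FALSE` row with `NA` cells — the "not
#' assessed" marker.
#'
#' @param responses data.frame as from [acceptability_table()]; `group` may
#'   also be the pooled label `"acute"`.
#' @param groups which groups (or `"acute"`) to summarize; default: both
#'   pooled acute and each observed label.
#' @return data.frame `group, item, n, mean, sd, assessed`.
#' @export
summarize_acceptability <- function(responses,
                                    groups = c(unique(responses$group),
                                               "acute")) {
  items <- c("comfort", "burden", "sleep_disturbance")
  rows <- list()
  for (g in groups) {
    sel <- if (identical(g, "acute")) is_acute_group(responses$group)
           else responses$group == g
    sub <- responses[sel, , drop = FALSE]
    for (it in items) {
      v <- sub[[it]][!is.na(sub[[it]])]
      rows[[length(rows) + 1L]] <- if (length(v) >= 1)
        data.frame(group = g, item = it, n = length(v), mean = mean(v),
                   sd = if (length(v) > 1) stats::sd(v) else 0,
                   assessed = TRUE)
      else
        data.frame(group = g, item = it, n = 0L, mean = NA_real_,
                   sd = NA_real_, assessed = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Adverse-reaction rates
#'
#' Per-group percentage reporting *no* adverse reaction (one decimal) and
#' the pooled percentage reporting *any* (two decimals), from either a
#' response table or explicit counts.
#'
#' @param responses data.frame with `group` and `adverse_reaction`; or
#'   `NULL` when counts are given directly.
#' @param adverse named integer vector of reporters per group (used with
#'   `total`).
#' @param total named integer vector of denominators per group.
#' @return list `per_group` (data.frame `group, n, adverse, pct_none`) and
#'   `pooled_pct_any`, `pooled_n`, `pooled_adverse`.
#' @export
adverse_rates <- function(responses = NULL, adverse = NULL, total = NULL) {
  if (!is.null(responses)) {
    adverse <- tapply(responses$adverse_reaction, responses$group, sum)
    total <- tapply(responses$adverse_reaction, responses$group, length)
  }
  if (any(total == 0)) stop("zero denominator", call. = FALSE)
  per_group <- data.frame(
    group = names(total), n = as.integer(total),
    adverse = as.integer(adverse[names(total)]),
    pct_none = round_half_up(100 * (total - adverse[names(total)]) / total, 1),
    row.names = NULL)
  list(per_group = per_group,
       pooled_n = sum(total), pooled_adverse = sum(adverse),
       pooled_pct_any = round_half_up(100 * sum(adverse) / sum(total), 2))
}
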