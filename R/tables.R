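#' Build the full acceptability/feasibility table grid
#'
#' Reproduces the three-table reporting structure of the feasibility
#' analysis from a scored cohort:
#'
#' * **acceptability** — per-item mean (SD) for the orthopedic, cardiac,
#'   pooled acute, and chronic groups, with pooled t tests for orthopedic
#'   vs cardiac and acute vs chronic;
#' * **day_compliance** — per-participant medians (ranges) of compliant
#'   days, study days, and compliance rate, group totals, and Mann-Whitney
#'   comparisons for the same two contrasts;
#' * **night_compliance** — the same rows for the within-sleep rule.
#'
#' A comparison whose groups fall below 2 participants is omitted with a
#' warning.
#'
#' @param scores a [score_cohort()] result.
#' @param responses an [acceptability_table()] data.frame (participants who
#'   skipped the survey may be absent).
#' @return list of class `table_suite` with elements `acceptability`,
#'   `day_compliance`, `night_compliance`, and `tests` (a data.frame of all
#'   statistics computed).
#' @export
run_table_suite <- function(scores, responses) {
  summ <- scores$summaries
  tests <- list()
  add_test <- function(table, row, contrast, res) {
    tests[[length(tests) + 1L]] <<- data.frame(
      table = table, row = row, contrast = contrast,
      method = res$method, statistic = res$statistic,
      df = if (!is.null(res$df)) res$df else NA_integer_,
      p_value = res$p_value)
  }

  grp <- function(df, g) {
    sel <- if (identical(g, "acute")) is_acute_group(df$group)
           else df$group == g
    df[sel, , drop = FALSE]
  }

  ## acceptability ----------------------------------------------------------
  acc_sum <- summarize_acceptability(responses)
  items <- c("comfort", "burden", "sleep_disturbance")
  acc_rows <- lapply(items, function(it) {
    cell <- function(g) {
      r <- acc_sum[acc_sum$group == g & acc_sum$item == it, ]
      if (nrow(r) == 0L || !r$assessed) "NA"
      else sprintf("%.2f (%.2f)", r$mean, r$sd)
    }
    data.frame(item = it,
               orthopedic = cell("acute-orthopedic"),
               cardiac = cell("acute-cardiac"),
               acute_total = cell("acute"),
               chronic = cell("chronic-IIPT"))
  })
  acceptability <- do.call(rbind, acc_rows)

  contrasts <- list(
    ortho_vs_cardiac = c("acute-orthopedic", "acute-cardiac"),
    acute_vs_chronic = c("acute", "chronic-IIPT"))
  for (cn in names(contrasts)) {
    gs <- contrasts[[cn]]
    for (it in items) {
      a <- grp(responses, gs[1])[[it]]; a <- a[!is.na(a)]
      b <- grp(responses, gs[2])[[it]]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) {
        if (it != "sleep_disturbance")
          warning("acceptability comparison ", cn, " / ", it,
                  " omitted: group below minimum size", call. = FALSE)
        next
      }
      add_test("acceptability", it, cn, pooled_t_test(a, b))
    }
  }

  ## compliance tables ------------------------------------------------------
  comp_table <- function(what) {
    ccol <- paste0("compliant_", if (what == "day") "days" else "nights")
    scol <- paste0("study_", if (what == "day") "days" else "nights")
    rcol <- paste0(what, "_rate_pct")
    cell_groups <- list(orthopedic = "acute-orthopedic",
                        cardiac = "acute-cardiac",
                        acute_total = "acute",
                        chronic = "chronic-IIPT")
    ag <- lapply(cell_groups, function(g)
      aggregate_group(summ, if (identical(g, "acute"))
        c("acute-orthopedic", "acute-cardiac") else g, what))
    mr <- function(m, r) sprintf("%g (%g-%g)", m, r[1], r[2])
    tab <- data.frame(
      row = c("compliant_median_range", "study_median_range",
              "total_compliant", "total_study", "rate_median_range"),
      stringsAsFactors = FALSE)
    for (g in names(ag)) {
      a <- ag[[g]]
      tab[[g]] <- c(mr(a$median_compliant, a$range_compliant),
                    mr(a$median_study, a$range_study),
                    as.character(a$total_compliant),
                    as.character(a$total_study),
                    sprintf("%.2f (%.2f-%.2f)", a$median_rate,
                            a$range_rate[1], a$range_rate[2]))
    }
    for (cn in names(contrasts)) {
      gs <- contrasts[[cn]]
      sa <- grp(summ, gs[1]); sb <- grp(summ, gs[2])
      if (what == "night") {
        sa <- sa[sa$study_nights > 0, ]; sb <- sb[sb$study_nights > 0, ]
      }
      if (nrow(sa) < 2 || nrow(sb) < 2) {
        warning(what, " comparison ", cn, " omitted: group below minimum size",
                call. = FALSE)
        next
      }
      add_test(paste0(what, "_compliance"), "compliant",
               cn, mann_whitney_u(sa[[ccol]], sb[[ccol]]))
      add_test(paste0(what, "_compliance"), "study",
               cn, mann_whitney_u(sa[[scol]], sb[[scol]]))
      add_test(paste0(what, "_compliance"), "rate",
               cn, mann_whitney_u(sa[[rcol]], sb[[rcol]]))
    }
    tab
  }
  day_tab <- comp_table("day")
  night_tab <- comp_table("night")

  tests_df <- do.call(rbind, tests)
  rownames(tests_df) <- NULL
  structure(list(acceptability = acceptability,
                 day_compliance = day_tab,
                 night_compliance = night_tab,
                 tests = tests_df), class = "table_suite")
}

#' @export
print.table_suite <- function(x, ...) {
  cat("== Acceptability (mean (SD)) ==\n")
  print(x$acceptability, row.names = FALSE)
  cat("\n== Day compliance ==\n")
  print(x$day_compliance, row.names = FALSE)
  cat("\n== Night compliance ==\n")
  print(x$night_compliance, row.names = FALSE)
  cat("\n== Tests ==\n")
  print(x$tests, row.names = FALSE, digits = 4)
  invisible(x)
}
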