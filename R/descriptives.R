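# Group descriptives: omnibus test per variable with FDR-corrected pairwise
# post-hoc contrasts, and a characteristics table in the usual
# median (IQR) / mean (SD) / N (%) layout.

#' Compare a variable between diagnosis groups
#'
#' Chooses the omnibus test from the declared variable kind -- ANOVA for
#' approximately normal continuous variables, Kruskal-Wallis for
#' ordinal/skewed variables, chi-squared for categoricals -- and runs
#' post-hoc pairwise contrasts (Welch t, Mann-Whitney U, or 2x2 chi-squared
#' respectively) with Benjamini-Hochberg adjustment within the variable's
#' pairwise family. Mann-Whitney contrasts use exact enumeration for small
#' tie-free samples and the midrank normal approximation with continuity
#' correction otherwise (the [stats::wilcox.test()] defaults).
#'
#' @param table data.frame.
#' @param variable column to compare.
#' @param kind one of `"continuous-normal"`, `"continuous-ordinal"`,
#'   `"categorical"`.
#' @param group grouping column (default `diagnosis`).
#' @return list of class `group_comparison`: `variable`, `test`,
#'   `statistic`, `df`, `p_raw` and a `pairwise` data.frame with BH-adjusted
#'   p-values.
#' @export
compare_groups <- function(table, variable,
                           kind = c("continuous-normal", "continuous-ordinal",
                                    "categorical"),
                           group = "diagnosis") {
  kind <- match.arg(kind)
  g <- droplevels(factor(table[[group]]))
  x <- table[[variable]]
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  sizes <- table(g)
  if (nlevels(g) < 2L || any(sizes == 0))
    stop(sprintf("compare_groups(): '%s' needs data in at least 2 groups", variable),
         call. = FALSE)
  pair_list <- utils::combn(levels(g), 2, simplify = FALSE)
  pw <- NULL
  if (kind == "continuous-normal") {
    fit <- stats::aov(x ~ g)
    s <- summary(fit)[[1]]
    test <- "ANOVA"; statistic <- s[["F value"]][1]
    df <- s[["Df"]]; p_raw <- s[["Pr(>F)"]][1]
    pw <- lapply(pair_list, function(pr) {
      tt <- stats::t.test(x[g == pr[1]], x[g == pr[2]])
      data.frame(group1 = pr[1], group2 = pr[2],
                 statistic = unname(tt$statistic), p_raw = tt$p.value)
    })
  } else if (kind == "continuous-ordinal") {
    kw <- stats::kruskal.test(x, g)
    test <- "Kruskal-Wallis"; statistic <- unname(kw$statistic)
    df <- unname(kw$parameter); p_raw <- kw$p.value
    pw <- lapply(pair_list, function(pr) {
      wt <- suppressWarnings(stats::wilcox.test(x[g == pr[1]], x[g == pr[2]]))
      data.frame(group1 = pr[1], group2 = pr[2],
                 statistic = unname(wt$statistic), p_raw = wt$p.value)
    })
  } else {
    tab <- table(x, g)
    ch <- suppressWarnings(stats::chisq.test(tab))
    test <- "chi-squared"; statistic <- unname(ch$statistic)
    df <- unname(ch$parameter); p_raw <- ch$p.value
    pw <- lapply(pair_list, function(pr) {
      sub <- tab[, pr, drop = FALSE]
      sub <- sub[rowSums(sub) > 0, , drop = FALSE]
      ch2 <- suppressWarnings(stats::chisq.test(sub))
      data.frame(group1 = pr[1], group2 = pr[2],
                 statistic = unname(ch2$statistic), p_raw = ch2$p.value)
    })
  }
  pairwise <- if (nlevels(g) >= 3L) {
    pwd <- do.call(rbind, pw)
    pwd$p_fdr <- fdr_adjust(pwd$p_raw, family = paste0("posthoc:", variable))
    rownames(pwd) <- NULL
    pwd
  }
  structure(list(variable = variable, kind = kind, test = test,
                 statistic = statistic, df = df, p_raw = p_raw,
                 pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s statistic = %.3f, p = %.4g\n",
              x$variable, x$test, x$statistic, x$p_raw))
  if (!is.null(x$pairwise)) {
    cat("  pairwise (BH-adjusted):\n")
    print(within(x$pairwise, {statistic <- round(statistic, 3)
                              p_raw <- signif(p_raw, 3)
                              p_fdr <- signif(p_fdr, 3)}), row.names = FALSE)
  }
  invisible(x)
}

fmt_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 1)
  sprintf("%g (%g-%g)", q[2], q[1], q[3])
}
fmt_mean_sd <- function(x) sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE),
                                   stats::sd(x, na.rm = TRUE))
fmt_n_pct <- function(flag) sprintf("%d (%.0f%%)", sum(flag, na.rm = TRUE),
                                    100 * mean(flag, na.rm = TRUE))

#' Cohort characteristics table with group comparisons
#'
#' Builds the standard participant-characteristics overview per diagnosis
#' group: group sizes; median (IQR) for age, education level and the MRI
#' ratings (Kruskal-Wallis with Mann-Whitney post-hocs); counts (%) for sex
#' and education categories; mean (SD) with ANOVA and Welch post-hocs for
#' the MMSE and the compound domain scores. Omnibus p-values are BH-adjusted
#' across the tested variables; significant FDR-corrected pairwise contrasts
#' are flagged in the `contrasts` column (`a` = SCD vs MCI, `b` = SCD vs AD,
#' `c` = MCI vs AD).
#'
#' @param scored scored cohort ([score_cohort()]).
#' @return data.frame with one row per characteristic and one column per
#'   group, plus test name, raw and FDR-adjusted omnibus p-values and
#'   pairwise flags.
#' @export
summary_table <- function(scored) {
  g <- droplevels(factor(scored$diagnosis))
  groups <- levels(g)
  spec <- list(
    list(var = "age", label = "Age, median (IQR)", kind = "continuous-ordinal", fmt = fmt_median_iqr),
    list(var = "sex", label = "Male sex, N (%)", kind = "categorical",
         fmt = function(x) fmt_n_pct(x == "male")),
    list(var = "verhage", label = "Education level, median (IQR)", kind = "continuous-ordinal", fmt = fmt_median_iqr),
    list(var = "mmse", label = "MMSE, mean (SD)", kind = "continuous-normal", fmt = fmt_mean_sd),
    list(var = "global_cognition", label = "Global cognition, mean (SD)", kind = "continuous-normal", fmt = fmt_mean_sd),
    list(var = "episodic_memory", label = "Episodic memory, mean (SD)", kind = "continuous-normal", fmt = fmt_mean_sd),
    list(var = "executive", label = "Executive functions, mean (SD)", kind = "continuous-normal", fmt = fmt_mean_sd),
    list(var = "mta", label = "MTA, median (IQR)", kind = "continuous-ordinal", fmt = fmt_median_iqr),
    list(var = "ga", label = "GA, median (IQR)", kind = "continuous-ordinal", fmt = fmt_median_iqr),
    list(var = "wmh", label = "WMH, median (IQR)", kind = "continuous-ordinal", fmt = fmt_median_iqr))
  rows <- list()
  rows[["N"]] <- c(list(characteristic = "N"),
                   stats::setNames(as.list(as.integer(table(g))), groups),
                   list(test = "", p_raw = NA_real_, contrasts = ""))
  comps <- list()
  for (s in spec) {
    cells <- lapply(groups, function(gr) s$fmt(scored[[s$var]][g == gr]))
    cmp <- compare_groups(scored, s$var, kind = s$kind)
    comps[[s$var]] <- cmp
    flags <- ""
    if (!is.null(cmp$pairwise)) {
      sig <- which(cmp$pairwise$p_fdr < 0.05)
      flags <- paste(letters[sig], collapse = "")
    }
    rows[[s$label]] <- c(list(characteristic = s$label),
                         stats::setNames(cells, groups),
                         list(test = cmp$test, p_raw = cmp$p_raw,
                              contrasts = flags))
  }
  # education category breakdown (no separate test; covered by the level test)
  for (lev in c("low", "average", "high")) {
    cells <- lapply(groups, function(gr)
      fmt_n_pct(scored$edu_category[g == gr] == lev))
    rows[[paste0(lev, " education, N (%)")]] <-
      c(list(characteristic = paste0(substr(toupper(lev), 1, 1),
                                     substr(lev, 2, nchar(lev)), " education, N (%)")),
        stats::setNames(cells, groups),
        list(test = "", p_raw = NA_real_, contrasts = ""))
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  tested <- !is.na(out$p_raw)
  out$p_fdr <- NA_real_
  out$p_fdr[tested] <- fdr_adjust(out$p_raw[tested], family = "descriptives")
  attr(out, "comparisons") <- comps
  out
}
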