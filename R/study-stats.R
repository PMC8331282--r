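#' Group summary (mean, SD, n)
#'
#' Container for a published per-group summary of a continuous variable, the
#' form in which clinical tables usually report measurement data
#' ("mean +/- SD", with the group size).
#'
#' @param mean group mean.
#' @param sd group standard deviation (>= 0).
#' @param n group size (>= 2 for any variance-based test).
#' @return object of class \code{group_summary}.
#' @export
group_summary <- function(mean, sd, n) {
  if (sd < 0) stop("sd must be nonnegative", call. = FALSE)
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

as_group_summary <- function(g) {
  if (inherits(g, "group_summary")) return(g)
  group_summary(g[[1]], g[[2]], g[[3]])
}

#' Two-sample pooled-variance Student t from summaries
#'
#' \eqn{t = (m_1 - m_2) / (s_p \sqrt{1/n_1 + 1/n_2})} with
#' \eqn{s_p^2 = ((n_1-1)s_1^2 + (n_2-1)s_2^2) / (n_1+n_2-2)} and
#' \eqn{df = n_1 + n_2 - 2}.  Computable from published group summaries
#' without raw data.
#'
#' @param g1,g2 \code{\link{group_summary}} objects (or (mean, sd, n)
#'   triples).
#' @return list of class \code{summary_test}: statistic, statistic_name
#'   ("t"), df, variant ("pooled"), p_value (two-sided).
#' @export
pooled_t <- function(g1, g2) {
  g1 <- as_group_summary(g1); g2 <- as_group_summary(g2)
  if (g1$sd == 0 && g2$sd == 0) {
    stop("undefined statistic: both group variances are zero", call. = FALSE)
  }
  df <- g1$n + g2$n - 2L
  sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
  t <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  structure(list(statistic = t, statistic_name = "t", df = df,
                 variant = "pooled",
                 p_value = 2 * stats::pt(-abs(t), df)),
            class = "summary_test")
}

#' Two-sample Welch t from summaries
#'
#' \eqn{t = (m_1 - m_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}} with the
#' Welch-Satterthwaite degrees of freedom; drops the equal-variance
#' assumption of \code{\link{pooled_t}}.
#'
#' @inheritParams pooled_t
#' @return list of class \code{summary_test}.
#' @export
welch_t <- function(g1, g2) {
  g1 <- as_group_summary(g1); g2 <- as_group_summary(g2)
  if (g1$sd == 0 && g2$sd == 0) {
    stop("undefined statistic: both group variances are zero", call. = FALSE)
  }
  v1 <- g1$sd^2 / g1$n
  v2 <- g2$sd^2 / g2$n
  t <- (g1$mean - g2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  structure(list(statistic = t, statistic_name = "t", df = df,
                 variant = "welch",
                 p_value = 2 * stats::pt(-abs(t), df)),
            class = "summary_test")
}

#' Pearson chi-square statistic for a 2x2 table
#'
#' Uncorrected Pearson statistic
#' \eqn{\chi^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}, df = 1; the Yates
#' variant subtracts N/2 from |ad - bc| before squaring (floored at 0).
#' Rows are the two groups, columns event / no event.
#'
#' @param a,b,c,d nonnegative integer cell counts, or \code{a} may be a
#'   2x2 matrix.
#' @param yates apply the continuity correction? (default FALSE)
#' @return list of class \code{summary_test}: statistic, statistic_name
#'   ("chi2"), df = 1, variant, p_value.
#' @export
chi2_2x2 <- function(a, b = NULL, c = NULL, d = NULL, yates = FALSE) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  N <- a + b + c + d
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) {
    stop("undefined statistic: zero marginal in 2x2 table", call. = FALSE)
  }
  num <- abs(a * d - b * c)
  if (yates) num <- max(num - N / 2, 0)
  stat <- N * num^2 / prod(marg)
  structure(list(statistic = stat, statistic_name = "chi2", df = 1L,
                 variant = if (yates) "yates" else "pearson-uncorrected",
                 p_value = stats::pchisq(stat, 1, lower.tail = FALSE)),
            class = "summary_test")
}

#' @export
print.summary_test <- function(x, ...) {
  cat(x$statistic_name, "=", format(x$statistic, digits = 6),
      "(", x$variant, ", df =", format(x$df, digits = 5),
      ", p =", format(x$p_value, digits = 4), ")\n")
  invisible(x)
}

read_fixture <- function(name) {
  path <- system.file("extdata", name, package = "ssfcm", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Recompute the packaged clinical-table statistics
#'
#' Recomputes every two-sample statistic from the packaged group summaries
#' (pooled t) and 2x2 counts (uncorrected Pearson chi-square), and compares
#' each, at 3-decimal rounding, with the value printed in the source tables.
#' One row (the maternal-age comparison) is carried as annotated: its printed
#' value matches the Welch form of the t statistic rather than the pooled
#' form used everywhere else, so it is reported but excluded from pass/fail.
#'
#' @param summaries,counts,printed optional data.frames overriding the
#'   packaged fixtures (same columns); intended for testing.
#' @return data.frame of class \code{stats_report} with columns table, row,
#'   statistic, computed, printed, match, annotated.
#' @export
reproduce_tables <- function(summaries = NULL, counts = NULL, printed = NULL) {
  if (is.null(summaries)) summaries <- read_fixture("group_summaries.tsv")
  if (is.null(counts)) counts <- read_fixture("contingency_2x2.tsv")
  if (is.null(printed)) printed <- read_fixture("printed_statistics.tsv")

  rows <- list()
  for (i in seq_len(nrow(printed))) {
    pr <- printed[i, ]
    if (pr$statistic == "t") {
      g <- summaries[summaries$table == pr$table & summaries$row == pr$row, ]
      if (nrow(g) != 2L) stop("fixture rows missing for ", pr$row, call. = FALSE)
      g <- g[order(g$group), ]
      res <- pooled_t(group_summary(g$mean[1], g$sd[1], g$n[1]),
                      group_summary(g$mean[2], g$sd[2], g$n[2]))
      computed <- abs(res$statistic)
    } else {
      ct <- counts[counts$table == pr$table & counts$row == pr$row, ]
      if (nrow(ct) != 1L) stop("fixture row missing for ", pr$row, call. = FALSE)
      res <- chi2_2x2(ct$a, ct$b, ct$c, ct$d)
      computed <- res$statistic
    }
    rows[[i]] <- data.frame(table = pr$table, row = pr$row,
                            statistic = pr$statistic,
                            computed = computed, printed = pr$printed,
                            match = round(computed, 3) == pr$printed,
                            annotated = as.logical(pr$annotated),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("stats_report", "data.frame")
  out
}

#' @export
print.stats_report <- function(x, ...) {
  cat("Recomputed clinical-table statistics (3-decimal rounding)\n\n")
  df <- as.data.frame(x)
  df$computed <- sprintf("%.3f", df$computed)
  df$printed <- sprintf("%.3f", df$printed)
  df$status <- ifelse(df$annotated, "annotated",
                      ifelse(df$match, "ok", "MISMATCH"))
  print(df[, c("table", "row", "statistic", "computed", "printed", "status")],
        row.names = FALSE)
  n_target <- sum(!df$annotated)
  n_ok <- sum(x$match & !x$annotated)
  cat("\n", n_ok, "of", n_target, "target statistics reproduced exactly\n")
  invisible(x)
}
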