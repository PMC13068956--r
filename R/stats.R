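# Replicate statistics: technical-replicate aggregation and the paired,
# ratio-paired and one-way ANOVA tests applied to per-biological-replicate
# averaged values. No multiple-testing correction is applied (per-panel
# tests are reported raw).

#' Aggregate technical replicates into biological-replicate values
#'
#' Arithmetic mean per (replicate, condition, measurement), recording the
#' number of technical replicates averaged. Row order of the input is
#' irrelevant.
#'
#' @param data Data.frame with columns `replicate`, `condition`,
#'   `measurement`, `value`.
#' @return Data.frame with one row per group: `replicate`, `condition`,
#'   `measurement`, `value` (mean), `n_technical`.
#' @export
aggregate_technical <- function(data) {
  stopifnot(all(c("replicate", "condition", "measurement", "value")
                %in% names(data)))
  if (nrow(data) == 0L) abort("no measurements to aggregate")
  key <- interaction(data$replicate, data$condition, data$measurement,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(data, key), function(g)
    data.frame(replicate = g$replicate[1], condition = g$condition[1],
               measurement = g$measurement[1], value = mean(g$value),
               n_technical = nrow(g))))
  out <- out[order(out$measurement, out$condition, out$replicate), ]
  rownames(out) <- NULL
  out
}

check_pairs <- function(a, b) {
  if (length(a) != length(b)) abort("paired vectors must have equal length")
  if (length(a) < 2L) abort("need at least 2 pairs")
  if (anyNA(a) || anyNA(b)) abort("paired values must be finite")
}

#' Two-sided paired t-test
#'
#' Standard paired t on the differences `b - a` with `df = n - 1`. Identical
#' values in every pair (zero difference variance) are rejected as
#' degenerate.
#'
#' @param a,b Paired value vectors (matched by replicate).
#' @return A list: `t`, `df`, `p`, `mean_difference`, `stars`.
#' @export
paired_t <- function(a, b) {
  check_pairs(a, b)
  d <- b - a
  # relative guard: constant differences up to floating-point noise
  if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + .Machine$double.xmin))
    abort("degenerate variance: all paired differences identical")
  ht <- stats::t.test(b, a, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_difference = mean(d),
       stars = p_stars(ht$p.value))
}

#' Two-sided ratio paired t-test
#'
#' Paired t applied to log-transformed values (natural log), i.e. a test of
#' a multiplicative (fold-change) null. Equivalent to
#' `paired_t(log(a), log(b))`; requires strictly positive values.
#'
#' @param a,b Paired positive value vectors.
#' @return A list: `t`, `df`, `p`, `mean_log_ratio`, `geometric_fold`,
#'   `stars`.
#' @export
ratio_paired_t <- function(a, b) {
  check_pairs(a, b)
  if (any(a <= 0) || any(b <= 0))
    abort("ratio paired t-test requires strictly positive values")
  lr <- log(b) - log(a)
  if (stats::sd(lr) <= 1e-10 * (abs(mean(lr)) + .Machine$double.xmin))
    abort("degenerate variance: constant ratio across pairs")
  res <- paired_t(log(a), log(b))
  c(res[c("t", "df", "p")],
    list(mean_log_ratio = mean(lr), geometric_fold = exp(mean(lr)),
         stars = p_stars(res$p)))
}

#' One-way ANOVA
#'
#' Standard between/within sum-of-squares decomposition across two or more
#' groups (equal variances assumed).
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return A list: `F`, `df_between`, `df_within`, `p`, `stars`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    abort("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    abort("every group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), df_between = unname(ht$parameter[1]),
       df_within = unname(ht$parameter[2]), p = ht$p.value,
       stars = p_stars(ht$p.value))
}

#' Significance stars
#'
#' Caption-style annotation: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001, `ns` otherwise.
#'
#' @param p P-value.
#' @return Character annotation.
#' @export
p_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "****" else if (p < 1e-3) "***"
  else if (p < 1e-2) "**" else if (p < 0.05) "*" else "ns"
}

#' Per-measurement summary report of paired comparisons
#'
#' Runs the requested test for each measurement in a replicate table with
#' exactly two conditions, pairing rows by replicate id.
#'
#' @param table A replicate table (see [aggregate_technical()]).
#' @param test `"paired"`, `"ratio"` or `"anova"`.
#' @return Data.frame: `measurement`, `n`, group means, `statistic`, `df`,
#'   `p`, `stars`.
#' @export
stats_report <- function(table, test = c("paired", "ratio", "anova")) {
  test <- match.arg(test)
  out <- lapply(split(table, table$measurement), function(g) {
    conds <- sort(unique(g$condition))
    if (test %in% c("paired", "ratio")) {
      if (length(conds) != 2L)
        abort("paired designs need exactly two conditions")
      a <- g$value[g$condition == conds[1]][order(g$replicate[g$condition == conds[1]])]
      b <- g$value[g$condition == conds[2]][order(g$replicate[g$condition == conds[2]])]
      res <- if (test == "paired") paired_t(a, b) else ratio_paired_t(a, b)
      data.frame(measurement = g$measurement[1], n = length(a),
                 mean_a = mean(a), mean_b = mean(b),
                 statistic = res$t, df = res$df, p = res$p,
                 stars = res$stars)
    } else {
      grp <- split(g$value, g$condition)
      res <- one_way_anova(grp)
      data.frame(measurement = g$measurement[1],
                 n = nrow(g), mean_a = NA_real_, mean_b = NA_real_,
                 statistic = res$F, df = res$df_between, p = res$p,
                 stars = res$stars)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
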