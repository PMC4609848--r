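#' Group summary: mean and t-based 95% confidence half-width
#'
#' The "mean +/- 95% CI" convention used in regional CEST/DTI comparison
#' tables: half-width = t(0.975, n-1) * sd / sqrt(n).
#'
#' @param x numeric samples, n >= 2.
#' @return list: `n`, `mean`, `ci95_halfwidth`.
#' @export
summarize_group <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 samples to summarize", call. = FALSE)
  n <- length(x)
  list(n = n, mean = mean(x),
       ci95_halfwidth = stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n))
}

#' Independent-samples t-test
#'
#' Student's pooled-variance test by default (the SPSS convention when equal
#' variances are assumed) or Welch. Two groups with zero variance and equal
#' means return p = 1 with a degenerate flag instead of an error.
#'
#' @param a,b numeric samples, each n >= 2.
#' @param variant `"student"` (pooled) or `"welch"`.
#' @return list: `t`, `df`, `p`, `variant`, `degenerate`.
#' @export
ttest_independent <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stop_if_not(length(a) >= 2 && length(b) >= 2, "each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  variant = variant, degenerate = TRUE))
    return(list(t = Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2, p = 0,
                variant = variant, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "student"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, variant = variant, degenerate = FALSE)
}

#' Welch t-test reconstructed from printed summary statistics
#'
#' Bridges "mean +/- 95% CI" table rows back to a p-value: each half-width is
#' converted to a standard error via SE = ci95 / t(0.975, n-1), then a Welch
#' t statistic with Welch-Satterthwaite degrees of freedom is formed. (No
#' pooled sd is recoverable from two CIs, so the Welch form is used.)
#'
#' @param mean_a,ci95_a,n_a group A mean, CI half-width, sample count.
#' @param mean_b,ci95_b,n_b group B likewise.
#' @return list: `t`, `df`, `p`.
#' @export
ttest_from_summary <- function(mean_a, ci95_a, n_a, mean_b, ci95_b, n_b) {
  stop_if_not(n_a >= 2 && n_b >= 2, "need n >= 2 per group")
  stop_if_not(ci95_a > 0 && ci95_b > 0, "CI half-widths must be positive")
  se_a <- ci95_a / stats::qt(0.975, n_a - 1)
  se_b <- ci95_b / stats::qt(0.975, n_b - 1)
  se2 <- se_a^2 + se_b^2
  t <- (mean_a - mean_b) / sqrt(se2)
  df <- se2^2 / (se_a^4 / (n_a - 1) + se_b^4 / (n_b - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Levene's test of homogeneity of variances (mean-centered)
#'
#' One-way ANOVA on the absolute deviations from the group means, the
#' classic mean-centered form.
#'
#' @param groups list of numeric vectors, each n >= 2.
#' @return list: `W`, `df1`, `df2`, `p`, `degenerate`.
#' @export
levene_test <- function(groups) {
  stop_if_not(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  stop_if_not(all(vapply(groups, length, integer(1)) >= 2), "each group needs n >= 2")
  z <- lapply(groups, function(g) abs(g - mean(g)))
  k <- length(z)
  n <- vapply(z, length, integer(1))
  N <- sum(n)
  zb <- vapply(z, mean, numeric(1))
  zg <- sum(unlist(z)) / N
  ssb <- sum(n * (zb - zg)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zb[i])^2), numeric(1)))
  if (ssw == 0)
    return(list(W = 0, df1 = k - 1, df2 = N - k, p = 1, degenerate = TRUE))
  W <- (ssb / (k - 1)) / (ssw / (N - k))
  list(W = W, df1 = k - 1, df2 = N - k,
       p = stats::pf(W, k - 1, N - k, lower.tail = FALSE), degenerate = FALSE)
}

#' One-way ANOVA
#'
#' Classic between/within decomposition (equal-variance F test), as used for
#' the three-group staging comparisons; `df_between = k - 1`.
#'
#' @param groups list of numeric vectors, each n >= 2.
#' @return list: `df_between`, `df_within`, `F`, `p`, `degenerate`.
#' @export
anova_oneway <- function(groups) {
  stop_if_not(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  stop_if_not(all(vapply(groups, length, integer(1)) >= 2), "each group needs n >= 2")
  k <- length(groups)
  N <- sum(lengths(groups))
  if (all(vapply(groups, stats::sd, numeric(1)) == 0)) {
    means <- vapply(groups, mean, numeric(1))
    if (max(means) == min(means))
      return(list(df_between = k - 1, df_within = N - k, F = 0, p = 1,
                  degenerate = TRUE))
    return(list(df_between = k - 1, df_within = N - k, F = Inf, p = 0,
                degenerate = TRUE))
  }
  val <- unlist(groups)
  g <- factor(rep(seq_len(k), lengths(groups)))
  ht <- stats::oneway.test(val ~ g, var.equal = TRUE)
  list(df_between = unname(ht$parameter[1]), df_within = unname(ht$parameter[2]),
       F = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
}

posthoc_frame <- function(labels, i, j, diff, p, lo, hi, method) {
  data.frame(group1 = labels[i], group2 = labels[j], diff = diff,
             p = pmin(pmax(p, 0), 1), ci_lo = lo, ci_hi = hi,
             method = method, row.names = NULL)
}

#' Tukey HSD post hoc comparisons
#'
#' All pairwise comparisons with the studentized-range distribution, pooled
#' variance and df = N - k; simultaneous 95% confidence intervals.
#'
#' @param groups named list of numeric vectors.
#' @param conf.level simultaneous confidence level.
#' @return data frame with one row per pair: `group1`, `group2`, `diff`
#'   (group1 - group2), `p`, `ci_lo`, `ci_hi`, `method`.
#' @export
tukey_hsd <- function(groups, conf.level = 0.95) {
  stop_if_not(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  labels <- if (!is.null(names(groups))) names(groups) else
    paste0("g", seq_along(groups))
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  s2 <- ssw / (N - k)
  pairs <- utils::combn(k, 2)
  out <- lapply(seq_len(ncol(pairs)), function(c) {
    i <- pairs[1, c]; j <- pairs[2, c]
    diff <- means[i] - means[j]
    se <- sqrt(s2 / 2 * (1 / n[i] + 1 / n[j]))
    if (se == 0) {
      p <- if (diff == 0) 1 else 0
      return(posthoc_frame(labels, i, j, diff, p, diff, diff, "tukey"))
    }
    q <- abs(diff) / se
    p <- stats::ptukey(q, k, N - k, lower.tail = FALSE)
    qc <- stats::qtukey(conf.level, k, N - k)
    posthoc_frame(labels, i, j, diff, p, diff - qc * se, diff + qc * se, "tukey")
  })
  do.call(rbind, out)
}

#' Games-Howell post hoc comparisons
#'
#' Pairwise comparisons for heteroscedastic groups: per-pair standard error
#' sqrt(s_i^2/n_i + s_j^2/n_j), Welch-Satterthwaite degrees of freedom, and
#' p from the studentized range with q = |diff| * sqrt(2) / SE.
#'
#' @inheritParams tukey_hsd
#' @return data frame as in [tukey_hsd()], `method = "games_howell"`.
#' @export
games_howell <- function(groups, conf.level = 0.95) {
  stop_if_not(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  labels <- if (!is.null(names(groups))) names(groups) else
    paste0("g", seq_along(groups))
  k <- length(groups)
  n <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  vars <- vapply(groups, stats::var, numeric(1))
  pairs <- utils::combn(k, 2)
  out <- lapply(seq_len(ncol(pairs)), function(c) {
    i <- pairs[1, c]; j <- pairs[2, c]
    diff <- means[i] - means[j]
    vi <- vars[i] / n[i]; vj <- vars[j] / n[j]
    se <- sqrt(vi + vj)
    if (se == 0) {
      p <- if (diff == 0) 1 else 0
      return(posthoc_frame(labels, i, j, diff, p, diff, diff, "games_howell"))
    }
    df <- (vi + vj)^2 / (vi^2 / (n[i] - 1) + vj^2 / (n[j] - 1))
    q <- abs(diff) * sqrt(2) / se
    p <- stats::ptukey(q, k, df, lower.tail = FALSE)
    qc <- stats::qtukey(conf.level, k, df)
    posthoc_frame(labels, i, j, diff, p,
                  diff - qc * se / sqrt(2), diff + qc * se / sqrt(2),
                  "games_howell")
  })
  do.call(rbind, out)
}

#' Full group-comparison chain on an ROI sample table
#'
#' For each region x metric cell: (a) control-vs-PD independent t-test with
#' mean +/- 95% CI summaries; (b) three-group one-way ANOVA across
#' control / early / advanced stages; (c) a Levene homogeneity gate selecting
#' the post hoc family - Tukey HSD when Levene's p >= `alpha_levene`,
#' Games-Howell otherwise. Bilateral ROIs enter as separate samples by
#' default; `sample_unit = "subject"` averages hemispheres first.
#'
#' @param table a long-format ROI table with columns `subject_id`, `group`,
#'   `stage`, `region`, `hemisphere`, `metric`, `value`.
#' @param sample_unit `"hemisphere"` (each side its own sample) or
#'   `"subject"`.
#' @param variant t-test flavor, see [ttest_independent()].
#' @param alpha_levene significance threshold of the homogeneity gate.
#' @return list of class `cohort_analysis`: `summaries`, `two_group`,
#'   `three_group`, `posthoc` data frames plus the options used.
#' @export
analyze_roi_table <- function(table, sample_unit = c("hemisphere", "subject"),
                              variant = c("student", "welch"),
                              alpha_levene = 0.05) {
  sample_unit <- match.arg(sample_unit)
  variant <- match.arg(variant)
  need <- c("subject_id", "group", "stage", "region", "metric", "value")
  stop_if_not(all(need %in% names(table)), "malformed ROI table")
  df <- as.data.frame(table)
  if (sample_unit == "subject") {
    df <- stats::aggregate(value ~ subject_id + group + stage + region + metric,
                           data = df, FUN = mean)
  }
  stages <- c("control", "early", "advanced")
  have_stages <- all(stages %in% unique(df$stage))
  if (!have_stages)
    warning("stage labels incomplete; only the two-group analysis is run")
  cells <- unique(df[, c("region", "metric")])
  summaries <- two_group <- three_group <- posthoc <- list()
  for (r in seq_len(nrow(cells))) {
    reg <- cells$region[r]; met <- cells$metric[r]
    sub <- df[df$region == reg & df$metric == met, ]
    ctrl <- sub$value[sub$group == "control"]
    pd <- sub$value[sub$group == "pd"]
    if (length(ctrl) < 2 || length(pd) < 2) next
    for (g in c("control", "pd")) {
      s <- summarize_group(sub$value[sub$group == g])
      summaries[[length(summaries) + 1]] <- data.frame(
        region = reg, metric = met, level = g, n = s$n, mean = s$mean,
        ci95 = s$ci95_halfwidth)
    }
    tt <- ttest_independent(ctrl, pd, variant = variant)
    two_group[[length(two_group) + 1]] <- data.frame(
      region = reg, metric = met, t = tt$t, df = tt$df, p = tt$p,
      significant = tt$p < 0.05)
    if (!have_stages) next
    gl <- lapply(stages, function(s) sub$value[sub$stage == s])
    names(gl) <- stages
    if (any(lengths(gl) < 2)) next
    for (s in stages) {
      ss <- summarize_group(gl[[s]])
      summaries[[length(summaries) + 1]] <- data.frame(
        region = reg, metric = met, level = paste0("stage:", s), n = ss$n,
        mean = ss$mean, ci95 = ss$ci95_halfwidth)
    }
    lv <- levene_test(gl)
    av <- anova_oneway(gl)
    use_gh <- lv$p < alpha_levene
    ph <- if (use_gh) games_howell(gl) else tukey_hsd(gl)
    three_group[[length(three_group) + 1]] <- data.frame(
      region = reg, metric = met, levene_W = lv$W, levene_p = lv$p,
      df_between = av$df_between, F = av$F, p = av$p,
      posthoc_method = if (use_gh) "games_howell" else "tukey")
    ph$region <- reg; ph$metric <- met
    posthoc[[length(posthoc) + 1]] <- ph
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else NULL
  structure(list(summaries = bind(summaries), two_group = bind(two_group),
                 three_group = bind(three_group), posthoc = bind(posthoc),
                 sample_unit = sample_unit, variant = variant,
                 alpha_levene = alpha_levene),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, digits = 3, ...) {
  cat("Cohort analysis (sample unit:", x$sample_unit, ")\n\n")
  if (!is.null(x$summaries)) {
    cat("Group summaries (mean +/- 95% CI):\n")
    s <- x$summaries
    s$summary <- sprintf("%.2f +/- %.2f", s$mean, s$ci95)
    print(s[, c("region", "metric", "level", "n", "summary")], row.names = FALSE)
    cat("\n")
  }
  if (!is.null(x$two_group)) {
    cat("Control vs PD t-tests:\n")
    print(transform(x$two_group, t = round(t, digits), df = round(df, 1),
                    p = signif(p, digits)), row.names = FALSE)
    cat("\n")
  }
  if (!is.null(x$three_group)) {
    cat("Staging one-way ANOVA (Levene-gated post hoc):\n")
    print(transform(x$three_group, levene_W = round(levene_W, digits),
                    levene_p = signif(levene_p, digits),
                    F = round(F, digits), p = signif(p, digits)),
          row.names = FALSE)
    cat("\n")
  }
  if (!is.null(x$posthoc)) {
    cat("Pairwise post hoc comparisons:\n")
    print(transform(x$posthoc, diff = round(diff, digits),
                    p = signif(p, digits), ci_lo = round(ci_lo, digits),
                    ci_hi = round(ci_hi, digits)), row.names = FALSE)
  }
  invisible(x)
}
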