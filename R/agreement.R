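#' Two-way intraclass correlation coefficient with F-based confidence interval
#'
#' Single-measurement ICC from a two-way mixed-effects model, used to
#' quantify agreement between two dietary assessment tools rated on the same
#' subjects. The default form is consistency, ICC(3,1):
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E)}
#' where \eqn{MS_R} is the between-subject and \eqn{MS_E} the residual mean
#' square of the subject-by-rater two-way ANOVA. `"absolute_agreement"`
#' (ICC(A,1)) additionally charges the rater variance to disagreement. 95%
#' confidence limits use the exact F-distribution method (consistency) or the
#' McGraw–Wong approximation (absolute agreement). The point estimate is
#' labelled with the conventional interpretation band: poor below 0.50,
#' moderate from 0.50, good from 0.75, excellent above 0.90.
#'
#' @param ratings Data frame or matrix with one row per subject and one
#'   numeric column per rater/tool (k >= 2 columns, n >= 3 complete rows).
#' @param form `"consistency"` (default) or `"absolute_agreement"`.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `icc_result`: list with `icc`, `ci_low`,
#'   `ci_high`, `n`, `k`, `form`, `band`, `conf_level` and the ANOVA mean
#'   squares `ms`.
#' @export
icc_two_way <- function(ratings, form = c("consistency", "absolute_agreement"),
                        conf_level = 0.95) {
  form <- match.arg(form)
  x <- as.matrix(as.data.frame(ratings)[, vapply(as.data.frame(ratings), is.numeric, TRUE), drop = FALSE])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  k <- ncol(x)
  if (k < 2L) nova_abort("need at least 2 raters/tools", "nova24r_contract_error")
  if (n < 3L) nova_abort("need at least 3 complete subject pairs", "nova24r_contract_error")

  m <- mean(x)
  ri <- rowMeans(x)
  cj <- colMeans(x)
  msr <- k * sum((ri - m)^2) / (n - 1)
  msc <- n * sum((cj - m)^2) / (k - 1)
  mse <- sum((x - outer(ri, rep(1, k)) - outer(rep(1, n), cj) + m)^2) /
    ((n - 1) * (k - 1))

  if (msr + (k - 1) * mse <= 0) {
    nova_abort("degenerate data: no between-subject or residual variance",
               "nova24r_degenerate_error")
  }

  alpha <- 1 - conf_level
  if (form == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse == 0) {
      lo <- hi <- icc
    } else {
      fobs <- msr / mse
      df1 <- n - 1
      df2 <- (n - 1) * (k - 1)
      fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
      fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
    }
  } else {
    denom <- msr + (k - 1) * mse + k / n * (msc - mse)
    icc <- (msr - mse) / denom
    if (mse == 0 && msc == mse) {
      lo <- hi <- icc
    } else {
      a <- (k * icc) / (n * (1 - icc))
      b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f1 <- stats::qf(1 - alpha / 2, n - 1, v)
      f2 <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - f1 * mse) / (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (f2 * msr - mse) / (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    }
  }
  structure(
    list(icc = icc, ci_low = min(lo, icc), ci_high = max(hi, icc),
         n = n, k = k, form = form, band = icc_band(icc),
         conf_level = conf_level, ms = c(msr = msr, msc = msc, mse = mse)),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (two-way mixed, single measurement, %s): %.3f (%.0f%% CI %.3f, %.3f)\n",
              gsub("_", " ", x$form), x$icc, 100 * x$conf_level, x$ci_low, x$ci_high))
  cat(sprintf("  n = %d subjects, k = %d raters; agreement: %s\n", x$n, x$k, x$band))
  invisible(x)
}

#' Interpretation bands for ICC and PABAK
#'
#' `icc_band()` labels an ICC as poor (below 0.50), moderate (0.50 to below
#' 0.75), good (0.75 to 0.90) or excellent (above 0.90). `pabak_band()`
#' labels a kappa-type statistic as none (at or below 0), none-to-slight
#' (below 0.20), fair (to 0.40), moderate (to 0.60), substantial (to 0.80)
#' or almost perfect (above 0.80). Both are total and monotone.
#'
#' @param x Numeric vector of coefficient values.
#' @return Character vector of band labels.
#' @export
icc_band <- function(x) {
  dplyr::case_when(
    is.na(x) ~ NA_character_,
    x < 0.50 ~ "poor",
    x < 0.75 ~ "moderate",
    x <= 0.90 ~ "good",
    TRUE ~ "excellent"
  )
}

#' @rdname icc_band
#' @export
pabak_band <- function(x) {
  dplyr::case_when(
    is.na(x) ~ NA_character_,
    x <= 0 ~ "none",
    x < 0.20 ~ "none_to_slight",
    x <= 0.40 ~ "fair",
    x <= 0.60 ~ "moderate",
    x <= 0.80 ~ "substantial",
    TRUE ~ "almost_perfect"
  )
}

#' Paired comparison of mean Nova energy shares between two tools
#'
#' For each Nova group, computes each tool's mean share with a normal-theory
#' 95% confidence interval, the mean paired difference with its confidence
#' interval, and a paired test of equality (t-test by default, Wilcoxon
#' signed-rank by flag). Zero variance of the paired differences makes the
#' test undefined; such groups are flagged `degenerate` with an `NA`
#' p-value.
#'
#' @param paired Long paired-shares tibble with columns `participant_id`,
#'   `tool`, `nova_group`, `share_pct`, containing exactly two tools.
#' @param method `"t"` (paired t-test, default) or `"wilcoxon"`.
#' @param conf_level Confidence level for all intervals.
#' @param alpha Significance threshold for the `significant` flag.
#' @return A tibble with one row per Nova group.
#' @export
compare_means <- function(paired, method = c("t", "wilcoxon"),
                          conf_level = 0.95, alpha = 0.05) {
  method <- match.arg(method)
  tools <- sort(unique(paired$tool))
  if (length(tools) != 2L) {
    nova_abort("paired shares must contain exactly two tools", "nova24r_contract_error")
  }
  norm_ci <- function(v) {
    se <- stats::sd(v) / sqrt(length(v))
    q <- stats::qt(1 - (1 - conf_level) / 2, length(v) - 1)
    c(mean(v) - q * se, mean(v) + q * se)
  }
  purrr::map_dfr(sort(unique(paired$nova_group)), function(g) {
    d <- paired[paired$nova_group == g, ]
    w <- tidyr::pivot_wider(d[, c("participant_id", "tool", "share_pct")],
                            names_from = "tool", values_from = "share_pct")
    w <- w[stats::complete.cases(w), ]
    a <- w[[tools[1]]]
    b <- w[[tools[2]]]
    if (length(a) < 2L) {
      nova_abort("need at least 2 complete pairs per group", "nova24r_contract_error")
    }
    diffs <- a - b
    # zero (or numerically negligible) variance of the differences makes the
    # paired test undefined
    degenerate <- stats::sd(diffs) <=
      1e-10 * max(1, abs(mean(diffs)), abs(mean(a)), abs(mean(b)))
    if (degenerate) {
      p <- NA_real_
      dci <- c(mean(diffs), mean(diffs))
    } else if (method == "t") {
      tt <- stats::t.test(a, b, paired = TRUE, conf.level = conf_level)
      p <- tt$p.value
      dci <- unname(tt$conf.int)
    } else {
      wt <- stats::wilcox.test(a, b, paired = TRUE, conf.int = TRUE,
                               conf.level = conf_level, exact = FALSE)
      p <- wt$p.value
      dci <- unname(wt$conf.int)
    }
    ca <- norm_ci(a)
    cb <- norm_ci(b)
    tibble(
      nova_group = g, n = length(a), method = method,
      mean_a = mean(a), ci_a_low = ca[1], ci_a_high = ca[2],
      mean_b = mean(b), ci_b_low = cb[1], ci_b_high = cb[2],
      mean_diff = mean(diffs), diff_ci_low = dci[1], diff_ci_high = dci[2],
      p_value = p, significant = !is.na(p) & p < alpha,
      degenerate = degenerate
    )
  })
}

#' Quintile cross-classification with prevalence- and bias-adjusted kappa
#'
#' Ranks participants into quintiles of one Nova group's energy share under
#' each tool separately (each tool's quintiles come from its own empirical
#' distribution), tabulates joint membership, and summarises ranking
#' agreement with the proportion classified into the same quintile, the
#' proportion in the same or an adjacent quintile, and PABAK
#' \eqn{= (5 P_o - 1)/4} for 5 categories.
#'
#' @param pairs Data frame with two numeric columns (tool A, tool B), one row
#'   per participant, n >= 5.
#' @param mode `"rank"` (default): rank-based fifths as balanced as possible,
#'   ties broken by stable row order; `"quantile"`: cut at each tool's
#'   empirical 20/40/60/80 percentiles — if heavy ties empty a quintile a
#'   warning is raised and the rank-based split is used instead.
#' @return An object of class `quintile_agreement`: `cross_table` (5 x 5),
#'   `p_same`, `p_same_or_adjacent`, `pabak`, `band`, `n`, `mode`.
#' @export
quintile_agreement <- function(pairs, mode = c("rank", "quantile")) {
  mode <- match.arg(mode)
  x <- as.data.frame(pairs)
  num <- x[, vapply(x, is.numeric, TRUE), drop = FALSE]
  if (ncol(num) < 2L) nova_abort("need two numeric columns", "nova24r_contract_error")
  a <- num[[1]]
  b <- num[[2]]
  keep <- stats::complete.cases(a, b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 5L) nova_abort("need at least 5 pairs for quintiles", "nova24r_contract_error")

  tie_fallback <- FALSE
  cut5 <- function(v) {
    if (mode == "quantile") {
      br <- unique(stats::quantile(v, probs = seq(0.2, 0.8, by = 0.2)))
      q <- findInterval(v, br, left.open = TRUE) + 1L
      if (length(unique(q)) < 5L) {
        tie_fallback <<- TRUE
        q <- dplyr::ntile(v, 5)
      }
      q
    } else {
      dplyr::ntile(v, 5)
    }
  }
  qa <- cut5(a)
  qb <- cut5(b)
  if (tie_fallback) {
    warn("heavy ties empty a quintile under quantile thresholds; using rank-based split",
         class = "nova24r_tie_warning")
  }
  tab <- table(factor(qa, 1:5), factor(qb, 1:5))
  p_same <- sum(diag(tab)) / n
  p_adj <- mean(abs(qa - qb) <= 1)
  pabak <- (5 * p_same - 1) / 4
  structure(
    list(cross_table = unclass(tab), p_same = p_same,
         p_same_or_adjacent = p_adj, pabak = pabak,
         band = pabak_band(pabak), n = n, mode = mode),
    class = "quintile_agreement"
  )
}

#' @export
print.quintile_agreement <- function(x, ...) {
  cat(sprintf("Quintile cross-classification (n = %d, %s split)\n", x$n, x$mode))
  print(x$cross_table)
  cat(sprintf("  same quintile: %.1f%%; same or adjacent: %.1f%%\n",
              100 * x$p_same, 100 * x$p_same_or_adjacent))
  cat(sprintf("  PABAK = %.3f (%s)\n", x$pabak, gsub("_", " ", x$band)))
  invisible(x)
}

#' Sample size for a reliability study based on the ICC
#'
#' Walter–Eliasziw–Donner approximation for the number of subjects needed to
#' detect an intraclass correlation `rho1` against the null value `rho0`
#' with `k` ratings per subject. With \eqn{\theta = \rho/(1-\rho)} and
#' \eqn{C_0 = (1 + k\theta_0)/(1 + k\theta_1)},
#' \deqn{n = 1 + \frac{2k (z_{1-\alpha} + z_{1-\beta})^2}{(k-1)(\ln C_0)^2}}
#' rounded up. `alpha` is one-sided, the standard framing for testing
#' reliability above a null value; at `rho0 = 0`, `rho1 = 0.2`, `k = 2`,
#' 80% power and one-sided 0.05, the minimum sample size is 152 subjects.
#'
#' @param rho0 Null ICC (0 <= rho0 < rho1).
#' @param rho1 Alternative ICC to detect (rho0 < rho1 < 1).
#' @param k Ratings per subject (>= 2).
#' @param alpha One-sided type-I error.
#' @param power Target power (1 - beta).
#' @return Minimum number of subjects (integer).
#' @export
icc_sample_size <- function(rho0, rho1, k = 2, alpha = 0.05, power = 0.80) {
  if (!(rho0 >= 0 && rho0 < 1 && rho1 < 1 && rho1 > rho0)) {
    nova_abort("need 0 <= rho0 < rho1 < 1", "nova24r_contract_error")
  }
  if (k < 2) nova_abort("need k >= 2 ratings per subject", "nova24r_contract_error")
  za <- stats::qnorm(1 - alpha)
  zb <- stats::qnorm(power)
  theta0 <- rho0 / (1 - rho0)
  theta1 <- rho1 / (1 - rho1)
  c0 <- (1 + k * theta0) / (1 + k * theta1)
  as.integer(ceiling(1 + 2 * k * (za + zb)^2 / ((k - 1) * log(c0)^2)))
}

#' Stratified ICC
#'
#' Applies [icc_two_way()] within each stratum (e.g. socio-demographic or
#' weight-status categories). Strata with fewer than 3 complete pairs are
#' skipped with a warning.
#'
#' @param ratings Two-column data frame of paired ratings.
#' @param strata Vector of stratum labels, one per row of `ratings`.
#' @inheritParams icc_two_way
#' @return A tibble with one row per analysed stratum: `stratum`, `n`,
#'   `icc`, `ci_low`, `ci_high`, `band`.
#' @export
stratified_icc <- function(ratings, strata, form = c("consistency", "absolute_agreement"),
                           conf_level = 0.95) {
  form <- match.arg(form)
  x <- as.data.frame(ratings)
  stopifnot(length(strata) == nrow(x))
  purrr::map_dfr(unique(strata), function(s) {
    xs <- x[strata == s, , drop = FALSE]
    xs <- xs[stats::complete.cases(xs), , drop = FALSE]
    if (nrow(xs) < 3L) {
      warn(sprintf("stratum '%s' has fewer than 3 complete pairs; skipped", s),
           class = "nova24r_stratum_warning")
      return(NULL)
    }
    r <- icc_two_way(xs, form = form, conf_level = conf_level)
    tibble(stratum = as.character(s), n = r$n, icc = r$icc,
           ci_low = r$ci_low, ci_high = r$ci_high, band = r$band)
  })
}

#' Full between-tool agreement report
#'
#' Runs the complete method-comparison suite on a long paired-shares table:
#' per Nova group, paired mean comparison ([compare_means()]), two-way ICC
#' with confidence interval and interpretation band ([icc_two_way()]), and
#' quintile cross-classification with PABAK ([quintile_agreement()]).
#'
#' @param paired Long tibble with columns `participant_id`, `tool`,
#'   `nova_group`, `share_pct` (exactly two tools).
#' @param icc_form Passed to [icc_two_way()].
#' @param quintile_mode Passed to [quintile_agreement()].
#' @param method Passed to [compare_means()].
#' @param alpha Significance threshold for mean comparisons.
#' @return An object of class `nova_agreement_report`.
#' @export
agreement_report <- function(paired, icc_form = c("consistency", "absolute_agreement"),
                             quintile_mode = c("rank", "quantile"),
                             method = c("t", "wilcoxon"), alpha = 0.05) {
  icc_form <- match.arg(icc_form)
  quintile_mode <- match.arg(quintile_mode)
  method <- match.arg(method)
  tools <- sort(unique(paired$tool))
  means <- compare_means(paired, method = method, alpha = alpha)
  groups <- sort(unique(paired$nova_group))
  per_group <- lapply(groups, function(g) {
    w <- tidyr::pivot_wider(
      paired[paired$nova_group == g, c("participant_id", "tool", "share_pct")],
      names_from = "tool", values_from = "share_pct")
    w <- w[stats::complete.cases(w), tools]
    list(
      icc = icc_two_way(w, form = icc_form),
      quintiles = quintile_agreement(w, mode = quintile_mode)
    )
  })
  names(per_group) <- paste0("nova", groups)
  structure(
    list(tools = tools, means = means, per_group = per_group,
         settings = list(icc_form = icc_form, quintile_mode = quintile_mode,
                         method = method, alpha = alpha)),
    class = "nova_agreement_report"
  )
}

#' @export
print.nova_agreement_report <- function(x, ...) {
  nova_names <- c("Unprocessed or minimally processed foods",
                  "Processed culinary ingredients",
                  "Processed foods", "Ultra-processed foods")
  cat(sprintf("Agreement between '%s' (A) and '%s' (B), n = %d participants\n",
              x$tools[1], x$tools[2], x$means$n[1]))
  cat(sprintf("ICC form: two-way mixed, single measurement, %s\n\n",
              gsub("_", " ", x$settings$icc_form)))
  for (i in seq_len(nrow(x$means))) {
    m <- x$means[i, ]
    g <- m$nova_group
    pg <- x$per_group[[paste0("nova", g)]]
    cat(sprintf("Nova %d — %s\n", g, nova_names[g]))
    cat(sprintf("  mean %% energy: A %.1f (%.1f, %.1f) v. B %.1f (%.1f, %.1f); diff %.2f, p %s\n",
                m$mean_a, m$ci_a_low, m$ci_a_high, m$mean_b, m$ci_b_low, m$ci_b_high,
                m$mean_diff,
                if (is.na(m$p_value)) "NA (degenerate)" else sprintf("= %.3f", m$p_value)))
    cat(sprintf("  ICC %.2f (95%% CI %.2f, %.2f) — %s agreement\n",
                pg$icc$icc, pg$icc$ci_low, pg$icc$ci_high, pg$icc$band))
    cat(sprintf("  same quintile %.1f%%, same/adjacent %.1f%%, PABAK %.2f — %s\n\n",
                100 * pg$quintiles$p_same, 100 * pg$quintiles$p_same_or_adjacent,
                pg$quintiles$pabak, gsub("_", " ", pg$quintiles$band)))
  }
  invisible(x)
}

# Serialisable form of the agreement report (used for the JSON output).
report_to_list <- function(x) {
  stopifnot(inherits(x, "nova_agreement_report"))
  list(
    tools = x$tools,
    settings = x$settings,
    means = x$means,
    per_group = lapply(x$per_group, function(pg) list(
      icc = pg$icc[c("icc", "ci_low", "ci_high", "n", "k", "form", "band")],
      quintiles = list(
        cross_table = unname(apply(pg$quintiles$cross_table, 1, as.integer, simplify = FALSE)),
        p_same = pg$quintiles$p_same,
        p_same_or_adjacent = pg$quintiles$p_same_or_adjacent,
        pabak = pg$quintiles$pabak, band = pg$quintiles$band,
        n = pg$quintiles$n, mode = pg$quintiles$mode
      )
    ))
  )
}
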