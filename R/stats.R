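#' Summary statistics in the report format M / IQR / mean +- SD
#'
#' Median, quartiles by linear interpolation between order statistics
#' (`stats::quantile` type 7; IQR values depend on the quartile method, so it
#' is fixed here), mean and sample SD (n - 1 denominator).
#'
#' @param values numeric, length >= 1.
#' @return list of class `summary_stats`: `median`, `q1`, `q3`, `mean`,
#'   `sd`, `n`.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("cannot summarize an empty vector")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 mean = mean(values),
                 sd = if (length(values) > 1) stats::sd(values) else 0,
                 n = length(values)),
            class = "summary_stats")
}

test_result <- function(statistic, p_value, test_name, n_pairs,
                        method = NA_character_, degenerate = FALSE,
                        estimate = NA_real_) {
  structure(list(statistic = statistic, p_value = p_value,
                 test_name = test_name, n_pairs = n_pairs, method = method,
                 degenerate = degenerate, estimate = estimate),
            class = "gtv_test")
}

#' @export
print.gtv_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g, n = %d%s%s\n", x$test_name,
              x$statistic, x$p_value, x$n_pairs,
              if (!is.na(x$method)) paste0(" (", x$method, ")") else "",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# exact null distribution of the signed-rank statistic W+ by convolution
# over doubled (integer) midranks; returns P(W+ <= w) and P(W+ >= w)
signed_rank_exact_p <- function(ranks, W) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in r2) {
    g <- numeric(total + 1)
    g[(r + 1):(total + 1)] <- f[1:(total + 1 - r)]
    f <- f + g
  }
  w2 <- round(2 * W)
  n <- length(ranks)
  c(lower = sum(f[seq_len(w2 + 1)]) / 2^n,
    upper = sum(f[(w2 + 1):(total + 1)]) / 2^n)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences of exactly zero are dropped; ties in absolute differences are
#' mid-ranked. The two-sided p-value comes from the exact null distribution
#' of the positive-rank sum (valid under ties) when the number of nonzero
#' pairs is at most `exact_n_max` (default 25), otherwise from the normal
#' approximation with tie-corrected variance and, optionally, a continuity
#' correction. The reported statistic is the standardized Z.
#'
#' @param a,b numeric vectors of equal length (n >= 2).
#' @param exact_n_max switch point between exact and approximate p-values.
#' @param continuity apply the 0.5 continuity correction in the normal
#'   approximation.
#' @return a `gtv_test`; degenerate (all differences zero) results carry NA
#'   statistics and `degenerate = TRUE`.
#' @export
wilcoxon_paired <- function(a, b, exact_n_max = 25, continuity = TRUE) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0)
    return(test_result(NA_real_, NA_real_, "wilcoxon_signed_rank",
                       n_pairs = length(d), degenerate = TRUE))
  ranks <- rank(abs(nz))
  W <- sum(ranks[nz > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(ranks)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0)
    return(test_result(NA_real_, NA_real_, "wilcoxon_signed_rank",
                       n_pairs = n, degenerate = TRUE))
  cc <- if (continuity) 0.5 * sign(W - mu) else 0
  z <- (W - mu - cc) / sqrt(sigma2)
  if (n <= exact_n_max) {
    pr <- signed_rank_exact_p(ranks, W)
    p <- min(1, 2 * min(pr))
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  test_result(z, p, "wilcoxon_signed_rank", n_pairs = n, method = method,
              estimate = W)
}

#' Paired-sample t test
#'
#' Classical two-sided paired t test (via [stats::t.test()]); zero-variance
#' differences are flagged degenerate rather than tested.
#'
#' @param a,b numeric vectors of equal length (n >= 2).
#' @return a `gtv_test` with the t statistic.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0)
    return(test_result(NA_real_, NA_real_, "paired_t", n_pairs = length(a),
                       degenerate = TRUE))
  tt <- stats::t.test(a, b, paired = TRUE)
  test_result(unname(tt$statistic), tt$p.value, "paired_t",
              n_pairs = length(a), method = "t",
              estimate = unname(tt$estimate))
}

#' Spearman rank correlation test
#'
#' Spearman rho with mid-ranks for ties; two-sided p-value by the asymptotic
#' t approximation (via [stats::cor.test()]). Constant input is flagged
#' degenerate.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return a `gtv_test`; `statistic` and `estimate` carry rho.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(test_result(NA_real_, NA_real_, "spearman", n_pairs = length(x),
                       degenerate = TRUE))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  test_result(unname(ct$estimate), ct$p.value, "spearman",
              n_pairs = length(x), method = "t_approx",
              estimate = unname(ct$estimate))
}

# run a paired test, degrading to a flagged degenerate result when a group
# has fewer than two records
safe_paired <- function(fun, a, b, name) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2)
    return(test_result(NA_real_, NA_real_, name, n_pairs = sum(ok),
                       degenerate = TRUE))
  fun(a[ok], b[ok])
}

test_row <- function(test, comparison, group) {
  data.frame(group = group, comparison = comparison,
             statistic = test$statistic, p = test$p_value,
             n = test$n_pairs, method = test$method,
             degenerate = test$degenerate, stringsAsFactors = FALSE)
}

summary_row <- function(s, ...) {
  data.frame(..., n = s$n, median = s$median, q1 = s$q1, q3 = s$q3,
             mean = s$mean, sd = s$sd, stringsAsFactors = FALSE)
}

#' Build the five cohort report tables
#'
#' From per-patient metric rows (see [as.data.frame.metric_record()], plus
#' `id` and `group` columns), builds the cohort tables stratified by tumor
#' location (Total and groups A/B/C):
#' \describe{
#'   \item{t2}{per-group mean +- SD of the 3D vector V per contour pair,
#'     with pairwise Wilcoxon comparisons of V between pairs.}
#'   \item{t3}{tumor volume summaries (median, IQR, mean +- SD) per variant,
#'     with Wilcoxon comparisons.}
#'   \item{t4}{length and maximum transverse diameter mean +- SD per
#'     variant, with paired-t comparisons.}
#'   \item{t5}{conformity index summaries per pair, Wilcoxon comparisons
#'     between pairs, and Spearman correlation of CI against V.}
#'   \item{t6}{all six ordered degree-of-inclusion entries per group, with
#'     the Wilcoxon DI comparisons.}
#' }
#' Groups without records are omitted with a message; tests on degenerate
#' input are flagged, not dropped. No multiple-testing correction is applied
#' by default (each comparison is read against alpha on its own); Holm
#' adjustment is available.
#'
#' @param metrics data.frame of per-patient metric rows with a `group`
#'   column (values among A/B/C).
#' @param holm apply Holm adjustment to each test table's p-values.
#' @return object of class `cohort_result`: `tables` (t2..t6 data frames),
#'   `tests` (per-table test data frames), `n` (group sizes).
#' @export
build_tables <- function(metrics, holm = FALSE) {
  stopifnot(is.data.frame(metrics), "group" %in% names(metrics))
  present <- intersect(c("A", "B", "C"), unique(metrics$group))
  missing_groups <- setdiff(c("A", "B", "C"), present)
  if (length(missing_groups))
    message("no records for group(s) ", paste(missing_groups, collapse = ", "),
            "; rows omitted")
  groups <- c("Total", present)
  gsel <- function(g) if (g == "Total") metrics else metrics[metrics$group == g, ]

  pair_tags <- c(reg_ref = "GTV_PET-reg and GTV_PET-ref",
                 reg_3d = "GTV_PET-reg and GTV_3D",
                 ref_3d = "GTV_PET-ref and GTV_3D")
  pair_cols <- c(reg_ref = "reg_ref", reg_3d = "reg_3d", ref_3d = "ref_3d")
  var_tags <- c(`3d` = "GTV_3D", ref = "GTV_PET-ref", reg = "GTV_PET-reg")
  pair_comparisons <- list(
    c("reg_ref", "reg_3d"), c("reg_ref", "ref_3d"), c("reg_3d", "ref_3d"))
  var_comparisons <- list(c("reg", "ref"), c("reg", "3d"), c("ref", "3d"))

  t2 <- t3 <- t4 <- t5 <- t6 <- list()
  t2_tests <- t3_tests <- t4_tests <- t5_tests <- t6_tests <- list()

  for (g in groups) {
    m <- gsel(g)
    # t2: 3D vector
    for (pt in names(pair_tags)) {
      s <- summarize_values(m[[paste0("v_", pair_cols[[pt]])]])
      t2[[length(t2) + 1]] <- summary_row(s, table = "t2", group = g,
                                          pair = pair_tags[[pt]])
    }
    for (cmp in pair_comparisons) {
      w <- safe_paired(wilcoxon_paired, m[[paste0("v_", cmp[1])]],
                       m[[paste0("v_", cmp[2])]], "wilcoxon_signed_rank")
      t2_tests[[length(t2_tests) + 1]] <- test_row(
        w, paste(pair_tags[[cmp[1]]], "vs", pair_tags[[cmp[2]]]), g)
    }
    # t3: volumes
    for (v in names(var_tags)) {
      s <- summarize_values(m[[paste0("vol_", v)]])
      t3[[length(t3) + 1]] <- summary_row(s, table = "t3", group = g,
                                          variant = var_tags[[v]])
    }
    for (cmp in var_comparisons) {
      w <- safe_paired(wilcoxon_paired, m[[paste0("vol_", cmp[1])]],
                       m[[paste0("vol_", cmp[2])]], "wilcoxon_signed_rank")
      t3_tests[[length(t3_tests) + 1]] <- test_row(
        w, paste(var_tags[[cmp[1]]], "vs", var_tags[[cmp[2]]]), g)
    }
    # t4: length and max transverse diameter
    for (meas in c("len", "diam")) {
      for (v in names(var_tags)) {
        s <- summarize_values(m[[paste0(meas, "_", v)]])
        t4[[length(t4) + 1]] <- summary_row(
          s, table = "t4", group = g,
          measure = if (meas == "len") "Length (cm)"
          else "Maximum transverse diameter (cm)",
          variant = var_tags[[v]])
      }
      for (cmp in var_comparisons) {
        tt <- safe_paired(paired_t, m[[paste0(meas, "_", cmp[1])]],
                          m[[paste0(meas, "_", cmp[2])]], "paired_t")
        t4_tests[[length(t4_tests) + 1]] <- test_row(
          tt, paste(if (meas == "len") "Length" else "Max transverse diameter",
                    ":", var_tags[[cmp[1]]], "vs", var_tags[[cmp[2]]]), g)
      }
    }
    # t5: CI
    for (pt in names(pair_tags)) {
      s <- summarize_values(m[[paste0("ci_", pair_cols[[pt]])]])
      t5[[length(t5) + 1]] <- summary_row(s, table = "t5", group = g,
                                          pair = pair_tags[[pt]])
    }
    for (cmp in pair_comparisons) {
      w <- safe_paired(wilcoxon_paired, m[[paste0("ci_", cmp[1])]],
                       m[[paste0("ci_", cmp[2])]], "wilcoxon_signed_rank")
      t5_tests[[length(t5_tests) + 1]] <- test_row(
        w, paste("CI:", pair_tags[[cmp[1]]], "vs", pair_tags[[cmp[2]]]), g)
    }
    if (nrow(m) >= 3) for (pt in names(pair_tags)) {
      sp <- spearman_test(m[[paste0("ci_", pair_cols[[pt]])]],
                          m[[paste0("v_", pair_cols[[pt]])]])
      t5_tests[[length(t5_tests) + 1]] <- test_row(
        sp, paste("Spearman CI vs V:", pair_tags[[pt]]), g)
    }
    # t6: the six ordered DI entries
    di_cols <- c("di_reg_in_3d", "di_ref_in_3d", "di_3d_in_reg",
                 "di_3d_in_ref", "di_reg_in_ref", "di_ref_in_reg")
    di_tags <- c("GTV_PET-reg in GTV_3D", "GTV_PET-ref in GTV_3D",
                 "GTV_3D in GTV_PET-reg", "GTV_3D in GTV_PET-ref",
                 "GTV_PET-reg in GTV_PET-ref", "GTV_PET-ref in GTV_PET-reg")
    for (i in seq_along(di_cols)) {
      s <- summarize_values(m[[di_cols[i]]])
      t6[[length(t6) + 1]] <- summary_row(s, table = "t6", group = g,
                                          di = di_tags[i])
    }
    di_comparisons <- list(c(1, 2), c(3, 4), c(1, 5), c(6, 3))
    for (cmp in di_comparisons) {
      w <- safe_paired(wilcoxon_paired, m[[di_cols[cmp[1]]]],
                       m[[di_cols[cmp[2]]]], "wilcoxon_signed_rank")
      t6_tests[[length(t6_tests) + 1]] <- test_row(
        w, paste("DI:", di_tags[cmp[1]], "vs", di_tags[cmp[2]]), g)
    }
  }

  bind <- function(lst) do.call(rbind, lst)
  tests <- list(t2 = bind(t2_tests), t3 = bind(t3_tests), t4 = bind(t4_tests),
                t5 = bind(t5_tests), t6 = bind(t6_tests))
  if (holm)
    tests <- lapply(tests, function(df) {
      df$p_holm <- stats::p.adjust(df$p, method = "holm")
      df
    })
  ns <- c(Total = nrow(metrics),
          stats::setNames(vapply(present, function(g) sum(metrics$group == g),
                                 integer(1)), present))
  structure(list(tables = list(t2 = bind(t2), t3 = bind(t3), t4 = bind(t4),
                               t5 = bind(t5), t6 = bind(t6)),
                 tests = tests, n = ns),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> n =", paste(names(x$n), x$n, sep = "=", collapse = ", "),
      "\n")
  t5 <- x$tables$t5
  tot <- t5[t5$group == "Total", ]
  for (i in seq_len(nrow(tot)))
    cat(sprintf("  CI %-28s M %.2f (IQR %.2f, %.2f)  %.2f +- %.2f\n",
                tot$pair[i], tot$median[i], tot$q1[i], tot$q3[i],
                tot$mean[i], tot$sd[i]))
  invisible(x)
}
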