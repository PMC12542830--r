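# Cohort-level aggregation and comparisons.  Continuous variables are
# summarised as mean +/- SD (sample SD over hearts); Shapiro-Wilk decides
# between a two-tailed unpaired Student's t-test and a Wilcoxon rank-sum
# test at alpha = 0.05.  "Combined" pacing groups pool the member protocols
# per heart (mean across protocols first, then across hearts).

#' Combined protocol groups
#'
#' Left bundle branch pacing combines the proximal and distal LBBP
#' protocols; the leadless group combines the three RV septal sites.
#' @export
COMBINED_GROUPS <- list(
  COMBINED_LBBP = c("PLBBP", "DLBBP"),
  COMBINED_LCPM = c("RVOT_S", "MS", "AS"))

#' Per-heart pooled metric values of a protocol group
#'
#' @param results metrics data.frame (one row per heart x scenario, columns
#'   heart, substrate, protocol and the metric columns).
#' @param metric metric column name.
#' @param substrate substrate to filter on.
#' @param protocols member protocols of the group.
#' @param pooling "per_heart_mean" (mean across member protocols per heart,
#'   the default) or "flat" (every heart x protocol row kept).
#' @return numeric vector (one value per heart for the default pooling).
#' @export
group_values <- function(results, metric, substrate, protocols,
                         pooling = c("per_heart_mean", "flat")) {
  pooling <- match.arg(pooling)
  r <- results[results$substrate == substrate &
               results$protocol %in% protocols, , drop = FALSE]
  missing_p <- setdiff(protocols, unique(r$protocol))
  if (length(missing_p))
    stop("missing scenario rows for protocol(s) ",
         paste(missing_p, collapse = ", "), " under substrate ", substrate)
  if (pooling == "flat") return(r[[metric]])
  as.numeric(tapply(r[[metric]], r$heart, mean))
}

#' Mean and SD summary of a protocol group
#'
#' @inheritParams group_values
#' @return named vector c(mean, sd, n); SD is the sample (N-1) SD across
#'   hearts.
#' @export
summarize_group <- function(results, metric, substrate, protocols,
                            pooling = "per_heart_mean") {
  v <- group_values(results, metric, substrate, protocols, pooling)
  if (length(v) < 2) stop("need at least 2 hearts to summarise")
  c(mean = mean(v), sd = stats::sd(v), n = length(v))
}

.is_normal <- function(x, alpha = 0.05) {
  if (length(x) < 3 || length(unique(x)) == 1L) return(NA)
  stats::shapiro.test(x)$p.value >= alpha
}

#' Compare two protocol groups on one metric
#'
#' Shapiro-Wilk normality on each group routes the comparison: both normal
#' (p >= 0.05) gives a two-tailed unpaired Student's t-test, otherwise a
#' Wilcoxon rank-sum test.  Groups with n < 3 (or constant values) skip the
#' normality test and use the rank-sum test with a warning.  A paired option
#' exists because scenarios share hearts, but the unpaired test is the
#' default.
#'
#' @inheritParams group_values
#' @param protocols_a,protocols_b member protocols of the two groups.
#' @param paired use paired tests (non-default alternative).
#' @return object of class `comparison_result`.
#' @export
compare_groups <- function(results, metric, substrate, protocols_a,
                           protocols_b, pooling = "per_heart_mean",
                           paired = FALSE) {
  a <- group_values(results, metric, substrate, protocols_a, pooling)
  b <- group_values(results, metric, substrate, protocols_b, pooling)
  if (!length(a) || !length(b)) stop("empty comparison group")
  na <- .is_normal(a); nb <- .is_normal(b)
  if (is.na(na) || is.na(nb)) {
    warning("group too small or degenerate for a normality test; ",
            "using the rank-sum test")
    normal <- FALSE
  } else normal <- na && nb
  if (normal) {
    ht <- stats::t.test(a, b, var.equal = TRUE, paired = paired)
    test <- if (paired) "paired_t_test" else "t_test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                              exact = FALSE, correct = TRUE))
    test <- if (paired) "wilcoxon_signed_rank" else "wilcoxon"
    # all observations tied across both groups: no evidence of a difference
    if (is.nan(ht$p.value)) ht$p.value <- 1
  }
  structure(list(
    metric = metric, substrate = substrate,
    mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
    mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
    normal_a = na, normal_b = nb, test = test,
    p_value = ht$p.value, significant = ht$p.value < 0.05,
    paired = paired), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s under %s: %.1f +/- %.1f vs %.1f +/- %.1f ms, %s p = %.3g%s\n",
              x$metric, x$substrate, x$mean_a, x$sd_a, x$mean_b, x$sd_b,
              x$test, x$p_value, if (x$significant) " (*)" else ""))
  invisible(x)
}

#' Cohort summary table across protocols and substrates
#'
#' One row per substrate x metric; columns for the baseline, each pacing
#' protocol, the combined LBBP and LCPM groups ("mean +/- sd"), the
#' LBBP-vs-LCPM p-value and the RVOT-S-vs-combined-LBBP p-value.
#'
#' @param results metrics data.frame.
#' @param metrics metric columns to tabulate.
#' @param digits digits for the formatted cells.
#' @return data.frame.
#' @export
cohort_summary_table <- function(results,
                                 metrics = c("veu", "abs_veu", "lvdi",
                                             "bivat90"),
                                 digits = 1) {
  fmt <- function(ms) sprintf("%.*f ± %.*f", digits, ms[1], digits, ms[2])
  substrates <- intersect(SUBSTRATE_LEVELS, unique(results$substrate))
  rows <- list()
  for (sub in substrates) for (met in metrics) {
    cells <- list(substrate = sub, metric = met)
    for (p in intersect(PROTOCOL_LEVELS, unique(results$protocol)))
      cells[[p]] <- fmt(summarize_group(results, met, sub, p))
    for (g in names(COMBINED_GROUPS))
      cells[[g]] <- fmt(summarize_group(results, met, sub,
                                        COMBINED_GROUPS[[g]]))
    cmp <- compare_groups(results, met, sub, COMBINED_GROUPS$COMBINED_LBBP,
                          COMBINED_GROUPS$COMBINED_LCPM)
    cells$p_lbbp_vs_lcpm <- signif(cmp$p_value, 3)
    cmp2 <- compare_groups(results, met, sub, "RVOT_S",
                           COMBINED_GROUPS$COMBINED_LBBP)
    cells$p_rvots_vs_lbbp <- signif(cmp2$p_value, 3)
    rows[[length(rows) + 1L]] <- as.data.frame(cells)
  }
  do.call(rbind, rows)
}
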