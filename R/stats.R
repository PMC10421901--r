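#' Associate a feature with a grouping variable
#'
#' Thin dispatcher over the standard nonparametric toolkit. Numeric values
#' against a 2-level group use the unpaired two-tailed Wilcoxon rank-sum
#' test; against 3 or more levels the Kruskal-Wallis test; two categorical
#' variables use the chi-square test (without continuity correction by
#' default). Ties are handled by the usual mid-rank convention; the Wilcoxon
#' p value is exact when the combined n is at most 20 and there are no ties,
#' otherwise a tie-corrected normal approximation.
#'
#' @param values Numeric (Wilcoxon/Kruskal-Wallis) or categorical
#'   (chi-square) vector, one entry per sample.
#' @param groups Grouping vector, coerced to factor; every level must be
#'   observed at least once.
#' @param feature Optional feature name carried into the result.
#' @param correct Continuity correction for the chi-square test.
#' @return One-row data.frame: \code{feature}, \code{group_var},
#'   \code{test}, \code{statistic}, \code{p_value}, \code{n_groups},
#'   \code{n_total}; per-group sizes in attribute \code{"n_per_group"}.
#' @examples
#' associate(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
associate <- function(values, groups, feature = NA_character_, correct = FALSE) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  tabg <- table(groups)
  if (length(tabg) < 2) stop("need at least 2 observed groups")
  if (any(tabg == 0))
    stop("group without observations: ", names(tabg)[tabg == 0][1])
  if (is.numeric(values)) {
    if (length(unique(values)) == 1L) {
      # fully tied data: no signal; the rank tests' tie-corrected variance
      # degenerates to 0/0, so report the null boundary directly
      ht <- list(statistic = if (nlevels(groups) == 2)
        prod(tabg[1:2]) / 2 else 0, p.value = 1)
      test <- if (nlevels(groups) == 2) "wilcoxon" else "kruskal_wallis"
    } else if (nlevels(groups) == 2) {
      exact <- length(values) <= 20 && anyDuplicated(values) == 0
      ht <- suppressWarnings(
        stats::wilcox.test(values ~ groups, exact = exact, correct = TRUE))
      test <- "wilcoxon"
    } else {
      ht <- stats::kruskal.test(values, groups)
      test <- "kruskal_wallis"
    }
  } else {
    ht <- stats::chisq.test(table(factor(values), groups), correct = correct)
    test <- "chi_square"
  }
  out <- data.frame(feature = feature, group_var = NA_character_,
                    test = test, statistic = unname(ht$statistic),
                    p_value = ht$p.value, n_groups = nlevels(groups),
                    n_total = length(values), stringsAsFactors = FALSE)
  attr(out, "n_per_group") <- tabg
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate correction of a family of p values
#' (wraps \code{stats::p.adjust}): order-preserving, never below the raw p,
#' idempotent on already-adjusted monotone families.
#'
#' @param p Numeric vector of p values in [0, 1]; \code{NA} passed through.
#' @return Adjusted p values.
#' @export
adjust_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Screen many features against one grouping variable
#'
#' Runs \code{\link{associate}} for each feature column and adjusts the
#' resulting p values as one Benjamini-Hochberg family (families are defined
#' per screen).
#'
#' @param data Data.frame of samples.
#' @param features Character vector of numeric feature columns.
#' @param group Name of the grouping column.
#' @return Data.frame of \code{\link{associate}} rows plus
#'   \code{p_adjusted}.
#' @export
associate_table <- function(data, features, group) {
  res <- do.call(rbind, lapply(features, function(f)
    associate(data[[f]], data[[group]], feature = f)))
  res$group_var <- group
  res$p_adjusted <- adjust_bh(res$p_value)
  res
}

#' Kaplan-Meier and log-rank comparison at a survival horizon
#'
#' Administratively censors all observations at \code{horizon_months}
#' (default 60, i.e. 5-year overall survival), then fits per-group
#' Kaplan-Meier curves and the log-rank test.
#'
#' @param times Follow-up times in months, >= 0.
#' @param events Event indicator (0/1 or logical).
#' @param groups Grouping vector (2 or more levels).
#' @param horizon_months Administrative censoring horizon; \code{Inf}
#'   disables it.
#' @return List with \code{statistic} (log-rank chi-square), \code{p_value},
#'   \code{fit} (a \code{survival::survfit} object for plotting) and
#'   \code{n_per_group}.
#' @export
survival_logrank <- function(times, events, groups, horizon_months = 60) {
  stopifnot(all(times >= 0, na.rm = TRUE))
  keep <- !is.na(times) & !is.na(events) & !is.na(groups)
  times <- times[keep]; events <- as.integer(events[keep])
  groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  over <- times > horizon_months
  events[over] <- 0L
  times[over] <- horizon_months
  for (g in levels(groups))
    if (!any(groups == g)) stop("group without observations: ", g)
  d <- data.frame(times = times, events = events, groups = groups)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups, data = d)
  stat <- unname(sd$chisq)
  p <- stats::pchisq(stat, df = nlevels(groups) - 1L, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups, data = d)
  list(statistic = stat, p_value = p, fit = fit,
       n_per_group = table(groups))
}
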