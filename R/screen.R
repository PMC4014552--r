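#' Split samples at the mean expression of a feature
#'
#' Samples strictly above the feature's mean are labelled `high`, all
#' others (including ties at the mean) `low`. A constant feature yields a
#' single group and is flagged degenerate.
#'
#' @param values numeric per-sample expression values (length >= 2).
#' @return List with `labels` (character vector of `"high"`/`"low"`),
#'   `n_high`, `n_low` and `degenerate`.
#' @export
dichotomize_by_mean <- function(values) {
  if (length(values) < 2) stop("need at least 2 samples")
  if (anyNA(values)) stop("missing expression values")
  labels <- ifelse(values > mean(values), "high", "low")
  n_high <- sum(labels == "high")
  list(labels = labels, n_high = n_high, n_low = length(values) - n_high,
       degenerate = n_high == 0L || n_high == length(values))
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank chi-square comparing the
#' survival curves of two groups, with a two-sided p-value from the upper
#' tail of the chi-square distribution. With no events at all the test is
#' undefined and `p = 1` is returned by convention.
#'
#' @param times non-negative survival times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param groups two-level group labels.
#' @return List with `statistic`, `p_value` and `group_sizes`.
#' @export
logrank_test <- function(times, events, groups) {
  stopifnot(length(times) == length(events),
            length(times) == length(groups))
  if (any(times < 0)) stop("times must be non-negative")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2 || any(table(groups) == 0)) {
    stop("exactly two non-empty groups are required")
  }
  sizes <- table(groups)
  if (sum(events) == 0) {
    return(list(statistic = 0, p_value = 1, group_sizes = sizes))
  }
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  stat <- unname(fit$chisq)
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       group_sizes = sizes)
}

#' Mean-split Kaplan-Meier screen of survival-associated features
#'
#' For every feature, samples are split at the feature's mean expression
#' and the two groups are compared by the log-rank test. Features with a
#' degenerate (constant) split are excluded. A feature is selected when
#' its p-value is strictly below `alpha`.
#'
#' @param expr expression matrix (features x samples).
#' @param clinical clinical data frame; only samples present in both
#'   inputs are used.
#' @param alpha selection level (strict `<`; default 0.001).
#' @return Data frame with one row per non-degenerate feature:
#'   `feature_id`, `n_low`, `n_high`, `statistic`, `p_value`, `selected`.
#' @export
screen_features <- function(expr, clinical, alpha = 0.001) {
  clinical <- validate_clinical(clinical)
  shared <- intersect(colnames(expr), clinical$sample_id)
  if (length(shared) == 0) stop("no overlapping samples")
  expr <- expr[, shared, drop = FALSE]
  cl <- clinical[match(shared, clinical$sample_id), ]
  times <- cl$survival_days
  events <- cl$event
  surv <- survival::Surv(times, events)
  no_events <- sum(events) == 0

  res <- lapply(rownames(expr), function(f) {
    split <- dichotomize_by_mean(expr[f, ])
    if (split$degenerate) return(NULL)
    if (no_events) {
      stat <- 0; p <- 1
    } else {
      grp <- factor(split$labels, levels = c("low", "high"))
      stat <- unname(survival::survdiff(surv ~ grp)$chisq)
      p <- pchisq(stat, df = 1, lower.tail = FALSE)
    }
    data.frame(feature_id = f, n_low = split$n_low, n_high = split$n_high,
               statistic = stat, p_value = p, selected = p < alpha,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(feature_id = character(), n_low = integer(),
                      n_high = integer(), statistic = numeric(),
                      p_value = numeric(), selected = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
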