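# ROC/AUC with DeLong CIs, Youden cutoff, Kaplan-Meier/log-rank, and
# contingency-table association tests.

# Mann-Whitney concordance AUC with ties counted 1/2
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels)
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with a DeLong 95% confidence interval
#'
#' AUC is the Mann-Whitney concordance probability (ties counted 1/2); the
#' confidence interval uses the DeLong placement-value variance estimator,
#' truncated to `[0, 1]`.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1), both classes present.
#' @param conf confidence level (default 0.95).
#' @return List with `auc`, `ci` (length 2), `se`, `n_pos`, `n_neg`.
#' @export
roc_auc_ci <- function(scores, labels, conf = 0.95) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("input error: labels contain a single class", call. = FALSE)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  auc <- auc_mw(scores, labels)
  # placement values
  v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n, 0)
  v01 <- vapply(neg, function(y) (sum(pos > y) + 0.5 * sum(pos == y)) / m, 0)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  list(auc = auc, ci = ci, se = se, n_pos = m, n_neg = n)
}

#' Maximum-Youden cutoff
#'
#' Evaluates `J = sensitivity + specificity - 1` at every threshold between
#' adjacent distinct observed scores (samples with score strictly above the
#' cutoff are called positive) and returns the maximizing threshold as the
#' midpoint of the corresponding gap. Ties in `J` resolve to the lower
#' threshold (higher sensitivity). All scores identical gives `J = 0`.
#'
#' @inheritParams roc_auc_ci
#' @return List with `cutoff`, `J`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("input error: labels contain a single class", call. = FALSE)
  s <- sort(unique(scores))
  if (length(s) == 1)
    return(list(cutoff = s, J = 0, sensitivity = 1, specificity = 0))
  thr <- (s[-length(s)] + s[-1]) / 2
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  stats <- vapply(thr, function(t) {
    sens <- sum(scores > t & labels == 1) / n1
    spec <- sum(scores <= t & labels == 0) / n0
    c(sens, spec)
  }, numeric(2))
  J <- stats[1, ] + stats[2, ] - 1
  best <- which.max(J)  # which.max returns the first (lowest threshold) tie
  list(cutoff = thr[best], J = J[best],
       sensitivity = stats[1, best], specificity = stats[2, best])
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimate per risk group with median (and IQR)
#' where reached, plus the two-group log-rank chi-square (1 df) and p
#' value.
#'
#' @param group factor/character per patient, values `"high"`/`"low"` (any
#'   two levels work).
#' @param time positive follow-up times (months).
#' @param event event indicator (1 = event, 0 = censored).
#' @return List of class `omr_km` with `fit` (a [survival::survfit()]
#'   object), `medians` (per group: median, q25, q75), `chisq`, `p`, `n`.
#' @export
km_logrank <- function(group, time, event) {
  group <- as.factor(group)
  if (any(table(group) == 0) || nlevels(droplevels(group)) < 2)
    stop("input error: both groups must be nonempty", call. = FALSE)
  group <- droplevels(group)
  if (sum(event) < 1)
    stop("input error: need at least one event", call. = FALSE)
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  qt <- stats::quantile(fit, probs = c(0.25, 0.5, 0.75))$quantile
  medians <- data.frame(group = levels(group),
                        q25 = qt[, 1], median = qt[, 2], q75 = qt[, 3],
                        row.names = NULL)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chisq <- sd$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  structure(list(fit = fit, medians = medians, chisq = chisq, p = p,
                 n = as.vector(table(group))),
            class = "omr_km")
}

#' @export
print.omr_km <- function(x, ...) {
  cat(sprintf("<omr_km> log-rank chi-square %.3f (df 1), p %s\n",
              x$chisq, format_pvalue(x$p)))
  print(x$medians, row.names = FALSE)
  invisible(x)
}

#' Format a p value the way clinical tables print it
#'
#' Three decimals; values above .999 print as `">.999"`, values below .001
#' as `"<.001"`.
#'
#' @param p numeric p value.
#' @return Character scalar.
#' @export
format_pvalue <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p > 0.999) return(">.999")
  if (p < 0.001) return("<.001")
  sub("^0", "", sprintf("%.3f", p))
}

#' Contingency-table association test
#'
#' Test choice follows the standard rule: a 2x2 table with all expected
#' counts >= 5 uses the Pearson chi-square with Yates continuity
#' correction; a larger r x c table with all expected counts >= 5 uses the
#' Pearson chi-square without correction; any expected count < 5 switches
#' to the Fisher exact test.
#'
#' @param tab integer matrix of observed counts (r x c), e.g. risk group by
#'   radiologic feature level; or two vectors via `group` and `variable`.
#' @param group,variable optional categorical vectors used when `tab` is
#'   missing.
#' @return List of class `omr_assoc` with `table`, `test` (one of
#'   `"chi-square-yates"`, `"chi-square"`, `"fisher"`), `statistic`, `p`,
#'   `p_formatted`, and `col_pct` (column percentages, rounded to integer).
#' @export
association_table <- function(tab = NULL, group = NULL, variable = NULL) {
  if (is.null(tab)) {
    if (is.null(group) || is.null(variable))
      stop("input error: supply a table or group + variable", call. = FALSE)
    tab <- table(variable, group)
  }
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("input error: negative cell count", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("input error: empty margin in contingency table", call. = FALSE)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("input error: need >= 2 categories on each margin", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    test <- "fisher"; statistic <- NA_real_; p <- ft$p.value
  } else if (nrow(tab) == 2 && ncol(tab) == 2) {
    ct <- stats::chisq.test(tab, correct = TRUE)
    test <- "chi-square-yates"; statistic <- unname(ct$statistic); p <- ct$p.value
  } else {
    ct <- stats::chisq.test(tab, correct = FALSE)
    test <- "chi-square"; statistic <- unname(ct$statistic); p <- ct$p.value
  }
  col_pct <- round(100 * sweep(tab, 2, colSums(tab), "/"))
  structure(list(table = tab, test = test, statistic = statistic, p = p,
                 p_formatted = format_pvalue(p), col_pct = col_pct),
            class = "omr_assoc")
}

#' @export
print.omr_assoc <- function(x, ...) {
  cat(sprintf("<omr_assoc> %s: p %s\n", x$test, x$p_formatted))
  print(x$table)
  invisible(x)
}

#' Stratify cohorts at the training-derived Youden cutoff
#'
#' Determines the maximum-Youden cutoff on the training cohort only, then
#' freezes it to split every cohort into high-risk (score above cutoff) and
#' low-risk groups, and runs Kaplan-Meier/log-rank per cohort and endpoint
#' where survival columns are available.
#'
#' @param scores named list of numeric score vectors per cohort; must
#'   include `training`.
#' @param labels named list of binary label vectors matching `scores`.
#' @param survival optional named list of data.frames per cohort with
#'   columns `time`/`event` (and optionally `dfs_time`/`dfs_event`).
#' @return List of class `omr_strat` with `cutoff`, `J`, `groups` (per
#'   cohort), `km` (per cohort/endpoint) and per-cohort AUC.
#' @export
stratify_cohorts <- function(scores, labels, survival = NULL) {
  if (!"training" %in% names(scores))
    stop("input error: scores must include a 'training' cohort", call. = FALSE)
  yc <- youden_cutoff(scores$training, labels$training)
  groups <- lapply(scores, function(s)
    factor(ifelse(s > yc$cutoff, "high", "low"), levels = c("low", "high")))
  aucs <- Map(function(s, y) {
    if (length(unique(y)) < 2) return(NULL)
    roc_auc_ci(s, y)
  }, scores, labels)
  km <- NULL
  if (!is.null(survival)) {
    km <- lapply(names(survival), function(ch) {
      sv <- survival[[ch]]
      g <- groups[[ch]]
      out <- list()
      if (all(c("time", "event") %in% names(sv)) && nlevels(droplevels(g)) == 2)
        out$os <- km_logrank(g, sv$time, sv$event)
      if (all(c("dfs_time", "dfs_event") %in% names(sv)) &&
          nlevels(droplevels(g)) == 2)
        out$dfs <- km_logrank(g, sv$dfs_time, sv$dfs_event)
      out
    })
    names(km) <- names(survival)
  }
  structure(list(cutoff = yc$cutoff, J = yc$J, groups = groups,
                 auc = aucs, km = km),
            class = "omr_strat")
}

#' @export
print.omr_strat <- function(x, ...) {
  cat(sprintf("<omr_strat> cutoff %.4f (J = %.3f)\n", x$cutoff, x$J))
  for (ch in names(x$groups)) {
    cnt <- table(x$groups[[ch]])
    auc <- if (!is.null(x$auc[[ch]])) sprintf(", AUC %.3f", x$auc[[ch]]$auc) else ""
    cat(sprintf("  %s: %d low / %d high%s\n", ch, cnt["low"], cnt["high"], auc))
    if (!is.null(x$km[[ch]])) for (ep in names(x$km[[ch]]))
      cat(sprintf("    %s log-rank p %s\n", toupper(ep),
                  format_pvalue(x$km[[ch]][[ep]]$p)))
  }
  invisible(x)
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' The Kaplan-Meier median of the censoring distribution (event indicator
#' flipped): the standard way to report how long a cohort was followed.
#'
#' @param time follow-up times.
#' @param event event indicator (1 = event, 0 = censored).
#' @return Median follow-up in the units of `time` (NA if not reached).
#' @export
median_followup <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  unname(stats::quantile(fit, probs = 0.5)$quantile)
}

#' Kaplan-Meier curves as a plain-text coordinate table
#'
#' @param km an `omr_km` from [km_logrank()].
#' @return Data.frame with `group`, `time`, `n_risk`, `surv`, `lower`,
#'   `upper`, suitable for CSV export or replotting.
#' @export
km_curve_table <- function(km) {
  sf <- summary(km$fit)
  data.frame(group = sub("^group=", "", as.character(sf$strata)),
             time = sf$time, n_risk = sf$n.risk, surv = sf$surv,
             lower = sf$lower, upper = sf$upper,
             stringsAsFactors = FALSE)
}
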