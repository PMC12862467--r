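# The core procedure: evaluate every selection chain on every margin-band
# spec and pick the optimal margin region (OMR) by internal-test AUC.

feature_columns <- function(X) {
  setdiff(colnames(X), c("patient_id", "label", "cohort"))
}

#' Grid search over margin regions and selection chains
#'
#' For each (band spec, chain) pair: run the selection chain and
#' (optionally) its cross-validated AUC on the training cohort, refit the
#' final logistic signature on the full training cohort, and score the
#' internal-test (and external-test, when present) cohorts, which are never
#' touched by selection, standardization or fitting. Results are ranked
#' primarily by internal-test AUC, ties broken by higher training CV AUC,
#' then by smaller `inner_mm + outer_mm` (the original-lesion VOI counts as
#' the widest region). Patients whose band is empty for a spec are dropped
#' from that spec only; specs evaluable on fewer than half of the training
#' cohort are skipped with a warning. Per-pair seeds are derived from the
#' master seed and the pair's own coordinates, so the ranking does not
#' depend on evaluation order.
#'
#' @param features_by_spec named list of per-spec feature tables as built
#'   by [extract_cohort_features()]: data.frames with columns `patient_id`,
#'   `label`, `cohort` plus feature columns (NA feature rows mark patients
#'   whose band was empty), each carrying a `spec` attribute.
#' @param chains character vector of chain names (default all nine).
#' @param seed master integer seed.
#' @param cv_folds folds for the training CV AUC; 0 skips CV (the CV AUC is
#'   then recorded as NA and plays no part except tie-breaking).
#' @param min_evaluable minimum fraction of training patients a spec must
#'   retain (default 0.5).
#' @return An object of class `omr_search`: a ranked `results` data.frame,
#'   the fitted `models` (one per (spec, chain)), and `top`, the best
#'   [omr_model].
#' @export
omr_search <- function(features_by_spec, chains = omr_chain_names, seed = 1L,
                       cv_folds = 0, min_evaluable = 0.5) {
  stopifnot(length(features_by_spec) >= 1)
  chains <- vapply(chains, function(ch) parse_chain(ch)$name, "")
  rows <- list(); models <- list()
  for (sp_name in names(features_by_spec)) {
    X <- features_by_spec[[sp_name]]
    spec <- attr(X, "spec")
    if (is.null(spec)) stop("feature table '", sp_name, "' lacks a spec attribute",
                            call. = FALSE)
    fc <- feature_columns(X)
    ok <- stats::complete.cases(X[, fc, drop = FALSE])
    tr_all <- X$cohort == "training"
    if (sum(ok & tr_all) < min_evaluable * sum(tr_all)) {
      warning("spec ", sp_name, " evaluable on ", sum(ok & tr_all), "/",
              sum(tr_all), " training patients; skipped")
      next
    }
    Xo <- X[ok, , drop = FALSE]
    tr <- Xo$cohort == "training"
    it <- Xo$cohort == "internal_test"
    ex <- Xo$cohort == "external_test"
    if (length(unique(Xo$label[tr])) < 2)
      stop("search error: training cohort has a single class", call. = FALSE)
    for (ch in chains) {
      # one derived seed per chain (not per spec): every margin region is
      # evaluated under the same fold randomness, so regions differ only in
      # their features, and evaluation order cannot matter
      pair_seed <- derive_seed(seed, ch)
      sel <- suppressWarnings(
        reduce_features(Xo[tr, fc, drop = FALSE], Xo$label[tr], ch,
                        seed = pair_seed))
      cv <- NA_real_
      if (cv_folds > 0 && length(sel) > 0) {
        cv <- tryCatch(
          crossval_auc(Xo[tr, fc, drop = FALSE], Xo$label[tr], ch,
                       folds = cv_folds, seed = pair_seed)$mean_auc,
          error = function(e) NA_real_)
      }
      if (length(sel) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          spec = sp_name, chain = ch,
          inner_mm = spec$inner_mm, outer_mm = spec$outer_mm,
          is_original = spec$is_original, n_features = 0L,
          auc_train = NA_real_, auc_train_cv = cv,
          auc_internal = NA_real_, auc_internal_lo = NA_real_,
          auc_internal_hi = NA_real_, auc_external = NA_real_,
          n_train = sum(tr), n_internal = sum(it), n_external = sum(ex),
          stringsAsFactors = FALSE)
        models[[paste(sp_name, ch, sep = "|")]] <- NULL
        next
      }
      sig <- suppressMessages(
        fit_logistic_signature(Xo[tr, , drop = FALSE], Xo$label[tr], sel))
      auc_tr <- roc_auc_ci(predict(sig, Xo[tr, , drop = FALSE]), Xo$label[tr])
      auc_it <- if (sum(it) > 0 && length(unique(Xo$label[it])) == 2)
        roc_auc_ci(predict(sig, Xo[it, , drop = FALSE]), Xo$label[it]) else NULL
      auc_ex <- if (sum(ex) > 0 && length(unique(Xo$label[ex])) == 2)
        roc_auc_ci(predict(sig, Xo[ex, , drop = FALSE]), Xo$label[ex]) else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        spec = sp_name, chain = ch,
        inner_mm = spec$inner_mm, outer_mm = spec$outer_mm,
        is_original = spec$is_original, n_features = length(sel),
        auc_train = auc_tr$auc, auc_train_cv = cv,
        auc_internal = if (is.null(auc_it)) NA_real_ else auc_it$auc,
        auc_internal_lo = if (is.null(auc_it)) NA_real_ else auc_it$ci[1],
        auc_internal_hi = if (is.null(auc_it)) NA_real_ else auc_it$ci[2],
        auc_external = if (is.null(auc_ex)) NA_real_ else auc_ex$auc,
        n_train = sum(tr), n_internal = sum(it), n_external = sum(ex),
        stringsAsFactors = FALSE)
      models[[paste(sp_name, ch, sep = "|")]] <- list(
        spec = spec, chain = ch, features = sel, signature = sig)
    }
  }
  if (length(rows) == 0)
    stop("search error: no evaluable spec", call. = FALSE)
  res <- do.call(rbind, rows)
  # band width for tie-breaking; the original VOI ranks widest. NA keys
  # (unscored models, skipped CV) are mapped below every real value so they
  # cannot disturb the ordering of the remaining keys.
  width <- ifelse(res$is_original, Inf, res$inner_mm + res$outer_mm)
  key_auc <- ifelse(is.na(res$auc_internal), -1, res$auc_internal)
  key_cv <- ifelse(is.na(res$auc_train_cv), -1, res$auc_train_cv)
  ord <- order(-key_auc, -key_cv, width, res$inner_mm, res$chain)
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  top_key <- paste(res$spec[1], res$chain[1], sep = "|")
  top <- models[[top_key]]
  if (!is.null(top)) {
    top$auc <- res[1, ]
    class(top) <- "omr_model"
  }
  structure(list(results = res, models = models, top = top, seed = seed,
                 chains = chains, cv_folds = cv_folds),
            class = "omr_search")
}

#' @export
print.omr_search <- function(x, ...) {
  cat(sprintf("<omr_search> %d (spec x chain) models over %d specs, %d chains\n",
              nrow(x$results), length(unique(x$results$spec)),
              length(unique(x$results$chain))))
  if (!is.null(x$top)) {
    cat(sprintf("  top: %s via '%s' (internal AUC %.3f)\n",
                spec_label(x$top$spec), x$top$chain,
                x$results$auc_internal[1]))
  }
  invisible(x)
}

#' @export
summary.omr_search <- function(object, k = 8, ...) {
  cat("Top", k, "regions by internal-test AUC:\n")
  print(summarize_top_regions(object, k), row.names = FALSE)
  invisible(object)
}

#' Heatmap of internal-test AUC over the margin-region grid
#'
#' One panel per chain; cells are (inner, outer) band coordinates.
#'
#' @param x an `omr_search`.
#' @param chain chain to display (default the top model's chain).
#' @param ... passed to [graphics::image()].
#' @export
plot.omr_search <- function(x, chain = NULL, ...) {
  if (is.null(chain)) chain <- x$results$chain[1]
  res <- x$results[x$results$chain == chain & !x$results$is_original, ]
  inn <- sort(unique(res$inner_mm)); out <- sort(unique(res$outer_mm))
  z <- matrix(NA_real_, length(inn), length(out))
  for (r in seq_len(nrow(res)))
    z[match(res$inner_mm[r], inn), match(res$outer_mm[r], out)] <-
      res$auc_internal[r]
  graphics::image(inn, out, z, xlab = "inner erosion (mm)",
                  ylab = "outer expansion (mm)",
                  main = sprintf("internal-test AUC, chain %s", chain), ...)
  invisible(x)
}

#' Table of the top-k margin regions
#'
#' Deterministic slice of the ranking with spec coordinates and AUCs;
#' `k = 1` returns the argmax of internal-test AUC, `k` beyond the result
#' count clamps to the full table.
#'
#' @param search an `omr_search` (or its `results` data.frame).
#' @param k number of rows (>= 1).
#' @return Data.frame slice of the ranked results.
#' @export
summarize_top_regions <- function(search, k = 8) {
  if (k < 1) stop("parameter error: k must be >= 1", call. = FALSE)
  res <- if (inherits(search, "omr_search")) search$results else search
  res[seq_len(min(k, nrow(res))),
      c("rank", "spec", "chain", "inner_mm", "outer_mm", "is_original",
        "n_features", "auc_train", "auc_train_cv", "auc_internal",
        "auc_external")]
}

#' @export
print.omr_model <- function(x, ...) {
  cat(sprintf("<omr_model> region %s, chain '%s', %d features\n",
              spec_label(x$spec), x$chain, length(x$features)))
  print(x$signature)
  if (!is.null(x$cutoff)) cat(sprintf("  risk cutoff: %.4f\n", x$cutoff))
  invisible(x)
}

#' Score patients with a fitted margin-region model
#'
#' @param object an `omr_model` from [omr_search()].
#' @param newdata a feature table containing the model's features.
#' @param type `"score"` (linear predictor) or `"group"` (requires a
#'   cutoff set by [stratify_cohorts()]/[run_omr_study()]).
#' @param ... unused.
#' @export
predict.omr_model <- function(object, newdata, type = c("score", "group"), ...) {
  type <- match.arg(type)
  sc <- predict(object$signature, newdata)
  if (type == "score") return(sc)
  if (is.null(object$cutoff))
    stop("model has no cutoff; run stratification first", call. = FALSE)
  factor(ifelse(sc > object$cutoff, "high", "low"), levels = c("low", "high"))
}
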