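#' @title Evaluation against a gold standard
#' @description Compares automatic to manual (gold-standard)
#'   classifications: exact-matching proportions overall and stratified by
#'   gold label size, one-vs-rest diagnostic-accuracy metrics per category
#'   (sensitivity, specificity, positive predictive value, likelihood
#'   ratios) with 95% confidence intervals, and gold-count-weighted
#'   averages across categories.
#' @name evaluation
NULL

# Predicted category sets as a named list trial_id -> character vector,
# from a list of classifications, a classification data frame, or a named
# list already holding the sets.
.pred_sets <- function(pred) {
  if (is.data.frame(pred)) {
    sets <- lapply(strsplit(ifelse(is.na(pred$categories), "",
                                   pred$categories), ";", fixed = TRUE),
                   function(x) sort(x[nzchar(x)]))
    return(stats::setNames(sets, pred$trial_id))
  }
  pred <- Filter(Negate(is.null), pred)
  if (length(pred) > 0L && inherits(pred[[1]], "gbd_classification")) {
    return(stats::setNames(lapply(pred, function(x) sort(x$categories)),
                           vapply(pred, function(x) x$trial_id, character(1))))
  }
  if (is.null(names(pred)) && length(pred) > 0L) {
    stop("category sets must be named by trial id", call. = FALSE)
  }
  lapply(pred, sort)
}

.gold_sets <- function(gold) {
  if (is.data.frame(gold)) return(.pred_sets(gold))
  if (length(gold) > 0L && inherits(gold[[1]], "gbd_classification")) {
    return(.pred_sets(gold))
  }
  gold
}

.match_ids <- function(pred_sets, gold_sets) {
  missing_gold <- setdiff(names(pred_sets), names(gold_sets))
  missing_pred <- setdiff(names(gold_sets), names(pred_sets))
  if (length(missing_gold) > 0L || length(missing_pred) > 0L) {
    stop(sprintf(
      "prediction/gold trial ids do not match (no gold: %s; no prediction: %s)",
      paste(utils::head(missing_gold, 5), collapse = ", "),
      paste(utils::head(missing_pred, 5), collapse = ", ")), call. = FALSE)
  }
}

#' Exact-matching proportions
#'
#' A trial is a hit when its predicted category set equals its gold set
#' exactly (both empty counts as a hit). Proportions are reported overall
#' and stratified by the gold label: a single category, two or more
#' categories, and no category.
#'
#' @param pred List of `gbd_classification`s or a classification data frame
#'   (columns `trial_id`, `categories` semicolon-joined).
#' @param gold Gold labels: data frame `trial_id`, `categories`
#'   (semicolon-joined, empty for "No GBD") or named list of sets.
#' @return List with elements `overall`, `one_category`,
#'   `two_plus_categories`, `no_category`, each holding `hits`, `n` and
#'   `proportion` (NA when the stratum is empty).
#' @export
exact_matching <- function(pred, gold) {
  pred_sets <- .pred_sets(pred)
  gold_sets <- .gold_sets(gold)
  .match_ids(pred_sets, gold_sets)
  ids <- names(gold_sets)
  hit <- vapply(ids, function(id) setequal(pred_sets[[id]], gold_sets[[id]]),
                logical(1))
  size <- lengths(gold_sets[ids])
  stratum <- function(keep) {
    n <- sum(keep)
    list(hits = sum(hit[keep]), n = n,
         proportion = if (n > 0L) sum(hit[keep]) / n else NA_real_)
  }
  list(overall = stratum(rep(TRUE, length(ids))),
       one_category = stratum(size == 1L),
       two_plus_categories = stratum(size >= 2L),
       no_category = stratum(size == 0L))
}

#' Wilson score interval for a proportion
#'
#' Two-sided 95% (by default) score interval.
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n > 0`.
#' @param conf Confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
proportion_ci <- function(successes, n, conf = 0.95) {
  if (n <= 0L) stop("proportion_ci() requires n > 0", call. = FALSE)
  stopifnot(successes >= 0L, successes <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

# Log-normal CI for a likelihood ratio given the 2x2 counts; NA when the
# ratio itself is undefined or degenerate.
.lr_ci <- function(lr, num_events, num_total, den_events, den_total,
                   conf = 0.95) {
  if (!is.finite(lr) || lr <= 0 || num_events == 0L || den_events == 0L) {
    return(c(lower = NA_real_, upper = NA_real_))
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / num_events - 1 / num_total + 1 / den_events - 1 / den_total)
  c(lower = exp(log(lr) - z * se), upper = exp(log(lr) + z * se))
}

#' Per-category diagnostic-accuracy metrics
#'
#' One-vs-rest scoring over the evaluated trials: a trial is positive for a
#' category when that category is in its set (multi-label trials count for
#' each of their categories); "No GBD" is scored as its own pseudo-category
#' (positive when the set is empty). Sensitivity, specificity and positive
#' predictive value carry Wilson 95% intervals; likelihood ratios LR+ =
#' Sen/(1-Spe) and LR- = (1-Sen)/Spe carry log-normal intervals. Metrics
#' with a zero denominator are reported as `NA` (printed "-" in the TSV
#' report).
#'
#' @inheritParams exact_matching
#' @param grouping The active `gbd_grouping` (supplies the category list).
#' @return Data frame, one row per non-residual category plus `"No GBD"`:
#'   counts `tp`, `fp`, `tn`, `fn` and the metrics with `_lo`/`_hi` bounds.
#' @export
per_category_metrics <- function(pred, gold, grouping) {
  stopifnot(inherits(grouping, "gbd_grouping"))
  pred_sets <- .pred_sets(pred)
  gold_sets <- .gold_sets(gold)
  .match_ids(pred_sets, gold_sets)
  ids <- names(gold_sets)
  n <- length(ids)
  cats <- grouping$categories$id[!grouping$categories$residual]

  one_category <- function(cat) {
    if (cat == "No GBD") {
      in_pred <- vapply(pred_sets[ids], function(s) length(s) == 0L, logical(1))
      in_gold <- vapply(gold_sets[ids], function(s) length(s) == 0L, logical(1))
    } else {
      in_pred <- vapply(pred_sets[ids], function(s) cat %in% s, logical(1))
      in_gold <- vapply(gold_sets[ids], function(s) cat %in% s, logical(1))
    }
    tp <- sum(in_pred & in_gold); fp <- sum(in_pred & !in_gold)
    fn <- sum(!in_pred & in_gold); tn <- sum(!in_pred & !in_gold)

    prop <- function(x, m) if (m > 0L) x / m else NA_real_
    ci <- function(x, m) {
      if (m > 0L) proportion_ci(x, m) else c(lower = NA_real_, upper = NA_real_)
    }
    sen <- prop(tp, tp + fn); sen_ci <- ci(tp, tp + fn)
    spe <- prop(tn, tn + fp); spe_ci <- ci(tn, tn + fp)
    ppv <- prop(tp, tp + fp); ppv_ci <- ci(tp, tp + fp)

    lr_plus <- if (!is.na(sen) && !is.na(spe) && (1 - spe) > 0) {
      sen / (1 - spe)
    } else NA_real_
    lr_minus <- if (!is.na(sen) && !is.na(spe) && spe > 0 && (1 - sen) > 0) {
      (1 - sen) / spe
    } else NA_real_
    lrp_ci <- .lr_ci(lr_plus, tp, tp + fn, fp, fp + tn)
    lrm_ci <- .lr_ci(lr_minus, fn, tp + fn, tn, fp + tn)

    data.frame(category_id = cat, tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity = sen, sensitivity_lo = sen_ci[[1]],
               sensitivity_hi = sen_ci[[2]],
               specificity = spe, specificity_lo = spe_ci[[1]],
               specificity_hi = spe_ci[[2]],
               ppv = ppv, ppv_lo = ppv_ci[[1]], ppv_hi = ppv_ci[[2]],
               lr_plus = lr_plus, lr_plus_lo = lrp_ci[[1]],
               lr_plus_hi = lrp_ci[[2]],
               lr_minus = lr_minus, lr_minus_lo = lrm_ci[[1]],
               lr_minus_hi = lrm_ci[[2]],
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(c(cats, "No GBD"), one_category))
  rownames(out) <- NULL
  stopifnot(all(out$tp + out$fp + out$tn + out$fn == n))
  out
}

#' Weighted average sensitivity and specificity
#'
#' Averages the per-category sensitivities (resp. specificities) weighted
#' by each category's gold-positive trial count, including the "No GBD"
#' pseudo-category. Categories with an undefined metric (no gold positives
#' for sensitivity) are excluded from that average.
#'
#' @param metrics Data frame from [per_category_metrics()].
#' @return List with `weighted_sensitivity` and `weighted_specificity`
#'   (proportions in `[0, 1]`).
#' @export
weighted_averages <- function(metrics) {
  w <- metrics$tp + metrics$fn  # gold-positive count per category
  avg <- function(value) {
    keep <- !is.na(value) & w > 0
    if (!any(keep)) stop("weighted_averages(): all weights zero", call. = FALSE)
    sum(value[keep] * w[keep]) / sum(w[keep])
  }
  list(weighted_sensitivity = avg(metrics$sensitivity),
       weighted_specificity = avg(metrics$specificity))
}

#' Full evaluation report
#'
#' Bundles [exact_matching()], [per_category_metrics()] and
#' [weighted_averages()], optionally broken down by a per-trial source
#' label.
#'
#' @inheritParams per_category_metrics
#' @param sources Optional named character vector `trial_id` -> source
#'   label; adds a per-source exact-matching breakdown.
#' @return List of class `gbd_eval_report` with elements `exact_matching`,
#'   `per_category`, `weighted` and (optionally) `by_source`.
#' @export
evaluate_classifications <- function(pred, gold, grouping, sources = NULL) {
  report <- list(exact_matching = exact_matching(pred, gold),
                 per_category = per_category_metrics(pred, gold, grouping))
  report$weighted <- weighted_averages(report$per_category)
  if (!is.null(sources)) {
    pred_sets <- .pred_sets(pred)
    gold_sets <- .gold_sets(gold)
    report$by_source <- lapply(split(names(gold_sets),
                                     sources[names(gold_sets)]),
                               function(ids) {
      exact_matching(pred_sets[ids], gold_sets[ids])
    })
  }
  class(report) <- "gbd_eval_report"
  report
}

#' @export
print.gbd_eval_report <- function(x, ...) {
  em <- x$exact_matching
  cat(sprintf("<evaluation over %d trials>\n", em$overall$n))
  cat(sprintf("  exact matching: %.1f%% overall (one: %s, two+: %s, none: %s)\n",
              100 * em$overall$proportion,
              .fmt_pct(em$one_category$proportion),
              .fmt_pct(em$two_plus_categories$proportion),
              .fmt_pct(em$no_category$proportion)))
  cat(sprintf("  weighted sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$weighted$weighted_sensitivity,
              100 * x$weighted$weighted_specificity))
  invisible(x)
}

.fmt_pct <- function(p) if (is.na(p)) "-" else sprintf("%.1f%%", 100 * p)
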