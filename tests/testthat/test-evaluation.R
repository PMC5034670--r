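two_cat_grouping <- function() {
  build_grouping(c("catA", "catB"), c("Category A", "Category B"),
                 c(FALSE, FALSE), c("A00-A99.9", "B00-B99.9"))
}

as_pred <- function(ids, sets) {
  data.frame(trial_id = ids,
             categories = vapply(sets, paste, character(1), collapse = ";"),
             stringsAsFactors = FALSE)
}

test_that("exact matching stratifies by the gold label size", {
  gold <- as_pred(paste0("T", 1:6),
                  list("catA", "catA", "catB", c("catA", "catB"), "", ""))
  pred <- as_pred(paste0("T", 1:6),
                  list("catA", "catB", "catB", c("catA", "catB"), "", "catA"))
  em <- exact_matching(pred, gold)
  expect_equal(em$overall$proportion, 4 / 6)
  expect_equal(em$one_category$proportion, 2 / 3)
  expect_equal(em$two_plus_categories$proportion, 1)
  expect_equal(em$no_category$proportion, 1 / 2)
  expect_equal(em$overall$n, 6L)

  # predicted {A} against gold {A, B} is a miss
  em2 <- exact_matching(as_pred("T1", list("catA")),
                        as_pred("T1", list(c("catA", "catB"))))
  expect_equal(em2$overall$proportion, 0)

  expect_error(exact_matching(as_pred("T1", list("catA")),
                              as_pred("T9", list("catA"))),
               "do not match")
})

test_that("per-category metrics reproduce the textbook arithmetic", {
  # 100 trials: catA has tp=8, fn=2, fp=5, tn=85
  ids <- paste0("T", 1:100)
  gold_sets <- c(rep(list("catA"), 10), rep(list(character(0)), 90))
  pred_sets <- c(rep(list("catA"), 8), rep(list(character(0)), 2),
                 rep(list("catA"), 5), rep(list(character(0)), 85))
  m <- per_category_metrics(as_pred(ids, pred_sets), as_pred(ids, gold_sets),
                            two_cat_grouping())
  a <- m[m$category_id == "catA", ]
  expect_equal(a$tp, 8); expect_equal(a$fn, 2)
  expect_equal(a$fp, 5); expect_equal(a$tn, 85)
  expect_equal(a$sensitivity, 0.80)
  expect_equal(a$specificity, 85 / 90)
  expect_equal(a$ppv, 8 / 13)
  expect_equal(a$lr_plus, 0.8 / (1 - 85 / 90))
  expect_equal(a$lr_minus, 0.2 / (85 / 90))
  expect_equal(round(100 * a$sensitivity, 1), 80.0)
  expect_equal(round(100 * a$specificity, 1), 94.4)
  expect_equal(round(100 * a$ppv, 1), 61.5)
  expect_equal(round(a$lr_plus, 1), 14.4)
  expect_equal(round(a$lr_minus, 3), 0.212)
})

test_that("undefined metrics are reported as absent, not as 0 or 100", {
  ids <- paste0("T", 1:10)
  # catA perfectly predicted with no false positives -> LR+ undefined
  gold_sets <- c(rep(list("catA"), 4), rep(list(character(0)), 6))
  m <- per_category_metrics(as_pred(ids, gold_sets), as_pred(ids, gold_sets),
                            two_cat_grouping())
  a <- m[m$category_id == "catA", ]
  expect_true(is.na(a$lr_plus))   # 1 - specificity is zero
  expect_true(is.na(a$lr_minus))  # 1 - sensitivity is zero
  # catB absent from both pred and gold: Sen undefined, Spe = 100%
  b <- m[m$category_id == "catB", ]
  expect_true(is.na(b$sensitivity))
  expect_equal(b$specificity, 1)
})

test_that("a perfect classifier scores 100% everywhere defined", {
  bundle <- generate_bundle(fixture_spec(n_trials = 40, seed = 11))
  res <- classify_batch(bundle$trials, bundle$lexicon, bundle$grouping)
  m <- per_category_metrics(res, bundle$gold, bundle$grouping)
  expect_true(all(m$sensitivity[!is.na(m$sensitivity)] == 1))
  expect_true(all(m$specificity[!is.na(m$specificity)] == 1))
  em <- exact_matching(res, res)
  expect_equal(em$overall$proportion, 1)
})

test_that("weighted averages use gold-positive counts as weights", {
  m <- data.frame(category_id = c("a", "b"),
                  tp = c(10, 5), fn = c(0, 5), fp = 0, tn = 0,
                  sensitivity = c(1, 0.5), specificity = c(0.9, 0.5))
  w <- weighted_averages(m)
  expect_equal(w$weighted_sensitivity, 0.75)
  expect_equal(w$weighted_specificity, 0.7)

  m2 <- data.frame(category_id = c("a", "b"),
                   tp = c(27, 5), fn = c(3, 5), fp = 0, tn = 0,
                   sensitivity = c(0.9, 0.5), specificity = c(1, 1))
  expect_equal(weighted_averages(m2)$weighted_sensitivity, 0.8)

  single <- m[1, ]
  expect_equal(weighted_averages(single)$weighted_sensitivity, 1)

  # undefined sensitivities are excluded from the average
  m3 <- m; m3$sensitivity[2] <- NA
  expect_equal(weighted_averages(m3)$weighted_sensitivity, 1)

  zero <- data.frame(category_id = "a", tp = 0, fn = 0, fp = 0, tn = 0,
                     sensitivity = NA_real_, specificity = NA_real_)
  expect_error(weighted_averages(zero), "weights zero")
})

test_that("the Wilson interval matches its closed form and boundaries", {
  # independent closed-form computation of the 95% Wilson interval
  wilson_oracle <- function(x, n, z = qnorm(0.975)) {
    p <- x / n
    (p + z^2 / (2 * n) + c(-1, 1) * z *
       sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / (1 + z^2 / n)
  }
  ci <- proportion_ci(50, 100)
  expect_equal(unname(ci), wilson_oracle(50, 100), tolerance = 1e-12)
  expect_equal(round(unname(ci), 3), c(0.404, 0.596))

  expect_equal(proportion_ci(0, 10)[["lower"]], 0)
  expect_equal(proportion_ci(10, 10)[["upper"]], 1)
  for (x in c(1, 5, 9)) {
    expect_equal(unname(proportion_ci(x, 10)), wilson_oracle(x, 10),
                 tolerance = 1e-12)
  }
  expect_error(proportion_ci(1, 0), "n > 0")
})

test_that("metric self-consistency holds on random prediction/gold pairs", {
  g <- two_cat_grouping()
  set.seed(99)
  for (rep in 1:10) {
    n <- 30
    ids <- paste0("T", seq_len(n))
    draw <- function() {
      lapply(seq_len(n), function(i) {
        sample(list(character(0), "catA", "catB", c("catA", "catB")), 1)[[1]]
      })
    }
    gold_sets <- draw(); pred_sets <- draw()
    gold <- as_pred(ids, gold_sets); pred <- as_pred(ids, pred_sets)
    m <- per_category_metrics(pred, gold, g)
    # tp + fn equals the gold-positive count per category
    gp <- vapply(c("catA", "catB"), function(cat) {
      sum(vapply(gold_sets, function(s) cat %in% s, logical(1)))
    }, numeric(1))
    expect_equal(m$tp[match(names(gp), m$category_id)] +
                   m$fn[match(names(gp), m$category_id)], unname(gp))
    expect_true(all(m$tp + m$fp + m$tn + m$fn == n))
    # LR+ recomputed from Sen/Spe matches stored value
    ok <- !is.na(m$lr_plus)
    expect_equal(m$lr_plus[ok],
                 m$sensitivity[ok] / (1 - m$specificity[ok]),
                 tolerance = 1e-10)
    expect_equal(exact_matching(pred, pred)$overall$proportion, 1)
    # weighted averages invariant to category ordering
    w1 <- weighted_averages(m)
    w2 <- weighted_averages(m[rev(seq_len(nrow(m))), ])
    expect_equal(w1, w2)
  }
})

test_that("the full report bundles strata, metrics and source breakdowns", {
  bundle <- generate_bundle(fixture_spec(n_trials = 30, seed = 5))
  res <- classify_batch(bundle$trials, bundle$lexicon, bundle$grouping)
  sources <- setNames(rep(c("reg1", "reg2"), length.out = 30),
                      bundle$trials$trial_id)
  report <- evaluate_classifications(res, bundle$gold, bundle$grouping,
                                     sources = sources)
  expect_s3_class(report, "gbd_eval_report")
  expect_equal(report$exact_matching$overall$proportion, 1)
  expect_named(report$by_source, c("reg1", "reg2"))
  expect_equal(report$by_source$reg1$overall$n, 15L)
  total <- with(report$exact_matching,
                one_category$n + two_plus_categories$n + no_category$n)
  expect_equal(total, report$exact_matching$overall$n)
})
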