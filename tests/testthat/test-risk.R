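test_that("the abnormality metric flags any nonzero incidence at slow rate", {
  tab <- data.frame(concentration = c(1, 3), frequency = 0.25,
                    incidence_pct = c(0, 0))
  expect_identical(classify_by_abnormality(tab)$prediction, "safe")
  tab$incidence_pct[2] <- 100 / 530       # one model in 530
  expect_identical(classify_by_abnormality(tab)$prediction, "risky")
  expect_error(classify_by_abnormality(
    data.frame(concentration = 1, frequency = 1, incidence_pct = 0)), "slow")
})

test_that("the APD90 metric uses a strict 10% threshold at 1 Hz", {
  mk <- function(p) data.frame(concentration = 1, frequency = 1, pct_APD90 = p)
  expect_identical(classify_by_apd90(mk(10.1))$prediction, "risky")
  expect_identical(classify_by_apd90(mk(9.9))$prediction, "safe")
  expect_identical(classify_by_apd90(mk(10.0))$prediction, "safe")
  expect_identical(classify_by_apd90(mk(-40))$prediction, "safe")
})

test_that("both classifiers are monotone in added concentrations", {
  tab <- data.frame(concentration = c(1, 3, 10), frequency = 0.25,
                    incidence_pct = c(0, 0, 12),
                    pct_APD90 = c(2, 8, 30))
  # dropping the top concentration can only move risky -> safe
  full <- classify_by_abnormality(tab)$prediction
  part <- classify_by_abnormality(tab[1:2, ])$prediction
  expect_identical(full, "risky")
  expect_identical(part, "safe")
  tab1 <- tab; tab1$frequency <- 1
  expect_identical(classify_by_apd90(tab1)$prediction, "risky")
  expect_identical(classify_by_apd90(tab1[1:2, ])$prediction, "safe")
})

test_that("confusion matrix and integer accuracy follow half-up rounding", {
  calls <- data.frame(prediction = c(rep("risky", 11), rep("safe", 3)),
                      truth = c(rep("risky", 11), rep("safe", 3)))
  cm <- confusion_and_accuracy(calls)
  expect_equal(cm$accuracy_pct, 100)
  # invert everything
  inv <- data.frame(prediction = ifelse(calls$truth == "risky", "safe", "risky"),
                    truth = calls$truth)
  expect_equal(confusion_and_accuracy(inv)$accuracy_pct, 0)
  # 11/14 rounds to 79, 12/14 to 86
  eleven <- data.frame(prediction = c(rep("risky", 8), rep("safe", 6)),
                       truth = c(rep("risky", 11), rep("safe", 3)))
  expect_equal(confusion_and_accuracy(eleven)$accuracy_pct, 79)
  twelve <- data.frame(prediction = c(rep("risky", 11), "risky", "risky", "safe"),
                       truth = c(rep("risky", 11), "safe", "safe", "safe"))
  expect_equal(confusion_and_accuracy(twelve)$accuracy_pct, 86)
  expect_error(confusion_and_accuracy(list()), "empty")
})

test_that("consistency categories follow trend and 15-point tolerance", {
  expect_identical(consistency_category(8, 10), "strong")
  expect_identical(consistency_category(20, 51), "qualitative")
  expect_identical(consistency_category(5, -4), "disagreement")
  # boundary counts as strong ("equal or less")
  expect_identical(consistency_category(0, 15), "strong")
  expect_identical(consistency_category(30, 15), "strong")
  # zero agrees in trend with either sign
  expect_identical(consistency_category(0, -10), "strong")
  expect_identical(consistency_category(0, -26), "qualitative")
  # symmetric up to labelling
  for (i in 1:20) {
    a <- runif(1, -60, 60); b <- runif(1, -60, 60)
    expect_identical(consistency_category(a, b), consistency_category(b, a))
  }
})

test_that("random predictions average near the majority-class rate", {
  truth <- c(rep("risky", 11), rep("safe", 3))
  set.seed(99)
  accs <- replicate(400, {
    confusion_and_accuracy(data.frame(
      prediction = sample(truth), truth = truth))$accuracy_pct
  })
  # expected accuracy of a permuted prediction: (11^2 + 3^2)/14^2 = 66.3%
  expect_equal(mean(accs), 66.3, tolerance = 0.05)
})
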