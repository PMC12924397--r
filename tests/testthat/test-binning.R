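test_that("single-label mappings follow the published scheme", {
  # two-state reads locomotion
  expect_equal(binFMCH("eating", "walking", "two_state"), "travelling")
  expect_equal(binFMCH("eating", "stationary awake", "two_state"),
               "stationary")
  expect_equal(binFMCH("napping", "napping", "two_state"), "stationary")
  expect_equal(binFMCH("travelling", "wading/swimming", "two_state"),
               "travelling")
  # three-state reads behaviour
  expect_equal(binFMCH("eating", "walking", "three_state"), "foraging")
  expect_equal(binFMCH("ruminating", "stationary awake", "three_state"),
               "stationary")
  expect_equal(binFMCH("travelling", "running", "three_state"), "travelling")
  # "other" is excluded everywhere
  expect_equal(binFMCH("other", "walking", "two_state"), "EXCLUDED")
  expect_equal(binFMCH("other", "walking", "three_state"), "EXCLUDED")
  # unknown labels are hard errors naming the label
  expect_error(binFMCH("grazing", "walking", "three_state"), "grazing")
  expect_error(binFMCH("eating", "flying", "two_state"), "flying")
})

test_that("multi-label precedence reproduces the worked co-occurrences", {
  expect_equal(binRFCH(list(c("walking", "eating")), "three_state"),
               "foraging")
  expect_equal(binRFCH(list(c("walking", "running")), "three_state"),
               "travelling")
  expect_equal(binRFCH(list(c("laying", "ruminating")), "three_state"),
               "stationary")
  expect_equal(binRFCH(list(c("eating", "walking")), "two_state"),
               "travelling")
  expect_equal(binRFCH(list(c("ruminating", "laying", "vigilant")),
                       "two_state"), "stationary")
  expect_equal(binRFCH(list(c("eating", "other")), "two_state"), "EXCLUDED")
  expect_equal(binRFCH("walking|eating", "three_state"), "foraging")
  expect_error(binRFCH(list(character(0)), "two_state"), "empty")
  expect_error(binRFCH(list("flying"), "two_state"), "flying")
  # "vigilance" is accepted as an alias of "vigilant"
  expect_equal(binRFCH(list("vigilance"), "three_state"), "stationary")
})

rfchVocab <- c("eating", "foraging", "drinking", "laying", "walking",
               "ruminating", "vigilant", "running", "swimming", "other")

allSubsets <- function(vocab) {
  n <- length(vocab)
  out <- vector("list", 2^n - 1)
  k <- 0
  for (m in 1:(2^n - 1)) {
    k <- k + 1
    out[[k]] <- vocab[bitwAnd(m, 2^(seq_len(n) - 1)) > 0]
  }
  out
}

test_that("every multi-label subset maps to exactly one category", {
  subs <- allSubsets(rfchVocab)
  for (scheme in c("two_state", "three_state")) {
    cats <- binRFCH(subs, scheme)
    expect_equal(length(cats), 2^10 - 1)
    expect_true(all(cats %in% c("stationary", "foraging", "travelling",
                                "EXCLUDED")))
    if (scheme == "two_state") expect_false(any(cats == "foraging"))
    # any subset containing "other" is excluded, and only those
    has_other <- vapply(subs, function(s) "other" %in% s, logical(1))
    expect_identical(cats == "EXCLUDED", has_other)
  }
})

test_that("binning is invariant to label order within a set", {
  set.seed(61)
  subs <- allSubsets(rfchVocab)
  pick <- sample(length(subs), 200)
  for (scheme in c("two_state", "three_state")) {
    a <- binRFCH(subs[pick], scheme)
    b <- binRFCH(lapply(subs[pick], sample), scheme)
    expect_identical(a, b)
  }
})

test_that("three-state travelling without feeding is two-state travelling", {
  subs <- allSubsets(rfchVocab)
  c3 <- binRFCH(subs, "three_state")
  c2 <- binRFCH(subs, "two_state")
  trav_no_feed <- c3 == "travelling"
  expect_true(all(c2[trav_no_feed] == "travelling"))
})

test_that("the clip-table front end matches the vectorized rules", {
  clips <- data.frame(id = "a",
                      timestamp = as.POSIXct("2018-06-01", tz = "UTC") + 1:3,
                      behaviour = c("eating", "other", "travelling"),
                      locomotion = c("walking", "walking", "running"),
                      stringsAsFactors = FALSE)
  out <- binBehaviours(clips, "FMCH", "three_state")
  expect_equal(out$category, c("foraging", "EXCLUDED", "travelling"))
  expect_equal(out$scheme, rep("three_state", 3))

  rf <- data.frame(id = "a",
                   timestamp = as.POSIXct("2018-06-01", tz = "UTC") + 1:2,
                   labels = c("walking|eating", "laying"),
                   stringsAsFactors = FALSE)
  out2 <- binBehaviours(rf, "RFCH", "three_state")
  expect_equal(out2$category, c("foraging", "stationary"))
})

test_that("the shipped rule file agrees with the code vocabularies", {
  rules <- binningRules()
  expect_equal(sort(rules$dialects$RFCH$vocabulary), sort(rfchVocab))
  two <- rules$dialects$FMCH$two_state$map
  expect_equal(two[["walking"]], "travelling")
  expect_equal(two[["napping"]], "stationary")
  three <- rules$dialects$FMCH$three_state$map
  expect_equal(three[["eating"]], "foraging")
})
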