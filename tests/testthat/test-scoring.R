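table1_lpa <- list(                 # measured LPA% per exercise level
  A = c(60, 48.2, 46.4, 47),
  B = c(43.4, 42.4, 42.8, 40.7),
  C = c(42, 42.3, 41.1, 40.7),
  D = c(40, 40.3, 40.8, 40.6)
)

test_that("balance indices recover the reference imbalance and instability", {
  expect_equal(balance_index(c(45, 45, 45))$imbalance, 0)
  expect_equal(balance_index(c(45, 45, 45))$instability, 0)
  expect_equal(balance_index(table1_lpa$A)$instability, 13.6)  # 60 - 46.4
  expect_equal(balance_index(table1_lpa$D)$instability, 0.8)
  # matrix form validates LPA + RPA = 100
  expect_error(balance_index(cbind(c(46, 47), c(50, 53))),
               class = "fontanflow_validation_error")
  # the measured splits rank B most balanced, then C, D, A
  imb <- vapply(table1_lpa, function(x) balance_index(x)$imbalance, 0)
  expect_equal(names(sort(imb)), c("B", "C", "D", "A"))
})

test_that("the 4/3/2/1 scheme reproduces the published score card", {
  # indicator values encoded by rank position (1 = best) from the reported
  # orderings: PG best-to-worst D,C,A,B; velocity A,D,C,B; efficiency
  # D,C,A,B; balance B,C,D,A
  tab <- data.frame(design = c("A", "B", "C", "D"),
                    pg = c(3, 4, 2, 1),
                    velocity = c(1, 4, 3, 2),
                    efficiency = c(3, 4, 2, 1),   # lower rank = better
                    balance = c(4, 1, 2, 3))
  card <- rank_and_score(tab, directions = c(pg = "lower",
                                             velocity = "lower",
                                             efficiency = "lower",
                                             balance = "lower"))
  expect_equal(unname(card$totals[c("A", "B", "C", "D")]), c(9, 7, 11, 13))
  expect_equal(unname(card$scores["A", ]), c(2, 4, 2, 1))
  expect_equal(unname(card$scores["B", ]), c(1, 1, 1, 4))
  expect_equal(unname(card$scores["C", ]), c(3, 2, 3, 3))
  expect_equal(unname(card$scores["D", ]), c(4, 3, 4, 2))
  expect_identical(select_best(card), "D")
})

test_that("ties share their scores and conservation holds for any input", {
  same <- data.frame(design = c("w", "x", "y", "z"),
                     pg = rep(1, 4), velocity = rep(2, 4),
                     efficiency = rep(0.9, 4), balance = rep(3, 4))
  card <- rank_and_score(same)
  expect_true(all(card$scores == 2.5))
  expect_true(all(card$totals == 10))

  set.seed(99)
  for (i in 1:20) {
    tab <- data.frame(design = letters[1:4],
                      pg = sample(3, 4, replace = TRUE),
                      velocity = runif(4),
                      efficiency = sample(2, 4, replace = TRUE),
                      balance = runif(4))
    card <- rank_and_score(tab)
    expect_equal(sum(card$totals), 40)
    expect_equal(unname(colSums(card$scores)), rep(10, 4))
    # permuting the rows permutes, but does not change, the scores
    perm <- sample(4)
    card2 <- rank_and_score(tab[perm, ])
    expect_equal(card2$scores[rownames(card$scores), ], card$scores)
    expect_identical(select_best(card2), select_best(card))
  }
})

test_that("total ties break towards the lower pressure gradient", {
  tab <- data.frame(design = c("p", "q"),
                    pg = c(2, 1), velocity = c(1, 2),
                    efficiency = c(0.9, 0.9), balance = c(1, 1))
  card <- rank_and_score(tab)
  expect_equal(unname(card$totals), c(6, 6))
  expect_identical(select_best(card), "q")
  expect_error(select_best(structure(list(totals = numeric(0)),
                                     class = "score_card")),
               class = "fontanflow_validation_error")
})

test_that("regional perfusion percentages sum to the lung totals", {
  scan <- read.csv(system.file("extdata", "postop_lung_perfusion.csv",
                               package = "fontanflow"))
  tot <- perfusion_totals(scan)
  expect_equal(unname(tot["left"]), 46.71)
  expect_equal(unname(tot["right"]), 53.29)
  expect_equal(sum(tot), 100)
})
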