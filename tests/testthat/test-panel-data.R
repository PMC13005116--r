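test_that("long and wide CSV round-trips give identical panels", {
  pd <- tinyPanel()
  lng <- withr::local_tempfile(fileext = ".csv")
  wde <- withr::local_tempfile(fileext = ".csv")
  writePanel(pd, lng, format = "long")
  writePanel(pd, wde, format = "wide")
  fromLong <- loadPanel(lng)
  fromWide <- loadPanel(wde)
  expect_identical(dim(fromLong$ratings), c(2L, 3L, 3L))
  expect_equal(fromLong$ratings, pd$ratings)
  expect_equal(fromWide$ratings, pd$ratings)
  expect_equal(fromWide$group, pd$group)
  # second round-trip is exact
  lng2 <- withr::local_tempfile(fileext = ".csv")
  writePanel(fromWide, lng2, format = "long")
  expect_equal(loadPanel(lng2)$ratings, pd$ratings)
})

test_that("out-of-range ratings are rejected with the offending row named", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(subject = c("a", "a", "b"), item = c("P1", "P2", "P1"),
                   wave = "T0", rating = c(3, 9, 2))
  write.csv(df, f, row.names = FALSE)
  expect_error(loadPanel(f), "row 2")
  df$rating <- c(3, 2.5, 2)
  write.csv(df, f, row.names = FALSE)
  expect_error(loadPanel(f), "out of range")
  # missing cells pass through as NA
  df$rating <- c(3, NA, 2)
  write.csv(df, f, row.names = FALSE)
  pd <- loadPanel(f)
  expect_true(is.na(pd$ratings["a", "P2", "T0"]))
})

test_that("selectItems restricts, reorders and validates", {
  pd <- tinyPanel()
  expect_equal(selectItems(pd, panelItems(pd))$ratings, pd$ratings)
  sub <- selectItems(pd, c("G5", "P1"))
  expect_identical(panelItems(sub), c("G5", "P1"))
  expect_equal(sub$ratings["a", "G5", "T0"], pd$ratings["a", "G5", "T0"])
  expect_identical(sub$group, pd$group)
  expect_error(selectItems(pd, "X9"), "unknown item X9")
})

test_that("remission rule: all items at the boundary rating of 3 still remit", {
  r <- array(3, c(1, 8, 1),
             dimnames = list("s", andreasenItems(), "T0"))
  pd <- panelData(r)
  expect_true(classifyRemission(pd, "T0")[["s"]])
  # a single rating of 4 on any remission item breaks remission
  for (it in andreasenItems()) {
    r2 <- r
    r2[1, it, 1] <- 4
    expect_false(classifyRemission(panelData(r2), "T0")[["s"]])
  }
  r[] <- 1
  expect_true(classifyRemission(panelData(r), "T0")[["s"]])
})

test_that("remission is monotone: lowering a rating never removes remission", {
  set.seed(42)
  for (i in 1:25) {
    r <- array(sample(1:5, 8, TRUE), c(1, 8, 1),
               dimnames = list("s", andreasenItems(), "T0"))
    base <- classifyRemission(panelData(r), "T0")[[1]]
    j <- sample(8, 1)
    r2 <- r
    r2[1, j, 1] <- max(1, r[1, j, 1] - sample(1:3, 1))
    lowered <- classifyRemission(panelData(r2), "T0")[[1]]
    expect_true(!base || lowered)
  }
})

test_that("missing remission items follow the configured policy", {
  r <- array(2, c(1, 8, 1), dimnames = list("s", andreasenItems(), "T0"))
  r[1, "P1", 1] <- NA
  pd <- panelData(r)
  expect_error(classifyRemission(pd, "T0"), "missing")
  expect_true(is.na(classifyRemission(pd, "T0", missing = "na")[[1]]))
})

test_that("total score sums the item set and propagates missingness", {
  p <- 21
  r <- array(1, c(2, p, 1),
             dimnames = list(c("a", "b"), panss21ItemSet()$codes, "T0"))
  r[2, , 1] <- 7
  pd <- panelData(r, items = panss21ItemSet())
  expect_equal(unname(totalScore(pd, "T0")), c(21, 147))
  r[1, 3, 1] <- NA
  expect_true(is.na(totalScore(panelData(r, items = panss21ItemSet()), "T0")[["a"]]))
  # arbitrary mixed vector is an arithmetic sum
  vals <- rep(c(2, 5, 3), length.out = p)
  r[1, , 1] <- vals
  expect_equal(unname(totalScore(panelData(r, items = panss21ItemSet()), "T0")[1]),
               sum(vals))
})

test_that("greedy nearest-neighbour matching is deterministic and exact on fixtures", {
  mk <- function(cov, grp) {
    n <- length(cov)
    r <- array(1, c(n, 2, 1),
               dimnames = list(sprintf("s%02d", seq_len(n)), c("P1", "P2"), "T0"))
    pd <- panelData(r, group = grp)
    list(pd = pd, cov = setNames(cov, pd$subjects))
  }
  # {1,10} vs {2,9,100}: hand-derived pairs (10,9), (1,2)
  fx <- mk(c(1, 10, 2, 9, 100), c("A", "A", "B", "B", "B"))
  m <- matchGroups(fx$pd, fx$cov)
  expect_equal(nrow(m$pairs), 2)
  got <- setNames(fx$cov[m$pairs$larger], fx$cov[m$pairs$smaller])
  expect_equal(got, setNames(c(9, 2), c(10, 1)), ignore_attr = TRUE)
  # sizes 5 vs 3 -> 3 pairs, equal kept-group sizes
  fx2 <- mk(c(5, 3, 8, 1, 9, 4, 2, 6), c(rep("A", 5), rep("B", 3)))
  m2 <- matchGroups(fx2$pd, fx2$cov)
  expect_equal(nrow(m2$pairs), 3)
  expect_equal(lengths(m2$keptIds), c(B = 3, A = 3), ignore_attr = TRUE)
  expect_lte(length(m2$keptIds[[1]]), 3)
  # identical covariates -> all distances zero
  fx3 <- mk(rep(2, 6), c(rep("A", 3), rep("B", 3)))
  expect_equal(matchGroups(fx3$pd, fx3$cov)$pairs$distance, rep(0, 3))
  # empty group errors
  fx4 <- mk(c(1, 2), c("A", "A"))
  expect_error(matchGroups(fx4$pd, fx4$cov), "2 groups")
})

test_that("item sets validate and survive a JSON round-trip", {
  expect_error(itemSet(c("P1", "P1")), "duplicate")
  expect_error(itemSet("P1", remissionItems = "P9"), "not in item set")
  set <- panss21ItemSet()
  expect_length(set$codes, 21)
  expect_true(all(set$remissionItems %in% set$codes))
  f <- withr::local_tempfile(fileext = ".json")
  writeItemSet(set, f)
  back <- readItemSet(f)
  expect_identical(back$codes, set$codes)
  expect_identical(back$domains, set$domains)
  expect_identical(back$remissionItems, set$remissionItems)
})
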