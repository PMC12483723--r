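test_that("wide files load with listwise deletion and code validation", {
  d <- data.frame(matrix(sample(0:3, 60, TRUE), nrow = 10))
  f <- tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  p <- read_panel(f, n_occasions = 6)
  expect_equal(p$n, 10)
  expect_equal(p$T, 6L)

  d2 <- d; d2[3, 4] <- NA
  write.csv(d2, f, row.names = FALSE)
  p2 <- read_panel(f, n_occasions = 6)
  expect_equal(p2$n, 9)
  expect_equal(p2$n_before, 10)

  d3 <- d; d3[1, 1] <- 7
  write.csv(d3, f, row.names = FALSE)
  expect_error(read_panel(f, n_occasions = 6, n_cat = 4), "codes outside")

  expect_error(ordinal_panel(d[, 1, drop = FALSE], n_occasions = 1),
               "two occasions")
  unlink(f)
})

test_that("labelled categories map through an ordered level vector", {
  d <- data.frame(a = c("low", "mid", "high"), b = c("mid", "mid", "low"))
  f <- tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  p <- read_panel(f, n_occasions = 2, levels = c("low", "mid", "high"))
  expect_equal(unname(p$data[, 1]), c(0L, 1L, 2L))
  d$b[1] <- "bogus"
  write.csv(d, f, row.names = FALSE)
  expect_error(read_panel(f, n_occasions = 2,
                          levels = c("low", "mid", "high")), "unmappable")
  unlink(f)
})

test_that("margins match brute-force tabulation and sum to one", {
  p <- tiny_panel()
  mg <- margins(p)
  for (j in seq_len(ncol(p$data))) {
    brute <- sapply(0:3, function(c) sum(p$data[, j] == c))
    expect_equal(mg[[j]]$counts[seq_along(brute)], brute)
    expect_equal(sum(mg[[j]]$props), 1)
  }
  pc <- ordinal_panel(cbind(rep(0L, 5), rep(0L, 5)), 2, n_cat = 3)
  expect_true(margins(pc)[[1]]$degenerate)
})

test_that("crosstabs conserve counts, transpose, and factorize under
           independence", {
  p <- tiny_panel()
  tab <- crosstab(p, 1, 2)
  expect_equal(sum(tab), p$n)
  expect_equal(unname(crosstab(p, 2, 1)), unname(t(tab)))
  expect_equal(rowSums(tab), margins(p)[[1]]$counts,
               ignore_attr = TRUE)
  # identical binary columns give a diagonal table
  pb <- ordinal_panel(cbind(c(0, 1, 0, 1), c(0, 1, 0, 1)), 2)
  expect_equal(unname(crosstab(pb, 1, 2)), diag(c(2, 2)))
  # independent columns: cell proportions near the product of margins
  set.seed(1)
  pi <- ordinal_panel(cbind(sample(0:3, 20000, TRUE),
                            sample(0:3, 20000, TRUE)), 2)
  tt <- crosstab(pi, 1, 2) / 20000
  mm <- outer(margins(pi)[[1]]$props, margins(pi)[[2]]$props)
  expect_lt(max(abs(tt - mm)), 0.01)
})

test_that("listwise deletion is idempotent", {
  p <- tiny_panel()
  p2 <- ordinal_panel(p$data, p$T)
  expect_equal(p2$n, p$n)
  expect_equal(p2$data, p$data)
})
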