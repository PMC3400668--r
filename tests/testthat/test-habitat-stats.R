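# Pearson p-values, missing-cell factorial ANOVA, Duncan letters.

make_missing_cell_design <- function(n_per_cell = 6) {
  d <- expand.grid(reach = c("lower", "middle", "upper"),
                   stream = c("main", "tributary"),
                   stringsAsFactors = FALSE)
  d <- d[!(d$reach == "upper" & d$stream == "tributary"), ]
  d[rep(seq_len(nrow(d)), each = n_per_cell), ]
}

test_that("p_from_r implements the two-sided t-transform", {
  expect_equal(p_from_r(0, 10), 1)
  expect_equal(p_from_r(0.5, 20), p_from_r(-0.5, 20))
  expect_equal(p_from_r(0.999999999, 5), 0, tolerance = 1e-6)
  expect_equal(p_from_r(1, 5), 0)
  # agrees with cor.test's t-based p on data
  set.seed(3)
  x <- rnorm(15); y <- x + rnorm(15)
  ct <- cor.test(x, y)
  res <- pearson_with_p(x, y)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_error(p_from_r(1.2, 5), "\\[-1, 1\\]")
})

test_that("pearson_with_p handles exact linearity and degenerate input", {
  x <- 1:10
  res <- pearson_with_p(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-12)
  expect_error(pearson_with_p(x, rep(3, 10)), "variance")
  expect_error(pearson_with_p(1:2, 2:3), "at least 3")
  # r and p are invariant to positive affine transforms
  set.seed(4)
  a <- rnorm(12); b <- rnorm(12)
  r1 <- pearson_with_p(a, b)
  r2 <- pearson_with_p(3 * a + 7, 0.2 * b - 4)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("balanced two-way ANOVA reproduces the classical decomposition", {
  set.seed(11)
  d <- expand.grid(f1 = c("A", "B"), f2 = c("X", "Y", "Z"))
  d <- d[rep(seq_len(nrow(d)), each = 5), ]
  d$y <- rnorm(nrow(d)) + ifelse(d$f1 == "A", 0.8, 0)
  got <- factorial_anova(d, "y", c("f1", "f2"))
  ref <- summary(aov(y ~ f1 * f2, d))[[1]]
  expect_equal(got$F, ref[["F value"]][1:3], tolerance = 1e-10)
  expect_equal(got$p, ref[["Pr(>F)"]][1:3], tolerance = 1e-10)
  expect_equal(got$df1, ref[["Df"]][1:3])
})

test_that("the missing-cell design keeps every term with reduced df", {
  set.seed(12)
  d <- make_missing_cell_design()
  d$y <- rnorm(nrow(d))
  res <- factorial_anova(d, "y", c("reach", "stream"))
  expect_setequal(res$term, c("reach", "stream", "reach:stream"))
  expect_equal(res$df1[res$term == "reach"], 2L)
  expect_equal(res$df1[res$term == "stream"], 1L)
  # only one interaction contrast is estimable without the upper-reach
  # tributary cell
  expect_equal(res$df1[res$term == "reach:stream"], 1L)
  expect_equal(attr(res, "missing_cells"),
               "reach=upper:stream=tributary")
})

test_that("a constant response gives F = 0 and p = 1", {
  d <- make_missing_cell_design()
  d$y <- 5
  res <- factorial_anova(d, "y", c("reach", "stream"))
  expect_true(all(res$F == 0))
  expect_true(all(res$p == 1))
})

test_that("ANOVA sums of squares ignore factor-level labels", {
  set.seed(13)
  d <- make_missing_cell_design()
  d$y <- rnorm(nrow(d))
  r1 <- factorial_anova(d, "y", c("reach", "stream"))
  d2 <- d
  d2$reach <- c(lower = "Z3", middle = "Z1", upper = "Z2")[d2$reach]
  r2 <- factorial_anova(d2, "y", c("reach", "stream"))
  expect_equal(sort(r1$ss), sort(r2$ss), tolerance = 1e-10)
})

test_that("Duncan letters separate what the ranges separate", {
  # identical groups share one letter
  same <- duncan_letters(rep(c(5, 5.0), 10), rep(c("a", "b"), 10))
  expect_true(all(same$letters == "a"))
  # far-apart groups get distinct letters
  set.seed(14)
  v <- c(rnorm(8, 0, 0.3), rnorm(8, 50, 0.3))
  far <- duncan_letters(v, rep(c("lo", "hi"), each = 8))
  expect_equal(far$letters, c("a", "b"))
  expect_error(duncan_letters(c(1, 2, 3), c("a", "a", "b")),
               "at least 2 observations")
})

test_that("letter displays form contiguous staircase blocks", {
  set.seed(15)
  for (rep_i in 1:20) {
    v <- rnorm(40, rep(runif(5, 0, 4), each = 8))
    g <- rep(paste0("g", 1:5), each = 8)
    res <- duncan_letters(v, g)
    for (lt in unique(unlist(strsplit(res$letters, "")))) {
      idx <- which(vapply(strsplit(res$letters, ""),
                          function(ch) lt %in% ch, logical(1)))
      expect_equal(idx, seq(min(idx), max(idx)))
    }
  }
})
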