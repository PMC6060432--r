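test_that("Fisher's two-sided test matches closed forms and enumeration", {
  gys1 <- fisher_exact_two_sided(matrix(c(0, 31, 2, 26), 2, 2, byrow = TRUE))
  expect_equal(gys1$p, 378 / 1711, tolerance = 1e-12)

  # the observed table is the distribution's mode -> p = 1
  expect_equal(
    fisher_exact_two_sided(matrix(c(5, 26, 5, 23), 2, 2, byrow = TRUE))$p, 1
  )
  # two equiprobable tables, both in the tail
  expect_equal(fisher_exact_two_sided(c(1, 0, 0, 1))$p, 1)

  expect_error(fisher_exact_two_sided(c(0, 0, 0, 0)), "at least one")
  expect_error(fisher_exact_two_sided(c(-1, 2, 3, 4)), "non-negative")
})

test_that("Fisher implementation equals brute-force enumeration for N <= 80", {
  set.seed(301)
  tables <- c(
    lapply(1:40, function(i) {
      matrix(sample(0:20, 4, replace = TRUE), 2, 2)
    }),
    list(
      matrix(c(9, 22, 5, 23), 2, 2, byrow = TRUE),
      matrix(c(26, 5, 18, 10), 2, 2, byrow = TRUE),
      matrix(c(0, 31, 2, 26), 2, 2, byrow = TRUE),
      matrix(c(40, 0, 0, 40), 2, 2)
    )
  )
  for (tab in tables) {
    if (sum(tab) == 0) next
    got <- fisher_exact_two_sided(tab)
    expect_equal(got$p, fisher_brute(tab), tolerance = 1e-12)
    expect_lte(got$point_prob, got$p + 1e-12)
    expect_gt(got$p, 0)
    expect_lte(got$p, 1)
    # invariance under simultaneous row and column swap
    swapped <- tab[2:1, 2:1]
    expect_equal(fisher_exact_two_sided(swapped)$p, got$p, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney exact mode equals full enumeration", {
  m <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(m$U, 0)
  expect_equal(m$p, 0.1) # 2 of the 20 rank splits are as extreme
  expect_equal(m$method, "exact")

  # independent oracle: the distribution-based exact two-sided p
  set.seed(99)
  for (sizes in list(c(3, 4), c(5, 5), c(7, 6), c(7, 7))) {
    x <- rnorm(sizes[1])
    y <- rnorm(sizes[2], mean = 0.8)
    ours <- mann_whitney_u(x, y, mode = "exact")
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("U statistics obey the rank-sum identities", {
  set.seed(17)
  for (i in 1:20) {
    n1 <- sample(2:12, 1)
    n2 <- sample(2:12, 1)
    x <- sample(1:8, n1, replace = TRUE) # ties on purpose
    y <- sample(1:8, n2, replace = TRUE)
    m <- mann_whitney_u(x, y, mode = "normal")
    r <- rank(c(x, y))
    u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    expect_equal(min(u1, n1 * n2 - u1), m$U) # U1 + U2 = n1 n2
    expect_lte(m$U, n1 * n2 / 2)
    expect_gt(m$p, 0)
    expect_lte(m$p, 1)
  }
  ident <- mann_whitney_u(rep(2, 5), rep(2, 7))
  expect_equal(ident$U, 5 * 7 / 2)
  expect_equal(ident$p, 1)
})

test_that("the normal approximation converges to the exact tail", {
  set.seed(402)
  for (i in 1:5) {
    x <- rnorm(20)
    y <- rnorm(22, mean = runif(1, 0, 1))
    approx_p <- mann_whitney_u(x, y, mode = "normal")$p
    exact_p <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value
    expect_lt(abs(approx_p - exact_p), 0.01)
  }
  expect_error(mann_whitney_u(c(1, 1, 2), c(2, 3), mode = "exact"), "untied")
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("percent occurrence rounds half away from zero", {
  expect_equal(percent_occurrence(17, 31), 55L)
  expect_equal(percent_occurrence(26, 31), 84L)
  expect_equal(percent_occurrence(0, 31), 0L)
  expect_equal(percent_occurrence(1, 200), 1L) # 0.5 rounds up
  expect_equal(percent_occurrence(c(9, 15), 31), c(29L, 48L))
  expect_error(percent_occurrence(5, 0), "> 0")
  expect_error(percent_occurrence(5, 4), "k <= n")
})

test_that("tidy and glance methods return one-row tibbles", {
  ft <- fisher_exact_two_sided(c(9, 22, 5, 23))
  expect_s3_class(tidy(ft), "tbl_df")
  expect_equal(nrow(tidy(ft)), 1)
  mw <- mann_whitney_u(1:5, 3:9)
  expect_named(glance(mw), c("statistic", "p.value", "n1", "n2", "method"))
})
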