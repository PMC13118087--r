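test_that("contingency tables tally the four joint cells", {
  m <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
  rownames(m) <- paste0("d", 1:4)
  tab <- build_contingency(m, "a", "b")
  expect_equal(c(tab$n11, tab$n10, tab$n01, tab$n00), c(1, 1, 1, 1))
  expect_equal(tab$n, 4)
  expect_error(build_contingency(m, "a", "a"), "self-pair")
  expect_error(build_contingency(m, "a", "zz"), "zz")
})

test_that("contingency cells match a brute-force tally and partition rows", {
  withr::with_seed(8, {
    for (i in 1:20) {
      m <- random_annotation(20, c("x", "y"), p = runif(1, 0.1, 0.9))
      tab <- build_contingency(m, "x", "y")
      brute <- c(sum(m[, "x"] == 1 & m[, "y"] == 1),
                 sum(m[, "x"] == 1 & m[, "y"] == 0),
                 sum(m[, "x"] == 0 & m[, "y"] == 1),
                 sum(m[, "x"] == 0 & m[, "y"] == 0))
      expect_equal(c(tab$n11, tab$n10, tab$n01, tab$n00), brute)
      expect_equal(tab$n, nrow(m))
    }
  })
})

test_that("phi matches hand values and the Pearson-correlation definition", {
  expect_equal(phi_coefficient(contingency_table(5, 0, 0, 5)), 1)
  expect_equal(phi_coefficient(contingency_table(0, 5, 5, 0)), -1)
  tab <- contingency_table(10, 20, 30, 40)
  expect_equal(phi_coefficient(tab), -200 / sqrt(30 * 70 * 40 * 60))
  expect_equal(phi_coefficient(tab), -0.0890871, tolerance = 1e-6)
  # independence-proportional table
  expect_equal(phi_coefficient(contingency_table(6, 4, 12, 8)), 0)
  # degenerate margin
  deg <- phi_coefficient(contingency_table(0, 0, 3, 7))
  expect_true(is.na(deg))
  expect_match(attr(deg, "degenerate_reason"), "margin")
})

test_that("phi equals cor() on the expanded binary vectors to 1e-12", {
  withr::with_seed(14, {
    for (i in 1:200) {
      tab <- random_table(150)
      x <- rep(c(1, 1, 0, 0), c(tab$n11, tab$n10, tab$n01, tab$n00))
      y <- rep(c(1, 0, 1, 0), c(tab$n11, tab$n10, tab$n01, tab$n00))
      expect_equal(phi_coefficient(tab), cor(x, y), tolerance = 1e-12)
    }
  })
})

test_that("the chi-squared statistic obeys the N-phi-squared identity", {
  tab <- contingency_table(10, 20, 30, 40)
  res <- chi_squared_test(tab)
  expect_equal(res$statistic, 100 * phi_coefficient(tab)^2)
  expect_equal(res$statistic, 0.7936508, tolerance = 1e-7)
  # agreement with the stock Pearson test, no continuity correction
  ref <- chisq.test(matrix(c(10, 30, 20, 40), 2), correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  # transpose invariance and the zero case
  tt <- contingency_table(10, 30, 20, 40)
  expect_equal(chi_squared_test(tt)$statistic, res$statistic)
  indep <- chi_squared_test(contingency_table(6, 4, 12, 8))
  expect_equal(indep$statistic, 0)
  expect_equal(indep$p_value, 1)
})

test_that("test selection switches at the five-document cell rule", {
  expect_equal(select_test(contingency_table(5, 5, 5, 5)), "chi_squared")
  expect_equal(select_test(contingency_table(4, 100, 100, 100)),
               "fisher_exact")
  expect_equal(select_test(contingency_table(0, 0, 3, 7)), "degenerate")
  # threshold is configurable
  expect_equal(select_test(contingency_table(4, 5, 5, 5), min_cell = 4L),
               "chi_squared")
  for (cells in asplit(expand.grid(a = 4:6, b = 4:6, c = 4:6, d = 4:6), 1L)) {
    tab <- contingency_table(cells[[1]], cells[[2]], cells[[3]], cells[[4]])
    expect_equal(select_test(tab),
                 if (min(unlist(cells)) >= 5L) "chi_squared"
                 else "fisher_exact")
  }
})

test_that("Fisher matches hand enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_test(contingency_table(3, 0, 0, 3))$p_value,
               0.1)
  expect_equal(fisher_exact_test(contingency_table(2, 3, 4, 6))$p_value, 1)
  expect_true(fisher_exact_test(contingency_table(0, 0, 3, 7))$degenerate)
  withr::with_seed(23, {
    for (i in 1:100) {
      tab <- random_table(40)
      mine <- fisher_exact_test(tab)$p_value
      ref <- stats::fisher.test(matrix(c(tab$n11, tab$n01, tab$n10,
                                         tab$n00), 2))$p.value
      expect_equal(mine, ref, tolerance = 1e-10)
      expect_equal(mine, oracle_fisher(tab$n11, tab$n10, tab$n01, tab$n00),
                   tolerance = 1e-12)
    }
  })
})

test_that("Fisher and chi-squared p-values converge as cells grow", {
  # the two-sided exact p is discrete, so pointwise agreement is loose at
  # moderate cell counts; assert convergence across size bands instead
  mean_gap <- function(lo, hi, reps = 60L) {
    mean(vapply(seq_len(reps), function(i) {
      cells <- sample(lo:hi, 4, replace = TRUE)
      tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
      abs(fisher_exact_test(tab)$p_value - chi_squared_test(tab)$p_value)
    }, numeric(1L)))
  }
  withr::with_seed(29, {
    small <- mean_gap(20, 80)
    mid <- mean_gap(100, 300)
    large <- mean_gap(500, 1200)
  })
  expect_gt(small, mid)
  expect_gt(mid, large)
  expect_lt(large, 0.01)
})

test_that("Holm adjustment reproduces hand step-down values", {
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(0.03, 0.031)), c(0.06, 0.06))
  expect_equal(holm_adjust(c(0.04, 0.01)), c(0.04, 0.02))  # order preserved
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_equal(holm_adjust(c(0.02, NA, 0.5)), c(0.04, NA, 0.5))
})

test_that("Holm is bounded by raw and Bonferroni values and is stable", {
  withr::with_seed(37, {
    for (i in 1:25) {
      p <- runif(sample(2:40, 1L))
      q <- holm_adjust(p)
      expect_equal(q, p.adjust(p, method = "holm"))
      expect_true(all(q >= p))
      expect_true(all(q <= pmin(1, length(p) * p)))
      perm <- sample(length(p))
      expect_equal(holm_adjust(p[perm]), q[perm])
    }
  })
})

test_that("the network agrees pairwise with the scalar route", {
  withr::with_seed(41, {
    m <- random_annotation(60, c("osteoporosis", "gait", "fall", "young"),
                           p = 0.4)
  })
  net <- association_network(m)
  for (r in seq_len(nrow(net$results))) {
    row <- net$results[r, ]
    tab <- build_contingency(m, row$keyword_i, row$keyword_j)
    expect_equal(c(row$n11, row$n10, row$n01, row$n00),
                 c(tab$n11, tab$n10, tab$n01, tab$n00))
    expect_equal(row$phi, as.numeric(phi_coefficient(tab)))
    expect_equal(row$test_used, select_test(tab))
    p_ref <- switch(row$test_used,
                    chi_squared = chi_squared_test(tab)$p_value,
                    fisher_exact = fisher_exact_test(tab)$p_value,
                    NA_real_)
    expect_equal(row$p_raw, p_ref)
  }
  expect_equal(net$results$q, holm_adjust(net$results$p_raw))
})

test_that("network matrices are symmetric, grouped, and masked", {
  withr::with_seed(43, {
    base <- rbinom(400, 1, 0.5)
    m <- cbind(osteoporosis = base, fragility = base,       # identical pair
               stroke = rbinom(400, 1, 0.3),
               sport = rep(c(1, 0), 200))
    rownames(m) <- sprintf("d%03d", 1:400)
  })
  net <- association_network(m)
  expect_true(isSymmetric(net$phi))
  expect_true(isSymmetric(net$q))
  # columns reordered into concept-group panel order
  expect_equal(net$keywords, c("fragility", "osteoporosis", "sport",
                               "stroke"))
  pair <- net$results[net$results$keyword_i %in% c("osteoporosis", "fragility") &
                        net$results$keyword_j %in% c("osteoporosis", "fragility"), ]
  expect_equal(pair$phi, 1)
  expect_true(pair$significant)
  expect_true(all(net$results$q >= net$results$p_raw, na.rm = TRUE))
  mp <- masked_phi(net)
  expect_equal(mp["osteoporosis", "fragility"], 1)
  expect_true(all(is.na(mp[!net$mask])))
})

test_that("degenerate keywords are recorded and kept out of the family", {
  m <- cbind(osteoporosis = rbinom(50, 1, 0.5),
             gait = rbinom(50, 1, 0.5),
             fall = rep(0, 50))
  rownames(m) <- sprintf("d%02d", 1:50)
  net <- association_network(m)
  deg <- net$results[net$results$keyword_i == "fall" |
                       net$results$keyword_j == "fall", ]
  expect_true(all(deg$test_used == "degenerate"))
  expect_true(all(is.na(deg$p_raw)))
  expect_false(any(deg$significant))
  tested <- net$results$p_raw[net$results$test_used != "degenerate"]
  expect_equal(net$results$q[net$results$test_used != "degenerate"],
               holm_adjust(tested))
})

test_that("alternative corrections are available and ordered as expected", {
  withr::with_seed(47, {
    m <- random_annotation(300, c("osteoporosis", "gait", "fall",
                                  "sarcopenia", "frail"), p = 0.3)
  })
  holm <- association_network(m, correction = "holm")
  bh <- association_network(m, correction = "bh")
  bonf <- association_network(m, correction = "bonferroni")
  expect_true(all(bh$results$q <= holm$results$q + 1e-12))
  expect_true(all(holm$results$q <= bonf$results$q + 1e-12))
  expect_equal(bonf$results$q,
               pmin(1, nrow(bonf$results) * bonf$results$p_raw))
})
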