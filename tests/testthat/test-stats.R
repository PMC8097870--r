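# brute-force one-way ANOVA from the sum-of-squares definitions
oracle_anova <- function(data) {
  groups <- split(data$value, data$group)
  grand <- mean(data$value)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                           numeric(1)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_b <- length(groups) - 1
  df_w <- nrow(data) - length(groups)
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(f = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

test_that("ANOVA matches the sums-of-squares oracle and handles degeneracy", {
  set.seed(11)
  for (i in 1:20) {
    data <- data.frame(
      group = rep(c("a", "b", "c"), times = c(4, 6, 5)),
      value = rnorm(15, mean = rep(c(0, 0.5, 1), times = c(4, 6, 5))))
    res <- one_way_anova(data)
    ref <- oracle_anova(data)
    expect_equal(res$statistic, ref$f, tolerance = 1e-10)
    expect_equal(res$p.value, ref$p, tolerance = 1e-10)
  }

  # all groups are the same constant: no variance anywhere, F defined as 0
  flat <- data.frame(group = rep(c("a", "b"), each = 3), value = 5)
  res <- one_way_anova(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)

  expect_error(one_way_anova(data.frame(group = "a", value = 1:4)), "groups")
  expect_error(one_way_anova(data.frame(group = c("a", "a", "b"),
                                        value = c(1, 2, 3))), ">= 2")
})

test_that("two-group Tukey HSD equals the pooled-variance t-test", {
  set.seed(5)
  for (i in 1:10) {
    data <- data.frame(group = rep(c("a", "b"), times = c(5, 7)),
                       value = rnorm(12, rep(c(0, 0.8), times = c(5, 7))))
    tk <- tukey_hsd(data)
    tt <- stats::t.test(value ~ group, data = data, var.equal = TRUE)
    expect_equal(tk$adj.p.value, tt$p.value, tolerance = 1e-8)
  }
})

test_that("identical groups give adjusted p near 1 for every pair", {
  data <- data.frame(group = rep(c("a", "b", "c"), each = 4),
                     value = rep(c(2, 3, 4, 5), times = 3))
  tk <- tukey_hsd(data)
  expect_equal(nrow(tk), 3L)
  expect_true(all(tk$adj.p.value > 0.999))
  expect_equal(tk$mean_diff, rep(0, 3))
})

test_that("Tukey adjustment is conservative relative to the pooled t p-value", {
  set.seed(23)
  for (i in 1:15) {
    k <- sample(3:5, 1)
    n <- sample(3:6, 1)
    data <- data.frame(group = rep(letters[1:k], each = n),
                       value = rnorm(k * n))
    tk <- tukey_hsd(data)
    fit <- aov(value ~ group, data = data)
    mse <- summary(fit)[[1]][["Mean Sq"]][2]
    df_w <- summary(fit)[[1]][["Df"]][2]
    for (j in seq_len(nrow(tk))) {
      g1 <- data$value[data$group == tk$group1[j]]
      g2 <- data$value[data$group == tk$group2[j]]
      tstat <- abs(mean(g1) - mean(g2)) /
        sqrt(mse * (1 / length(g1) + 1 / length(g2)))
      p_unadj <- 2 * stats::pt(tstat, df_w, lower.tail = FALSE)
      expect_gte(tk$adj.p.value[j] + 1e-12, p_unadj)
    }
  }
})

test_that("ANOVA p agrees with the exact permutation distribution at tiny n", {
  set.seed(31)
  value <- c(rnorm(4, 0), rnorm(4, 1.0), rnorm(4, 0.5))
  group <- rep(c("a", "b", "c"), each = 4)
  obs <- one_way_anova(data.frame(group = group, value = value))

  # enumerate all 12! / (4! 4! 4!) = 34,650 assignments of values to groups
  f_of <- function(assign_a, assign_b) {
    idx <- seq_along(value)
    a <- value[assign_a]
    b <- value[assign_b]
    c_ <- value[setdiff(idx, c(assign_a, assign_b))]
    grand <- mean(value)
    ssb <- 4 * ((mean(a) - grand)^2 + (mean(b) - grand)^2 + (mean(c_) - grand)^2)
    ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2) + sum((c_ - mean(c_))^2)
    (ssb / 2) / (ssw / 9)
  }
  combs_a <- utils::combn(12, 4)
  count_ge <- 0L
  total <- 0L
  for (ia in seq_len(ncol(combs_a))) {
    rest <- setdiff(1:12, combs_a[, ia])
    combs_b <- utils::combn(rest, 4)
    for (ib in seq_len(ncol(combs_b))) {
      total <- total + 1L
      if (f_of(combs_a[, ia], combs_b[, ib]) >= obs$statistic - 1e-12) {
        count_ge <- count_ge + 1L
      }
    }
  }
  p_perm <- count_ge / total
  expect_equal(total, 34650L)
  expect_lt(abs(obs$p.value - p_perm), 0.02)
})

test_that("significance stars follow the figure-caption thresholds", {
  expect_equal(significance_stars(c(0.2, 0.049, 0.003, 5e-4, 5e-5)),
               c("ns", "*", "**", "***", "****"))
  # boundary values fall to the weaker category
  expect_equal(significance_stars(c(0.05, 0.01, 0.001, 1e-4)),
               c("ns", "*", "**", "***"))
})

test_that("group comparison bundles ANOVA, Tukey table and report files", {
  set.seed(2)
  data <- data.frame(group = rep(c("FaDu", "Kyse30", "HFF"), each = 5),
                     value = rnorm(15, rep(c(0.25, 0.45, 0.08), each = 5),
                                   sd = 0.04))
  cmp <- compare_groups(data)
  expect_s3_class(glance(cmp), "tbl_df")
  expect_equal(nrow(tidy(cmp)), 3L)
  expect_lt(glance(cmp)$p.value, 0.05)

  csv <- withr::local_tempfile(fileext = ".csv")
  txt <- withr::local_tempfile(fileext = ".txt")
  write_comparison(cmp, csv, txt)
  df <- utils::read.csv(csv)
  expect_named(df, c("group1", "group2", "mean_diff", "adj_p", "stars"))
  expect_match(readLines(txt)[1], "One-way ANOVA")
  p <- autoplot(cmp)
  expect_s3_class(p, "ggplot")
})
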