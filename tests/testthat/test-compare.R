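make_cov_cohort <- function(cov) {
  traces <- lapply(cov$participant_id, function(i) make_trace(i))
  cohort_dataset(traces, cov)
}

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(21)
  cov <- data.frame(participant_id = sprintf("p%02d", 1:40),
                    y = c(rnorm(20, 0), rnorm(20, 1)),
                    stringsAsFactors = FALSE)
  cohort <- make_cov_cohort(cov)
  labels <- stats::setNames(rep(1:2, each = 20), cov$participant_id)
  res <- compare_groups(cohort, labels, comparison_spec("y", "continuous"),
                        t_variant = "pooled")
  tt <- t.test(cov$y[1:20], cov$y[21:40], var.equal = TRUE)
  expect_equal(res[[1]]$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res[[1]]$p, tt$p.value, tolerance = 1e-9)
})

test_that("identical categorical distributions give chi-square 0 and p 1", {
  cov <- data.frame(participant_id = sprintf("p%02d", 1:60),
                    grp_var = rep(rep(c("a", "b", "c"), each = 10), 2),
                    stringsAsFactors = FALSE)
  cohort <- make_cov_cohort(cov)
  labels <- stats::setNames(rep(1:2, each = 30), cov$participant_id)
  res <- compare_groups(cohort, labels, comparison_spec("grp_var", "categorical"))
  expect_equal(res[[1]]$statistic, 0, tolerance = 1e-12)
  expect_equal(res[[1]]$p, 1, tolerance = 1e-12)
  expect_equal(nrow(res[[1]]$pairwise), 0L)
})

test_that("chi-square statistic is invariant under level permutation", {
  set.seed(22)
  cov <- data.frame(participant_id = sprintf("p%03d", 1:120),
                    v = sample(c("x", "y", "z"), 120, replace = TRUE,
                               prob = c(.5, .3, .2)),
                    stringsAsFactors = FALSE)
  labels <- stats::setNames(sample(1:3, 120, replace = TRUE), cov$participant_id)
  cohort <- make_cov_cohort(cov)
  s1 <- compare_groups(cohort, labels, comparison_spec("v", "categorical"))[[1]]
  cov2 <- cov
  cov2$v <- c(x = "z", y = "x", z = "y")[cov$v]
  s2 <- compare_groups(make_cov_cohort(cov2), labels,
                       comparison_spec("v", "categorical"))[[1]]
  expect_equal(s1$statistic, s2$statistic, tolerance = 1e-9)
})

test_that("strong separation triggers pairwise follow-ups; null does not", {
  set.seed(23)
  cov <- data.frame(participant_id = sprintf("p%03d", 1:100),
                    strong = c(rnorm(50, 0), rnorm(50, 5)),
                    flat = rnorm(100),
                    stringsAsFactors = FALSE)
  cohort <- make_cov_cohort(cov)
  labels <- stats::setNames(rep(1:2, each = 50), cov$participant_id)
  specs <- rbind(comparison_spec("strong", "continuous"),
                 comparison_spec("flat", "continuous"))
  res <- compare_groups(cohort, labels, specs)
  expect_lt(res[[1]]$p, 0.001)
  expect_gt(nrow(res[[1]]$pairwise), 0L)
  # pairwise gated on the overall test
  expect_true(res[[2]]$p >= 0.05 || nrow(res[[2]]$pairwise) > 0L)
  if (res[[2]]$p >= 0.05) expect_equal(nrow(res[[2]]$pairwise), 0L)
})

test_that("zero within-group variance is flagged with NA p-value", {
  cov <- data.frame(participant_id = sprintf("p%02d", 1:30),
                    constant = rep(c(1, 2, 3), each = 10),
                    stringsAsFactors = FALSE)
  cohort <- make_cov_cohort(cov)
  labels <- stats::setNames(rep(1:3, each = 10), cov$participant_id)
  res <- compare_groups(cohort, labels, comparison_spec("constant", "continuous"))
  expect_true(is.na(res[[1]]$p))
  expect_equal(res[[1]]$note, "zero within-group variance")
})

test_that("summary table renders the baseline-table shape", {
  set.seed(24)
  cov <- data.frame(participant_id = sprintf("p%03d", 1:215),
                    age = rnorm(215, 52.4, 11.2),
                    edu = sample(c("hs", "college"), 215, replace = TRUE),
                    stringsAsFactors = FALSE)
  cohort <- make_cov_cohort(cov)
  labels <- stats::setNames(rep(1:3, times = c(65, 48, 102)), cov$participant_id)
  specs <- rbind(comparison_spec("age", "continuous"),
                 comparison_spec("edu", "categorical"))
  res <- compare_groups(cohort, labels, specs)
  tab <- cluster_summary_table(res, labels)
  expect_true(any(grepl("n=65", names(tab))))
  expect_true(any(grepl("n=48", names(tab))))
  expect_true(any(grepl("n=102", names(tab))))
  age_cell <- tab[tab$variable == "age", 2]
  expect_match(age_cell, "^-?[0-9.]+ \\([0-9.]+\\)$")   # mean (SD)
  expect_true(any(grepl("%", unlist(tab[grepl("edu", tab$variable), 2:4]))))
})

test_that("overall null rejection rate is calibrated near alpha", {
  set.seed(25)
  rejections <- 0
  n_sim <- 400
  for (i in seq_len(n_sim)) {
    v <- rnorm(90)
    g <- rep(1:3, each = 30)
    p <- anova(lm(v ~ factor(g)))[["Pr(>F)"]][1]
    ours <- actipatterns:::overall_test(v, g, "continuous")
    expect_equal(ours$p, p, tolerance = 1e-12)
    if (ours$p < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / n_sim, 0.02)
  expect_lt(rejections / n_sim, 0.09)
})
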