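test_that("percent delivering reproduces the fixture group outcomes", {
  br <- make_breeding_fixture()
  expect_equal(percent_delivering(br, "control"), 100)
  expect_equal(percent_delivering(br, "adenomyosis"), 33.33)
  none <- data.frame(dam_id = sprintf("d%d", 1:5), group = "g",
                     month = NA_integer_, pups_born = 0, pups_weaned = 0)
  expect_equal(percent_delivering(none, "g"), 0)
  expect_error(percent_delivering(br, "nonexistent"), "empty group")
})

test_that("mean litter size pools pups over litters", {
  rec <- data.frame(dam_id = c("d1", "d1"), group = "g", month = c(1, 2),
                    pups_born = c(10, 14), pups_weaned = c(8, 12))
  expect_equal(mean_litter_size(rec, "g", at_weaning = FALSE)$pooled, 12)
  expect_equal(mean_litter_size(rec, "g", at_weaning = TRUE)$pooled, 10)
  empty <- data.frame(dam_id = "d1", group = "g", month = NA_integer_,
                      pups_born = 0, pups_weaned = 0)
  ls <- mean_litter_size(empty, "g")
  expect_true(is.na(ls$pooled))
  expect_equal(ls$flag, "no litters")
})

test_that("litter sizes match a naive loop oracle on random records", {
  withr::with_seed(44, {
    for (rep in 1:10) {
      nd <- sample(3:8, 1)
      rows <- lapply(seq_len(nd), function(i) {
        nl <- sample(0:3, 1)
        if (nl == 0)
          return(data.frame(dam_id = sprintf("d%d", i), group = "g",
                            month = NA_integer_, pups_born = 0, pups_weaned = 0))
        born <- sample(5:15, nl, replace = TRUE)
        data.frame(dam_id = sprintf("d%d", i), group = "g",
                   month = sample(1:3, nl), pups_born = born,
                   pups_weaned = pmax(0, born - sample(0:3, nl, replace = TRUE)))
      })
      rec <- do.call(rbind, rows)
      if (all(is.na(rec$month))) next
      expect_equal(mean_litter_size(rec, "g")$pooled,
                   oracle_mean_litter_size(rec, "g", TRUE))
      expect_equal(mean_litter_size(rec, "g", at_weaning = FALSE)$pooled,
                   oracle_mean_litter_size(rec, "g", FALSE))
    }
  })
})

test_that("the fixture's pooled litter sizes match the printed group means", {
  br <- make_breeding_fixture()
  expect_equal(round_half_up(mean_litter_size(br, "control")$pooled, 2), 12.94)
  expect_equal(round_half_up(mean_litter_size(br, "adenomyosis")$pooled, 2), 6.33)
})

test_that("cumulative pup series are per-dam and non-decreasing", {
  rec <- data.frame(dam_id = "d1", group = "g", month = c(1, 3),
                    pups_born = c(10, 8), pups_weaned = c(10, 8))
  cp <- cumulative_pups(rec)
  expect_equal(unlist(cp[1, c("month1", "month2", "month3")], use.names = FALSE),
               c(10, 10, 18))
  none <- data.frame(dam_id = "d2", group = "g", month = NA_integer_,
                     pups_born = 0, pups_weaned = 0)
  expect_equal(unlist(cumulative_pups(none)[1, 3:5], use.names = FALSE), c(0, 0, 0))
  br <- make_breeding_fixture()
  cb <- cumulative_pups(br)
  mono <- apply(cb[, c("month1", "month2", "month3")], 1,
                function(v) all(diff(v) >= 0))
  expect_true(all(mono))
  gm <- aggregate(cb[, 3:5], list(group = cb$group), mean)
  expect_true(all(gm[gm$group == "control", -1] >= gm[gm$group == "adenomyosis", -1]))
})

test_that("violating pup accounting errors", {
  bad <- data.frame(dam_id = "d1", group = "g", month = 1,
                    pups_born = 5, pups_weaned = 7)
  expect_error(percent_delivering(bad, "g"), "pups_weaned")
})

test_that("exact Mann-Whitney matches the enumeration example and symmetry", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 0.1)                       # 2/20 assignments as extreme
  expect_equal(r$method, "exact")
  expect_equal(mann_whitney(c(4, 5, 6), c(1, 2, 3))$p, r$p)
  ident <- mann_whitney(c(2, 4, 9, 11), c(2, 4, 9, 11))
  expect_gte(ident$p, 0.99)
  expect_equal(ident$method, "tie-corrected normal")
})

test_that("exact path agrees with wilcox.test on random tie-free samples", {
  withr::with_seed(71, {
    for (rep in 1:60) {
      n <- sample(2:7, 1); m <- sample(2:7, 1)
      v <- sample(1:60, n + m)                 # distinct -> tie-free
      x <- v[1:n]; y <- v[-(1:n)]
      ours <- mann_whitney(x, y)
      ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
      expect_equal(ours$method, "exact")
      expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("the exact test is conservative under the null", {
  withr::with_seed(29, {
    reps <- 2000
    rej <- 0
    for (i in seq_len(reps)) {
      x <- rnorm(5); y <- rnorm(5)
      if (mann_whitney(x, y)$p <= 0.05) rej <- rej + 1
    }
    expect_lte(rej / reps, 0.05)
  })
})

test_that("two-way ANOVA recovers a hand-computed balanced decomposition", {
  # 2x2 balanced, 2 reps/cell: values chosen for an easy hand calculation
  d <- data.frame(g = rep(c("a", "b"), each = 4),
                  t = rep(rep(c("t1", "t2"), each = 2), 2),
                  y = c(1, 3, 5, 7, 2, 4, 10, 12))
  # grand mean 5.5; group means 4 / 7; time means 2.5 / 8.5;
  # cell means 2, 6, 3, 11 -> SS: group 18, time 72, interaction 8, resid 8
  res <- two_way_anova(d$y, d$g, d$t)
  expect_equal(res$sum_sq[res$term == "group"], 18)
  expect_equal(res$sum_sq[res$term == "time"], 72)
  expect_equal(res$sum_sq[res$term == "group:time"], 8)
  expect_equal(res$sum_sq[res$term == "Residuals"], 8)
  expect_equal(sum(res$sum_sq), sum((d$y - mean(d$y))^2))
})

test_that("zero effect with zero noise reports F = 0, and single-level factors error", {
  d <- data.frame(g = rep(c("a", "b"), each = 4),
                  t = rep(rep(c("t1", "t2"), each = 2), 2))
  y <- ifelse(d$t == "t1", 1, 5)               # pure time effect
  res <- two_way_anova(y, d$g, d$t)
  expect_equal(res$F[res$term == "group"], 0)
  expect_error(two_way_anova(y, rep("a", 8), d$t), "two levels")
})

test_that("group-term p is approximately uniform under label permutation", {
  withr::with_seed(63, {
    y <- rnorm(24)
    tt <- rep(1:3, 8)
    ps <- vapply(1:500, function(i)
      two_way_anova(y, sample(rep(c("a", "b"), 12)), tt)$p[1], numeric(1))
    expect_gt(mean(ps), 0.42)
    expect_lt(mean(ps), 0.58)
    expect_lt(mean(ps <= 0.05), 0.10)
  })
})

test_that("the enrolment ledger sums euthanasia groups per arm", {
  led <- cohort_ledger_check(list(control = c(12, 66), adenomyosis = c(14, 55)),
                             declared = c(control = 78, adenomyosis = 69))
  expect_equal(led$total, c(78L, 69L))
  expect_true(all(led$consistent))
  expect_equal(cohort_ledger_check(list(a = integer(0)))$total, 0L)
})
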