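test_that("Dice similarity satisfies its axioms and closed forms", {
  set.seed(71)
  a <- mk_mask(array(runif(8^3) < 0.3, dim = c(8, 8, 8)))
  b <- mk_mask(array(runif(8^3) < 0.3, dim = c(8, 8, 8)))
  none <- mk_mask(array(FALSE, dim = c(8, 8, 8)))

  expect_equal(as.numeric(dsc(a, a)), 1.0)
  expect_equal(dsc(a, b), dsc(b, a))
  expect_gte(dsc(a, b), 0); expect_lte(dsc(a, b), 1)
  # a missed lesion scores 0
  expect_equal(as.numeric(dsc(none, a)), 0)
  # both empty: 1 by convention, flagged as trivial
  both <- dsc(none, none)
  expect_equal(as.numeric(both), 1)
  expect_true(attr(both, "trivial"))

  # |A| = 4, |B| = 6, |A n B| = 3 -> 2*3/10 = 0.6
  x <- array(FALSE, dim = c(8, 8, 8)); x[1:4] <- TRUE
  y <- array(FALSE, dim = c(8, 8, 8)); y[2:7] <- TRUE
  expect_equal(as.numeric(dsc(mk_mask(x), mk_mask(y))), 0.6)
})

test_that("voxel confusion counts respect the evaluation domain", {
  set.seed(72)
  dmn <- mk_mask(array(runif(8^3) < 0.7, dim = c(8, 8, 8)))
  p <- mk_mask(array(runif(8^3) < 0.3, dim = c(8, 8, 8)))
  r <- mk_mask(array(runif(8^3) < 0.2, dim = c(8, 8, 8)))

  same <- voxel_confusion(p, p, dmn)
  expect_equal(same$fp + same$fn, 0)

  none <- mk_mask(array(FALSE, dim = c(8, 8, 8)))
  e <- voxel_confusion(none, r, dmn)
  expect_equal(e$tp + e$fp, 0)
  expect_equal(e$fn, sum(r$data & dmn$data))

  cf <- voxel_confusion(p, r, dmn)
  expect_equal(cf$tp + cf$fp + cf$fn + cf$tn, sum(dmn$data))
  oracle <- naive_confusion(p$data, r$data, dmn$data)
  expect_equal(unclass(cf)[c("tp", "fp", "fn", "tn")], oracle)
})

test_that("pooled confusion counts are additive across scans", {
  set.seed(73)
  dmn <- mk_mask(array(TRUE, dim = c(6, 6, 6)))
  total <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  pl <- array(FALSE, dim = c(6, 6, 18)); rl <- pl; dl <- pl
  for (s in 1:3) {
    p <- array(runif(6^3) < 0.3, dim = c(6, 6, 6))
    r <- array(runif(6^3) < 0.3, dim = c(6, 6, 6))
    cf <- voxel_confusion(mk_mask(p), mk_mask(r), dmn)
    total <- total + unlist(cf)
    pl[, , (s - 1) * 6 + 1:6] <- p
    rl[, , (s - 1) * 6 + 1:6] <- r
    dl[, , (s - 1) * 6 + 1:6] <- TRUE
  }
  concat <- voxel_confusion(mk_mask(pl), mk_mask(rl), mk_mask(dl))
  expect_equal(unlist(concat), total)
})

test_that("confusion metrics follow their defining ratios", {
  perfect <- confusion_counts(10, 0, 0, 90)
  expect_equal(unlist(confusion_metrics(perfect)), c(sensitivity = 1,
               specificity = 1, ppv = 1, npv = 1))

  set.seed(74)
  for (i in 1:5) {
    k <- as.list(sample(1:500, 4))
    m <- confusion_metrics(confusion_counts(k[[1]], k[[2]], k[[3]], k[[4]]))
    expect_equal(m$sensitivity, k[[1]] / (k[[1]] + k[[3]]))
    expect_equal(m$specificity, k[[4]] / (k[[4]] + k[[2]]))
    expect_equal(m$ppv, k[[1]] / (k[[1]] + k[[2]]))
    expect_equal(m$npv, k[[4]] / (k[[4]] + k[[3]]))
  }

  # all-negative prediction on a domain with positives
  allneg <- confusion_metrics(confusion_counts(0, 0, 5, 95))
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 1)
  expect_true(is.na(allneg$ppv))
  expect_equal(allneg$npv, 0.95)
})

test_that("cohort summaries aggregate scores both pooled and per scan", {
  scores <- data.frame(scan_id = 1:3, dsc = c(0.9, 0.7, 0.95),
                       tp = c(50, 20, 80), fp = c(5, 10, 2),
                       fn = c(5, 15, 3), tn = c(940, 955, 915))
  cs <- cohort_summary(scores, detection_threshold = 0.8, n_boot = 200,
                       seed = 7)
  expect_equal(cs$detection_rate, 2 / 3)
  expect_equal(cs$median_dsc, 0.9)
  expect_equal(cs$pooled$sensitivity, 150 / (150 + 23))
  per <- mean(c(50 / 55, 20 / 35, 80 / 83))
  expect_equal(cs$per_scan$sensitivity$mean, per)
  expect_true(cs$median_dsc_ci[1] <= cs$median_dsc &&
                cs$median_dsc <= cs$median_dsc_ci[2])

  # identical scores collapse the CI onto the point value
  same <- data.frame(scan_id = 1:4, dsc = rep(0.88, 4))
  cs2 <- cohort_summary(same, n_boot = 100, seed = 1)
  expect_equal(cs2$median_dsc_ci, c(0.88, 0.88))

  # fixed seed reproduces the bootstrap CIs exactly
  csa <- cohort_summary(scores, n_boot = 300, seed = 42)
  csb <- cohort_summary(scores, n_boot = 300, seed = 42)
  expect_identical(csa$median_dsc_ci, csb$median_dsc_ci)
  expect_identical(csa$per_scan, csb$per_scan)
  expect_error(cohort_summary(scores[0, ]), "at least one")
})

test_that("bootstrap median CIs bracket the truth at near-nominal rate", {
  set.seed(75)
  true_median <- qbeta(0.5, 8, 2)
  hits <- 0L
  for (rep in 1:100) {
    x <- rbeta(30, 8, 2)
    ci <- cohort_summary(data.frame(scan_id = 1:30, dsc = x),
                         n_boot = 400)$median_dsc_ci
    if (ci[1] <= true_median && true_median <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 93)
})

test_that("percentile case selection matches a sort-based oracle", {
  one <- data.frame(scan_id = "a", dsc = 0.5)
  sel1 <- select_percentile_cases(one, c(2, 50, 98))
  expect_equal(sel1$scan_id, rep("a", 3))

  five <- data.frame(scan_id = 1:5, dsc = c(0.3, 0.9, 0.5, 0.7, 0.1))
  expect_equal(select_percentile_cases(five, 50)$dsc, 0.5)

  set.seed(76)
  scores <- data.frame(scan_id = seq_len(109), dsc = runif(109))
  sel <- select_percentile_cases(scores, c(2, 50, 98))
  srt <- sort(scores$dsc)
  for (i in seq_len(3)) {
    p <- c(2, 50, 98)[i]
    target <- srt[max(1L, ceiling(p / 100 * 109))]   # nearest rank
    expect_equal(sel$dsc[i], target)
  }
})

test_that("metric concordance recovers exact linear relations", {
  x <- c(1, 2, 3, 4, 5)
  same <- metric_concordance(x, x)
  expect_equal(same$r, 1)
  expect_equal(same$slope, 1)
  expect_equal(same$intercept, 0)

  doubled <- metric_concordance(x, 2 * x)
  expect_equal(doubled$r, 1)
  expect_equal(doubled$slope, 2)

  # textbook formula oracle on noisy data
  set.seed(77)
  a <- runif(40); b <- 0.8 * a + rnorm(40, 0, 0.1)
  got <- metric_concordance(a, b)
  r_ref <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, r_ref, tolerance = 1e-12)

  # pairwise missing handling and the 3-pair floor
  withna <- metric_concordance(c(x, NA), c(2 * x, 1))
  expect_equal(withna$n_used, 5)
  expect_equal(withna$n_dropped, 1)
  expect_error(metric_concordance(c(1, 2, NA), c(1, 2, 3)), "3 complete")
})

test_that("longitudinal congruence flags direction agreement with a dead zone", {
  a <- data.frame(tbr_mean = c(2, 2.5, 3), tbr_max = c(3, 3.6, 4.2),
                  btv_ml = c(5, 10, 20))
  rec <- longitudinal_record("p1", 1:3, a, a)
  cg <- longitudinal_congruence(rec)
  expect_true(all(cg$congruent))
  expect_equal(nrow(cg), 6)              # 2 follow-ups x 3 metrics

  # BTV doubles in one method, halves in the other: discordant
  b <- a; b$btv_ml <- c(5, 2.5, 1.25)
  cg2 <- longitudinal_congruence(longitudinal_record("p2", 1:3, a, b))
  expect_true(all(!cg2$congruent[cg2$metric == "btv_ml"]))
  expect_true(all(cg2$congruent[cg2$metric != "btv_ml"]))

  # opposite jitter inside the dead zone still counts as agreement
  c1 <- a; c1$btv_ml <- c(5, 5.1, 5.2)
  c2 <- a; c2$btv_ml <- c(5, 4.9, 4.8)
  cg3 <- longitudinal_congruence(longitudinal_record("p3", 1:3, c1, c2),
                                 dead_zone = 0.05)
  expect_true(all(cg3$congruent[cg3$metric == "btv_ml"]))

  expect_error(longitudinal_record("p", 1:2, a[1:2, ], a[1:2, ]), ">= 3")
})
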