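test_that("pose RMSD: identity, closed form, mismatch errors", {
  pose <- tibble::tibble(element = c("C", "N", "O"), x = c(0, 1, 2), y = 0, z = 0)
  expect_equal(pose_rmsd(pose, pose), 0)
  one <- tibble::tibble(element = "C", x = 0, y = 0, z = 0)
  moved <- dplyr::mutate(one, x = 2)
  expect_equal(pose_rmsd(one, moved), 2)
  expect_error(pose_rmsd(pose, one), "heavy-atom count")
  # hydrogens are excluded
  withH <- dplyr::bind_rows(pose, tibble::tibble(element = "H", x = 99, y = 0, z = 0))
  expect_equal(pose_rmsd(withH, pose, "element_hungarian"), 0)
})

test_that("element-aware matching beats ordered on a swapped symmetric pair", {
  a <- tibble::tibble(
    element = c("C", "O", "O", "N"),
    x = c(0, 1, -1, 0), y = c(0, 0, 0, 1), z = 0
  )
  b <- a[c(1, 3, 2, 4), ] # symmetric oxygens swapped
  ord <- pose_rmsd(a, b, "ordered")
  hun <- pose_rmsd(a, b, "element_hungarian")
  expect_lt(hun, ord)
  expect_equal(hun, 0)
})

test_that("hungarian pose RMSD equals the exhaustive-permutation oracle", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    a <- tibble::tibble(
      element = sample(c("C", "C", "N", "O"), n, replace = TRUE),
      x = rnorm(n), y = rnorm(n), z = rnorm(n)
    )
    b <- a
    b$x <- b$x + rnorm(n, sd = 0.5)
    b <- b[sample(n), ]
    # re-sort b so element multisets align arbitrarily
    expect_equal(
      pose_rmsd(a, b, "element_hungarian"),
      bruteforce_pose_rmsd(a, b),
      tolerance = 1e-10
    )
  }
})

test_that("assignment solver matches brute force on random cost matrices", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n)
    asg <- dockscreen:::solve_assignment(cost)
    got <- sum(cost[cbind(seq_len(n), asg)])
    pm <- perms(n)
    want <- min(apply(pm, 1, function(p) sum(cost[cbind(seq_len(n), p)])))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("docking power is inclusive at 2.0 A", {
  expect_true(docking_power(0.776))
  expect_true(docking_power(2.0))
  expect_false(docking_power(2.01))
  expect_error(docking_power(-0.1), "negative")
})

test_that("student t-test matches hand computation and stats::t.test", {
  res <- score_ttest(c(1, 2, 3), c(2, 3, 4), variant = "student")
  expect_equal(res$t, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.2878641, tolerance = 1e-6)
  ref <- stats::t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # welch agrees with stats::t.test default
  set.seed(2)
  a <- rnorm(20); b <- rnorm(30, 1, 2)
  rw <- score_ttest(a, b, variant = "welch")
  refw <- stats::t.test(a, b)
  expect_equal(rw$t, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(rw$df, unname(refw$parameter), tolerance = 1e-9)
})

test_that("t-test degenerate conventions and log-space p-values", {
  same <- score_ttest(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  expect_warning(diffm <- score_ttest(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(diffm$p_value, 0)
  # identical samples with spread: t = 0, p = 1
  eq <- score_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p_value, 1)
  # big separation: p underflows but log10_p stays informative
  set.seed(3)
  big <- score_ttest(rnorm(2000, 0), rnorm(2000, 3))
  expect_lt(big$p_value, 1e-10)
  expect_lt(big$log10_p, -100)
  expect_true(is.finite(big$log10_p))
  # student equals welch for equal n and equal variance structure
  a <- rnorm(50); b <- rnorm(50)
  s <- score_ttest(a, b, "student"); w <- score_ttest(a, b, "welch")
  expect_equal(s$t, w$t, tolerance = 1e-12)
})

test_that("rank AUC reproduces worked examples and the pairwise oracle", {
  expect_equal(roc_auc(c(-9, -7, -8, -6), c(1, 0, 1, 0)), 1.0)
  expect_equal(roc_auc(c(-9, -8, -7, -6), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(rep(1, 10), rep(c(1, 0), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  set.seed(13)
  for (rep in 1:50) {
    n <- sample(5:200, 1)
    scores <- sample(round(rnorm(n), 1), n, replace = TRUE) # ties injected
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_identical(
      roc_auc(scores, labels),
      pairwise_auc(scores, labels)
    )
  }
})

test_that("AUC complement and monotone-transform invariance hold", {
  set.seed(17)
  scores <- round(rnorm(100), 1)
  labels <- rbinom(100, 1, 0.25)
  expect_equal(roc_auc(scores, labels) + roc_auc(scores, 1 - labels), 1)
  expect_equal(
    roc_auc(scores, labels),
    roc_auc(exp(scores / 2), labels)
  )
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = ">", levels = c(0, 1))))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("gaussian-separation AUC approaches its closed form", {
  tab <- gen_score_table(
    n_active = 2000, n_decoy = 2000, n_conformations = 1,
    mu_active = -8, mu_decoy = -5, sigma = 1, rho = 0, seed = 99
  )
  auc <- roc_auc(tab$score, tab$label)
  expect_equal(auc, pnorm(3 / sqrt(2)), tolerance = 0.01)
})

test_that("enrichment factor: closed form, hand count, random expectation", {
  # perfect ranking, 5% actives, top 5% -> EF = 20
  scores <- c(seq(-10, -9.1, length.out = 5), seq(-5, -1, length.out = 95))
  labels <- c(rep(1, 5), rep(0, 95))
  expect_equal(enrichment_factor(scores, labels, 0.05), 20)
  # worked 10-compound table: top 5 hold 2 of 3 actives -> (2/5)/(3/10)
  s10 <- c(-9, -8, -7, -6, -5, -4, -3, -2, -1, 0)
  l10 <- c(1, 0, 1, 0, 0, 1, 0, 0, 0, 0)
  expect_equal(enrichment_factor(s10, l10, 0.5), (2 / 5) / (3 / 10))
  # label-shuffled expectation near 1
  set.seed(21)
  efs <- replicate(200, {
    l <- sample(l10)
    enrichment_factor(s10, l, 0.5)
  })
  expect_equal(mean(efs), 1, tolerance = 0.15)
  expect_error(enrichment_factor(s10, l10, 0.01), "empty")
})

test_that("mode choice prefers smaller p, then higher AUC, then first listed", {
  report <- tibble::tibble(
    conformation_id = c("2A5U", "2A5U", "4WWO", "4WWO", "TIE", "TIE"),
    mode = c("SP", "XP", "SP", "XP", "SP", "XP"),
    log10_p = c(-158, -128, -84, -103, -50, -50),
    auc = c(0.8, 0.8, 0.7, 0.75, 0.8, 0.8)
  )
  ch <- choose_mode(report)
  expect_equal(ch$chosen_mode[ch$conformation_id == "2A5U"], "SP")
  expect_equal(ch$chosen_mode[ch$conformation_id == "4WWO"], "XP")
  expect_equal(ch$chosen_mode[ch$conformation_id == "TIE"], "SP")
})

test_that("validate_conformations reports t, AUC and dock success per mode", {
  tab <- dplyr::bind_rows(
    gen_score_table(40, 800, 2, mu_active = -8, mu_decoy = -6, seed = 4),
    gen_score_table(40, 800, 2, mu_active = -8, mu_decoy = -6.5, seed = 5) %>%
      dplyr::mutate(mode = "XP")
  )
  redock <- tibble::tibble(
    conformation_id = rep(c("conf01", "conf02"), each = 2),
    mode = rep(c("SIM", "XP"), 2),
    redock_rmsd = c(0.8, 2.1, 1.9, 0.3)
  )
  rep <- validate_conformations(tab, redock = redock)
  expect_equal(nrow(rep), 4)
  expect_true(all(rep$p_value >= 0 & rep$p_value <= 1))
  expect_true(all(rep$auc > 0.5)) # separated by construction
  expect_equal(rep$dock_success, docking_power(rep$redock_rmsd))
  expect_true(all(rep$satisfactory == (rep$auc > 0.7)))
})
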