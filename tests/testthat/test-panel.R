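test_that("Mann-Whitney U equals the brute-force pair count", {
  mw <- mann_whitney(c(3, 4), c(1, 2))
  expect_equal(mw$U, 4)          # every case beats every control
  expect_equal(mw$auc, 1)

  set.seed(31)
  for (k in 1:50) {
    case <- sample(0:5, sample(3:8, 1), replace = TRUE)   # ties guaranteed
    control <- sample(0:5, sample(3:8, 1), replace = TRUE)
    mw <- mann_whitney(case, control)
    expect_equal(mw$U, brute_U(case, control))
  }

  tied <- mann_whitney(c(2, 2, 2), c(2, 2))
  expect_equal(tied$p, 1)
  expect_equal(tied$U, 3)   # n1 n2 / 2
})

test_that("ROC AUC obeys the U identity, anti-symmetry and null level", {
  set.seed(8)
  for (k in 1:200) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    scores <- c(sample(1:10, n1, replace = TRUE) + rnorm(n1, 0, 0.01),
                sample(1:10, n2, replace = TRUE) + rnorm(n2, 0, 0.01))
    if (k %% 2 == 0) scores <- round(scores)   # force heavy ties half the time
    labels <- rep(c("case", "control"), c(n1, n2))
    r <- roc_auc(scores, labels)
    mw <- mann_whitney(scores[labels == "case"], scores[labels == "control"])
    expect_equal(r$auc, mw$U / (n1 * n2), tolerance = 1e-12)
    r_neg <- roc_auc(-scores, labels)
    expect_equal(r$auc + r_neg$auc, 1, tolerance = 1e-12)
  }

  # perfect separation
  expect_equal(roc_auc(c(5, 6, 1, 2), c("case", "case", "control", "control"))$auc, 1)
  expect_error(roc_auc(1:4, rep("case", 4)), "2 classes")

  # shuffled labels: AUC near 1/2
  set.seed(9)
  sc <- rnorm(2000)
  lb <- sample(rep(c("case", "control"), 1000))
  expect_lt(abs(roc_auc(sc, lb)$auc - 0.5), 0.02)
})

test_that("BH adjustment matches the hand-computed worked example", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.01, 0.9)
  q <- bh_fdr(p)
  expect_equal(q, c(0.003, 0.015, 0.9))
  expect_true(all(diff(q[order(p)]) >= 0))   # monotone in rank
  st <- data.frame(mab_id = c("a", "b"), U = 1, p = 1, auc = 0.5, q = 1)
  expect_length(select_features(st), 0)
})

test_that("feature selection ranks planted effects first at FDR < 0.01", {
  pf <- planted_features(n_per_group = 150, n_feat = 12, n_effect = 3,
                         effect = 1.2, seed = 44)
  fs <- feature_stats(pf$x, pf$labels)
  sel <- select_features(fs, q_threshold = 0.01)
  expect_setequal(sel, pf$effect_ids)
  expect_true(all(fs$q[match(sel, fs$mab_id)] < 0.01))
  expect_equal(fs$auc, fs$U / (fs$U * 0 + 150 * 150), tolerance = 1e-12)
})

test_that("logistic panel report reproduces the Wald / odds-ratio
           arithmetic", {
  # printed-coefficient arithmetic
  row <- panel_row_stats(0.069, 0.038)
  expect_equal(round(row$ExpB, 3), 1.071)
  expect_equal(row$Wald, (0.069 / 0.038)^2)
  zero <- panel_row_stats(0, 0.1)
  expect_equal(zero$ExpB, 1)
  expect_equal(zero$Wald, 0)

  pf <- planted_features(n_per_group = 150, n_feat = 5, n_effect = 2,
                         effect = 1, seed = 3)
  fit <- fit_logistic_panel(pf$x, pf$labels)
  rep_tab <- fit$report
  # self-consistency before rounding
  expect_true(all(abs(rep_tab$ExpB - exp(rep_tab$B)) < 5e-4 * rep_tab$ExpB))
  expect_true(all(abs(rep_tab$Wald - (rep_tab$B / rep_tab$SE)^2) < 1e-6))
  expect_true(all(rep_tab$df == 1))
  expect_equal(rep_tab$variable[nrow(rep_tab)], "Constant")
  # agrees with glm's own summary
  expect_equal(unname(coef(fit)[-1]),
               rep_tab$B[rep_tab$variable != "Constant"])
  expect_error(fit_logistic_panel(cbind(pf$x, flat = 1), pf$labels),
               "constant")
})

test_that("logistic coefficients are recovered within 3 SE on synthetic
           cohorts", {
  # planted linear log-odds model, 20 seeded repetitions
  beta <- c(0.8, -0.6, 0.4)
  cover <- 0
  n_runs <- 20
  for (s in 1:n_runs) {
    set.seed(1000 + s)
    n <- 2000
    x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
    eta <- x %*% beta
    y <- ifelse(runif(n) < plogis(eta), "case", "control")
    fit <- fit_logistic_panel(x, y)
    rp <- fit$report[fit$report$variable != "Constant", ]
    cover <- cover + sum(abs(rp$B - beta) <= 3 * rp$SE)
  }
  expect_gte(cover / (3 * n_runs), 0.94)
})

test_that("the split + repeated-CV protocol is deterministic and calibrated", {
  pf <- planted_features(n_per_group = 100, n_feat = 8, n_effect = 4,
                         effect = 1, seed = 6)
  pr1 <- evaluate_protocol(pf$x, pf$labels,
                           cv_protocol(0.7, folds = 5, repeats = 2, seed = 10))
  pr2 <- evaluate_protocol(pf$x, pf$labels,
                           cv_protocol(0.7, folds = 5, repeats = 2, seed = 10))
  expect_identical(pr1$train_idx, pr2$train_idx)
  expect_equal(pr1$test_roc$auc, pr2$test_roc$auc)
  expect_gt(pr1$test_roc$auc, 0.8)
  expect_gt(pr1$cv_auc, 0.8)

  pr3 <- evaluate_protocol(pf$x, pf$labels,
                           cv_protocol(0.7, folds = 5, repeats = 2, seed = 11))
  expect_false(identical(pr1$train_idx, pr3$train_idx))

  small <- c(1:6, 101:106)   # 6 cases + 6 controls
  expect_error(
    evaluate_protocol(pf$x[small, ], pf$labels[small],
                      cv_protocol(0.7, folds = 10, repeats = 1, seed = 1)),
    "fewer folds")
})

test_that("alternative model kinds run under the same protocol", {
  pf <- planted_features(n_per_group = 60, n_feat = 5, n_effect = 3,
                         effect = 1.2, seed = 13)
  proto <- cv_protocol(0.7, folds = 3, repeats = 1, seed = 2)
  for (kind in c("svm", "knn", "rf")) {
    pr <- evaluate_protocol(pf$x, pf$labels, proto, model = kind)
    expect_gt(pr$test_roc$auc, 0.7)
  }
})

test_that("subgroup ROC reuses scores and skips one-class levels", {
  pf <- planted_features(n_per_group = 150, n_feat = 6, n_effect = 3,
                         effect = 1, seed = 18)
  fit <- suppressWarnings(fit_logistic_panel(pf$x, pf$labels))
  scores <- as.numeric(predict(fit, pf$x, type = "response"))

  # whole cohort as one subgroup reproduces the overall ROC
  md <- data.frame(all = rep("everyone", nrow(pf$x)))
  sg <- subgroup_roc(scores, pf$labels, md, "all")
  expect_equal(sg$by_level$everyone$auc, sg$overall$auc)

  # a confounder with no planted interaction: subgroup AUCs near overall
  sg2 <- subgroup_roc(scores, pf$labels, pf$metadata, "sex")
  for (lvl in names(sg2$by_level))
    expect_lt(abs(sg2$by_level[[lvl]]$auc - sg2$overall$auc), 0.06)

  # a level holding only controls is skipped with notice
  grp <- ifelse(pf$labels == "control", "ctl_only", "mixed")
  grp[which(pf$labels == "control")[1:20]] <- "mixed"
  sg3 <- subgroup_roc(scores, pf$labels, data.frame(grp = grp), "grp")
  expect_equal(sg3$skipped, "ctl_only")
  expect_named(sg3$by_level, "mixed")
})
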