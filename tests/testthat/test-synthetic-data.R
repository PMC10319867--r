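test_that("cohort generator plants null and log-fold effects correctly", {
  # null model: no effect, group means agree
  cc0 <- cohort_config(500, 500, 4, seed = 11)
  ch0 <- generate_cohort(cc0)
  is_case <- ch0$metadata$group == "case"
  gm_ratio <- exp(colMeans(log(ch0$abundance[is_case, ])) -
                    colMeans(log(ch0$abundance[!is_case, ])))
  expect_true(all(abs(log(gm_ratio)) < 0.15))

  # planted +0.5 natural-log effect on one mAb: geometric-mean ratio e^0.5
  cc <- cohort_config(2000, 2000, 8,
                      effect_mabs = data.frame(mab_id = "mab_007",
                                               effect = 0.5),
                      seed = 7)
  ch <- generate_cohort(cc)
  is_case <- ch$metadata$group == "case"
  ratio <- exp(mean(log(ch$abundance[is_case, "mab_007"])) -
                 mean(log(ch$abundance[!is_case, "mab_007"])))
  expect_equal(ratio, exp(0.5), tolerance = 0.05)
  expect_true(all(ch$abundance > 0))
  expect_setequal(names(ch$metadata),
                  c("sample_id", "group", "sex", "age", "copd_grade",
                    "bmi_class", "smoking_class", "stage", "histology_code"))
})

test_that("generators are deterministic in (config, seed) and validate ids", {
  cc <- cohort_config(20, 20, 5, seed = 3)
  expect_identical(generate_cohort(cc), generate_cohort(cc))
  expect_error(
    cohort_config(5, 5, 3,
                  effect_mabs = data.frame(mab_id = "mab_099", effect = 1)),
    "unknown mAb")

  ab <- generate_cohort(cc)$abundance
  r1 <- generate_biochip_runs(ab, "QP69", noise_model(0.1, 0.1, 0.1, 0.1),
                              seed = 5)
  r2 <- generate_biochip_runs(ab, "QP69", noise_model(0.1, 0.1, 0.1, 0.1),
                              seed = 5)
  r3 <- generate_biochip_runs(ab, "QP69", noise_model(0.1, 0.1, 0.1, 0.1),
                              seed = 6)
  expect_identical(r1, r2)
  expect_false(identical(r1$rlu, r3$rlu))
})

test_that("biochip simulator obeys the assay physics limits", {
  # zero abundance, zero noise: sample RLU equals RLUmax (no competition)
  ab <- matrix(0, 4, 3, dimnames = list(sprintf("s%d", 1:4),
                                        sprintf("mab_%03d", 1:3)))
  meas <- generate_biochip_runs(ab, "QP69", noise_model(0, 0, 0, 0),
                                seed = 1, rlumax_mean = 5e4)
  tr <- meas[meas$role == "tracer_only", ]
  sm <- meas[meas$role == "sample", ]
  key <- paste(sm$run_id, sm$mab_id)
  tkey <- paste(tr$run_id, tr$mab_id)
  expect_equal(sm$rlu, tr$rlu[match(key, tkey)])
  expect_true(all(meas$rlu >= 0))

  # zero noise: replicate RLUs identical
  ab2 <- matrix(2, 2, 2, dimnames = list(c("sA", "sB"), c("mab_001", "mab_002")))
  m2 <- generate_biochip_runs(ab2, "QP300", noise_model(0, 0, 0, 0),
                              seed = 1, n_replicates = 3)
  s2 <- m2[m2$role == "sample", ]
  spread <- tapply(s2$rlu, paste(s2$sample_id, s2$mab_id, s2$dilution),
                   function(v) diff(range(v)))
  expect_true(all(spread == 0))

  # layout structure: QP69 has 2 tracer positions per run, QP300 has 1
  m69 <- generate_biochip_runs(ab, "QP69", noise_model(0, 0, 0, 0), seed = 1)
  t69 <- m69[m69$role == "tracer_only", ]
  expect_true(all(tapply(t69$position, t69$run_id,
                         function(p) length(unique(p))) == 2))
  t300 <- m2[m2$role == "tracer_only", ]
  expect_true(all(tapply(t300$position, t300$run_id,
                         function(p) length(unique(p))) == 1))
  expect_equal(sort(unique(m69$dilution)), c(100, 1000))
})

test_that("intra-assay noise calibrates to the configured CV", {
  # Monte-Carlo: 1000 replicates of one sample at cv_intra = 0.10
  ab <- matrix(1, 1, 1, dimnames = list("s1", "mab_001"))
  meas <- generate_biochip_runs(ab, "QP300", noise_model(0.10, 0, 0, 0),
                                seed = 42, n_replicates = 1000)
  s <- meas[meas$role == "sample", ]
  emp_cv <- stats::sd(s$rlu) / mean(s$rlu)
  se <- 0.10 / sqrt(2 * (1000 - 1))   # approx SE of a CV estimate
  expect_lt(abs(emp_cv - 0.10), 3 * se)
})

test_that("mimotope generator plants the requested shared structure", {
  # full sharing with a single peptide forces Red = 100
  tab1 <- generate_mimotope_sets(
    2, pairs = data.frame(mab_a = "mab_001", mab_b = "mab_002", shared = 1),
    seed = 1)
  sets1 <- peptide_table_to_sets(tab1)
  expect_equal(redundancy(sets1$mab_001, sets1$mab_002), 100)

  # zero sharing: disjoint 12-mers, Red = 0 (collisions astronomically rare)
  tab0 <- generate_mimotope_sets(
    2, pairs = data.frame(mab_a = "mab_001", mab_b = "mab_002", shared = 0),
    seed = 2)
  sets0 <- peptide_table_to_sets(tab0)
  expect_equal(redundancy(sets0$mab_001, sets0$mab_002), 0)

  # half sharing with 12 clones: 6 shared / 6 private, Red = 25 exactly
  tabh <- generate_mimotope_sets(
    4, pairs = data.frame(mab_a = "mab_002", mab_b = "mab_004", shared = 0.5),
    seed = 3)
  setsh <- peptide_table_to_sets(tabh)
  expect_equal(redundancy(setsh$mab_002, setsh$mab_004), 25)
  expect_true(all(tapply(tabh$count, tabh$mab_id, sum) == 12))
})

test_that("planted-effect mAbs are recovered by the zero-noise pool screen", {
  cc <- cohort_config(40, 40, 10,
                      effect_mabs = data.frame(mab_id = c("mab_003", "mab_008"),
                                               effect = c(1.2, -1.2)),
                      baseline_log_sd = 0.3, seed = 21)
  ch <- generate_cohort(cc)
  meas <- generate_biochip_runs(ch$abundance, "QP69",
                                noise_model(0, 0, 0, 0), seed = 1)
  prof <- aggregate_replicates(normalize_qp69(meas))
  m <- profile_matrix(prof, dilution = 100)
  is_case <- ch$metadata$group == "case"
  ctrl_pool <- colMeans(m[!is_case, ])
  case_pool <- colMeans(m[is_case, ])
  sel <- differential_mabs(ctrl_pool, case_pool, rel_threshold = 0.30)
  expect_setequal(sel$selected, c("mab_003", "mab_008"))
})
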