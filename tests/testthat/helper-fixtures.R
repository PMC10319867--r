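# Fixture builders and independent oracles used across the suite.

# Minimal single-run measurement table.
make_run <- function(run_id = "r1", sample_rlu, tracer_rlu,
                     mab_id = "m1", dilution = 100,
                     operator = "op_01", lot = "lot_01") {
  n_s <- length(sample_rlu); n_t <- length(tracer_rlu)
  data.frame(
    sample_id = c(sprintf("s%d", seq_len(n_s)), rep(NA_character_, n_t)),
    mab_id = mab_id, run_id = run_id, rack = 1L,
    position = seq_len(n_s + n_t),
    role = rep(c("sample", "tracer_only"), c(n_s, n_t)),
    operator = operator, lot = lot, dilution = dilution,
    replicate = 1L, rlu = c(sample_rlu, tracer_rlu),
    stringsAsFactors = FALSE)
}

# Brute-force mimotope redundancy: explicit double loop over every peptide
# of X crossed with every peptide of Y, independent of the package's
# intersect-based implementation.
brute_redundancy <- function(x, y) {
  fx <- x$counts / x$total_clones
  fy <- y$counts / y$total_clones
  total <- 0
  for (px in names(fx)) for (py in names(fy))
    if (px == py) total <- total + fx[[px]] * fy[[py]]
  total * 100
}

# Random small mimotope set over a tiny alphabet so collisions are common.
random_set <- function(id, n_pep = 4, n_clones = 12) {
  peps <- replicate(n_pep, paste(sample(c("A", "C", "D", "E"), 3,
                                        replace = TRUE), collapse = ""))
  cnt <- as.vector(stats::rmultinom(1, n_clones - n_pep, rep(1, n_pep))) + 1L
  suppressWarnings(mimotope_set(id, stats::setNames(cnt, peps)))
}

# Brute-force Mann-Whitney U: all case x control pairs, ties count 1/2.
brute_U <- function(case, control) {
  wins <- outer(case, control, ">")
  ties <- outer(case, control, "==")
  sum(wins) + 0.5 * sum(ties)
}

# Two-group planted cohort feature matrix for panel tests.
planted_features <- function(n_per_group = 200, n_feat = 10, n_effect = 5,
                             effect = 1.0, seed = 1) {
  cc <- cohort_config(
    n_cases = n_per_group, n_controls = n_per_group, n_mabs = n_feat,
    effect_mabs = data.frame(
      mab_id = sprintf("mab_%03d", seq_len(n_effect)),
      effect = effect),
    seed = seed)
  ch <- generate_cohort(cc)
  list(x = log(ch$abundance), labels = ch$metadata$group,
       metadata = ch$metadata,
       effect_ids = sprintf("mab_%03d", seq_len(n_effect)))
}
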