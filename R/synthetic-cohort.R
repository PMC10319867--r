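#' Configuration for a synthetic case--control cohort
#'
#' Describes a cohort of plasma samples profiled on an antibody biochip:
#' numbers of cases and controls, the monoclonal antibody (mAb) panel size,
#' planted case-vs-control effects on selected mAbs, optional
#' confounder-linked effects, and the log-normal baseline of the latent
#' epitope abundance for each mAb.
#'
#' Latent abundances are log-normal: \code{log(A)} is Gaussian with per-mAb
#' \code{baseline_log_mean} and \code{baseline_log_sd}. A planted effect
#' \code{e} multiplies case abundances by \code{exp(e)} (natural-log fold
#' change). Confounder effects do the same for every sample whose metadata
#' field equals the given level, regardless of group.
#'
#' @param n_cases,n_controls Number of case and control samples (each >= 1).
#' @param n_mabs Number of mAbs on the panel.
#' @param effect_mabs Data frame with columns \code{mab_id}, \code{effect}
#'   (natural-log fold change applied to cases), or \code{NULL} for none.
#' @param confounder_effects Data frame with columns \code{field},
#'   \code{level}, \code{mab_id}, \code{effect}, or \code{NULL}.
#' @param baseline_log_mean,baseline_log_sd Scalars or length-\code{n_mabs}
#'   vectors for the abundance baseline.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return An object of class \code{"cohort_config"}.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_cases, n_controls, n_mabs,
                          effect_mabs = NULL, confounder_effects = NULL,
                          baseline_log_mean = 0, baseline_log_sd = 0.5,
                          seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_mabs >= 1)
  mab_ids <- sprintf("mab_%03d", seq_len(n_mabs))
  if (!is.null(effect_mabs)) {
    stopifnot(is.data.frame(effect_mabs),
              all(c("mab_id", "effect") %in% names(effect_mabs)))
    bad <- setdiff(effect_mabs$mab_id, mab_ids)
    if (length(bad))
      stop("effect_mabs refers to unknown mAb id(s): ",
           paste(bad, collapse = ", "))
  }
  if (!is.null(confounder_effects)) {
    stopifnot(is.data.frame(confounder_effects),
              all(c("field", "level", "mab_id", "effect") %in%
                    names(confounder_effects)))
    bad <- setdiff(confounder_effects$mab_id, mab_ids)
    if (length(bad))
      stop("confounder_effects refers to unknown mAb id(s): ",
           paste(bad, collapse = ", "))
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_mabs = as.integer(n_mabs), mab_ids = mab_ids,
    effect_mabs = effect_mabs, confounder_effects = confounder_effects,
    baseline_log_mean = rep_len(baseline_log_mean, n_mabs),
    baseline_log_sd = rep_len(baseline_log_sd, n_mabs),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Multiplicative noise model for biochip measurements
#'
#' Fractional coefficients of variation for the four replicate dimensions of
#' the assay: within-run replicates, run-to-run, operator-to-operator and
#' reagent lot-to-lot. Each component acts as an independent unit-mean
#' log-normal factor on the measured RLU; setting every component to zero
#' yields exactly noise-free measurements.
#'
#' @param cv_intra,cv_inter_run,cv_operator,cv_lot Fractional CVs (>= 0).
#' @return An object of class \code{"noise_model"}.
#' @export
noise_model <- function(cv_intra = 0.08, cv_inter_run = 0.05,
                        cv_operator = 0.05, cv_lot = 0.05) {
  vals <- c(cv_intra = cv_intra, cv_inter_run = cv_inter_run,
            cv_operator = cv_operator, cv_lot = cv_lot)
  stopifnot(all(vals >= 0))
  structure(as.list(vals), class = "noise_model")
}

# Table-5-style categorical codings used for synthetic metadata.
.copd_levels <- c("non", "A", "B", "C", "D")
.bmi_levels <- c("A", "B", "C")
.smoking_levels <- c("non", "A", "B", "C", "D")
.stage_levels <- c("I", "II", "III", "IV")
.histology_codes <- 0:10

#' Generate a synthetic cohort with known ground truth
#'
#' Draws sample metadata (group, sex, age, COPD grade, BMI class, smoking
#' pack-year class, stage and histology code for cases) and a strictly
#' positive latent epitope-abundance matrix with the planted effects of the
#' configuration.
#'
#' @param config A [cohort_config()].
#' @return A list with \code{metadata} (data frame, one row per sample) and
#'   \code{abundance} (samples x mAbs matrix, strictly positive).
#' @examples
#' cc <- cohort_config(10, 10, 5,
#'                     effect_mabs = data.frame(mab_id = "mab_003", effect = 0.5))
#' cohort <- generate_cohort(cc)
#' dim(cohort$abundance)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_cases + config$n_controls
  with_seed(config$seed, {
    metadata <- data.frame(
      sample_id = sprintf("s_%04d", seq_len(n)),
      group = rep(c("case", "control"), c(config$n_cases, config$n_controls)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      age = round(stats::rnorm(n, 61, 8)),
      copd_grade = sample(.copd_levels, n, replace = TRUE,
                          prob = c(0.33, 0.13, 0.26, 0.13, 0.15)),
      bmi_class = sample(.bmi_levels, n, replace = TRUE,
                         prob = c(0.12, 0.65, 0.23)),
      smoking_class = sample(.smoking_levels, n, replace = TRUE,
                             prob = c(0.2, 0.05, 0.06, 0.14, 0.55)),
      stage = NA_character_, histology_code = NA_integer_,
      stringsAsFactors = FALSE
    )
    is_case <- metadata$group == "case"
    metadata$stage[is_case] <- sample(.stage_levels, sum(is_case),
                                      replace = TRUE,
                                      prob = c(0.14, 0.07, 0.33, 0.46))
    metadata$histology_code[is_case] <- sample(.histology_codes, sum(is_case),
                                               replace = TRUE)

    logA <- matrix(stats::rnorm(n * config$n_mabs,
                                mean = rep(config$baseline_log_mean, each = n),
                                sd = rep(config$baseline_log_sd, each = n)),
                   nrow = n, ncol = config$n_mabs,
                   dimnames = list(metadata$sample_id, config$mab_ids))
    if (!is.null(config$effect_mabs)) {
      for (i in seq_len(nrow(config$effect_mabs))) {
        j <- config$effect_mabs$mab_id[i]
        logA[is_case, j] <- logA[is_case, j] + config$effect_mabs$effect[i]
      }
    }
    if (!is.null(config$confounder_effects)) {
      ce <- config$confounder_effects
      for (i in seq_len(nrow(ce))) {
        fld <- ce$field[i]
        if (!fld %in% names(metadata))
          stop("confounder field not in metadata: ", fld)
        hit <- metadata[[fld]] == ce$level[i]
        logA[hit, ce$mab_id[i]] <- logA[hit, ce$mab_id[i]] + ce$effect[i]
      }
    }
    list(metadata = metadata, abundance = exp(logA))
  })
}

# Layout constants: samples per run and tracer-only positions per run.
.layouts <- list(
  QP69 = list(n_sample_pos = 16L, n_tracer_pos = 2L, dilutions = c(100, 1000)),
  QP300 = list(n_sample_pos = 2L, n_tracer_pos = 1L, dilutions = 300)
)

#' Simulate raw biochip measurement records
#'
#' Turns a latent abundance matrix into per-spot relative light unit (RLU)
#' records laid out as QP69 or QP300 runs, including the tracer-only
#' positions that carry the maximal signal (RLUmax). The competition
#' transfer function is one-site competitive binding:
#' \code{RLU = RLUmax / (1 + abundance_effective / k50)}, so higher epitope
#' abundance lowers the signal, and zero abundance returns RLUmax exactly.
#' The effective competing abundance scales inversely with sample dilution
#' relative to the layout's reference dilution (100x for QP69, 300x for
#' QP300). Noise components (intra, run, operator, lot) are independent
#' unit-mean log-normal multiplicative factors.
#'
#' QP69 runs hold 16 sample positions plus 2 tracer-only positions out of 18;
#' QP300 runs hold 2 sample positions plus 1 tracer-only position out of 3.
#'
#' @param abundance Samples x mAbs matrix (e.g. from [generate_cohort()]).
#' @param layout_kind \code{"QP69"} or \code{"QP300"}.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param n_replicates Within-run repeated measurements per sample.
#' @param rlumax_mean Mean tracer-only signal in RLU.
#' @param k50 Abundance giving half-maximal competition.
#' @param n_operators,n_lots Number of operators / reagent lots cycled over
#'   runs.
#' @return A measurement-record data frame with columns \code{sample_id},
#'   \code{mab_id}, \code{run_id}, \code{rack}, \code{position}, \code{role},
#'   \code{operator}, \code{lot}, \code{dilution}, \code{replicate},
#'   \code{rlu}.
#' @export
generate_biochip_runs <- function(abundance, layout_kind = c("QP69", "QP300"),
                                  noise = noise_model(), seed = 1L,
                                  n_replicates = 1L, rlumax_mean = 1e5,
                                  k50 = 1, n_operators = 2L, n_lots = 2L) {
  layout_kind <- match.arg(layout_kind)
  stopifnot(is.matrix(abundance), all(abundance >= 0),
            inherits(noise, "noise_model"), n_replicates >= 1)
  lay <- .layouts[[layout_kind]]
  sample_ids <- rownames(abundance) %||% sprintf("s_%04d", seq_len(nrow(abundance)))
  mab_ids <- colnames(abundance) %||% sprintf("mab_%03d", seq_len(ncol(abundance)))
  m <- length(mab_ids)

  # one (sample, replicate) unit per occupied sample position, chunked into runs
  units <- expand.grid(replicate = seq_len(n_replicates),
                       sample = seq_along(sample_ids))
  run_of <- (seq_len(nrow(units)) - 1L) %/% lay$n_sample_pos + 1L
  pos_of <- (seq_len(nrow(units)) - 1L) %% lay$n_sample_pos + 1L
  n_runs <- max(run_of)
  operators <- sprintf("op_%02d", (seq_len(n_runs) - 1L) %% n_operators + 1L)
  lots <- sprintf("lot_%02d", (seq_len(n_runs) - 1L) %/%
                    ceiling(n_runs / n_lots) + 1L)

  with_seed(seed, {
    # per-(run, mab) true RLUmax with lot/operator/run factors
    run_fac <- matrix(lnorm_factor(n_runs * m, noise$cv_inter_run), n_runs, m)
    op_levels <- unique(operators)
    lot_levels <- unique(lots)
    op_fac <- matrix(lnorm_factor(length(op_levels) * m, noise$cv_operator),
                     length(op_levels), m, dimnames = list(op_levels, NULL))
    lot_fac <- matrix(lnorm_factor(length(lot_levels) * m, noise$cv_lot),
                      length(lot_levels), m, dimnames = list(lot_levels, NULL))
    rlumax_true <- rlumax_mean * run_fac *
      op_fac[operators, , drop = FALSE] * lot_fac[lots, , drop = FALSE]

    out <- vector("list", length(lay$dilutions))
    for (di in seq_along(lay$dilutions)) {
      dil <- lay$dilutions[di]
      a_eff <- abundance * (min(lay$dilutions) / dil)
      # sample records
      srec <- data.frame(
        sample_id = rep(sample_ids[units$sample], each = m),
        mab_id = rep(mab_ids, times = nrow(units)),
        run_id = sprintf("run_%03d_d%d", rep(run_of, each = m), dil),
        rack = rep((pos_of - 1L) %/% 3L + 1L, each = m),
        position = rep(pos_of, each = m),
        role = "sample",
        operator = rep(operators[run_of], each = m),
        lot = rep(lots[run_of], each = m),
        dilution = dil,
        replicate = rep(units$replicate, each = m),
        stringsAsFactors = FALSE
      )
      mu <- rlumax_true[cbind(rep(run_of, each = m),
                              rep(seq_len(m), times = nrow(units)))] /
        (1 + a_eff[cbind(rep(units$sample, each = m),
                         rep(seq_len(m), times = nrow(units)))] / k50)
      srec$rlu <- mu * lnorm_factor(nrow(srec), noise$cv_intra)

      # tracer-only records: lay$n_tracer_pos positions per run
      tgrid <- expand.grid(mab = seq_len(m), tpos = seq_len(lay$n_tracer_pos),
                           run = seq_len(n_runs))
      trec <- data.frame(
        sample_id = NA_character_,
        mab_id = mab_ids[tgrid$mab],
        run_id = sprintf("run_%03d_d%d", tgrid$run, dil),
        rack = 1L,
        position = lay$n_sample_pos + tgrid$tpos,
        role = "tracer_only",
        operator = operators[tgrid$run],
        lot = lots[tgrid$run],
        dilution = dil,
        replicate = 1L,
        stringsAsFactors = FALSE
      )
      trec$rlu <- rlumax_true[cbind(tgrid$run, tgrid$mab)] *
        lnorm_factor(nrow(trec), noise$cv_intra)
      out[[di]] <- rbind(srec, trec)
    }
    meas <- do.call(rbind, out)
    rownames(meas) <- NULL
    attr(meas, "layout_kind") <- layout_kind
    meas
  })
}
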