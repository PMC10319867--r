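#' Coefficient of variation
#'
#' \code{100 * sd / mean} with the sample (n-1) standard deviation. Returns
#' \code{NA} when fewer than two finite values are available or when the
#' mean is zero (the CV is undefined there, and it is reported missing
#' rather than zero or infinite).
#'
#' @param values Numeric vector, typically RLU/RLUmax percent or raw RLUmax.
#' @return CV in percent, or \code{NA_real_}.
#' @examples
#' compute_cv(c(90, 100, 110))  # 10
#' @export
compute_cv <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) return(NA_real_)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  100 * stats::sd(values) / m
}

.cv_components <- c("intra_run", "inter_run", "operator", "lot")

#' Decompose assay variability into CV components
#'
#' Computes, per mAb and dilution, the analytical reproducibility of the
#' assay along the replicate dimensions of the data:
#' \describe{
#'   \item{intra_run}{pooled repeatability: the square root of the mean
#'     within-run, within-sample variance (over groups with >= 2 replicate
#'     values), divided by the grand mean, in percent.}
#'   \item{inter_run}{per sample, the CV of its per-run mean values across
#'     runs, averaged over samples measured in >= 2 runs.}
#'   \item{operator}{as inter_run, grouped by operator.}
#'   \item{lot}{as inter_run, grouped by reagent lot.}
#' }
#' Grouping per sample keeps biological sample-to-sample spread out of the
#' analytical components; when no \code{sample_id} column is present (or
#' for tracer-only records, which carry none) all records are treated as
#' one material. Components whose grouping has fewer than two levels are
#' reported missing, never zero. Competition measurements should be
#' supplied as normalized RLU/RLUmax percent values; tracer-only
#' reproducibility is assessed on raw RLUmax by passing tracer records with
#' \code{value_col = "rlu"}.
#'
#' @param data Long data frame with columns \code{mab_id}, \code{run_id},
#'   \code{operator}, \code{lot}, the value column, and optionally
#'   \code{dilution}.
#' @param value_col Name of the value column (default \code{"value"}).
#' @param components Subset of \code{"intra_run"}, \code{"inter_run"},
#'   \code{"operator"}, \code{"lot"}.
#' @return A CV report data frame: \code{mab_id}, \code{dilution},
#'   \code{component}, \code{cv_percent}, \code{n} (groups or runs used).
#' @export
cv_decompose <- function(data, value_col = "value",
                         components = .cv_components) {
  components <- match.arg(components, .cv_components, several.ok = TRUE)
  need <- c("mab_id", value_col,
            if ("intra_run" %in% components || "inter_run" %in% components) "run_id",
            if ("operator" %in% components) "operator",
            if ("lot" %in% components) "lot")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("grouping column(s) absent: ", paste(missing_cols, collapse = ", "))
  if (!"dilution" %in% names(data)) data$dilution <- NA_real_
  v <- data[[value_col]]

  grp_cv <- function(x, g, of_means, sample_id = NULL) {
    # of_means: CV of per-group mean values. When sample identity is
    # available the CV is computed per sample across groups (the same
    # sample re-measured in different runs / by different operators) and
    # averaged, so biological sample-to-sample spread does not inflate the
    # analytical component.
    if (of_means) {
      if (!is.null(sample_id)) {
        per_sample <- tapply(seq_along(x), sample_id, function(ii) {
          means <- tapply(x[ii], droplevels(factor(g[ii])), mean,
                          na.rm = TRUE)
          if (sum(is.finite(means)) < 2) NA_real_ else compute_cv(means)
        })
        ok <- is.finite(per_sample)
        if (!any(ok)) return(c(NA_real_, 0))
        return(c(mean(per_sample[ok]), sum(ok)))
      }
      means <- tapply(x, g, mean, na.rm = TRUE)
      if (sum(is.finite(means)) < 2) return(c(NA_real_, sum(is.finite(means))))
      c(compute_cv(means), sum(is.finite(means)))
    } else {
      # pooled repeatability: sqrt of the mean within-group variance over
      # the grand mean (unbiased in the variance, unlike averaging the
      # per-group CVs of tiny groups)
      vars <- tapply(x, g, function(v) {
        v <- v[is.finite(v)]
        if (length(v) < 2) NA_real_ else stats::var(v)
      })
      ok <- is.finite(vars)
      if (!any(ok)) return(c(NA_real_, 0))
      grand <- mean(x[is.finite(x) & g %in% names(vars)[ok]])
      if (grand == 0) return(c(NA_real_, sum(ok)))
      c(100 * sqrt(mean(vars[ok])) / grand, sum(ok))
    }
  }

  key <- interaction(data$mab_id, data$dilution, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(data)), key), function(idx) {
    d <- data[idx, ]; x <- v[idx]
    sid <- if ("sample_id" %in% names(d)) d$sample_id else NULL
    if (!is.null(sid)) sid[is.na(sid)] <- "<pooled>"   # tracer-only records
    intra_grp <- if (is.null(sid)) d$run_id else paste(d$run_id, sid)
    res <- lapply(components, function(comp) {
      cv_n <- switch(comp,
        intra_run = grp_cv(x, intra_grp, of_means = FALSE),
        inter_run = grp_cv(x, d$run_id, of_means = TRUE, sample_id = sid),
        operator = grp_cv(x, d$operator, of_means = TRUE, sample_id = sid),
        lot = grp_cv(x, d$lot, of_means = TRUE, sample_id = sid))
      data.frame(mab_id = d$mab_id[1], dilution = d$dilution[1],
                 component = comp, cv_percent = cv_n[1], n = cv_n[2],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the analytical qualification gate (CV < threshold)
#'
#' A mAb qualifies when every available CV component, across all dilutions
#' in the report, is strictly below the threshold (default 20 percent, the
#' analytical acceptance limit of the assay). Missing components do not
#' block qualification.
#'
#' @param report CV report from [cv_decompose()].
#' @param threshold Gate in percent.
#' @return List with \code{passing} (character vector of mAb ids),
#'   \code{fraction} (passes / total mAbs in the report), and \code{per_mab}
#'   (data frame with each mAb's worst component).
#' @export
cv_gate <- function(report, threshold = 20) {
  stopifnot(nrow(report) > 0, threshold > 0)
  worst <- tapply(report$cv_percent, report$mab_id,
                  function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  pass <- !is.na(worst) & worst < threshold
  # mAbs with no measurable CV at all cannot be qualified
  per_mab <- data.frame(mab_id = names(worst), worst_cv = as.numeric(worst),
                        pass = as.logical(pass), stringsAsFactors = FALSE,
                        row.names = NULL)
  list(passing = per_mab$mab_id[per_mab$pass],
       fraction = mean(per_mab$pass),
       per_mab = per_mab)
}
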