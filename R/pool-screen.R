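#' Average repeated pooled-sample measurements
#'
#' Pooled plasma samples are measured two or three times; the per-mAb mean
#' RLU/RLUmax percent over those repeats is the pool profile used for
#' differential screening.
#'
#' @param pools Data frame \code{pool_id}, \code{mab_id}, \code{repeat_idx},
#'   \code{value}.
#' @return Named list of pool profiles; each profile is a named numeric
#'   vector of per-mAb means with attribute \code{n_repeats}.
#' @export
pool_profiles <- function(pools) {
  stopifnot(all(c("pool_id", "mab_id", "value") %in% names(pools)))
  lapply(split(pools, pools$pool_id), function(g) {
    n_rep <- tapply(g$value, g$mab_id, function(v) sum(!is.na(v)))
    if (any(!n_rep %in% 2:3))
      warning("pool ", g$pool_id[1],
              ": expected 2-3 repeats per mAb, found range ",
              min(n_rep), "-", max(n_rep))
    prof <- tapply(g$value, g$mab_id, mean, na.rm = TRUE)
    structure(stats::setNames(as.numeric(prof), names(prof)),
              n_repeats = as.integer(n_rep))
  })
}

#' Differential screen of pooled case vs control profiles
#'
#' A mAb is selected when the difference between the case-pool and
#' control-pool normalized signal strictly exceeds 30 percent (by default)
#' of the control value: \code{|case - control| > rel_threshold * control}.
#' mAbs with a zero (or missing) control value cannot be screened and are
#' skipped and reported. Signed up/down classifications are reported
#' alongside the absolute-difference selection.
#'
#' @param control,case Named numeric vectors (names = mAb ids), e.g. from
#'   [pool_profiles()].
#' @param rel_threshold Relative-difference threshold (default 0.30).
#' @return List of class \code{"pep_differential"}: \code{selected} (mAb
#'   ids), \code{up}, \code{down} (signed subsets of \code{selected}),
#'   \code{rel_diff} (named signed relative differences),
#'   \code{skipped} (mAbs with control <= 0 or missing values).
#' @examples
#' ctrl <- c(m1 = 50, m2 = 50)
#' case <- c(m1 = 70, m2 = 65)
#' differential_mabs(ctrl, case)$selected  # only m1 (20 > 15; 15 > 15 fails)
#' @export
differential_mabs <- function(control, case, rel_threshold = 0.30) {
  common <- intersect(names(control), names(case))
  if (!length(common))
    stop("control and case pools share no mAbs")
  ctrl <- control[common]; cs <- case[common]
  usable <- !is.na(ctrl) & !is.na(cs) & ctrl > 0
  rel <- (cs[usable] - ctrl[usable]) / ctrl[usable]
  sel <- abs(rel) > rel_threshold
  structure(list(
    selected = names(rel)[sel],
    up = names(rel)[sel & rel > 0],
    down = names(rel)[sel & rel < 0],
    rel_diff = rel,
    skipped = common[!usable],
    rel_threshold = rel_threshold
  ), class = "pep_differential")
}

#' @export
print.pep_differential <- function(x, ...) {
  cat("Differential pool screen (>", 100 * x$rel_threshold,
      "% of control): ", length(x$selected), " mAb(s) selected (",
      length(x$up), " up, ", length(x$down), " down), ",
      length(x$skipped), " skipped\n", sep = "")
  invisible(x)
}

#' Venn partition of differential selections across contrasts
#'
#' Counts, for every combination of contrasts, the mAbs selected in exactly
#' that combination. "Shared" mAbs appear in at least two contrasts,
#' "non-shared" in exactly one.
#'
#' @param selections Named list of character vectors (one per contrast,
#'   e.g. lung/colon/breast vs control).
#' @return List: \code{regions} (data frame \code{region}, \code{count},
#'   \code{mab_ids}), \code{n_unique} (in exactly one contrast),
#'   \code{n_shared} (in two or more).
#' @export
venn_partition <- function(selections) {
  stopifnot(length(selections) >= 2, !is.null(names(selections)))
  all_ids <- sort(unique(unlist(selections)))
  membership <- vapply(selections, function(s) all_ids %in% s,
                       logical(length(all_ids)))
  if (length(all_ids) == 1) membership <- matrix(membership, nrow = 1,
                                                 dimnames = list(NULL, names(selections)))
  region_of <- apply(membership, 1, function(r)
    paste(names(selections)[r], collapse = "&"))
  counts <- table(region_of)
  regions <- data.frame(
    region = names(counts), count = as.integer(counts),
    mab_ids = vapply(names(counts), function(r)
      paste(all_ids[region_of == r], collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  n_contrasts <- rowSums(membership)
  list(regions = regions,
       n_unique = sum(n_contrasts == 1),
       n_shared = sum(n_contrasts >= 2))
}

#' Correlation structure of an epitome feature matrix
#'
#' Pairwise Pearson correlations between mAb columns using observations
#' complete for each pair, a histogram of the off-diagonal coefficients
#' over [-1, 1] in bins of width 0.1 (right-closed), and the fraction of
#' coefficients in the top bin [0.8, 1.0] (0.8 included). Zero-variance
#' columns yield missing correlations for their pairs and are reported.
#'
#' @param x Samples x mAbs numeric matrix (e.g. [profile_matrix()] of the
#'   100-fold-dilution subset for QP69 data), or a \code{"pep_profile"}.
#' @param dilution Dilution filter applied when \code{x} is a profile.
#' @param use Observation policy: \code{"pairwise"} (default) or
#'   \code{"listwise"} complete observations.
#' @return List of class \code{"pep_corsummary"}: \code{cor} (matrix),
#'   \code{hist} (data frame \code{lower}, \code{upper}, \code{fraction}),
#'   \code{high_fraction} (fraction of r in [0.8, 1]), \code{n_pairs},
#'   \code{degenerate} (zero-variance mAbs).
#' @export
correlation_summary <- function(x, dilution = NULL,
                                use = c("pairwise", "listwise")) {
  use <- match.arg(use)
  if (inherits(x, "pep_profile")) x <- profile_matrix(x, dilution)
  stopifnot(is.matrix(x), ncol(x) >= 2, nrow(x) >= 3)
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  degenerate <- colnames(x)[!is.na(sds) & sds == 0]
  cm <- suppressWarnings(stats::cor(
    x, use = if (use == "pairwise") "pairwise.complete.obs"
             else "complete.obs"))
  r <- cm[upper.tri(cm)]
  r <- r[!is.na(r)]
  breaks <- seq(-1, 1, by = 0.1)
  h <- hist(r, breaks = breaks, right = TRUE, include.lowest = TRUE,
            plot = FALSE)
  hist_df <- data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
                        fraction = if (length(r)) h$counts / length(r)
                                   else rep(0, length(breaks) - 1))
  high_fraction <- if (length(r)) mean(r >= 0.8) else NA_real_
  structure(list(cor = cm, hist = hist_df, high_fraction = high_fraction,
                 n_pairs = length(r), degenerate = degenerate),
            class = "pep_corsummary")
}

#' @export
print.pep_corsummary <- function(x, ...) {
  cat("Pairwise Pearson summary over", ncol(x$cor), "mAbs:",
      x$n_pairs, "pairs;",
      sprintf("%.2f%%", 100 * x$high_fraction), "of r in [0.8, 1.0]\n")
  if (length(x$degenerate))
    cat("  zero-variance mAbs:", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Ward clustering of profiles
#'
#' Hierarchical clustering with Euclidean distance and the Ward criterion
#' (\code{ward.D2}, Ward's method on unsquared Euclidean distances). Rows
#' are ordered by their names before clustering so the result is invariant
#' to input row permutations.
#'
#' @param x Numeric matrix without missing cells (rows = objects to
#'   cluster); rows must be named.
#' @param k Number of flat clusters to cut, or \code{NULL} for dendrogram
#'   only.
#' @return List of class \code{"pep_clustering"}: \code{hclust} (the
#'   dendrogram) and \code{clusters} (named integer vector, when \code{k}
#'   given).
#' @export
cluster_profiles <- function(x, k = NULL) {
  stopifnot(is.matrix(x))
  if (anyNA(x))
    stop("matrix contains missing cells; complete or impute before clustering")
  if (is.null(rownames(x))) rownames(x) <- sprintf("row_%04d", seq_len(nrow(x)))
  x <- x[order(rownames(x)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "ward.D2")
  clusters <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  structure(list(hclust = hc, clusters = clusters),
            class = "pep_clustering")
}

#' @export
print.pep_clustering <- function(x, ...) {
  cat("Ward (Euclidean) clustering of", length(x$hclust$labels), "objects")
  if (!is.null(x$clusters))
    cat(";", length(unique(x$clusters)), "flat clusters")
  cat("\n")
  invisible(x)
}

#' @method plot pep_clustering
#' @export
plot.pep_clustering <- function(x, ...) plot(x$hclust, ...)
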