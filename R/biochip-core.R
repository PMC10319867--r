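#' @title Biochip measurement tables and RLU/RLUmax normalization
#' @description Raw measurement records hold one background-corrected RLU
#'   value per spot, tied to the chip layout (run, rack, position), the
#'   replicate structure (operator, lot, dilution, replicate index) and the
#'   spot role: \code{"sample"} for competition measurements or
#'   \code{"tracer_only"} for maximal-signal (RLUmax) positions.
#' @name biochip-core
NULL

.meas_cols <- c("sample_id", "mab_id", "run_id", "rack", "position", "role",
                "operator", "lot", "dilution", "replicate", "rlu")

validate_measurements <- function(meas) {
  missing_cols <- setdiff(.meas_cols, names(meas))
  if (length(missing_cols))
    stop("measurement table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(!is.finite(meas$rlu) | meas$rlu < 0)) {
    bad <- which(!is.finite(meas$rlu) | meas$rlu < 0)[1]
    stop("negative or non-finite rlu at row ", bad)
  }
  if (!all(meas$role %in% c("sample", "tracer_only")))
    stop("role must be 'sample' or 'tracer_only'")
  invisible(meas)
}

#' Read / write biochip measurement tables
#'
#' Tab-separated files with the canonical measurement header. Rows with a
#' negative RLU are rejected with their line number.
#'
#' @param path File path.
#' @return \code{read_measurements} returns a validated measurement data
#'   frame; \code{write_measurements} returns \code{path} invisibly.
#' @export
read_measurements <- function(path) {
  meas <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.meas_cols, names(meas))
  if (length(missing_cols))
    stop("measurement file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(meas$rlu) | meas$rlu < 0)
  if (length(bad))
    stop("invalid rlu in ", path, " at line ", bad[1] + 1L,
         " (header is line 1)")
  validate_measurements(meas)
  meas
}

#' @rdname read_measurements
#' @param meas A measurement data frame.
#' @export
write_measurements <- function(meas, path) {
  validate_measurements(meas)
  utils::write.table(meas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Shared normalization engine. `n_tracer` gives the required tracer-position
# count per run: QP69 averages two parallel RLUmax positions, QP300 uses the
# single tracer-only sample.
.normalize_runs <- function(meas, n_tracer, exact = FALSE, layout = "") {
  validate_measurements(meas)
  out <- lapply(split(meas, meas$run_id), function(run) {
    run_id <- run$run_id[1]
    tr <- run[run$role == "tracer_only", ]
    n_pos <- length(unique(tr$position))
    if (n_pos < n_tracer)
      stop("run ", run_id, ": expected ", if (exact) "exactly " else ">= ",
           n_tracer, " tracer-only position(s) for ", layout,
           ", found ", n_pos)
    if (exact && n_pos != n_tracer)
      stop("run ", run_id, ": expected exactly ", n_tracer,
           " tracer-only position(s) for ", layout, ", found ", n_pos)
    rlumax <- tapply(tr$rlu, tr$mab_id, mean)
    smp <- run[run$role == "sample", ]
    if (!nrow(smp)) return(NULL)
    rm_vals <- rlumax[smp$mab_id]
    if (anyNA(rm_vals))
      stop("run ", run_id, ": no tracer-only record for mAb(s) ",
           paste(unique(smp$mab_id[is.na(rm_vals)]), collapse = ", "))
    value <- ifelse(rm_vals > 0, 100 * smp$rlu / rm_vals, NA_real_)
    data.frame(sample_id = smp$sample_id, mab_id = smp$mab_id,
               run_id = run_id, operator = smp$operator, lot = smp$lot,
               dilution = smp$dilution, replicate = smp$replicate,
               value = value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalize raw RLU records to RLU/RLUmax percent
#'
#' Per-run normalization of competition signals against the tracer-only
#' maximal signal. For the QP69 layout the two parallel RLUmax measurements
#' of a run are first averaged per mAb and the sample RLU values are divided
#' by that average; for the QP300 layout a run carries exactly one
#' tracer-only position and its RLUmax is used directly. Values are
#' expressed as percent (\code{100 * RLU / RLUmax}); no information crosses
#' run boundaries. A run-level RLUmax of zero marks that mAb's values
#' missing (\code{NA}) for the run.
#'
#' @param meas Measurement data frame (see [read_measurements()]).
#' @return Long data frame: \code{sample_id}, \code{mab_id}, \code{run_id},
#'   \code{operator}, \code{lot}, \code{dilution}, \code{replicate},
#'   \code{value} (percent).
#' @examples
#' run <- data.frame(sample_id = c("s1", NA, NA), mab_id = "m1",
#'                   run_id = "r1", rack = 1, position = c(1, 17, 18),
#'                   role = c("sample", "tracer_only", "tracer_only"),
#'                   operator = "op", lot = "l1", dilution = 100,
#'                   replicate = 1, rlu = c(50, 90, 110))
#' normalize_qp69(run)$value  # 100 * 50 / mean(c(90, 110)) = 50
#' @export
normalize_qp69 <- function(meas) {
  .normalize_runs(meas, n_tracer = 2L, exact = FALSE, layout = "QP69")
}

#' @rdname normalize_qp69
#' @export
normalize_qp300 <- function(meas) {
  .normalize_runs(meas, n_tracer = 1L, exact = TRUE, layout = "QP300")
}

#' Average replicates and cap the normalized signal
#'
#' Collapses replicate RLU/RLUmax percent values to one biomarker signal
#' intensity (BSI) value per (sample, mAb, dilution): replicates are
#' averaged first, then any mean above the cap is replaced by the cap
#' (default 120). Empty cells stay missing. The operation is idempotent.
#'
#' @param norm Long normalized table from [normalize_qp69()] /
#'   [normalize_qp300()], or a previously aggregated profile.
#' @param cap Upper cap in percent.
#' @return A data frame of class \code{"pep_profile"} with columns
#'   \code{sample_id}, \code{mab_id}, \code{dilution}, \code{value},
#'   \code{n_replicates}, and attributes \code{cap} and \code{n_capped}.
#' @export
aggregate_replicates <- function(norm, cap = 120) {
  stopifnot(all(c("sample_id", "mab_id", "value") %in% names(norm)), cap > 0)
  if (!"dilution" %in% names(norm)) norm$dilution <- NA_real_
  key <- interaction(norm$sample_id, norm$mab_id, norm$dilution, drop = TRUE)
  agg <- do.call(rbind, lapply(split(norm, key), function(g) {
    ok <- !is.na(g$value)
    data.frame(sample_id = g$sample_id[1], mab_id = g$mab_id[1],
               dilution = g$dilution[1],
               value = if (any(ok)) mean(g$value[ok]) else NA_real_,
               n_replicates = sum(ok), stringsAsFactors = FALSE)
  }))
  n_capped <- sum(agg$value > cap, na.rm = TRUE)
  agg$value <- pmin(agg$value, cap)
  agg <- agg[order(agg$sample_id, agg$mab_id, agg$dilution), ]
  rownames(agg) <- NULL
  structure(agg, cap = cap, n_capped = n_capped,
            class = c("pep_profile", "data.frame"))
}

#' Cast a long profile into a samples x mAbs matrix
#'
#' @param profile A \code{"pep_profile"} (or compatible long data frame).
#' @param dilution Keep only this dilution (required when the profile holds
#'   more than one).
#' @return Numeric matrix, rows samples, columns mAbs; missing cells `NA`.
#' @export
profile_matrix <- function(profile, dilution = NULL) {
  if (!is.null(dilution)) profile <- profile[profile$dilution %in% dilution, ]
  dils <- unique(profile$dilution)
  if (length(dils) > 1)
    stop("profile holds several dilutions (", paste(dils, collapse = ", "),
         "); pick one with `dilution`")
  samples <- sort(unique(profile$sample_id))
  mabs <- sort(unique(profile$mab_id))
  m <- matrix(NA_real_, length(samples), length(mabs),
              dimnames = list(samples, mabs))
  m[cbind(match(profile$sample_id, samples), match(profile$mab_id, mabs))] <-
    profile$value
  m
}

#' Read / write long profile tables
#'
#' @param profile A \code{"pep_profile"}.
#' @param path File path (TSV).
#' @param cap Cap recorded on the re-read profile.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path, cap = 120) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "mab_id", "dilution", "value", "n_replicates")
  missing_cols <- setdiff(need, names(p))
  if (length(missing_cols))
    stop("profile file lacks column(s): ", paste(missing_cols, collapse = ", "))
  structure(p, cap = cap, n_capped = 0L,
            class = c("pep_profile", "data.frame"))
}
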