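#' Mann-Whitney U test oriented to the case group
#'
#' U counts the pairs in which the case value exceeds the control value,
#' with ties counted one half (midrank convention), so that
#' \code{U / (n1 * n2)} is exactly the ROC AUC of the feature. Two-sided
#' p-values come from \code{stats::wilcox.test}: exact enumeration when
#' \code{n1 * n2 <= 400} and there are no ties, otherwise the normal
#' approximation with tie correction.
#'
#' @param case,control Numeric vectors (non-finite values dropped).
#' @return List: \code{U}, \code{p}, \code{n_case}, \code{n_control},
#'   \code{auc} (\code{U / (n_case * n_control)}).
#' @export
mann_whitney <- function(case, control) {
  case <- case[is.finite(case)]; control <- control[is.finite(control)]
  n1 <- length(case); n2 <- length(control)
  if (!n1 || !n2) stop("both groups must be nonempty")
  r <- rank(c(case, control))           # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_vals <- c(case, control)
  if (length(unique(all_vals)) == 1L)
    return(list(U = n1 * n2 / 2, p = 1, n_case = n1, n_control = n2,
                auc = 0.5))
  has_ties <- anyDuplicated(all_vals) > 0
  p <- suppressWarnings(stats::wilcox.test(
    case, control, exact = (n1 * n2 <= 400) && !has_ties,
    correct = FALSE)$p.value)
  list(U = U, p = p, n_case = n1, n_control = n2, auc = U / (n1 * n2))
}

.case_level <- function(labels, case_level = NULL) {
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2)
    stop("labels must have exactly 2 classes, found: ",
         paste(lv, collapse = ", "))
  if (is.null(case_level)) case_level <- if ("case" %in% lv) "case" else lv[2]
  if (!case_level %in% lv) stop("case_level not present in labels")
  case_level
}

#' ROC curve and AUC of a score
#'
#' Empirical ROC curve (midrank / trapezoid convention for tied scores) via
#' \pkg{pROC}, oriented so that higher scores indicate the case class. The
#' AUC equals the Mann-Whitney identity \code{U / (n1 * n2)}. The reported
#' operating point maximizes Youden's J.
#'
#' @param scores Numeric scores.
#' @param labels Two-class labels aligned with \code{scores}.
#' @param case_level Label of the case (positive) class; defaults to
#'   \code{"case"} when present, else the last level alphabetically.
#' @return Object of class \code{"pep_roc"}: \code{curve} (data frame
#'   \code{fpr}, \code{tpr}), \code{auc}, \code{sensitivity},
#'   \code{specificity}, \code{threshold}, \code{n_case}, \code{n_control}.
#' @export
roc_auc <- function(scores, labels, case_level = NULL) {
  case_level <- .case_level(labels, case_level)
  labels <- as.character(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  ctrl <- setdiff(sort(unique(labels)), case_level)
  if (!sum(labels == case_level) || !sum(labels == ctrl))
    stop("one class absent from labels")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(ctrl, case_level), direction = "<",
                 quiet = TRUE)
  cc <- pROC::coords(r, "all", ret = c("specificity", "sensitivity"),
                     transpose = FALSE)
  curve <- data.frame(fpr = 1 - cc$specificity, tpr = cc$sensitivity)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  rownames(curve) <- NULL
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "specificity", "sensitivity"),
                       transpose = FALSE)
  best <- best[1, ]
  structure(list(curve = curve, auc = as.numeric(pROC::auc(r)),
                 sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 threshold = best$threshold,
                 n_case = sum(labels == case_level),
                 n_control = sum(labels == ctrl),
                 case_level = case_level),
            class = "pep_roc")
}

#' @export
print.pep_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (n_case = %d, n_control = %d)\n",
              x$auc, x$n_case, x$n_control))
  cat(sprintf("  Youden point: sensitivity %.3f, specificity %.3f\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' @method plot pep_roc
#' @export
plot.pep_roc <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "l",
       xlab = "False positive rate", ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")}; q-values are
#' monotone non-decreasing in the rank of p.
#'
#' @param p P-values in [0, 1].
#' @return Adjusted q-values.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = "BH")
}

#' Per-feature nonparametric statistics
#'
#' For every feature (mAb) column: Mann-Whitney U oriented to the case
#' group, two-sided p, ROC AUC (\code{U / (n1 n2)}) and the BH-adjusted q.
#'
#' @param x Samples x features numeric matrix.
#' @param labels Two-class labels (rows of \code{x}).
#' @param case_level See [roc_auc()].
#' @return Data frame: \code{mab_id}, \code{U}, \code{p}, \code{auc},
#'   \code{q}, ordered as the columns of \code{x}.
#' @export
feature_stats <- function(x, labels, case_level = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  case_level <- .case_level(labels, case_level)
  is_case <- as.character(labels) == case_level
  res <- lapply(seq_len(ncol(x)), function(j) {
    mw <- mann_whitney(x[is_case, j], x[!is_case, j])
    data.frame(mab_id = colnames(x)[j] %||% paste0("f", j),
               U = mw$U, p = mw$p, auc = mw$auc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out
}

#' Select panel features at an FDR threshold
#'
#' Keeps features with \code{q < q_threshold} (default 0.01), ranked by the
#' distance of their AUC from 0.5 (strongest discriminators first,
#' regardless of direction).
#'
#' @param stats Output of [feature_stats()].
#' @param q_threshold FDR cutoff.
#' @return Character vector of selected feature ids, ranked.
#' @export
select_features <- function(stats, q_threshold = 0.01) {
  sel <- stats[!is.na(stats$q) & stats$q < q_threshold, ]
  sel$mab_id[order(abs(sel$auc - 0.5), decreasing = TRUE)]
}

#' Wald-report arithmetic for one logistic coefficient
#'
#' Given a coefficient and its standard error, returns the derived columns
#' of the standard logistic panel report: the Wald chi-square
#' \code{(B/SE)^2} on 1 degree of freedom, its tail p-value, and the odds
#' ratio \code{Exp(B) = exp(B)}.
#'
#' @param B Log-odds coefficient.
#' @param SE Standard error of \code{B}.
#' @return Data frame \code{B}, \code{SE}, \code{Wald}, \code{df},
#'   \code{Sig}, \code{ExpB}.
#' @examples
#' panel_row_stats(0.069, 0.038)  # ExpB = 1.071
#' @export
panel_row_stats <- function(B, SE) {
  wald <- (B / SE)^2
  data.frame(B = B, SE = SE, Wald = wald, df = 1L,
             Sig = stats::pchisq(wald, df = 1, lower.tail = FALSE),
             ExpB = exp(B))
}

#' Fit a logistic-regression biomarker panel
#'
#' Unpenalized maximum-likelihood logistic regression of the case/control
#' label on the panel's feature matrix, reported in the standard panel
#' format: per variable the coefficient B, its standard error (from the
#' inverse observed information), the Wald chi-square \code{(B/SE)^2} with
#' 1 df, its p-value, and the odds ratio \code{Exp(B)}, plus a
#' \code{"Constant"} row for the intercept. Quasi-complete separation is
#' detected from the glm warning and flagged; coefficients are still
#' reported.
#'
#' @param x Samples x features numeric matrix (no constant columns).
#' @param labels Two-class labels.
#' @param case_level See [roc_auc()].
#' @return Object of class \code{"pep_panel"}: \code{report} (data frame
#'   \code{variable}, \code{B}, \code{SE}, \code{Wald}, \code{df},
#'   \code{Sig}, \code{ExpB}), \code{glm}, \code{separation} flag,
#'   \code{case_level}.
#' @export
fit_logistic_panel <- function(x, labels, case_level = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  case_level <- .case_level(labels, case_level)
  if (nrow(x) <= ncol(x))
    stop("need more samples than features (n = ", nrow(x),
         ", p = ", ncol(x), ")")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant feature column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.integer(as.character(labels) == case_level)
  dat <- data.frame(.y = y, x, check.names = FALSE)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separation)
    warning("possible complete separation; coefficients reported with caution")
  sm <- summary(fit)$coefficients
  vars <- rownames(sm)
  rows <- panel_row_stats(sm[, "Estimate"], sm[, "Std. Error"])
  report <- cbind(
    data.frame(variable = ifelse(vars == "(Intercept)", "Constant",
                                 gsub("^`|`$", "", vars)),
               stringsAsFactors = FALSE),
    rows)
  # intercept row last, as in the conventional panel table
  report <- rbind(report[report$variable != "Constant", ],
                  report[report$variable == "Constant", ])
  rownames(report) <- NULL
  structure(list(report = report, glm = fit, separation = separation,
                 case_level = case_level, features = colnames(x)),
            class = "pep_panel")
}

#' @export
print.pep_panel <- function(x, digits = 3, ...) {
  cat("Logistic biomarker panel (", length(x$features), " variables",
      if (x$separation) "; WARNING: separation flagged", ")\n", sep = "")
  rep_fmt <- x$report
  num <- vapply(rep_fmt, is.numeric, logical(1))
  rep_fmt[num] <- lapply(rep_fmt[num], round, digits = digits)
  print(rep_fmt, row.names = FALSE)
  invisible(x)
}

#' @method coef pep_panel
#' @export
coef.pep_panel <- function(object, ...) stats::coef(object$glm)

#' @export
predict.pep_panel <- function(object, newdata = NULL,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) return(stats::predict(object$glm, type = type))
  stopifnot(is.matrix(newdata) || is.data.frame(newdata))
  nd <- as.data.frame(newdata, check.names = FALSE)
  stats::predict(object$glm, newdata = nd, type = type)
}

#' @method summary pep_panel
#' @export
summary.pep_panel <- function(object, ...) object$report

#' Cross-validation protocol for panel evaluation
#'
#' Fixes the evaluation design: a single stratified train/test split (train
#' fraction conventionally 0.70 or 0.66), model building on the training
#' set with k-fold cross-validation repeated several times (10-fold, 3
#' repeats by convention), and one final ROC on the untouched test set.
#'
#' @param train_frac Fraction of samples in the training set.
#' @param folds Number of CV folds (>= 2).
#' @param repeats CV repetitions (>= 1).
#' @param seed Integer seed driving the split and fold assignment.
#' @param stratified Stratify split and folds by class (default TRUE).
#' @return Object of class \code{"cv_protocol"}.
#' @export
cv_protocol <- function(train_frac = 0.70, folds = 10L, repeats = 3L,
                        seed = 1L, stratified = TRUE) {
  stopifnot(train_frac > 0, train_frac < 1, folds >= 2, repeats >= 1)
  structure(list(train_frac = train_frac, folds = as.integer(folds),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "cv_protocol")
}

# Fit a model of the requested kind and return a scoring closure
# (higher score = more case-like).
.fit_scorer <- function(kind, x, y, case_level, knn_k = 5L) {
  ctrl <- setdiff(levels(y), case_level)
  switch(kind,
    logistic = {
      dat <- data.frame(.y = as.integer(y == case_level), x,
                        check.names = FALSE)
      fit <- suppressWarnings(
        stats::glm(.y ~ ., data = dat, family = stats::binomial()))
      function(newx) as.numeric(stats::predict(
        fit, newdata = as.data.frame(newx, check.names = FALSE),
        type = "response"))
    },
    svm = {
      fit <- e1071::svm(x, y, kernel = "radial", probability = TRUE)
      function(newx) {
        pr <- attr(stats::predict(fit, newx, probability = TRUE),
                   "probabilities")
        as.numeric(pr[, case_level])
      }
    },
    knn = {
      function(newx) {
        pred <- class::knn(x, newx, cl = y, k = knn_k, prob = TRUE)
        pwin <- attr(pred, "prob")
        ifelse(pred == case_level, pwin, 1 - pwin)
      }
    },
    rf = {
      fit <- randomForest::randomForest(x, y)
      function(newx) as.numeric(
        stats::predict(fit, newx, type = "prob")[, case_level])
    },
    stop("unknown model kind: ", kind))
}

.stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Evaluate a biomarker panel under the split + repeated-CV protocol
#'
#' Splits samples into training and test sets (stratified by class when
#' the protocol says so), estimates model performance by repeated
#' stratified k-fold cross-validation on the training set only, refits the
#' model on the full training set, and reports a single ROC on the
#' untouched test set. Missing feature values are mean-imputed using
#' training-data means only (per fold inside the CV, training-set means for
#' the final model).
#'
#' @param x Samples x features numeric matrix.
#' @param labels Two-class labels.
#' @param protocol A [cv_protocol()].
#' @param model \code{"logistic"} (default), \code{"svm"}, \code{"knn"} or
#'   \code{"rf"}.
#' @param case_level See [roc_auc()].
#' @param knn_k Neighbours for the kNN model.
#' @return Object of class \code{"pep_protocol_result"}: \code{test_roc} (a
#'   [roc_auc()] result on the test set), \code{cv_auc} (mean CV AUC on the
#'   training set), \code{cv_aucs} (per fold x repeat), \code{train_idx},
#'   \code{test_idx}, \code{model}, \code{protocol}.
#' @export
evaluate_protocol <- function(x, labels, protocol = cv_protocol(),
                              model = c("logistic", "svm", "knn", "rf"),
                              case_level = NULL, knn_k = 5L) {
  model <- match.arg(model)
  stopifnot(inherits(protocol, "cv_protocol"),
            is.matrix(x), nrow(x) == length(labels))
  case_level <- .case_level(labels, case_level)
  y <- factor(as.character(labels))
  if (min(table(y)) < protocol$folds)
    stop("smallest class (n = ", min(table(y)),
         ") cannot populate ", protocol$folds,
         " folds; use fewer folds")

  impute_means <- function(train_x) {
    mu <- colMeans(train_x, na.rm = TRUE)
    mu[is.na(mu)] <- 0
    mu
  }
  apply_impute <- function(m, mu) {
    for (j in seq_len(ncol(m))) {
      miss <- is.na(m[, j])
      if (any(miss)) m[miss, j] <- mu[j]
    }
    m
  }

  with_seed(protocol$seed, {
    n <- nrow(x)
    if (protocol$stratified) {
      train_idx <- sort(unlist(lapply(levels(y), function(lv) {
        idx <- which(y == lv)
        sample(idx, round(protocol$train_frac * length(idx)))
      })))
    } else {
      train_idx <- sort(sample(n, round(protocol$train_frac * n)))
    }
    test_idx <- setdiff(seq_len(n), train_idx)
    xtr <- x[train_idx, , drop = FALSE]; ytr <- droplevels(y[train_idx])
    xte <- x[test_idx, , drop = FALSE]; yte <- y[test_idx]

    cv_aucs <- c()
    for (rep_i in seq_len(protocol$repeats)) {
      fold <- .stratified_folds(ytr, protocol$folds)
      for (f in seq_len(protocol$folds)) {
        in_val <- fold == f
        if (length(unique(ytr[in_val])) < 2) next
        mu <- impute_means(xtr[!in_val, , drop = FALSE])
        scorer <- .fit_scorer(model,
                              apply_impute(xtr[!in_val, , drop = FALSE], mu),
                              droplevels(ytr[!in_val]), case_level, knn_k)
        sc <- scorer(apply_impute(xtr[in_val, , drop = FALSE], mu))
        cv_aucs <- c(cv_aucs, roc_auc(sc, ytr[in_val], case_level)$auc)
      }
    }

    mu <- impute_means(xtr)
    scorer <- .fit_scorer(model, apply_impute(xtr, mu), ytr, case_level,
                          knn_k)
    test_scores <- scorer(apply_impute(xte, mu))
    test_roc <- roc_auc(test_scores, yte, case_level)
    structure(list(test_roc = test_roc, cv_auc = mean(cv_aucs),
                   cv_aucs = cv_aucs, train_idx = train_idx,
                   test_idx = test_idx, test_scores = test_scores,
                   model = model, protocol = protocol,
                   case_level = case_level),
              class = "pep_protocol_result")
  })
}

#' @export
print.pep_protocol_result <- function(x, ...) {
  cat(sprintf(
    "Panel evaluation (%s, %d/%d split, %d-fold CV x %d)\n",
    x$model, round(100 * x$protocol$train_frac),
    round(100 * (1 - x$protocol$train_frac)),
    x$protocol$folds, x$protocol$repeats))
  cat(sprintf("  training CV AUC: %.3f\n", x$cv_auc))
  cat(sprintf("  held-out test AUC: %.3f\n", x$test_roc$auc))
  invisible(x)
}

#' ROC within confounder subgroups
#'
#' Scores are computed once (from a fitted panel or supplied directly);
#' within every level of a metadata field the ROC is recomputed using that
#' level's cases and controls. Levels missing a class are reported as
#' skipped, not evaluated.
#'
#' @param scores Numeric scores per sample, or a \code{"pep_panel"} (then
#'   \code{x} must be given).
#' @param labels Two-class labels per sample.
#' @param metadata Data frame aligned with the samples.
#' @param field Metadata column to subgroup by (e.g. \code{"copd_grade"},
#'   \code{"sex"}, \code{"bmi_class"}, \code{"smoking_class"}).
#' @param x Feature matrix, needed only when \code{scores} is a panel.
#' @param case_level See [roc_auc()].
#' @return List: \code{by_level} (named list of [roc_auc()] results),
#'   \code{skipped} (levels lacking a class), \code{overall}.
#' @export
subgroup_roc <- function(scores, labels, metadata, field, x = NULL,
                         case_level = NULL) {
  if (inherits(scores, "pep_panel")) {
    stopifnot(!is.null(x))
    scores <- as.numeric(predict(scores, x, type = "response"))
  }
  stopifnot(is.data.frame(metadata), field %in% names(metadata),
            nrow(metadata) == length(scores),
            length(labels) == length(scores))
  case_level <- .case_level(labels, case_level)
  lv <- unique(as.character(metadata[[field]]))
  lv <- lv[!is.na(lv)]
  by_level <- list(); skipped <- character()
  for (l in lv) {
    idx <- which(metadata[[field]] == l)
    if (length(unique(as.character(labels[idx]))) < 2) {
      skipped <- c(skipped, l)
      next
    }
    by_level[[l]] <- roc_auc(scores[idx], labels[idx], case_level)
  }
  list(by_level = by_level, skipped = skipped,
       overall = roc_auc(scores, labels, case_level))
}
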