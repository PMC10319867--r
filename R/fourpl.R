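#' Four-parameter logistic (4PL) Hill-slope model
#'
#' \deqn{y = d + (a - d) / (1 + (x / c)^b)}
#' with upper asymptote \code{a}, lower asymptote \code{d}, inflection
#' (EC50/IC50) \code{c} in the units of \code{x}, and Hill slope \code{b}.
#'
#' @param x Dose / dilution (positive).
#' @param a,b,c,d Model parameters; \code{c > 0}.
#' @return Predicted response.
#' @export
fourpl <- function(x, a, b, c, d) d + (a - d) / (1 + (x / c)^b)

#' Fit the 4PL model to an inhibition or competition curve
#'
#' Nonlinear least squares on the log10-dose axis (dose-response series
#' span decades, so curvature is balanced there). Initialization is fixed
#' and deterministic: \code{a = max(y)}, \code{d = min(y)},
#' \code{c =} geometric mean of \code{x}, \code{b = 1}, with a second start
#' at \code{b = -1}; the better converged fit wins. The fitted parameters
#' are canonicalized to \code{a >= d} (swapping asymptotes and negating
#' \code{b} leaves the curve unchanged). \code{r2} is
#' \code{1 - SSres/SStot} on the response scale; a fit that fails to
#' converge is flagged with \code{r2 = -Inf} so it can never pass a
#' qualification gate.
#'
#' @param x Doses / competitor dilutions (> 0, >= 4 distinct values).
#' @param y Responses (e.g. Vmax in mOD/min, or RLU).
#' @return Object of class \code{"pep_4pl"}: list with \code{coefficients}
#'   (a, b, c, d), \code{r2}, \code{r2_loglinear} (R^2 of a straight line in
#'   log10(x), reported for transparency), \code{converged}, \code{fitted},
#'   \code{data}.
#' @examples
#' x <- c(10, 30, 100, 300, 1000)
#' y <- fourpl(x, a = 100, b = 1, c = 100, d = 0)
#' coef(fit_4pl(x, y))
#' @export
fit_4pl <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (any(x <= 0)) stop("doses must be positive (fit is on the log axis)")
  if (length(unique(x)) < 4)
    stop("need >= 4 distinct doses to fit 4 parameters")

  u <- log10(x)
  sstot <- sum((y - mean(y))^2)
  # residuals parameterized in (a, d, log10 c, b)
  resid_fn <- function(p) y - (p[2] + (p[1] - p[2]) / (1 + 10^(p[4] * (u - p[3]))))
  starts <- list(c(max(y), min(y), mean(u), 1),
                 c(max(y), min(y), mean(u), -1))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    return(structure(list(coefficients = c(a = NA, b = NA, c = NA, d = NA),
                          r2 = -Inf, r2_loglinear = NA_real_,
                          converged = FALSE, fitted = rep(NA_real_, length(y)),
                          data = data.frame(x = x, y = y)),
                     class = "pep_4pl"))
  }
  p <- best$fit$par
  a <- p[1]; d <- p[2]; c_ <- 10^p[3]; b <- p[4]
  if (a < d) { tmp <- a; a <- d; d <- tmp; b <- -b }   # canonical a >= d
  fitted <- fourpl(x, a, b, c_, d)
  r2 <- if (sstot > 0) 1 - sum((y - fitted)^2) / sstot else -Inf
  ll <- stats::lm(y ~ u)
  r2_ll <- if (sstot > 0) summary(ll)$r.squared else NA_real_
  converged <- best$fit$info %in% 1:4
  structure(list(coefficients = c(a = a, b = b, c = c_, d = d),
                 r2 = if (converged) r2 else -Inf,
                 r2_loglinear = r2_ll, converged = converged,
                 fitted = fitted, data = data.frame(x = x, y = y)),
            class = "pep_4pl")
}

#' @method coef pep_4pl
#' @export
coef.pep_4pl <- function(object, ...) object$coefficients

#' @export
predict.pep_4pl <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else
    if (is.data.frame(newdata)) newdata$x else newdata
  p <- object$coefficients
  fourpl(x, p["a"], p["b"], p["c"], p["d"])
}

#' @export
print.pep_4pl <- function(x, ...) {
  cat("4PL Hill-slope fit\n")
  if (x$converged) {
    p <- x$coefficients
    cat(sprintf("  a = %.4g  b = %.4g  c = %.4g  d = %.4g\n",
                p["a"], p["b"], p["c"], p["d"]))
    cat(sprintf("  R^2 = %.4f (log-linear R^2 = %.4f)\n",
                x$r2, x$r2_loglinear))
  } else cat("  fit did not converge (R^2 = -Inf)\n")
  invisible(x)
}

#' @method residuals pep_4pl
#' @export
residuals.pep_4pl <- function(object, ...) object$data$y - object$fitted

#' Qualify a mAb from its inhibition-curve fit
#'
#' A mAb qualifies for biochip use when its single-binder capture inhibition
#' curve is well described by the 4PL model: strictly \code{r2 > threshold}
#' (default 0.9). A flagged non-converged fit (\code{r2 = -Inf}) is always
#' rejected.
#'
#' @param fit A \code{"pep_4pl"} fit (or anything with an \code{r2} field).
#' @param threshold R-squared gate.
#' @return \code{"qualified"} or \code{"rejected"}.
#' @export
qualify_mab <- function(fit, threshold = 0.9) {
  r2 <- if (inherits(fit, "pep_4pl")) fit$r2 else as.numeric(fit)
  if (is.na(r2)) return("rejected")
  if (r2 > threshold) "qualified" else "rejected"
}

#' Assign qualified mAbs to the QP69 / QP300 libraries
#'
#' mAbs qualifying with the total-plasma tracer join the abundant-protein
#' QP69 library; those qualifying with the depleted-plasma tracer join the
#' medium-abundance QP300 library. A mAb qualifying with both tracers is
#' assigned to both and flagged.
#'
#' @param qualification Data frame with columns \code{mab_id},
#'   \code{tracer_kind} (\code{"total_plasma"} / \code{"depleted_plasma"})
#'   and \code{qualified} (logical or "qualified"/"rejected").
#' @return List with \code{QP69}, \code{QP300} (character vectors) and
#'   \code{dual} (mAbs in both).
#' @export
assign_library <- function(qualification) {
  stopifnot(all(c("mab_id", "tracer_kind", "qualified") %in%
                  names(qualification)))
  q <- qualification
  if (!is.logical(q$qualified)) q$qualified <- q$qualified == "qualified"
  ok <- q[q$qualified, ]
  qp69 <- unique(ok$mab_id[ok$tracer_kind == "total_plasma"])
  qp300 <- unique(ok$mab_id[ok$tracer_kind == "depleted_plasma"])
  list(QP69 = qp69, QP300 = qp300, dual = intersect(qp69, qp300))
}

#' Simulate 4PL inhibition curves
#'
#' Noise-free responses are exactly the 4PL model evaluated at the dilution
#' series; optional multiplicative log-normal noise with fractional CV
#' \code{cv} is applied per point.
#'
#' @param params Data frame with columns \code{mab_id}, \code{a}, \code{b},
#'   \code{c}, \code{d} (one row per mAb / curve).
#' @param dilutions Positive competitor dilution series.
#' @param cv Fractional CV of the multiplicative noise (0 = noise free).
#' @param seed Integer seed.
#' @return Data frame \code{mab_id}, \code{dilution}, \code{response}.
#' @export
generate_inhibition_curves <- function(params, dilutions, cv = 0, seed = 1L) {
  stopifnot(is.data.frame(params),
            all(c("mab_id", "a", "b", "c", "d") %in% names(params)))
  if (any(dilutions <= 0)) stop("dilutions must be positive")
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      y <- fourpl(dilutions, p$a, p$b, p$c, p$d)
      data.frame(mab_id = p$mab_id, dilution = dilutions,
                 response = y * lnorm_factor(length(y), cv),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Maximal slope of a kinetic colorimetric trace
#'
#' Helper for synthetic kinetic reads only: estimates Vmax as the largest
#' slope over a sliding window of the absorbance-vs-time trace.
#'
#' @param time,absorbance Numeric vectors.
#' @param window Number of consecutive points per local regression.
#' @return Vmax (units of absorbance per unit time).
#' @export
vmax_from_trace <- function(time, absorbance, window = 5L) {
  stopifnot(length(time) == length(absorbance), window >= 2,
            length(time) >= window)
  slopes <- vapply(seq_len(length(time) - window + 1L), function(i) {
    idx <- i:(i + window - 1L)
    stats::coef(stats::lm(absorbance[idx] ~ time[idx]))[2]
  }, numeric(1))
  max(slopes)
}
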