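#' Two-state (conformation change) binding parameters
#'
#' The two-state SPR model: analyte A binds ligand L with rates
#' \code{ka1} (1/(M s)) / \code{kd1} (1/s), and the encounter complex AL
#' isomerizes to AL* with rates \code{ka2} / \code{kd2} (both 1/s).
#' \code{Rmax} is the saturating response in resonance units (RU).
#'
#' @param ka1,kd1,ka2,kd2 Rate constants (>= 0).
#' @param Rmax Maximal response (RU, > 0).
#' @return Object of class \code{"two_state_params"}.
#' @export
two_state_params <- function(ka1, kd1, ka2, kd2, Rmax = 100) {
  stopifnot(ka1 >= 0, kd1 >= 0, ka2 >= 0, kd2 >= 0, Rmax > 0,
            all(is.finite(c(ka1, kd1, ka2, kd2, Rmax))))
  structure(list(ka1 = ka1, kd1 = kd1, ka2 = ka2, kd2 = kd2, Rmax = Rmax),
            class = "two_state_params")
}

#' Apparent affinity and dissociation constants of the two-state model
#'
#' \deqn{K = (ka_1 / kd_1) (1 + ka_2 / kd_2), \qquad K_D = 1 / K.}
#' At \code{ka2 = 0} this reduces exactly to the 1:1 Langmuir affinity
#' \code{ka1/kd1}.
#'
#' @param params A [two_state_params()].
#' @return List: \code{K} (1/M), \code{K_D} (M).
#' @examples
#' apparent_K(two_state_params(ka1 = 1e5, kd1 = 1e-3, ka2 = 1e-3,
#'                             kd2 = 1e-3))
#' @export
apparent_K <- function(params) {
  stopifnot(inherits(params, "two_state_params"))
  if (params$kd1 == 0 || params$kd2 == 0)
    stop("kd1 and kd2 must be positive for the apparent K to be defined")
  K <- (params$ka1 / params$kd1) * (1 + params$ka2 / params$kd2)
  list(K = K, K_D = 1 / K)
}

# Closed-form solution of the two-state system at constant analyte
# concentration C: the ODE is linear, x' = A x + b with
#   x = (AL, AL*),
#   A = [ -(ka1 C + kd1 + ka2),  kd2 - ka1 C ;  ka2, -kd2 ],
#   b = (ka1 C Rmax, 0).
# The 2x2 matrix exponential is evaluated analytically from the eigenvalues
# (Putzer's form), including the defective repeated-eigenvalue case that
# arises e.g. at ka2 = 0 with kd1 = kd2. Complex-conjugate eigenvalues give
# a real trajectory, so Re() is taken at the end.
.two_state_segment <- function(p, C, x0, times) {
  A <- matrix(c(-(p$ka1 * C + p$kd1 + p$ka2), p$ka2,
                p$kd2 - p$ka1 * C, -p$kd2), 2, 2)
  b <- c(p$ka1 * C * p$Rmax, 0)
  xss <- if (all(b == 0)) c(0, 0) else as.numeric(solve(A, -b))
  v <- x0 - xss
  tr <- A[1, 1] + A[2, 2]
  disc <- sqrt(as.complex(tr^2 - 4 * (A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1])))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  if (abs(l1 - l2) > 1e-9 * max(abs(l1), abs(l2), 1e-300)) {
    # exp(At) v = e^{l1 t} u1 + e^{l2 t} u2
    u1 <- (A %*% v - l2 * v) / (l1 - l2)
    u2 <- -(A %*% v - l1 * v) / (l1 - l2)
    out <- exp(outer(times, c(l1))) %*% t(u1) +
      exp(outer(times, c(l2))) %*% t(u2)
  } else {
    # defective: exp(At) v = e^{l t} (v + t (A - l I) v)
    w <- A %*% v - l1 * v
    E <- exp(times * l1)
    out <- E %*% t(v) + (times * E) %*% t(w)
  }
  Re(out) + matrix(xss, length(times), 2, byrow = TRUE)
}

#' Simulate a two-state sensorgram
#'
#' Integrates the two-state binding system
#' \deqn{d[AL]/dt = ka_1 C (R_{max} - AL - AL^*) - kd_1 AL - ka_2 AL + kd_2 AL^*}
#' \deqn{d[AL^*]/dt = ka_2 AL - kd_2 AL^*}
#' with response \code{AL + AL*}, analyte concentration \code{C} held
#' constant during the association phase and zero during dissociation.
#' With constant C the system is linear, so the trajectory is evaluated in
#' closed form (matrix exponential); no step-size error is incurred.
#'
#' @param params A [two_state_params()].
#' @param conc Analyte concentration (M, >= 0).
#' @param t_assoc,t_dissoc Durations (s) of the association and dissociation
#'   phases (> 0).
#' @param step Sampling interval (s).
#' @param noise_sd Additive white noise in RU (0 = ideal trace).
#' @param seed Seed for the noise (ignored when \code{noise_sd = 0}).
#' @return Data frame: \code{time}, \code{response} (RU), \code{phase}
#'   (\code{"association"}/\code{"dissociation"}), \code{conc}.
#' @export
simulate_two_state <- function(params, conc, t_assoc = 180, t_dissoc = 120,
                               step = 1, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(params, "two_state_params"), conc >= 0,
            t_assoc > 0, t_dissoc > 0, step > 0, noise_sd >= 0)
  ta <- seq(0, t_assoc, by = step)
  td <- seq(step, t_dissoc, by = step)
  xa <- .two_state_segment(params, conc, c(0, 0), ta)
  xd <- .two_state_segment(params, 0, xa[nrow(xa), ], td)
  out <- data.frame(
    time = c(ta, t_assoc + td),
    response = c(rowSums(xa), rowSums(xd)),
    phase = rep(c("association", "dissociation"), c(length(ta), length(td))),
    conc = conc, stringsAsFactors = FALSE)
  if (noise_sd > 0)
    out$response <- out$response +
      with_seed(seed, stats::rnorm(nrow(out), 0, noise_sd))
  out
}

#' Simulate a concentration series of sensorgrams
#'
#' One trace per analyte concentration (the conventional series is 666,
#' 266, 133, 66, 27 and 13 nM).
#'
#' @inheritParams simulate_two_state
#' @param concs Analyte concentrations (M, > 0).
#' @return Data frame with a \code{trace_id} column in addition to the
#'   [simulate_two_state()] columns.
#' @export
generate_sensorgrams <- function(params,
                                 concs = c(666, 266, 133, 66, 27, 13) * 1e-9,
                                 t_assoc = 180, t_dissoc = 120, step = 1,
                                 noise_sd = 0, seed = 1L) {
  if (any(concs <= 0)) stop("concentrations must be positive")
  out <- do.call(rbind, lapply(seq_along(concs), function(i) {
    tr <- simulate_two_state(params, concs[i], t_assoc, t_dissoc, step,
                             noise_sd, seed = seed + i)
    tr$trace_id <- sprintf("trace_%02d", i)
    tr
  }))
  rownames(out) <- NULL
  out
}

#' Fit the two-state model to a sensorgram series
#'
#' Global nonlinear least squares over all traces simultaneously (default),
#' or per-concentration fits whose apparent K values are averaged. Rate
#' constants are optimized on the log scale from a fixed multi-start grid,
#' so the fit is deterministic. The apparent affinity and \code{K_D} are
#' derived from the fitted rates via [apparent_K()].
#'
#' @param sensorgrams Data frame from [generate_sensorgrams()] (columns
#'   \code{trace_id}, \code{conc}, \code{time}, \code{response},
#'   \code{phase}); >= 3 concentrations, both phases present.
#' @param mode \code{"global"} or \code{"per_conc"}.
#' @return Object of class \code{"pep_two_state"}: \code{params} (a
#'   [two_state_params()]), \code{K}, \code{K_D}, \code{sse},
#'   \code{converged}, \code{mode}, and for per-concentration fits
#'   \code{K_values} (one per trace).
#' @export
fit_two_state <- function(sensorgrams, mode = c("global", "per_conc")) {
  mode <- match.arg(mode)
  need <- c("trace_id", "conc", "time", "response", "phase")
  stopifnot(all(need %in% names(sensorgrams)))
  traces <- split(sensorgrams, sensorgrams$trace_id)
  if (length(unique(sensorgrams$conc)) < 3)
    stop("need >= 3 analyte concentrations")
  if (!all(c("association", "dissociation") %in% sensorgrams$phase))
    stop("both association and dissociation phases are required")

  predict_trace <- function(p, tr) {
    ia <- tr$phase == "association"
    ta <- tr$time[ia]; td <- tr$time[!ia]
    xa <- .two_state_segment(p, tr$conc[1], c(0, 0), ta)
    t0 <- max(ta)
    xd <- .two_state_segment(p, 0, xa[nrow(xa), ], td - t0)
    c(rowSums(xa), rowSums(xd))
  }
  resid_all <- function(theta, trs) {
    p <- list(ka1 = exp(theta[1]), kd1 = exp(theta[2]),
              ka2 = exp(theta[3]), kd2 = exp(theta[4]),
              Rmax = exp(theta[5]))
    unlist(lapply(trs, function(tr) tr$response - predict_trace(p, tr)))
  }
  fit_traces <- function(trs) {
    rmax0 <- max(sensorgrams$response) * 1.1
    grid <- expand.grid(ka1 = c(1e4, 1e5, 1e6), kd1 = c(1e-3, 1e-2),
                        ka2 = c(1e-3, 1e-2), kd2 = c(1e-3, 1e-2))
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      theta0 <- log(c(grid$ka1[g], grid$kd1[g], grid$ka2[g], grid$kd2[g],
                      rmax0))
      fit <- tryCatch(minpack.lm::nls.lm(
        par = theta0, fn = resid_all, trs = trs,
        control = minpack.lm::nls.lm.control(maxiter = 150)),
        error = function(e) NULL)
      if (is.null(fit)) next
      sse <- sum(fit$fvec^2)
      if (is.null(best) || sse < best$sse)
        best <- list(fit = fit, sse = sse)
    }
    best
  }

  if (mode == "global") {
    best <- fit_traces(traces)
    if (is.null(best))
      return(structure(list(params = NULL, K = NA_real_, K_D = NA_real_,
                            sse = Inf, converged = FALSE, mode = mode),
                       class = "pep_two_state"))
    th <- best$fit$par
    p <- two_state_params(exp(th[1]), exp(th[2]), exp(th[3]), exp(th[4]),
                          exp(th[5]))
    kk <- apparent_K(p)
    structure(list(params = p, K = kk$K, K_D = kk$K_D, sse = best$sse,
                   converged = best$fit$info %in% 1:4, mode = mode),
              class = "pep_two_state")
  } else {
    fits <- lapply(traces, function(tr) fit_traces(list(tr)))
    ok <- !vapply(fits, is.null, logical(1))
    K_values <- vapply(fits[ok], function(b) {
      th <- b$fit$par
      apparent_K(two_state_params(exp(th[1]), exp(th[2]), exp(th[3]),
                                  exp(th[4]), exp(th[5])))$K
    }, numeric(1))
    K <- mean(K_values)
    structure(list(params = NULL, K = K, K_D = 1 / K,
                   K_values = K_values,
                   sse = sum(vapply(fits[ok], `[[`, numeric(1), "sse")),
                   converged = any(ok), mode = mode),
              class = "pep_two_state")
  }
}

#' @export
print.pep_two_state <- function(x, ...) {
  cat("Two-state SPR fit (", x$mode, ")\n", sep = "")
  if (!x$converged) {
    cat("  fit did not converge\n")
    return(invisible(x))
  }
  if (!is.null(x$params))
    cat(sprintf("  ka1 = %.3g 1/(M s)  kd1 = %.3g 1/s  ka2 = %.3g 1/s  kd2 = %.3g 1/s  Rmax = %.3g RU\n",
                x$params$ka1, x$params$kd1, x$params$ka2, x$params$kd2,
                x$params$Rmax))
  cat(sprintf("  apparent K = %.3g 1/M, K_D = %.3g M\n", x$K, x$K_D))
  invisible(x)
}

#' @method coef pep_two_state
#' @export
coef.pep_two_state <- function(object, ...) {
  if (is.null(object$params)) return(c(K = object$K, K_D = object$K_D))
  unlist(object$params)
}

#' Competition IC50 from a sigmoidal fit
#'
#' Fits the 4PL sigmoid to the competition signal (response at the start of
#' the dissociation phase) versus competitor level, on the log-level axis,
#' and reads the IC50 from the inflection. Non-positive competitor levels
#' cannot sit on the log axis and are dropped before fitting. The IC50 is
#' flagged \code{extrapolated} when it falls outside the tested range, and
#' \code{no_inhibition} when the fitted curve does not decrease over the
#' tested range.
#'
#' @param level Competitor level (percent plasma or molar ratio).
#' @param signal Competition signal (RU).
#' @return Object of class \code{"pep_ic50"}: \code{ic50}, \code{fit} (the
#'   [fit_4pl()] object), \code{extrapolated}, \code{no_inhibition},
#'   \code{n_dropped} (non-positive levels removed).
#' @export
fit_ic50 <- function(level, signal) {
  stopifnot(length(level) == length(signal))
  keep <- level > 0
  n_dropped <- sum(!keep)
  level <- level[keep]; signal <- signal[keep]
  if (length(unique(level)) < 4)
    stop("need >= 4 distinct positive competitor levels")
  fit <- fit_4pl(level, signal)
  p <- coef(fit)
  ic50 <- as.numeric(p["c"])
  decreasing <- fit$converged &&
    fourpl(max(level), p["a"], p["b"], p["c"], p["d"]) <
    fourpl(min(level), p["a"], p["b"], p["c"], p["d"]) - 1e-9
  structure(list(ic50 = if (fit$converged) ic50 else NA_real_, fit = fit,
                 extrapolated = fit$converged &&
                   (ic50 < min(level) || ic50 > max(level)),
                 no_inhibition = !decreasing, n_dropped = n_dropped),
            class = "pep_ic50")
}

#' @export
print.pep_ic50 <- function(x, ...) {
  if (x$no_inhibition) {
    cat("Competition fit: no inhibition detected\n")
  } else {
    cat(sprintf("Competition IC50 = %.4g%s\n", x$ic50,
                if (x$extrapolated) " (extrapolated)" else ""))
  }
  invisible(x)
}
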