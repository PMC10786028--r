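# Stretched-exponential exchange kinetics: D(t) = A * (1 - exp(-(k_obs t)^beta)).
# beta = 1 is a single exponential; beta < 1 models rate heterogeneity among
# the amides contributing to one peptide envelope.

#' Stretched-exponential uptake model
#'
#' `D(t) = A * (1 - exp(-(k_obs * t)^beta))`. At `t = 0` the uptake is 0; the
#' curve is monotone non-decreasing and approaches the plateau `A`.
#'
#' @param t Time(s) in seconds, `>= 0`.
#' @param A Plateau amplitude (relative-uptake units).
#' @param k_obs Observed exchange rate in 1/s.
#' @param beta Stretching exponent in (0, 1].
#' @return Predicted relative uptake, same length as `t`.
#' @export
stretched_exp <- function(t, A, k_obs, beta) {
  A * (1 - exp(-(k_obs * t)^beta))
}

#' Fit a stretched exponential to an uptake time course
#'
#' Nonlinear least squares (Levenberg-Marquardt) with multi-start over
#' log-spaced `k_obs` values and two `beta` starts, keeping the best-RSS fit.
#' `k_obs` is optimized on a log10 scale for stability across the many-decade
#' time window. Bounds: `A` in (0, 1.2], `k_obs` in \[1e-8, 1e3\] 1/s, `beta`
#' in (0, 1]. Ties in RSS break toward the lower `k_obs`.
#'
#' A series with no measurable exchange (all uptakes ~ 0) is reported with
#' `k_obs` at the lower bound and `converged = FALSE` rather than an error.
#'
#' @param times Exposure times in seconds (`>= 4` points; a span of more than
#'   one decade is recommended and warned about otherwise).
#' @param uptakes Relative uptake values, same length as `times`.
#' @param weights Optional fitting weights (e.g. `1/sd^2`); default unweighted.
#' @param k_starts Multi-start grid for `k_obs` (1/s).
#' @param beta_starts Multi-start values for `beta`.
#' @return An object of class `hdx_fit` with components `estimate`
#'   (named: `A`, `k_obs`, `beta`), `rss`, `converged`, `flat`, `n_points`,
#'   plus the data for the `predict`/`residuals` methods.
#' @export
fit_stretched_exponential <- function(times, uptakes, weights = NULL,
                                      k_starts = c(1e-6, 1e-4, 1e-2, 1, 1e2),
                                      beta_starts = c(0.5, 1.0)) {
  stopifnot(length(times) == length(uptakes))
  ok <- is.finite(times) & is.finite(uptakes)
  times <- times[ok]; uptakes <- uptakes[ok]
  if (!is.null(weights)) weights <- weights[ok]
  if (length(times) < 4L)
    stop("need at least 4 (time, uptake) pairs, got ", length(times))
  pos <- times > 0
  if (any(pos) && diff(range(log10(times[pos]))) <= 1)
    warning("time points span <= 1 decade; rate estimates may be poorly determined")

  new_fit <- function(est, rss, converged, flat) {
    structure(list(estimate = est, rss = rss, converged = converged,
                   flat = flat, n_points = length(times),
                   times = times, uptakes = uptakes, weights = weights),
              class = "hdx_fit")
  }

  if (max(abs(uptakes)) < 1e-6)  # no exchange observed
    return(new_fit(c(A = 1e-6, k_obs = 1e-8, beta = 1), rss = sum(uptakes^2),
                   converged = FALSE, flat = TRUE))

  df <- data.frame(t = times, u = uptakes)
  w <- if (is.null(weights)) rep(1, nrow(df)) else weights
  A0 <- min(1.2, max(0.05, max(uptakes)))
  best <- NULL
  for (k0 in k_starts) for (b0 in beta_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(u ~ A * (1 - exp(-(10^lk * t)^beta)), data = df,
                        start = list(A = A0, lk = log10(k0), beta = b0),
                        lower = c(A = 1e-8, lk = -8, beta = 1e-3),
                        upper = c(A = 1.2, lk = 3, beta = 1),
                        weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    p <- coef(fit)
    rss <- sum((df$u - stretched_exp(df$t, p[["A"]], 10^p[["lk"]], p[["beta"]]))^2)
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && 10^p[["lk"]] < best$k)) {
      best <- list(rss = rss, A = p[["A"]], k = 10^p[["lk"]], beta = p[["beta"]])
    }
  }
  if (is.null(best))  # no start converged
    return(new_fit(c(A = A0, k_obs = 1e-8, beta = 1),
                   rss = sum(uptakes^2), converged = FALSE, flat = FALSE))
  new_fit(c(A = best$A, k_obs = best$k, beta = best$beta), rss = best$rss,
          converged = TRUE, flat = FALSE)
}

#' Classify a fitted peptide or residue as a slow exchanger
#'
#' A series is slow when its fitted rate is below `threshold`, when the fit
#' failed on a flat (no-exchange) series, or when the fitted plateau is below
#' `min_amplitude`: on noisy near-flat data least squares happily explains the
#' noise with a tiny fast exponential, and `k_obs` is meaningless when
#' essentially no exchange occurred within the observation window.
#'
#' @param fit An `hdx_fit`.
#' @param threshold Rate threshold in 1/s (default `1e-5`).
#' @param min_amplitude Plateau floor in relative-uptake units (default 0.05).
#' @return Logical.
#' @export
classify_slow <- function(fit, threshold = 1e-5, min_amplitude = 0.05) {
  unname(fit$estimate["k_obs"] < threshold ||
           (!fit$converged && fit$flat) ||
           fit$estimate["A"] < min_amplitude)
}

#' Fit stretched exponentials across a table of time courses
#'
#' Fits each (peptide, state) — or (residue, state) — time course and collects
#' the parameters in one table.
#'
#' @param x `hdx_peptide_means` (from [average_replicates()]) or
#'   `hdx_residue_profiles` (from [peptide_to_residue()]).
#' @param weighted If `TRUE`, weight each point by `1/sd^2` (points with
#'   missing or zero SD get the median weight).
#' @param slow_threshold Passed to [classify_slow()].
#' @return Data.frame (class `hdx_fit_table`): `id`, `state`, `A`, `k_obs`,
#'   `beta`, `rss`, `converged`, `n_points`, `slow`.
#' @export
fit_kinetics <- function(x, weighted = FALSE, slow_threshold = 1e-5) {
  if (inherits(x, "hdx_residue_profiles")) {
    id <- as.character(x$residue); val <- x$rel_uptake; sdv <- x$sd_rel_uptake
  } else {
    id <- x$peptide_id; val <- x$rel_uptake; sdv <- x$sd_rel_uptake
  }
  key <- interaction(id, x$state, drop = TRUE)
  rows <- split(seq_along(id), key)
  out <- lapply(rows, function(ii) {
    w <- NULL
    if (weighted) {
      s <- sdv[ii]
      w <- 1 / s^2
      bad <- !is.finite(w)
      if (all(bad)) w <- NULL else w[bad] <- stats::median(w[!bad])
    }
    f <- suppressWarnings(fit_stretched_exponential(x$exposure_s[ii], val[ii], w))
    data.frame(id = id[ii][1L], state = x$state[ii][1L],
               A = f$estimate[["A"]], k_obs = f$estimate[["k_obs"]],
               beta = f$estimate[["beta"]], rss = f$rss,
               converged = f$converged, n_points = f$n_points,
               slow = classify_slow(f, slow_threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("hdx_fit_table", "data.frame")
  out
}

#' @export
print.hdx_fit <- function(x, ...) {
  cat("Stretched-exponential uptake fit: D(t) = A (1 - exp(-(k t)^beta))\n")
  cat(sprintf("  A      = %.4g\n  k_obs  = %.4g 1/s\n  beta   = %.4g\n",
              x$estimate[["A"]], x$estimate[["k_obs"]], x$estimate[["beta"]]))
  cat(sprintf("  RSS    = %.4g on %d points;%s converged\n", x$rss,
              x$n_points, if (x$converged) "" else " NOT"))
  if (x$flat) cat("  (flat series: no exchange observed)\n")
  invisible(x)
}

#' @export
coef.hdx_fit <- function(object, ...) object$estimate

#' @export
predict.hdx_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times
       else if (is.list(newdata)) newdata$t else newdata
  stretched_exp(t, object$estimate[["A"]], object$estimate[["k_obs"]],
                object$estimate[["beta"]])
}

#' @export
residuals.hdx_fit <- function(object, ...) object$uptakes - predict(object)

#' @export
fitted.hdx_fit <- function(object, ...) predict(object)
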