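#' Fit the strain--stiffness power law
#'
#' Fits the model \eqn{\varepsilon = a E^{b}} to a strain--stiffness
#' sweep, where `E` is the soft-tissue compressive stiffness (MPa) and
#' \eqn{\varepsilon} the simulated joint compressive strain. `a` is the
#' scaling coefficient (N/mm^2, interpretable as a mean contact stress)
#' and `b` the unitless power coefficient, stored signed and expected
#' negative (b = -1 in the flat-punch limit where the contact area does
#' not change; curved contact gives -1 < b < -2/3).
#'
#' Coefficients are obtained by Levenberg--Marquardt nonlinear least
#' squares on the original strain scale, initialized from an ordinary
#' least-squares fit of log(strain) on log(stiffness). The goodness of
#' fit is reported on the original scale,
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}.
#'
#' @param sweep A sweep table: data.frame with numeric columns
#'   `stiffness_mpa` and `strain` (rows with `NA` strain, e.g.
#'   non-converged solver runs, are dropped before fitting).
#' @return An object of class `power_law_fit`: list with elements `a`,
#'   `b` (signed), `r_squared`, `se` (named standard errors), `residuals`
#'   (original scale), `fitted`, `n`, `data`.
#' @export
#' @examples
#' tab <- data.frame(stiffness_mpa = c(1, 2, 3, 5, 10, 15, 20, 25, 30, 50))
#' tab$strain <- 0.2279 * tab$stiffness_mpa^-0.8315
#' fit <- fit_power_law(tab)
#' c(fit$a, fit$b, fit$r_squared)
fit_power_law <- function(sweep) {
  if (!is.data.frame(sweep) ||
      !all(c("stiffness_mpa", "strain") %in% names(sweep))) {
    stop("`sweep` must be a data.frame with columns `stiffness_mpa` and `strain`")
  }
  tab <- sweep[is.finite(sweep$strain) & is.finite(sweep$stiffness_mpa), ,
               drop = FALSE]
  if (nrow(tab) < 3L) {
    stop("power-law fit needs at least 3 converged sweep rows, got ",
         nrow(tab))
  }
  if (any(tab$strain <= 0)) stop("all strains must be positive")
  if (any(tab$stiffness_mpa <= 0)) stop("all stiffness values must be positive")

  E <- tab$stiffness_mpa
  eps <- tab$strain

  # log-log OLS start values (exact when the data are noise-free)
  init <- stats::coef(stats::lm(log(eps) ~ log(E)))
  start <- list(a = exp(unname(init[1])), b = unname(init[2]))

  nfit <- minpack.lm::nlsLM(
    eps ~ a * E^b,
    start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  cf <- stats::coef(nfit)
  fitted_eps <- cf[["a"]] * E^cf[["b"]]
  res <- eps - fitted_eps
  ss_res <- sum(res^2)
  ss_tot <- sum((eps - mean(eps))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1

  # heteroscedasticity-consistent (HC3) standard errors: sweep noise is
  # multiplicative, so the residual variance concentrates in the
  # large-strain rows and the ordinary nls vcov understates the
  # uncertainty of the original-scale estimator
  se <- tryCatch({
    J <- cbind(E^cf[["b"]], fitted_eps * log(E))
    JtJi <- solve(crossprod(J))
    h <- rowSums((J %*% JtJi) * J)
    V <- JtJi %*% crossprod(J * (res / (1 - h)), J * (res / (1 - h))) %*% JtJi
    c(a = sqrt(V[1, 1]), b = sqrt(V[2, 2]))
  }, error = function(e) c(a = NA_real_, b = NA_real_))

  structure(
    list(a = cf[["a"]], b = cf[["b"]], r_squared = r2,
         se = c(a = unname(se["a"]), b = unname(se["b"])),
         residuals = res, fitted = fitted_eps, n = nrow(tab),
         data = tab[, c("stiffness_mpa", "strain")]),
    class = "power_law_fit"
  )
}

#' Construct a power-law fit from known coefficients
#'
#' Wraps externally supplied coefficients (for instance the published
#' subject-specific pairs, or the generalized cohort pair) in a
#' `power_law_fit` object so they can be used for prediction and
#' inversion without re-running the FEM sweep ("fit-bypass").
#'
#' @param a Scaling coefficient (N/mm^2), positive.
#' @param b Power coefficient, signed (negative for compressive contact).
#' @param r_squared Optional goodness of fit; `NA` when unknown.
#' @return A `power_law_fit`.
#' @export
power_law_fit <- function(a, b, r_squared = NA_real_) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0,
            is.numeric(b), length(b) == 1L, is.finite(b))
  structure(
    list(a = as.numeric(a), b = as.numeric(b),
         r_squared = as.numeric(r_squared),
         se = c(a = NA_real_, b = NA_real_),
         residuals = numeric(0), fitted = numeric(0), n = 0L,
         data = NULL),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("Strain-stiffness power law: strain = a * E^b\n")
  cat(sprintf("  a = %.4f N/mm^2   b = %.4f   R^2 = %s   (n = %d)\n",
              x$a, x$b,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              x$n))
  invisible(x)
}

#' Predict strain at a given stiffness
#'
#' Evaluates \eqn{\varepsilon = a E^{b}} (signed-`b` convention).
#'
#' @param fit A `power_law_fit`.
#' @param stiffness_mpa Stiffness values E (MPa), all positive.
#' @return Predicted strains (vectorized over `stiffness_mpa`).
#' @export
predict_strain <- function(fit, stiffness_mpa) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (any(!is.finite(stiffness_mpa)) || any(stiffness_mpa <= 0)) {
    stop("stiffness must be positive and finite")
  }
  fit$a * stiffness_mpa^fit$b
}

#' Estimate combined compressive stiffness from a measured strain
#'
#' Inverts the power law: \eqn{E = (\varepsilon / a)^{1/b}}. With the
#' generalized cohort coefficients this is the closed-form estimator
#' E = (eps / 0.2196)^(1 / -0.8495).
#'
#' @param fit A `power_law_fit` (subject-specific or generalized).
#' @param strain Measured compressive strain (ΔmBGFT / unloaded mBGFT),
#'   positive.
#' @param session Optional session identifier carried into the result.
#' @param source Provenance tag: `"subject-specific"` or `"generalized"`.
#' @return A `stiffness_estimate`: list with `session`, `strain`,
#'   `stiffness_mpa`, `source`, `fit`.
#' @export
#' @examples
#' gen <- power_law_fit(a = 0.2196, b = -0.8495)
#' estimate_stiffness(gen, strain = 0.11028)$stiffness_mpa
estimate_stiffness <- function(fit, strain, session = NA_character_,
                               source = "subject-specific") {
  stopifnot(inherits(fit, "power_law_fit"))
  if (!is.numeric(strain) || length(strain) != 1L || !is.finite(strain) ||
      strain <= 0) {
    stop("strain must be a single positive number")
  }
  E <- (strain / fit$a)^(1 / fit$b)
  structure(
    list(session = session, strain = strain, stiffness_mpa = E,
         source = source, fit = fit),
    class = "stiffness_estimate"
  )
}

#' @export
print.stiffness_estimate <- function(x, ...) {
  cat(sprintf("CCS estimate%s: E = %.4g MPa at strain %.5f (%s model)\n",
              if (is.na(x$session)) "" else paste0(" [", x$session, "]"),
              x$stiffness_mpa, x$strain, x$source))
  invisible(x)
}

#' Generalized cohort model from subject-specific fits
#'
#' Averages the subject-specific coefficients arithmetically:
#' \eqn{\bar a = \mathrm{mean}(a_i)}, \eqn{\bar b = \mathrm{mean}(b_i)}
#' (signed). The generalized R^2 is left unset.
#'
#' @param fits List of `power_law_fit` objects (at least one).
#' @return A `power_law_fit` with the averaged coefficients.
#' @export
generalized_model <- function(fits) {
  if (inherits(fits, "power_law_fit")) fits <- list(fits)
  if (length(fits) == 0L) stop("need at least one fit")
  ok <- vapply(fits, inherits, logical(1), what = "power_law_fit")
  if (!all(ok)) stop("all elements must be power_law_fit objects")
  if (length(fits) == 1L) return(fits[[1L]])
  power_law_fit(
    a = mean(vapply(fits, `[[`, numeric(1), "a")),
    b = mean(vapply(fits, `[[`, numeric(1), "b"))
  )
}

#' Cohort summary of stiffness estimates
#'
#' Aggregates per-session stiffness estimates into the cohort mean and
#' standard deviation, and computes intra-subject repeatability as the
#' absolute difference between a subject's two scan-session estimates.
#'
#' @param estimates Either a list of `stiffness_estimate` objects or a
#'   data.frame with columns `session` and `stiffness_mpa`.
#' @param subject_pairs Optional named list; each element is a character
#'   vector of two session identifiers belonging to one subject.
#' @param sd_type `"sample"` (n-1 denominator, default) or
#'   `"population"` (n denominator).
#' @return A `cohort_summary`: list with `estimates` (data.frame),
#'   `mean_mpa`, `sd_mpa` (`NA` for a single session),
#'   `intra_subject_mpa` (named numeric), `sd_type`.
#' @export
cohort_summary <- function(estimates, subject_pairs = NULL,
                           sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (is.data.frame(estimates)) {
    est <- estimates[, c("session", "stiffness_mpa")]
  } else {
    est <- data.frame(
      session = vapply(estimates, function(e) as.character(e$session),
                       character(1)),
      stiffness_mpa = vapply(estimates, `[[`, numeric(1), "stiffness_mpa"),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(est) == 0L) stop("no estimates supplied")
  x <- est$stiffness_mpa
  n <- length(x)
  sdv <- if (n < 2L) NA_real_
         else if (sd_type == "sample") stats::sd(x)
         else stats::sd(x) * sqrt((n - 1) / n)

  intra <- NULL
  if (!is.null(subject_pairs)) {
    intra <- vapply(subject_pairs, function(p) {
      idx <- match(p, est$session)
      if (anyNA(idx)) {
        stop("subject pair references unknown session(s): ",
             paste(p[is.na(idx)], collapse = ", "))
      }
      abs(est$stiffness_mpa[idx[1]] - est$stiffness_mpa[idx[2]])
    }, numeric(1))
  }
  structure(
    list(estimates = est, mean_mpa = mean(x), sd_mpa = sdv,
         intra_subject_mpa = intra, sd_type = sd_type),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort CCS: %.4f %s %s MPa (%s SD, n = %d)\n",
              x$mean_mpa, "±",
              if (is.na(x$sd_mpa)) "NA" else sprintf("%.3f", x$sd_mpa),
              x$sd_type, nrow(x$estimates)))
  if (!is.null(x$intra_subject_mpa)) {
    cat("Intra-subject |difference| (MPa):\n")
    print(round(x$intra_subject_mpa, 4))
  }
  invisible(x)
}
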