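#' MMRT activation parameters
#'
#' Container for the activation parameters of macromolecular rate theory
#' (MMRT): the activation enthalpy and entropy at a reference temperature
#' `T0`, and the activation heat capacity change `dCp`, which is assumed
#' temperature independent over the range studied. A negative `dCp` bends
#' the Eyring plot and, when `dCp < -R`, produces a finite temperature
#' optimum.
#'
#' @param dH_T0 activation enthalpy at `T0` (kJ mol^-1).
#' @param dS_T0 activation entropy at `T0` (kJ mol^-1 K^-1).
#' @param dCp activation heat capacity change (kJ mol^-1 K^-1).
#' @param T0 reference temperature (K), strictly positive.
#' @param kappa transmission coefficient; fixed at 1.
#' @return Object of class `"mmrt_params"`.
#' @seealso [mmrt_lnk()], [fit_mmrt()], [topt_closed_form()]
#' @export
mmrt_params <- function(dH_T0, dS_T0, dCp, T0, kappa = 1) {
  stopifnot(is.numeric(dH_T0), length(dH_T0) == 1L, is.finite(dH_T0),
            is.numeric(dS_T0), length(dS_T0) == 1L, is.finite(dS_T0),
            is.numeric(dCp), length(dCp) == 1L, is.finite(dCp),
            is.numeric(T0), length(T0) == 1L, is.finite(T0))
  if (T0 <= 0) stop("reference temperature T0 must be positive")
  if (!isTRUE(all.equal(kappa, 1))) {
    stop("transmission coefficient kappa is fixed at 1")
  }
  structure(list(dH_T0 = dH_T0, dS_T0 = dS_T0, dCp = dCp, T0 = T0,
                 kappa = 1),
            class = "mmrt_params")
}

#' @export
print.mmrt_params <- function(x, ...) {
  cat("MMRT activation parameters\n")
  cat(sprintf("  dH_T0: %.6g kJ mol^-1\n", x$dH_T0))
  cat(sprintf("  dS_T0: %.6g kJ mol^-1 K^-1\n", x$dS_T0))
  cat(sprintf("  dCp  : %.6g kJ mol^-1 K^-1\n", x$dCp))
  cat(sprintf("  T0   : %.6g K\n", x$T0))
  invisible(x)
}

#' Temperature-rate profile
#'
#' A set of rate measurements for one enzyme across temperatures. Rates may
#' be supplied on the linear scale (s^-1) or already as natural logs; the
#' scale is always declared explicitly by using the matching argument,
#' never auto-detected.
#'
#' @param temperature_K temperatures in kelvin; at least 5 distinct values.
#' @param rate rate constants (s^-1), strictly positive. Exactly one of
#'   `rate` and `ln_rate` must be given.
#' @param ln_rate natural log of the rate constants.
#' @param sd_ln_rate optional per-point standard deviation of ln(rate),
#'   used as inverse-variance weights by [fit_mmrt()].
#' @param label free-text label for the profile.
#' @return Object of class `"rate_profile"` with elements `temperature_K`,
#'   `ln_rate`, `sd_ln_rate` and `label`.
#' @export
rate_profile <- function(temperature_K, rate = NULL, ln_rate = NULL,
                         sd_ln_rate = NULL, label = "") {
  temperature_K <- as.numeric(temperature_K)
  if (any(!is.finite(temperature_K)) || any(temperature_K <= 0)) {
    stop("temperatures must be finite and strictly positive")
  }
  if (length(unique(temperature_K)) < 5L) {
    stop("a rate profile needs at least 5 distinct temperatures")
  }
  if (is.null(rate) == is.null(ln_rate)) {
    stop("supply exactly one of 'rate' (linear scale) or 'ln_rate'")
  }
  # missing measurements are allowed and dropped at fit time
  if (!is.null(rate)) {
    rate <- as.numeric(rate)
    if (any((!is.finite(rate) | rate <= 0) & !is.na(rate))) {
      stop("rates on the linear scale must be strictly positive")
    }
    ln_rate <- log(rate)
  } else {
    ln_rate <- as.numeric(ln_rate)
    if (any(!is.finite(ln_rate) & !is.na(ln_rate))) {
      stop("ln_rate must be finite or NA")
    }
  }
  if (length(ln_rate) != length(temperature_K)) {
    stop("temperature and rate arrays must have equal length")
  }
  if (!is.null(sd_ln_rate)) {
    sd_ln_rate <- as.numeric(sd_ln_rate)
    if (length(sd_ln_rate) != length(temperature_K)) {
      stop("sd_ln_rate must match the number of points")
    }
    if (any(!is.finite(sd_ln_rate)) || any(sd_ln_rate <= 0)) {
      stop("sd_ln_rate must be finite and positive")
    }
  }
  structure(list(temperature_K = temperature_K, ln_rate = ln_rate,
                 sd_ln_rate = sd_ln_rate, label = as.character(label)[1L]),
            class = "rate_profile")
}

#' @export
print.rate_profile <- function(x, ...) {
  cat(sprintf("Rate profile%s: %d points, %.4g-%.4g K%s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$temperature_K), min(x$temperature_K),
              max(x$temperature_K),
              if (is.null(x$sd_ln_rate)) "" else " (with replicate sd)"))
  invisible(x)
}

#' MMRT log-rate
#'
#' Evaluates the MMRT expression for the natural log of a rate constant,
#'
#'   ln k = ln(kB T / h)
#'          - (dH_T0 + dCp (T - T0)) / (R T)
#'          + (dS_T0 + dCp ln(T / T0)) / R
#'
#' with the transmission coefficient fixed at 1.
#'
#' @param params [mmrt_params()] object.
#' @param temperature_K temperatures (K), strictly positive; vectorised.
#' @return Numeric vector of ln(rate) values (rate in s^-1).
#' @examples
#' p <- mmrt_params(dH_T0 = 50, dS_T0 = -0.05, dCp = -11.6, T0 = 316)
#' mmrt_lnk(p, seq(280, 330, by = 10))
#' @export
mmrt_lnk <- function(params, temperature_K) {
  stopifnot(inherits(params, "mmrt_params"))
  T <- as.numeric(temperature_K)
  if (any(!is.finite(T)) || any(T <= 0)) {
    stop("temperatures must be finite and strictly positive")
  }
  log(.kB * T / .h) -
    (params$dH_T0 + params$dCp * (T - params$T0)) / (.R * T) +
    (params$dS_T0 + params$dCp * log(T / params$T0)) / .R
}

#' Closed-form temperature optimum of the MMRT curve
#'
#' Setting the temperature derivative of the MMRT log-rate to zero gives the
#' stationary point
#'
#'   Topt = (dCp * T0 - dH_T0) / (dCp + R),
#'
#' which is a maximum exactly when `dCp < -R`. When `dCp >= -R` (or the
#' stationary point is non-positive) the log-rate is monotonic over positive
#' temperatures and no optimum exists.
#'
#' @param params [mmrt_params()] object.
#' @return Topt in kelvin, or `NA_real_` when no optimum exists.
#' @examples
#' topt_closed_form(mmrt_params(50, -0.05, -11.6, 316))
#' @export
topt_closed_form <- function(params) {
  stopifnot(inherits(params, "mmrt_params"))
  if (params$dCp >= -.R) return(NA_real_)
  topt <- (params$dCp * params$T0 - params$dH_T0) / (params$dCp + .R)
  if (!is.finite(topt) || topt <= 0) return(NA_real_)
  topt
}

# design matrix of the MMRT model at fixed T0: ln k minus the Eyring
# prefactor is linear in (dH_T0, dS_T0, dCp)
.mmrt_basis <- function(T, T0) {
  cbind(dH_T0 = -1 / (.R * T),
        dS_T0 = rep(1 / .R, length(T)),
        dCp = -(T - T0) / (.R * T) + log(T / T0) / .R)
}

.mmrt_fit_at_T0 <- function(T, y, w, T0) {
  X <- .mmrt_basis(T, T0)
  y0 <- y - log(.kB * T / .h)
  dat <- data.frame(y0 = y0, X)
  fit <- if (is.null(w)) {
    stats::lm(y0 ~ dH_T0 + dS_T0 + dCp - 1, data = dat)
  } else {
    stats::lm(y0 ~ dH_T0 + dS_T0 + dCp - 1, data = dat, weights = w)
  }
  fit
}

#' Fit MMRT to a temperature-rate profile
#'
#' Estimates the three activation parameters (dH_T0, dS_T0, dCp) by weighted
#' least squares on ln(rate). At fixed reference temperature the MMRT model
#' is linear in the three parameters, so each inner fit is solved exactly;
#' the reference temperature is then updated to the experimental convention
#' `T0 = Topt - 4 K` and the fit repeated until `T0` moves by less than
#' `t0_tol` kelvin (self-consistency loop). `dCp` itself is independent of
#' the reference choice; the loop only fixes the reporting convention for
#' `dH_T0` and `dS_T0`.
#'
#' When `sd_ln_rate` is present in the profile, points are weighted by the
#' inverse replicate variance; otherwise the fit is unweighted.
#'
#' @param profile [rate_profile()] object.
#' @param init optional [mmrt_params()] supplying a starting `T0`; otherwise
#'   `T0` is initialised at the vertex of a quadratic smooth of ln k vs T
#'   (falling back to the median temperature when the data show no concavity).
#' @param t0_offset offset (K) subtracted from the fitted optimum to give the
#'   reference temperature; default 4.
#' @param t0_tol convergence tolerance (K) on the reference temperature.
#' @param max_refits maximum number of reference-temperature refits.
#' @return Object of class `"mmrt_fit"`: `params` (converged
#'   [mmrt_params()]), `param_sd` (standard errors of the three parameters),
#'   `covariance` (3x3), `residual_sd` (ln-rate units), `topt` (K or `NA`),
#'   `n_iter_T0`, `df_residual`, and the data with fitted values/residuals.
#' @examples
#' p <- mmrt_params(50, -0.05, -11.6, 316)
#' prof <- rate_profile(seq(280, 330, 2), ln_rate = mmrt_lnk(p, seq(280, 330, 2)))
#' fit <- fit_mmrt(prof)
#' fit$params$dCp
#' @export
fit_mmrt <- function(profile, init = NULL, t0_offset = 4, t0_tol = 0.01,
                     max_refits = 20) {
  stopifnot(inherits(profile, "rate_profile"))
  T <- profile$temperature_K
  y <- profile$ln_rate
  ok <- is.finite(T) & is.finite(y)
  if (sum(ok) < 4L) {
    stop("insufficient data: fewer than 4 usable points for the MMRT fit")
  }
  T <- T[ok]; y <- y[ok]
  w <- if (is.null(profile$sd_ln_rate)) NULL else 1 / profile$sd_ln_rate[ok]^2

  # initial reference temperature: vertex of a quadratic smooth
  if (!is.null(init)) {
    stopifnot(inherits(init, "mmrt_params"))
    T0 <- init$T0
  } else {
    qf <- stats::lm(y ~ T + I(T^2), weights = w)
    a <- stats::coef(qf)[["I(T^2)"]]
    b <- stats::coef(qf)[["T"]]
    T0 <- if (is.finite(a) && a < 0) {
      min(max(-b / (2 * a), min(T) - 50), max(T) + 50)
    } else {
      stats::median(T)
    }
  }

  n_iter <- 0L
  repeat {
    fit <- .mmrt_fit_at_T0(T, y, w, T0)
    cf <- stats::coef(fit)
    params <- mmrt_params(cf[["dH_T0"]], cf[["dS_T0"]], cf[["dCp"]], T0)
    topt <- topt_closed_form(params)
    if (is.na(topt)) break           # monotonic curve: convention undefined
    T0_new <- topt - t0_offset
    if (abs(T0_new - T0) < t0_tol) break
    n_iter <- n_iter + 1L
    if (n_iter > max_refits) {
      cond <- simpleError(sprintf(
        "MMRT reference-temperature loop did not converge in %d refits",
        max_refits))
      cond$last_params <- params
      stop(cond)
    }
    T0 <- T0_new
  }

  sm <- summary(fit)
  vc <- stats::vcov(fit)
  dimnames(vc) <- list(c("dH_T0", "dS_T0", "dCp"), c("dH_T0", "dS_T0", "dCp"))
  structure(list(
    params = params,
    param_sd = stats::setNames(sm$coefficients[, "Std. Error"],
                               c("dH_T0", "dS_T0", "dCp")),
    covariance = vc,
    residual_sd = sm$sigma,
    topt = topt,
    n_iter_T0 = n_iter,
    df_residual = fit$df.residual,
    data = data.frame(temperature_K = T, ln_rate = y,
                      fitted = mmrt_lnk(params, T),
                      residual = y - mmrt_lnk(params, T)),
    weighted = !is.null(w),
    label = profile$label
  ), class = "mmrt_fit")
}

#' @export
print.mmrt_fit <- function(x, ...) {
  cat("MMRT fit", if (nzchar(x$label)) paste0(" '", x$label, "'"), "\n", sep = "")
  cat(sprintf("  dCp  : %.4f +/- %.4f kJ mol^-1 K^-1\n",
              x$params$dCp, x$param_sd[["dCp"]]))
  cat(sprintf("  dH_T0: %.4f +/- %.4f kJ mol^-1 (T0 = %.2f K)\n",
              x$params$dH_T0, x$param_sd[["dH_T0"]], x$params$T0))
  cat(sprintf("  dS_T0: %.5f +/- %.5f kJ mol^-1 K^-1\n",
              x$params$dS_T0, x$param_sd[["dS_T0"]]))
  cat(sprintf("  Topt : %s\n",
              if (is.na(x$topt)) "none (monotonic)" else sprintf("%.2f K", x$topt)))
  cat(sprintf("  residual sd: %.4g (ln rate), %d refits of T0\n",
              x$residual_sd, x$n_iter_T0))
  invisible(x)
}

#' @export
predict.mmrt_fit <- function(object, temperature_K = NULL, ...) {
  if (is.null(temperature_K)) temperature_K <- object$data$temperature_K
  mmrt_lnk(object$params, temperature_K)
}

#' @export
confint.mmrt_fit <- function(object, parm = c("dH_T0", "dS_T0", "dCp"),
                             level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  est <- unlist(object$params[parm])
  se <- object$param_sd[parm]
  q <- stats::qt(1 - (1 - level) / 2, df = object$df_residual)
  out <- cbind(lower = est - q * se, upper = est + q * se)
  rownames(out) <- parm
  out
}

#' Read a temperature-rate table
#'
#' Reads a delimited text file (comma or tab separated, `#` comments, header
#' required) with columns `temperature_K` and either `rate_per_s` or
#' `ln_rate`, plus optional `sd_ln_rate`.
#'
#' @param path file path.
#' @param label optional profile label; defaults to the file name.
#' @return A [rate_profile()].
#' @export
read_rate_profile <- function(path, label = basename(path)) {
  tab <- .read_delim(path)
  if (!"temperature_K" %in% names(tab)) {
    stop("rate table ", path, " lacks required column 'temperature_K'")
  }
  sd <- if ("sd_ln_rate" %in% names(tab)) tab$sd_ln_rate else NULL
  if ("rate_per_s" %in% names(tab)) {
    rate_profile(tab$temperature_K, rate = tab$rate_per_s,
                 sd_ln_rate = sd, label = label)
  } else if ("ln_rate" %in% names(tab)) {
    rate_profile(tab$temperature_K, ln_rate = tab$ln_rate,
                 sd_ln_rate = sd, label = label)
  } else {
    stop("rate table ", path, " needs a 'rate_per_s' or 'ln_rate' column")
  }
}

#' Write an MMRT fit report
#'
#' Writes a machine-readable JSON report (parameters, standard errors,
#' covariance, optimum, residuals) next to a human-readable `key: value`
#' text rendering.
#'
#' @param fit an `"mmrt_fit"` object.
#' @param json_path output path for the JSON report; the text report is
#'   written alongside with extension `.txt` unless `txt_path` is given.
#' @param txt_path optional path for the text report.
#' @return Invisibly, the report list.
#' @export
write_fit_report <- function(fit, json_path, txt_path = NULL) {
  stopifnot(inherits(fit, "mmrt_fit"))
  report <- list(
    label = fit$label,
    params = list(dH_T0 = fit$params$dH_T0, dS_T0 = fit$params$dS_T0,
                  dCp = fit$params$dCp, T0 = fit$params$T0, kappa = 1),
    param_sd = as.list(fit$param_sd),
    covariance = unname(apply(fit$covariance, 1, as.list)),
    residual_sd = fit$residual_sd,
    topt = if (is.na(fit$topt)) "none" else fit$topt,
    n_iter_T0 = fit$n_iter_T0,
    residuals = fit$data$residual
  )
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA)
  if (is.null(txt_path)) txt_path <- sub("\\.json$", ".txt", json_path)
  lines <- c(
    sprintf("label: %s", fit$label),
    sprintf("dCp_kJ_mol_K: %.6g", fit$params$dCp),
    sprintf("dCp_sd: %.6g", fit$param_sd[["dCp"]]),
    sprintf("dH_T0_kJ_mol: %.6g", fit$params$dH_T0),
    sprintf("dH_T0_sd: %.6g", fit$param_sd[["dH_T0"]]),
    sprintf("dS_T0_kJ_mol_K: %.6g", fit$params$dS_T0),
    sprintf("dS_T0_sd: %.6g", fit$param_sd[["dS_T0"]]),
    sprintf("T0_K: %.6g", fit$params$T0),
    sprintf("topt_K: %s", if (is.na(fit$topt)) "none" else sprintf("%.6g", fit$topt)),
    sprintf("residual_sd_ln_rate: %.6g", fit$residual_sd),
    sprintf("n_iter_T0: %d", fit$n_iter_T0))
  writeLines(lines, txt_path)
  invisible(report)
}

# shared reader for comma/tab delimited tables with '#' comments
.read_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^\\s*#", first) & nzchar(first)]
  if (!length(first)) stop("file ", path, " contains no data")
  sep <- if (grepl("\t", first[1L])) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
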