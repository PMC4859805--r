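#' Fit a fluorescence-polarization titration
#'
#' Nonlinear least-squares fit of a direct or competition
#' fluorescence-polarization binding curve. The direct mode fits the
#' trace-labeled hyperbola of [direct_polarization()] for `kd`, `a_free` and
#' `a_bound`; the competition mode fits [competition_polarization()] for
#' `kd`, `a0` and `af` at a known total hub concentration `p_tot`.
#'
#' `kd` is log-parameterised to enforce positivity and the optimiser
#' (Levenberg-Marquardt, via \pkg{minpack.lm}) is multi-started over
#' `kd` in \{1, 10, 100, 1000\} uM; the lowest-deviance converged start wins.
#'
#' @param conc Total titrant concentrations (uM): hub for `mode = "direct"`,
#'   unlabeled peptide for `mode = "competition"`.
#' @param polarization Observed polarization values (dimensionless).
#' @param mode `"direct"` or `"competition"`.
#' @param p_tot Total hub-subunit concentration (uM); required for
#'   competition. Defaults to 10 uM, the final hub concentration after the
#'   assay's three-fold dilution of a 30 uM stock.
#' @param kd_starts Multi-start grid of initial `kd` values (uM).
#' @param data Optional data frame with columns `conc_uM` and `polarization`;
#'   if supplied, `conc` and `polarization` are taken from it.
#' @return An object of class `"fp_fit"` with components `coefficients`
#'   (named: `kd` and the two polarization end points), `se` (delta-method
#'   standard error for `kd`, direct for the rest), `sigma` (residual
#'   standard deviation), `fitted`, `residuals`, `mode`, `p_tot`,
#'   `data`, `converged`, and `deviance`.
#' @examples
#' curve <- gen_direct_curve(kd = 100, seed = 1)
#' fit <- fit_fp(curve$conc_uM, curve$polarization, mode = "direct")
#' coef(fit)
#' @export
fit_fp <- function(conc, polarization, mode = c("direct", "competition"),
                   p_tot = 10, kd_starts = c(1, 10, 100, 1000),
                   data = NULL) {
  mode <- match.arg(mode)
  if (!is.null(data)) {
    stopifnot(all(c("conc_uM", "polarization") %in% names(data)))
    conc <- data$conc_uM
    polarization <- data$polarization
  }
  stopifnot(is.numeric(conc), is.numeric(polarization))
  if (length(conc) != length(polarization))
    stop("'conc' and 'polarization' must have equal length")
  ord <- order(conc)
  conc <- conc[ord]; polarization <- polarization[ord]
  if (length(conc) < 4L) stop("need at least 4 points to fit")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  span <- diff(range(polarization))
  if (span < 1e-12 || stats::sd(polarization) < 1e-12)
    stop("no binding signal: polarization is constant across the titration")
  if (mode == "competition" && (length(p_tot) != 1L || p_tot <= 0))
    stop("competition mode requires a single positive 'p_tot'")

  model_fun <- switch(mode,
    direct = function(par, x)
      direct_polarization(x, exp(par[1]), par[2], par[3]),
    competition = function(par, x)
      competition_polarization(x, exp(par[1]), p_tot, par[2], par[3]))
  # par = (log kd, high-signal end point, low-signal end point)
  hi0 <- if (mode == "direct") max(polarization) else polarization[1]
  lo0 <- if (mode == "direct") min(polarization) else
    polarization[length(polarization)]

  best <- NULL
  for (kd0 in kd_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(log(kd0), if (mode == "direct") c(lo0, hi0) else c(hi0, lo0)),
        fn = function(par) polarization - model_fun(par, conc),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("fit did not converge from any start in kd_starts = {",
         paste(kd_starts, collapse = ", "), "} uM")

  par <- best$par
  n <- length(conc); p <- length(par)
  sigma <- sqrt(best$deviance / max(n - p, 1))
  vcov_par <- tryCatch(sigma^2 * solve(best$hessian),
                       error = function(e) matrix(NA_real_, p, p))
  se_par <- sqrt(pmax(diag(vcov_par), 0))
  kd <- exp(par[1])
  cf <- c(kd = kd,
          if (mode == "direct") c(a_free = par[2], a_bound = par[3])
          else c(a0 = par[2], af = par[3]))
  se <- c(kd = kd * se_par[1], se_par[2], se_par[3])  # delta method on log kd
  names(se) <- names(cf)
  fitted <- model_fun(par, conc)

  structure(list(
    coefficients = cf, se = se, sigma = sigma,
    fitted = fitted, residuals = polarization - fitted,
    mode = mode, p_tot = if (mode == "competition") p_tot else NA_real_,
    data = data.frame(conc_uM = conc, polarization = polarization),
    converged = TRUE, deviance = best$deviance, niter = best$niter),
    class = "fp_fit")
}

#' @export
print.fp_fit <- function(x, ...) {
  cat("Fluorescence-polarization binding fit (", x$mode, " mode)\n", sep = "")
  if (x$mode == "competition")
    cat("  total hub concentration:", x$p_tot, "uM\n")
  cat("  n =", nrow(x$data), "points\n")
  est <- cbind(Estimate = x$coefficients, `Std. Error` = x$se)
  print(round(est, 5))
  cat("Residual standard deviation:", signif(x$sigma, 4), "\n")
  invisible(x)
}

#' @export
coef.fp_fit <- function(object, ...) object$coefficients

#' @export
residuals.fp_fit <- function(object, ...) object$residuals

#' @export
fitted.fp_fit <- function(object, ...) object$fitted

#' @rdname fit_fp
#' @param object,x An `fp_fit` object.
#' @param newdata Optional vector of concentrations (uM) or data frame with a
#'   `conc_uM` column at which to evaluate the fitted model.
#' @param ... Unused.
#' @export
predict.fp_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc_uM
          else if (is.data.frame(newdata)) newdata$conc_uM else newdata
  cf <- object$coefficients
  if (object$mode == "direct")
    direct_polarization(conc, cf[["kd"]], cf[["a_free"]], cf[["a_bound"]])
  else
    competition_polarization(conc, cf[["kd"]], object$p_tot,
                             cf[["a0"]], cf[["af"]])
}

#' @export
summary.fp_fit <- function(object, ...) {
  out <- list(
    mode = object$mode, p_tot = object$p_tot, n = nrow(object$data),
    coefficients = cbind(Estimate = object$coefficients,
                         `Std. Error` = object$se),
    sigma = object$sigma, deviance = object$deviance,
    ic50 = if (object$mode == "competition")
      ic50_from_model(object$coefficients[["kd"]], object$p_tot)
      else NA_real_)
  class(out) <- "summary.fp_fit"
  out
}

#' @export
print.summary.fp_fit <- function(x, ...) {
  cat("Fluorescence-polarization binding fit (", x$mode, " mode), n = ",
      x$n, "\n", sep = "")
  print(round(x$coefficients, 5))
  cat("Residual standard deviation:", signif(x$sigma, 4), "\n")
  if (!is.na(x$ic50))
    cat("Model-implied IC50:", signif(x$ic50, 4), "uM at p_tot =",
        x$p_tot, "uM\n")
  invisible(x)
}

#' @rdname fit_fp
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed passed to [set.seed()].
#' @export
simulate.fp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(object$data)
  out <- as.data.frame(replicate(
    nsim, object$fitted + stats::rnorm(n, sd = object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(conc_uM = object$data$conc_uM, out)
}

#' @rdname fit_fp
#' @export
plot.fp_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$conc_uM, d$polarization, xlab = "concentration (uM)",
                 ylab = "polarization",
                 main = paste0("FP ", x$mode, " fit, KD = ",
                               signif(x$coefficients[["kd"]], 3), " uM"), ...)
  grid_x <- seq(min(d$conc_uM), max(d$conc_uM), length.out = 200)
  graphics::lines(grid_x, predict(x, grid_x))
  invisible(x)
}
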