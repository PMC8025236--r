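# Four-parameter logistic dose-response fitting, IC50 extraction and
# relative potency between conditions.
#
# Model: y = bottom + (top - bottom) / (1 + (x / ic50)^hill). Fitting is
# done on log-concentration (the 4PL is a logistic in log x), with bounded
# Levenberg-Marquardt least squares; hill is kept positive and the curve
# direction (inhibition vs activation) handled by a reflection detected
# from the data.

check_dr_table <- function(dr) {
  if (!is.data.frame(dr) ||
      !all(c("concentration", "viability") %in% names(dr))) {
    stop("dose-response table needs columns `concentration` and `viability`",
         call. = FALSE)
  }
  if (any(dr$concentration <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (any(!is.finite(dr$viability))) {
    stop("viability must be finite", call. = FALSE)
  }
  invisible(dr)
}

fourpl_mean <- function(logx, top, bottom, log_ic50, hill, direction) {
  bottom + (top - bottom) / (1 + exp(direction * hill * (logx - log_ic50)))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Unweighted least-squares fit of
#' `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)` by bounded
#' Levenberg-Marquardt on log-concentration. Initialization is
#' deterministic: `top = max(y)`, `bottom = min(y)`, `ic50` at the
#' geometric mid-concentration, `hill = 1`; convergence tolerance 1e-8 on
#' the relative change in the residual sum of squares. `ic50` is bounded to
#' `[min(conc) / 100, max(conc) * 100]` and `hill` to `[0.1, 10]`.
#' Ascending (activation-like) data are detected and fitted as the
#' reflected curve, recorded in `direction`.
#'
#' @param dr DoseResponseTable data frame with columns `concentration`
#'   (> 0) and `viability` (replicate rows allowed).
#' @return Object of class `fourpl_fit`: `coefficients` (`top`, `bottom`,
#'   `ic50`, `hill`), `se` (per-parameter standard errors on the internal
#'   scale: `log_ic50` for the midpoint), `rss`, `converged`, `degenerate`,
#'   `direction` (`"descending"` or `"ascending"`), the data, and fitted
#'   values.
#' @seealso [relative_potency()], [fold_sensitivity()], [fourpl_curve()]
#' @export
#' @examples
#' dr <- simulate_dose_response(
#'   list(top = 1, bottom = 0, ic50 = 100, hill = 1),
#'   concentrations = 10^seq(0, 4, length.out = 8), noise_sd = 0, seed = 1)
#' coef(fit_4pl(dr))
fit_4pl <- function(dr) {
  check_dr_table(dr)
  if (length(unique(dr$concentration)) < 4L) {
    stop("need at least 4 distinct concentrations for a free 4PL fit",
         call. = FALSE)
  }
  x <- dr$concentration
  y <- dr$viability
  logx <- log(x)

  # Degenerate flat response: ic50/hill unidentifiable.
  if (diff(range(y)) < 1e-12) {
    return(new_fourpl_fit(
      c(top = y[1L], bottom = y[1L], ic50 = NA_real_, hill = NA_real_),
      se = rep(NA_real_, 4L), rss = 0, converged = FALSE, degenerate = TRUE,
      direction = "descending", data = dr, fitted = y))
  }

  # Direction: does the response fall or rise with concentration?
  slope <- stats::coef(stats::lm(y ~ logx))[2L]
  direction <- if (slope <= 0) 1 else -1  # +1: descending inhibition curve

  start <- c(top = max(y), bottom = min(y),
             log_ic50 = mean(range(logx)), hill = 1)
  lower <- c(top = -Inf, bottom = -Inf, log_ic50 = log(min(x) / 100),
             hill = 0.1)
  upper <- c(top = Inf, bottom = Inf, log_ic50 = log(max(x) * 100),
             hill = 10)
  resid_fn <- function(p) {
    y - fourpl_mean(logx, p["top"], p["bottom"], p["log_ic50"], p["hill"],
                    direction)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-8, ptol = 1e-10, maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(new_fourpl_fit(
      c(top = NA_real_, bottom = NA_real_, ic50 = NA_real_, hill = NA_real_),
      se = rep(NA_real_, 4L), rss = NA_real_, converged = FALSE,
      degenerate = TRUE,
      direction = if (direction == 1) "descending" else "ascending",
      data = dr, fitted = rep(NA_real_, length(y))))
  }
  cf <- fit$par
  se <- lm_param_se(fit, length(y))
  est <- c(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
           ic50 = exp(unname(cf["log_ic50"])), hill = unname(cf["hill"]))
  # Report with bottom <= top regardless of which plateau the optimizer
  # labelled "top".
  if (est["bottom"] > est["top"]) {
    est[c("top", "bottom")] <- est[c("bottom", "top")]
    se[c("top", "bottom")] <- se[c("bottom", "top")]
  }
  rss <- sum(fit$fvec^2)
  new_fourpl_fit(est, se = se, rss = rss,
                 converged = TRUE, degenerate = FALSE,
                 direction = if (direction == 1) "descending" else "ascending",
                 data = dr, fitted = y - fit$fvec)
}

# Wald standard errors from a converged nls.lm fit: sigma^2 (J'J)^{-1},
# with J'J taken from the returned hessian.
lm_param_se <- function(fit, n_obs) {
  p <- length(fit$par)
  out <- rep(NA_real_, p)
  names(out) <- names(fit$par)
  df <- n_obs - p
  if (df <= 0L) return(out)
  sigma2 <- sum(fit$fvec^2) / df
  covar <- tryCatch(sigma2 * solve(fit$hessian),
                    error = function(e) NULL)
  if (!is.null(covar)) out[] <- sqrt(pmax(diag(covar), 0))
  out
}

new_fourpl_fit <- function(coefficients, se, rss, converged, degenerate,
                           direction, data, fitted) {
  names(se) <- c("top", "bottom", "log_ic50", "hill")
  structure(list(
    coefficients = coefficients, se = se, rss = rss, converged = converged,
    degenerate = degenerate, direction = direction, data = data,
    fitted = fitted
  ), class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat("Four-parameter logistic fit")
  if (x$degenerate) {
    cat(" [degenerate / not converged]\n")
    return(invisible(x))
  }
  cat(sprintf(" (%s)\n", x$direction))
  cat(sprintf("  top = %.4g, bottom = %.4g, IC50 = %.4g, hill = %.3g\n",
              x$coefficients["top"], x$coefficients["bottom"],
              x$coefficients["ic50"], x$coefficients["hill"]))
  cat(sprintf("  RSS = %.4g on %d observations\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
coef.fourpl_fit <- function(object, ...) object$coefficients

#' @export
predict.fourpl_fit <- function(object, newdata = NULL, ...) {
  if (object$degenerate) stop("cannot predict from a degenerate fit",
                              call. = FALSE)
  x <- if (is.null(newdata)) object$data$concentration else
    newdata$concentration
  cf <- object$coefficients
  d <- if (object$direction == "descending") 1 else -1
  fourpl_mean(log(x), cf["top"], cf["bottom"], log(cf["ic50"]), cf["hill"], d)
}

#' @export
residuals.fourpl_fit <- function(object, ...) {
  object$data$viability - object$fitted
}

#' @export
summary.fourpl_fit <- function(object, ...) {
  print(object)
  if (!object$degenerate) {
    cat("  standard errors (internal scale):\n")
    print(round(object$se, 5))
    cat(sprintf("  residual sd = %.4g\n",
                sqrt(object$rss / max(1L, nrow(object$data) - 4L))))
  }
  invisible(object)
}

#' @export
plot.fourpl_fit <- function(x, n_grid = 200L, ...) {
  if (x$degenerate) stop("cannot plot a degenerate fit", call. = FALSE)
  conc <- x$data$concentration
  grid <- exp(seq(log(min(conc)), log(max(conc)), length.out = n_grid))
  plot(conc, x$data$viability, log = "x",
       xlab = "concentration", ylab = "viability", ...)
  graphics::lines(grid, predict(x, data.frame(concentration = grid)))
  graphics::abline(v = x$coefficients["ic50"], lty = 2)
  invisible(x)
}

#' @export
simulate.fourpl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$degenerate) stop("cannot simulate from a degenerate fit",
                              call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sd_hat <- sqrt(object$rss / max(1L, nrow(object$data) - 4L))
  mu <- object$fitted
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu),
                                                         sd = sd_hat)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Relative potency of two conditions by shared-shape parallel fit
#'
#' Jointly fits both tables with common `top`, `bottom` and `hill` and a
#' group-specific log-IC50 shift (`parallel` 4PL fit); the potency ratio is
#' `IC50(reference) / IC50(test) = exp(shift)` with a Wald CI from the
#' shift's standard error. Shape heterogeneity is screened by an F-test of
#' the constrained fit against the two free fits; at `p < 0.01` a warning
#' is attached (the ratio is still reported). The ratio of independently
#' fitted IC50s is returned alongside.
#'
#' @param reference,test DoseResponseTable data frames.
#' @param conf_level Confidence level for the ratio CI.
#' @return Object of class `potency_ratio`: `ratio`, `ci`, `ratio_free`
#'   (from independent fits), shared-shape parameters, `shape_f_p` and
#'   `shape_warning`.
#' @export
#' @examples
#' shape <- list(top = 1, bottom = 0, hill = 1)
#' ref <- simulate_dose_response(c(shape, ic50 = 3560),
#'   concentrations = 10^seq(0, 5, length.out = 8), noise_sd = 0, seed = 1)
#' tst <- simulate_dose_response(c(shape, ic50 = 71),
#'   concentrations = 10^seq(0, 5, length.out = 8), noise_sd = 0, seed = 2)
#' relative_potency(ref, tst)$ratio   # ~50
relative_potency <- function(reference, test, conf_level = 0.95) {
  fit_ref <- fit_4pl(reference)
  fit_test <- fit_4pl(test)
  if (fit_ref$degenerate || fit_test$degenerate) {
    stop("one of the tables does not support a 4PL fit", call. = FALSE)
  }
  dat <- rbind(
    data.frame(logx = log(reference$concentration),
               y = reference$viability, is_test = 0),
    data.frame(logx = log(test$concentration), y = test$viability,
               is_test = 1)
  )
  d <- if (fit_ref$direction == "descending") 1 else -1
  conc_all <- exp(dat$logx)
  start <- list(
    top = unname(mean(c(coef(fit_ref)["top"], coef(fit_test)["top"]))),
    bottom = unname(mean(c(coef(fit_ref)["bottom"],
                           coef(fit_test)["bottom"]))),
    log_ic50_ref = log(unname(coef(fit_ref)["ic50"])),
    dlog = log(unname(coef(fit_ref)["ic50"] / coef(fit_test)["ic50"])),
    hill = unname(mean(c(coef(fit_ref)["hill"], coef(fit_test)["hill"])))
  )
  start <- unlist(start)
  joint_resid <- function(p) {
    dat$y - fourpl_mean(dat$logx, p["top"], p["bottom"],
                        p["log_ic50_ref"] - p["dlog"] * dat$is_test,
                        p["hill"], d)
  }
  joint <- minpack.lm::nls.lm(
    par = start, fn = joint_resid,
    lower = c(top = -Inf, bottom = -Inf,
              log_ic50_ref = log(min(conc_all) / 100), dlog = -Inf,
              hill = 0.1),
    upper = c(top = Inf, bottom = Inf,
              log_ic50_ref = log(max(conc_all) * 100), dlog = Inf,
              hill = 10),
    control = minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-10,
                                         maxiter = 500)
  )
  cf <- joint$par
  se_dlog <- lm_param_se(joint, nrow(dat))["dlog"]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ratio <- exp(unname(cf["dlog"]))
  ci <- exp(unname(cf["dlog"]) + c(-1, 1) * z * se_dlog)

  # Shape-heterogeneity screen: constrained (5 parameters) vs free
  # (2 x 4 parameters) fits.
  rss_free <- fit_ref$rss + fit_test$rss
  rss_con <- sum(joint$fvec^2)
  df_den <- nrow(dat) - 8L
  shape_p <- NA_real_
  if (rss_free > 1e-12 && df_den > 0L) {
    f_stat <- ((rss_con - rss_free) / 3) / (rss_free / df_den)
    shape_p <- stats::pf(max(f_stat, 0), 3, df_den, lower.tail = FALSE)
  }
  shape_warning <- is.finite(shape_p) && shape_p < 0.01
  if (shape_warning) {
    warning("dose-response shapes differ between groups (F-test p < 0.01); ",
            "parallel-fit potency ratio may be biased", call. = FALSE)
  }
  structure(list(
    ratio = ratio, ci = ci,
    ratio_free = unname(coef(fit_ref)["ic50"] / coef(fit_test)["ic50"]),
    shared = c(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
               hill = unname(cf["hill"])),
    ic50_reference = exp(unname(cf["log_ic50_ref"])),
    ic50_test = exp(unname(cf["log_ic50_ref"] - cf["dlog"])),
    shape_f_p = shape_p, shape_warning = shape_warning,
    conf_level = conf_level
  ), class = "potency_ratio")
}

#' @export
print.potency_ratio <- function(x, ...) {
  cat("Relative potency (shared-shape parallel 4PL fit)\n")
  cat(sprintf("  IC50 reference = %.4g, IC50 test = %.4g\n",
              x$ic50_reference, x$ic50_test))
  cat(sprintf("  ratio (reference / test) = %.4g  [%.0f%% CI %.4g - %.4g]\n",
              x$ratio, 100 * x$conf_level, x$ci[1L], x$ci[2L]))
  if (isTRUE(x$shape_warning)) cat("  warning: shape heterogeneity detected\n")
  invisible(x)
}

#' Fold-change in drug sensitivity between two IC50s
#'
#' Plain IC50 ratio `ic50_a / ic50_b`: how many times less sensitive
#' condition A is than condition B.
#'
#' @param ic50_a,ic50_b Positive IC50 values in the same units.
#' @return The ratio.
#' @export
#' @examples
#' fold_sensitivity(3560, 71)   # ~50-fold
fold_sensitivity <- function(ic50_a, ic50_b) {
  stop_if_not_scalar_number(ic50_a, "ic50_a", positive = TRUE)
  stop_if_not_scalar_number(ic50_b, "ic50_b", positive = TRUE)
  ic50_a / ic50_b
}
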