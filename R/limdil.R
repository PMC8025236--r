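# Single-hit limiting-dilution analysis: tumor-initiating-cell frequency
# estimation, group comparison, model adequacy, and small phenotype
# formulas (sphere-forming efficiency, tumor volume).
#
# Under the single-hit model a graft takes iff it received at least one
# initiating cell, so P(take | dose d) = 1 - exp(-f d). On the
# complementary log-log scale this is linear with slope 1 in log(d):
# cloglog(p) = log(f) + log(d), which is why the MLE is a binomial GLM with
# a cloglog link and log-dose offset — the ELDA formulation.

check_ld_assay <- function(assay) {
  needed <- c("dose", "n_tested", "n_responded")
  if (!is.data.frame(assay) || !all(needed %in% names(assay))) {
    stop("LD assay needs columns dose, n_tested, n_responded", call. = FALSE)
  }
  if (nrow(assay) == 0L) stop("LD assay has no rows", call. = FALSE)
  if (any(assay$dose <= 0)) stop("doses must be positive", call. = FALSE)
  if (any(assay$n_responded < 0 | assay$n_responded > assay$n_tested)) {
    stop("n_responded must lie in [0, n_tested]", call. = FALSE)
  }
  invisible(assay)
}

ld_loglik <- function(f, assay) {
  p <- 1 - exp(-f * assay$dose)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(assay$n_responded * log(p) +
        (assay$n_tested - assay$n_responded) * log1p(-p))
}

#' Estimate tumor-initiating-cell frequency from a limiting-dilution assay
#'
#' Maximum-likelihood estimate of the initiating-cell frequency `f` in the
#' single-hit model `P(response | dose) = 1 - exp(-f * dose)`, fitted as a
#' binomial regression with complementary log-log link and `log(dose)` as a
#' fixed-unit offset. The 95\% confidence interval is a Wald interval on
#' `log(f)`, back-transformed (a profile-likelihood interval is available
#' via `ci = "profile"`). Saturated assays (all or no responders) are
#' reported as one-sided bounds with a `boundary` flag rather than refused.
#'
#' @param assay LDAssay data frame with columns `dose`, `n_tested`,
#'   `n_responded` (a `group` column, if present, is carried along).
#' @param conf_level Confidence level for the interval.
#' @param ci `"wald"` (default) or `"profile"`.
#' @return Object of class `ld_fit` with components `frequency`,
#'   `one_in` (`1 / frequency`), `ci_lower`, `ci_upper`, `log_likelihood`,
#'   `boundary` (`"none"`, `"all_responded"` or `"none_responded"`), the
#'   fitted `glm` (non-boundary fits) and the input data.
#' @seealso [compare_frequencies()], [single_hit_adequacy()]
#' @export
#' @examples
#' a <- data.frame(dose = 1000, n_tested = 10, n_responded = 5)
#' estimate_frequency(a)    # 1 in 1443 cells
estimate_frequency <- function(assay, conf_level = 0.95,
                               ci = c("wald", "profile")) {
  ci <- match.arg(ci)
  check_ld_assay(assay)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  total_resp <- sum(assay$n_responded)
  total_tested <- sum(assay$n_tested)

  if (total_resp == 0L) {
    # Zero responders: the MLE is f = 0; an upper confidence bound comes
    # from the exact probability of observing no response.
    alpha <- 1 - conf_level
    f_up <- -log(alpha) / sum(assay$dose * assay$n_tested)
    return(new_ld_fit(0, NA_real_, f_up, ld_loglik(0, assay),
                      "none_responded", NULL, assay, conf_level))
  }
  if (total_resp == total_tested) {
    # Saturation: the likelihood increases in f without bound; report the
    # lower confidence bound solving P(all respond | f) = alpha.
    alpha <- 1 - conf_level
    g <- function(lf) {
      sum(assay$n_tested * log1p(-exp(-exp(lf) * assay$dose))) - log(alpha)
    }
    lo <- stats::uniroot(g, lower = -40, upper = 40, tol = 1e-12)$root
    return(new_ld_fit(Inf, exp(lo), NA_real_, 0, "all_responded", NULL,
                      assay, conf_level))
  }

  fit <- stats::glm(
    cbind(n_responded, n_tested - n_responded) ~ 1,
    family = stats::binomial(link = "cloglog"),
    offset = log(dose), data = assay
  )
  log_f <- unname(stats::coef(fit)[1L])
  se <- sqrt(stats::vcov(fit)[1L, 1L])
  f <- exp(log_f)
  if (ci == "wald") {
    lower <- exp(log_f - z * se)
    upper <- exp(log_f + z * se)
  } else {
    ll_max <- ld_loglik(f, assay)
    crit <- stats::qchisq(conf_level, df = 1L) / 2
    h <- function(lf) ld_loglik(exp(lf), assay) - (ll_max - crit)
    lower <- exp(stats::uniroot(h, lower = log_f - 20, upper = log_f,
                                tol = 1e-10)$root)
    upper <- exp(stats::uniroot(h, lower = log_f, upper = log_f + 20,
                                tol = 1e-10)$root)
  }
  new_ld_fit(f, lower, upper, ld_loglik(f, assay), "none", fit, assay,
             conf_level)
}

new_ld_fit <- function(f, lower, upper, ll, boundary, glm_fit, assay,
                       conf_level) {
  structure(list(
    frequency = f, one_in = if (is.finite(f) && f > 0) 1 / f else NA_real_,
    ci_lower = lower, ci_upper = upper, log_likelihood = ll,
    boundary = boundary, glm = glm_fit, data = assay,
    conf_level = conf_level
  ), class = "ld_fit")
}

#' @export
print.ld_fit <- function(x, ...) {
  cat("Single-hit limiting-dilution fit\n")
  if (x$boundary == "none") {
    cat(sprintf("  frequency: %.4g  (1 in %.0f cells)\n", x$frequency,
                x$one_in))
    cat(sprintf("  %.0f%% CI: 1 in %.0f to 1 in %.0f\n",
                100 * x$conf_level, 1 / x$ci_upper, 1 / x$ci_lower))
  } else if (x$boundary == "none_responded") {
    cat(sprintf("  no responders: frequency 0, upper bound %.4g (1 in %.0f)\n",
                x$ci_upper, 1 / x$ci_upper))
  } else {
    cat(sprintf("  all responded: lower bound %.4g (1 in %.0f)\n",
                x$ci_lower, 1 / x$ci_lower))
  }
  invisible(x)
}

#' @export
coef.ld_fit <- function(object, ...) c(frequency = object$frequency)

#' @export
confint.ld_fit <- function(object, parm, level, ...) {
  c(lower = object$ci_lower, upper = object$ci_upper)
}

#' @export
logLik.ld_fit <- function(object, ...) {
  structure(object$log_likelihood, df = 1L, class = "logLik")
}

#' @export
predict.ld_fit <- function(object, newdata = NULL, ...) {
  dose <- if (is.null(newdata)) object$data$dose else newdata$dose
  1 - exp(-object$frequency * dose)
}

#' @export
summary.ld_fit <- function(object, ...) {
  print(object)
  obs <- object$data$n_responded / object$data$n_tested
  cat("\n  dose  tested  responded  observed  fitted\n")
  fitted <- predict(object)
  for (i in seq_len(nrow(object$data))) {
    cat(sprintf("  %6g %6d %9d %9.3f %8.3f\n", object$data$dose[i],
                object$data$n_tested[i], object$data$n_responded[i],
                obs[i], fitted[i]))
  }
  invisible(object)
}

#' Compare initiating-cell frequencies between two assays
#'
#' Likelihood-ratio test (df = 1) of a shared single-hit frequency against
#' group-specific frequencies, plus the frequency fold-change `f_a / f_b`.
#'
#' @param a,b LDAssay data frames, both estimable (non-boundary).
#' @return Object of class `ld_comparison` with `fold_change`, `lrt`,
#'   `p_value`, and the two `ld_fit` objects.
#' @export
#' @examples
#' ctrl <- simulate_ld_assay(1 / 200, n_per_dose = 12, seed = 2, group = "ctrl")
#' kd <- simulate_ld_assay(1 / 1000, n_per_dose = 12, seed = 3, group = "kd")
#' compare_frequencies(ctrl, kd)
compare_frequencies <- function(a, b) {
  fit_a <- estimate_frequency(a)
  fit_b <- estimate_frequency(b)
  if (fit_a$boundary != "none" || fit_b$boundary != "none") {
    stop("boundary estimate (all or no responders) in a group; ",
         "inspect estimate_frequency() bounds instead", call. = FALSE)
  }
  pooled <- rbind(a[c("dose", "n_tested", "n_responded")],
                  b[c("dose", "n_tested", "n_responded")])
  fit_0 <- estimate_frequency(pooled)
  lrt <- 2 * (fit_a$log_likelihood + fit_b$log_likelihood -
                fit_0$log_likelihood)
  lrt <- max(lrt, 0)
  structure(list(
    fold_change = fit_a$frequency / fit_b$frequency,
    lrt = lrt,
    p_value = stats::pchisq(lrt, df = 1L, lower.tail = FALSE),
    fit_a = fit_a, fit_b = fit_b
  ), class = "ld_comparison")
}

#' @export
print.ld_comparison <- function(x, ...) {
  cat("Frequency comparison (single-hit model)\n")
  cat(sprintf("  group A: 1 in %.0f   group B: 1 in %.0f\n",
              x$fit_a$one_in, x$fit_b$one_in))
  cat(sprintf("  fold-change f_A / f_B = %.3g; LRT = %.3f (df 1), p = %.3g\n",
              x$fold_change, x$lrt, x$p_value))
  invisible(x)
}

#' Test the single-hit assumption
#'
#' Refits the binomial cloglog regression with a free slope on `log(dose)`
#' and Wald-tests slope = 1. Under the single-hit model the slope is 1;
#' a significant departure indicates multi-hit-like or heterogeneous
#' dose dependence.
#'
#' @param assay LDAssay with at least two distinct doses and a non-boundary
#'   response pattern.
#' @return List with `slope`, `se`, `statistic` (z), `p_value`.
#' @export
single_hit_adequacy <- function(assay) {
  check_ld_assay(assay)
  if (length(unique(assay$dose)) < 2L) {
    stop("slope is unidentifiable with a single dose", call. = FALSE)
  }
  fit <- stats::glm(
    cbind(n_responded, n_tested - n_responded) ~ log(dose),
    family = stats::binomial(link = "cloglog"), data = assay
  )
  slope <- unname(stats::coef(fit)["log(dose)"])
  se <- sqrt(stats::vcov(fit)["log(dose)", "log(dose)"])
  z <- (slope - 1) / se
  list(slope = slope, se = se, statistic = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Sphere-forming efficiency
#'
#' Percentage of plated cells that gave rise to spheres:
#' `100 * n_spheres / n_plated`.
#'
#' @param n_spheres Number of spheres counted (>= 0).
#' @param n_plated Number of cells plated (> 0).
#' @return SFE as a percentage.
#' @export
#' @examples
#' sphere_forming_efficiency(150, 1000)   # 15
sphere_forming_efficiency <- function(n_spheres, n_plated) {
  stop_if_not_scalar_number(n_spheres, "n_spheres", nonneg = TRUE)
  stop_if_not_scalar_number(n_plated, "n_plated", positive = TRUE)
  100 * n_spheres / n_plated
}

#' Ellipsoid tumor volume from caliper measurements
#'
#' `L * W^2 / 2`, with `L` the longest diameter and `W` the shorter one.
#' If the arguments arrive swapped they are exchanged with a warning.
#'
#' @param length Longest diameter (mm).
#' @param width Shorter diameter (mm).
#' @return Volume in mm^3.
#' @export
#' @examples
#' tumor_volume(10, 4)   # 80
tumor_volume <- function(length, width) {
  stop_if_not_scalar_number(length, "length", positive = TRUE)
  stop_if_not_scalar_number(width, "width", positive = TRUE)
  if (width > length) {
    warning("width > length; swapping inputs", call. = FALSE)
    tmp <- length; length <- width; width <- tmp
  }
  length * width^2 / 2
}
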