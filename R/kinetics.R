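GAS_CONSTANT_KCAL <- 1.987e-3 # kcal mol^-1 K^-1

check_time_course <- function(data) {
  stopifnot(is.data.frame(data), all(c("time", "fraction") %in% names(data)))
  t <- data$time
  f <- data$fraction
  if (length(t) < 3) stop("need at least 3 time points", call. = FALSE)
  if (any(t < 0) || any(diff(t) <= 0)) {
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  }
  if (any(f < 0 | f > 1)) {
    stop("fraction extended must lie in [0, 1]", call. = FALSE)
  }
  invisible(data)
}

#' Fit a pseudo-first-order primer-extension time course
#'
#' Fits `F(t) = P * (1 - exp(-k * t))` by nonlinear least squares, where
#' `k` is the pseudo-first-order rate constant (h^-1) and `P` the
#' reaction plateau (fitted, bounded in (0, 1], because primer-extension
#' end points rarely reach completion). Starting values come from the
#' log-linear transform `log(P0 - F) ~ t` with `P0 = min(1.05 * max(F), 1)`.
#'
#' @param data A data frame with columns `time` (hours, strictly
#'   increasing, >= 0) and `fraction` (fraction primer extended, in
#'   \[0, 1\]); at least 3 points.
#' @return An object of class `first_order_fit` with elements `kobs`,
#'   `plateau`, `kobs_se`, `plateau_se`, `converged`, `fit` (the
#'   underlying `nls` object) and `data`.
#' @examples
#' tc <- simulate_time_course(2, 0.9, seq(0, 3, 0.25), noise_sd = 0)
#' fit_first_order(tc)
#' @export
fit_first_order <- function(data) {
  check_time_course(data)
  f <- data$fraction
  if (max(f) <= 0) {
    stop("fit failure: no extension signal (all fractions zero)",
         call. = FALSE)
  }
  p0 <- min(max(f) * 1.05, 1)
  k0 <- tryCatch({
    sub <- data[p0 - data$fraction > 1e-12, ]
    -unname(stats::coef(stats::lm(log(p0 - fraction) ~ time, data = sub))[2])
  }, error = function(e) NA_real_)
  if (!is.finite(k0) || k0 <= 0) k0 <- 1 / max(data$time[data$time > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fraction ~ P * (1 - exp(-k * time)),
      data = data,
      start = list(k = k0, P = p0),
      lower = c(k = 1e-12, P = 1e-12),
      upper = c(k = Inf, P = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("fit failure: ", conditionMessage(e), call. = FALSE)
    }
  )
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(k = NA_real_, P = NA_real_))
  structure(
    list(kobs = unname(est["k"]), plateau = unname(est["P"]),
         kobs_se = unname(se["k"]), plateau_se = unname(se["P"]),
         converged = fit$convInfo$isConv %||% TRUE,
         fit = fit, data = data),
    class = "first_order_fit"
  )
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat(sprintf("<first_order_fit> kobs = %.4g h^-1 (SE %.3g), plateau = %.4g (SE %.3g)\n",
              x$kobs, x$kobs_se, x$plateau, x$plateau_se))
  invisible(x)
}

check_saturation_curve <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("concentration", "kobs") %in% names(data)))
  if (length(unique(data$concentration)) < 3) {
    stop("need at least 3 distinct concentrations", call. = FALSE)
  }
  if (any(data$concentration <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (any(data$kobs < 0)) stop("kobs must be non-negative", call. = FALSE)
  invisible(data)
}

#' Fit a Michaelis-Menten saturation curve
#'
#' Fits `kobs(c) = kobs_max * c / (Km + c)` to observed pseudo-first-order
#' rate constants as a function of substrate concentration, by unweighted
#' nonlinear least squares. Starting values come from the
#' double-reciprocal linearization `1/kobs ~ 1/c`. The specificity is
#' `kobs_max / Km` (h^-1 mM^-1), the low-concentration slope of the
#' curve. When the data show essentially no saturation the fit succeeds
#' with a wide-SE warning rather than failing silently.
#'
#' @param data A data frame with columns `concentration` (mM, > 0, at
#'   least 3 distinct values) and `kobs` (h^-1, >= 0). Replicate
#'   concentrations are allowed and weighted equally.
#' @return An object of class `mm_fit` with elements `kobs_max`, `Km`,
#'   `specificity`, `kobs_max_se`, `Km_se`, `converged`, `fit`, `data`.
#' @examples
#' sc <- tibble::tibble(concentration = c(0.01, 0.033, 0.1, 0.64, 2),
#'                      kobs = 20 * concentration / (0.033 + concentration))
#' fit_michaelis_menten(sc)
#' @export
fit_michaelis_menten <- function(data) {
  check_saturation_curve(data)
  ok <- data$kobs > 0
  init <- tryCatch({
    lb <- stats::lm(I(1 / kobs) ~ I(1 / concentration), data = data[ok, ])
    co <- stats::coef(lb)
    unname(c(1 / co[1], co[2] / co[1]))
  }, error = function(e) c(NA_real_, NA_real_))
  if (!all(is.finite(init)) || any(init <= 0)) {
    init <- c(max(data$kobs) * 1.5, stats::median(data$concentration))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      kobs ~ kmax * concentration / (Km + concentration),
      data = data,
      start = list(kmax = init[1], Km = init[2]),
      lower = c(kmax = 1e-12, Km = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      msg <- conditionMessage(e)
      if (grepl("singular gradient", msg)) {
        # exactly linear kobs(c): kmax and Km are not separately
        # identifiable, only their ratio (the specificity) is
        slope <- unname(stats::coef(
          stats::lm(kobs ~ 0 + concentration, data = data)))
        km_floor <- 1e6 * max(data$concentration)
        warning("little saturation in the data: only the specificity ",
                "kobs_max/Km is identifiable; Km is reported at an ",
                "arbitrary large value with infinite SE", call. = FALSE)
        return(structure(
          list(kobs_max = slope * km_floor, Km = km_floor,
               specificity = slope,
               kobs_max_se = Inf, Km_se = Inf,
               converged = FALSE, fit = NULL, data = data),
          class = "mm_fit"
        ))
      }
      stop("fit failure: ", msg, call. = FALSE)
    }
  )
  if (inherits(fit, "mm_fit")) return(fit)
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(kmax = NA_real_, Km = NA_real_))
  if (is.finite(se["Km"]) && se["Km"] > unname(est["Km"])) {
    warning("little saturation in the data: Km is poorly determined ",
            "(SE exceeds the estimate)", call. = FALSE)
  }
  structure(
    list(kobs_max = unname(est["kmax"]), Km = unname(est["Km"]),
         specificity = unname(est["kmax"] / est["Km"]),
         kobs_max_se = unname(se["kmax"]), Km_se = unname(se["Km"]),
         converged = fit$convInfo$isConv %||% TRUE,
         fit = fit, data = data),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> kobs_max = %.4g h^-1 (SE %.3g), Km = %.4g mM (SE %.3g)\n",
              x$kobs_max, x$kobs_max_se, x$Km, x$Km_se))
  cat(sprintf("  specificity kobs_max/Km = %.4g h^-1 mM^-1 (%.2g at 2 s.f.)\n",
              x$specificity, signif(x$specificity, 2)))
  invisible(x)
}

#' @rdname tidy_kinetics
#' @export
tidy.first_order_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kobs", "plateau"),
    estimate = c(x$kobs, x$plateau),
    std.error = c(x$kobs_se, x$plateau_se)
  )
}

#' Broom-style accessors for kinetic fits
#'
#' `tidy()` returns one row per fitted parameter with its standard error;
#' `glance()` returns a one-row model summary.
#'
#' @param x A `first_order_fit` or `mm_fit` object.
#' @param ... Unused.
#' @name tidy_kinetics
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kobs_max", "Km"),
    estimate = c(x$kobs_max, x$Km),
    std.error = c(x$kobs_max_se, x$Km_se)
  )
}

#' @rdname tidy_kinetics
#' @export
glance.first_order_fit <- function(x, ...) {
  tibble::tibble(
    kobs = x$kobs, plateau = x$plateau,
    sigma = tryCatch(summary(x$fit)$sigma, error = function(e) NA_real_),
    converged = x$converged, nobs = nrow(x$data)
  )
}

#' @rdname tidy_kinetics
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(
    kobs_max = x$kobs_max, Km = x$Km, specificity = x$specificity,
    sigma = tryCatch(summary(x$fit)$sigma, error = function(e) NA_real_),
    converged = x$converged, nobs = nrow(x$data)
  )
}

#' Binding free-energy difference from a Km ratio
#'
#' Treating Km as an effective dissociation constant of the
#' substrate-template complex, the free-energy difference between two
#' substrates is `ddG = R * T * log(Km_alt / Km_ref)` with
#' `R = 1.987e-3 kcal mol^-1 K^-1`; negative values mean the alternative
#' substrate binds more tightly.
#'
#' @param Km_alt,Km_ref Michaelis constants (mM, > 0) of the alternative
#'   and reference substrates.
#' @param temperature Temperature in kelvin (default 298.15, i.e. 25 C).
#' @return Free-energy difference in kcal/mol.
#' @examples
#' delta_delta_g(0.033, 0.64) # about -1.76
#' @export
delta_delta_g <- function(Km_alt, Km_ref, temperature = 298.15) {
  if (any(c(Km_alt, Km_ref, temperature) <= 0)) {
    stop("Km values and temperature must be positive", call. = FALSE)
  }
  GAS_CONSTANT_KCAL * temperature * log(Km_alt / Km_ref)
}

#' Stalling factor from a pair of rate constants
#'
#' `S = k_matched / k_mismatched`: the fold-reduction in the
#' primer-extension rate caused by a mismatched rather than complementary
#' terminal base pair.
#'
#' @param k_matched,k_mismatched Pseudo-first-order rate constants
#'   (h^-1, > 0) for extension past a complementary and a mismatched
#'   terminal pair.
#' @return The stalling factor S.
#' @examples
#' stalling_factor_rates(12, 1) # 12
#' @export
stalling_factor_rates <- function(k_matched, k_mismatched) {
  if (any(c(k_matched, k_mismatched) <= 0)) {
    stop("rate constants must be positive", call. = FALSE)
  }
  k_matched / k_mismatched
}

#' Simulate a pseudo-first-order time course
#'
#' Generates `fraction = plateau * (1 - exp(-k * time))` with additive
#' Gaussian noise, clipped to \[0, 1\] — a seeded fixture generator for
#' testing the kinetic fitters.
#'
#' @param k Rate constant (h^-1, > 0).
#' @param plateau Reaction plateau in (0, 1\].
#' @param times Time points (hours).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Optional integer seed.
#' @return A tibble with `time` and `fraction`.
#' @export
simulate_time_course <- function(k, plateau, times, noise_sd = 0,
                                 seed = NULL) {
  stopifnot(k > 0, plateau > 0, plateau <= 1, all(times >= 0))
  if (!is.null(seed)) set.seed(seed)
  f <- plateau * (1 - exp(-k * times))
  if (noise_sd > 0) f <- f + stats::rnorm(length(times), 0, noise_sd)
  tibble::tibble(time = times, fraction = pmin(pmax(f, 0), 1))
}
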