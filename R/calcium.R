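# Hill calibration of anisotropy vs free Ca2+ and its inversion.

#' Construct a Hill calibration
#'
#' Four-parameter Hill dose-response mapping free Ca2+ concentration to
#' sensor anisotropy:
#' `r(c) = r_free + (r_bound - r_free) * c^n / (Kd'^n + c^n)`.
#'
#' @param n_hill Hill coefficient, > 0.
#' @param kd_app Apparent dissociation constant Kd' in nM, > 0.
#' @param r_free Anisotropy at zero Ca2+.
#' @param r_bound Anisotropy at saturating Ca2+ (must differ from `r_free`).
#' @param std_errors Optional named numeric vector of parameter
#'   uncertainties.
#' @return An object of class `hill_cal`.
#' @examples
#' hill_calibration(1.9, 71, 0.10, -0.03)
#' @export
hill_calibration <- function(n_hill, kd_app, r_free, r_bound,
                             std_errors = NULL) {
  stopifnot(is.finite(n_hill), is.finite(kd_app), n_hill > 0, kd_app > 0)
  if (r_free == r_bound) abort("`r_free` and `r_bound` must differ.")
  structure(
    list(
      n_hill = n_hill, kd_app = kd_app, r_free = r_free, r_bound = r_bound,
      std_errors = std_errors
    ),
    class = "hill_cal"
  )
}

#' @export
print.hill_cal <- function(x, ...) {
  cat(sprintf(
    "Hill calibration: n = %.3g, Kd' = %.4g nM, r_free = %.3g, r_bound = %.3g\n",
    x$n_hill, x$kd_app, x$r_free, x$r_bound
  ))
  invisible(x)
}

#' Hill model: anisotropy at a free Ca2+ concentration
#'
#' @param conc Free Ca2+ concentration(s) in nM, >= 0.
#' @param cal A [hill_calibration()].
#' @return Anisotropy value(s).
#' @export
hill_model <- function(conc, cal) {
  if (any(conc < 0)) abort("`conc` must be >= 0.")
  h <- conc^cal$n_hill / (cal$kd_app^cal$n_hill + conc^cal$n_hill)
  h[is.infinite(conc)] <- 1
  cal$r_free + (cal$r_bound - cal$r_free) * h
}

#' Fit the Hill dose-response of a titration table
#'
#' Non-linear least squares (Levenberg-Marquardt) over
#' `(n, Kd', r_free, r_bound)`, with deterministic initialization: plateau
#' values from the concentration extremes, `Kd'` from the point nearest the
#' midpoint response, `n = 1`. The fit is orientation-agnostic (increasing or
#' decreasing response) and, through fitting `log Kd'`, invariant under
#' concentration unit rescaling.
#'
#' @param table Tibble with columns `conc` (nM) and `r`, optionally `sigma`
#'   (per-point uncertainty used as weights). At least 5 points spanning at
#'   least one decade.
#' @return A `hill_fit` object; the calibration itself is in `$calibration`.
#' @examples
#' tt <- make_titration(seed = 1)
#' fit <- fit_hill(tt)
#' glance(fit)
#' @export
fit_hill <- function(table) {
  if (!all(c("conc", "r") %in% names(table))) {
    abort("`table` needs columns `conc` and `r`.")
  }
  if (nrow(table) < 5) abort("Need at least 5 titration points.")
  pos <- table$conc[table$conc > 0]
  if (length(pos) < 2 || max(pos) / min(pos) < 10) {
    abort("Concentrations must span at least one decade.")
  }
  tab <- dplyr::arrange(table, .data$conc)
  w <- if (!is.null(tab$sigma)) 1 / pmax(tab$sigma, 1e-6) else rep(1, nrow(tab))
  r_free0 <- tab$r[1]
  r_bound0 <- tab$r[nrow(tab)]
  mid <- (r_free0 + r_bound0) / 2
  kd0 <- tab$conc[which.min(abs(tab$r - mid))]
  if (kd0 <= 0) kd0 <- stats::quantile(pos, 0.5)
  if (!(kd0 >= min(pos) && kd0 <= max(pos))) {
    warn("Concentration range may not bracket Kd'; fit may be poorly constrained.")
  }
  resid_fn <- function(par) {
    cal <- hill_calibration(exp(par[1]), exp(par[2]), par[3], par[4])
    (tab$r - hill_model(tab$conc, cal)) * w
  }
  fit <- minpack.lm::nls.lm(
    par = c(log(1), log(kd0), r_free0, r_bound0),
    lower = c(log(0.1), log(min(pos) / 100), -0.5, -0.5),
    upper = c(log(10), log(max(pos) * 100), 1, 1),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (fit$info == 0 || fit$info == 5) warn("Hill fit did not converge.")
  n_hat <- exp(fit$par[1])
  kd_hat <- exp(fit$par[2])
  se <- tryCatch(
    {
      cv <- solve(fit$hessian)
      s <- sqrt(pmax(diag(cv), 0))
      c(
        n_hill = n_hat * s[1], kd_app = kd_hat * s[2],
        r_free = s[3], r_bound = s[4]
      )
    },
    error = function(e) {
      c(n_hill = NA_real_, kd_app = NA_real_, r_free = NA_real_, r_bound = NA_real_)
    }
  )
  cal <- hill_calibration(n_hat, kd_hat, fit$par[3], fit$par[4], std_errors = se)
  structure(
    list(
      calibration = cal,
      residuals = tab$r - hill_model(tab$conc, cal),
      data = tab,
      converged = !(fit$info %in% c(0, 5))
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  print(x$calibration)
  invisible(x)
}

#' @rdname fit_hill
#' @param x,object A `hill_fit` object.
#' @param ... Unused.
#' @export
tidy.hill_fit <- function(x, ...) {
  cal <- x$calibration
  tibble(
    term = c("n_hill", "kd_app", "r_free", "r_bound"),
    estimate = c(cal$n_hill, cal$kd_app, cal$r_free, cal$r_bound),
    std.error = unname(cal$std_errors)
  )
}

#' @rdname fit_hill
#' @export
glance.hill_fit <- function(x, ...) {
  cal <- x$calibration
  tibble(
    n_hill = cal$n_hill, kd_app = cal$kd_app, r_free = cal$r_free,
    r_bound = cal$r_bound, rss = sum(x$residuals^2),
    n_points = nrow(x$data), converged = x$converged
  )
}

#' @rdname fit_hill
#' @export
autoplot.hill_fit <- function(object, ...) {
  cal <- object$calibration
  pos <- object$data$conc[object$data$conc > 0]
  grid <- 10^seq(log10(min(pos)) - 0.3, log10(max(pos)) + 0.3, length.out = 200)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc, y = .data$r)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = tibble(conc = grid, r = hill_model(grid, cal)),
      colour = "red"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "free Ca2+ (nM)", y = "anisotropy r")
}

#' Invert a Hill calibration: concentration from anisotropy
#'
#' Closed-form inversion
#' `c = Kd' * ((r_free - r) / (r - r_bound))^(1/n)`. Values outside the open
#' interval between `r_free` and `r_bound` are clamped to the nearer bound
#' (0 or Inf nM) and flagged in the `clamped` attribute, with a warning.
#'
#' @param r Anisotropy value(s).
#' @param cal A [hill_calibration()] or `hill_fit`.
#' @return Free Ca2+ concentration(s) in nM, with a logical attribute
#'   `clamped`.
#' @examples
#' cal <- hill_calibration(1.9, 71, 0.10, -0.03)
#' invert_calibration(hill_model(150, cal), cal) # 150
#' @export
invert_calibration <- function(r, cal) {
  if (inherits(cal, "hill_fit")) cal <- cal$calibration
  lo <- min(cal$r_free, cal$r_bound)
  hi <- max(cal$r_free, cal$r_bound)
  clamped <- r <= lo | r >= hi
  rc <- pmin(pmax(r, lo), hi)
  out <- cal$kd_app * ((cal$r_free - rc) / (rc - cal$r_bound))^(1 / cal$n_hill)
  out[rc == cal$r_free] <- 0
  out[rc == cal$r_bound] <- Inf
  if (any(clamped)) {
    warn("Some anisotropy values lie outside the calibration range; clamped.")
  }
  attr(out, "clamped") <- clamped
  out
}
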