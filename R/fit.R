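#' Fit the Jeffreys model to a recovered modulus curve
#'
#' Levenberg-Marquardt fit of the analytic single-mode Jeffreys modulus
#' (parameters `G`, `tau`, `eta1`, all positive, optimised in log space) to
#' a measured/recovered `G*(omega)`. Residuals are the real and imaginary
#' misfits scaled by `|G*|` at each frequency, so both components are
#' weighted evenly across the decades. Flagged frequencies (`in_band =
#' FALSE` or `trap_dominated = TRUE`, when present) are excluded.
#'
#' @param curve A [modulus_curve()].
#' @param start Optional named list/vector with starting values `G`, `tau`,
#'   `eta1`; `NULL` for data-driven heuristics (high-frequency `G'` plateau,
#'   half-plateau crossing, high-frequency `G''/omega`).
#' @return An object of class `jeffreys_fit` with [tidy()] and [glance()]
#'   methods; fields `estimate` (named vector), `fitted` (model curve on
#'   the data grid), `data`, `convergence` info.
#' @examples
#' fl <- jeffreys_fluid(1e-3, eta2 = 0.01, G = 1e-3)
#' curve <- complex_modulus_jeffreys(fl, 10^seq(-2, 2, 0.2))
#' fit <- fit_jeffreys(curve)
#' tidy(fit)
#' @export
fit_jeffreys <- function(curve, start = NULL) {
  dat <- as_tibble(curve)
  if ("in_band" %in% names(dat)) dat <- dat[dat$in_band, ]
  if ("trap_dominated" %in% names(dat)) dat <- dat[!dat$trap_dominated, ]
  dat <- dat[is.finite(dat$g_prime) & is.finite(dat$g_loss), ]
  if (nrow(dat) < 4L) abort("too few usable frequencies to fit.")
  w <- dat$omega
  mag <- Mod(complex(real = dat$g_prime, imaginary = dat$g_loss))

  if (is.null(start)) {
    hi <- order(w, decreasing = TRUE)[seq_len(max(2L, nrow(dat) %/% 5L))]
    G0 <- max(mean(dat$g_prime[hi]), 1e-12)
    eta10 <- max(mean((dat$g_loss / w)[hi]), 1e-15)
    half <- which.min(abs(dat$g_prime - G0 / 2))
    tau0 <- 1 / w[half]
    start <- c(G = G0, tau = tau0, eta1 = eta10)
  }
  start <- unlist(start)[c("G", "tau", "eta1")]
  if (anyNA(start) || any(start <= 0)) abort("`start` must give positive G, tau, eta1.")

  resid_fn <- function(logp) {
    p <- exp(logp)
    den <- 1 + w^2 * p[2L]^2
    gp <- p[1L] * w^2 * p[2L]^2 / den
    gl <- w * (p[3L] + p[1L] * p[2L] / den)
    c((gp - dat$g_prime) / mag, (gl - dat$g_loss) / mag)
  }
  res <- minpack.lm::nls.lm(par = log(start), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- exp(res$par)
  names(est) <- c("G", "tau", "eta1")
  fitted_fluid <- jeffreys_fluid(eta1 = est[["eta1"]],
                                 eta2 = est[["G"]] * est[["tau"]],
                                 G = est[["G"]])
  structure(
    list(estimate = est,
         fluid = fitted_fluid,
         fitted = complex_modulus_jeffreys(fitted_fluid, w),
         data = dat,
         convergence = list(info = res$info, message = res$message,
                            niter = res$niter,
                            rmse = sqrt(mean(res$fvec^2)))),
    class = "jeffreys_fit"
  )
}

#' @export
print.jeffreys_fit <- function(x, ...) {
  cat("<Jeffreys modulus fit>\n")
  cat(sprintf("  G    = %.4g Pa\n  tau  = %.4g s\n  eta1 = %.4g Pa s\n",
              x$estimate[["G"]], x$estimate[["tau"]], x$estimate[["eta1"]]))
  cat(sprintf("  relative rmse %.3g over %d frequencies\n",
              x$convergence$rmse, nrow(x$data)))
  invisible(x)
}

#' @rdname fit_jeffreys
#' @param x A `jeffreys_fit`.
#' @param ... Unused.
#' @export
tidy.jeffreys_fit <- function(x, ...) {
  tibble(term = names(x$estimate), estimate = unname(x$estimate))
}

#' @rdname fit_jeffreys
#' @export
glance.jeffreys_fit <- function(x, ...) {
  tibble(rmse = x$convergence$rmse,
         niter = x$convergence$niter,
         converged = x$convergence$info %in% 1:3,
         nobs = nrow(x$data))
}
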