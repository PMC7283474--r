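## 1:1 Langmuir SPR binding model: closed-form simulation, equilibrium
## (steady-state) KD fits and global kinetic kon/koff fits.
##
## Association: R(t) = Req (1 - exp(-(kon C + koff) t)),
##              Req  = Rmax C / (C + KD),  KD = koff / kon.
## Dissociation from the association end point: R(t) = R_end exp(-koff dt).
## The model is evaluated in closed form; no ODE integration is needed.

#' Kinetic parameter set for the 1:1 binding model
#'
#' @param kon Association rate, 1/(M s); must be > 0.
#' @param koff Dissociation rate, 1/s; must be >= 0.
#' @param rmax Saturating response, RU; must be > 0.
#' @return A `kinetic_params` list with the derived `kd` (M).
#' @export
kinetic_params <- function(kon, koff, rmax) {
  if (kon <= 0) stop_tcrpmhc("kon must be positive", "tcrpmhc_domain_error")
  if (koff < 0) stop_tcrpmhc("koff must be non-negative", "tcrpmhc_domain_error")
  if (rmax <= 0) stop_tcrpmhc("rmax must be positive", "tcrpmhc_domain_error")
  structure(list(kon = kon, koff = koff, rmax = rmax,
                 kd = kd_from_rates(kon, koff)),
            class = "kinetic_params")
}

#' Equilibrium dissociation constant from rate constants
#'
#' `KD = koff / kon`.
#'
#' @param kon Association rate constant, 1/(M s).
#' @param koff Dissociation rate constant, 1/s.
#' @return KD in molar.
#' @examples
#' kd_from_rates(2.5e4, 0.032)  # 1.28e-6 M, i.e. 1.3 uM at 2 sig. figures
#' @export
kd_from_rates <- function(kon, koff) {
  if (any(kon <= 0)) stop_tcrpmhc("kon must be positive", "tcrpmhc_domain_error")
  koff / kon
}

#' Simulate a 1:1 sensorgram
#'
#' Closed-form association and dissociation phases with optional
#' additive Gaussian noise (RU) and an optional multiplicative term.
#' Deterministic for a fixed seed; the caller's RNG state is preserved.
#'
#' @param params A `kinetic_params` (or list with kon, koff, rmax).
#' @param conc Analyte concentration, M (>= 0).
#' @param t_assoc Association phase duration, s.
#' @param t_dissoc Dissociation phase duration, s.
#' @param dt Sampling interval, s.
#' @param noise_sd Additive noise standard deviation, RU.
#' @param noise_cv Multiplicative noise coefficient of variation.
#' @param seed Integer seed; `NULL` uses (and advances) the session RNG.
#' @return A `sensorgram`: data frame with `time` and `response`,
#'   attributes `conc` (M) and `t_assoc` (s).
#' @export
simulate_sensorgram <- function(params, conc, t_assoc, t_dissoc,
                                dt = 1, noise_sd = 0, noise_cv = 0,
                                seed = NULL) {
  if (conc < 0) stop_tcrpmhc("concentration must be non-negative",
                             "tcrpmhc_domain_error")
  if (t_assoc <= 0 || t_dissoc < 0 || dt <= 0) {
    stop_tcrpmhc("durations and dt must be positive", "tcrpmhc_domain_error")
  }
  time <- seq(0, t_assoc + t_dissoc, by = dt)
  response <- langmuir_response(time, conc, t_assoc,
                                params$kon, params$koff, params$rmax)
  if (noise_sd > 0 || noise_cv > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      }
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    response <- response * (1 + noise_cv * rnorm(length(time))) +
      noise_sd * rnorm(length(time))
  }
  out <- data.frame(time = time, response = response)
  attr(out, "conc") <- conc
  attr(out, "t_assoc") <- t_assoc
  class(out) <- c("sensorgram", "data.frame")
  out
}

## Vectorised closed-form 1:1 response.
langmuir_response <- function(time, conc, t_assoc, kon, koff, rmax) {
  kd <- koff / kon
  req <- if (conc + kd > 0) rmax * conc / (conc + kd) else 0
  kobs <- kon * conc + koff
  assoc <- time <= t_assoc
  r <- numeric(length(time))
  r[assoc] <- req * (1 - exp(-kobs * time[assoc]))
  r_end <- req * (1 - exp(-kobs * t_assoc))
  r[!assoc] <- r_end * exp(-koff * (time[!assoc] - t_assoc))
  r
}

#' Fit the equilibrium (steady-state) binding isotherm
#'
#' Nonlinear least squares of `Req(C) = Rmax C / (C + KD)` on
#' concentration/steady-response pairs, unweighted.
#'
#' @param conc Analyte concentrations, M (or a 2-column data frame of
#'   conc and response).
#' @param response Steady-state responses, RU.
#' @return An `equilibrium_fit`: list with `kd` (M), `rmax` (RU),
#'   `se_kd`, `se_rmax`, `residual_sse` (RU^2), `n`, and
#'   `poorly_determined` (`TRUE` unless the concentrations span both
#'   sides of the fitted KD with at least 3 distinct values).
#' @export
fit_equilibrium <- function(conc, response = NULL) {
  if (is.null(response)) { response <- conc[[2]]; conc <- conc[[1]] }
  if (length(unique(conc)) < 2) {
    stop_tcrpmhc("need at least 2 distinct concentrations to identify KD",
                 "tcrpmhc_identifiability_error")
  }
  if (all(abs(response) < 1e-12)) {
    stop_tcrpmhc("all responses are zero; isotherm is degenerate",
                 "tcrpmhc_fit_error")
  }
  rmax0 <- max(response) * 1.5
  half <- max(response) / 2
  kd0 <- conc[which.min(abs(response - half))]
  if (kd0 <= 0) kd0 <- median(conc)
  dat <- data.frame(conc = conc, response = response)
  fit <- tryCatch(
    minpack.lm::nlsLM(response ~ rmax * conc / (conc + kd),
                      data = dat,
                      start = list(rmax = rmax0, kd = kd0),
                      lower = c(rmax = 1e-12, kd = 1e-15),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop_tcrpmhc(paste("equilibrium fit failed:", conditionMessage(e)),
                   "tcrpmhc_fit_error")
    })
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(rmax = NA_real_, kd = NA_real_))
  poorly <- length(unique(conc)) < 3 ||
    !(min(conc) < est["kd"] && max(conc) > est["kd"])
  out <- list(kd = unname(est["kd"]), rmax = unname(est["rmax"]),
              se_kd = unname(se["kd"]), se_rmax = unname(se["rmax"]),
              residual_sse = sum(stats::resid(fit)^2),
              n = length(conc), poorly_determined = poorly)
  class(out) <- "equilibrium_fit"
  out
}

#' @export
print.equilibrium_fit <- function(x, ...) {
  cat(sprintf("<equilibrium_fit> KD = %.3g M (SE %.2g), Rmax = %.3g RU (SE %.2g), n = %d%s\n",
              x$kd, x$se_kd, x$rmax, x$se_rmax, x$n,
              if (x$poorly_determined) " [poorly determined]" else ""))
  invisible(x)
}

#' Global kinetic fit of 1:1 sensorgrams
#'
#' Fits kon, koff and Rmax jointly across a concentration series by
#' unweighted nonlinear least squares on the closed-form model
#' (association and dissociation phases together).  Parameters are
#' fitted on the log scale to enforce positivity.
#'
#' @param sensorgrams List of `sensorgram` objects (>= 2 concentrations,
#'   both phases present in each).
#' @param kobs_threshold Resolvability limit for the observed rate
#'   `kobs = kon C + koff`, 1/s; the fit is flagged unreliable when the
#'   largest kobs exceeds it.  Default: half the sampling rate
#'   (0.5 / median time step), beyond which the exponential rise is not
#'   resolved by the time grid.
#' @return A `kinetic_params` with additional fields `rmsd_ru`
#'   (residual RMS in RU), `kobs_max`, `kobs_threshold` and `reliable`.
#' @export
fit_kinetics <- function(sensorgrams, kobs_threshold = NULL) {
  if (length(sensorgrams) < 2) {
    stop_tcrpmhc("need sensorgrams at >= 2 concentrations",
                 "tcrpmhc_identifiability_error")
  }
  concs <- vapply(sensorgrams, function(s) attr(s, "conc"), numeric(1))
  tas <- vapply(sensorgrams, function(s) attr(s, "t_assoc"), numeric(1))
  for (k in seq_along(sensorgrams)) {
    s <- sensorgrams[[k]]
    if (!any(s$time <= tas[k]) || !any(s$time > tas[k])) {
      stop_tcrpmhc("sensorgram lacks an association or dissociation phase",
                   "tcrpmhc_phase_error")
    }
    if (any(diff(s$time) <= 0)) {
      stop_tcrpmhc("time must be strictly increasing", "tcrpmhc_phase_error")
    }
  }
  time <- unlist(lapply(sensorgrams, `[[`, "time"))
  resp <- unlist(lapply(sensorgrams, `[[`, "response"))
  conc <- rep(concs, vapply(sensorgrams, nrow, integer(1)))
  tass <- rep(tas, vapply(sensorgrams, nrow, integer(1)))

  ## starting values: koff from the tail of the highest-concentration
  ## dissociation, rmax from the largest response, kon from koff/KD0
  hi <- which.max(concs)
  sh <- sensorgrams[[hi]]
  dis <- sh[sh$time > tas[hi] & sh$response > 0, , drop = FALSE]
  koff0 <- 0.01
  if (nrow(dis) >= 3) {
    sl <- stats::lm(log(response) ~ time, data = dis)
    koff0 <- max(1e-5, -unname(coef(sl)[2]))
  }
  rmax0 <- max(resp) * 1.5
  kd0 <- median(concs)
  kon0 <- koff0 / kd0

  model <- function(lkon, lkoff, lrmax) {
    langmuir_global(time, conc, tass, exp(lkon), exp(lkoff), exp(lrmax))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(resp ~ model(lkon, lkoff, lrmax),
                      start = list(lkon = log(kon0), lkoff = log(koff0),
                                   lrmax = log(rmax0)),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop_tcrpmhc(paste("kinetic fit failed:", conditionMessage(e)),
                   "tcrpmhc_fit_error")
    })
  est <- exp(coef(fit))
  out <- kinetic_params(est[["lkon"]], est[["lkoff"]], est[["lrmax"]])
  out$rmsd_ru <- sqrt(mean(stats::resid(fit)^2))
  dts <- unlist(lapply(sensorgrams, function(s) diff(s$time)))
  out$kobs_threshold <- kobs_threshold %||% (0.5 / median(dts))
  out$kobs_max <- out$kon * max(concs) + out$koff
  out$reliable <- out$kobs_max <= out$kobs_threshold
  out
}

langmuir_global <- function(time, conc, t_assoc, kon, koff, rmax) {
  out <- numeric(length(time))
  for (c0 in unique(conc)) {
    sel <- conc == c0
    out[sel] <- langmuir_response(time[sel], c0, t_assoc[sel][1],
                                  kon, koff, rmax)
  }
  out
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> kon = %.3g 1/(M s), koff = %.3g 1/s, KD = %.3g M, Rmax = %.3g RU\n",
              x$kon, x$koff, x$kd, x$rmax))
  if (!is.null(x$reliable) && !x$reliable) {
    cat(sprintf("  warning: kobs_max %.3g 1/s exceeds resolvability threshold %.3g\n",
                x$kobs_max, x$kobs_threshold))
  }
  invisible(x)
}

#' Read or write sensorgrams as TSV
#'
#' Columns `time`, `response`, `conc` (M), `t_assoc` (s); multiple
#' concentrations are stacked and split on read.
#'
#' @param sensorgrams List of `sensorgram` objects.
#' @param path File path.
#' @return `write_sensorgrams`: `path`; `read_sensorgrams`: list of
#'   `sensorgram` objects.
#' @export
write_sensorgrams <- function(sensorgrams, path) {
  tab <- do.call(rbind, lapply(sensorgrams, function(s) {
    data.frame(time = s$time, response = s$response,
               conc = attr(s, "conc"), t_assoc = attr(s, "t_assoc"))
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensorgrams
#' @export
read_sensorgrams <- function(path) {
  tab <- read.delim(path, sep = "\t")
  lapply(split(tab, tab$conc), function(d) {
    out <- data.frame(time = d$time, response = d$response)
    attr(out, "conc") <- d$conc[1]
    attr(out, "t_assoc") <- d$t_assoc[1]
    class(out) <- c("sensorgram", "data.frame")
    out
  })
}
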