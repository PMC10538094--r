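# Independent oracles used to cross-check the implementation paths.

# Brute-force minimiser of the weighted least-squares objective via a
# generic numeric optimiser (never touches fit_calibration's lm path).
oracle_wls <- function(batch, weighting = "1/x") {
  w <- switch(weighting,
              "unweighted" = rep(1, nrow(batch)),
              "1/x" = 1 / batch$level,
              "1/x^2" = 1 / batch$level^2)
  obj <- function(par) sum(w * (batch$response - par[1] * batch$level - par[2])^2)
  fit <- stats::optim(c(1, 0), obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 10000))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 10000))
  c(slope = fit$par[1], intercept = fit$par[2])
}

# Exhaustive enumeration of candidate terminal windows using stats::lm,
# independent of the package's fast window scan.
oracle_select_window <- function(profile, min_points = 3L, tie_tol = 1e-9) {
  q <- !profile$blq & !is.na(profile$conc)
  conc <- profile$conc
  times <- profile$times
  cmax_i <- which(q)[which.max(conc[q])]
  elig <- which(q & times > times[cmax_i] & conc > 0)
  if (length(elig) < min_points) return(integer(0))
  wins <- lapply(seq_len(length(elig) - min_points + 1L),
                 function(s) elig[s:length(elig)])
  r2a <- vapply(wins, function(idx) {
    s <- summary(stats::lm(log(conc[idx]) ~ times[idx]))$adj.r.squared
    if (is.nan(s)) -Inf else s
  }, numeric(1))
  best <- max(r2a)
  tied <- which(r2a >= best - tie_tol)
  wins[[tied[which.max(lengths(wins)[tied])]]]
}

# Typical-subject parameters used across tests (single-peak oral profile).
typical_params <- function() pk_params()

# A short, strictly decaying multi-exponential profile with a defined peak,
# for window-selection oracle checks.
biexp_profile <- function() {
  times <- c(0, 0.5, 1, 1.5, 2, 3, 5, 8, 12, 24)
  conc <- 60 * exp(-0.8 * pmax(times - 0.25, 0)) +
    25 * exp(-0.15 * pmax(times - 0.25, 0))
  conc[1] <- 0
  pk_profile("BX", 100, times, conc)
}

study_schedule <- c(0, 0.5, 1, 1.5, 2, 3, 5, 8, 24)
printed_levels <- c(7.5, 10, 25, 50, 100, 250, 500)
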