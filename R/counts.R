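#' Transcript count variability
#'
#' The coefficient `eta = var / mean` of the renewal cycle time between
#' successive transcription events. By renewal theory the transcript count
#' `N(t)` has squared coefficient of variation approximately `eta / t`, so
#' `eta` (which carries units of time) measures the cell-to-cell variability
#' in total transcript number at any late time.
#'
#' @param mu mean cycle time (> 0).
#' @param var cycle time variance (>= 0).
#' @return `var / mu`.
#' @export
eta <- function(mu, var) {
  if (any(mu <= 0)) stop_domain("mean cycle time must be positive")
  if (any(var < 0)) stop_domain("cycle variance must be nonnegative")
  var / mu
}

#' Reinitiation cycle model
#'
#' Describes the renewal cycle between successive transcription events when a
#' residual scaffold of general transcription factors may survive each firing.
#' With probability `ps` the scaffold survives and the next polymerase is
#' recruited at the scaffold restart state; with probability `1 - ps` the
#' scaffold disassembles and activation restarts from the fully unbound state
#' `(initial, A)`. Repeated scaffold survivals produce bursts of transcripts
#' from a single promoter-opening event, with geometric burst size of mean
#' `1 / (1 - ps)`.
#'
#' The enhancer coordinate at a scaffold restart is set by `restart_policy`:
#' `"bound"` (default; both gates require the permissive configuration at the
#' moment of synthesis, and it is frozen downstream), `"unbound"`, or
#' `"stationary"` (resampled from the enhancer's stationary law).
#'
#' @param spec a [gated_chain_spec()] with a `scaffold_state` (all catalog
#'   models have one).
#' @param rates named rate vector.
#' @param ps scaffold survival probability in `[0, 1]`.
#' @param restart_policy `"bound"`, `"unbound"`, or `"stationary"`.
#' @return an object of class `cycle_model` with the full-restart chain, the
#'   scaffold-restart chain and its start distribution.
#' @export
cycle_model <- function(spec, rates, ps = 0,
                        restart_policy = c("bound", "unbound", "stationary")) {
  stopifnot(inherits(spec, "gated_chain_spec"))
  restart_policy <- match.arg(restart_policy)
  if (ps < 0 || ps > 1) stop_domain("ps must lie in [0, 1]")
  if (is.null(spec$scaffold_state))
    stop_spec("the model has no scaffold restart state")
  rates <- check_rates(spec, rates)
  chain_start <- build_composite(spec, rates)
  s <- spec$scaffold_state
  if (restart_policy == "bound") {
    chain_scaffold <- build_composite(spec, rates, start = c(s, "B"))
    alpha <- NULL
  } else if (restart_policy == "unbound") {
    chain_scaffold <- build_composite(spec, rates, start = c(s, "A"))
    alpha <- NULL
  } else {
    # stationary: chain built from (s, A) contains both enhancer coordinates
    chain_scaffold <- build_composite(spec, rates, start = c(s, "A"))
    sub <- stopped_subgenerator(chain_scaffold)
    pi_b <- rates[["k_on"]] / (rates[["k_on"]] + rates[["k_off"]])
    alpha <- numeric(length(sub$states))
    alpha[[match(paste0(s, "A"), sub$states)]] <- 1 - pi_b
    alpha[[match(paste0(s, "B"), sub$states)]] <- pi_b
  }
  structure(list(chain_start = chain_start, chain_scaffold = chain_scaffold,
                 scaffold_alpha = alpha, ps = ps,
                 restart_policy = restart_policy, rates = rates, spec = spec),
            class = "cycle_model")
}

#' Moments of the stationary reinitiation cycle
#'
#' The stationary cycle time is a two-component mixture: with probability
#' `ps` the passage time from the scaffold restart state, with probability
#' `1 - ps` the passage time from the fully unbound state. Raw moments
#' combine linearly across the mixture; the variance is formed from the
#' mixture raw moments.
#'
#' @param cycle a [cycle_model()].
#' @return list with `mean`, `var`, and `raw_moments` of the cycle time.
#' @export
cycle_moments <- function(cycle) {
  stopifnot(inherits(cycle, "cycle_model"))
  m_full <- fpt_moments(cycle$chain_start)
  m_scaf <- fpt_moments(cycle$chain_scaffold, start = cycle$scaffold_alpha)
  raw <- cycle$ps * m_scaf$raw_moments + (1 - cycle$ps) * m_full$raw_moments
  list(mean = raw[[1L]], var = raw[[2L]] - raw[[1L]]^2, raw_moments = raw)
}

#' Renewal statistics of the transcript count
#'
#' Applies the elementary renewal approximations to the stationary cycle:
#' `N(t)` has mean about `t / mu`, variance about `t * var / mu^3`, squared
#' coefficient of variation about `eta / t` with `eta = var / mu`, and Fano
#' factor about `var / mu^2`. The approximations are asymptotic in `t / mu`
#' and exact at all `t` for exponential (Poisson) cycles.
#'
#' @param cycle a [cycle_model()].
#' @param t elapsed time since induction (> 0).
#' @return an object of class `count_stats`: list with `t`, `mean_N`,
#'   `var_N`, `cv2`, `eta`, and `fano`.
#' @export
count_stats <- function(cycle, t) {
  stopifnot(inherits(cycle, "cycle_model"))
  if (any(t <= 0)) stop_domain("t must be positive")
  m <- cycle_moments(cycle)
  structure(list(t = t, mean_N = t / m$mean, var_N = t * m$var / m$mean^3,
                 cv2 = (m$var / m$mean) / t, eta = eta(m$mean, m$var),
                 fano = m$var / m$mean^2,
                 cycle_mean = m$mean, cycle_var = m$var),
            class = "count_stats")
}

#' @exportS3Method base::print
print.count_stats <- function(x, ...) {
  cat(sprintf("Transcript count statistics at t = %g:\n", x$t))
  cat(sprintf("  mean N = %.6g, var N = %.6g, CV^2 = %.6g\n",
              x$mean_N, x$var_N, x$cv2))
  cat(sprintf("  eta = %.6g (time units), Fano = %.6g\n", x$eta, x$fano))
  invisible(x)
}

#' Mean burst size under geometric scaffold survival
#'
#' The number of transcripts synthesized per promoter-opening event is
#' geometric with success probability `1 - ps`, so the mean burst size is
#' `1 / (1 - ps)`.
#'
#' @param ps scaffold survival probability in `[0, 1)`.
#' @return mean burst size (>= 1).
#' @export
mean_burst_size <- function(ps) {
  if (any(ps < 0) || any(ps > 1)) stop_domain("ps must lie in [0, 1]")
  if (any(ps == 1))
    stop_gatedtx("ps = 1 gives an infinite mean burst size",
                 "gatedtx_infinite_burst_error")
  1 / (1 - ps)
}

#' Scaffold-survival regimes examined in the bursting sweeps
#'
#' The four regimes span a fully stable scaffold (`ps = 1`), mean burst sizes
#' of 10 and 1.4 (`ps = 0.9` and `ps = 1 - 1/1.4`), and no bursting
#' (`ps = 0`).
#'
#' @return named numeric vector of scaffold survival probabilities.
#' @export
ps_regimes <- function() {
  c(stable = 1.0, burst10 = 0.9, burst1.4 = 1 - 1 / 1.4, none = 0.0)
}
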