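#' Exact stochastic simulation of the induction-to-expression delay
#'
#' Gillespie simulation of the composite chain from its start state to
#' absorption. Each replicate runs on its own random substream derived from
#' the master seed, so results are reproducible and independent of execution
#' order. This is the brute-force oracle for the analytic first-passage
#' quantities.
#'
#' @param chain a `composite_chain`.
#' @param n_reps number of replicates (>= 1).
#' @param seed master seed (integer).
#' @param keep_paths if `TRUE`, also record the visited states and entry
#'   times of each trajectory (slower; simulated in R).
#' @return list with `first_passage_times` (numeric vector of length
#'   `n_reps`), `seed`, and, when requested, `paths` (list of data.frames
#'   with columns `state`, `time`).
#' @examples
#' ch <- build_composite(toy_model("IR"),
#'                       setNames(rep(1, 6), rate_names(toy_model("IR"))))
#' sim <- gillespie_fpt(ch, n_reps = 1000, seed = 1)
#' mean(sim$first_passage_times)
#' @export
gillespie_fpt <- function(chain, n_reps, seed, keep_paths = FALSE) {
  stopifnot(inherits(chain, "composite_chain"))
  if (n_reps < 1) stop_domain("n_reps must be at least 1")
  if (!keep_paths) {
    fpt <- .ssa_fpt(chain$Q, chain$start, chain$absorbing, as.integer(n_reps),
                    as.double(seed))
    return(list(first_passage_times = fpt, seed = seed))
  }
  paths <- vector("list", n_reps)
  fpt <- numeric(n_reps)
  rates_out <- -diag(chain$Q)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    state <- chain$start
    t <- 0
    visited <- state
    times <- 0
    while (state != chain$absorbing) {
      row <- chain$Q[state, ]
      row[state] <- 0
      t <- t + stats::rexp(1, rates_out[[state]])
      state <- sample.int(length(row), 1L, prob = row)
      visited <- c(visited, state)
      times <- c(times, t)
    }
    fpt[[r]] <- t
    paths[[r]] <- data.frame(state = chain$states[visited], time = times)
  }
  list(first_passage_times = fpt, seed = seed, paths = paths)
}

#' Population transcript-count simulation
#'
#' Simulates `n_cells` independent cells for `t_end` time units. Each cell
#' first passes from the fully unbound state to expression, then runs
#' repeated reinitiation cycles: after each synthesis event the scaffold
#' survives with probability `ps` (next cycle starts at the scaffold restart
#' state) and otherwise activation restarts from the unbound state.
#' Synthesis events strictly before `t_end` are counted.
#'
#' @param cycle a [cycle_model()].
#' @param t_end observation time (> 0).
#' @param n_cells number of cells (>= 1).
#' @param seed master seed; each cell runs on its own substream.
#' @return an object of class `population_sim`: list with `counts` (integer
#'   vector, transcripts per cell), `event_times` (list of per-cell synthesis
#'   times), `burst_sizes` (completed transcripts-per-opening counts pooled
#'   across cells), `t_end`, and `seed`.
#' @export
simulate_population <- function(cycle, t_end, n_cells, seed) {
  stopifnot(inherits(cycle, "cycle_model"))
  if (t_end <= 0) stop_domain("t_end must be positive")
  if (n_cells < 1) stop_domain("n_cells must be at least 1")
  ch_full <- cycle$chain_start
  ch_scaf <- cycle$chain_scaffold
  if (is.null(cycle$scaffold_alpha)) {
    starts <- ch_scaf$start
    probs <- 1
  } else {
    sub_states <- ch_scaf$states[-ch_scaf$absorbing]
    nz <- which(cycle$scaffold_alpha > 0)
    starts <- match(sub_states[nz], ch_scaf$states)
    probs <- cycle$scaffold_alpha[nz]
  }
  res <- .ssa_population(ch_full$Q, ch_full$start, ch_full$absorbing,
                         ch_scaf$Q, ch_scaf$absorbing,
                         as.integer(starts), as.double(probs),
                         as.double(cycle$ps), as.double(t_end),
                         as.integer(n_cells), as.double(seed))
  structure(list(counts = vapply(res$event_times, length, integer(1)),
                 event_times = res$event_times,
                 burst_sizes = res$bursts, t_end = t_end, seed = seed),
            class = "population_sim")
}

#' Summary statistics of a simulated cell population
#'
#' @param sim a `population_sim`.
#' @return list with `mean`, `var`, `cv2`, `fano`, and the fractions of
#'   cells below two-thirds (`frac_low`) and above three-halves
#'   (`frac_high`) of the mean transcript count.
#' @export
population_summary <- function(sim) {
  stopifnot(inherits(sim, "population_sim"))
  n <- sim$counts
  m <- mean(n)
  v <- stats::var(n)
  list(mean = m, var = v, cv2 = v / m^2, fano = v / m,
       frac_low = mean(n < 2 / 3 * m), frac_high = mean(n > 3 / 2 * m))
}

#' @exportS3Method base::print
print.population_sim <- function(x, ...) {
  s <- population_summary(x)
  cat(sprintf("Population simulation: %d cells to t = %g\n",
              length(x$counts), x$t_end))
  cat(sprintf("  mean count %.4g, var %.4g, CV^2 %.4g, Fano %.4g\n",
              s$mean, s$var, s$cv2, s$fano))
  cat(sprintf("  fraction < 2/3 of mean: %.3f; fraction > 3/2 of mean: %.3f\n",
              s$frac_low, s$frac_high))
  invisible(x)
}

#' Random gated-chain fixtures for property testing
#'
#' Generates a random valid gated chain: a forward spine `1 -> 2 -> ... -> n`
#' with random backward edges, a gate placed uniformly on a spine edge, and
#' i.i.d. uniform(0, 1) rates for every edge plus `k_on` and `k_off`.
#'
#' @param n_promoter_states number of promoter states (3 to 10).
#' @param seed integer seed; fixtures are deterministic given the seed.
#' @return list with `spec` (a [gated_chain_spec()]) and `rates` (named
#'   vector), guaranteed valid for [build_composite()].
#' @export
random_fixture_chain <- function(n_promoter_states, seed) {
  if (n_promoter_states < 3 || n_promoter_states > 10)
    stop_domain("n_promoter_states must be between 3 and 10")
  set.seed(seed)
  n <- n_promoter_states
  states <- as.character(seq_len(n))
  trans <- lapply(seq_len(n - 1L), function(i)
    c(states[[i]], states[[i + 1L]], sprintf("k%d_%d", i, i + 1L)))
  # random backward edges among non-final states
  for (j in seq(2, n - 1L)) {
    for (i in seq_len(j - 1L)) {
      if (stats::runif(1) < 0.3)
        trans <- c(trans, list(c(states[[j]], states[[i]],
                                 sprintf("k%d_%d", j, i))))
    }
  }
  prom <- promoter_spec(states, trans, final = states[[n]])
  g <- sample.int(n - 1L, 1L)
  spec <- gated_chain_spec(prom, c(states[[g]], states[[g + 1L]]),
                           scaffold_state = states[[max(2L, n - 2L)]],
                           name = sprintf("fixture_n%d_seed%d", n, seed))
  rn <- rate_names(spec)
  rates <- stats::setNames(stats::runif(length(rn)), rn)
  list(spec = spec, rates = rates)
}
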