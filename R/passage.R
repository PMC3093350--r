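# First-passage law of the induction-to-expression delay T: the absorption
# time of the composite chain is phase-type with sub-generator Qtilde, start
# distribution alpha and exit-rate vector into the expressing state.

# normalize the `start` argument into a distribution over transient states
start_distribution <- function(chain, sub, start = NULL) {
  n <- length(sub$states)
  if (is.null(start)) {
    alpha <- numeric(n)
    alpha[[sub$start]] <- 1
    return(alpha)
  }
  if (is.character(start) && length(start) == 1L) {
    i <- match(start, sub$states)
    if (is.na(i)) stop_domain(paste0("unknown transient state: ", start))
    alpha <- numeric(n)
    alpha[[i]] <- 1
    return(alpha)
  }
  if (is.numeric(start) && length(start) == n) {
    if (any(start < 0) || abs(sum(start) - 1) > 1e-12)
      stop_domain("start distribution must be a probability vector")
    return(as.numeric(start))
  }
  stop_domain("start must be NULL, a state label, or a distribution vector")
}

#' Laplace transform of the induction-to-expression delay
#'
#' Evaluates `E[exp(-s T)]` for the absorption time `T` of a composite chain,
#' i.e. the start-state entry of the resolvent `(sI - Qtilde)^{-1}` applied to
#' the exit-rate vector (the Feynman-Kac representation of the first-passage
#' transform).
#'
#' @param chain a `composite_chain`.
#' @param s nonnegative transform argument (may be a vector).
#' @param start optional start state label or distribution over transient
#'   states; defaults to the chain's start state.
#' @return numeric vector of transform values in `(0, 1]`.
#' @export
laplace_transform <- function(chain, s, start = NULL) {
  stopifnot(inherits(chain, "composite_chain"))
  if (any(s < 0)) stop_domain("s must be nonnegative")
  sub <- stopped_subgenerator(chain)
  alpha <- start_distribution(chain, sub, start)
  n <- length(sub$states)
  vapply(s, function(si) {
    x <- solve(diag(si, n) - sub$Qtilde, sub$exit)
    sum(alpha * x)
  }, numeric(1))
}

#' Moments of the induction-to-expression delay
#'
#' Computes raw moments `E[T^n] = n! * alpha' (-Qtilde)^{-n} 1` of the
#' first-passage time by repeated linear solves against the sub-generator
#' (no differentiation of the transform is needed), plus the mean and
#' variance.
#'
#' @param chain a `composite_chain`.
#' @param n_max highest moment order (default 2).
#' @param start optional start state label or distribution.
#' @return an object of class `passage_time`: list with `mean`, `var`,
#'   `raw_moments`, and `transform` (a function of `s`).
#' @examples
#' toy <- toy_model("ER")
#' ch <- build_composite(toy, setNames(rep(1, 6), rate_names(toy)))
#' fpt_moments(ch)
#' @export
fpt_moments <- function(chain, n_max = 2L, start = NULL) {
  stopifnot(inherits(chain, "composite_chain"))
  if (n_max < 1L) stop_domain("n_max must be at least 1")
  sub <- stopped_subgenerator(chain)
  alpha <- start_distribution(chain, sub, start)
  negQ <- -sub$Qtilde
  w <- rep(1, length(sub$states))
  raw <- numeric(n_max)
  lu <- tryCatch(solve(negQ), error = function(e)
    stop_model("singular sub-generator: absorption is not certain"))
  for (k in seq_len(n_max)) {
    w <- lu %*% w
    raw[[k]] <- factorial(k) * sum(alpha * w)
  }
  mu <- raw[[1L]]
  v <- if (n_max >= 2L) raw[[2L]] - mu^2 else NA_real_
  structure(list(mean = mu, var = v, raw_moments = raw,
                 transform = function(s) laplace_transform(chain, s, start)),
            class = "passage_time")
}

#' @exportS3Method base::print
print.passage_time <- function(x, ...) {
  cat(sprintf("First-passage time: mean = %.6g, var = %.6g (sd = %.6g)\n",
              x$mean, x$var, sqrt(x$var)))
  invisible(x)
}

#' Phase-type density of the induction-to-expression delay
#'
#' Evaluates `f(t) = alpha' exp(t Qtilde) exit` on a grid of times. The
#' density is exact for the finite chain (no transform inversion involved)
#' and integrates to one as the grid extends well beyond `mean + 10 sd`.
#'
#' @param chain a `composite_chain`.
#' @param t_grid strictly increasing vector of nonnegative times.
#' @param start optional start state label or distribution.
#' @return numeric vector of density values, one per grid time.
#' @export
fpt_density <- function(chain, t_grid, start = NULL) {
  stopifnot(inherits(chain, "composite_chain"))
  if (!length(t_grid)) stop_domain("t_grid must be non-empty")
  if (any(t_grid < 0) || any(diff(t_grid) <= 0) && length(t_grid) > 1L)
    stop_domain("t_grid must be nonnegative and strictly increasing")
  sub <- stopped_subgenerator(chain)
  alpha <- start_distribution(chain, sub, start)
  vapply(t_grid, function(t) {
    E <- as.matrix(Matrix::expm(sub$Qtilde * t))
    max(0, sum(alpha * (E %*% sub$exit)))
  }, numeric(1))
}

# first-passage quantities between two interior states: the chain stopped on
# first hitting `to`, restricted to states reachable from `from`
segment_chain <- function(chain, from, to) {
  e <- chain$edges
  e_stop <- e[e$from != to, , drop = FALSE]
  keep <- reachable_from(from, e_stop)
  states <- chain$states[chain$states %in% keep]
  e_seg <- e_stop[e_stop$from %in% states & e_stop$to %in% states, , drop = FALSE]
  n <- length(states)
  Q <- matrix(0, n, n, dimnames = list(states, states))
  Q[cbind(match(e_seg$from, states), match(e_seg$to, states))] <-
    chain$rates[e_seg$rate]
  diag(Q) <- -rowSums(Q)
  a <- match(to, states)
  Q[a, ] <- 0
  seg <- list(states = states, Q = Q, start = match(from, states),
              absorbing = a, edges = e_seg, rates = chain$rates,
              rate_names = chain$rate_names, downstream = chain$downstream,
              spec = chain$spec)
  class(seg) <- "composite_chain"
  seg
}

#' Pinch-point decomposition of a composite chain
#'
#' A pinch point is a composite state that every positive-probability path
#' from the start state to the absorbing state must visit. Because first
#' hitting times of successive pinch points telescope and the chain is strong
#' Markov, the delay `T` splits into a sum of independent segment passage
#' times, and the full Laplace transform factorizes into the product of the
#' segment transforms. Pinch points are found by exhaustive vertex-removal
#' reachability tests and ordered along the path from start to absorption.
#'
#' @param chain a `composite_chain`.
#' @return an object of class `pinch_decomposition`: list with `pinch_points`
#'   (ordered labels), `segments` (list of segment chains, each a
#'   `composite_chain` from one pinch point to the next), `moments`
#'   (per-segment mean and variance), and `transform` (the recombined product
#'   transform, a function of `s`).
#' @examples
#' ch <- build_composite(realistic_model("IR"),
#'                       setNames(rep(1, 16), rate_names(realistic_model("IR"))))
#' pinch_decompose(ch)$pinch_points
#' @export
pinch_decompose <- function(chain) {
  stopifnot(inherits(chain, "composite_chain"))
  e <- chain$edges
  start <- chain$states[[chain$start]]
  absorbing <- chain$states[[chain$absorbing]]
  interior <- setdiff(chain$states, c(start, absorbing))
  is_pinch <- vapply(interior, function(v) {
    ev <- e[e$from != v & e$to != v, , drop = FALSE]
    !absorbing %in% reachable_from(start, ev)
  }, logical(1))
  pinch <- interior[is_pinch]
  if (length(pinch) > 1L) {
    # order: p precedes q iff q is unreachable once p is removed
    prec <- function(p, q) {
      ev <- e[e$from != p & e$to != p, , drop = FALSE]
      !q %in% reachable_from(start, ev)
    }
    ord <- order(vapply(pinch, function(p)
      sum(vapply(pinch, function(q) p != q && prec(p, q), logical(1))),
      numeric(1)), decreasing = TRUE)
    pinch <- pinch[ord]
  }
  waypoints <- c(start, pinch, absorbing)
  segments <- lapply(seq_len(length(waypoints) - 1L), function(k)
    segment_chain(chain, waypoints[[k]], waypoints[[k + 1L]]))
  moments <- do.call(rbind, lapply(segments, function(s) {
    m <- fpt_moments(s)
    data.frame(from = s$states[[s$start]], to = s$states[[s$absorbing]],
               mean = m$mean, var = m$var)
  }))
  structure(list(pinch_points = pinch, segments = segments, moments = moments,
                 transform = function(s)
                   Reduce(`*`, lapply(segments, laplace_transform, s = s))),
            class = "pinch_decomposition")
}

#' @exportS3Method base::print
print.pinch_decomposition <- function(x, ...) {
  cat("Pinch-point decomposition:",
      if (length(x$pinch_points)) paste(x$pinch_points, collapse = " -> ")
      else "(no interior pinch points)", "\n")
  cat(sprintf("  %d segment(s); total mean = %.6g, total var = %.6g\n",
              length(x$segments), sum(x$moments$mean), sum(x$moments$var)))
  invisible(x)
}

#' Enhancer-equilibrium reduction for elongation-type gates
#'
#' For a gate placed late in the promoter chain, assume the enhancer has
#' reached its stationary law by the time the promoter arrives at the
#' pre-gate state: every composite jump into that promoter state resamples
#' the enhancer coordinate as permissive with probability
#' `pi = k_on / (k_on + k_off)`. The returned chain makes the pre-gate state
#' behave as a regeneration point, enabling pinch-point factorization for ER
#' topologies. Exact computations on the full composite remain the default
#' throughout the package; this reduction is provided for validation and
#' fast approximation.
#'
#' @param spec a [gated_chain_spec()] whose gate does not leave the initial
#'   promoter state (an initiation-type gate has no pre-gate assembly phase to
#'   equilibrate over, and is rejected).
#' @param rates named rate vector.
#' @return a `composite_chain` with the resampling edges substituted.
#' @export
enhancer_equilibrium_approx <- function(spec, rates) {
  stopifnot(inherits(spec, "gated_chain_spec"))
  if (spec$gate[[1L]] == spec$promoter$initial)
    stop_gatedtx("enhancer-equilibrium reduction requires an elongation-type gate (gate out of the initial state is initiation regulation)",
                 "gatedtx_unsupported_error")
  rates <- check_rates(spec, rates)
  chain <- build_composite(spec, rates)
  pre <- spec$gate[[1L]]
  pi_b <- rates[["k_on"]] / (rates[["k_on"]] + rates[["k_off"]])
  e <- chain$edges
  into_pre <- substr(e$to, 1, nchar(e$to) - 1L) == pre &
    substr(e$from, 1, nchar(e$from) - 1L) != pre
  split_rows <- which(into_pre)
  if (length(split_rows)) {
    add <- e[split_rows, , drop = FALSE]
    e$to[split_rows] <- paste0(pre, "B")
    add$to <- paste0(pre, "A")
    e <- rbind(e, add)
    # per-edge weights: pi to the permissive copy, 1 - pi to the open copy
    w <- rep(1, nrow(e))
    w[split_rows] <- pi_b
    w[seq.int(nrow(e) - length(split_rows) + 1L, nrow(e))] <- 1 - pi_b
  } else {
    w <- rep(1, nrow(e))
  }
  # collapse duplicate directed edges (a split edge can coincide with an
  # existing one); weights stay attached to their rate names via `w`
  states <- chain$states
  n <- length(states)
  Q <- matrix(0, n, n, dimnames = list(states, states))
  keep <- w > 0 & e$to %in% states
  idx <- cbind(match(e$from[keep], states), match(e$to[keep], states))
  vals <- w[keep] * rates[e$rate[keep]]
  for (r in seq_len(nrow(idx))) Q[idx[r, 1L], idx[r, 2L]] <-
      Q[idx[r, 1L], idx[r, 2L]] + vals[[r]]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q[chain$absorbing, ] <- 0
  chain$Q <- Q
  chain$edges <- e[keep, , drop = FALSE]
  chain$edge_weights <- w[keep]
  chain$equilibrium_reduced <- TRUE
  chain
}
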