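#' Build the composite promoter-enhancer Markov chain
#'
#' Constructs the continuous-time Markov chain on reachable pairs
#' `(promoter_state, enhancer_state)` implied by a gated chain specification
#' and a rate vector. Jump rules:
#' \itemize{
#'   \item a promoter edge `p -> p'` fires at its rate irrespective of the
#'     enhancer, except the gated edge, which fires only while the enhancer is
#'     in the permissive configuration `B`;
#'   \item the enhancer switches `A -> B` at `k_on` and `B -> A` at `k_off`,
#'     except that the `B -> A` switch is deleted while the promoter occupies
#'     a state downstream of the gate (the enhancer stays permissive there);
#'   \item pairs unreachable from the start state are biochemically
#'     inaccessible and are pruned.
#' }
#' Arrival of the promoter at its final (expressing) state absorbs the chain;
#' all composite transitions into the final promoter state are collected into
#' the single absorbing state, whose generator row is zero.
#'
#' @param spec a [gated_chain_spec()].
#' @param rates named numeric vector covering all of [rate_names()]
#'   (strictly positive; `k_off` may be zero).
#' @param start length-2 character vector `c(promoter_state, enhancer_state)`;
#'   defaults to the fully unbound state `(initial, A)`.
#' @return an object of class `composite_chain` with elements `states` (labels
#'   such as `"1A"`), `Q` (generator matrix, absorbing row zero), `start`,
#'   `absorbing` (state indices), `edges` (composite edge table with rate
#'   names), `downstream` (frozen promoter states), `rates`, and `spec`.
#' @examples
#' toy <- toy_model("IR")
#' r <- setNames(rep(1, 6), rate_names(toy))
#' ch <- build_composite(toy, r)
#' ch$states  # 5 reachable states; "2A" is inaccessible under IR gating
#' @export
build_composite <- function(spec, rates, start = NULL) {
  stopifnot(inherits(spec, "gated_chain_spec"))
  rates <- check_rates(spec, rates)
  prom <- spec$promoter
  D <- downstream_set(prom, spec$gate)
  final <- prom$final
  if (is.null(start)) start <- c(prom$initial, "A")
  start <- as.character(start)
  if (!start[[1L]] %in% prom$states || !start[[2L]] %in% c("A", "B"))
    stop_spec("start must be a (promoter_state, enhancer_state) pair")
  if (start[[1L]] == final)
    stop_spec("start must not be the expressing state")

  pair <- function(p, e) paste0(p, e)
  absorbing_label <- pair(final, "B")

  # composite edge table over all candidate pairs; pruning happens below
  es <- spec$promoter$edges
  is_gate <- es$from == spec$gate[[1L]] & es$to == spec$gate[[2L]]
  from <- character(0); to <- character(0); rname <- character(0)
  for (i in seq_len(nrow(es))) {
    if (es$from[[i]] == final) next  # the expressing state is absorbing
    tgt <- function(e) if (es$to[[i]] == final) absorbing_label else pair(es$to[[i]], e)
    for (e in c("A", "B")) {
      if (is_gate[[i]] && e == "A") next
      from <- c(from, pair(es$from[[i]], e))
      to <- c(to, tgt(e))
      rname <- c(rname, es$rate[[i]])
    }
  }
  for (p in setdiff(prom$states, final)) {
    from <- c(from, pair(p, "A")); to <- c(to, pair(p, "B"))
    rname <- c(rname, spec$enhancer$on)
    if (!p %in% D) {  # B -> A deleted while downstream of the gate
      from <- c(from, pair(p, "B")); to <- c(to, pair(p, "A"))
      rname <- c(rname, spec$enhancer$off)
    }
  }
  edges <- data.frame(from = from, to = to, rate = rname,
                      stringsAsFactors = FALSE)
  # drop edges with zero rate (k_off = 0) before reachability analysis
  edges <- edges[rates[edges$rate] > 0, , drop = FALSE]

  start_label <- pair(start[[1L]], start[[2L]])
  keep <- reachable_from(start_label, edges)
  if (!absorbing_label %in% keep)
    stop_model("the expressing state is unreachable from the start state")
  # absorption must be certain: every retained state must reach absorption
  can_absorb <- reachable_from(absorbing_label,
                               data.frame(from = edges$to, to = edges$from))
  stuck <- setdiff(keep, can_absorb)
  if (length(stuck))
    stop_model(paste0("absorption is not certain; trapped states: ",
                      paste(stuck, collapse = ", ")))

  # promoter-major, enhancer-minor ordering for reproducible matrices
  all_labels <- c(t(outer(prom$states, c("A", "B"), pair)))
  states <- all_labels[all_labels %in% keep]
  edges <- edges[edges$from %in% states & edges$to %in% states, , drop = FALSE]
  rownames(edges) <- NULL

  chain <- structure(list(states = states,
                          start = match(start_label, states),
                          absorbing = match(absorbing_label, states),
                          edges = edges, downstream = D,
                          rate_names = rate_names(spec),
                          rates = rates, spec = spec, Q = NULL),
                     class = "composite_chain")
  chain$Q <- assemble_generator(chain, rates)
  chain
}

# fill the generator matrix for a given rate vector, reusing the chain's
# composite edge structure (used heavily by parameter sweeps)
assemble_generator <- function(chain, rates) {
  n <- length(chain$states)
  Q <- matrix(0, n, n, dimnames = list(chain$states, chain$states))
  i <- match(chain$edges$from, chain$states)
  j <- match(chain$edges$to, chain$states)
  Q[cbind(i, j)] <- rates[chain$edges$rate]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q[chain$absorbing, ] <- 0  # stopped at the expressing state
  Q
}

#' Re-parameterize a composite chain
#'
#' Returns the same composite chain with a new rate vector substituted into
#' the generator. The state space (hence the reachability structure) is the
#' one determined at construction; use [build_composite()] if a rate has been
#' set to zero.
#'
#' @param chain a `composite_chain`.
#' @param rates named numeric vector of strictly positive rates.
#' @return a `composite_chain`.
#' @export
set_rates <- function(chain, rates) {
  stopifnot(inherits(chain, "composite_chain"))
  rates <- check_rates(chain$spec, rates)
  chain$rates <- rates
  chain$Q <- assemble_generator(chain, rates)
  chain
}

#' Stopped sub-generator of a composite chain
#'
#' Removes the absorbing row and column from the stopped generator, yielding
#' the sub-generator over transient states together with the exit-rate vector
#' into the absorbing state. Rows satisfy `Qtilde %*% 1 + exit = 0`.
#'
#' @param chain a `composite_chain`.
#' @return list with `Qtilde` (the (n-1) x (n-1) sub-generator), `exit`
#'   (rates into the absorbing state), `start` (start index within the
#'   transient states), and `states` (transient state labels).
#' @export
stopped_subgenerator <- function(chain) {
  stopifnot(inherits(chain, "composite_chain"))
  a <- chain$absorbing
  Qt <- chain$Q[-a, -a, drop = FALSE]
  exit <- chain$Q[-a, a]
  idx <- seq_along(chain$states)[-a]
  list(Qtilde = Qt, exit = exit, start = match(chain$start, idx),
       states = chain$states[-a])
}

#' @exportS3Method base::print
print.composite_chain <- function(x, ...) {
  cat("Composite chain:", length(x$states), "states\n")
  cat("  states:", paste(x$states, collapse = " "), "\n")
  cat("  start:", x$states[[x$start]], "  absorbing:", x$states[[x$absorbing]], "\n")
  if (length(x$downstream))
    cat("  enhancer frozen (B) at promoter states:",
        paste(x$downstream, collapse = " "), "\n")
  invisible(x)
}

#' Export a generator matrix as TSV
#'
#' Writes the generator with composite state labels as row and column headers.
#'
#' @param chain a `composite_chain`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_generator_tsv <- function(chain, path) {
  stopifnot(inherits(chain, "composite_chain"))
  df <- data.frame(state = rownames(chain$Q), chain$Q, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
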