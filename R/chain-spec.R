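#' Promoter chain specification
#'
#' A promoter chain enumerates the configurations of the transcription
#' machinery at the promoter (e.g. naked DNA, polymerase bound, paused
#' polymerase) and the single-molecular-event transitions between them. The
#' final state is the expressing configuration with a productively elongating
#' polymerase; arrival there marks the start of one transcript.
#'
#' @param states character vector of state labels, ordered; the first label is
#'   the initial (unbound) configuration.
#' @param transitions a list of length-3 character vectors `c(from, to,
#'   rate_name)`, or a 3-column matrix/data.frame. Each directed edge carries
#'   its own named jump rate.
#' @param final label of the expressing (absorbing) configuration.
#' @return an object of class `promoter_spec`.
#' @examples
#' promoter_spec(
#'   states = as.character(1:4),
#'   transitions = list(c("1", "2", "k12"), c("2", "1", "k21"),
#'                      c("2", "3", "k23"), c("3", "4", "k34")),
#'   final = "4")
#' @export
promoter_spec <- function(states, transitions, final) {
  states <- as.character(states)
  if (anyDuplicated(states)) stop_spec("duplicate promoter state labels")
  if (is.matrix(transitions) || is.data.frame(transitions)) {
    transitions <- lapply(seq_len(nrow(transitions)),
                          function(i) as.character(unlist(transitions[i, ])))
  }
  tr <- do.call(rbind, lapply(transitions, function(e) {
    e <- as.character(e)
    if (length(e) != 3L) stop_spec("each transition must be (from, to, rate_name)")
    e
  }))
  edges <- data.frame(from = tr[, 1], to = tr[, 2], rate = tr[, 3],
                      stringsAsFactors = FALSE)
  if (!all(c(edges$from, edges$to) %in% states))
    stop_spec("transition endpoints must be promoter states")
  if (any(edges$from == edges$to)) stop_spec("self-loops are not allowed")
  if (anyDuplicated(edges$rate)) stop_spec("rate names must be unique per edge")
  if (anyDuplicated(paste(edges$from, edges$to)))
    stop_spec("duplicate directed transitions")
  if (!final %in% states) stop_spec("final state must be a promoter state")
  spec <- structure(list(states = states, edges = edges,
                         initial = states[[1L]], final = as.character(final)),
                    class = "promoter_spec")
  # every non-final state must have a path to the final state
  no_path <- setdiff(setdiff(states, reaches_final(spec)), final)
  if (length(no_path))
    stop_spec(paste0("no path to the final state from: ",
                     paste(no_path, collapse = ", ")))
  spec
}

# states from which the final state is reachable (backward BFS)
reaches_final <- function(promoter) {
  e <- promoter$edges
  reach <- promoter$final
  repeat {
    new <- unique(e$from[e$to %in% reach])
    new <- setdiff(new, reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  reach
}

# forward reachability over an arbitrary edge table with columns from/to
reachable_from <- function(origin, edges) {
  reach <- origin
  repeat {
    new <- setdiff(unique(edges$to[edges$from %in% reach]), reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  reach
}

#' Two-state enhancer specification
#'
#' The enhancer is abstracted to two configurations: `A` (open) and `B`
#' (bound). `B` is the permissive configuration that licenses the gated
#' promoter transition. The switching rates are named `k_on` (A to B) and
#' `k_off` (B to A) in every rate vector.
#'
#' @return an object of class `enhancer_spec`.
#' @export
enhancer_spec <- function() {
  structure(list(states = c("A", "B"), permissive = "B",
                 on = "k_on", off = "k_off"),
            class = "enhancer_spec")
}

#' Gated promoter-enhancer chain specification
#'
#' Couples a promoter chain to the two-state enhancer through a single
#' regulated (gated) transition: the designated promoter edge can only fire
#' while the enhancer is in its permissive configuration `B`, and the enhancer
#' is held in `B` while the promoter occupies a state downstream of the gate.
#'
#' @param promoter a [promoter_spec()].
#' @param gate length-2 character vector `c(from, to)`; must be an edge of the
#'   promoter chain.
#' @param enhancer an [enhancer_spec()]; defaults to the standard two-state
#'   enhancer.
#' @param scaffold_state optional promoter state at which a surviving scaffold
#'   recruits the next polymerase (reinitiation); used by [cycle_model()].
#' @param name optional model name.
#' @return an object of class `gated_chain_spec`.
#' @seealso [toy_model()], [realistic_model()], [build_composite()]
#' @export
gated_chain_spec <- function(promoter, gate, enhancer = enhancer_spec(),
                             scaffold_state = NULL, name = NULL) {
  stopifnot(inherits(promoter, "promoter_spec"))
  gate <- as.character(gate)
  if (length(gate) != 2L ||
      !any(promoter$edges$from == gate[[1L]] & promoter$edges$to == gate[[2L]]))
    stop_spec("gate must be a directed edge of the promoter chain")
  if (!is.null(scaffold_state) && !as.character(scaffold_state) %in% promoter$states)
    stop_spec("scaffold_state must be a promoter state")
  structure(list(promoter = promoter, enhancer = enhancer, gate = gate,
                 scaffold_state = if (is.null(scaffold_state)) NULL
                                  else as.character(scaffold_state),
                 name = name),
            class = "gated_chain_spec")
}

#' Rate names of a gated chain specification
#'
#' @param spec a [gated_chain_spec()].
#' @return character vector: the promoter edge rate names followed by
#'   `"k_on"` and `"k_off"`.
#' @export
rate_names <- function(spec) {
  stopifnot(inherits(spec, "gated_chain_spec"))
  c(spec$promoter$edges$rate, spec$enhancer$on, spec$enhancer$off)
}

# validate a named rate vector against a spec; k_off may be zero (an enhancer
# that never unbinds), every other rate must be strictly positive
check_rates <- function(spec, rates) {
  wanted <- rate_names(spec)
  rates <- unlist(rates)
  missing <- setdiff(wanted, names(rates))
  if (length(missing))
    stop_spec(paste0("missing rates: ", paste(missing, collapse = ", ")))
  extra <- setdiff(names(rates), wanted)
  if (length(extra))
    stop_spec(paste0("unknown rates: ", paste(extra, collapse = ", ")))
  if (any(!is.finite(rates)))
    stop_spec("rates must be finite")
  bad <- names(rates)[rates < 0 | (rates == 0 & names(rates) != "k_off")]
  if (length(bad))
    stop_spec(paste0("rates must be strictly positive: ",
                     paste(bad, collapse = ", ")))
  rates[wanted]
}

#' Downstream set of a gated transition
#'
#' The set of promoter states that can only be reached from the initial
#' (unbound) configuration by passing through the gated transition. While the
#' promoter occupies one of these states the enhancer is held in its
#' permissive configuration.
#'
#' @param promoter a [promoter_spec()].
#' @param gate length-2 character vector `c(from, to)`.
#' @return character vector of promoter state labels (possibly empty).
#' @examples
#' toy <- toy_model("ER")
#' downstream_set(toy$promoter, toy$gate)  # "4"
#' @export
downstream_set <- function(promoter, gate) {
  stopifnot(inherits(promoter, "promoter_spec"))
  gate <- as.character(gate)
  e <- promoter$edges
  if (length(gate) != 2L || !any(e$from == gate[[1L]] & e$to == gate[[2L]]))
    stop_spec("gate must be a directed edge of the promoter chain")
  with_gate <- reachable_from(promoter$initial, e)
  sans <- e[!(e$from == gate[[1L]] & e$to == gate[[2L]]), , drop = FALSE]
  without_gate <- reachable_from(promoter$initial, sans)
  out <- setdiff(with_gate, without_gate)
  out[order(match(out, promoter$states))]
}

#' @exportS3Method base::print
print.promoter_spec <- function(x, ...) {
  cat("Promoter chain:", length(x$states), "states (",
      paste(x$states, collapse = " "), "), final =", x$final, "\n")
  cat("  transitions:",
      paste(sprintf("%s->%s[%s]", x$edges$from, x$edges$to, x$edges$rate),
            collapse = " "), "\n")
  invisible(x)
}

#' @exportS3Method base::print
print.gated_chain_spec <- function(x, ...) {
  if (!is.null(x$name)) cat("Gated chain model:", x$name, "\n")
  print(x$promoter)
  cat("  enhancer: A <-> B (k_on, k_off), permissive = B\n")
  cat("  gate:", paste(x$gate, collapse = " -> "))
  if (!is.null(x$scaffold_state)) cat("; scaffold restart state:", x$scaffold_state)
  cat("\n")
  invisible(x)
}
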