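# Brute-force oracles kept independent of the package internals they check.

# all simple directed paths between two promoter states (DFS)
all_simple_paths <- function(edges, from, to) {
  out <- list()
  recurse <- function(node, visited, path_edges) {
    if (node == to) {
      out[[length(out) + 1L]] <<- path_edges
      return(invisible())
    }
    nxt <- which(edges$from == node & !(edges$to %in% visited))
    for (k in nxt)
      recurse(edges$to[[k]], c(visited, edges$to[[k]]),
              c(path_edges, sprintf("%s->%s", edges$from[[k]], edges$to[[k]])))
  }
  recurse(from, from, character(0))
  out
}

# downstream set by exhaustive path enumeration: states whose every simple
# path from the initial state uses the gate edge
oracle_downstream <- function(promoter, gate) {
  gate_lab <- sprintf("%s->%s", gate[[1L]], gate[[2L]])
  Filter(function(q) {
    paths <- all_simple_paths(promoter$edges, promoter$initial, q)
    length(paths) > 0 && all(vapply(paths, function(p) gate_lab %in% p,
                                    logical(1)))
  }, setdiff(promoter$states, promoter$initial))
}

# brute-force reachable composite pairs under the gating rules, enumerated
# directly from the rules (not via build_composite)
oracle_composite_states <- function(spec) {
  prom <- spec$promoter
  D <- character(0)
  # downstream via the path oracle
  D <- unlist(oracle_downstream(prom, spec$gate))
  final <- prom$final
  lab <- function(p, e) paste0(p, e)
  moves <- function(state) {
    p <- substr(state, 1, nchar(state) - 1L)
    e <- substr(state, nchar(state), nchar(state))
    out <- character(0)
    if (p == final) return(out)
    for (k in seq_len(nrow(prom$edges))) {
      ed <- prom$edges[k, ]
      if (ed$from != p) next
      gated <- ed$from == spec$gate[[1L]] && ed$to == spec$gate[[2L]]
      if (gated && e == "A") next
      out <- c(out, lab(ed$to, if (ed$to == final) "B" else e))
    }
    if (e == "A") out <- c(out, lab(p, "B"))
    if (e == "B" && !p %in% D) out <- c(out, lab(p, "A"))
    out
  }
  reach <- lab(prom$initial, "A")
  repeat {
    new <- setdiff(unique(unlist(lapply(reach, moves))), reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  sort(reach)
}

# central finite-difference gradient of a scalar function of a rate vector
fd_gradient <- function(f, rates, h = 1e-6) {
  vapply(names(rates), function(nm) {
    up <- rates; up[[nm]] <- up[[nm]] + h
    dn <- rates; dn[[nm]] <- dn[[nm]] - h
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
}

unit_rates <- function(spec, value = 1) {
  stats::setNames(rep(value, length(rate_names(spec))), rate_names(spec))
}
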