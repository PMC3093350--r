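#' Toy four-step model of transcription
#'
#' Transcription in four promoter steps: (1) naked DNA, (2) DNA-polymerase
#' complex, (3) actively transcribing (paused) polymerase, (4) completed
#' mRNA. Polymerase association is reversible (`k12`, `k21`); pause entry
#' (`k23`) and pause release / completion (`k34`) are irreversible. Under
#' initiation regulation (IR) the gate sits on `1 -> 2`; under elongation
#' regulation (ER) it sits on `3 -> 4`. Both schemes share the same six rate
#' parameters (`k12`, `k21`, `k23`, `k34`, `k_on`, `k_off`).
#'
#' @param scheme `"IR"` or `"ER"`.
#' @return a [gated_chain_spec()] (scaffold restart state 2, the assembled
#'   DNA-polymerase complex).
#' @export
toy_model <- function(scheme = c("IR", "ER")) {
  scheme <- match.arg(scheme)
  prom <- promoter_spec(
    states = as.character(1:4),
    transitions = list(c("1", "2", "k12"), c("2", "1", "k21"),
                       c("2", "3", "k23"), c("3", "4", "k34")),
    final = "4")
  gate <- if (scheme == "IR") c("1", "2") else c("3", "4")
  gated_chain_spec(prom, gate, scaffold_state = "2",
                   name = paste0("toy/", scheme))
}

#' Realistic eight-state model of PIC assembly
#'
#' Pre-initiation complex assembly as an eight-state promoter chain:
#' (1) TFIID/A/B promoter complex, (2) + Pol II, (3)/(4) + TFIIE or TFIIF in
#' either order, (5) both bound, (6) + TFIIH, (7) promoter escape into the
#' proximal paused state (TFIIH evicted), (8) pause release and productive
#' elongation. Forward edges `1->2, 2->3, 2->4, 3->5, 4->5, 5->6, 6->7, 7->8`
#' and backward edges `2->1, 3->2, 4->2, 5->3, 5->4, 6->5` give 14 promoter
#' rates; with the enhancer rates `k_on`, `k_off` the model has 16 parameters.
#' The IR gate sits on `1 -> 2` (polymerase recruitment); the ER gate sits on
#' `7 -> 8` (release from pausing). A surviving scaffold recruits the next
#' polymerase at state 5.
#'
#' @param scheme `"IR"` or `"ER"`.
#' @return a [gated_chain_spec()].
#' @export
realistic_model <- function(scheme = c("IR", "ER")) {
  scheme <- match.arg(scheme)
  prom <- promoter_spec(
    states = as.character(1:8),
    transitions = list(
      c("1", "2", "k12"), c("2", "1", "k21"),
      c("2", "3", "k23"), c("3", "2", "k32"),
      c("2", "4", "k24"), c("4", "2", "k42"),
      c("3", "5", "k35"), c("5", "3", "k53"),
      c("4", "5", "k45"), c("5", "4", "k54"),
      c("5", "6", "k56"), c("6", "5", "k65"),
      c("6", "7", "k67"), c("7", "8", "k78")),
    final = "8")
  gate <- if (scheme == "IR") c("1", "2") else c("7", "8")
  gated_chain_spec(prom, gate, scaffold_state = "5",
                   name = paste0("realistic/", scheme))
}

#' Topology variants of the toy model
#'
#' Two modifications probing which features of elongation regulation matter:
#' \describe{
#'   \item{`toy_pause_exit`}{adds a reverse transition `3 -> 2` (rate `k32`)
#'     so polymerase can exit the paused state back to a pre-initiated state;
#'     7 rate parameters.}
#'   \item{`toy_escape_gate`}{moves the ER gate from pause release (`3 -> 4`)
#'     to promoter escape (`2 -> 3`), so regulation acts before the stable
#'     paused state.}
#' }
#'
#' @param name `"toy_pause_exit"` or `"toy_escape_gate"`.
#' @param scheme `"IR"` or `"ER"`.
#' @return a [gated_chain_spec()].
#' @export
variant_model <- function(name = c("toy_pause_exit", "toy_escape_gate"),
                          scheme = c("IR", "ER")) {
  if (!is.character(name) || !name[[1L]] %in% c("toy_pause_exit", "toy_escape_gate"))
    stop_spec(paste0("unknown model variant: ", name[[1L]]))
  name <- match.arg(name)
  scheme <- match.arg(scheme)
  if (name == "toy_pause_exit") {
    prom <- promoter_spec(
      states = as.character(1:4),
      transitions = list(c("1", "2", "k12"), c("2", "1", "k21"),
                         c("2", "3", "k23"), c("3", "2", "k32"),
                         c("3", "4", "k34")),
      final = "4")
    gate <- if (scheme == "IR") c("1", "2") else c("3", "4")
  } else {
    prom <- toy_model("IR")$promoter
    gate <- if (scheme == "IR") c("1", "2") else c("2", "3")
  }
  gated_chain_spec(prom, gate, scaffold_state = "2",
                   name = paste0(name, "/", scheme))
}

#' The model catalog
#'
#' @param name one of `"toy"`, `"realistic"`, `"toy_pause_exit"`,
#'   `"toy_escape_gate"`.
#' @param scheme `"IR"` or `"ER"`.
#' @return `catalog_model()` returns the requested [gated_chain_spec()];
#'   `model_catalog()` returns a data.frame listing every catalog entry with
#'   its scheme, gate, and parameter count.
#' @export
catalog_model <- function(name, scheme = c("IR", "ER")) {
  scheme <- match.arg(scheme)
  switch(name,
         toy = toy_model(scheme),
         realistic = realistic_model(scheme),
         toy_pause_exit = variant_model("toy_pause_exit", scheme),
         toy_escape_gate = variant_model("toy_escape_gate", scheme),
         stop_spec(paste0("unknown model: ", name)))
}

#' @rdname catalog_model
#' @export
model_catalog <- function() {
  entries <- expand.grid(name = c("toy", "realistic", "toy_pause_exit",
                                  "toy_escape_gate"),
                         scheme = c("IR", "ER"), stringsAsFactors = FALSE)
  entries <- entries[order(entries$name), ]
  info <- lapply(seq_len(nrow(entries)), function(i) {
    s <- catalog_model(entries$name[[i]], entries$scheme[[i]])
    data.frame(name = entries$name[[i]], scheme = entries$scheme[[i]],
               gate = paste(s$gate, collapse = "->"),
               n_promoter_states = length(s$promoter$states),
               n_rates = length(rate_names(s)),
               scaffold_state = s$scaffold_state)
  })
  out <- do.call(rbind, info)
  rownames(out) <- NULL
  out
}
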