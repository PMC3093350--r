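#' Read a rate vector from file
#'
#' Accepts JSON (an object mapping rate names to positive numbers) or a
#' two-column TSV (`name`, `value`, no header required). The vector is
#' validated against a model's rate names when a spec is supplied: missing
#' and unknown names are reported by name, and nonpositive values are
#' rejected.
#'
#' @param path path to a JSON or TSV file.
#' @param spec optional [gated_chain_spec()] to validate against.
#' @return named numeric rate vector.
#' @export
load_rates <- function(path, spec = NULL) {
  if (!file.exists(path)) stop_domain(paste0("no such file: ", path))
  first <- readChar(path, 1L)
  if (first %in% c("{", "[")) {
    vals <- jsonlite::fromJSON(path)
    rates <- unlist(vals)
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("name", "value"),
                            stringsAsFactors = FALSE)
    if (identical(tolower(df$name[[1L]]), "name")) df <- df[-1L, ]
    rates <- stats::setNames(as.numeric(df$value), df$name)
  }
  if (!is.numeric(rates) || is.null(names(rates)))
    stop_spec("rate file must map rate names to numbers")
  if (!is.null(spec)) rates <- check_rates(spec, rates)
  rates
}

#' Write a rate vector to JSON
#'
#' @param rates named numeric vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_rates <- function(rates, path) {
  jsonlite::write_json(as.list(rates), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write gated chain specifications as JSON
#'
#' The on-disk format is
#' `{"promoter": {"states": [...], "transitions": [["1","2","k12"], ...],
#' "final": "8"}, "enhancer": {"k_on": "k_on", "k_off": "k_off"},
#' "gate": ["1","2"], "scaffold_state": "5"}`.
#'
#' @param spec a [gated_chain_spec()].
#' @param path file path.
#' @return `write_chain_spec()` returns the path invisibly;
#'   `read_chain_spec()` returns a [gated_chain_spec()].
#' @export
write_chain_spec <- function(spec, path) {
  stopifnot(inherits(spec, "gated_chain_spec"))
  obj <- list(
    promoter = list(states = spec$promoter$states,
                    transitions = lapply(seq_len(nrow(spec$promoter$edges)),
                                         function(i) unname(unlist(spec$promoter$edges[i, ]))),
                    final = spec$promoter$final),
    enhancer = list(k_on = spec$enhancer$on, k_off = spec$enhancer$off),
    gate = spec$gate)
  if (!is.null(spec$scaffold_state)) obj$scaffold_state <- spec$scaffold_state
  if (!is.null(spec$name)) obj$name <- spec$name
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chain_spec
#' @export
read_chain_spec <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  trans <- obj$promoter$transitions
  if (is.matrix(trans)) trans <- lapply(seq_len(nrow(trans)), function(i) trans[i, ])
  prom <- promoter_spec(obj$promoter$states, trans, obj$promoter$final)
  gated_chain_spec(prom, unlist(obj$gate),
                   scaffold_state = obj$scaffold_state, name = obj$name)
}

# short stable configuration hash (31-polynomial over the deparsed config,
# modulo a Mersenne prime), recorded in every output file so a run can be
# traced back to its inputs
config_hash <- function(config) {
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write tabular and summary results
#'
#' Tabular results (data.frames, matrices) are written as TSV with a stable
#' column order; summaries (lists) as JSON. Every JSON summary records the
#' seed and a configuration hash when present in the object.
#'
#' @param result a data.frame/matrix (TSV) or list (JSON).
#' @param path output path.
#' @param config optional named list recorded (hashed) alongside summaries.
#' @return the path, invisibly.
#' @export
write_results <- function(result, path, config = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (is.data.frame(result) || is.matrix(result)) {
    utils::write.table(as.data.frame(result), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else if (is.list(result)) {
    if (!is.null(config)) {
      result$config <- config
      result$config_hash <- config_hash(config)
    }
    jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop_domain("unsupported result type")
  }
  invisible(path)
}
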