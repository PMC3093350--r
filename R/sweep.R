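#' Sample uniform rate-parameter vectors
#'
#' Draws `n` i.i.d. rate vectors with every entry uniform on (0, 1). Because
#' all compared quantities are ratios invariant under a common rescaling of
#' time, sampling on the unit cube effectively covers all of parameter space.
#'
#' @param n number of vectors.
#' @param rate_names character vector of parameter names.
#' @param seed integer seed.
#' @return an `n` by `length(rate_names)` numeric matrix with named columns.
#' @export
sample_parameters <- function(n, rate_names, seed) {
  if (n < 1) stop_domain("n must be at least 1")
  set.seed(seed)
  matrix(stats::runif(n * length(rate_names)), nrow = n,
         dimnames = list(NULL, rate_names))
}

# fast per-vector moments: reuse the composite template, refill Q, two solves
# returns c(mu, var) for the given start index (over transient states)
moments_from_template <- function(tpl, rates) {
  Q <- tpl$Q
  Q[tpl$fill_idx] <- rates[tpl$fill_rate]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q[tpl$absorbing, ] <- 0
  Qt <- Q[-tpl$absorbing, -tpl$absorbing, drop = FALSE]
  w1 <- solve(-Qt, rep(1, nrow(Qt)))
  w2 <- solve(-Qt, w1)
  mu <- w1[[tpl$start_t]]
  c(mu = mu, var = 2 * w2[[tpl$start_t]] - mu^2,
    mu_scaf = if (is.na(tpl$scaffold_t)) NA_real_ else w1[[tpl$scaffold_t]],
    m2_scaf = if (is.na(tpl$scaffold_t)) NA_real_ else 2 * w2[[tpl$scaffold_t]])
}

# precompute the fill structure of a composite chain for repeated use
chain_template <- function(spec, rates_probe) {
  chain <- build_composite(spec, rates_probe)
  n <- length(chain$states)
  i <- match(chain$edges$from, chain$states)
  j <- match(chain$edges$to, chain$states)
  trans_idx <- seq_len(n)[-chain$absorbing]
  scaffold_label <- if (!is.null(spec$scaffold_state))
    paste0(spec$scaffold_state, "B") else NA_character_
  list(Q = matrix(0, n, n), fill_idx = cbind(i, j),
       fill_rate = chain$edges$rate, absorbing = chain$absorbing,
       start_t = match(chain$start, trans_idx),
       scaffold_t = if (is.na(scaffold_label)) NA_integer_
                    else match(match(scaffold_label, chain$states), trans_idx),
       chain = chain)
}

#' Compare IR and ER topologies across parameter vectors
#'
#' For each rate vector, builds the initiation-regulated and
#' elongation-regulated composite chains of the named model from the same
#' vector and computes the mean and variance of the induction-to-expression
#' delay plus the transcript count variability `eta` of the reinitiation
#' cycle at scaffold survival probability `ps` (`ps = 0`, the default, is the
#' no-bursting cycle restarting from the unbound state). Log10 IR/ER ratios
#' are reported per metric. Vectors producing a numerically singular
#' sub-generator are flagged rather than dropped silently; the run aborts if
#' more than 0.1% of rows are flagged.
#'
#' @param model_name a catalog model name (see [model_catalog()]).
#' @param params parameter matrix from [sample_parameters()] (columns must
#'   match the model's [rate_names()]).
#' @param ps scaffold survival probability used for `eta`.
#' @return an object of class `sweep_result`: list with `metrics` (data.frame
#'   of per-vector `mu`, `var`, `eta` for both schemes and `log10_ratio_*`
#'   columns), `params`, `ps`, `model`, and `flagged` (row indices).
#' @export
compare_schemes <- function(model_name, params, ps = 0) {
  spec_ir <- catalog_model(model_name, "IR")
  spec_er <- catalog_model(model_name, "ER")
  rn <- rate_names(spec_ir)
  if (!identical(sort(colnames(params)), sort(rn)))
    stop_spec("parameter columns must match the model's rate names")
  params <- params[, rn, drop = FALSE]
  probe <- stats::setNames(rep(0.5, length(rn)), rn)
  tpl <- list(IR = chain_template(spec_ir, probe),
              ER = chain_template(spec_er, probe))
  n <- nrow(params)
  out <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("mu_IR", "var_IR", "eta_IR",
                                        "mu_ER", "var_ER", "eta_ER")))
  flagged <- integer(0)
  for (i in seq_len(n)) {
    r <- params[i, ]
    row <- tryCatch({
      vals <- lapply(tpl, moments_from_template, rates = r)
      unlist(lapply(vals, function(v) {
        raw1 <- ps * v[["mu_scaf"]] + (1 - ps) * v[["mu"]]
        raw2 <- ps * v[["m2_scaf"]] +
          (1 - ps) * (v[["var"]] + v[["mu"]]^2)
        c(v[["mu"]], v[["var"]], (raw2 - raw1^2) / raw1)
      }), use.names = FALSE)
    }, error = function(e) NULL)
    if (is.null(row) || any(!is.finite(row))) flagged <- c(flagged, i)
    else out[i, ] <- row
  }
  if (length(flagged) > 0.001 * n)
    stop_model(sprintf("%d of %d parameter vectors produced singular systems",
                       length(flagged), n))
  metrics <- as.data.frame(out)
  for (m in c("mu", "var", "eta"))
    metrics[[paste0("log10_ratio_", m)]] <-
      log10(metrics[[paste0(m, "_IR")]] / metrics[[paste0(m, "_ER")]])
  structure(list(metrics = metrics, params = params, ps = ps,
                 model = model_name, flagged = flagged,
                 n = n),
            class = "sweep_result")
}

#' @exportS3Method base::print
print.sweep_result <- function(x, ...) {
  cat(sprintf("Scheme comparison sweep: model %s, %d vectors, ps = %g\n",
              x$model, x$n, x$ps))
  cat(sprintf("  IR faster (mean): %.4f of vectors\n",
              fraction_reversed(x, "mu", "IR")))
  cat(sprintf("  ER smaller mu, var and eta simultaneously: %.4f\n",
              fraction_er_dominant(x)))
  invisible(x)
}

#' Fraction of parameter space where one scheme beats the other
#'
#' @param sweep a [compare_schemes()] result.
#' @param metric `"mu"`, `"var"`, or `"eta"`.
#' @param direction which scheme must have the smaller value: `"IR"` or
#'   `"ER"`.
#' @return exact count divided by the number of unflagged vectors.
#' @export
fraction_reversed <- function(sweep, metric = c("mu", "var", "eta"),
                              direction = c("IR", "ER")) {
  stopifnot(inherits(sweep, "sweep_result"))
  metric <- match.arg(metric)
  direction <- match.arg(direction)
  lr <- sweep$metrics[[paste0("log10_ratio_", metric)]]
  lr <- lr[is.finite(lr)]
  if (direction == "IR") mean(lr < 0) else mean(lr > 0)
}

#' Fraction of parameter space where ER dominates all three metrics
#'
#' @param sweep a [compare_schemes()] result.
#' @return fraction of vectors where the ER scheme simultaneously has smaller
#'   mean delay, delay variance, and transcript count variability.
#' @export
fraction_er_dominant <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  m <- sweep$metrics
  ok <- stats::complete.cases(m)
  mean(m$log10_ratio_mu[ok] > 0 & m$log10_ratio_var[ok] > 0 &
         m$log10_ratio_eta[ok] > 0)
}

#' Discard vectors with rate-limiting enhancer dynamics
#'
#' Removes parameter vectors in which `k_on` or `k_off` is the smallest entry
#' of the vector (the enhancer chain is then slow to equilibrate relative to
#' the promoter chain). Used to check robustness of sweep conclusions to the
#' treatment of the enhancer.
#'
#' @param sweep a [compare_schemes()] result.
#' @return a filtered `sweep_result`; the removed row indices are recorded in
#'   `$removed`.
#' @export
filter_slow_enhancer <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  p <- sweep$params
  argmin <- colnames(p)[apply(p, 1L, which.min)]
  drop <- argmin %in% c("k_on", "k_off")
  out <- sweep
  out$metrics <- sweep$metrics[!drop, , drop = FALSE]
  out$params <- p[!drop, , drop = FALSE]
  out$removed <- which(drop)
  out$n <- sum(!drop)
  out
}

#' Histogram counts of log ratios with clamped extremes
#'
#' Bins log10 IR/ER ratios on a fixed grid; values beyond the grid edges are
#' collected into the outermost bins rather than dropped.
#'
#' @param x numeric vector of log ratios.
#' @param breaks strictly increasing vector of bin edges.
#' @return data.frame with bin midpoints and counts.
#' @export
log_ratio_histogram <- function(x, breaks = seq(-3, 3, by = 0.25)) {
  x <- x[is.finite(x)]
  x <- pmin(pmax(x, breaks[[1L]] + 1e-9), breaks[[length(breaks)]] - 1e-9)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}
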