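# Analytic gradients of first-passage metrics with respect to jump rates.
#
# With M = (-Qtilde)^{-1}, mu = alpha' M 1 and E[T^2] = 2 alpha' M^2 1.
# Perturbing a single rate perturbs Qtilde linearly, and
# d(-Qtilde)^{-1} = M dQtilde M, so
#   d mu      = u1' dQ v1,               u1 = M' alpha, v1 = M 1
#   d E[T^2]  = 2 (u1' dQ v2 + u2' dQ v1), u2 = M' u1,  v2 = M v1.
# Each composite edge carrying rate k contributes +1 at (i, j) and -1 at
# (i, i) to dQtilde/dk (edges into the absorbing state contribute only the
# diagonal term), so the gradient accumulates as edge sums.

fpt_gradient_core <- function(chain, start = NULL) {
  sub <- stopped_subgenerator(chain)
  alpha <- start_distribution(chain, sub, start)
  negQ <- -sub$Qtilde
  ones <- rep(1, length(sub$states))
  v1 <- solve(negQ, ones)
  v2 <- solve(negQ, v1)
  u1 <- solve(t(negQ), alpha)
  u2 <- solve(t(negQ), u1)
  # map composite edges to transient indices; absorbing target -> NA
  i <- match(chain$edges$from, sub$states)
  j <- match(chain$edges$to, sub$states)
  w <- if (is.null(chain$edge_weights)) rep(1, nrow(chain$edges))
       else chain$edge_weights
  vj1 <- ifelse(is.na(j), 0, v1[ifelse(is.na(j), 1L, j)])
  vj2 <- ifelse(is.na(j), 0, v2[ifelse(is.na(j), 1L, j)])
  d_mu_edge <- w * u1[i] * (vj1 - v1[i])
  d_m2_edge <- 2 * w * (u1[i] * (vj2 - v2[i]) + u2[i] * (vj1 - v1[i]))
  rn <- chain$rate_names
  grad_mu <- vapply(rn, function(r)
    sum(d_mu_edge[chain$edges$rate == r]), numeric(1))
  grad_m2 <- vapply(rn, function(r)
    sum(d_m2_edge[chain$edges$rate == r]), numeric(1))
  mu <- sum(alpha * v1)
  m2 <- 2 * sum(alpha * v2)
  list(mu = mu, m2 = m2, grad_mu = grad_mu, grad_m2 = grad_m2)
}

#' Gradient and relative sensitivity of first-passage metrics
#'
#' `fpt_gradient()` computes the analytic gradient of a first-passage metric
#' of a composite chain with respect to every rate parameter, via the
#' resolvent perturbation identity (no finite differencing).
#' `fpt_sensitivity()` squares the gradient entries and normalizes them to
#' sum to one, the relative sensitivity profile: the share of local
#' parameter-variation response attributable to each rate, analogous to a
#' percent-variance-explained decomposition.
#'
#' @param chain a `composite_chain`.
#' @param metric `"mean"`, `"variance"`, or `"eta"` (the no-bursting cycle
#'   variability `var/mean` of the same chain).
#' @param start optional start state label or distribution.
#' @param elasticity if `TRUE`, gradients are multiplied by the rate value
#'   before squaring (sensitivity to relative rather than absolute rate
#'   changes).
#' @return `fpt_gradient()`: named numeric gradient vector.
#'   `fpt_sensitivity()`: named numeric vector of nonnegative sensitivities
#'   summing to one.
#' @export
fpt_gradient <- function(chain, metric = c("mean", "variance", "eta"),
                         start = NULL) {
  stopifnot(inherits(chain, "composite_chain"))
  metric <- match.arg(metric)
  if (any(chain$rates < 0) ||
      any(chain$rates == 0 & names(chain$rates) != "k_off"))
    stop_domain("gradients require strictly positive rates")
  g <- fpt_gradient_core(chain, start)
  mu <- g$mu
  grad_var <- g$grad_m2 - 2 * mu * g$grad_mu
  switch(metric,
         mean = g$grad_mu,
         variance = grad_var,
         eta = {
           v <- g$m2 - mu^2
           (grad_var * mu - v * g$grad_mu) / mu^2
         })
}

#' @rdname fpt_gradient
#' @export
fpt_sensitivity <- function(chain, metric = c("mean", "variance", "eta"),
                            start = NULL, elasticity = FALSE) {
  grad <- fpt_gradient(chain, metric, start)
  if (elasticity) grad <- grad * chain$rates[names(grad)]
  s2 <- grad^2
  tot <- sum(s2)
  if (tot == 0) stop_domain("zero gradient: sensitivity profile undefined")
  s2 / tot
}

#' Relative sensitivity of a catalog model at one rate vector
#'
#' @param model a catalog model name or a [gated_chain_spec()].
#' @param scheme `"IR"` or `"ER"` (ignored when `model` is already a spec).
#' @param metric `"mean"`, `"variance"`, or `"eta"`.
#' @param rates named rate vector.
#' @param elasticity see [fpt_sensitivity()].
#' @return named sensitivity vector summing to one.
#' @examples
#' r <- setNames(rep(0.5, 6), rate_names(toy_model("ER")))
#' relative_sensitivity("toy", "ER", "mean", r)
#' @export
relative_sensitivity <- function(model, scheme = c("IR", "ER"),
                                 metric = c("mean", "variance", "eta"),
                                 rates, elasticity = FALSE) {
  spec <- if (inherits(model, "gated_chain_spec")) model
          else catalog_model(model, match.arg(scheme))
  chain <- build_composite(spec, rates)
  fpt_sensitivity(chain, match.arg(metric), elasticity = elasticity)
}

#' Sensitivity profiles across a parameter sweep
#'
#' Computes the relative sensitivity of a metric to every rate at each
#' parameter vector, plus a per-vector record of the most and second-most
#' influential parameters and their values.
#'
#' @param model_name a catalog model name.
#' @param scheme `"IR"` or `"ER"`.
#' @param metric `"mean"`, `"variance"`, or `"eta"`.
#' @param params parameter matrix from [sample_parameters()].
#' @param elasticity see [fpt_sensitivity()].
#' @return an object of class `sensitivity_profile`: list with
#'   `sensitivities` (matrix, vectors by rates), `top` (data.frame with the
#'   top-1/top-2 parameter names and values per vector), `model`, `scheme`,
#'   and `metric`.
#' @export
sensitivity_sweep <- function(model_name, scheme = c("IR", "ER"),
                              metric = c("mean", "variance", "eta"),
                              params, elasticity = FALSE) {
  scheme <- match.arg(scheme)
  metric <- match.arg(metric)
  spec <- catalog_model(model_name, scheme)
  rn <- rate_names(spec)
  params <- params[, rn, drop = FALSE]
  chain <- build_composite(spec, stats::setNames(rep(0.5, length(rn)), rn))
  n <- nrow(params)
  S <- matrix(NA_real_, n, length(rn), dimnames = list(NULL, rn))
  for (i in seq_len(n)) {
    ch <- set_rates(chain, params[i, ])
    S[i, ] <- fpt_sensitivity(ch, metric, elasticity = elasticity)
  }
  ord <- t(apply(S, 1L, order, decreasing = TRUE))
  top <- data.frame(
    top1 = rn[ord[, 1L]], top2 = rn[ord[, 2L]],
    top1_value = params[cbind(seq_len(n), ord[, 1L])],
    top2_value = params[cbind(seq_len(n), ord[, 2L])],
    top1_sensitivity = S[cbind(seq_len(n), ord[, 1L])])
  structure(list(sensitivities = S, top = top, model = model_name,
                 scheme = scheme, metric = metric),
            class = "sensitivity_profile")
}

#' @exportS3Method base::print
print.sensitivity_profile <- function(x, ...) {
  cat(sprintf("Sensitivity sweep: model %s/%s, metric %s, %d vectors\n",
              x$model, x$scheme, x$metric, nrow(x$sensitivities)))
  cat(sprintf("  mean value of most influential parameter: %.3f\n",
              mean(x$top$top1_value)))
  dom <- sort(colMeans(x$sensitivities), decreasing = TRUE)
  cat("  mean sensitivity by rate:",
      paste(sprintf("%s=%.3f", names(head(dom, 5)), head(dom, 5)),
            collapse = " "), "...\n")
  invisible(x)
}
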