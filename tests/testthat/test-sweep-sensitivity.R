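test_that("uniform parameter sampling is shaped, bounded, and reproducible", {
  rn <- rate_names(realistic_model("IR"))
  p <- sample_parameters(2000, rn, seed = 3)
  expect_equal(dim(p), c(2000L, 16L))
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, sample_parameters(2000, rn, seed = 3))
  expect_true(all(abs(colMeans(p) - 0.5) < 4 * 0.2887 / sqrt(2000)))
})

test_that("scheme comparison is consistent with single-chain computations", {
  p <- sample_parameters(50, rate_names(toy_model("IR")), seed = 4)
  sw <- compare_schemes("toy", p)
  for (i in c(1L, 17L, 50L)) {
    r <- p[i, ]
    expect_equal(sw$metrics$mu_IR[[i]],
                 fpt_moments(build_composite(toy_model("IR"), r))$mean,
                 tolerance = 1e-12)
    expect_equal(sw$metrics$var_ER[[i]],
                 fpt_moments(build_composite(toy_model("ER"), r))$var,
                 tolerance = 1e-12)
  }
  # eta at ps = 0 is var/mean of the full passage
  expect_equal(sw$metrics$eta_IR, sw$metrics$var_IR / sw$metrics$mu_IR,
               tolerance = 1e-12)
  # IR-better and ER-better fractions partition the vectors
  expect_equal(fraction_reversed(sw, "mu", "IR") +
                 fraction_reversed(sw, "mu", "ER"), 1)
})

test_that("log ratios are invariant under global rate rescaling", {
  p <- sample_parameters(20, rate_names(toy_model("IR")), seed = 5)
  sw <- compare_schemes("toy", p, ps = 0.9)
  sw100 <- compare_schemes("toy", p * 100, ps = 0.9)
  for (m in c("log10_ratio_mu", "log10_ratio_var", "log10_ratio_eta"))
    expect_equal(sw$metrics[[m]], sw100$metrics[[m]], tolerance = 1e-9)
})

test_that("two independent sweeps agree within binomial error", {
  p1 <- sample_parameters(3000, rate_names(toy_model("IR")), seed = 11)
  p2 <- sample_parameters(3000, rate_names(toy_model("IR")), seed = 22)
  f1 <- fraction_reversed(compare_schemes("toy", p1), "mu", "IR")
  f2 <- fraction_reversed(compare_schemes("toy", p2), "mu", "IR")
  se <- sqrt(f1 * (1 - f1) / 3000 + f2 * (1 - f2) / 3000)
  expect_lt(abs(f1 - f2), 4 * se)
})

test_that("slow-enhancer filtering removes exactly the flagged vectors", {
  p <- sample_parameters(500, rate_names(toy_model("IR")), seed = 6)
  sw <- compare_schemes("toy", p)
  swf <- filter_slow_enhancer(sw)
  argmin <- colnames(p)[apply(p, 1L, which.min)]
  expect_identical(swf$removed, which(argmin %in% c("k_on", "k_off")))
  expect_equal(swf$n, sum(!argmin %in% c("k_on", "k_off")))
  # a vector whose smallest entry is a promoter rate is retained
  keep_row <- which(!argmin %in% c("k_on", "k_off"))[1L]
  expect_identical(unname(swf$params[1L, ]), unname(p[keep_row, ]))
  # robustness: the IR-better fraction moves by a bounded amount
  expect_lt(abs(fraction_reversed(swf, "mu", "IR") -
                  fraction_reversed(sw, "mu", "IR")), 0.1)
})

test_that("analytic sensitivity gradients match finite differences", {
  set.seed(7)
  for (nm in c("toy", "realistic")) for (scheme in c("IR", "ER")) {
    spec <- catalog_model(nm, scheme)
    rn <- rate_names(spec)
    r <- setNames(runif(length(rn), 0.2, 1), rn)
    ch <- build_composite(spec, r)
    for (metric in c("mean", "variance", "eta")) {
      g <- fpt_gradient(ch, metric)
      f <- function(rr) {
        m <- fpt_moments(build_composite(spec, rr))
        switch(metric, mean = m$mean, variance = m$var, eta = m$var / m$mean)
      }
      fd <- fd_gradient(f, r)
      expect_equal(g, fd, tolerance = 1e-5)
    }
  }
})

test_that("relative sensitivities are normalized and match symmetry", {
  # single-rate chain: all sensitivity on that rate
  prom <- promoter_spec(c("1", "2"), list(c("1", "2", "k")), final = "2")
  ch1 <- build_composite(gated_chain_spec(prom, c("1", "2")),
                         c(k = 0.7, k_on = 1, k_off = 0), start = c("1", "B"))
  s1 <- fpt_sensitivity(ch1, "mean")
  expect_equal(unname(s1[["k"]]), 1)
  expect_equal(sum(s1), 1, tolerance = 1e-10)
  # two equal irreversible steps split the mean sensitivity evenly
  prom2 <- promoter_spec(as.character(1:3),
                         list(c("1", "2", "k1"), c("2", "3", "k2")),
                         final = "3")
  ch2 <- build_composite(gated_chain_spec(prom2, c("1", "2")),
                         c(k1 = 1, k2 = 1, k_on = 1, k_off = 0),
                         start = c("1", "B"))
  s2 <- fpt_sensitivity(ch2, "mean")
  expect_equal(unname(s2[["k1"]]), 0.5, tolerance = 1e-12)
  expect_equal(unname(s2[["k2"]]), 0.5, tolerance = 1e-12)
  expect_error(
    fpt_gradient(build_composite(gated_chain_spec(prom, c("1", "2")),
                                 c(k = 1, k_on = 1, k_off = 0),
                                 start = c("1", "B")), "mean", start = "9Z"),
    class = "gatedtx_domain_error")
})

test_that("sensitivity sweeps normalize rows and find rate-limiting steps", {
  p <- sample_parameters(300, rate_names(toy_model("IR")), seed = 8)
  prof_ir <- sensitivity_sweep("toy", "IR", "mean", p)
  expect_true(all(abs(rowSums(prof_ir$sensitivities) - 1) < 1e-10))
  # the dominant parameter tends to be the one taking the smallest value
  expect_lt(mean(prof_ir$top$top1_value), 0.5)
  expect_lt(mean(prof_ir$top$top1_value), mean(prof_ir$top$top2_value))
  # initiation regulation is sensitive to the enhancer association rate on a
  # nontrivial share of parameter space
  expect_gt(mean(prof_ir$sensitivities[, "k_on"] > 0.01), 0.1)
  # elasticity option still normalizes
  prof_el <- sensitivity_sweep("toy", "IR", "mean", p[1:20, ],
                               elasticity = TRUE)
  expect_true(all(abs(rowSums(prof_el$sensitivities) - 1) < 1e-10))
})
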