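# a minimal gated spec whose composite is a single exponential step:
# promoter 1 -> 2 at rate k, gate on 1 -> 2, enhancer already bound at start
single_step_chain <- function(k, k_on = 1, k_off = 0) {
  prom <- promoter_spec(c("1", "2"), list(c("1", "2", "k")), final = "2")
  spec <- gated_chain_spec(prom, c("1", "2"))
  build_composite(spec, c(k = k, k_on = k_on, k_off = k_off),
                  start = c("1", "B"))
}

two_step_chain <- function(k1, k2) {
  prom <- promoter_spec(as.character(1:3),
                        list(c("1", "2", "k1"), c("2", "3", "k2")), final = "3")
  spec <- gated_chain_spec(prom, c("1", "2"))
  build_composite(spec, c(k1 = k1, k2 = k2, k_on = 1, k_off = 0),
                  start = c("1", "B"))
}

test_that("transform matches closed forms and is monotone in s", {
  ch <- single_step_chain(2)
  expect_equal(laplace_transform(ch, 0), 1)
  expect_equal(laplace_transform(ch, 2), 0.5)          # k/(k+s) at k = s = 2
  s <- c(0, 0.5, 1, 2, 5)
  expect_equal(laplace_transform(ch, s), 2 / (2 + s))
  expect_true(all(diff(laplace_transform(ch, s)) < 0))
  expect_error(laplace_transform(ch, -1), class = "gatedtx_domain_error")
  # independent dense resolvent solve on the toy IR chain
  toy <- toy_model("IR")
  chi <- build_composite(toy, unit_rates(toy))
  sub <- stopped_subgenerator(chi)
  direct <- unname(solve(diag(1, 4) - sub$Qtilde, sub$exit)[sub$start])
  expect_equal(laplace_transform(chi, 1), direct, tolerance = 1e-12)
})

test_that("moments match closed forms and transform derivatives", {
  m <- fpt_moments(single_step_chain(2))
  expect_equal(m$mean, 0.5)
  expect_equal(m$var, 0.25)
  m2 <- fpt_moments(two_step_chain(1, 1))
  expect_equal(m2$mean, 2)
  expect_equal(m2$var, 2)
  # numerically differentiating the transform at 0 recovers the moments
  toy <- toy_model("ER")
  ch <- build_composite(toy, unit_rates(toy))
  m3 <- fpt_moments(ch)
  h <- 1e-5 / m3$mean
  f <- function(s) laplace_transform(ch, s)
  # second-order one-sided differences at s = 0 (transform domain is s >= 0)
  mu_fd <- -(-3 * f(0) + 4 * f(h) - f(2 * h)) / (2 * h)
  m2_fd <- (f(0) - 2 * f(h) + f(2 * h)) / h^2
  expect_equal(mu_fd, m3$mean, tolerance = 1e-4)
  expect_equal(m2_fd, m3$raw_moments[[2L]], tolerance = 1e-4)
  expect_error(fpt_moments(ch, n_max = 0), class = "gatedtx_domain_error")
})

test_that("phase-type density matches closed forms and integrates to one", {
  ch <- single_step_chain(1.5)
  tg <- seq(0, 10, length.out = 200)
  expect_equal(fpt_density(ch, tg), 1.5 * exp(-1.5 * tg), tolerance = 1e-8)
  erl <- two_step_chain(1, 1)
  tg2 <- seq(0, 30, length.out = 400)
  d <- fpt_density(erl, tg2)
  expect_equal(d, tg2 * exp(-tg2), tolerance = 1e-8)
  expect_equal(tg2[which.max(d)], 1, tolerance = 0.1)
  # quadrature check on a seed-fixed toy IR chain
  set.seed(31)
  toy <- toy_model("IR")
  r <- setNames(runif(6, 0.2, 1), rate_names(toy))
  chi <- build_composite(toy, r)
  m <- fpt_moments(chi)
  grid <- seq(0, m$mean + 12 * sqrt(m$var), length.out = 600)
  dens <- fpt_density(chi, grid)
  expect_true(all(dens >= 0))
  mass <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid))
  expect_equal(mass, 1, tolerance = 1e-3)
  expect_error(fpt_density(chi, numeric(0)), class = "gatedtx_domain_error")
})

test_that("analytic moments agree with the Gillespie oracle on fixtures", {
  n_reps <- 20000
  for (seed in 1:6) {
    fx <- random_fixture_chain(3 + (seed %% 6), seed)
    ch <- build_composite(fx$spec, fx$rates)
    m <- fpt_moments(ch)
    s <- gillespie_fpt(ch, n_reps, seed + 100)$first_passage_times
    se_mean <- sd(s) / sqrt(n_reps)
    expect_lt(abs(mean(s) - m$mean), 4 * se_mean)
    se_var <- sd((s - mean(s))^2) / sqrt(n_reps)
    expect_lt(abs(var(s) - m$var), 4 * se_var)
  }
})

test_that("global rate rescaling rescales moments and preserves ratios", {
  set.seed(32)
  toy_ir <- toy_model("IR"); toy_er <- toy_model("ER")
  r <- setNames(runif(6, 0.05, 1), rate_names(toy_ir))
  base_ir <- fpt_moments(build_composite(toy_ir, r))
  base_er <- fpt_moments(build_composite(toy_er, r))
  for (c_scale in c(0.01, 100)) {
    m_ir <- fpt_moments(build_composite(toy_ir, r * c_scale))
    expect_equal(m_ir$mean, base_ir$mean / c_scale, tolerance = 1e-10)
    expect_equal(m_ir$var, base_ir$var / c_scale^2, tolerance = 1e-10)
    m_er <- fpt_moments(build_composite(toy_er, r * c_scale))
    expect_equal(m_ir$mean / m_er$mean, base_ir$mean / base_er$mean,
                 tolerance = 1e-10)
  }
})

test_that("pinch decomposition finds cut states and recombines exactly", {
  lin <- two_step_chain(1, 2)
  pd <- pinch_decompose(lin)
  expect_identical(pd$pinch_points, "2B")
  expect_length(pd$segments, 2L)
  set.seed(33)
  for (nm in c("toy", "realistic", "toy_pause_exit")) {
    spec <- catalog_model(nm, "IR")
    r <- setNames(runif(length(rate_names(spec)), 0.05, 1), rate_names(spec))
    ch <- build_composite(spec, r)
    pd <- pinch_decompose(ch)
    for (s in c(0.1, 1, 10))
      expect_lt(abs(pd$transform(s) - laplace_transform(ch, s)), 1e-8)
    m <- fpt_moments(ch)
    expect_equal(sum(pd$moments$mean), m$mean, tolerance = 1e-10)
    expect_equal(sum(pd$moments$var), m$var, tolerance = 1e-8)
  }
  # realistic IR: the bound-enhancer unbound-promoter state funnels all paths
  r16 <- unit_rates(realistic_model("IR"))
  pdr <- pinch_decompose(build_composite(realistic_model("IR"), r16))
  expect_true("1B" %in% pdr$pinch_points)
  # toy ER: promoter can progress with the enhancer in either state, so no
  # enhancer-bound state before the gate is forced
  pde <- pinch_decompose(build_composite(toy_model("ER"),
                                         unit_rates(toy_model("ER"))))
  expect_identical(pde$pinch_points, "3B")
})

test_that("enhancer-equilibrium reduction behaves as an ER approximation", {
  expect_equal(1 / (1 + 1), 0.5)  # pi at k_on = k_off, by definition
  set.seed(34)
  toy <- toy_model("ER")
  r <- setNames(runif(6, 0.2, 1), rate_names(toy))
  # fast enhancer: reduction within 1% of the exact mean
  r_fast <- r; r_fast[c("k_on", "k_off")] <- r[c("k_on", "k_off")] * 1000
  mu_exact <- fpt_moments(build_composite(toy, r_fast))$mean
  mu_approx <- fpt_moments(enhancer_equilibrium_approx(toy, r_fast))$mean
  expect_lt(abs(mu_approx - mu_exact) / mu_exact, 0.01)
  # k_off = 0 gives pi = 1: the reduced chain's gate never blocks, so its
  # moments equal those of the ungated promoter chain (enhancer pinned to B)
  r0 <- r; r0[["k_off"]] <- 0
  mu_red <- fpt_moments(enhancer_equilibrium_approx(toy, r0))$mean
  mu_ungated <- fpt_moments(build_composite(toy, r0,
                                            start = c("1", "B")))$mean
  expect_equal(mu_red, mu_ungated, tolerance = 1e-10)
  expect_error(enhancer_equilibrium_approx(toy_model("IR"), r),
               class = "gatedtx_unsupported_error")
  # realistic ER with fast enhancer
  real <- realistic_model("ER")
  r16 <- setNames(runif(16, 0.2, 1), rate_names(real))
  r16[c("k_on", "k_off")] <- r16[c("k_on", "k_off")] * 1000
  mu_e <- fpt_moments(build_composite(real, r16))$mean
  mu_a <- fpt_moments(enhancer_equilibrium_approx(real, r16))$mean
  expect_lt(abs(mu_a - mu_e) / mu_e, 0.01)
})
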