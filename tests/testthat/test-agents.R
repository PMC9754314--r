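test_that("Asch-type estimates follow the built-in rule", {
  noiseless <- agent_config("asch", initial_weight = 0.61, eta_support = 0L)
  expect_equal(asch_estimate(noiseless, 40), 24)  # round(24.4)
  plus2 <- agent_config("asch", initial_weight = 0.61, eta_support = 2L)
  expect_equal(asch_estimate(plus2, 40), 26)

  over <- agent_config("asch", initial_weight = 1.21, eta_support = 0L)
  expect_equal(over$initial_weight, 1.21)

  # noise support bound over many draws
  cfg <- agent_config("asch", initial_weight = 0.61)
  set.seed(1)
  draws <- replicate(1e4, asch_estimate(cfg, 37))
  expect_true(all(abs(draws - round_half_away(0.61 * 37)) <= 2))
  expect_setequal(unique(draws - round_half_away(0.61 * 37)), -2:2)
})

test_that("Sherif weight update evaluates the lag-5 recurrence", {
  cfg <- agent_config("sherif")
  state <- list(w_history = rep(0.61, 5), partner_w_history = rep(0.61, 5))
  upd <- sherif_update_weight(cfg, state)
  expect_equal(upd$weight, 0.61 + sum(cfg$a) * 0.61 + sum(cfg$b) * 0.61)
  expect_equal(upd$weight, 0.78324, tolerance = 1e-10)
  expect_equal(upd$state$w_history[1], upd$weight)  # history shifted

  zero <- agent_config("sherif", a = rep(0, 5), b = rep(0, 5))
  st <- sherif_init_state(zero)
  for (k in 1:10) {
    u <- sherif_update_weight(zero, st)
    st <- u$state
    expect_equal(u$weight, 0.61)
  }

  bad <- state
  bad$w_history[2] <- NaN
  expect_error(sherif_update_weight(cfg, bad), "non-finite")
})

test_that("Sherif recurrence converges to its fixed point against a static participant", {
  cfg <- agent_config("sherif")
  st <- sherif_init_state(cfg)
  w <- NA
  for (k in 1:200) {
    u <- sherif_update_weight(cfg, st)
    w <- u$weight
    st <- observe_participant(u$state, 0.91 * 40, 40)
  }
  target <- (0.61 + sum(cfg$b) * 0.91) / (1 - sum(cfg$a))
  expect_equal(target, 0.8561, tolerance = 1e-4)
  expect_equal(w, target, tolerance = 1e-8)
})

test_that("Sherif weight increases monotonically from warm start under a high-weight participant", {
  cfg <- agent_config("sherif")
  st <- sherif_init_state(cfg)
  ws <- numeric(10)
  for (k in 1:10) {
    u <- sherif_update_weight(cfg, st)
    ws[k] <- u$weight
    st <- observe_participant(u$state, round(0.95 * 42), 42)
  }
  expect_true(all(diff(c(0.61, ws)) > 0))
})

test_that("Sherif estimates round half away from zero, with noise after rounding", {
  zero <- agent_config("sherif", a = rep(0, 5), b = rep(0, 5),
                       eta_support = 0L)
  st <- sherif_init_state(zero)
  out <- sherif_estimate(zero, st, 50)
  expect_equal(out$estimate, 31)  # round(30.5) half away from zero

  # fixed-point regime estimate
  cfg <- agent_config("sherif", eta_support = 0L)
  st <- sherif_init_state(cfg)
  for (k in 1:200) {
    u <- sherif_estimate(cfg, st, 40)
    st <- observe_participant(u$state, 0.91 * 40, 40)
  }
  expect_equal(u$estimate, 34)

  # seeded determinism of a 48-trial trace
  cfg2 <- agent_config("sherif")
  dots <- rep(seq(25, 58, 3), 4)
  trace <- round(0.9 * dots)
  expect_identical(run_agent(cfg2, dots, trace, seed = 7),
                   run_agent(cfg2, dots, trace, seed = 7))
})

test_that("observe_participant maintains the implied-weight lag buffer", {
  st <- sherif_init_state(agent_config("sherif"))
  st <- observe_participant(st, 40, 40)
  expect_equal(st$partner_w_history[1], 1.0)
  st <- observe_participant(st, 24, 40)
  expect_equal(st$partner_w_history[1], 0.6)
  for (k in 1:100) st <- observe_participant(st, k, 40)
  expect_length(st$partner_w_history, 5)
  expect_error(observe_participant(st, 30, 0), "positive")
})

test_that("Sherif recurrence is stable for bounded participant input (property)", {
  cfg <- agent_config("sherif")
  set.seed(13)
  for (rep in 1:5) {
    st <- sherif_init_state(cfg)
    ws <- numeric(300)
    for (k in 1:300) {
      u <- sherif_update_weight(cfg, st)
      ws[k] <- u$weight
      st <- observe_participant(u$state, runif(1, 0, 2) * 40, 40)
    }
    expect_true(all(ws >= 0 & ws <= 3))
  }
})

test_that("overestimating Sherif variants expose both intercept conventions", {
  hist_mode <- agent_config("sherif", initial_weight = 1.21)
  expect_equal(hist_mode$intercept, 0.61)
  expect_equal(sherif_init_state(hist_mode)$w_history, rep(1.21, 5))

  rescaled <- agent_config("sherif", initial_weight = 1.21,
                           intercept_mode = "rescale")
  expect_equal(rescaled$intercept,
               1.21 * (1 - sum(rescaled$a)) - sum(rescaled$b) * 0.91)
  # rescaled intercept keeps the all-warm-start fixed point at 1.21 when the
  # participant also sits at the reference weight
  st <- sherif_init_state(rescaled)
  st$partner_w_history <- rep(0.91, 5)
  for (k in 1:300) {
    u <- sherif_update_weight(rescaled, st)
    st <- observe_participant(u$state, 0.91 * 40, 40)
  }
  expect_equal(u$weight, 1.21, tolerance = 1e-6)
})
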