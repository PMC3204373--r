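test_that("reward maps distance to (0, 1] via the exponential", {
  expect_equal(compute_reward(0), 1)
  expect_equal(compute_reward(10.9, alpha = 0.01), exp(-0.109))
  expect_lt(compute_reward(1e6), 1e-6)
  expect_error(compute_reward(-1), "non-negative")
  expect_error(compute_reward(1, alpha = 0), "alpha")
})

test_that("temporal-difference error scales the reward change", {
  expect_equal(td_error(0.9, 0.9, mu = 7), 0)
  expect_equal(td_error(0.9, 0.8, mu = 7), 0.7)
  expect_equal(td_error(0.8, 0.9, mu = 7), -0.7)
})

test_that("learning_config validates its hyperparameters", {
  expect_error(learning_config(eta = 1.5), "eta")
  expect_error(learning_config(alpha = -1), "alpha")
  expect_error(learning_config(mu = 0), "mu")
  cfg <- learning_config()
  expect_equal(cfg$eta, 0.01)
  expect_equal(cfg$mu, 7)
  expect_equal(cfg$alpha, 0.01)
  expect_equal(cfg$lambda_trace, 1)
})

test_that("eligibility covers exactly the input-to-hidden synapses", {
  set.seed(1)
  net5 <- build_network(5)
  expect_equal(length(eligible_synapses(net5)), 10)
  net7 <- build_network(7)
  idx <- eligible_synapses(net7)
  expect_equal(length(idx), 14)
  expect_true(all(net7$synapses$layer[idx] == "ih"))
  expect_false(any(net7$synapses$layer[idx] == "ho"))
})

test_that("the multiplicative update follows the printed arithmetic", {
  cfg <- learning_config()
  syn <- tibble::tibble(
    syn_id = 1L, U_SE = 0.5, tau_rec = 100, tau_fac = 50, inhibitory = FALSE
  )
  # zero error: nothing moves
  expect_equal(update_parameters(syn, 0, cfg), syn)
  # tau_rec has sign +1: delta = 0.7 adds eta * m * delta = 0.7
  up <- update_parameters(syn, 0.7, cfg)
  expect_equal(up$tau_rec, 100.7)
  expect_equal(up$U_SE, 0.5 - 0.01 * 0.5 * 0.7)
  expect_equal(up$tau_fac, 50 - 0.01 * 50 * 0.7)
  # clipping at the U_SE ceiling
  syn2 <- dplyr::mutate(syn, U_SE = 1)
  expect_equal(update_parameters(syn2, -3, cfg)$U_SE, 1)
  expect_error(update_parameters(syn, Inf, cfg), "finite")
})

test_that("parameters stay positive and inside bounds under arbitrary errors", {
  set.seed(31)
  cfg <- learning_config()
  syn <- tibble::tibble(
    syn_id = 1:4, U_SE = c(0.5, 0.1, 0.9, 0.02),
    tau_rec = c(100, 5, 900, 40), tau_fac = c(50, 999, 2, 70),
    inhibitory = c(FALSE, TRUE, FALSE, TRUE)
  )
  for (i in 1:200) {
    syn <- update_parameters(syn, runif(1, -7, 7), cfg,
                             attribution = runif(4, -1, 1))
    expect_true(all(syn$U_SE >= 0.01 & syn$U_SE <= 1))
    expect_true(all(syn$tau_rec >= 1 & syn$tau_rec <= 1000))
    expect_true(all(syn$tau_fac >= 1 & syn$tau_fac <= 1000))
  }
})

test_that("per-episode relative change is bounded by eta * mu", {
  cfg <- learning_config()
  syn <- tibble::tibble(syn_id = 1L, U_SE = 0.5, tau_rec = 500, tau_fac = 500,
                        inhibitory = FALSE)
  # |delta| <= mu because rewards live in (0, 1]
  for (delta in seq(-7, 7, by = 0.5)) {
    up <- update_parameters(syn, delta, cfg)
    for (m in c("U_SE", "tau_rec", "tau_fac")) {
      expect_lte(abs(up[[m]] - syn[[m]]) / syn[[m]],
                 cfg$eta * cfg$mu + 1e-12)
    }
  }
})

test_that("learning_step skips the first episode and rolls the reward state", {
  set.seed(2)
  net <- build_network(5)
  cfg <- learning_config()
  st <- learning_step(list(previous = NULL, current = 0.9), net, cfg)
  expect_identical(st$network$synapses, net$synapses)
  expect_true(is.na(st$delta))
  expect_equal(st$reward_state$previous, 0.9)
  expect_equal(nrow(st$log), 0)

  # identical consecutive rewards: delta = 0, nothing moves
  st2 <- learning_step(list(previous = 0.9, current = 0.9), net, cfg)
  expect_equal(st2$delta, 0)
  expect_identical(st2$network$synapses, net$synapses)
})

test_that("signed coupling moves all parameters with the error sign", {
  set.seed(2)
  net <- build_network(5)
  cfg <- learning_config(td_coupling = "signed", attribution = "none")
  # reward got worse: delta = 7 * (0.9 - 0.8) > 0
  st <- learning_step(list(previous = 0.9, current = 0.8), net, cfg)
  idx <- eligible_synapses(net)
  expect_true(all(st$network$synapses$U_SE[idx] < net$synapses$U_SE[idx]))
  expect_true(all(st$network$synapses$tau_fac[idx] < net$synapses$tau_fac[idx]))
  expect_true(all(st$network$synapses$tau_rec[idx] > net$synapses$tau_rec[idx]))
  # hidden-to-output synapses are never touched
  ho <- which(net$synapses$layer == "ho")
  expect_identical(st$network$synapses[ho, ], net$synapses[ho, ])
})

test_that("magnitude coupling follows the attribution direction", {
  set.seed(2)
  net <- build_network(5)
  cfg <- learning_config()  # td_coupling = "magnitude"
  idx <- eligible_synapses(net)
  h <- rep(c(1, -1), length.out = length(idx))
  st <- learning_step(list(previous = 0.8, current = 0.9), net, cfg,
                      attribution = h)
  dU <- st$network$synapses$U_SE[idx] - net$synapses$U_SE[idx]
  expect_true(all(dU[h > 0] > 0))  # positively attributed: facilitation up
  expect_true(all(dU[h < 0] < 0))
  # step size is eta * m * |delta| regardless of the error's sign
  st2 <- learning_step(list(previous = 0.9, current = 0.8), net, cfg,
                       attribution = h)
  expect_equal(st2$network$synapses$U_SE, st$network$synapses$U_SE)
})

test_that("hebbian attribution classifies hits and false alarms per pathway", {
  set.seed(6)
  net <- build_network(5)
  nb <- 8L
  # hidden neuron 1 fires in bins 1 and 3; all others silent
  hidden_bits <- matrix(FALSE, nb * 5L, 5L)
  hidden_bits[c(1, 11), 1] <- TRUE  # steps in bins 1 and 3 (W = 5)
  G <- binned_train(c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L), 5)
  preA <- binned_train(c(1L, 0L, 1L, 0L, 1L, 0L, 0L, 0L), 5)
  preB <- binned_train(rep(0L, nb), 5)
  h <- hebbian_attribution(net, list(preA, preB), hidden_bits, G,
                           attribution = "hit_false_alarm")
  idx <- eligible_synapses(net)
  syn <- net$synapses[idx, ]
  # synapse input1 -> hidden1: bin1 is a hit (pre, post, G all high),
  # bin3 a false alarm -> tie -> 0
  expect_equal(h[syn$pre == 1 & syn$post == 1], 0)
  # input2 never active: no evidence either way
  expect_true(all(h[syn$pre == 2] == 0))
  # error variant: hidden1's pathway missed bin 5 (G high, pre active,
  # no spike) and false-alarmed bin 3 -> tie -> 0; the other hidden
  # neurons are silent, so their input-1 pathways show net misses
  he <- hebbian_attribution(net, list(preA, preB), hidden_bits, G,
                            attribution = "error")
  expect_equal(he[syn$pre == 1 & syn$post == 1], 0)
  expect_true(all(he[syn$pre == 1 & syn$post != 1] == 1))
  expect_true(all(hebbian_attribution(net, list(preA, preB), hidden_bits, G,
                                      attribution = "none") == 1))
})
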