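# Frequency-domain components and the closed-loop sensitivity.

test_that("component responses match their closed forms", {
  p <- test_params()
  # PD controller at DC: derivative term vanishes
  expect_equal(component_response("NC", p, 0), complex(real = p$K_P))
  # zero delay is the identity
  a <- robot_anthro()
  p0 <- ic_parameters(a, W_p = 0.5, K_P = 2 * grav_stiffness(a), K_D = 300,
                      tau_D = 0, tau_F = 15, K_F = 8e-4)
  expect_equal(component_response("TD", p0, c(0, 0.7, 2.05)),
               rep(complex(real = 1), 3))
  # inverted pendulum at DC: -1/(m g h), robot anthropometry
  expect_equal(component_response("BD", p0, 0),
               complex(real = -1 / (51 * 9.81 * 0.97)))
  # first-order low-pass at DC passes the full gain
  expect_equal(component_response("FF", p0, 0), complex(real = p0$K_F))
})

test_that("a pure delay preserves magnitude at every frequency", {
  p <- test_params(tau_D = 0.23)
  f <- c(0, 0.05, 0.7, 2.05, 10)
  expect_equal(Mod(component_response("TD", p, f)), rep(1, 5))
})

test_that("component and frequency validation errors are raised", {
  p <- test_params()
  expect_error(component_response("XX", p, 1), "BD")
  expect_error(component_response("NC", p, NaN), "finite")
  expect_error(component_response("NC", p, -1), "non-negative")
  expect_error(closed_loop_sensitivity(p, numeric(0)), "non-empty")
})

test_that("closed-loop sensitivity vanishes with the proprioceptive weight", {
  p <- test_params(W_p = 0)
  h <- closed_loop_sensitivity(p, excited_frequencies())
  expect_equal(Mod(h), rep(0, 21))
})

test_that("closed-loop DC gain without force feedback has its closed form", {
  a <- test_anthro()
  mgh <- grav_stiffness(a)
  p <- ic_parameters(a, W_p = 0.5, K_P = 2 * mgh, K_D = 0.3 * mgh,
                     tau_D = 0.15, tau_F = 15, K_F = 0)
  expect_equal(closed_loop_sensitivity(p, 0), complex(real = 1))
  # general closed form W_p K_P / (K_P - mgh)
  p2 <- ic_parameters(a, W_p = 0.31, K_P = 1.7 * mgh, K_D = 0.3 * mgh,
                      tau_D = 0.1, tau_F = 10, K_F = 0)
  expect_equal(closed_loop_sensitivity(p2, 0),
               complex(real = 0.31 * 1.7 * mgh / (1.7 * mgh - mgh)))
})

test_that("sensitivity matches an independent complex-arithmetic oracle", {
  withr::local_seed(11)
  f <- excited_frequencies(20, 2.05)
  a <- test_anthro()
  mgh <- grav_stiffness(a)
  for (i in 1:1000) {
    W_p <- runif(1); kp <- runif(1, 1.05, 6); kd <- runif(1, 0, 2)
    tau_D <- runif(1, 0, 0.4); tau_F <- runif(1, 1, 100); K_F <- runif(1, 0, 0.01)
    p <- ic_parameters(a, W_p = W_p, K_P = kp * mgh, K_D = kd * mgh,
                       tau_D = tau_D, tau_F = tau_F, K_F = K_F)
    h <- closed_loop_sensitivity(p, f)
    ho <- oracle_sensitivity(a$mass, a$com_height, a$inertia, a$g,
                             W_p, kp * mgh, kd * mgh, tau_D, tau_F, K_F, f)
    expect_lt(max(Mod(h - ho) / pmax(Mod(ho), 1e-300)), 1e-10)
  }
})

test_that("the sensitivity derivative in W_p is independent of W_p", {
  # numerator-only dependence: H(f; W_p)/W_p is constant in W_p
  f <- excited_frequencies()
  h1 <- closed_loop_sensitivity(test_params(W_p = 0.2), f) / 0.2
  h2 <- closed_loop_sensitivity(test_params(W_p = 0.9), f) / 0.9
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("normalized gains scale by the gravitational stiffness", {
  a <- test_anthro(); mgh <- grav_stiffness(a)
  p <- ic_parameters(a, W_p = 0.5, K_P = 2 * mgh, K_D = 0.5 * mgh,
                     tau_D = 0.15, tau_F = 15, K_F = 0)
  expect_equal(unname(normalized_gains(p)), c(2, 0.5))
  # robot body, hand-computed
  pr <- ic_parameters(robot_anthro(), W_p = 0.5, K_P = 970.7, K_D = 100,
                      tau_D = 0.15, tau_F = 15, K_F = 0)
  expect_equal(normalized_gains(pr)[["stiffness"]], 970.7 / (51 * 9.81 * 0.97))
})

test_that("winter anthropometry derives a plausible single-link body", {
  a <- winter_anthropometry(77.7, 1.79)
  expect_lt(a$mass, 77.7)
  expect_gt(a$mass, 0)
  expect_gt(a$com_height, 0)
  expect_lt(a$com_height, 1.79)
  expect_gt(a$inertia, 0)
  # linear in mass: doubling total mass doubles m and J, h unchanged
  a2 <- winter_anthropometry(2 * 77.7, 1.79)
  expect_equal(a2$mass, 2 * a$mass)
  expect_equal(a2$inertia, 2 * a$inertia)
  expect_equal(a2$com_height, a$com_height)
  expect_error(winter_anthropometry(-1, 1.79), "positive")
  expect_error(winter_anthropometry(77.7, 0), "positive")
})

test_that("parameter invariants are enforced", {
  a <- test_anthro(); mgh <- grav_stiffness(a)
  expect_error(ic_parameters(a, W_p = 0.5, K_P = 0.9 * mgh, K_D = 100,
                             tau_D = 0.1, tau_F = 10, K_F = 0),
               "gravitational stiffness")
  expect_error(ic_parameters(a, W_p = 1.2, K_P = 2 * mgh, K_D = 100,
                             tau_D = 0.1, tau_F = 10, K_F = 0), "0, 1")
  expect_error(ic_parameters(a, W_p = 0.5, K_P = 2 * mgh, K_D = 100,
                             tau_D = 0.1, tau_F = 10, K_F = 0,
                             W_vis = 0.4, W_ves = 0.4), "sum to one")
  # serialisation round trip
  p <- test_params()
  expect_equal(as_ic_parameters(ic_parameters_flatten(p))$K_P, p$K_P)
})
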