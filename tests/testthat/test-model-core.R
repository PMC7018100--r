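test_that("default parameters reproduce the published set exactly", {
  p <- model_parameters()
  published <- list(
    tau_S = 100, tau_h = 50, tau_mc = 150,
    a = 270, b = 108, d = 0.154,
    I_0 = 0.3255, J_N_ii = 0.248, J_N_ij = 0.0497,
    mu_0 = 30, J_A_ext = 0.00052,
    J_mc0 = 0.002, J_VHU = 10,
    J_N_LR = 1, J_N_RL = 1,
    S_th = 42.5, H_th = 17.4, G_S = 1.12,
    C_pos = 760, dt = 0.5, t_gate = 600, t_stim = 800,
    g_pre = 1000, g_post = 3000
  )
  for (nm in names(published)) {
    expect_identical(p[[nm]], published[[nm]], label = nm)
  }
})

test_that("parameter invariants are enforced", {
  expect_error(model_parameters(dt = -1), "dt")
  expect_error(model_parameters(dt = 5, tau_noise = 2), "tau_noise")
  expect_error(model_parameters(gamma = 1.5), "gamma")
  expect_error(model_parameters(sigma_noise = -0.1), "sigma_noise")
  expect_error(model_parameters(nonsense = 1), "nonsense")
  expect_error(model_parameters(tau_S = Inf), "tau_S")
})

test_that("threshold-linear function clips negatives and rejects non-finite",
{
  expect_equal(threshold_linear(-5), 0)
  expect_equal(threshold_linear(0), 0)
  expect_equal(threshold_linear(3), 3)
  expect_equal(threshold_linear(c(-1, 2)), c(0, 2))
  expect_error(threshold_linear(NaN))
})

test_that("f-I curve handles the removable singularity and its limit", {
  p <- model_parameters()
  # oracle: approach the singular point from both sides
  x0 <- p$b / p$a
  lim <- mean(io_gain(x0 + c(-1e-9, 1e-9), p))
  expect_equal(io_gain(x0, p), p$G_S / p$d, tolerance = 1e-10)
  expect_equal(io_gain(x0, p), lim, tolerance = 1e-6)
  expect_equal(io_gain(x0, p), 7.2727, tolerance = 1e-4)
})

test_that("f-I curve matches its asymptotic branches", {
  p <- model_parameters()
  # at x = 1 nA the exponential term is negligible: H ~ G_S (a x - b)
  expect_equal(io_gain(1, p), p$G_S * (p$a - p$b), tolerance = 1e-8)
  expect_equal(io_gain(1, p), 181.44, tolerance = 1e-6)
  expect_lt(io_gain(-5, p), 1e-10)   # H -> 0 far below threshold current
})

test_that("f-I curve is continuous and strictly increasing across a fine
           grid spanning the singularity", {
  p <- model_parameters()
  x <- seq(0.38, 0.42, length.out = 10000)  # brackets b/a = 0.4
  H <- io_gain(x, p)
  expect_true(all(diff(H) > 0))
  expect_lt(max(abs(diff(H))), 0.01)  # no jump at the singular point
  expect_true(all(H >= 0))
})

test_that("stimulus currents follow the coherence biasing rule and the
           stimulus window", {
  p <- model_parameters()
  base <- p$J_A_ext * p$mu_0
  expect_equal(unname(stimulus_current(0, "left", 100, p)),
               c(base, base))
  expect_equal(base, 0.0156)
  hi <- stimulus_current(0.512, "right", 100, p)
  expect_equal(unname(hi["I_R"]), 0.0235872, tolerance = 1e-12)
  expect_equal(unname(hi["I_L"]), 0.0076128, tolerance = 1e-12)
  expect_equal(unname(stimulus_current(0.512, "right", 900, p)), c(0, 0))
  expect_equal(unname(stimulus_current(0.3, "left", -5, p)), c(0, 0))
  expect_error(stimulus_current(1.2, "left", 0, p), "coherence")
})

test_that("sensorimotor input sums its five current sources", {
  p <- model_parameters()
  expect_equal(sensorimotor_input(0, 0, 0, 0, 0, p), p$I_0)
  # symmetric states receive symmetric input
  expect_equal(sensorimotor_input(0.3, 0.3, 0.0156, 10, 0, p),
               sensorimotor_input(0.3, 0.3, 0.0156, 10, 0, p))
  expect_equal(sensorimotor_input(0.1, 0.2, 0.0156, 15, 0, p),
               0.248 * 0.1 - 0.0497 * 0.2 + 0.3255 + 0.0156 + 0.002 * 15,
               tolerance = 1e-15)
  expect_equal(sensorimotor_input(0.1, 0.2, 0.0156, 15, 0, p), 0.38596)
})

test_that("gating-variable drift keeps the unit interval invariant", {
  p <- model_parameters()
  expect_equal(unname(synaptic_drift(0, 0, 0, 0, p)), c(0, 0))
  d1 <- synaptic_drift(1, 0.5, 100, 100, p)
  expect_equal(unname(d1["dS_L"]), -1 / p$tau_S)
  expect_lt(d1[["dS_L"]], 0)
  d2 <- synaptic_drift(0.5, 0.5, 20, 20, p)
  expect_equal(unname(d2["dS_L"]), -0.005 + 0.5 * 0.641 * 0.020,
               tolerance = 1e-12)
  expect_equal(unname(d2["dS_L"]), 0.00141, tolerance = 1e-12)
  expect_gte(synaptic_drift(0, 0, 50, 0, p)[["dS_L"]], 0)
})

test_that("uncertainty drift implements gated leaky integration of the
           summed rates", {
  p <- model_parameters()
  expect_equal(uncertainty_drift(10, 0, 0, 0, p), -10 / 150)
  expect_equal(uncertainty_drift(0, 20, 20, 0, p), 400 / 150)
  # strong inhibition rectifies the input away: pure decay
  expect_equal(uncertainty_drift(5, 20, 20, 1000, p), -5 / 150)
})

test_that("hand drift forms a mutually inhibiting race gated by top-down
           inhibition", {
  p <- model_parameters()
  d <- hand_drift(3, 7, 500, 900, 1000, p)
  expect_equal(unname(d), c(-3 / 50, -7 / 50))
  d2 <- hand_drift(5, 5, 30, 30, 0, p)
  expect_equal(d2[["dy_HL"]], d2[["dy_HR"]])
  d3 <- hand_drift(0, 10, 40, 0, 0, p)
  expect_equal(d3[["dy_HL"]], (40 - 1 * 10) / 50)
  expect_equal(d3[["dy_HL"]], 0.6)
})

test_that("OU noise parameters give the closed-form stationary variance", {
  p <- model_parameters(sigma_noise = 0.02)
  od <- ou_noise_drift(0.02, p)
  expect_equal(od[["drift"]], -0.02 / 2)
  expect_equal(od[["diffusion"]], 0.02 * sqrt(2 / 2))
  expect_equal(ou_noise_drift(1, model_parameters(sigma_noise = 0))[["diffusion"]], 0)
  # oracle: Euler-Maruyama path against sigma^2 (1 - dt/(2 tau)) discrete
  # stationary variance
  set.seed(42)
  dt <- p$dt
  n <- 2e5
  x <- numeric(n)
  coef <- od[["diffusion"]] * sqrt(dt)
  for (k in 2:n) {
    x[k] <- x[k - 1] - x[k - 1] / p$tau_noise * dt + coef * rnorm(1)
  }
  # discrete-time stationary variance of the Euler chain:
  # sigma^2 / (1 - dt / (2 tau)); approaches sigma^2 as dt -> 0
  v_theory <- p$sigma_noise^2 / (1 - dt / (2 * p$tau_noise))
  expect_equal(var(x[1000:n]), v_theory, tolerance = 0.05)
  expect_equal(var(x[1000:n]), p$sigma_noise^2, tolerance = 0.2)
})

test_that("cursor mapping is linear, antisymmetric and anchored at the
           choice target", {
  p <- model_parameters()
  expect_equal(map_hand_to_x(5, 5, p), 0)
  expect_equal(abs(map_hand_to_x(17.4, 0, p)), 760)
  expect_equal(map_hand_to_x(3, 10, p), -map_hand_to_x(10, 3, p))
  expect_error(map_hand_to_x(-1, 0, p), "nonnegative")
})

test_that("config round-trip preserves parameters and an empty config gives
           the published defaults", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", cfg)
  expect_equal(load_config(cfg), model_parameters())
  write_config(model_parameters(dt = 0.25, sigma_noise = 0.01), cfg)
  p <- load_config(cfg)
  expect_equal(p$dt, 0.25)
  expect_equal(p$sigma_noise, 0.01)
  writeLines("not_a_parameter: 3", cfg)
  expect_error(load_config(cfg), "not_a_parameter")
})
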