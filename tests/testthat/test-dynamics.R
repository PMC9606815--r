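p0 <- model_params()

test_that("excitatory input assembles feedforward, spread, self-excitation and feedback", {
  # all silent: every term vanishes
  r <- region_state(3, "CTX")
  expect_equal(excitatory_input(r, numeric(3), numeric(3), p0), numeric(3))

  # self-excitation sigmoid is at half-maximum at its threshold
  r1 <- region_state(1, "CTX")
  r1$a <- p0$t_a
  expect_equal(excitatory_input(r1, 0, 0, p0), p0$alpha / 2)

  # hand-computed: F = 0.1 (mu_c = 1), one neighbour a_y = 0.5 with w_yx = 0.4
  r2 <- region_state(2, "CTX")
  r2$a <- c(0.5, 0)
  r2$exists[1, 2] <- TRUE
  r2$W[1, 2] <- 0.4
  E <- excitatory_input(r2, c(0, 0.1), c(0, 0), p0)
  expect_equal(E[2], 0.1 + 0.9 * 0.4 * 0.5)  # 0.28

  # hippocampal gain mu_h = 2 applies to the cortical feedforward
  rh <- region_state(1, "HC")
  expect_equal(excitatory_input(rh, 0.3, 0, p0), 2 * 0.3)

  expect_error(excitatory_input(r2, 0.1, c(0, 0), p0), "length")
})

test_that("inhibitory input sums lateral inhibition and the inactivation sigmoid", {
  r <- region_state(2, "CTX")
  expect_equal(inhibitory_input(r, p0), c(0, 0))

  r$g <- c(p0$t_h, 0)  # sigmoid half-maximum: theta / 2
  expect_equal(inhibitory_input(r, p0)[1], p0$theta / 2)

  r2 <- region_state(2, "CTX")
  r2$a <- c(0, 0.1)
  expect_equal(inhibitory_input(r2, p0)[1], p0$beta * 0.1)  # 1.5
})

test_that("a silent network with zero input is a fixed point", {
  st <- network_state(c("A", "B"), p0)
  out <- step_network(st, c(0, 0), p0)
  expect_equal(out$dadt_ctx, c(0, 0))
  expect_equal(out$dadt_hc, c(0, 0))
  expect_identical(out$state$ctx$a, c(0, 0))
  expect_identical(out$state$hc$g, c(0, 0))
})

test_that("one Euler step from rest matches the hand computation", {
  # a = 0, E = mu_c * 0.1, sigma_a = 2: a <- (0.1 / 2) * 0.001 = 5e-5
  st <- network_state("A", p0)
  out <- step_network(st, 0.1, p0)
  expect_equal(out$state$ctx$a, 5e-5)
  expect_equal(out$dadt_ctx, 0.05)
})

test_that("constant drive converges to the shunting equilibrium E/(1/tau_a + E + I)", {
  # discrete Euler recurrence as independent oracle, then the network itself
  euler_limit <- function(E, I, p) {
    a <- 0
    for (i in seq_len(40000)) a <- a + p$dt * (-a / p$tau_a + (1 - a) * E - a * I) / p$sigma_a_wake
    a
  }
  for (case in list(c(E = 1, I = 0), c(E = 1, I = 2), c(E = 0.3, I = 0.5))) {
    a_star <- case["E"] / (1 / p0$tau_a + case["E"] + case["I"])
    expect_equal(euler_limit(case["E"], case["I"], p0), unname(a_star),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }

  # full network with self-excitation, inactivation and the inter-region
  # feedback loop ablated: E = mu_c * F, constant
  p <- model_params(alpha = 0, kappa = 0, zeta = 0)
  st <- network_state("A", p)
  for (i in seq_len(30000)) st <- step_network(st, 1, p)$state
  expect_equal(st$ctx$a, 1 / (1 / p$tau_a + 1), tolerance = 1e-3)
})

test_that("reset_transients zeroes activity but not weights or salience", {
  st <- network_state(c("A", "B"), p0)
  st$ctx$a <- c(0.5, 0.2); st$hc$g <- c(0.3, 0.1)
  st$ctx$exists[1, 2] <- TRUE; st$ctx$W[1, 2] <- 0.7
  st$salience[] <- c(5, 2)
  st2 <- reset_transients(st)
  expect_equal(st2$ctx$a, c(0, 0))
  expect_equal(st2$hc$g, c(0, 0))
  expect_equal(st2$ctx$W[1, 2], 0.7)
  expect_equal(unname(st2$salience), c(5, 2))
  expect_identical(reset_transients(st2), st2)  # idempotent
  # a reset state stays silent under zero input
  st3 <- step_network(st2, c(0, 0), p0)$state
  expect_equal(st3$ctx$a, c(0, 0))
})

test_that("activations and currents stay in [0, 1] under random drive", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(2:6, 1)
    st <- network_state(LETTERS[1:n], p0)
    st$ctx$exists <- st$hc$exists <- matrix(TRUE, n, n) & !diag(n)
    st$ctx$W <- matrix(runif(n * n), n) * st$ctx$exists
    st$hc$W <- matrix(runif(n * n), n) * st$hc$exists
    st$mode <- sample(c("wake", "sleep"), 1)
    inp <- runif(n, 0, 0.3)
    for (i in 1:400) st <- step_network(st, inp, p0)$state
    for (v in list(st$ctx$a, st$ctx$g, st$hc$a, st$hc$g)) {
      expect_true(all(v >= 0 & v <= 1))
    }
  }
})

test_that("sub-threshold activity decays monotonically to rest without input", {
  st <- network_state("A", p0)
  st$ctx$a <- 0.04  # below the self-excitation regime
  st$ctx$g <- 0.5
  a_tr <- g_tr <- numeric(5000)
  for (i in 1:5000) {
    st <- step_network(st, 0, p0)$state
    a_tr[i] <- st$ctx$a; g_tr[i] <- st$ctx$g
  }
  expect_true(all(diff(a_tr) <= 1e-15))
  expect_true(all(diff(g_tr) <= 1e-15))
  expect_lt(st$ctx$a, 1e-3)
})

test_that("sleep dynamics are a time-rescaled copy of wake dynamics", {
  # inactivation ablated (its speed factor is mode-independent); fine dt so
  # that discretization does not distort the fast sleep trajectory
  p <- model_params(kappa = 0, dt = 1e-4)
  time_to <- function(mode, level) {
    st <- network_state("A", p)
    st$mode <- mode
    for (i in 1:30000) {
      st <- step_network(st, 0.1, p)$state
      if (st$ctx$a >= level) return(i * p$dt)
    }
    NA_real_
  }
  ratio <- time_to("wake", 0.05) / time_to("sleep", 0.05)
  expect_equal(ratio, p$sigma_a_wake / p$sigma_a_sleep, tolerance = 0.05)
})

test_that("the compiled engine reproduces the reference R step exactly", {
  set.seed(7)
  n <- 4
  p <- model_params()
  st <- network_state(LETTERS[1:n], p)
  st$ctx$exists <- st$hc$exists <- matrix(TRUE, n, n) & !diag(n)
  st$ctx$W <- matrix(runif(n * n, 0, 0.5), n) * st$ctx$exists
  st$hc$W <- matrix(runif(n * n, 0, 0.9), n) * st$hc$exists
  st$salience[] <- runif(n, 0, 10)
  inp <- c(0.1, 0, 0.2, 0)

  for (mode in c("wake", "sleep")) {
    st$mode <- mode
    st_r <- st
    for (i in 1:200) {
      out <- step_network(st_r, inp, p)
      a_c <- st_r$ctx$a; a_h <- st_r$hc$a
      st_r <- out$state
      st_r$ctx <- update_weights(st_r$ctx, a_c, out$dadt_ctx, p)
      st_r$hc <- update_weights(st_r$hc, a_h, out$dadt_hc, p)
      if (mode == "wake") {
        tmp <- st_r; tmp$ctx$a <- a_c  # salience reads the pre-update state
        tmp <- update_salience(tmp, p)
        st_r$salience <- tmp$salience
      }
    }
    n_items <- length(st$catalog)
    out_c <- seqconsol:::cpp_integrate(
      st$ctx$a, st$ctx$g, st$hc$a, st$hc$g, st$ctx$W, st$hc$W,
      st$ctx$exists, st$hc$exists, unname(st$salience),
      inp, numeric(n_items), 200L, unclass(p),
      identical(mode, "sleep"), TRUE, TRUE, TRUE, FALSE, mode == "wake",
      rep(FALSE, n_items), integer(), 0L,
      matrix(integer(), 0, 2), matrix(integer(), 0, 2))
    expect_equal(out_c$a_c, st_r$ctx$a, tolerance = 1e-12)
    expect_equal(out_c$a_h, st_r$hc$a, tolerance = 1e-12)
    expect_equal(out_c$g_c, st_r$ctx$g, tolerance = 1e-12)
    expect_equal(out_c$W_c, st_r$ctx$W, tolerance = 1e-12)
    expect_equal(out_c$W_h, st_r$hc$W, tolerance = 1e-12)
    expect_equal(out_c$s, unname(st_r$salience), tolerance = 1e-12)
  }
})
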