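two_node_map <- function() {
  knowledge_map(c("A", "B"), data.frame(from = 1, to = 2, weight = 1))
}

test_that("elliott squashing is odd, bounded and exact", {
  expect_identical(elliott(0), 0)
  expect_identical(elliott(2), 2 / 3)
  expect_identical(elliott(-2), -(2 / 3))
  x <- seq(-50, 50, by = 0.37)
  expect_identical(elliott(-x), -elliott(x))
  expect_true(all(abs(elliott(x * 1e6)) < 1))
  expect_true(all(diff(elliott(x)) > 0))
  expect_error(elliott(Inf), class = "domain_error")
  expect_error(elliott(c(1, NA)), class = "domain_error")
})

test_that("initial_state places transient and locked values", {
  m <- knowledge_map(c("OCT3/4", "SOX2", "KLF4", "MECP2"))
  expect_identical(unname(initial_state(m, simulation_protocol())),
                   rep(0, 4))
  x <- initial_state(m, simulation_protocol(on = c("OCT3/4", "SOX2"),
                                            locked_off = "MECP2"))
  expect_identical(unname(x), c(1, 1, 0, -1))
  expect_identical(names(x), m$labels)
  expect_error(
    initial_state(m, simulation_protocol(on = "NANOG")),
    "NANOG", class = "protocol_error")
})

test_that("protocol construction enforces its invariants", {
  expect_error(simulation_protocol(on = "A", locked_on = "A"),
               class = "protocol_error")
  expect_error(simulation_protocol(tolerance = 0), class = "protocol_error")
  expect_error(simulation_protocol(max_iterations = 0),
               class = "protocol_error")
  expect_error(simulation_protocol(activation = "relu"),
               class = "protocol_error")
})

test_that("sim_step matches hand evaluation", {
  m <- two_node_map()
  p <- simulation_protocol()
  s1 <- sim_step(c(A = 1, B = 0), m, p)
  expect_identical(unname(s1), c(0, 0.5))
  # A has no inputs, so B's source decays on the next step
  expect_identical(unname(sim_step(s1, m, p)), c(0, 0))

  # unit self-loop, and the clamp overrides the activation
  m1 <- knowledge_map("A", data.frame(from = 1, to = 1, weight = 1))
  expect_identical(unname(sim_step(c(A = 1), m1, p)), 0.5)
  expect_identical(
    unname(sim_step(c(A = 1), m1, simulation_protocol(locked_on = "A"))), 1)

  ind <- knowledge_map(c("A", "B"),
                       data.frame(from = 1, to = 2, weight = NA))
  expect_error(sim_step(c(A = 1, B = 0), ind, p), "to_fuzzy",
               class = "indeterminate_error")
  expect_error(sim_step(c(A = 1), m, p), "length",
               class = "format_error")
})

test_that("mse is the mean squared displacement", {
  expect_identical(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(mse(c(0, 0), c(1, 1)), 1)
  expect_identical(mse(c(0.5, 0), c(0, 0)), 0.125)
  expect_error(mse(1, c(1, 2)), class = "format_error")
  expect_error(mse(numeric(0), numeric(0)), class = "domain_error")
})

test_that("a zero-edge map converges at iteration 2 to the zero vector", {
  m <- knowledge_map(c("A", "B", "C"))
  r <- run_simulation(m, simulation_protocol(on = "A", off = "B"))
  expect_true(r$converged)
  expect_identical(r$iterations_to_converge, 2L)
  expect_identical(unname(r$final_state), c(0, 0, 0))
  expect_identical(r$mse_trajectory[2], 0)
  expect_false(r$overtraining_detected)
})

test_that("fully locked protocols are fixed points by construction", {
  m <- two_node_map()
  p <- simulation_protocol(locked_on = "A", locked_off = "B")
  r <- run_simulation(m, p)
  expect_true(r$converged)
  expect_identical(r$final_state, initial_state(m, p))
})

test_that("sparse step agrees with a naive dense oracle", {
  for (seed in 1:20) {
    m <- to_fuzzy(random_test_map(seed, n = sample(2:50, 1)))
    labs <- m$labels
    p <- simulation_protocol(locked_on = labs[1],
                             locked_off = labs[length(labs)])
    set.seed(seed * 7)
    state <- stats::setNames(stats::runif(n_nodes(m), -1, 1), labs)
    expect_equal(sim_step(state, m, p), dense_step_oracle(state, m, p),
                 tolerance = 1e-14)
  }
})

test_that("trajectories are bounded and locked nodes never move", {
  for (seed in 1:10) {
    m <- random_test_map(seed, n = 12)
    labs <- m$labels
    p <- simulation_protocol(on = labs[2], locked_on = labs[1],
                             locked_off = labs[12])
    x <- initial_state(m, p)
    fm <- to_fuzzy(m)
    for (t in 1:30) {
      x <- sim_step(x, fm, p)
      expect_true(all(x >= -1 & x <= 1))
      free <- setdiff(labs, c(labs[1], labs[12]))
      expect_true(all(abs(x[free]) < 1))
      expect_identical(unname(x[labs[1]]), 1)
      expect_identical(unname(x[labs[12]]), -1)
    }
  }
})

test_that("negating initial and clamped values negates the trajectory exactly", {
  for (seed in 1:10) {
    m <- random_test_map(seed, n = 15)
    labs <- m$labels
    p_pos <- simulation_protocol(on = labs[1], off = labs[2],
                                 locked_on = labs[3], locked_off = labs[4],
                                 max_iterations = 60)
    p_neg <- simulation_protocol(on = labs[2], off = labs[1],
                                 locked_on = labs[4], locked_off = labs[3],
                                 max_iterations = 60)
    a <- run_simulation(m, p_pos)
    b <- run_simulation(m, p_neg)
    expect_identical(a$final_state, -(b$final_state))
    expect_identical(a$mse_trajectory, b$mse_trajectory)
  }
})

test_that("identical inputs give bit-identical trajectories", {
  m <- random_test_map(99, n = 25)
  p <- simulation_protocol(on = m$labels[1:3], locked_off = m$labels[10])
  a <- run_simulation(m, p)
  b <- run_simulation(m, p)
  expect_identical(a$mse_trajectory, b$mse_trajectory)
  expect_identical(a$final_state, b$final_state)
})

test_that("converged flag is equivalent to min(MSE) < tolerance", {
  cases <- list(
    run_simulation(two_node_map(), simulation_protocol(on = "A")),
    run_simulation(two_node_map(),
                   simulation_protocol(on = "A", max_iterations = 1)),
    run_simulation(random_test_map(5, n = 10),
                   simulation_protocol(on = "N01"))
  )
  for (r in cases) {
    expect_identical(r$converged,
                     min(r$mse_trajectory) < r$protocol$tolerance)
    if (r$converged) {
      expect_identical(r$iterations_to_converge,
                       which(r$mse_trajectory < r$protocol$tolerance)[1L])
    } else {
      expect_true(is.na(r$iterations_to_converge))
    }
  }
})

test_that("single-node self-loops relax to zero, matching the scalar oracle", {
  for (w in c(0.25, 0.6, 1)) {
    m <- knowledge_map("A", data.frame(from = 1, to = 1, weight = w))
    p <- simulation_protocol(on = "A")
    r <- run_simulation(m, p)
    oracle <- scalar_fixed_point_oracle(w, 0, 1,
                                        length(r$mse_trajectory))
    expect_identical(unname(r$final_state), oracle)
    expect_lt(abs(r$final_state), 0.05)
  }
})

test_that("overtraining: false early convergence followed by MSE rebound", {
  # mutual +1/-1 pair with unit self-loops and a weak locked driver: the
  # near-zero start converges spuriously at iteration 1, then the locally
  # unstable rotation grows until squashing saturates
  m <- knowledge_map(c("A", "B", "D"), data.frame(
    from = c(1, 1, 2, 2, 3), to = c(2, 1, 1, 2, 1),
    weight = c(1, 1, -1, 1, 0.001)))
  r <- run_simulation(m, simulation_protocol(locked_on = "D"))
  expect_true(r$converged)
  expect_true(r$overtraining_detected)
  expect_gte(max(r$mse_trajectory[-seq_len(r$iterations_to_converge)]),
             r$protocol$tolerance)
  # without the overtraining check the run stops at (false) convergence
  r2 <- run_simulation(m, simulation_protocol(locked_on = "D",
                                              overtraining_check = FALSE))
  expect_identical(length(r2$mse_trajectory), r2$iterations_to_converge)
  expect_false(r2$overtraining_detected)
})

test_that("alternative activations are selectable and bounded", {
  m <- random_test_map(11, n = 8)
  for (act in c("logistic-symmetric", "hyperbolic-tangent")) {
    r <- run_simulation(m, simulation_protocol(on = m$labels[1],
                                               activation = act,
                                               max_iterations = 200))
    expect_true(all(abs(r$final_state) <= 1))
  }
})
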