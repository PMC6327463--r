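#' Elliott squashing activation
#'
#' `f(x) = x / (1 + |x|)`: odd, strictly increasing, bounded in (-1, 1).
#' It is the default activation of the simulation engine, chosen for fast,
#' reproducible relaxation to steady state; its fixed-point algebra is simple
#' enough that planted-attractor fixtures have closed-form steady values.
#'
#' @param x numeric vector, all elements finite.
#' @return `x / (1 + abs(x))`, elementwise.
#' @examples
#' elliott(c(-2, 0, 2))   # -2/3, 0, 2/3
#' @export
elliott <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_ncm("domain_error", "elliott() requires finite numeric input")
  }
  x / (1 + abs(x))
}

.activations <- list(
  "elliott" = elliott,
  "logistic-symmetric" = function(x) 2 / (1 + exp(-x)) - 1,
  "hyperbolic-tangent" = tanh
)

resolve_activation <- function(name) {
  f <- .activations[[name]]
  if (is.null(f)) {
    stop_ncm("protocol_error", "unknown activation '", name, "'; one of: ",
             paste(names(.activations), collapse = ", "))
  }
  f
}

#' Define a simulation protocol
#'
#' A protocol names the intervention: nodes turned on (+1) or off (-1) for the
#' first iteration only (transient, "not locked" — all subsequent values are
#' determined by system behaviour), and nodes locked on/off (clamped to +/-1
#' at every iteration, modelling constitutive overexpression or knockout).
#'
#' @param on,off labels set to +1 / -1 in the initial state only.
#' @param locked_on,locked_off labels clamped to +1 / -1 every iteration.
#' @param activation one of `"elliott"` (default), `"logistic-symmetric"`,
#'   `"hyperbolic-tangent"`.
#' @param tolerance convergence threshold on the mean squared error between
#'   successive states; default 0.001.
#' @param max_iterations iteration cap; default 1000.
#' @param overtraining_check if `TRUE` (default), iteration continues to
#'   `max_iterations` after first convergence and any MSE rebound at or above
#'   `tolerance` is flagged as overtraining.
#' @param seed integer, reserved for stochastic extensions; the core engine is
#'   deterministic.
#' @return an object of class `simulation_protocol`.
#' @export
simulation_protocol <- function(on = character(0), off = character(0),
                                locked_on = character(0),
                                locked_off = character(0),
                                activation = "elliott",
                                tolerance = 0.001,
                                max_iterations = 1000L,
                                overtraining_check = TRUE,
                                seed = NULL) {
  p <- structure(list(
    on = unique(as.character(on)), off = unique(as.character(off)),
    locked_on = unique(as.character(locked_on)),
    locked_off = unique(as.character(locked_off)),
    activation = activation,
    tolerance = as.numeric(tolerance),
    max_iterations = as.integer(max_iterations),
    overtraining_check = isTRUE(overtraining_check),
    seed = seed
  ), class = "simulation_protocol")
  if (!is.finite(p$tolerance) || p$tolerance <= 0) {
    stop_ncm("protocol_error", "tolerance must be > 0")
  }
  if (is.na(p$max_iterations) || p$max_iterations < 1L) {
    stop_ncm("protocol_error", "max_iterations must be >= 1")
  }
  resolve_activation(p$activation)
  sets <- list(p$on, p$off, p$locked_on, p$locked_off)
  all_lab <- unlist(sets)
  if (anyDuplicated(all_lab)) {
    stop_ncm("protocol_error", "node appears in more than one protocol set: ",
             paste(unique(all_lab[duplicated(all_lab)]), collapse = ", "))
  }
  p
}

#' @rdname simulation_protocol
#' @param protocol a `simulation_protocol`.
#' @param map a [knowledge_map] the protocol must refer to.
#' @export
validate_protocol <- function(protocol, map) {
  stopifnot(inherits(protocol, "simulation_protocol"),
            inherits(map, "knowledge_map"))
  named <- c(protocol$on, protocol$off, protocol$locked_on,
             protocol$locked_off)
  missing <- setdiff(named, map$labels)
  if (length(missing)) {
    stop_ncm("protocol_error", "protocol names unknown concept(s): ",
             paste(missing, collapse = ", "))
  }
  invisible(protocol)
}

#' @export
print.simulation_protocol <- function(x, ...) {
  fmt <- function(s) if (length(s)) paste(s, collapse = ", ") else "-"
  cat("simulation_protocol\n",
      "  on:         ", fmt(x$on), "\n",
      "  off:        ", fmt(x$off), "\n",
      "  locked_on:  ", fmt(x$locked_on), "\n",
      "  locked_off: ", fmt(x$locked_off), "\n",
      sprintf("  activation: %s, tolerance %g, max %d iterations%s\n",
              x$activation, x$tolerance, x$max_iterations,
              if (x$overtraining_check) ", overtraining check" else ""),
      sep = "")
  invisible(x)
}

#' Initial state vector for a protocol
#'
#' All components zero except `on`/`locked_on` nodes (+1) and
#' `off`/`locked_off` nodes (-1).
#'
#' @inheritParams validate_protocol
#' @return a named numeric vector of length `n_nodes(map)`.
#' @export
initial_state <- function(map, protocol) {
  validate_protocol(protocol, map)
  x <- stats::setNames(numeric(n_nodes(map)), map$labels)
  x[protocol$on] <- 1
  x[protocol$locked_on] <- 1
  x[protocol$off] <- -1
  x[protocol$locked_off] <- -1
  x
}

# weight matrix of a fuzzified map, as dgCMatrix so the per-iteration cost is
# proportional to the stored-edge count rather than N^2
as_weight_matrix <- function(map) {
  if (anyNA(map$edges$weight)) {
    stop_ncm("indeterminate_error",
             "map contains indeterminate edges; apply to_fuzzy() first")
  }
  n <- n_nodes(map)
  Matrix::sparseMatrix(i = map$edges$from, j = map$edges$to,
                       x = map$edges$weight, dims = c(n, n))
}

#' One synchronous update of the state vector
#'
#' Computes `raw_j = sum_i W[i, j] * state_i` by sparse vector-matrix
#' multiplication, squashes through the protocol's activation, then applies
#' the clamps (`locked_on` to +1, `locked_off` to -1). There is no implicit
#' self-memory term: a node's next value depends only on its weighted inputs,
#' so persistence must be wired as an explicit self-loop.
#'
#' @param state named numeric state vector of length `n_nodes(map)`.
#' @inheritParams validate_protocol
#' @return the next state vector (the input is not modified).
#' @export
sim_step <- function(state, map, protocol) {
  if (length(state) != n_nodes(map)) {
    stop_ncm("format_error", sprintf(
      "state length %d does not match map size %d",
      length(state), n_nodes(map)))
  }
  validate_protocol(protocol, map)
  W <- as_weight_matrix(map)
  act <- resolve_activation(protocol$activation)
  new <- act(as.numeric(Matrix::crossprod(W, state)))
  names(new) <- map$labels
  new[protocol$locked_on] <- 1
  new[protocol$locked_off] <- -1
  new
}

#' Mean squared error between two state vectors
#'
#' @param a,b numeric vectors of equal positive length.
#' @return `mean((a - b)^2)`.
#' @export
mse <- function(a, b) {
  if (length(a) != length(b)) {
    stop_ncm("format_error", "state vectors differ in length")
  }
  if (length(a) == 0L) {
    stop_ncm("domain_error", "MSE of zero-length vectors is undefined")
  }
  mean((a - b)^2)
}

#' Iterate a knowledge map to steady state
#'
#' Runs the synchronous update of [sim_step()] from [initial_state()],
#' recording after each iteration the MSE between the new and previous state.
#' The system has converged at the first iteration whose MSE falls below
#' `protocol$tolerance`. If `overtraining_check` is `TRUE`, iteration
#' continues to `max_iterations` and any later MSE at or above the tolerance
#' is flagged as overtraining (evidence the apparent steady state was not
#' stable); otherwise iteration stops at first convergence.
#'
#' The reported `final_state` is the state when iteration stopped: at first
#' convergence when `overtraining_check = FALSE`, and after the full run
#' otherwise (the fully relaxed state, which pins slow attractors far more
#' accurately than the first tolerance crossing).
#'
#' Indeterminate edges are resolved with [to_fuzzy()] before iterating.
#'
#' @inheritParams validate_protocol
#' @return an object of class `simulation_result`: list with `final_state`
#'   (named numeric), `iterations_to_converge` (1-based index of the first
#'   converging iteration, or `NA`), `mse_trajectory`, `converged`,
#'   `overtraining_detected`, and the `protocol` used.
#' @export
run_simulation <- function(map, protocol) {
  validate_protocol(protocol, map)
  if (n_nodes(map) == 0L) {
    stop_ncm("domain_error", "cannot simulate an empty map")
  }
  fmap <- to_fuzzy(map)
  W <- as_weight_matrix(fmap)
  act <- resolve_activation(protocol$activation)
  lon <- match(protocol$locked_on, map$labels)
  loff <- match(protocol$locked_off, map$labels)
  x <- unname(initial_state(map, protocol))
  traj <- numeric(protocol$max_iterations)
  conv_at <- NA_integer_
  n_done <- 0L
  for (t in seq_len(protocol$max_iterations)) {
    new <- act(as.numeric(Matrix::crossprod(W, x)))
    new[lon] <- 1
    new[loff] <- -1
    traj[t] <- mean((new - x)^2)
    x <- new
    n_done <- t
    if (is.na(conv_at) && traj[t] < protocol$tolerance) {
      conv_at <- t
      if (!protocol$overtraining_check) break
    }
  }
  traj <- traj[seq_len(n_done)]
  converged <- !is.na(conv_at)
  overtraining <- converged && conv_at < n_done &&
    any(traj[(conv_at + 1L):n_done] >= protocol$tolerance)
  structure(list(
    final_state = stats::setNames(x, map$labels),
    iterations_to_converge = conv_at,
    mse_trajectory = traj,
    converged = converged,
    overtraining_detected = overtraining,
    protocol = protocol
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("converged at iteration %d (MSE %.3g < %g)%s\n",
                x$iterations_to_converge,
                x$mse_trajectory[x$iterations_to_converge],
                x$protocol$tolerance,
                if (x$overtraining_detected) "; OVERTRAINING detected"
                else ", no overtraining"))
  } else {
    cat(sprintf("did NOT converge within %d iterations (last MSE %.3g)\n",
                length(x$mse_trajectory),
                x$mse_trajectory[length(x$mse_trajectory)]))
  }
  invisible(x)
}
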