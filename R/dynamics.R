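#' One synchronous network update
#'
#' `u' = tanh(W u + r * eta)` with independent standard-normal noise per
#' neuron. With `noise = 0` the update is deterministic and consumes no
#' random numbers.
#'
#' @param u current state vector in `[-1, 1]^n`.
#' @param weights a `weight_matrix` or a plain numeric matrix.
#' @param noise noise strength r (>= 0).
#' @return the next state vector, componentwise in `(-1, 1)`.
#' @export
step_state <- function(u, weights, noise = 0) {
  w <- if (inherits(weights, "weight_matrix")) as.matrix(weights) else weights
  if (length(u) != nrow(w)) stop("state length does not match network size")
  a <- as.vector(w %*% u)
  if (noise > 0) a <- a + noise * rnorm(length(u))
  tanh(a)
}

#' Binarize continuous states
#'
#' Thresholds at zero: `u > 0` maps to 1, `u <= 0` (ties included) to 0.
#'
#' @param u numeric vector or matrix of continuous states.
#' @return integer vector/matrix of 0/1 values with the same shape.
#' @export
binarize <- function(u) {
  s <- (u > 0) + 0L
  if (is.matrix(u)) dim(s) <- dim(u)
  s
}

#' Encode binary states as integers
#'
#' Standard binary-to-decimal encoding with neuron 1 as the least
#' significant bit: `z = sum_k s_k 2^(k-1)`, so the all-zeros state is 0 and
#' the all-ones state of m neurons is `2^m - 1`.
#'
#' @param s 0/1 vector, or a matrix with one state per row.
#' @return integer code(s) in `[0, 2^m)`.
#' @export
encode_states <- function(s) {
  if (!all(s %in% c(0L, 1L))) stop("states must be binary (0/1)")
  if (is.matrix(s)) {
    m <- ncol(s)
    if (m > 30) stop("alphabet exceeds integer range (m > 30)")
    as.integer(s %*% 2^(seq_len(m) - 1))
  } else {
    m <- length(s)
    if (m > 30) stop("alphabet exceeds integer range (m > 30)")
    as.integer(sum(s * 2^(seq_len(m) - 1)))
  }
}

#' Decode integer state codes back to binary vectors
#'
#' @param z integer code(s) in `[0, 2^m)`.
#' @param m number of neurons.
#' @return a 0/1 matrix with one state per row (or a vector for scalar `z`).
#' @export
decode_state <- function(z, m) {
  out <- vapply(seq_len(m), function(k) bitwAnd(bitwShiftR(as.integer(z), k - 1L), 1L),
                integer(length(z)))
  if (length(z) == 1L) as.integer(out) else matrix(out, nrow = length(z))
}

#' Simulate the stochastic recurrent network
#'
#' Runs `steps` synchronous updates of `u_{t+1} = tanh(W u_t + r eta_t)`
#' from the initial state and records every post-update step (no burn-in is
#' discarded). The run is bit-reproducible from the seed; with `noise = 0`
#' the trajectory is deterministic given the initial state.
#'
#' @param weights a `weight_matrix` (its scale W applies) or numeric matrix.
#' @param steps number of recorded steps T (>= 1).
#' @param noise noise strength r (>= 0).
#' @param seed integer seed; controls the initial state draw and the noise.
#' @param init `"uniform"` (default: u0 drawn uniformly on `[-1,1]^n`, since
#'   the zero state is a deterministic fixed point at r = 0), `"zero"`, or
#'   an explicit numeric vector.
#' @return an object of class `trajectory` with fields `continuous`
#'   (T x n), `binary` (T x n), `encoded` (length T, codes in `[0, 2^n)`),
#'   `initial`, `noise`, `seed`.
#' @export
simulate_network <- function(weights, steps, noise = 0, seed = NULL,
                             init = "uniform") {
  w <- if (inherits(weights, "weight_matrix")) as.matrix(weights) else weights
  n <- nrow(w)
  if (!is.null(seed)) set.seed(seed)
  u0 <- if (is.numeric(init)) {
    if (length(init) != n) stop("initial state length does not match n")
    init
  } else if (identical(init, "zero")) {
    rep(0, n)
  } else if (identical(init, "uniform")) {
    runif(n, -1, 1)
  } else stop("init must be 'uniform', 'zero' or a numeric vector")
  cont <- simulate_tanh_cpp(w, as.integer(steps), noise, u0)
  bin <- binarize(cont)
  structure(list(continuous = cont, binary = bin,
                 encoded = encode_states(bin), n = n,
                 steps = as.integer(steps), noise = noise, seed = seed,
                 initial = u0),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: n=%d, T=%d, r=%g, %d distinct encoded states\n",
              x$n, x$steps, x$noise, length(unique(x$encoded))))
  invisible(x)
}

#' Subsample a trajectory for raster display
#'
#' Keeps the binary states at times 1, 1 + interval, 1 + 2*interval, ...
#' (so `interval = 1` is the identity and an interval exceeding T leaves a
#' single row).
#'
#' @param traj a `trajectory` (or a binary matrix).
#' @param interval sampling interval (>= 1).
#' @return binary matrix of the retained rows.
#' @export
raster <- function(traj, interval = 1) {
  if (interval < 1) stop("interval must be >= 1")
  b <- if (inherits(traj, "trajectory")) traj$binary else traj
  b[seq(1, nrow(b), by = interval), , drop = FALSE]
}

#' Write a trajectory as delimited text
#'
#' Writes the encoded state series (one integer per line) and optionally the
#' full binary state matrix alongside it.
#'
#' @param traj a `trajectory`.
#' @param path output file for the encoded series.
#' @param binary_path optional CSV path for the T x n binary matrix.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, binary_path = NULL) {
  writeLines(as.character(traj$encoded), path)
  if (!is.null(binary_path)) {
    utils::write.table(traj$binary, binary_path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Encoded series of a subsystem
#'
#' Restricts a trajectory to a subset of neurons and encodes the resulting
#' binary states; subsystem observables are always computed from the global
#' trajectory's columns, never from a separate simulation.
#'
#' @param traj a `trajectory`.
#' @param neurons integer indices of the subsystem's neurons.
#' @return integer vector of length T with codes in `[0, 2^m)`.
#' @export
subsystem_series <- function(traj, neurons) {
  encode_states(traj$binary[, neurons, drop = FALSE])
}
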