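#' Empirical state transition matrix
#'
#' Counts transitions between consecutive encoded states and normalises each
#' visited row to a conditional distribution `T_xy = N_xy / sum_k N_xk`.
#' Rows of states never visited (zero row sums) are left all-zero and
#' flagged rather than uniform-filled: the normalisation would divide by
#' zero and a uniform fill would fabricate transitions.
#'
#' The marginal `P_x` is the row mass `sum_y N_xy / sum N`, the visitation
#' gain is `G(x) = P_x * 2^m` (ratio to the uniform baseline
#' `P_uni = 1 / 2^m`), and the baseline stability is the arithmetic mean of
#' the diagonal `T_xx` over visited states (unvisited diagonals are
#' undefined).
#'
#' @param encoded integer state series with codes in `[0, 2^m)`, length >= 2.
#' @param m number of observed neurons (state space size `2^m`).
#' @return an object of class `transition_model` with fields `counts`,
#'   `stm`, `marginal`, `gain`, `diag`, `baseline`, `visited`, `m`.
#' @export
build_stm <- function(encoded, m) {
  z <- .check_symbols(encoded)
  if (length(z) < 2) stop("need at least two time steps")
  K <- 2L^as.integer(m)
  if (max(z) >= K) stop("symbol out of range for 2^m states")
  x <- z[-length(z)]; y <- z[-1]
  counts <- matrix(tabulate(y * K + x + 1, nbins = K * K), nrow = K)
  # column-major fill: counts[x+1, y+1] = N_xy
  rs <- rowSums(counts)
  visited <- rs > 0
  stm <- counts / ifelse(rs > 0, rs, 1)
  marginal <- rs / sum(rs)
  d <- diag(stm)
  structure(list(counts = counts, stm = stm, marginal = marginal,
                 gain = marginal * K, diag = d,
                 baseline = mean(d[visited]), visited = visited,
                 m = as.integer(m)),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("transition_model: %d states (m=%d), %d visited, baseline Txx=%.4f\n",
              length(x$marginal), x$m, sum(x$visited), x$baseline))
  invisible(x)
}

#' Visitation gain
#'
#' `G(x) = P_x / P_uni = P_x * 2^m`. Averaged over the whole state space the
#' gain is exactly 1.
#'
#' @param model a `transition_model`.
#' @return numeric vector of per-state gains.
#' @export
gain <- function(model) model$gain

#' Classify states into strong / weak attractors and transient noise
#'
#' Hierarchical operational rule on the gain and the diagonal stability:
#' states at or below the uniform-randomness floor (`G <= g_transient`) are
#' transient noise; states with substantial visitation (`G > g_strong`) and
#' high diagonal stability (`T_xx > stability_factor * baseline`) are strong
#' attractors; every remaining state above the noise floor is a weak
#' attractor. Weak attractors subdivide by stability: `high_stability`
#' (at or above the baseline: deep but rarely entered local traps) versus
#' `structural_hub` (below the baseline: frequently traversed, shallow
#' states that knit the landscape together).
#'
#' @param model a `transition_model`.
#' @param g_transient transient-noise gain threshold (default 1).
#' @param g_strong strong-attractor gain threshold (default 2).
#' @param stability_factor multiple of the baseline diagonal required of a
#'   strong attractor (default 1.5).
#' @param visited_only classify only states with `P_x > 0` (default); set
#'   `FALSE` to include never-visited states (all transient by definition).
#' @return data frame with columns `state`, `P`, `G`, `Txx`, `label`
#'   (`strong` / `weak` / `transient`) and `subtype` (`high_stability` /
#'   `structural_hub` for weak attractors, `NA` otherwise); the thresholds
#'   used are attached as attributes.
#' @export
classify_attractors <- function(model, g_transient = 1, g_strong = 2,
                                stability_factor = 1.5,
                                visited_only = TRUE) {
  keep <- if (visited_only) which(model$visited) else
    seq_along(model$marginal)
  G <- model$gain[keep]
  Txx <- model$diag[keep]
  label <- ifelse(G <= g_transient, "transient",
                  ifelse(G > g_strong & Txx > stability_factor * model$baseline,
                         "strong", "weak"))
  subtype <- ifelse(label == "weak",
                    ifelse(Txx >= model$baseline, "high_stability",
                           "structural_hub"), NA_character_)
  out <- data.frame(state = keep - 1L, P = model$marginal[keep], G = G,
                    Txx = Txx, label = label, subtype = subtype,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(g_transient = g_transient,
                               g_strong = g_strong,
                               stability_factor = stability_factor,
                               baseline = model$baseline)
  out
}

#' Hopfield-type energy of a binary state
#'
#' `E(s) = -1/2 sum_{i != j} w_ij s_i s_j` with `s in {0,1}^n`; self-terms
#' are excluded, so the energy is invariant to the diagonal of the weight
#' matrix. The effective (scaled) weights are used.
#'
#' @param s 0/1 state vector.
#' @param weights a `weight_matrix` or numeric matrix.
#' @return energy value.
#' @export
state_energy <- function(s, weights) {
  w <- if (inherits(weights, "weight_matrix")) as.matrix(weights) else weights
  if (length(s) != nrow(w)) stop("state length does not match network size")
  if (!all(s %in% c(0, 1))) stop("state must be binary (0/1)")
  w0 <- w
  diag(w0) <- 0
  -0.5 * as.numeric(t(s) %*% w0 %*% s)
}

#' Exhaustive energy landscape and its strict local minima
#'
#' Enumerates all `2^n` binary states, computes the energy of each, and
#' finds the strict local minima over one-bit (Hamming-1) neighbourhoods.
#' For each minimum the escape barrier is reported as the smallest energy
#' excess among its neighbours.
#'
#' @param weights a `weight_matrix` or numeric matrix with `n <= 20`.
#' @return an object of class `energy_landscape`: `energy` (length `2^n`,
#'   indexed by encoded state + 1), `minima` (encoded states), `barrier`
#'   (named by minimum).
#' @export
energy_landscape <- function(weights) {
  w <- if (inherits(weights, "weight_matrix")) as.matrix(weights) else weights
  n <- nrow(w)
  if (n > 20) stop("state space too large for enumeration (n > 20)")
  w0 <- w
  diag(w0) <- 0
  idx <- 0:(2^n - 1)
  S <- decode_state(idx, n)
  E <- -0.5 * rowSums((S %*% w0) * S)
  strict <- rep(TRUE, length(idx))
  excess <- rep(Inf, length(idx))
  for (k in seq_len(n)) {
    nb <- bitwXor(idx, bitwShiftL(1L, k - 1L))
    strict <- strict & (E < E[nb + 1])
    excess <- pmin(excess, E[nb + 1] - E)
  }
  minima <- idx[strict]
  structure(list(energy = E, minima = minima,
                 barrier = stats::setNames(excess[strict], minima), n = n),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("energy_landscape: n=%d, %d strict local minima\n",
              x$n, length(x$minima)))
  invisible(x)
}

#' Export a transition model as CSV
#'
#' Writes the dense row-stochastic matrix plus a per-state table of
#' marginals, gains and diagonal stabilities.
#'
#' @param model a `transition_model`.
#' @param path CSV path for the matrix.
#' @param states_path optional CSV path for the per-state table.
#' @return `path`, invisibly.
#' @export
write_stm <- function(model, path, states_path = NULL) {
  write.csv(model$stm, path, row.names = FALSE)
  if (!is.null(states_path)) {
    write.csv(data.frame(state = seq_along(model$marginal) - 1L,
                         P = model$marginal, G = model$gain,
                         Txx = model$diag, visited = model$visited),
              states_path, row.names = FALSE)
  }
  invisible(path)
}
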