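# Independent oracles, deliberately written as naive direct translations of
# the defining formulas (loops, list-based set algebra), kept separate from
# the package's vectorised/bitmask implementations.

# Closure operator by literal set manipulation: r*(F) collects columns
# related to members of F; R*(G) drops rows related to any column outside G.
oracle_closure <- function(F, rel) {
  inc <- rel$incidence
  G <- character(0)
  for (f in F) {
    fi <- match(f, rel$u1)
    for (gj in seq_along(rel$u2)) if (inc[fi, gj]) G <- union(G, rel$u2[gj])
  }
  out <- character(0)
  for (fi in seq_along(rel$u1)) {
    related_outside <- FALSE
    for (gj in seq_along(rel$u2)) {
      if (inc[fi, gj] && !(rel$u2[gj] %in% G)) related_outside <- TRUE
    }
    if (!related_outside) out <- c(out, rel$u1[fi])
  }
  out
}

# All closure fixed points by subset enumeration over the label list.
oracle_lattice_elements <- function(rel) {
  n <- length(rel$u1)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    F <- rel$u1[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L]
    if (setequal(oracle_closure(F, rel), F)) out[[length(out) + 1L]] <- sort(F)
  }
  out
}

# Plugin entropy by direct summation over the empirical distribution.
oracle_entropy <- function(x) {
  p <- as.vector(table(x)) / length(x)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  as.numeric(h)
}

# Plugin mutual information by direct summation over the joint table.
oracle_mi <- function(x, y) {
  jt <- table(factor(x), factor(y)) / length(x)
  px <- rowSums(jt); py <- colSums(jt)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (jt[i, j] > 0) s <- s + jt[i, j] * log2(jt[i, j] / (px[i] * py[j]))
  }
  as.numeric(s)
}

# Plugin transfer entropy by direct summation over the (b', b, a) joint.
oracle_te <- function(a, b) {
  T1 <- length(b) - 1
  b1 <- b[-1]; b0 <- b[-length(b)]; a0 <- a[-length(a)]
  jt <- table(factor(b1), factor(b0), factor(a0)) / T1
  p_ba <- apply(jt, c(2, 3), sum)   # P(b, a)
  p_bb <- apply(jt, c(1, 2), sum)   # P(b', b)
  p_b <- apply(jt, 2, sum)          # P(b)
  s <- 0
  d <- dim(jt)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (jt[i, j, k] > 0) {
      cond_full <- jt[i, j, k] / p_ba[j, k]
      cond_self <- p_bb[i, j] / p_b[j]
      s <- s + jt[i, j, k] * log2(cond_full / cond_self)
    }
  }
  as.numeric(s)
}

# Strict Hamming-1 local minima of the pair energy by brute force.
oracle_minima <- function(w) {
  n <- nrow(w)
  w0 <- w; diag(w0) <- 0
  energy <- function(s) -0.5 * sum(w0 * outer(s, s))
  minima <- integer(0)
  for (z in 0:(2^n - 1)) {
    s <- as.integer(bitwAnd(bitwShiftR(z, 0:(n - 1)), 1L))
    e <- energy(s)
    strict <- TRUE
    for (k in seq_len(n)) {
      s2 <- s; s2[k] <- 1L - s2[k]
      if (energy(s2) <= e) strict <- FALSE
    }
    if (strict) minima <- c(minima, z)
  }
  minima
}

# Random binary relation on labelled universes of size n.
random_relation <- function(n, density = 0.4) {
  inc <- matrix(runif(n * n) < density, n, n)
  binary_relation(paste0("R", seq_len(n)), paste0("c", seq_len(n)), inc)
}
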