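# Plugin (maximum-likelihood) estimators on integer symbol series.
# No bias correction is applied anywhere: the elevated mutual-information
# floor of large state spaces at finite T is a plugin artifact that the
# analysis relies on reproducing as such. Logarithms are base 2; empty
# cells are skipped (0 log 0 := 0).

.check_symbols <- function(x) {
  if (!length(x)) stop("empty symbol series")
  x <- as.integer(x)
  if (anyNA(x) || min(x) < 0) stop("symbols must be non-negative integers")
  x
}

.entropy_counts <- function(counts, total) {
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

# entropy of an integer code vector via dense tabulation
.H <- function(code) {
  .entropy_counts(tabulate(code + 1, nbins = max(code) + 1), length(code))
}

#' Plugin entropy of a symbol series
#'
#' `H(X) = -sum_x p(x) log2 p(x)` with probabilities estimated as empirical
#' frequencies. For a series over an alphabet of size `2^m` the result lies
#' in `[0, m]` bits.
#'
#' @param x integer symbol series (non-negative codes).
#' @return entropy in bits.
#' @export
entropy_plugin <- function(x) {
  .H(.check_symbols(x))
}

#' Plugin mutual information between two symbol series
#'
#' `I(X;Y) = sum p(x,y) log2( p(x,y) / (p(x) p(y)) )`, estimated from the
#' empirical joint of paired samples; equals `H(X) + H(Y) - H(X,Y)` and is
#' non-negative, bounded by `min(H(X), H(Y))`.
#'
#' @param x,y integer symbol series of equal length.
#' @return mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  x <- .check_symbols(x); y <- .check_symbols(y)
  if (length(x) != length(y)) stop("series lengths differ")
  ky <- max(y) + 1
  if ((max(x) + 1) * as.double(ky) > 2^31 - 1) stop("joint alphabet too large")
  .H(x) + .H(y) - .H(x * ky + y)
}

#' Temporal mutual information of a state sequence
#'
#' Mutual information between the encoded state at time t and at time t+1,
#' estimated from the T-1 consecutive pairs `(z_t, z_{t+1})`. This is the
#' quantity whose interior maximum over noise strength (with entropy still
#' rising) signals recurrence resonance.
#'
#' @param z integer encoded state series, length >= 2.
#' @return mutual information in bits.
#' @export
temporal_mi <- function(z) {
  z <- .check_symbols(z)
  if (length(z) < 2) stop("need at least two time steps")
  mutual_information(z[-length(z)], z[-1])
}

#' Plugin transfer entropy between subsystems
#'
#' First-order transfer entropy from a source series A to a target series B:
#' `TE = sum p(b', b, a) log2( p(b' | b, a) / p(b' | b) )`, estimated from
#' the empirical joint of `(target_{t+1}, target_t, source_t)`. Computed via
#' the entropy identity `TE = H(B', B) + H(B, A) - H(B', B, A) - H(B)`.
#'
#' @param source,target integer symbol series of equal length T >= 2.
#' @return transfer entropy in bits (non-negative up to floating error).
#' @export
transfer_entropy <- function(source, target) {
  a <- .check_symbols(source); b <- .check_symbols(target)
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(b) < 2) stop("need at least two time steps")
  T1 <- length(b) - 1
  b1 <- b[-1]; b0 <- b[-length(b)]; a0 <- a[-length(a)]
  ka <- max(a0) + 1; kb <- max(c(b0, b1)) + 1
  if (as.double(kb) * kb * ka > 2^31 - 1) stop("joint alphabet too large")
  .H(b1 * kb + b0) + .H(b0 * ka + a0) - .H((b1 * kb + b0) * ka + a0) - .H(b0)
}

#' Default noise-strength grid
#'
#' Fine resolution (step 0.2) over the resonance region 0–3, plus sparse
#' points out to r = 18 where the dynamics are noise-dominated.
#'
#' @return numeric vector of noise strengths.
#' @export
default_noise_grid <- function() c(seq(0, 3, by = 0.2), 4, 6, 9, 12, 18)

#' Ensemble noise scan
#'
#' For each trial, one weight matrix is drawn from the trial seed and held
#' fixed across the whole noise grid (the protocol varies noise on a fixed
#' connectivity); each (trial, r) cell is an independent simulation. Global
#' entropy and temporal mutual information are always computed; optional
#' subsystem observables and transfer entropy are computed from the same
#' global trajectory's columns.
#'
#' @param spec a `condition_spec` (see [network_condition()]).
#' @param W weight scaling factor.
#' @param grid noise strengths.
#' @param trials number of independent trials (fresh seeds).
#' @param steps simulation length T per run.
#' @param subsystems optional named list of neuron index vectors, e.g.
#'   `list(A = 1:5, B = 6:10)`; adds per-subsystem entropy/MI.
#' @param te optional character pair naming source and target subsystems,
#'   e.g. `c("A", "B")`; adds the observable `TE_A_B`.
#' @param seed master seed; all trial and run seeds derive from it.
#' @param redraw_weights draw a fresh weight matrix for every grid point
#'   instead of one per trial.
#' @return an object of class `scan_result`: `data` (long data frame with
#'   columns condition, W, r, trial, observable, value), `summary` (mean and
#'   sd per r and observable), plus the scan settings.
#' @export
noise_scan <- function(spec, W = 1, grid = default_noise_grid(), trials = 20,
                       steps = 20000, subsystems = NULL, te = NULL,
                       seed = 1L, redraw_weights = FALSE) {
  if (trials < 1) stop("trials must be >= 1")
  if (!length(grid)) stop("empty noise grid")
  if (!is.null(te)) {
    if (length(te) != 2 || !all(te %in% names(subsystems))) {
      stop("te must name two entries of subsystems")
    }
  }
  grid <- sort(grid)
  seeds <- derive_seeds(seed, trials * (length(grid) + 1))
  trial_seeds <- seeds[seq_len(trials)]
  run_seeds <- matrix(seeds[-seq_len(trials)], nrow = trials)
  rows <- vector("list", trials * length(grid))
  k <- 0L
  for (t in seq_len(trials)) {
    wm <- scale_weights(build_weight_matrix(spec, seed = trial_seeds[t]), W)
    for (g in seq_along(grid)) {
      if (redraw_weights && g > 1) {
        wm <- scale_weights(build_weight_matrix(spec, seed = run_seeds[t, g]), W)
      }
      traj <- simulate_network(wm, steps, grid[g], seed = run_seeds[t, g])
      vals <- c(H_global = entropy_plugin(traj$encoded),
                MI_global = temporal_mi(traj$encoded))
      if (!is.null(subsystems)) {
        for (nm in names(subsystems)) {
          zs <- subsystem_series(traj, subsystems[[nm]])
          vals[paste0("H_", nm)] <- entropy_plugin(zs)
          vals[paste0("MI_", nm)] <- temporal_mi(zs)
        }
        if (!is.null(te)) {
          vals[paste("TE", te[1], te[2], sep = "_")] <- transfer_entropy(
            subsystem_series(traj, subsystems[[te[1]]]),
            subsystem_series(traj, subsystems[[te[2]]]))
        }
      }
      k <- k + 1L
      rows[[k]] <- data.frame(condition = spec$name, W = W, r = grid[g],
                              trial = t, observable = names(vals),
                              value = unname(vals),
                              stringsAsFactors = FALSE)
    }
  }
  data <- do.call(rbind, rows)
  summary <- aggregate(value ~ r + observable, data, function(v) {
    c(mean = mean(v), sd = sd(v))
  })
  summary <- data.frame(r = summary$r, observable = summary$observable,
                        mean = summary$value[, "mean"],
                        sd = summary$value[, "sd"],
                        stringsAsFactors = FALSE)
  summary$sd[is.na(summary$sd)] <- 0
  summary <- summary[order(summary$observable, summary$r), ]
  rownames(summary) <- NULL
  structure(list(data = data, summary = summary, grid = grid,
                 trials = trials, steps = steps, W = W,
                 condition = spec$name, subsystems = subsystems,
                 seed = seed),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: %s, W=%g, %d noise levels x %d trials, T=%d\n",
              x$condition, x$W, length(x$grid), x$trials, x$steps))
  cat("  observables:", paste(unique(x$summary$observable), collapse = ", "),
      "\n")
  invisible(x)
}

#' Locate the resonance peak of a scan
#'
#' Argmax of the trial-mean curve of an observable over the noise grid; ties
#' are broken toward the smaller noise strength.
#'
#' @param scan a `scan_result`.
#' @param observable observable name (default the global temporal MI).
#' @return list with `r` (peak noise strength), `value` (peak mean) and `sd`
#'   (trial SD at the peak).
#' @export
find_peak <- function(scan, observable = "MI_global") {
  s <- scan$summary[scan$summary$observable == observable, ]
  if (!nrow(s)) stop("observable not present in scan: ", observable)
  s <- s[order(s$r), ]
  i <- which.max(s$mean)
  list(r = s$r[i], value = s$mean[i], sd = s$sd[i])
}

#' Per-trial values at the ensemble peak
#'
#' Extracts each trial's value of an observable at the single grid point
#' that maximises the ensemble-mean curve, so all trials are compared at one
#' common noise strength.
#'
#' @param scan a `scan_result`.
#' @param observable observable name.
#' @return numeric vector of length `trials`.
#' @export
peak_trial_values <- function(scan, observable = "MI_global") {
  pk <- find_peak(scan, observable)
  d <- scan$data[scan$data$observable == observable & scan$data$r == pk$r, ]
  d$value[order(d$trial)]
}

#' Export a scan as tidy CSV
#'
#' Writes the long per-trial table and (optionally) the mean/SD summary.
#'
#' @param scan a `scan_result`.
#' @param path CSV path for the long table.
#' @param summary_path optional CSV path for the summary table.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, summary_path = NULL) {
  write.csv(scan$data, path, row.names = FALSE)
  if (!is.null(summary_path)) write.csv(scan$summary, summary_path,
                                        row.names = FALSE)
  invisible(path)
}
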