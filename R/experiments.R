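# End-to-end protocols: named, fully serialisable descriptions of the
# study's experiments, and the statistics used to compare conditions.

.SUBSYS_10 <- list(A = 1:5, B = 6:10)

#' Named experiment protocols
#'
#' Each protocol bundles a connectivity condition with the weight scaling
#' factors, simulation length, trial count, noise grid and observables used
#' by the corresponding experiment:
#' \describe{
#'   \item{`"rr5_excitatory"`, `"rr5_inhibitory"`, `"diag5_excitatory"`,
#'     `"diag5_inhibitory"`}{five-neuron resonance scans, T = 20,000,
#'     W in 1, 2, 5, 10, global entropy/MI.}
#'   \item{`"rr10_global"`, `"rr10_diagonal"`, `"rr10_broken"`}{ten-neuron
#'     scans, T = 100,000 for global observables, with the subsystem
#'     partition A = neurons 1–5, B = neurons 6–10 (subsystem scans use
#'     T = 20,000, sufficient for ergodic sampling of 32 states).}
#'   \item{`"te_comparison"`}{transfer entropy A -> B for the quantum-logic,
#'     diagonal and broken conditions at W = 1 and W = 2 over a 0–6 noise
#'     grid, T = 100,000, 20 trials.}
#' }
#'
#' @param name protocol name.
#' @param seed master seed stored in the protocol.
#' @return a list of class `protocol`.
#' @export
rr_protocol <- function(name = c("rr5_excitatory", "rr5_inhibitory",
                                 "diag5_excitatory", "diag5_inhibitory",
                                 "rr10_global", "rr10_diagonal",
                                 "rr10_broken", "te_comparison"),
                        seed = 1L) {
  name <- match.arg(name)
  base5 <- list(W = c(1, 2, 5, 10), steps = 20000, trials = 20,
                grid = default_noise_grid(), subsystems = NULL, te = NULL)
  base10 <- list(W = c(1, 2, 5, 10), steps = 100000, trials = 20,
                 grid = default_noise_grid(), subsystems = .SUBSYS_10,
                 subsystem_steps = 20000, te = NULL)
  p <- switch(name,
    rr5_excitatory = c(list(condition = "ql5_exc"), base5),
    rr5_inhibitory = c(list(condition = "ql5_inh"), base5),
    diag5_excitatory = c(list(condition = "diag5_exc"), base5),
    diag5_inhibitory = c(list(condition = "diag5_inh"), base5),
    rr10_global = c(list(condition = "ql10_inh"), base10),
    rr10_diagonal = c(list(condition = "diag10"), base10),
    rr10_broken = c(list(condition = "broken10"), base10),
    te_comparison = list(condition = c("ql10_inh", "diag10", "broken10"),
                         W = c(1, 2), steps = 100000, trials = 20,
                         grid = seq(0, 6, by = 0.5),
                         subsystems = .SUBSYS_10, te = c("A", "B"))
  )
  structure(c(list(name = name, seed = seed), p), class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("protocol %s: condition(s) %s, W = %s, T = %d, %d trials\n",
              x$name, paste(x$condition, collapse = "/"),
              paste(x$W, collapse = ","), x$steps, x$trials))
  invisible(x)
}

#' Run a protocol end to end
#'
#' Executes the protocol's scans (one per condition and W), locates the
#' resonance peak, and — for single-condition protocols — rebuilds the
#' state transition model, attractor classification and raster matrices of
#' one representative trial at the peak noise strength. All randomness
#' derives from the protocol seed, so the bundle replays identically.
#'
#' @param p a `protocol` (or a name accepted by [rr_protocol()]).
#' @param dir optional output directory; when given, tidy CSV tables and a
#'   JSON manifest are written.
#' @param seed overrides the protocol seed.
#' @return a list of class `protocol_bundle` with `scans` (per condition/W),
#'   `peaks`, and for single-condition protocols `stm`, `classification`,
#'   `raster_fine`, `raster_coarse`; for `te_comparison`, `peak_te` (per
#'   trial) and `stats` (see [compare_conditions()]).
#' @export
run_protocol <- function(p, dir = NULL, seed = NULL) {
  if (is.character(p)) p <- rr_protocol(p)
  seed <- seed %||% p$seed
  seeds <- derive_seeds(seed, length(p$condition) * length(p$W) + 1L)
  scans <- list()
  peaks <- list()
  k <- 0L
  for (cond in p$condition) {
    for (W in p$W) {
      k <- k + 1L
      id <- sprintf("%s_W%g", cond, W)
      scans[[id]] <- noise_scan(network_condition(cond), W = W,
                                grid = p$grid, trials = p$trials,
                                steps = p$steps, subsystems = p$subsystems,
                                te = p$te, seed = seeds[k])
      obs <- if (!is.null(p$te)) paste("TE", p$te[1], p$te[2], sep = "_")
             else "MI_global"
      peaks[[id]] <- find_peak(scans[[id]], obs)
    }
  }
  bundle <- list(protocol = p, scans = scans, peaks = peaks, seed = seed)
  if (length(p$condition) == 1L) {
    id <- sprintf("%s_W%g", p$condition, p$W[1])
    pk <- peaks[[id]]
    wm <- scale_weights(build_weight_matrix(network_condition(p$condition),
                                            seed = seeds[length(seeds)]),
                        p$W[1])
    traj <- simulate_network(wm, p$steps, pk$r, seed = seeds[length(seeds)])
    n <- nrow(wm$values)
    bundle$stm <- build_stm(traj$encoded, n)
    bundle$classification <- classify_attractors(bundle$stm)
    bundle$raster_fine <- raster(traj, 1)[seq_len(min(300, p$steps)), ,
                                          drop = FALSE]
    bundle$raster_coarse <- raster(traj, 200)
  } else {
    bundle$peak_te <- lapply(scans, peak_trial_values,
                             observable = paste("TE", p$te[1], p$te[2],
                                                sep = "_"))
    for (W in p$W) {
      ids <- sprintf("%s_W%g", p$condition, W)
      bundle$stats[[sprintf("W%g", W)]] <-
        compare_conditions(bundle$peak_te[ids])
    }
  }
  class(bundle) <- "protocol_bundle"
  if (!is.null(dir)) .write_bundle(bundle, dir)
  bundle
}

.write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(bundle$scans)) {
    write_scan(bundle$scans[[id]], file.path(dir, paste0("scan_", id, ".csv")),
               file.path(dir, paste0("scan_", id, "_summary.csv")))
  }
  if (!is.null(bundle$stm)) {
    write_stm(bundle$stm, file.path(dir, "stm.csv"),
              file.path(dir, "stm_states.csv"))
    write.csv(bundle$classification, file.path(dir, "classification.csv"),
              row.names = FALSE)
  }
  manifest <- list(protocol = bundle$protocol[setdiff(names(bundle$protocol),
                                                      "subsystems")],
                   subsystems = bundle$protocol$subsystems,
                   seed = bundle$seed,
                   peaks = bundle$peaks,
                   files = list.files(dir))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Compare per-trial peak statistics across conditions
#'
#' One-way ANOVA across all groups plus pairwise two-sample t-tests
#' (classic pooled-variance by default; Welch optionally). Degenerate
#' inputs — identical values within every group — are flagged instead of
#' reporting an infinite variance ratio.
#'
#' @param groups named list of numeric vectors (>= 2 groups, >= 2 values
#'   each), e.g. per-trial peak transfer entropies per condition.
#' @param welch use Welch's unequal-variance t-test.
#' @return list with `anova` (data frame: F, df1, df2, p, degenerate) and
#'   `pairwise` (data frame: group1, group2, t, df, p).
#' @export
compare_conditions <- function(groups, welch = FALSE) {
  if (length(groups) < 2) stop("need at least two conditions")
  if (any(vapply(groups, length, 0L) < 2)) {
    stop("need at least two trials per condition")
  }
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, 0L))))
  fit <- aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  # a zero-variance stack makes the variance ratio 0/0; flag it instead of
  # reporting a meaningless F
  degenerate <- !is.finite(tab[["F value"]][1]) ||
    isTRUE(all.equal(stats::var(df$value), 0))
  anova_df <- data.frame(F = if (degenerate) NA_real_ else tab[["F value"]][1],
                         df1 = tab$Df[1], df2 = tab$Df[2],
                         p = if (degenerate) NA_real_ else tab[["Pr(>F)"]][1],
                         degenerate = degenerate)
  pairs <- combn(names(groups), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    if (sd(groups[[a]]) == 0 && sd(groups[[b]]) == 0) {
      return(data.frame(group1 = a, group2 = b, t = NA_real_, df = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    tt <- t.test(groups[[a]], groups[[b]], var.equal = !welch)
    data.frame(group1 = a, group2 = b, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  list(anova = anova_df, pairwise = pw)
}
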