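#' Weight class specification
#'
#' A weight class is a truncated normal sampler confined to a deterministic
#' range `[lower, upper]`, with mean `mu = (lower + upper) / 2` and standard
#' deviation `sigma` (default `(upper - lower) / 4`, so about 95% of the
#' untruncated mass already lies inside the range). The degenerate class
#' `"none"` (`lower == upper == 0`) stands for eliminated connections and
#' always yields exact zeros.
#'
#' @param name class label, e.g. `"strong"`, `"intermediate"`, `"weak"`,
#'   `"negligible"`, `"inhibitory"`, `"none"`.
#' @param lower,upper range bounds, `lower < upper` (or both 0 for `"none"`).
#' @param sigma standard deviation of the untruncated normal; must be > 0.
#' @return an object of class `weight_class`.
#' @export
weight_class <- function(name, lower, upper, sigma = (upper - lower) / 4) {
  if (lower == 0 && upper == 0) {
    return(structure(list(name = name, lower = 0, upper = 0, mu = 0, sigma = 0),
                     class = "weight_class"))
  }
  if (lower >= upper) stop("weight class requires lower < upper")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  structure(list(name = name, lower = lower, upper = upper,
                 mu = (lower + upper) / 2, sigma = sigma),
            class = "weight_class")
}

#' Sample a truncated normal by rejection
#'
#' Exact rejection sampling (redraw until inside the range), not clipping:
#' clipping would pile probability mass on the interval boundaries.
#'
#' @param count number of draws (>= 0).
#' @param lower,upper truncation range.
#' @param mu,sigma parameters of the underlying normal. Defaults centre the
#'   distribution on the range midpoint with `sigma = (upper - lower) / 4`.
#' @return numeric vector of `count` draws, all within `[lower, upper]`.
#' @export
sample_truncated_normal <- function(count, lower, upper,
                                    mu = (lower + upper) / 2,
                                    sigma = (upper - lower) / 4) {
  if (count < 0) stop("count must be >= 0")
  if (lower >= upper) stop("requires lower < upper")
  if (sigma <= 0) stop("sigma must be > 0")
  out <- numeric(count)
  need <- seq_len(count)
  while (length(need)) {
    draw <- rnorm(length(need), mu, sigma)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

.sample_class <- function(cls, count) {
  if (cls$name == "none" || (cls$lower == 0 && cls$upper == 0)) {
    return(numeric(count) * 0)
  }
  sample_truncated_normal(count, cls$lower, cls$upper, cls$mu, cls$sigma)
}

#' Connectivity condition specification
#'
#' Describes one experimental connectivity condition: network size, block
#' structure (for lattice-derived conditions), the topological condition,
#' excitatory vs inhibitory variant, the weight classes, and the layout rule
#' mapping matrix cells to classes.
#'
#' Layout rules under `quantum_logic` / `broken_quantum_logic`:
#' \describe{
#'   \item{`"pasted"`}{the layout that instantiates the pasted-lattice
#'     relation: the main diagonal is `strong` (the within-block diagonal
#'     pairs), within-block off-diagonal cells take the secondary positive
#'     class (the weakest non-negative class), and cross-block cells take
#'     the `inhibitory` class (the bounding pairs of the pasting).}
#'   \item{`"border_intermediate"`}{the whole within-block region is
#'     `strong`; cells coupling the last neuron of one block to the first of
#'     the next (both directions) take the `intermediate` class; every other
#'     off-block cell is `weak`.}
#'   \item{`"border_weak"`}{within-block `strong`; the same border cells take
#'     the `weak` class; every other off-block cell is `inhibitory`.}
#'   \item{`"border_negligible"`}{within-block `strong`; border cells
#'     `negligible`; every other off-block cell `inhibitory`.}
#'   \item{`"adjacent_inhibitory"`}{within-block `strong`; cells between
#'     adjacent blocks of the one-dimensional chain are `inhibitory`; cells
#'     between non-adjacent blocks are `negligible`.}
#'   \item{`"uniform"`}{within-block `strong`; all off-block cells take the
#'     single non-strong class.}
#' }
#' Under `diagonal` the main diagonal is `strong` and all off-diagonal cells
#' take the background class (the unique non-strong class in `classes`).
#'
#' @param n neuron count.
#' @param blocks integer block sizes summing to `n` (lattice conditions).
#' @param condition `"quantum_logic"`, `"diagonal"` or
#'   `"broken_quantum_logic"`.
#' @param variant `"excitatory"` or `"inhibitory"`.
#' @param classes named list of [weight_class()] objects; must include
#'   `"strong"`.
#' @param layout layout rule, see Details.
#' @param seed optional default seed used by [build_weight_matrix()].
#' @param name optional condition label.
#' @return an object of class `condition_spec`.
#' @export
condition_spec <- function(n, blocks = NULL,
                           condition = c("quantum_logic", "diagonal",
                                         "broken_quantum_logic"),
                           variant = c("excitatory", "inhibitory"),
                           classes, layout = "uniform", seed = NULL,
                           name = NULL) {
  condition <- match.arg(condition)
  variant <- match.arg(variant)
  if (condition != "diagonal") {
    if (is.null(blocks)) stop("lattice conditions require block sizes")
    if (sum(blocks) != n) stop("block sizes must sum to n")
  }
  if (!"strong" %in% names(classes)) stop("classes must include 'strong'")
  structure(list(n = n, blocks = blocks, condition = condition,
                 variant = variant, classes = classes, layout = layout,
                 seed = seed, name = name %||% condition),
            class = "condition_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preset connectivity conditions
#'
#' The study conditions, with their published weight-class ranges:
#' \describe{
#'   \item{`"ql5_exc"`}{5 neurons, blocks (3, 2), quantum logic, purely
#'     excitatory: strong 0.7–1.0 within blocks, intermediate 0.2–0.3 on the
#'     cross-block border cells, weak 0.0–0.05 elsewhere.}
#'   \item{`"ql5_inh"`}{the inhibitory-modulated variant: strong 0.7–1.0 is
#'     retained on the main diagonal only (the primary signal pathways), the
#'     remaining within-block cells are attenuated to 0.0–0.05, and the
#'     cross-block background is reassigned to inhibitory -0.8 to -0.4
#'     (the `"pasted"` layout).}
#'   \item{`"diag5_exc"`}{5 neurons, strong 0.7–1.0 self-coupling, weak
#'     0.0–0.05 off-diagonal.}
#'   \item{`"diag5_inh"`}{5 neurons, strong 0.7–1.0 self-coupling,
#'     inhibitory -0.26 to -0.16 off-diagonal.}
#'   \item{`"ql10_inh"`}{10 neurons, blocks (2, 5, 3), quantum logic with
#'     inhibitory modulation, `"pasted"` layout: strong 0.95–1.05 on the
#'     diagonal, negligible 0.02–0.08 within-block off-diagonal, inhibitory
#'     -0.75 to -0.55 on all cross-block cells.}
#'   \item{`"broken10"`}{as `"ql10_inh"` but with the background (non-strong)
#'     cell values and class labels randomly permuted among background
#'     positions (per-class cell counts conserved), destroying the
#'     background topology while preserving connectivity density.}
#'   \item{`"diag10"`}{10 neurons, strong 0.95–1.05 self-coupling, all
#'     off-diagonal connections eliminated (exact zeros).}
#' }
#'
#' @param name one of the preset names above.
#' @param seed optional default seed stored in the spec.
#' @return a `condition_spec`.
#' @export
network_condition <- function(name = c("ql5_exc", "ql5_inh", "diag5_exc",
                                       "diag5_inh", "ql10_inh", "broken10",
                                       "diag10"),
                              seed = NULL) {
  name <- match.arg(name)
  switch(name,
    ql5_exc = condition_spec(5, c(3, 2), "quantum_logic", "excitatory",
      classes = list(strong = weight_class("strong", 0.7, 1.0),
                     intermediate = weight_class("intermediate", 0.2, 0.3),
                     weak = weight_class("weak", 0.0, 0.05)),
      layout = "border_intermediate", seed = seed, name = name),
    ql5_inh = condition_spec(5, c(3, 2), "quantum_logic", "inhibitory",
      classes = list(strong = weight_class("strong", 0.7, 1.0),
                     weak = weight_class("weak", 0.0, 0.05),
                     inhibitory = weight_class("inhibitory", -0.8, -0.4)),
      layout = "pasted", seed = seed, name = name),
    diag5_exc = condition_spec(5, NULL, "diagonal", "excitatory",
      classes = list(strong = weight_class("strong", 0.7, 1.0),
                     weak = weight_class("weak", 0.0, 0.05)),
      seed = seed, name = name),
    diag5_inh = condition_spec(5, NULL, "diagonal", "inhibitory",
      classes = list(strong = weight_class("strong", 0.7, 1.0),
                     inhibitory = weight_class("inhibitory", -0.26, -0.16)),
      seed = seed, name = name),
    ql10_inh = condition_spec(10, c(2, 5, 3), "quantum_logic", "inhibitory",
      classes = list(strong = weight_class("strong", 0.95, 1.05),
                     negligible = weight_class("negligible", 0.02, 0.08),
                     inhibitory = weight_class("inhibitory", -0.75, -0.55)),
      layout = "pasted", seed = seed, name = name),
    broken10 = condition_spec(10, c(2, 5, 3), "broken_quantum_logic",
      "inhibitory",
      classes = list(strong = weight_class("strong", 0.95, 1.05),
                     negligible = weight_class("negligible", 0.02, 0.08),
                     inhibitory = weight_class("inhibitory", -0.75, -0.55)),
      layout = "pasted", seed = seed, name = name),
    diag10 = condition_spec(10, NULL, "diagonal", "excitatory",
      classes = list(strong = weight_class("strong", 0.95, 1.05),
                     none = weight_class("none", 0, 0)),
      seed = seed, name = name)
  )
}

#' Block membership of each neuron
#' @param spec a `condition_spec` with blocks.
#' @return integer vector of block ids, length `n`.
#' @export
block_index <- function(spec) {
  if (is.null(spec$blocks)) stop("condition has no block structure")
  rep(seq_along(spec$blocks), spec$blocks)
}

#' Cell-level class assignment
#'
#' Computes the n x n matrix of weight-class names implied by a condition
#' spec: within-block cells (including the diagonal) are `strong` under the
#' lattice conditions; off-block cells follow the spec's layout rule.
#'
#' @param spec a `condition_spec`.
#' @return character matrix of class names.
#' @export
cell_classes <- function(spec) {
  n <- spec$n
  if (spec$condition == "diagonal") {
    bg <- setdiff(names(spec$classes), "strong")[1]
    cl <- matrix(bg, n, n)
    diag(cl) <- "strong"
    return(cl)
  }
  b <- block_index(spec)
  within <- outer(b, b, "==")
  cl <- matrix(NA_character_, n, n)
  border <- matrix(FALSE, n, n)
  ends <- cumsum(spec$blocks)
  starts <- c(1L, head(ends, -1L) + 1L)
  for (k in seq_len(length(spec$blocks) - 1L)) {
    border[ends[k], starts[k + 1L]] <- TRUE
    border[starts[k + 1L], ends[k]] <- TRUE
  }
  if (spec$layout == "pasted") {
    # weakest non-negative class fills the within-block off-diagonal;
    # inhibitory bounding pairs fill the cross-block region
    pos <- names(spec$classes)[vapply(spec$classes, function(x) x$lower >= 0,
                                      logical(1))]
    secondary <- pos[which.min(vapply(spec$classes[pos], `[[`, 0, "upper"))]
    cl[within] <- secondary
    diag(cl) <- "strong"
    cl[!within] <- "inhibitory"
    missing <- setdiff(unique(as.vector(cl)), names(spec$classes))
    if (length(missing)) {
      stop("layout assigns classes absent from the spec: ",
           paste(missing, collapse = ", "))
    }
    return(cl)
  }
  cl[within] <- "strong"
  off <- !within
  cl[off] <- switch(spec$layout,
    border_intermediate = ifelse(border[off], "intermediate", "weak"),
    border_weak = ifelse(border[off], "weak", "inhibitory"),
    border_negligible = ifelse(border[off], "negligible", "inhibitory"),
    adjacent_inhibitory = {
      adj <- abs(outer(b, b, "-")) == 1L
      ifelse(adj[off], "inhibitory", "negligible")
    },
    uniform = setdiff(names(spec$classes), "strong")[1],
    stop("unknown layout rule: ", spec$layout)
  )
  missing <- setdiff(unique(as.vector(cl)), names(spec$classes))
  if (length(missing)) {
    stop("layout assigns classes absent from the spec: ",
         paste(missing, collapse = ", "))
  }
  cl
}

#' Build a weight matrix for a condition
#'
#' Each directed entry is drawn independently from its class's truncated
#' normal (the matrix is not symmetrised unless `symmetric = TRUE`). Under
#' `broken_quantum_logic` the matrix is built as under quantum logic and the
#' off-block cells (values and class labels jointly) are then randomly
#' permuted among off-block positions, conserving per-class cell counts.
#' The result is exactly regenerable from the seed.
#'
#' @param spec a `condition_spec`.
#' @param seed integer seed; defaults to `spec$seed`.
#' @param symmetric mirror the upper triangle onto the lower (requires a
#'   symmetric class layout).
#' @return an object of class `weight_matrix` with fields `values` (unscaled
#'   draws), `classes`, `scale` (the multiplier W, initially 1) and `spec`.
#' @export
build_weight_matrix <- function(spec, seed = spec$seed, symmetric = FALSE) {
  n <- spec$n
  if (!is.null(seed)) set.seed(seed)
  classes <- cell_classes(spec)
  values <- matrix(0, n, n)
  for (nm in names(spec$classes)) {
    idx <- which(classes == nm)
    if (length(idx)) values[idx] <- .sample_class(spec$classes[[nm]], length(idx))
  }
  if (symmetric) {
    if (!identical(classes, t(classes))) {
      stop("symmetric sampling requires a symmetric class layout")
    }
    values[lower.tri(values)] <- t(values)[lower.tri(values)]
  }
  wm <- structure(list(values = values, classes = classes, scale = 1,
                       spec = spec, seed = seed),
                  class = "weight_matrix")
  if (spec$condition == "broken_quantum_logic") {
    wm$spec$condition <- "quantum_logic"
    wm <- break_background(wm)
    wm$spec$condition <- "broken_quantum_logic"
  }
  wm
}

#' Disrupt the background topology of a quantum-logic matrix
#'
#' Randomly permutes the background cells (weight values together with their
#' class labels) among the background positions, where the background is
#' every cell not in the strong class. Strong cells are untouched and the
#' per-class cell counts — hence the connectivity density and the sorted
#' multiset of weights — are conserved.
#'
#' @param wm a `weight_matrix` built under the quantum-logic condition.
#' @param seed optional seed for the permutation.
#' @return the perturbed `weight_matrix`.
#' @export
break_background <- function(wm, seed = NULL) {
  if (wm$spec$condition == "diagonal") {
    stop("break_background applies to quantum-logic matrices only")
  }
  if (!is.null(seed)) set.seed(seed)
  off <- which(wm$classes != "strong")
  perm <- sample(length(off))
  wm$values[off] <- wm$values[off][perm]
  wm$classes[off] <- wm$classes[off][perm]
  wm
}

#' Apply a weight scaling factor
#'
#' Sets the global multiplier W; the effective coupling matrix returned by
#' [as.matrix()] is `W * values`. Class labels are unchanged.
#'
#' @param wm a `weight_matrix`.
#' @param W positive scaling factor (the experiments use W in 1, 2, 5, 10).
#' @return the rescaled `weight_matrix`.
#' @export
scale_weights <- function(wm, W) {
  if (!is.numeric(W) || W <= 0) stop("W must be > 0")
  wm$scale <- W
  wm
}

#' Effective (scaled) coupling matrix
#' @param x a `weight_matrix`.
#' @param ... unused.
#' @export
as.matrix.weight_matrix <- function(x, ...) x$values * x$scale

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("weight_matrix: n=%d, condition=%s, W=%g\n",
              nrow(x$values), x$spec$condition, x$scale))
  tab <- table(x$classes)
  cat("  cells:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write / read a weight matrix as delimited text
#'
#' Values go to `path` as CSV (17 significant digits, so the round trip is
#' exact); class labels, the condition spec, scale and seed go to a sidecar
#' JSON file `paste0(path, ".json")`.
#'
#' @param wm a `weight_matrix`.
#' @param path CSV file path.
#' @return `write_weight_matrix` returns `path` invisibly;
#'   `read_weight_matrix` returns the reconstructed `weight_matrix`.
#' @export
write_weight_matrix <- function(wm, path) {
  txt <- apply(wm$values, 1, function(row) {
    paste(vapply(row, function(v) format(v, digits = 17), character(1)),
          collapse = ",")
  })
  writeLines(txt, path)
  meta <- list(classes = wm$classes, scale = wm$scale, seed = wm$seed,
               spec = .spec_meta(wm$spec))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.spec_meta <- function(spec) {
  list(n = spec$n, blocks = spec$blocks, condition = spec$condition,
       variant = spec$variant, layout = spec$layout, name = spec$name,
       classes = lapply(spec$classes, function(cl) {
         list(name = cl$name, lower = cl$lower, upper = cl$upper,
              sigma = cl$sigma)
       }))
}

#' @rdname write_weight_matrix
#' @export
read_weight_matrix <- function(path) {
  values <- as.matrix(read.csv(path, header = FALSE))
  dimnames(values) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  classes <- lapply(meta$spec$classes, function(cl) {
    if (cl$lower == 0 && cl$upper == 0) weight_class(cl$name, 0, 0)
    else weight_class(cl$name, cl$lower, cl$upper, cl$sigma)
  })
  spec <- condition_spec(meta$spec$n, meta$spec$blocks, meta$spec$condition,
                         meta$spec$variant, classes, meta$spec$layout,
                         name = meta$spec$name)
  structure(list(values = values, classes = matrix(meta$classes,
                                                   nrow(values), ncol(values)),
                 scale = meta$scale, spec = spec, seed = meta$seed),
            class = "weight_matrix")
}
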