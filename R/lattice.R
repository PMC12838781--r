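#' Binary relation between two neuron universes
#'
#' A relation I between an ordered universe U1 of row labels and an ordered
#' universe U2 of column labels, stored as a logical incidence matrix.
#'
#' @param u1,u2 character vectors of labels (equal length n).
#' @param pairs either a two-column integer matrix of (i, j) index pairs or
#'   a logical incidence matrix of dimension `length(u1) x length(u2)`.
#' @return an object of class `binary_relation`.
#' @export
binary_relation <- function(u1, u2, pairs) {
  n1 <- length(u1); n2 <- length(u2)
  if (anyDuplicated(u1) || anyDuplicated(u2)) stop("universe labels must be unique")
  if (is.matrix(pairs) && is.logical(pairs)) {
    if (!all(dim(pairs) == c(n1, n2))) stop("incidence dimensions do not match universes")
    inc <- pairs
  } else {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2) stop("pairs must have two columns")
    if (nrow(pairs) && (min(pairs) < 1 || max(pairs[, 1]) > n1 || max(pairs[, 2]) > n2)) {
      stop("pair indices outside the universes")
    }
    inc <- matrix(FALSE, n1, n2)
    inc[pairs] <- TRUE
  }
  dimnames(inc) <- list(u1, u2)
  structure(list(u1 = u1, u2 = u2, incidence = inc),
            class = "binary_relation")
}

#' @export
print.binary_relation <- function(x, ...) {
  cat(sprintf("binary_relation: %d x %d, %d pairs\n",
              length(x$u1), length(x$u2), sum(x$incidence)))
  invisible(x)
}

#' Pasted block relation
#'
#' The relation whose rough-set lattice is the pasting of Boolean algebras:
#' within each block only the diagonal pairs are related, while every
#' cross-block pair is related ("diagonal sub-relations bounded by related
#' pairs"). Its closure fixed points are the empty set, the full universe,
#' and every proper nonempty subset of each block, so the lattice has
#' `sum(2^blocks - 2) + 2` elements and is non-distributive whenever there
#' are at least two blocks with one of size >= 2.
#'
#' @param blocks integer block sizes.
#' @param u1,u2 optional label vectors (defaults: `LETTERS` and `letters`).
#' @return a `binary_relation`.
#' @export
pasted_relation <- function(blocks, u1 = NULL, u2 = NULL) {
  n <- sum(blocks)
  u1 <- u1 %||% make.unique(rep(LETTERS, length.out = n))
  u2 <- u2 %||% make.unique(rep(letters, length.out = n))
  b <- rep(seq_along(blocks), blocks)
  inc <- outer(b, b, "!=") | diag(n) > 0
  binary_relation(u1, u2, inc)
}

#' Identity (diagonal) relation
#'
#' Relates each row label only to the same-position column label; its
#' rough-set lattice is the full power set (a Boolean algebra).
#'
#' @param n universe size.
#' @param u1,u2 optional label vectors.
#' @return a `binary_relation`.
#' @export
diagonal_relation <- function(n, u1 = NULL, u2 = NULL) {
  u1 <- u1 %||% make.unique(rep(LETTERS, length.out = n))
  u2 <- u2 %||% make.unique(rep(letters, length.out = n))
  binary_relation(u1, u2, diag(n) > 0)
}

#' Threshold a weight matrix into a binary relation
#'
#' Pair (i, j) is related iff the unscaled weight `w_ij >= theta`. The
#' default threshold separates the related (within-block) classes from the
#' background: when inhibitory classes are present it is the midpoint
#' between their largest upper bound and the smallest lower bound of the
#' non-negative classes; otherwise it is the midpoint between the strong
#' class's lower bound and the largest upper bound of the other classes.
#' Either way the generated block (or diagonal) relation is recovered
#' exactly.
#'
#' @param wm a `weight_matrix`.
#' @param theta threshold; `NULL` for the default rule.
#' @return a `binary_relation` on labels `N1..Nn` / `n1..nn`.
#' @export
relation_from_weights <- function(wm, theta = NULL) {
  n <- nrow(wm$values)
  if (is.null(theta)) {
    cls <- wm$spec$classes
    if (is.null(cls$strong)) stop("no strong class; supply theta explicitly")
    others <- cls[setdiff(names(cls), "strong")]
    if (!length(others)) stop("single-class matrix; supply theta explicitly")
    neg <- vapply(cls, function(x) x$upper < 0, logical(1))
    if (any(neg)) {
      theta <- (max(vapply(cls[neg], `[[`, 0, "upper")) +
                  min(vapply(cls[!neg], `[[`, 0, "lower"))) / 2
    } else {
      theta <- (cls$strong$lower + max(vapply(others, `[[`, 0, "upper"))) / 2
    }
  }
  inc <- wm$values >= theta
  if (!any(inc)) warning("empty relation: theta exceeds every weight")
  binary_relation(paste0("N", seq_len(n)), paste0("n", seq_len(n)), inc)
}

.labels_to_idx <- function(labels, u) {
  if (is.numeric(labels)) {
    idx <- as.integer(labels)
    if (length(idx) && (min(idx) < 1 || max(idx) > length(u))) {
      stop("indices outside U1")
    }
    return(idx)
  }
  idx <- match(labels, u)
  if (anyNA(idx)) stop("labels not in U1: ",
                       paste(labels[is.na(idx)], collapse = ", "))
  idx
}

#' Rough-set closure operator
#'
#' `Cl(F) = R*(r*(F))` where `r*(F)` collects every column related to some
#' element of F and `R*(G)` removes from U1 every row related to a column
#' outside G. Cl is extensive, idempotent and monotone; its fixed points
#' form the rough-set lattice.
#'
#' @param F subset of U1 (labels or indices); may be empty.
#' @param rel a `binary_relation`.
#' @return character vector: the closed set, in U1 order.
#' @export
closure <- function(F, rel) {
  idx <- .labels_to_idx(F, rel$u1)
  inc <- rel$incidence
  G <- if (length(idx)) colSums(inc[idx, , drop = FALSE]) > 0 else
    rep(FALSE, length(rel$u2))
  keep <- rowSums(inc[, !G, drop = FALSE]) == 0
  rel$u1[keep]
}

# closure on a bitmask over U1, given per-row image bitmasks over U2
.cl_mask <- function(imgs, mask, n1) {
  G <- 0L
  for (i in seq_len(n1)) {
    if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) != 0L) G <- bitwOr(G, imgs[i])
  }
  cl <- 0L
  for (i in seq_len(n1)) {
    if (bitwAnd(imgs[i], bitwNot(G)) == 0L) cl <- bitwOr(cl, bitwShiftL(1L, i - 1L))
  }
  cl
}

.row_images <- function(rel) {
  vapply(seq_along(rel$u1), function(i) {
    bits <- which(rel$incidence[i, ])
    Reduce(bitwOr, bitwShiftL(1L, bits - 1L), 0L)
  }, integer(1))
}

#' Build the rough-set lattice of a binary relation
#'
#' Enumerates all 2^n subsets of U1 and keeps the fixed points of the
#' closure operator, ordered canonically by (cardinality, lexicographic
#' label order). The empty set and U1 are always elements; the order is set
#' inclusion; meet is the greatest fixed point below the intersection and
#' join is the closure of the union.
#'
#' @param rel a `binary_relation` with `|U1| <= 20`.
#' @param covers also compute the Hasse cover edges (skipped automatically
#'   for lattices with more than 2000 elements).
#' @return an object of class `rough_lattice` with fields `elements` (list
#'   of label vectors), `masks`, `universe`, `covers` and the generating
#'   relation.
#' @export
build_lattice <- function(rel, covers = TRUE) {
  n <- length(rel$u1)
  if (n > 20) stop("universe too large for subset enumeration (n > 20)")
  imgs <- .row_images(rel)
  total <- bitwShiftL(1L, n)
  masks <- 0:(total - 1L)
  # G[mask] = union of row images over the rows in mask, by prefix doubling
  G <- integer(total)
  if (n >= 1) {
    for (b in seq_len(n)) {
      lo <- bitwShiftL(1L, b - 1L)
      idx <- (lo + 1L):(2L * lo)
      G[idx] <- bitwOr(G[idx - lo], imgs[b])
    }
  }
  # Cl[mask]: rows whose image is contained in G[mask]
  cl <- integer(total)
  notG <- bitwNot(G)
  for (i in seq_len(n)) {
    inside <- bitwAnd(imgs[i], notG) == 0L
    cl[inside] <- bitwOr(cl[inside], bitwShiftL(1L, i - 1L))
  }
  fixed <- masks[cl == masks]
  elements <- lapply(fixed, function(m) rel$u1[bitwAnd(bitwShiftR(m, 0:(n - 1L)), 1L) == 1L])
  card <- vapply(elements, length, integer(1))
  key <- vapply(elements, function(e) paste(sort(e), collapse = "\r"), character(1))
  ord <- order(card, key)
  lat <- structure(list(elements = elements[ord], masks = fixed[ord],
                        universe = rel$u1, relation = rel, covers = NULL),
                   class = "rough_lattice")
  if (covers && length(fixed) <= 2000) lat$covers <- .compute_covers(lat)
  lat
}

.compute_covers <- function(lat) {
  m <- lat$masks
  L <- length(m)
  below <- outer(m, m, function(a, b) bitwAnd(a, b) == a) & outer(m, m, "!=")
  covers <- which(below, arr.ind = TRUE)
  keep <- vapply(seq_len(nrow(covers)), function(k) {
    i <- covers[k, 1]; j <- covers[k, 2]
    !any(below[i, ] & below[, j])
  }, logical(1))
  covers[keep, , drop = FALSE]
}

#' Number of lattice elements
#' @param x a `rough_lattice`.
#' @export
length.rough_lattice <- function(x) length(x$masks)

#' @export
print.rough_lattice <- function(x, ...) {
  cat(sprintf("rough_lattice: %d elements over U1 = {%s}\n",
              length(x$masks), paste(x$universe, collapse = ",")))
  invisible(x)
}

.format_element <- function(e) paste0("{", paste(e, collapse = ","), "}")

#' Hasse cover edges
#'
#' (F, G) is a cover iff F is strictly included in G with no lattice element
#' strictly between them.
#'
#' @param lat a `rough_lattice`.
#' @return data frame with columns `from` and `to` (formatted element
#'   labels, lower element first).
#' @export
hasse_edges <- function(lat) {
  cov <- lat$covers %||% .compute_covers(lat)
  data.frame(
    from = vapply(cov[, 1], function(i) .format_element(lat$elements[[i]]), character(1)),
    to = vapply(cov[, 2], function(i) .format_element(lat$elements[[i]]), character(1)),
    stringsAsFactors = FALSE
  )
}

.meet_idx <- function(lat, i, j) {
  # greatest fixed point below the intersection, by search over elements
  target <- bitwAnd(lat$masks[i], lat$masks[j])
  cand <- which(bitwAnd(lat$masks, target) == lat$masks)
  cand[which.max(vapply(lat$masks[cand], .popcount, integer(1)))]
}

.join_idx <- function(lat, i, j) {
  u <- bitwOr(lat$masks[i], lat$masks[j])
  imgs <- .row_images(lat$relation)
  match(.cl_mask(imgs, u, length(lat$universe)), lat$masks)
}

.popcount <- function(x) sum(bitwAnd(bitwShiftR(x, 0:30), 1L))

#' Lattice meet and join
#'
#' @param lat a `rough_lattice`.
#' @param x,y elements given as label vectors.
#' @return the resulting element as a label vector.
#' @export
lattice_meet <- function(lat, x, y) {
  i <- .find_element(lat, x); j <- .find_element(lat, y)
  lat$elements[[.meet_idx(lat, i, j)]]
}

#' @rdname lattice_meet
#' @export
lattice_join <- function(lat, x, y) {
  i <- .find_element(lat, x); j <- .find_element(lat, y)
  lat$elements[[.join_idx(lat, i, j)]]
}

.find_element <- function(lat, e) {
  idx <- .labels_to_idx(e, lat$universe)
  mask <- Reduce(bitwOr, bitwShiftL(1L, idx - 1L), 0L)
  pos <- match(mask, lat$masks)
  if (is.na(pos)) stop("not a lattice element: ", .format_element(e))
  pos
}

#' Distributivity check
#'
#' Tests the identity `x & (y | z) == (x & y) | (x & z)` over all ordered
#' element triples; a Boolean (power-set) lattice passes, while the pasted
#' quantum-logic lattice fails. Returns the first failing triple in the
#' canonical element order as a witness.
#'
#' @param lat a `rough_lattice`.
#' @return list with `distributive` (logical) and `witness` (`NULL` or a
#'   list of elements x, y, z plus both sides of the identity).
#' @export
check_distributivity <- function(lat) {
  L <- length(lat$masks)
  meetT <- matrix(0L, L, L)
  joinT <- matrix(0L, L, L)
  imgs <- .row_images(lat$relation)
  n1 <- length(lat$universe)
  pc <- vapply(lat$masks, .popcount, integer(1))
  for (i in seq_len(L)) {
    for (j in i:L) {
      tgt <- bitwAnd(lat$masks[i], lat$masks[j])
      cand <- which(bitwAnd(lat$masks, tgt) == lat$masks)
      mi <- cand[which.max(pc[cand])]
      meetT[i, j] <- meetT[j, i] <- mi
      ji <- match(.cl_mask(imgs, bitwOr(lat$masks[i], lat$masks[j]), n1),
                  lat$masks)
      joinT[i, j] <- joinT[j, i] <- ji
    }
  }
  for (x in seq_len(L)) {
    for (y in seq_len(L)) {
      lhs <- meetT[x, joinT[y, ]]
      rhs <- joinT[cbind(meetT[x, y], meetT[x, ])]
      bad <- which(lhs != rhs)
      if (length(bad)) {
        z <- bad[1]
        return(list(distributive = FALSE,
                    witness = list(x = lat$elements[[x]],
                                   y = lat$elements[[y]],
                                   z = lat$elements[[z]],
                                   lhs = lat$elements[[lhs[z]]],
                                   rhs = lat$elements[[rhs[z]]])))
      }
    }
  }
  list(distributive = TRUE, witness = NULL)
}

#' Export a lattice
#'
#' `lattice_json()` serialises elements (as sorted label lists) and cover
#' edges to a JSON string; `write_lattice_json()` writes it to a file.
#' `lattice_dot()` renders the Hasse diagram in Graphviz DOT.
#'
#' @param lat a `rough_lattice`.
#' @return a JSON string / DOT string; `write_lattice_json` returns `path`
#'   invisibly.
#' @export
lattice_json <- function(lat) {
  cov <- hasse_edges(lat)
  jsonlite::toJSON(list(
    universe = lat$universe,
    elements = lapply(lat$elements, sort),
    covers = cov
  ), auto_unbox = FALSE, digits = NA)
}

#' @rdname lattice_json
#' @param path output file.
#' @export
write_lattice_json <- function(lat, path) {
  writeLines(as.character(lattice_json(lat)), path)
  invisible(path)
}

#' @rdname lattice_json
#' @export
lattice_dot <- function(lat) {
  cov <- hasse_edges(lat)
  lines <- c("digraph hasse {", "  rankdir=BT;",
             sprintf("  \"%s\" -> \"%s\";", cov$from, cov$to), "}")
  paste(lines, collapse = "\n")
}
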