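# The pasted two-block relation on five neurons is the running example:
# blocks {A,B,C} and {D,E} with diagonal within-block pairs and all
# cross-block pairs related.
rel5 <- pasted_relation(c(3, 2), u1 = c("A", "B", "C", "D", "E"),
                        u2 = c("a", "b", "c", "d", "e"))

test_that("closure reproduces the worked examples of the pasted relation", {
  expect_setequal(closure("A", rel5), "A")
  expect_setequal(closure(c("B", "C"), rel5), c("B", "C"))
  expect_setequal(closure(c("C", "D"), rel5), c("A", "B", "C", "D", "E"))
  expect_equal(closure(character(0), rel5), character(0))
  expect_setequal(closure(c("A", "B", "C", "D", "E"), rel5), rel5$u1)
  expect_error(closure("Z", rel5), "not in U1")
})

test_that("closure satisfies the closure-operator axioms on random relations", {
  set.seed(42)
  for (i in 1:60) {
    rel <- random_relation(sample(3:6, 1))
    F <- sample(rel$u1, sample(0:length(rel$u1), 1))
    G <- union(F, sample(rel$u1, 1))
    clF <- closure(F, rel)
    expect_true(all(F %in% clF))                       # extensive
    expect_setequal(closure(clF, rel), clF)            # idempotent
    expect_true(all(clF %in% closure(G, rel)))         # monotone
    expect_setequal(clF, oracle_closure(F, rel))       # matches naive oracle
  }
})

test_that("build_lattice enumerates exactly the closure fixed points", {
  lat <- build_lattice(rel5)
  expect_equal(length(lat), 10L)
  els <- lapply(lat$elements, sort)
  # empty set, U, all proper nonempty subsets of {A,B,C}, and {D}, {E}
  expect_true(any(vapply(els, function(e) length(e) == 0, TRUE)))
  expect_true(any(vapply(els, function(e) setequal(e, rel5$u1), TRUE)))
  expect_true(any(vapply(els, function(e) setequal(e, c("A", "B")), TRUE)))
  expect_true(any(vapply(els, function(e) setequal(e, "D"), TRUE)))
  expect_false(any(vapply(els, function(e) setequal(e, c("A", "B", "C")), TRUE)))
  expect_false(any(vapply(els, function(e) setequal(e, c("D", "E")), TRUE)))
  # agreement with the naive enumeration oracle
  oracle <- oracle_lattice_elements(rel5)
  expect_setequal(vapply(els, paste, "", collapse = ","),
                  vapply(oracle, paste, "", collapse = ","))
})

test_that("lattice size follows the Boolean-pasting law and identity gives a power set", {
  expect_equal(length(build_lattice(diagonal_relation(3))), 8L)
  lat10 <- build_lattice(pasted_relation(c(2, 5, 3)), covers = FALSE)
  expect_equal(length(lat10), (2^2 - 2) + (2^5 - 2) + (2^3 - 2) + 2)
  set.seed(7)
  for (i in 1:5) {
    blocks <- sample(1:4, sample(2:3, 1), replace = TRUE)
    lat <- build_lattice(pasted_relation(blocks), covers = FALSE)
    if (length(blocks) >= 2) {
      expect_equal(length(lat), sum(2^blocks - 2) + 2)
    }
    # cross-check against the naive oracle on small universes
    if (sum(blocks) <= 6) {
      expect_equal(length(lat),
                   length(oracle_lattice_elements(pasted_relation(blocks))))
    }
  }
  # complete relation collapses to the two-element lattice
  full <- binary_relation(c("A", "B", "C"), c("a", "b", "c"),
                          matrix(TRUE, 3, 3))
  expect_equal(length(build_lattice(full)), 2L)
  expect_error(build_lattice(random_relation(21)), "too large")
})

test_that("distributivity holds for Boolean lattices and fails for pasted ones", {
  expect_true(check_distributivity(build_lattice(diagonal_relation(3)))$distributive)
  full <- binary_relation(c("A", "B"), c("a", "b"), matrix(TRUE, 2, 2))
  expect_true(check_distributivity(build_lattice(full))$distributive)
  res <- check_distributivity(build_lattice(rel5))
  expect_false(res$distributive)
  w <- res$witness
  lat <- build_lattice(rel5)
  lhs <- lattice_meet(lat, w$x, lattice_join(lat, w$y, w$z))
  rhs <- lattice_join(lat, lattice_meet(lat, w$x, w$y),
                      lattice_meet(lat, w$x, w$z))
  expect_false(setequal(lhs, rhs))
  # the canonical counterexample: {A} with the two singletons of the other block
  a_dz <- lattice_meet(lat, "A", lattice_join(lat, "D", "E"))
  expect_setequal(a_dz, "A")
  expect_setequal(lattice_join(lat, lattice_meet(lat, "A", "D"),
                               lattice_meet(lat, "A", "E")), character(0))
})

test_that("Hasse covers are immediate-inclusion edges", {
  lat <- build_lattice(rel5)
  edges <- hasse_edges(lat)
  expect_true(any(edges$from == "{}" & edges$to == "{D}"))
  expect_true(any(edges$from == "{D}" & edges$to == "{A,B,C,D,E}"))
  expect_true(any(edges$from == "{B,C}" & edges$to == "{A,B,C,D,E}"))
  expect_false(any(edges$from == "{}" & edges$to == "{A,B}"))
  # Boolean square has exactly 4 edges
  expect_equal(nrow(hasse_edges(build_lattice(diagonal_relation(2)))), 4L)
})

test_that("relation thresholding recovers the generating block structure", {
  wm <- build_weight_matrix(network_condition("ql10_inh"), seed = 5)
  rel <- relation_from_weights(wm)
  blocks <- rep(1:3, c(2, 5, 3))
  expect_equal(unname(rel$incidence), outer(blocks, blocks, "=="))
  wm5 <- build_weight_matrix(network_condition("ql5_exc"), seed = 5)
  rel5w <- relation_from_weights(wm5)
  b5 <- rep(1:2, c(3, 2))
  expect_equal(unname(rel5w$incidence), outer(b5, b5, "=="))
  # theta above every weight leaves an empty relation, with a warning
  expect_warning(r0 <- relation_from_weights(wm5, theta = 2), "empty")
  expect_equal(sum(r0$incidence), 0L)
  # theta at or below the minimum weight relates everything -> {0, U} lattice
  rall <- relation_from_weights(wm5, theta = -1)
  expect_equal(length(build_lattice(rall)), 2L)
})

test_that("lattice exports are well-formed", {
  lat <- build_lattice(rel5)
  js <- jsonlite::fromJSON(lattice_json(lat), simplifyVector = FALSE)
  expect_length(js$elements, 10L)
  dot <- lattice_dot(lat)
  expect_match(dot, "digraph")
  expect_match(dot, "\\{D\\}")
  tmp <- tempfile(fileext = ".json")
  write_lattice_json(lat, tmp)
  expect_true(file.exists(tmp))
  unlink(tmp)
})
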