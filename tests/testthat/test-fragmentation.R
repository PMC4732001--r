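test_that("bond energies are symmetric with a fallback for unknown pairs", {
  t <- default_bde_table()
  expect_equal(bond_energy(t, "C", "C", 1), 348)
  expect_equal(bond_energy(t, "N", "C", 1), bond_energy(t, "C", "N", 1))
  expect_equal(bond_energy(t, "Se", "Ca", 1), 348)  # not tabulated
  # aromatic entry is the mean of the pair's single and double energies
  expect_equal(bond_energy(t, "C", "C", 4), (348 + 614) / 2)
})

test_that("propane skeleton at depth 1 yields the four proper fragments", {
  fs <- generate_fragments(parse_structure("CCC"), 1L)
  proper <- Filter(function(f) f$matchable, fs$fragments)
  expect_length(proper, 4L)
  sizes <- sort(vapply(proper, function(f) length(f$atoms), integer(1)))
  expect_equal(sizes, c(1L, 1L, 2L, 2L))
  expect_length(fs$fragments, 5L)  # plus the parent
  ch3 <- proper[[which.min(vapply(proper, `[[`, numeric(1), "mass"))]]
  expect_equal(ch3$mass, 12 + 3 * 1.0078250319, tolerance = 1e-9)
})

test_that("benzene at depth 2 yields the 30 contiguous-arc fragments", {
  fs <- generate_fragments(parse_structure("c1ccccc1"), 2L)
  proper <- Filter(function(f) f$matchable, fs$fragments)
  expect_length(proper, 30L)
  # arcs of 1..5 atoms, 6 start positions each
  sizes <- table(vapply(proper, function(f) length(f$atoms), integer(1)))
  expect_equal(unname(c(sizes)), rep(6L, 5L))
})

test_that("depth 0 returns only the parent and disconnected input errors", {
  fs <- generate_fragments(parse_structure("CCO"), 0L)
  expect_length(fs$fragments, 1L)
  expect_false(fs$fragments[[1]]$matchable)
  expect_equal(fs$fragments[[1]]$bde, 0)
  expect_error(generate_fragments(parse_structure("[Na+].CC([O-])=O"), 1L),
               "not connected")
})

test_that("fragment enumeration matches the brute-force oracle on small molecules", {
  lib <- make_toy_library()
  small <- Filter(function(r) {
    is_connected(r$structure) && n_atoms(r$structure) <= 8L
  }, unclass(lib))
  expect_gt(length(small), 10)
  for (r in small) {
    for (depth in 1:2) {
      got <- fragset_keys(generate_fragments(r$structure, depth))
      want <- oracle_fragments(r$structure, depth)
      expect_equal(names(got), names(want),
                   label = paste0(r$id, " depth ", depth, " keys"))
      expect_equal(unname(got), unname(want), tolerance = 1e-9,
                   label = paste0(r$id, " depth ", depth, " energies"))
    }
  }
})

test_that("fragment sets grow monotonically with depth", {
  for (id in c("TRZ_TERB", "SUL_MES", "ACETONE")) {
    r <- toy_record(id)
    k1 <- names(fragset_keys(generate_fragments(r$structure, 1L)))
    k2 <- names(fragset_keys(generate_fragments(r$structure, 2L)))
    expect_true(all(k1 %in% k2), label = id)
  }
})

test_that("every fragment formula is a sub-formula of the parent", {
  r <- toy_record("SUL_MES")
  fs <- generate_fragments(r$structure, 2L)
  parent <- molecular_formula(r$structure)
  for (f in fs$fragments) {
    ff <- fragment_formula(f, r$structure)
    expect_true(all(names(ff) %in% names(parent)))
    expect_true(all(unclass(ff) <= unclass(parent)[names(ff)]))
  }
})

test_that("complementary fragments of one acyclic cleavage sum to the parent mass", {
  r <- toy_record("BUOH1")  # acyclic chain
  fs <- generate_fragments(r$structure, 1L)
  proper <- Filter(function(f) f$matchable, fs$fragments)
  parent_mass <- r$mass
  n <- n_atoms(r$structure)
  for (f in proper) {
    comp <- Filter(function(g) {
      length(g$atoms) == n - length(f$atoms) &&
        !any(g$atoms %in% f$atoms)
    }, proper)
    expect_true(any(vapply(comp, function(g) {
      abs(f$mass + g$mass - parent_mass) < 1e-9
    }, logical(1))), label = paste("complement of", paste(f$atoms, collapse = ",")))
  }
  expect_equal(fs$fragments[[length(fs$fragments)]]$mass, parent_mass,
               tolerance = 1e-9)
})

test_that("duplicate fragments keep the minimal cumulative energy", {
  # in a ring, each arc is reachable by cutting two bonds in either order;
  # the stored energy must be the cheapest total over all paths
  r <- toy_record("PYRIDINE")
  got <- fragset_keys(generate_fragments(r$structure, 2L))
  want <- oracle_fragments(r$structure, 2L)
  expect_equal(unname(got), unname(want), tolerance = 1e-9)
})
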