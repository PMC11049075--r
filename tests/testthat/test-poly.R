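test_that("monomials recover the Markov-blanket counting identity", {
  p <- make_monomial(c("a1", "a2"), c("s1", "s2", "s3"))
  expect_length(p$positions, 2)
  expect_length(total_set(p), 6) # |A x S|
  expect_length(total_set(poly_y()), 1)
  expect_length(total_set(make_monomial("u1", c("o1", "o2"))), 2)
  p2 <- polynomial(c("i", "j"), list(i = c("d1", "d2"), j = c("e1", "e2", "e3")))
  expect_length(total_set(p2), 5)
  expect_error(make_monomial(character(), "s1"), "non-empty")
})

test_that("tensor multiplies positions and directions", {
  m <- make_monomial(c("a1", "a2"), c("s1", "s2", "s3"))
  tm <- poly_tensor(m, m)
  expect_length(tm$positions, 4)
  expect_true(all(vapply(tm$directions, length, integer(1)) == 9))
  # y is the tensor unit (cardinality profile)
  ty <- poly_tensor(m, poly_y())
  expect_equal(poly_profile(ty)$positions, poly_profile(m)$positions)
  expect_equal(unname(poly_profile(ty)$profile), unname(poly_profile(m)$profile))
  # symmetry up to relabelling
  p <- polynomial(c("i", "j"), list(i = "d1", j = c("d1", "d2")))
  expect_equal(poly_profile(poly_tensor(p, m)), poly_profile(poly_tensor(m, p)))
})

test_that("tensor total-set cardinality is the double sum of products", {
  set.seed(21)
  for (i in 1:10) {
    np <- sample(1:3, 1); nq <- sample(1:3, 1)
    p <- polynomial(paste0("p", 1:np),
      lapply(stats::setNames(1:np, paste0("p", 1:np)),
        function(.) paste0("d", seq_len(sample(1:3, 1)))))
    q <- polynomial(paste0("q", 1:nq),
      lapply(stats::setNames(1:nq, paste0("q", 1:nq)),
        function(.) paste0("e", seq_len(sample(1:3, 1)))))
    sp <- vapply(p$directions, length, integer(1))
    sq <- vapply(q$directions, length, integer(1))
    expect_identical(length(total_set(poly_tensor(p, q))),
      as.integer(sum(outer(sp, sq))))
  }
})

test_that("morphism enumeration matches closed-form counts", {
  q <- polynomial(c("j1", "j2"), list(j1 = c("e1", "e2"), j2 = "e1"))
  # from y: backward into a singleton is unique, one morphism per target position
  expect_length(enumerate_morphisms(poly_y(), q), 2)
  # y^2 -> 2y: 2 forward choices x 2 backward choices
  p <- polynomial("i", list(i = c("d1", "d2")))
  two_y <- polynomial(c("j1", "j2"), list(j1 = "e", j2 = "e"))
  ms <- enumerate_morphisms(p, two_y)
  expect_length(ms, 4)
  for (a in seq_along(ms)) for (b in seq_along(ms)) {
    if (a < b) expect_false(same_morphism(ms[[a]], ms[[b]]))
  }
  # y -> y: identity only
  expect_length(enumerate_morphisms(poly_y(), poly_y()), 1)
  expect_error(enumerate_morphisms(p, two_y, cap = 3), "exceeds cap")
})

test_that("morphisms into y are the sections of the bundle", {
  for (p in poly_shape_grid(3, 3)) {
    sizes <- vapply(p$directions, length, integer(1))
    expect_length(enumerate_morphisms(p, poly_y()), prod(sizes))
  }
})

test_that("hom polynomials have the expected cardinality profiles", {
  q <- polynomial(c("j1", "j2"), list(j1 = c("e1", "e2"), j2 = "e1"))
  expect_equal(poly_profile(poly_hom(poly_y(), q)), poly_profile(q))
  expect_equal(poly_profile(poly_hom(poly_y(), poly_y())),
    poly_profile(poly_y()))
  # p = y^2 + y^3: [p, y] has prod(2, 3) = 6 positions, each with |p(1)| = 2
  # directions
  p <- polynomial(c("i", "j"), list(i = c("d1", "d2"), j = c("e1", "e2", "e3")))
  hp <- poly_hom(p, poly_y())
  expect_length(hp$positions, 6)
  expect_true(all(vapply(hp$directions, length, integer(1)) == 2))
})

test_that("curry_check profiles agree with explicit hom construction", {
  small <- list(
    polynomial("i", list(i = "d1")),
    polynomial("i", list(i = c("d1", "d2"))),
    polynomial(c("i", "j"), list(i = "d1", j = "d1")))
  for (p in small) for (q in small) for (r in small) {
    rep <- curry_check(p, q, r)
    left_explicit <- poly_profile(poly_hom(p, poly_hom(q, r)))
    right_explicit <- poly_profile(poly_hom(poly_tensor(p, q), r))
    expect_equal(rep$left$positions, left_explicit$positions)
    expect_equal(rep$left$profile, left_explicit$profile)
    expect_equal(rep$right$positions, right_explicit$positions)
    expect_equal(rep$right$profile, right_explicit$profile)
    expect_true(rep$isomorphic)
  }
})

test_that("currying holds across the small-polynomial grid", {
  grid <- poly_shape_grid(2, 2)
  for (p in grid) for (q in grid) for (r in grid) {
    expect_true(curry_check(p, q, r)$isomorphic)
  }
})

test_that("morphism composition is associative with identity units", {
  p <- polynomial("i", list(i = c("d1", "d2")))
  endos <- enumerate_morphisms(p, p)
  idp <- poly_identity(p)
  for (f in endos) {
    expect_true(same_morphism(compose_poly_morphism(f, idp), f))
    expect_true(same_morphism(compose_poly_morphism(idp, f), f))
    for (g in endos) for (h in endos) {
      lhs <- compose_poly_morphism(h, compose_poly_morphism(g, f))
      rhs <- compose_poly_morphism(compose_poly_morphism(h, g), f)
      expect_true(same_morphism(lhs, rhs))
    }
  }
})

test_that("run_system unrolls deterministic systems as forced", {
  iface <- make_monomial(c("c1", "c2"), c("in1", "in2"))
  const <- dynamical_system(c("s1", "s2"), iface,
    output = c(s1 = "c1", s2 = "c2"),
    update = list(s1 = c(in1 = "s1", in2 = "s1"), s2 = c(in1 = "s2", in2 = "s2")))
  tr <- run_system(const, rep("in1", 5), "s1")
  expect_equal(tr$state, rep("s1", 6))
  toggle <- dynamical_system(c("s1", "s2"), iface,
    output = c(s1 = "c1", s2 = "c2"),
    update = list(s1 = c(in1 = "s2", in2 = "s2"), s2 = c(in1 = "s1", in2 = "s1")))
  tr <- run_system(toggle, rep("in2", 4), "s1")
  expect_equal(tr$state, c("s1", "s2", "s1", "s2", "s1"))
  expect_equal(nrow(tr), 5)
})

test_that("run_system rejects inadmissible inputs, naming the step", {
  iface <- polynomial(c("c1", "c2"), list(c1 = "in1", c2 = "in2"))
  sys <- dynamical_system(c("s1", "s2"), iface,
    output = c(s1 = "c1", s2 = "c2"),
    update = list(s1 = c(in1 = "s2"), s2 = c(in2 = "s1")))
  expect_error(run_system(sys, c("in2"), "s1"), "step 1")
})

test_that("stochastic stay-probability matches the binomial oracle", {
  iface <- make_monomial("c", "go")
  stay <- matrix(c(0.9, 0.1), 2, 1, dimnames = list(c("s1", "s2"), "go"))
  leave <- matrix(c(0.9, 0.1), 2, 1, dimnames = list(c("s1", "s2"), "go"))
  sys <- dynamical_system(c("s1", "s2"), iface,
    output = c(s1 = "c", s2 = "c"),
    update = list(s1 = stoch_map(stay), s2 = stoch_map(leave)))
  tr <- run_system(sys, rep("go", 10000), "s1", seed = 77)
  frac_s1 <- mean(tr$state == "s1")
  # stationary P(s1) = 0.9; 3 sigma of a binomial proportion at n = 10000
  expect_lt(abs(frac_s1 - 0.9), 3 * sqrt(0.9 * 0.1 / 10000))
})
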