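two_agent_one_site <- function(vL = c(k1 = 1, k2 = 0), vR = c(k1 = 0, k2 = 1)) {
  cov <- cover(c("x1", "x2", "x3"),
    list(a = c("x1", "x2"), b = c("x2", "x3")))
  secs <- list(
    a = section("a", list(x1 = c(k1 = 0.5, k2 = 0.5), x2 = vL)),
    b = section("b", list(x2 = vR, x3 = c(k1 = 0.5, k2 = 0.5))))
  list(cov = cov, secs = secs)
}

test_that("restriction is functorial sub-indexing", {
  s <- section("a", list(x1 = c(k1 = 0.2, k2 = 0.8), x2 = c(k1 = 1, k2 = 0),
    x3 = c(k1 = 0.5, k2 = 0.5)))
  expect_equal(restrict_section(s, c("x1", "x2", "x3")), s)
  r1 <- restrict_section(restrict_section(s, c("x1", "x2")), "x1")
  expect_equal(r1, restrict_section(s, "x1"))
  expect_length(restrict_section(s, "x2")$data, 1)
  expect_error(restrict_section(s, "x9"), "outside")
})

test_that("disagreement energy matches hand computations", {
  w <- two_agent_one_site()
  rep <- disagreement(w$secs, w$cov)
  expect_equal(rep$energy, 2) # (1-0)^2 + (0-1)^2
  expect_equal(rep$max_discrepancy, 1)
  same <- two_agent_one_site(vL = c(k1 = 0.3, k2 = 0.7), vR = c(k1 = 0.3, k2 = 0.7))
  expect_equal(disagreement(same$secs, same$cov)$energy, 0)
  # disjoint patches: vacuously glueable
  cov <- cover(c("x1", "x2"), list(a = "x1", b = "x2"))
  secs <- list(a = section("a", list(x1 = c(k1 = 1, k2 = 0))),
    b = section("b", list(x2 = c(k1 = 0, k2 = 1))))
  rep <- disagreement(secs, cov)
  expect_equal(rep$energy, 0)
  expect_true(rep$vacuous)
})

test_that("gluing checks follow the fixture's controlled epsilon", {
  okw <- make_shared_world(3, 6, overlap = 1, epsilon = 0, seed = 2)
  chk <- check_gluing(okw$sections, okw$cover, tol = 1e-12)
  expect_true(chk$ok)
  pert <- make_shared_world(3, 6, overlap = 1, epsilon = 0.2, seed = 2)
  chk2 <- check_gluing(pert$sections, pert$cover, tol = 0.1)
  expect_false(chk2$ok)
  expect_equal(max(chk2$report$pairs$tv_dist), 0.2, tolerance = 1e-12)
  expect_true(check_gluing(pert$sections, pert$cover, tol = Inf)$ok)
})

test_that("gluing reproduces local sections on restriction", {
  w1 <- make_shared_world(1, 4, overlap = 0, epsilon = 0, seed = 3)
  g <- glue_sections(w1$sections, w1$cover)
  expect_equal(unclass(g)[w1$cover$base],
    w1$sections[[1]]$data[w1$cover$base])
  shared <- two_agent_one_site(vL = c(k1 = 0.4, k2 = 0.6),
    vR = c(k1 = 0.4, k2 = 0.6))
  g2 <- glue_sections(shared$secs, shared$cov)
  expect_equal(g2$x2, c(k1 = 0.4, k2 = 0.6))
  # three-patch path cover, consistent by construction
  w3 <- make_shared_world(3, 7, overlap = 2, epsilon = 0, seed = 5)
  g3 <- glue_sections(w3$sections, w3$cover, tol = 1e-12)
  for (j in names(w3$cover$patches)) {
    for (site in w3$cover$patches[[j]]) {
      expect_equal(g3[[site]], w3$sections[[j]]$data[[site]],
        tolerance = 1e-12)
    }
  }
  # failure carries the obstruction
  bad <- two_agent_one_site()
  expect_error(glue_sections(bad$secs, bad$cov), "do not glue")
})

test_that("consensus steps fix consistent sections and average overlaps", {
  same <- two_agent_one_site(vL = c(k1 = 0.3, k2 = 0.7), vR = c(k1 = 0.3, k2 = 0.7))
  out <- consensus_step(same$secs, same$cov, eta = 0.7)
  expect_equal(out, check <- same$secs[names(out)])
  w <- two_agent_one_site(vL = c(k1 = 0.8, k2 = 0.2), vR = c(k1 = 0.2, k2 = 0.8))
  out <- consensus_step(w$secs, w$cov, eta = 1)
  expect_equal(out$a$data$x2, c(k1 = 0.5, k2 = 0.5))
  expect_equal(out$b$data$x2, c(k1 = 0.5, k2 = 0.5))
  expect_error(consensus_step(w$secs, w$cov, eta = 0), "eta")
})

test_that("consensus follows the closed-form geometric decay", {
  w <- two_agent_one_site(vL = c(k1 = 0.9, k2 = 0.1), vR = c(k1 = 0.1, k2 = 0.9))
  res <- run_consensus(w$secs, w$cov, eta = 0.5, max_iter = 25, tol = 1e-6)
  e0 <- res$trace[1]
  # each step moves both vectors halfway to the midpoint: energy scales 1/4
  for (k in seq_along(res$trace)) {
    expect_equal(res$trace[k], e0 * 0.25^(k - 1), tolerance = 1e-10)
  }
  expect_true(res$converged)
  expect_lte(length(res$trace) - 1, 25)
  # limit is the renormalized mean of the initial vectors
  expect_equal(res$sections$a$data$x2, c(k1 = 0.5, k2 = 0.5), tolerance = 1e-3)
  # consistent input: trace is [0] and no iterations run
  same <- two_agent_one_site(vL = c(k1 = 0.3, k2 = 0.7), vR = c(k1 = 0.3, k2 = 0.7))
  res0 <- run_consensus(same$secs, same$cov)
  expect_equal(res0$trace, 0)
  expect_true(res0$converged)
})

test_that("consensus energy is non-increasing on seeded random scenarios", {
  for (s in 1:50) {
    w <- make_shared_world(3, 6, overlap = 1, epsilon = 0, seed = 100 + s)
    secs <- perturb_sections(w$sections, 0.5, seed = 200 + s)
    res <- run_consensus(secs, w$cover, eta = runif(1, 0.1, 1),
      max_iter = 30, tol = 1e-12)
    expect_true(all(diff(res$trace) <= 1e-12))
  }
})

test_that("spatial validation localizes inadmissible observation mass", {
  tm <- make_tmaze()
  chk <- validate_spatial_model(tm$model, tm$site_assignment, tm$admissibility)
  expect_true(chk$ok)
  # everything admissible everywhere passes trivially
  all_ok <- validate_spatial_model(tm$model, tm$site_assignment,
    stats::setNames(rep(list(tm$model$obs), 4), names(tm$admissibility)))
  expect_true(all_ok$ok)
  # corrupt A: cue signal leaking at the center site
  A <- tm$model$A
  A["cue-left", "center.L"] <- 0.1
  A["start", "center.L"] <- 0.9
  bad <- generative_model(stoch_map(A), tm$model$B, tm$model$C, tm$model$D)
  chk2 <- validate_spatial_model(bad, tm$site_assignment, tm$admissibility)
  expect_false(chk2$ok)
  expect_true(any(chk2$violations$state == "center.L" &
    chk2$violations$observation == "cue-left"))
  expect_equal(chk2$violations$mass[1], 0.1)
})
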