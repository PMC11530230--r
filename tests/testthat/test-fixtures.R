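# Synthetic generators: determinism, geometry, labels.

test_that("chain building is deterministic with ideal helical geometry", {
  h1 <- build_chain(rep(deg2rad(-57), 15L), rep(deg2rad(-47), 15L))
  h2 <- build_chain(rep(deg2rad(-57), 15L), rep(deg2rad(-47), 15L))
  expect_identical(h1$coords, h2$coords)
  ca <- h1$coords$CA
  # alpha-helical i,i+3 CA packing near 5 A
  d3 <- sqrt(rowSums((ca[4:15, ] - ca[1:12, ])^2))
  expect_true(all(abs(d3 - 5.2) < 0.4))
  # extended chains grow monotonically with length
  e2e <- vapply(c(8L, 16L, 24L), function(L) {
    cf <- build_chain(rep(deg2rad(-139), L), rep(deg2rad(135), L))
    sqrt(sum((cf$coords$CA[L, ] - cf$coords$CA[1L, ])^2))
  }, numeric(1L))
  expect_true(all(diff(e2e) > 0))
})

test_that("generated ensembles are seeded-deterministic with exact labels", {
  specs <- list(family_spec("coil", count = 5L),
                family_spec("turn_segment", segment = c(6L, 15L), count = 4L),
                family_spec("longrange_contact", contact_pair = c(5L, 22L),
                            count = 3L))
  a <- make_ensemble(specs, strrep("A", 27L), seed = 99L)
  b <- make_ensemble(specs, strrep("A", 27L), seed = 99L)
  expect_identical(a$labels, c(rep(1L, 5L), rep(2L, 4L), rep(3L, 3L)))
  for (k in seq_len(a$ensemble$n))
    expect_identical(a$ensemble$conformations[[k]]$coords,
                     b$ensemble$conformations[[k]]$coords)
  # every generated conformation passes the structural invariants
  for (cf in a$ensemble$conformations)
    expect_silent(validate_conformation(cf))
})

test_that("long-range closure pulls the designated pair below 6 A while coil stays far", {
  lr <- make_ensemble(list(family_spec("longrange_contact",
                                       contact_pair = c(5L, 22L),
                                       count = 15L)),
                      strrep("A", 27L), seed = 31L)
  d_lr <- vapply(lr$ensemble$conformations, interaction_distance,
                 numeric(1L), i = 5L, j = 22L)
  expect_true(all(d_lr < 6))
  coil <- make_ensemble(list(family_spec("coil", count = 30L)),
                        strrep("A", 27L), seed = 31L)
  d_coil <- vapply(coil$ensemble$conformations, interaction_distance,
                   numeric(1L), i = 5L, j = 22L)
  expect_gt(mean(d_coil), 10)
  # an impossible closure must fail loudly with diagnostics
  expect_error(make_ensemble(list(family_spec("longrange_contact",
                                              contact_pair = c(1L, 27L),
                                              count = 1L)),
                             strrep("A", 27L), seed = 1L, max_tries = 3L),
               "rejection sampling")
})

test_that("the reference set mixes structure kinds and concentrates helical orientations", {
  expect_error(make_reference_set(0L), "positive")
  ref <- make_reference_set(25L, seed = 14L)
  expect_length(ref, 25L)
  # helix-rich reference: range-4 relative orientations far from uniform.
  # Chordal-mean resultant length of a uniform rotation sample is near 0;
  # concentrated orientations push the top eigenvalue of the quaternion
  # outer-product mean well above the uniform value of 1/4.
  obs <- wfcm:::.collect_observations(ref, 14)
  q <- obs$q[["ANY:ANY:4"]]
  keep <- obs$d[["ANY:ANY:4"]] <= 8
  ev <- eigen(crossprod(q[keep, , drop = FALSE]) / sum(keep),
              symmetric = TRUE)$values[1L]
  set.seed(1)
  qu <- wfcm:::runif_quat(sum(keep))
  ev_unif <- eigen(crossprod(qu) / nrow(qu), symmetric = TRUE)$values[1L]
  expect_gt(ev, ev_unif + 0.1)
})

test_that("planted observations encode their ground truth", {
  obs <- make_planted_observations(2000L, interval = c(5, 8),
                                   sigma_theta = 0.15, seed = 4L)
  # the stated interval holds ~60% of the distances
  frac <- mean(obs$d >= 5 & obs$d <= 8)
  expect_lt(abs(frac - 0.6), 0.05)
  # angular deviations from the planted rotation have the stated scale
  th <- wfcm:::quat_angle(obs$quat, obs$truth$q_pref)
  expect_lt(abs(sqrt(mean(th^2)) - 0.15), 0.03)
})
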