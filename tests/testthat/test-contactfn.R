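# The continuous contact function and its parameter estimation.

test_that("range classes follow sequence separation with long at 5+", {
  expect_identical(range_class(c(1L, 2L, 3L, 4L, 5L, 11L)),
                   c("1", "2", "3", "4", "long", "long"))
  expect_error(range_class(0L))
})

test_that("contact value is a cosine ramp with exact edge values", {
  p <- structure(list(d_lo = 5, d_hi = 8, q_pref = NULL, theta_max = NULL,
                      alpha_max = 1.5, support = 10L), class = "pair_params")
  expect_identical(contact_value(5, p), 1)
  expect_identical(contact_value(8, p), 0)
  expect_equal(contact_value(6.5, p), 0.5, tolerance = 1e-12)
  expect_identical(contact_value(2, p), 1)
  expect_identical(contact_value(12, p), 0)
  # strictly decreasing across the interval
  g <- contact_value(seq(5, 8, length.out = 50L), p)
  expect_true(all(diff(g) < 0))
})

test_that("pose distance equals the Euclidean distance for unoriented ranges and honors the contracts", {
  p <- structure(list(d_lo = 5, d_hi = 8, q_pref = c(1, 0, 0, 0),
                      theta_max = 0.8, alpha_max = 1.5, support = 10L),
                 class = "pair_params")
  pose <- list(d = 6.5, theta = 0.2)
  expect_identical(pose_distance(pose, p, "long"), 6.5)
  expect_identical(pose_distance(pose, p, "1"), 6.5)
  # aligned pose within the interval: full bonus
  expect_equal(pose_distance(list(d = 6.5, theta = 0), p, "3"),
               6.5 - p$alpha_max, tolerance = 1e-12)
  # monotone in theta below theta_max
  ds <- vapply(c(0.1, 0.4, 0.7), function(th)
    pose_distance(list(d = 6.5, theta = th), p, "3"), numeric(1L))
  expect_true(all(diff(ds) > 0))
  # no bonus at or beyond theta_max, or beyond the faded interval
  expect_identical(pose_distance(list(d = 6.5, theta = 0.8), p, "3"), 6.5)
  expect_identical(pose_distance(list(d = 10.1, theta = 0), p, "3"), 10.1)
})

test_that("relative pose theta matches the quaternion angle for random rotations", {
  set.seed(3)
  for (i in 1:25) {
    R1 <- random_rotation(i); R2 <- random_rotation(50L + i)
    qp <- wfcm:::runif_quat(1L)
    p <- structure(list(d_lo = 5, d_hi = 8, q_pref = as.vector(qp),
                        theta_max = 1, alpha_max = 1, support = 1L),
                   class = "pair_params")
    pose <- relative_pose(list(rotation = R1), list(rotation = R2), 6, p)
    qij <- wfcm:::rot_to_quat(crossprod(R1, R2))
    expect_equal(pose$theta, 2 * acos(min(1, abs(sum(qij * qp)))),
                 tolerance = 1e-9)
  }
  # identity and half-turn extremes
  p <- structure(list(d_lo = 5, d_hi = 8, q_pref = c(1, 0, 0, 0),
                      theta_max = 1, alpha_max = 1, support = 1L),
                 class = "pair_params")
  expect_equal(relative_pose(list(rotation = diag(3)),
                             list(rotation = diag(3)), 6, p)$theta, 0)
  half <- diag(c(1, -1, -1))  # pi rotation about x
  expect_equal(relative_pose(list(rotation = diag(3)),
                             list(rotation = half), 6, p)$theta, pi,
               tolerance = 1e-9)
})

test_that("planted interval and preferred rotation are recovered by the estimator", {
  obs <- make_planted_observations(3000L, interval = c(6, 9),
                                   sigma_theta = 0.2, seed = 11L)
  p <- estimate_pair_params(obs$d, obs$quat)
  expect_lt(abs(p$d_lo - 6), 0.5)
  expect_lt(abs(p$d_hi - 9), 0.5)
  expect_lt(wfcm:::quat_angle(matrix(p$q_pref, 1L), obs$truth$q_pref), 0.1)
  expect_true(p$alpha_max <= p$d_lo && p$alpha_max >= 0)
})

test_that("degenerate single-observation estimation brackets the observation", {
  p <- estimate_pair_params(7.2)
  expect_lt(p$d_lo, 7.2)
  expect_gt(p$d_hi, 7.2)
  expect_identical(p$support, 1L)
})

test_that("table estimation from helical toy references concentrates short-range geometry", {
  # ideal alpha-helices with small noise as the whole reference set
  set.seed(21)
  ref <- lapply(1:30, function(s) {
    L <- 20L
    build_chain(deg2rad(-57) + rnorm(L, 0, 0.08),
                deg2rad(-47) + rnorm(L, 0, 0.08),
                sample(c("A", "L", "E", "K"), L, replace = TRUE))
  })
  tab <- estimate_parameters(ref, settings = list(min_support = 1e9))
  for (rc in c("3", "4")) {
    p <- resolve_params(tab, "A", "A", rc)
    expect_lt(p$d_hi, 9)
    expect_gt(p$d_hi, p$d_lo)
    expect_lt(p$theta_max, pi / 2)  # tightly clustered helical orientations
  }
  expect_error(estimate_parameters(list()), "empty")
})

test_that("parameter tables resolve with swap symmetry and pooled backoff", {
  set.seed(8)
  ref <- make_reference_set(60L, seed = 8L)
  tab <- estimate_parameters(ref, settings = list(min_support = 40L))
  keys <- names(tab$entries)
  pair_keys <- keys[!grepl("^ANY", keys)]
  expect_gt(length(pair_keys), 0L)
  k <- strsplit(pair_keys[1L], ":", fixed = TRUE)[[1L]]
  a <- resolve_params(tab, k[1L], k[2L], k[3L])
  b <- resolve_params(tab, k[2L], k[1L], k[3L])
  expect_identical(a$d_lo, b$d_lo)
  expect_identical(a$d_hi, b$d_hi)
  if (!is.null(a$q_pref)) {
    # swapped query sees the inverse preferred rotation
    expect_equal(wfcm:::quat_mult(matrix(a$q_pref, 1L), matrix(b$q_pref, 1L)),
                 matrix(c(1, 0, 0, 0), 1L), tolerance = 1e-12)
  }
  # a pair never observed resolves through the pooled entry
  pooled <- resolve_params(tab, "W", "W", "long")
  expect_identical(pooled$d_lo, tab$entries[["ANY:ANY:long"]]$d_lo)
})

test_that("serialization round-trips contact values exactly", {
  tab <- toy_table()
  f <- tempfile(fileext = ".json")
  write_param_table(tab, f)
  tab2 <- read_param_table(f)
  set.seed(99)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  n_eval <- 10000L
  a1 <- sample(aas, n_eval, replace = TRUE)
  a2 <- sample(aas, n_eval, replace = TRUE)
  rc <- sample(c("1", "2", "3", "4", "long"), n_eval, replace = TRUE)
  d <- runif(n_eval, 1, 14)
  th <- runif(n_eval, 0, pi)
  w1 <- w2 <- numeric(n_eval)
  for (i in seq_len(n_eval)) {
    p1 <- resolve_params(tab, a1[i], a2[i], rc[i])
    p2 <- resolve_params(tab2, a1[i], a2[i], rc[i])
    pose <- list(d = d[i], theta = th[i])
    w1[i] <- contact_value(pose_distance(pose, p1, rc[i]), p1)
    w2[i] <- contact_value(pose_distance(pose, p2, rc[i]), p2)
  }
  expect_identical(w1, w2)
})

test_that("equal-distance pairs with better orientation score strictly higher", {
  # two Ala-Ala pairs at range 4 with the same 7.4 A separation: the one
  # aligned with the preferred rotation must win
  tab <- toy_table()
  p <- resolve_params(tab, "A", "A", "4")
  expect_false(is.null(p$q_pref))  # the bundled table carries range-4 orientations
  d <- 7.4
  aligned <- contact_value(pose_distance(list(d = d, theta = 0), p, "4"), p)
  misaligned <- contact_value(
    pose_distance(list(d = d, theta = min(pi, p$theta_max * 1.5)), p, "4"), p)
  expect_gt(aligned, misaligned)
})

test_that("long-range and range-1 contacts depend on distance only", {
  tab <- toy_table()
  conf <- one_conformation(14L)
  # twist one residue's frame in place: move its N around CA without
  # touching CA or CB, so distances are fixed but the frame rotates
  twist <- conf
  ca <- twist$coords$CA[1L, ]
  nvec <- twist$coords$N[1L, ] - ca
  R <- random_rotation(13L)
  twist$coords$N[1L, ] <- ca + as.vector(R %*% nvec)
  for (pr in list(c(1L, 14L), c(1L, 2L))) {      # long range and range 1
    expect_equal(pair_contact(conf, pr[1L], pr[2L], tab),
                 pair_contact(twist, pr[1L], pr[2L], tab), tolerance = 1e-12)
  }
  # determinism: identical evaluation twice is bitwise equal
  expect_identical(pair_contact(conf, 2L, 9L, tab),
                   pair_contact(conf, 2L, 9L, tab))
})
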