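# Feature matrices: shapes, oracles, invariances.

test_that("feature matrices have L(L-1)/2 lexicographic columns and the right ranges", {
  syn <- small_two_family(6L)
  tab <- toy_table()
  fo <- featurize_omega(syn$ensemble, tab)
  fd <- featurize_distance(syn$ensemble)
  L <- syn$ensemble$L
  expect_identical(ncol(fo$values), L * (L - 1L) %/% 2L)
  expect_identical(dim(fo$values), dim(fd$values))
  expect_identical(fo$pairs[1L, ], c(i = 1L, j = 2L))
  expect_identical(fo$pairs[nrow(fo$pairs), ], c(i = L - 1L, j = L))
  expect_true(all(fo$values >= 0 & fo$values <= 1))
  expect_true(all(fd$values > 0))
})

test_that("omega featurization equals the per-pair contact composition", {
  syn <- small_two_family(3L, seed = 9L)
  tab <- toy_table()
  fo <- featurize_omega(syn$ensemble, tab)
  for (k in seq_len(syn$ensemble$n)) {
    conf <- syn$ensemble$conformations[[k]]
    fr <- build_frames(conf)
    for (p in sample(nrow(fo$pairs), 40L)) {
      i <- fo$pairs[p, 1L]; j <- fo$pairs[p, 2L]
      expect_equal(fo$values[k, p], pair_contact(conf, i, j, tab, frames = fr),
                   tolerance = 1e-12)
    }
  }
})

test_that("featurizers are row-wise independent and translation invariant", {
  syn <- small_two_family(4L, seed = 31L)
  ens <- syn$ensemble
  tab <- toy_table()
  fo <- featurize_omega(ens, tab)
  # permuting conformations permutes rows identically
  perm <- c(3L, 1L, 4L, 2L, 8L, 5L, 7L, 6L)
  ens_p <- ens
  ens_p$conformations <- ens$conformations[perm]
  fo_p <- featurize_omega(ens_p, tab)
  expect_identical(fo_p$values, fo$values[perm, ])
  # duplicating a conformation duplicates its row exactly
  ens_d <- ens
  ens_d$conformations <- ens$conformations[c(1L, 1L)]
  ens_d$n <- 2L
  fo_d <- featurize_omega(ens_d, tab)
  expect_identical(fo_d$values[1L, ], fo_d$values[2L, ])
  # rigid translation leaves distance features unchanged
  ens_t <- ens
  ens_t$conformations <- lapply(ens$conformations, apply_rigid,
                                R = diag(3L), t = c(10, -4, 2))
  expect_equal(featurize_distance(ens_t)$values,
               featurize_distance(ens)$values, tolerance = 1e-9)
})

test_that("LJ featurization matches a brute-force atom-pair sum on a toy chain", {
  conf <- build_chain(rep(deg2rad(-120), 3L), rep(deg2rad(130), 3L),
                      c("A", "A", "A"))
  ens <- structure(list(sequence = "AAA", conformations = list(conf),
                        provenance = character(), n = 1L, L = 3L),
                   class = "ensemble")
  lj <- featurize_lj(ens)
  pars <- default_lj_params()
  sig <- setNames(pars$sigma, pars$class)
  eps <- setNames(pars$epsilon, pars$class)
  cls <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
  # topology indices for the bonded-pair exclusion (see featurize_lj)
  tpos <- c(N = 0, CA = 1, C = 2, O = 2, CB = 1)
  tbr <- c(N = 0, CA = 0, C = 0, O = 1, CB = 1)
  brute <- function(i, j) {
    v <- 0
    for (a in names(cls)) for (b in names(cls)) {
      pa <- conf$coords[[a]][i, ]; pb <- conf$coords[[b]][j, ]
      if (anyNA(pa) || anyNA(pb)) next
      bonds <- abs((3 * (i - 1) + tpos[[a]]) - (3 * (j - 1) + tpos[[b]])) +
        tbr[[a]] + tbr[[b]]
      if (bonds <= 3) next
      r <- sqrt(sum((pa - pb)^2))
      if (r >= 10) next
      s <- (sig[[cls[[a]]]] + sig[[cls[[b]]]]) / 2
      e <- sqrt(eps[[cls[[a]]]] * eps[[cls[[b]]]])
      v <- v + 4 * e * ((s / r)^12 - (s / r)^6) -
        4 * e * ((s / 10)^12 - (s / 10)^6)
    }
    v
  }
  expect_equal(lj$values[1L, 1L], brute(1L, 2L), tolerance = 1e-9)
  expect_equal(lj$values[1L, 2L], brute(1L, 3L), tolerance = 1e-9)
  expect_equal(lj$values[1L, 3L], brute(2L, 3L), tolerance = 1e-9)
})

test_that("residue pairs fully beyond the LJ cutoff contribute exactly zero", {
  ext <- build_chain(rep(deg2rad(-139), 12L), rep(deg2rad(135), 12L))
  ens <- structure(list(sequence = strrep("A", 12L),
                        conformations = list(ext), provenance = character(),
                        n = 1L, L = 12L), class = "ensemble")
  lj <- featurize_lj(ens)
  far <- which(lj$pairs[, 2L] - lj$pairs[, 1L] >= 8L)
  expect_true(all(lj$values[1L, far] == 0))
})

test_that("the naive binary map is the symmetric fraction of sub-threshold conformations", {
  syn <- small_two_family(10L, seed = 17L)
  ens <- syn$ensemble
  map <- mean_binary_contact_map(ens, threshold = 8)
  expect_identical(dim(map), c(ens$L, ens$L))
  expect_true(all(map >= 0 & map <= 1))
  expect_identical(map, t(map))
  expect_true(all(diag(map) == 0))
  # direct count oracle on an arbitrary pair
  i <- 4L; j <- 18L
  cnt <- sum(vapply(ens$conformations, function(cf)
    interaction_distance(cf, i, j) <= 8, logical(1L)))
  expect_identical(map[i, j], cnt / ens$n)
  # identical conformations give entries in {0, 1}
  ens1 <- ens
  ens1$conformations <- ens$conformations[rep(1L, 5L)]
  ens1$n <- 5L
  m1 <- mean_binary_contact_map(ens1)
  expect_true(all(m1 %in% c(0, 1)))
})
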