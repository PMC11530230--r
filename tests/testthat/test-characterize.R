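# Cluster maps, weights, descriptors and the report writer.

test_that("cluster maps are row-mean reshapes with exact occupancy weights", {
  syn <- small_two_family(8L, seed = 41L)
  fm <- featurize_omega(syn$ensemble, toy_table())
  members <- c(2L, 5L, 9L)
  map <- cluster_contact_map(fm, members)
  mu <- colMeans(fm$values[members, ])
  expect_equal(map$values[fm$pairs], mu, tolerance = 1e-15)
  expect_identical(map$values, t(map$values))
  expect_true(all(diag(map$values) == 0))
  expect_identical(map$weight, 3L / fm$n)
  expect_error(cluster_contact_map(fm, integer()), "empty")
  expect_error(cluster_contact_map(featurize_distance(syn$ensemble), 1L),
               "omega")
  # two members averaging 0.2 and 0.4 give exactly 0.3
  fm2 <- fm
  fm2$values[1L, 1L] <- 0.2
  fm2$values[2L, 1L] <- 0.4
  expect_equal(cluster_contact_map(fm2, c(1L, 2L))$values[1L, 2L], 0.3,
               tolerance = 1e-12)
  # full-ensemble cluster has weight exactly 1
  expect_identical(cluster_contact_map(fm, seq_len(fm$n))$weight, 1)
})

test_that("characterization conserves mass and orders maps by weight", {
  syn <- small_two_family(20L, seed = 19L)
  fm <- featurize_omega(syn$ensemble, toy_table())
  labels <- c(rep(1L, 12L), rep(2L, 20L), rep(0L, 8L))
  asn <- structure(list(labels = labels, K = 2L,
                        min_cluster_fraction = 0.1,
                        cluster_sizes = c(12L, 20L)),
                   class = "cluster_assignment")
  ch <- characterize_ensemble(fm, asn)
  expect_identical(sum(ch$weights) + ch$noise_fraction, 1)
  expect_true(all(diff(ch$weights) <= 0))
  expect_identical(ch$maps[[1L]]$cluster_id, 2L)  # the bigger cluster first
  # brute-force oracle for each map
  for (m in ch$maps) {
    mem <- which(labels == m$cluster_id)
    mu <- colMeans(fm$values[mem, , drop = FALSE])
    expect_equal(m$values[fm$pairs], mu, tolerance = 1e-12)
  }
  # merging two clusters gives the weight-weighted mean of their maps
  merged <- cluster_contact_map(fm, which(labels %in% c(1L, 2L)))
  blend <- (12 * ch$maps[[2L]]$values + 20 * ch$maps[[1L]]$values) / 32
  expect_equal(merged$values, blend, tolerance = 1e-12)
  expect_error(characterize_ensemble(fm, structure(list(labels = 1L, K = 1L),
                                                   class = "cluster_assignment")),
               "do not match")
})

test_that("radius of gyration matches the closed-form mass-weighted formula", {
  # a bare CA chain on a line: hand-computable
  conf <- structure(list(aa = c("G", "G", "G"),
                         coords = list(CA = rbind(c(0, 0, 0), c(3, 0, 0),
                                                  c(6, 0, 0))),
                         residue_ids = 1:3), class = "conformation")
  # equal masses on a line at 0, 3, 6: center 3, rg = sqrt(mean(9, 0, 9))
  expect_equal(radius_of_gyration(conf), sqrt(6), tolerance = 1e-12)
  # identical conformations give rg_sd of 0
  syn <- small_two_family(3L, seed = 77L)
  ens1 <- syn$ensemble
  ens1$conformations <- ens1$conformations[rep(1L, 4L)]
  ens1$n <- 4L
  d <- cluster_descriptors(ens1, 1:4)
  expect_identical(d$rg_sd, 0)
  expect_gt(d$rg_mean, 0)
})

test_that("descriptor propensities sum to one and detect planted helices", {
  syn <- make_ensemble(list(
    family_spec("helix_segment", segment = c(8L, 20L), count = 12L),
    family_spec("coil", count = 12L)), strrep("A", 27L), seed = 3L)
  helix_d <- cluster_descriptors(syn$ensemble, which(syn$labels == 1L))
  coil_d <- cluster_descriptors(syn$ensemble, which(syn$labels == 2L))
  expect_equal(rowSums(helix_d$ss_propensity), rep(1, 27L), tolerance = 1e-9)
  expect_gt(mean(helix_d$ss_propensity[10:18, "helix"]), 0.8)
  expect_lt(mean(coil_d$ss_propensity[10:18, "helix"]), 0.2)
  # end-to-end is the CA(1)-CA(L) distance
  cf <- syn$ensemble$conformations[[1L]]
  d1 <- cluster_descriptors(syn$ensemble, 1L)
  expect_equal(d1$end_to_end_mean,
               sqrt(sum((cf$coords$CA[27L, ] - cf$coords$CA[1L, ])^2)),
               tolerance = 1e-12)
})

test_that("the report writes a consistent summary, maps, samples and labels", {
  syn <- small_two_family(15L, seed = 55L)
  fm <- featurize_omega(syn$ensemble, toy_table())
  labels <- c(rep(1L, 18L), rep(2L, 10L), rep(0L, 2L))
  asn <- structure(list(labels = labels, K = 2L, min_cluster_fraction = 0.1,
                        cluster_sizes = c(18L, 10L)),
                   class = "cluster_assignment")
  ch <- characterize_ensemble(fm, asn)
  out <- file.path(tempdir(), "wfcm_report_test")
  write_report(ch, syn$ensemble, asn, out, n_samples = 4L, seed = 1L)
  summ <- jsonlite::read_json(file.path(out, "summary.json"))
  w <- sum(vapply(summ$clusters, function(cl) cl$weight, numeric(1L)))
  expect_equal(w + summ$noise_fraction, 1, tolerance = 1e-12)
  expect_true(file.exists(file.path(out, "labels.csv")))
  expect_true(file.exists(file.path(out, "naive_binary_map.png")))
  for (k in 1:2) {
    pdb <- file.path(out, sprintf("cluster%02d_samples.pdb", k))
    expect_true(file.exists(pdb))
    expect_lte(sum(grepl("^MODEL", readLines(pdb))), 4L)
  }
  lab2 <- utils::read.csv(file.path(out, "labels.csv"))
  expect_identical(lab2$label, labels)
})
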