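# Shared fixtures. The bundled toy parameter table is used wherever a table
# is needed but its values are not under test; small ensembles are built in
# code with fixed seeds.

toy_table <- function() default_param_table()

# a small labelled two-family ensemble for pipeline-level tests
small_two_family <- function(n_per = 40L, seed = 123L) {
  make_ensemble(list(
    family_spec("coil", count = n_per),
    family_spec("helix_segment", segment = c(8L, 20L), count = n_per)),
    strrep("A", 27L), seed = seed)
}

# a single deterministic mixed-sequence conformation
one_conformation <- function(L = 12L, seed = 5L) {
  set.seed(seed)
  di <- list(phi = deg2rad(stats::runif(L, -150, -50)),
             psi = deg2rad(stats::runif(L, -60, 160)))
  aa <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], L, replace = TRUE)
  build_chain(di$phi, di$psi, aa)
}

# random rigid motion applied to every atom of a conformation
apply_rigid <- function(conf, R, t = c(0, 0, 0)) {
  conf$coords <- lapply(conf$coords, function(m) {
    out <- m %*% t(R)
    sweep(out, 2L, -t)
  })
  conf
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}
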