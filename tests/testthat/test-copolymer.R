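test_that("block specs and chain building satisfy their contracts", {
  # single coil block: all beads coil
  conf <- build_chain(block_spec(data.frame(kind = "coil", n_beads = 7)), 16)
  expect_false(any(conf$rod))
  expect_equal(nrow(conf$coords), 7)
  # minimal (rod 1, coil 1) chain
  conf <- build_chain(block_spec(data.frame(kind = c("rod", "coil"),
                                            n_beads = c(1, 1))), 8)
  expect_equal(attr(conf, "rod_fraction"), 0.5)
  expect_equal(length(conf$rod), 2)
  # default composition: rod fraction exactly 12%
  expect_equal(attr(default_block_spec(2), "rod_fraction"), 0.12)
  # chains too long for the box are rejected
  expect_error(build_chain(block_spec(data.frame(kind = "coil",
                                                 n_beads = 200)), 4),
               "lattice")
  expect_error(block_spec(data.frame(kind = "blob", n_beads = 3)), "rod")
})

test_that("energy matches hand-computed cases and the compiled engine", {
  p <- sim_params(16, epsilon_rr = 1, kappa_rod = 2, n_steps = 0, seed = 1)
  # straight chain: no bends, no contacts
  conf <- build_chain(block_spec(data.frame(kind = "rod", n_beads = 10)), 16)
  expect_equal(chain_energy(conf, p), 0)
  # two rod segments, one lattice contact between non-bonded rods:
  # U-shape rod-coil-coil-rod where beads 1 and 4 are adjacent
  conf <- as_conformation(rbind(c(1, 1, 1), c(2, 1, 1), c(2, 2, 1),
                                c(1, 2, 1)),
                          rod = c(TRUE, FALSE, FALSE, TRUE), 8)
  pc <- sim_params(8, epsilon_rr = 1, kappa_rod = 0, n_steps = 0, seed = 1)
  expect_equal(chain_energy(conf, pc), -1)
  # right angle at a rod bead costs kappa
  conf <- as_conformation(rbind(c(1, 1, 1), c(2, 1, 1), c(2, 2, 1)),
                          rod = c(FALSE, TRUE, FALSE), 8)
  pk <- sim_params(8, epsilon_rr = 0, kappa_rod = 2, n_steps = 0, seed = 1)
  expect_equal(chain_energy(conf, pk), 2)
  # the compiled engine agrees with the R energy on evolved chains
  conf <- build_chain(default_block_spec(1, spacer_beads = 100), 24)
  warm <- run_mc(conf, sim_params(24, 2, 1, 5e4, seed = 5))
  p2 <- sim_params(24, 2, 1, 0, seed = 6)
  expect_equal(run_mc(warm$final, p2)$energy,
               chain_energy(warm$final, p2))
})

test_that("zero steps return the input and athermal acceptance is high", {
  conf <- build_chain(default_block_spec(1, spacer_beads = 50), 24)
  tr <- run_mc(conf, sim_params(24, 3, 2, 0, seed = 2))
  expect_identical(tr$final$coords, conf$coords)
  tr <- run_mc(conf, sim_params(24, 0, 0, 2e5, seed = 3))
  expect_gt(tr$acceptance_rate, 0.2)
  # reproducible from seed
  p <- sim_params(24, 1, 1, 1e4, seed = 11)
  expect_identical(run_mc(conf, p)$final$coords,
                   run_mc(conf, p)$final$coords)
})

test_that("domain metrics handle canonical shapes", {
  # all rods in one adjacent block: a single domain holding everything
  conf <- as_conformation(cbind(1:10, rep(1, 10), rep(1, 10)),
                          rod = rep(TRUE, 10), 16)
  dm <- domain_metrics(conf)
  expect_equal(dm$n_domains, 1)
  expect_equal(dm$largest_domain_fraction, 1)
  # a straight rod segment is maximally aspherical (a line)
  expect_equal(dm$domain_asphericity, 1, tolerance = 1e-12)
  # two far-apart compact rod balls: two near-spherical domains
  # (domain metrics act on rod positions, so a direct construction is fine)
  ball1 <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  ball2 <- ball1 + 10
  conf2 <- structure(list(coords = rbind(ball1, ball2),
                          rod = rep(TRUE, 16), lattice_size = 32L),
                     class = "copolymer_conformation")
  dm2 <- domain_metrics(conf2)
  expect_equal(dm2$n_domains, 2)
  expect_equal(dm2$largest_domain_fraction, 0.5)
  expect_lt(dm2$domain_asphericity, 0.1)   # compact cubes are near-spherical
  expect_error(domain_metrics(structure(list(coords = cbind(1, 1, 1),
                                             rod = FALSE,
                                             lattice_size = 8L),
                                        class = "copolymer_conformation")),
               "no rod beads")
})

test_that("treatments map onto the interaction parameters as specified", {
  p <- sim_params(32, epsilon_rr = 3, kappa_rod = 2, n_steps = 10, seed = 1)
  pf <- apply_treatment(p, "formamide")
  expect_equal(pf$epsilon_rr, 0)
  expect_equal(attr(pf, "treatment"), "formamide")
  for (tr in c("DRB", "heat_shock", "NaCl")) {
    pt <- apply_treatment(p, tr)
    expect_equal(pt$epsilon_rr, 3)
  }
  expect_error(apply_treatment(p, "bleach"), "formamide, DRB")
})

test_that("the energy trace falls during equilibration from an extended start", {
  conf <- build_chain(default_block_spec(1, spacer_beads = 100), 32)
  tr <- run_mc(conf, sim_params(32, 3, 2, 4e6, trace_every = 2e5, seed = 41))
  e <- tr$trace$energy
  expect_lt(mean(tail(e, 5)), mean(head(e, 5)))
  expect_lt(tr$energy, 0)
})
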