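# geometric fixtures built in code

make_disc <- function(r, pad = 6) {
  s <- 2 * r + 2 * pad
  c0 <- (s + 1) / 2
  m <- matrix(0, s, s)
  m[(row(m) - c0)^2 + (col(m) - c0)^2 <= r^2] <- 1
  m
}

make_square <- function(a, pad = 6) {
  s <- a + 2 * pad
  m <- matrix(0, s, s)
  m[(pad + 1):(pad + a), (pad + 1):(pad + a)] <- 1
  m
}

# a hand-built fibre with given track starts/ends (Kb)
make_fibre <- function(starts, ends, id = "f1",
                       tmarks = numeric(0), pmarks = numeric(0),
                       cluster_ids = rep(1L, length(starts))) {
  structure(list(fibre_id = id,
                 tracks = data.frame(start_kb = starts, end_kb = ends),
                 transcript_marks = tmarks, polii_marks = pmarks,
                 truth_cluster_ids = cluster_ids,
                 fibre_length_kb = max(ends) + 500),
            class = "spread_fibre")
}

as_conformation <- function(coords, rod, L) {
  structure(list(coords = matrix(as.integer(coords), ncol = 3),
                 rod = rod, lattice_size = as.integer(L)),
            class = "copolymer_conformation")
}
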