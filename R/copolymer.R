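#' Rod-coil block composition of a chromatin-like copolymer chain
#'
#' A chain is an ordered sequence of stiff "rod" blocks (hyperacetylated,
#' transcriptionally active chromatin) and flexible "coil" blocks, with one
#' lattice bead per Kb.
#'
#' @param blocks data frame with columns `kind` (`"rod"` or `"coil"`) and
#'   `n_beads` (positive integers).
#' @return An object of class `block_spec` with a `rod_fraction` attribute.
#' @seealso [default_block_spec()]
#' @export
block_spec <- function(blocks) {
  if (!is.data.frame(blocks) || !all(c("kind", "n_beads") %in% names(blocks)))
    stop("blocks must be a data frame with columns kind, n_beads", call. = FALSE)
  if (nrow(blocks) < 1) stop("at least one block is required", call. = FALSE)
  if (!all(blocks$kind %in% c("rod", "coil")))
    stop("kind must be 'rod' or 'coil'", call. = FALSE)
  if (any(blocks$n_beads < 1)) stop("n_beads must be >= 1", call. = FALSE)
  blocks$n_beads <- as.integer(blocks$n_beads)
  structure(blocks,
            rod_fraction = sum(blocks$n_beads[blocks$kind == "rod"]) /
              sum(blocks$n_beads),
            class = c("block_spec", "data.frame"))
}

#' Default chromatin-calibrated chain composition
#'
#' Mirrors the measured linear organisation at 1 bead per Kb: clusters of
#' `rods_per_cluster` rod blocks of `rod_beads` beads separated by coil gaps
#' of `gap_beads`, with an inter-cluster coil spacer of `spacer_beads` after
#' each cluster. The defaults (15-bead rods, 30-bead gaps, 8 rods/cluster,
#' 670-bead spacers) give a rod fraction of exactly 12%.
#'
#' @param n_clusters number of rod clusters (default 2, a 2000-bead chain).
#' @param rods_per_cluster,rod_beads,gap_beads,spacer_beads composition
#'   integers (defaults 8, 15, 30, 670).
#' @return A [block_spec()].
#' @export
default_block_spec <- function(n_clusters = 2L, rods_per_cluster = 8L,
                               rod_beads = 15L, gap_beads = 30L,
                               spacer_beads = 670L) {
  rows <- list()
  for (cl in seq_len(n_clusters)) {
    for (r in seq_len(rods_per_cluster)) {
      rows[[length(rows) + 1L]] <- data.frame(kind = "rod", n_beads = rod_beads)
      if (r < rods_per_cluster)
        rows[[length(rows) + 1L]] <- data.frame(kind = "coil", n_beads = gap_beads)
    }
    rows[[length(rows) + 1L]] <- data.frame(kind = "coil", n_beads = spacer_beads)
  }
  block_spec(do.call(rbind, rows))
}

#' Monte-Carlo simulation parameters
#'
#' @param lattice_size cubic box edge length (single integer, default 48).
#' @param epsilon_rr rod-rod non-bonded contact attraction, kT (default 3).
#' @param kappa_rod bending penalty per non-straight bond pair centred at a
#'   rod bead, kT (default 2).
#' @param n_steps Monte-Carlo proposal count.
#' @param move_set subset of `c("local_crankshaft", "end_rotation",
#'   "reptation")`; the default local move set is kink-jump plus two-bead
#'   crankshaft (`"local_crankshaft"`) and end rotation. Reptation is
#'   opt-in: it slides the label pattern relative to the backbone,
#'   requiring a full energy recomputation per attempt.
#' @param reptation_prob probability of attempting reptation per step when
#'   enabled (default 0.2).
#' @param trace_every record the energy every this many steps (default
#'   `max(1, n_steps / 200)`).
#' @param snapshot_every record coordinates every this many steps
#'   (0 = never, the default).
#' @param seed integer seed, required by [run_mc()].
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(lattice_size = 48L, epsilon_rr = 3, kappa_rod = 2,
                       n_steps = 1e6,
                       move_set = c("local_crankshaft", "end_rotation"),
                       reptation_prob = 0.2,
                       trace_every = NULL, snapshot_every = 0L, seed = NULL) {
  if (length(lattice_size) != 1 || lattice_size < 2)
    stop("lattice_size must be a single integer >= 2", call. = FALSE)
  if (epsilon_rr < 0 || kappa_rod < 0)
    stop("epsilon_rr and kappa_rod must be >= 0", call. = FALSE)
  if (n_steps < 0) stop("n_steps must be >= 0", call. = FALSE)
  ok <- c("local_crankshaft", "end_rotation", "reptation")
  if (!length(move_set) || !all(move_set %in% ok))
    stop("move_set must be a subset of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  if (is.null(trace_every)) trace_every <- max(1, floor(n_steps / 200))
  structure(list(lattice_size = as.integer(lattice_size),
                 epsilon_rr = epsilon_rr, kappa_rod = kappa_rod,
                 n_steps = n_steps, move_set = move_set,
                 reptation_prob = reptation_prob,
                 trace_every = as.integer(trace_every),
                 snapshot_every = as.integer(snapshot_every),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_params")
}

#' Build the initial chain conformation
#'
#' Lays the labelled chain on the cubic lattice as a straight line when it
#' fits, otherwise as an extended diagonal zig-zag staircase (one staircase
#' per lattice layer, layers joined by single z-steps). Self-avoiding by
#' construction, dilute, and with every interior bead at a corner so the
#' kink-jump move is immediately productive.
#'
#' @param spec a [block_spec()].
#' @param lattice_size cubic box edge (default 48).
#' @return An object of class `copolymer_conformation`: `coords` (N x 3
#'   integer matrix, 0-based lattice positions), `rod` (logical per bead),
#'   `lattice_size`.
#' @examples
#' conf <- build_chain(block_spec(data.frame(kind = c("rod", "coil"),
#'                                           n_beads = c(1, 1))), 8)
#' attr(conf, "rod_fraction")
#' @export
build_chain <- function(spec, lattice_size = 48L) {
  if (!inherits(spec, "block_spec"))
    stop("spec must be built with block_spec()", call. = FALSE)
  L <- as.integer(lattice_size)
  rod <- rep(spec$kind == "rod", spec$n_beads)
  n <- length(rod)
  if (n > L^3) stop("chain of ", n, " beads cannot fit a ", L, "^3 lattice",
                    call. = FALSE)
  if (n <= L) {
    coords <- cbind(seq_len(n) - 1L, rep(L %/% 2, n), rep(L %/% 2, n))
  } else {
    # extended zig-zag: a diagonal staircase (alternating +x, +y steps)
    # per z-layer, reversed on odd layers and connected by single +z
    # steps. Every interior bead sits at a corner, so the kink-jump move
    # can act on it immediately, and each layer holds only 2L-1 beads,
    # keeping the start dilute.
    per_layer <- 2L * L - 1L
    if (n > per_layer * L)
      stop("chain of ", n, " beads needs a staircase of more than ", L,
           " layers; increase lattice_size", call. = FALSE)
    xs <- ys <- integer(per_layer)
    x <- 0L; y <- 0L
    for (k in seq_len(per_layer)) {
      xs[k] <- x; ys[k] <- y
      if (k %% 2 == 1L) x <- x + 1L else y <- y + 1L
    }
    i <- seq_len(n) - 1L
    z <- i %/% per_layer
    r <- i %% per_layer
    fwd <- z %% 2L == 0L
    px <- ifelse(fwd, xs[r + 1L], rev(xs)[r + 1L])
    py <- ifelse(fwd, ys[r + 1L], rev(ys)[r + 1L])
    coords <- cbind(as.integer(px), as.integer(py), as.integer(z))
  }
  structure(list(coords = coords, rod = rod, lattice_size = L),
            rod_fraction = attr(spec, "rod_fraction"),
            class = "copolymer_conformation")
}

#' @export
print.copolymer_conformation <- function(x, ...) {
  cat(sprintf("<copolymer_conformation> %d beads (%d rod, %.1f%%), box %d^3\n",
              length(x$rod), sum(x$rod), 100 * mean(x$rod), x$lattice_size))
  invisible(x)
}

validate_conformation <- function(conf) {
  C <- conf$coords
  if (anyDuplicated(paste(C[, 1], C[, 2], C[, 3])))
    stop("conformation is not self-avoiding", call. = FALSE)
  if (nrow(C) > 1) {
    d <- abs(diff(C[, 1])) + abs(diff(C[, 2])) + abs(diff(C[, 3]))
    if (any(d != 1))
      stop("consecutive beads are not lattice-adjacent", call. = FALSE)
  }
  if (any(C < 0) || any(C >= conf$lattice_size))
    stop("beads outside the lattice", call. = FALSE)
  invisible(TRUE)
}

#' Energy of a conformation
#'
#' `E = -epsilon_rr * (non-bonded rod-rod nearest-neighbour contacts)
#'    + kappa_rod * (non-collinear bond pairs whose central bead is a rod)`,
#' in units of kT.
#'
#' @param conf a `copolymer_conformation`.
#' @param params a [sim_params()].
#' @return Energy in kT.
#' @export
chain_energy <- function(conf, params) {
  validate_conformation(conf)
  C <- conf$coords
  n <- nrow(C)
  L <- conf$lattice_size
  key <- (C[, 3] * L + C[, 2]) * L + C[, 1]
  occ <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = occ)
  E <- 0
  if (params$epsilon_rr > 0) {
    shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    for (i in which(conf$rod)) {
      for (d in seq_len(6)) {
        q <- C[i, ] + shifts[d, ]
        if (any(q < 0) || any(q >= L)) next
        j <- mget(as.character((q[3] * L + q[2]) * L + q[1]),
                  envir = occ, ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && j > i && j != i + 1 && conf$rod[j])
          E <- E - params$epsilon_rr
      }
    }
  }
  if (params$kappa_rod > 0 && n > 2) {
    v <- diff(C)
    bend <- rowSums(abs(v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])) > 0
    centre_rod <- conf$rod[2:(n - 1)]
    E <- E + params$kappa_rod * sum(bend & centre_rod)
  }
  E
}

#' Run the Metropolis Monte-Carlo simulation
#'
#' Evolves the chain with the configured move set at temperature 1 kT,
#' enforcing self-avoidance, and records an energy trace (and optional
#' coordinate snapshots). Fully reproducible from `params$seed`.
#'
#' @param conf starting `copolymer_conformation`.
#' @param params a [sim_params()] with a non-`NULL` seed.
#' @return An object of class `mc_trajectory`: `final` (conformation),
#'   `trace` (data frame step/energy), `acceptance_rate`, `snapshots`
#'   (list of coordinate matrices) and `params`.
#' @examples
#' conf <- build_chain(default_block_spec(1), 32)
#' run_mc(conf, sim_params(32, n_steps = 1000, seed = 1))
#' @export
run_mc <- function(conf, params) {
  if (!inherits(params, "sim_params"))
    stop("params must be built with sim_params()", call. = FALSE)
  if (is.null(params$seed))
    stop("params$seed is required: the trajectory must be reproducible",
         call. = FALSE)
  validate_conformation(conf)
  if (conf$lattice_size != params$lattice_size)
    stop("conformation and params disagree on lattice_size", call. = FALSE)
  set.seed(params$seed)
  res <- .mc_run_cpp(conf$coords, conf$rod, conf$lattice_size,
                     params$epsilon_rr, params$kappa_rod, params$n_steps,
                     "local_crankshaft" %in% params$move_set,
                     "end_rotation" %in% params$move_set,
                     "reptation" %in% params$move_set, params$reptation_prob,
                     params$trace_every, params$snapshot_every)
  if (params$n_steps >= length(conf$rod) && res$accepted == 0)
    warning("no move was accepted over the whole run: the system appears ",
            "frozen at this epsilon/kappa", call. = FALSE)
  final <- conf
  final$coords <- res$coords
  structure(list(final = final,
                 trace = data.frame(step = res$trace_step,
                                    energy = res$trace_energy),
                 energy = res$energy,
                 acceptance_rate = if (params$n_steps > 0)
                   res$accepted / params$n_steps else NA_real_,
                 snapshots = res$snapshots,
                 snapshot_step = res$snapshot_step,
                 params = params),
            class = "mc_trajectory")
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat(sprintf(
    "<mc_trajectory> %g steps, acceptance %.3f, final energy %.1f kT\n",
    x$params$n_steps, x$acceptance_rate, x$energy))
  invisible(x)
}

#' Rod microdomain metrics of a conformation
#'
#' Domains are connected components of rod beads under lattice adjacency.
#' Reports the number of domains, the fraction of rod beads in the largest
#' one, the mean domain size, and a size-weighted mean normalised
#' asphericity from the gyration-tensor eigenvalues
#' (`[(l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2] / (2 (l1+l2+l3)^2)`, 0 for a
#' sphere, 1 for a straight line; single-bead domains count as 0).
#'
#' @param conf a `copolymer_conformation` with at least one rod bead.
#' @return A list of class `domain_metrics`: `n_domains`,
#'   `largest_domain_fraction`, `mean_domain_size`, `domain_asphericity`,
#'   `sizes`.
#' @export
domain_metrics <- function(conf) {
  rods <- which(conf$rod)
  if (!length(rods)) stop("no rod beads in the conformation", call. = FALSE)
  C <- conf$coords[rods, , drop = FALSE]
  n <- nrow(C)
  # adjacency: Manhattan distance 1
  edges <- integer(0)
  if (n > 1) {
    ord <- order(C[, 1], C[, 2], C[, 3])
    key <- paste(C[, 1], C[, 2], C[, 3])
    pos <- stats::setNames(seq_len(n), key)
    shifts <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    for (s in seq_len(3)) {
      nb <- sweep(C, 2, shifts[s, ], "+")
      hit <- pos[paste(nb[, 1], nb[, 2], nb[, 3])]
      ok <- !is.na(hit)
      if (any(ok)) edges <- c(edges, rbind(which(ok), hit[ok]))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  sizes <- as.integer(comp$csize)
  asph <- vapply(seq_len(comp$no), function(k) {
    P <- C[comp$membership == k, , drop = FALSE]
    if (nrow(P) < 2) return(0)
    Pc <- sweep(P, 2, colMeans(P))
    ev <- eigen(crossprod(Pc) / nrow(P), symmetric = TRUE,
                only.values = TRUE)$values
    s <- sum(ev)
    if (s <= 0) return(0)
    ((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 + (ev[1] - ev[3])^2) / (2 * s^2)
  }, 0)
  structure(list(n_domains = comp$no,
                 largest_domain_fraction = max(sizes) / n,
                 mean_domain_size = mean(sizes),
                 domain_asphericity = sum(asph * sizes) / sum(sizes),
                 sizes = sort(sizes, decreasing = TRUE)),
            class = "domain_metrics")
}

#' @export
print.domain_metrics <- function(x, ...) {
  cat(sprintf(
    "Rod domains: %d (largest holds %.1f%% of rod beads, mean size %.1f, asphericity %.3f)\n",
    x$n_domains, 100 * x$largest_domain_fraction, x$mean_domain_size,
    x$domain_asphericity))
  invisible(x)
}

#' Map a chemical treatment onto simulation parameters
#'
#' Formamide destroys the acetylation-driven self-assembly of stiff blocks,
#' so it zeroes the rod-rod attraction; DRB, heat shock and NaCl extraction
#' remove polymerases or labile proteins but leave the acetylation-driven
#' interaction intact, so they leave `epsilon_rr` unchanged.
#'
#' @param params a [sim_params()].
#' @param treatment one of `"formamide"`, `"DRB"`, `"heat_shock"`, `"NaCl"`.
#' @return A new `sim_params` with a `treatment` attribute recording the
#'   provenance.
#' @export
apply_treatment <- function(params, treatment) {
  valid <- c("formamide", "DRB", "heat_shock", "NaCl")
  if (length(treatment) != 1 || !treatment %in% valid)
    stop("unknown treatment; valid names: ", paste(valid, collapse = ", "),
         call. = FALSE)
  out <- params
  if (treatment == "formamide") out$epsilon_rr <- 0
  attr(out, "treatment") <- treatment
  out
}
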