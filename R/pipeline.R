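#' Pipeline configuration
#'
#' Bundles the per-stage parameter groups with a single global seed from
#' which every stage seed is derived deterministically (stage index offsets
#' added to the global seed, kept within the 32-bit integer range), plus
#' stage enable flags. The configuration round-trips losslessly through
#' YAML via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param seed global integer seed.
#' @param spread a [spread_gen_params()] (seed field ignored; derived).
#' @param cowindow a [cowindow_params()] (seed derived).
#' @param images an [image_gen_params()] (seed derived).
#' @param sim a [sim_params()] (seed derived).
#' @param expression an [expr_gen_params()] (seed derived).
#' @param stages character subset of
#'   `c("spreads", "cowindow", "images", "copolymer")` to run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            spread = spread_gen_params(),
                            expression = expr_gen_params(
                              n_genes = 2000, chrom_length_kb = 20000,
                              planted_clusters = data.frame(
                                chrom = "chr1", start_kb = 5000, span_kb = 500,
                                n_genes_expressed = 8)),
                            cowindow = cowindow_params(n_permutations = 200),
                            images = image_gen_params(n_images = 10),
                            sim = sim_params(n_steps = 2e5),
                            stages = c("spreads", "cowindow", "images",
                                       "copolymer")) {
  if (missing(seed)) stop("a global seed is required", call. = FALSE)
  ok <- c("spreads", "cowindow", "images", "copolymer")
  if (!all(stages %in% ok))
    stop("stages must be a subset of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  seed <- as.integer(seed)
  # deterministic per-stage seeds, kept below 2^31
  derive <- function(k) as.integer((abs(seed) + 1009L * k) %% .Machine$integer.max)
  spread$seed <- derive(1L)
  expression$seed <- derive(2L)
  cowindow$seed <- derive(3L)
  images$seed <- derive(4L)
  sim$seed <- derive(5L)
  structure(list(seed = seed, spread = spread, expression = expression,
                 cowindow = cowindow, images = images, sim = sim,
                 stages = stages),
            class = "pipeline_config")
}

#' Serialise a pipeline configuration to YAML
#'
#' @param config a [pipeline_config()].
#' @param path output `.yaml` path.
#' @export
write_pipeline_config <- function(config, path) {
  strip <- function(x) {
    cl <- class(x)
    x <- unclass(x)
    if (is.data.frame(x)) x <- as.list(x)
    attr(x, "sf_class") <- NULL
    c(list(.class = paste(cl, collapse = ",")), x)
  }
  doc <- list(seed = config$seed, stages = config$stages,
              spread = strip(config$spread),
              expression = strip(lapply(config$expression, function(v)
                if (is.data.frame(v)) as.list(v) else v)),
              cowindow = strip(config$cowindow),
              images = strip(config$images),
              sim = strip(config$sim))
  doc$expression$.class <- "expr_gen_params"
  write_atomic(function(tmp) yaml::write_yaml(doc, tmp), path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path file written by [write_pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  doc <- yaml::read_yaml(path)
  restore <- function(x) {
    cl <- strsplit(x$.class, ",")[[1]]
    x$.class <- NULL
    # yaml scalars come back length-1; re-vectorise known fields
    structure(x, class = cl)
  }
  spread <- restore(doc$spread)
  expression <- restore(doc$expression)
  if (!is.null(expression$planted_clusters))
    expression$planted_clusters <- as.data.frame(expression$planted_clusters)
  cow <- restore(doc$cowindow)
  img <- restore(doc$images)
  img$image_size_px <- as.integer(unlist(img$image_size_px))
  sim <- restore(doc$sim)
  sim$move_set <- unlist(sim$move_set)
  structure(list(seed = as.integer(doc$seed), spread = spread,
                 expression = expression, cowindow = cow, images = img,
                 sim = sim, stages = unlist(doc$stages)),
            class = "pipeline_config")
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes the enabled stages in dependency order — generate chromatin
#' spreads then measure them; generate an expression table then run the
#' sliding-window test; generate nucleus images then segment and measure
#' foci; build and equilibrate the copolymer chain then compute domain
#' metrics — writing each stage's tables under `out_dir` and returning a
#' manifest. Rerunning with the same configuration reproduces byte-identical
#' tables. A stage failure aborts with the stage name; the manifest of
#' already-written outputs is attached to the error condition.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return Data frame manifest (class `pipeline_manifest`): `stage`, `file`,
#'   `seed`; also written to `manifest.tsv`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be built with pipeline_config()", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(stage = character(0), file = character(0),
                         seed = integer(0), stringsAsFactors = FALSE)
  note <- function(stage, file, seed) {
    manifest <<- rbind(manifest, data.frame(stage = stage, file = file,
                                            seed = seed))
  }
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      cond <- simpleError(sprintf("pipeline stage '%s' failed: %s",
                                  stage, conditionMessage(e)))
      cond$manifest <- manifest
      stop(cond)
    })
  }
  tsv <- function(df, name, stage, seed) {
    p <- file.path(out_dir, name)
    write_atomic(function(tmp)
      utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                         row.names = FALSE), p)
    note(stage, name, seed)
  }

  if ("spreads" %in% config$stages) run_stage("spreads", function() {
    fib <- generate_spread_fibres(config$spread)
    write_tracks_bed(fib, file.path(out_dir, "tracks.bed"))
    note("spreads", "tracks.bed", config$spread$seed)
    cl <- detect_clusters(fib, config$spread$max_gap_kb)
    st <- cluster_statistics(cl, fib)
    mk <- marks_per_track(fib)
    tsv(data.frame(
      metric = c("n_clusters", "tus_mean", "tus_sd", "span_mean_kb",
                 "span_sd_kb", "track_mean_kb", "gap_mean_kb",
                 "transcripts_per_track", "polii_per_track",
                 "active_fraction"),
      value = c(st$n_clusters, st$tus["mean"], st$tus["sd"],
                st$span_kb["mean"], st$span_kb["sd"],
                mean(track_lengths(fib)), mean(intra_cluster_gaps(fib)),
                mk$transcripts$mean, mk$polii$mean, active_fraction(fib))),
      "spread_stats.tsv", "spreads", config$spread$seed)
  })

  if ("cowindow" %in% config$stages) run_stage("cowindow", function() {
    genes <- generate_expression_table(config$expression)
    write_gene_table(genes, file.path(out_dir, "genes.tsv"))
    note("cowindow", "genes.tsv", config$expression$seed)
    res <- permutation_test(genes, config$cowindow,
                            chrom_length_kb = config$expression$chrom_length_kb)
    tsv(as.data.frame(res), "windows.tsv", "cowindow", config$cowindow$seed)
    tsv(merge_significant(res), "coexpression_regions.tsv", "cowindow",
        config$cowindow$seed)
  })

  if ("images" %in% config$stages) run_stage("images", function() {
    imgs <- generate_nucleus_images(config$images)
    feats <- list(); cvs <- list()
    for (i in seq_along(imgs)) {
      seg <- segment_foci(imgs[[i]]$image, imgs[[i]]$mask)
      f <- measure_foci(seg, imgs[[i]]$image)
      if (nrow(f)) { f$image <- i; feats[[length(feats) + 1L]] <- f }
      cv <- intensity_cv(imgs[[i]]$image, imgs[[i]]$mask, image_id = i)
      cvs[[i]] <- data.frame(image = i, mean = cv$mean_intensity,
                             sd = cv$sd_intensity, cv = cv$cv)
    }
    tsv(do.call(rbind, feats), "foci.tsv", "images", config$images$seed)
    tsv(do.call(rbind, cvs), "nucleus_cv.tsv", "images", config$images$seed)
  })

  if ("copolymer" %in% config$stages) run_stage("copolymer", function() {
    conf <- build_chain(default_block_spec(2), config$sim$lattice_size)
    traj <- run_mc(conf, config$sim)
    dm <- domain_metrics(traj$final)
    tsv(traj$trace, "mc_energy_trace.tsv", "copolymer", config$sim$seed)
    tsv(data.frame(metric = c("n_domains", "largest_domain_fraction",
                              "mean_domain_size", "domain_asphericity",
                              "acceptance_rate"),
                   value = c(dm$n_domains, dm$largest_domain_fraction,
                             dm$mean_domain_size, dm$domain_asphericity,
                             traj$acceptance_rate)),
        "copolymer_metrics.tsv", "copolymer", config$sim$seed)
    bead <- data.frame(bead = seq_along(traj$final$rod),
                       x = traj$final$coords[, 1], y = traj$final$coords[, 2],
                       z = traj$final$coords[, 3],
                       label = ifelse(traj$final$rod, "rod", "coil"))
    tsv(bead, "final_conformation.tsv", "copolymer", config$sim$seed)
  })

  p <- file.path(out_dir, "manifest.tsv")
  write_atomic(function(tmp)
    utils::write.table(manifest, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE), p)
  class(manifest) <- c("pipeline_manifest", "data.frame")
  manifest
}
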