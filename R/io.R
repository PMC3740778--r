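## Atomic write helper: write to a temporary file in the same directory,
## then rename into place.
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file into place at ", path, call. = FALSE)
  invisible(path)
}

unit_to_kb <- function(x, unit, calibration) {
  switch(unit,
         kb = x,
         bp = x / 1000,
         um = {
           if (is.null(calibration))
             stop("micron-unit input requires a calibration", call. = FALSE)
           microns_to_kb(x, calibration)
         },
         stop("unit must be one of kb, bp, um", call. = FALSE))
}

kb_to_unit <- function(x, unit, calibration) {
  switch(unit,
         kb = x,
         bp = round(x * 1000),
         um = {
           if (is.null(calibration))
             stop("micron-unit output requires a calibration", call. = FALSE)
           kb_to_microns(x, calibration)
         },
         stop("unit must be one of kb, bp, um", call. = FALSE))
}

#' Write spread-fibre tracks as BED
#'
#' BED-like 0-based half-open records, one per track, with the fibre id as
#' the chromosome column and `fibre|cluster<id>` as the name (carrying the
#' ground-truth cluster assignment). Coordinates are written in the chosen
#' unit: real-valued Kb (the package dialect), integer bp, or microns via a
#' calibration.
#'
#' @param fibres a `spread_fibre_set` or list of `spread_fibre`.
#' @param path output file.
#' @param unit `"kb"` (default), `"bp"` or `"um"`.
#' @param calibration a [spread_calibration()], required for `"um"`.
#' @return The path, invisibly.
#' @export
write_tracks_bed <- function(fibres, path, unit = "kb", calibration = NULL) {
  rows <- lapply(fibres, function(f) {
    if (!nrow(f$tracks)) return(NULL)
    data.frame(chrom = f$fibre_id,
               start = kb_to_unit(f$tracks$start_kb, unit, calibration),
               end = kb_to_unit(f$tracks$end_kb, unit, calibration),
               name = sprintf("%s|cluster%d", f$fibre_id, f$truth_cluster_ids),
               stringsAsFactors = FALSE)
  })
  bed <- do.call(rbind, rows)
  write_atomic(function(tmp)
    utils::write.table(bed, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE), path)
}

#' Write fibre marks as BED
#'
#' Point marks (transcripts or polymerases) as zero-width-adjacent BED
#' records `[pos, pos + eps)` is avoided: each mark is written as a 1-unit
#' interval starting at its position, named by mark type.
#'
#' @inheritParams write_tracks_bed
#' @param which mark type, `"transcripts"` or `"polii"`.
#' @export
write_marks_bed <- function(fibres, path, which = c("transcripts", "polii"),
                            unit = "kb", calibration = NULL) {
  which <- match.arg(which)
  field <- if (which == "transcripts") "transcript_marks" else "polii_marks"
  rows <- lapply(fibres, function(f) {
    pos <- f[[field]]
    if (!length(pos)) return(NULL)
    data.frame(chrom = f$fibre_id,
               start = kb_to_unit(pos, unit, calibration),
               end = kb_to_unit(pos, unit, calibration) +
                 if (unit == "bp") 1 else 0.001,
               name = which, stringsAsFactors = FALSE)
  })
  bed <- do.call(rbind, rows)
  write_atomic(function(tmp)
    utils::write.table(bed, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE), path)
}

#' Read spread-fibre tracks from BED
#'
#' Groups BED records into fibres by the chromosome column, restores
#' ground-truth cluster ids from names of the form `fibre|cluster<k>` when
#' present, converts coordinates to Kb, and enforces the fibre invariants
#' (sorted, non-overlapping tracks), reporting the offending line on
#' failure.
#'
#' @param path BED file written by [write_tracks_bed()] (or compatible).
#' @param unit coordinate unit in the file: `"kb"`, `"bp"` or `"um"`.
#' @param calibration required when `unit = "um"`.
#' @return A `spread_fibre_set` (without marks).
#' @export
read_tracks_bed <- function(path, unit = "kb", calibration = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bed <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "start", "end", "name"),
                      colClasses = c("character", "numeric", "numeric",
                                     "character")),
    error = function(e) stop("malformed BED at ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  bed$line <- seq_len(nrow(bed))
  bed$start_kb <- unit_to_kb(bed$start, unit, calibration)
  bed$end_kb <- unit_to_kb(bed$end, unit, calibration)
  fibres <- lapply(split(bed, bed$chrom), function(b) {
    b <- b[order(b$start_kb), , drop = FALSE]
    if (any(b$end_kb <= b$start_kb))
      stop("non-positive interval at line ",
           b$line[which(b$end_kb <= b$start_kb)[1]], call. = FALSE)
    if (nrow(b) > 1 && any(b$start_kb[-1] < b$end_kb[-nrow(b)]))
      stop("overlapping tracks in fibre ", b$chrom[1], " near line ",
           b$line[which(b$start_kb[-1] < b$end_kb[-nrow(b)])[1] + 1],
           call. = FALSE)
    ids <- suppressWarnings(as.integer(sub(".*\\|cluster", "", b$name)))
    if (anyNA(ids)) ids <- rep(NA_integer_, nrow(b))
    new_spread_fibre(b$chrom[1],
                     data.frame(start_kb = b$start_kb, end_kb = b$end_kb),
                     numeric(0), numeric(0), ids,
                     fibre_length_kb = max(b$end_kb))
  })
  structure(unname(fibres), class = "spread_fibre_set")
}

#' Write a gene table as tab-delimited text
#'
#' Columns `chrom`, `start_kb`, `end_kb`, `gene_id`, `expressed`.
#' @param genes gene table data frame.
#' @param path output file.
#' @export
write_gene_table <- function(genes, path) {
  write_atomic(function(tmp)
    utils::write.table(
      genes[, c("chrom", "start_kb", "end_kb", "gene_id", "expressed")],
      tmp, sep = "\t", quote = FALSE, row.names = FALSE), path)
}

#' Read a gene table (tab or comma delimited, autodetected)
#'
#' @param path file with columns `chrom`, `start_kb`, `end_kb`, `gene_id`,
#'   `expressed`.
#' @return Gene table data frame.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  g <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("chrom", "start_kb", "end_kb", "gene_id", "expressed")
  if (!all(need %in% names(g)))
    stop("gene table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(g$expressed %in% c(0, 1)))
    stop("expressed must be 0/1", call. = FALSE)
  g
}

#' Write a nucleus image as 16-bit TIFF
#'
#' Intensities are stored on the 16-bit scale (values are divided by 65535
#' on write and restored on read).
#'
#' @param image numeric matrix of intensities in `[0, 65535]`.
#' @param path output `.tif` path.
#' @export
write_image_tiff <- function(image, path) {
  img <- pmin(pmax(image, 0), 65535) / 65535
  write_atomic(function(tmp)
    tiff::writeTIFF(img, tmp, bits.per.sample = 16L), path)
}

#' Read a nucleus image from 16-bit TIFF or PNG
#'
#' @param path image file (`.tif`/`.tiff`/`.png`).
#' @return Numeric matrix on the 16-bit intensity scale.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * 65535
}
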