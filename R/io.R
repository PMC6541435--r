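# Serialization: TSV matrices at full double precision, NIfTI volumes with a
# 1-D spatial layout, netmat tables with mode labels, and JSON run manifests
# with file checksums.

#' Write / read a numeric matrix as tab-separated text
#'
#' TSV files carry a one-line header and full double precision (17
#' significant digits), so a write/read round trip is lossless.
#'
#' @param x numeric matrix.
#' @param path file path.
#' @return `read_matrix_tsv` returns the matrix; `write_matrix_tsv` returns
#'   `path` invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  x <- as.matrix(x)
  cols <- colnames(x) %||% sprintf("c%d", seq_len(ncol(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  body <- apply(x, 1L, function(row) paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "numeric")
  m <- as.matrix(df)
  rownames(m) <- NULL
  m
}

#' Write / read a timepoints x voxels data matrix
#'
#' `format = "tsv"` stores the matrix as tab-separated text (one row per
#' timepoint). `format = "nifti"` stores it as a 4-D NIfTI image with the
#' voxels unravelled along the first spatial axis (dims
#' `n_voxels x 1 x 1 x timepoints`); on read, native 3-D/4-D volumes are
#' vectorised row-major over their spatial dimensions.
#'
#' @param x timepoints x voxels matrix.
#' @param path output path (use `.nii` or `.nii.gz` for NIfTI).
#' @param format `"tsv"` or `"nifti"`.
#' @return `read_bold` returns the matrix; `write_bold` returns `path`
#'   invisibly.
#' @export
write_bold <- function(x, path, format = c("tsv", "nifti")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write_matrix_tsv(x, path)
  } else {
    arr <- array(t(x), dim = c(ncol(x), 1L, 1L, nrow(x)))
    RNifti::writeNifti(RNifti::asNifti(arr), path)
    invisible(path)
  }
}

#' @rdname write_bold
#' @export
read_bold <- function(path, format = c("auto", "tsv", "nifti")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "tsv"
  }
  if (format == "tsv") {
    read_matrix_tsv(path)
  } else {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) < 2L) stop_config("NIfTI image in %s has no time axis", path)
    nt <- d[length(d)]
    nv <- prod(d[-length(d)])
    t(matrix(as.vector(img), nrow = nv, ncol = nt))
  }
}

#' Write / read a network matrix as labelled TSV
#'
#' The TSV carries mode labels as the header and first column; the reader
#' validates symmetry to within 1e-12 and restores the `netmat` attributes.
#'
#' @param nm a `netmat` (or square matrix).
#' @param path file path.
#' @return `read_netmat_tsv` returns a `netmat`; the writer returns `path`
#'   invisibly.
#' @export
write_netmat_tsv <- function(nm, path) {
  m <- unclass(nm)
  labels <- rownames(m) %||% sprintf("mode%d", seq_len(nrow(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(sprintf("#kind=%s", attr(nm, "kind") %||% "unknown"),
                     labels), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(labels[i], sprintf("%.17g", m[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_netmat_tsv
#' @export
read_netmat_tsv <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  kind <- sub("^#kind=", "", header[1])
  labels <- header[-1]
  body <- do.call(rbind, lapply(lines[-1], function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]]
  }))
  m <- matrix(as.numeric(body[, -1, drop = FALSE]), nrow = nrow(body))
  rownames(m) <- colnames(m) <- labels
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-12) {
    stop_config("netmat in %s is not symmetric within 1e-12", path)
  }
  new_netmat(m, kind = kind)
}

#' Write a run manifest with config, seeds and file checksums
#'
#' Every emitted file of a pipeline run is inventoried with its MD5
#' checksum, alongside a snapshot of the configuration and seeds, so a rerun
#' from the manifest can be verified to reproduce identical outputs.
#'
#' @param dir output directory of the run.
#' @param command the subcommand or function that produced the outputs.
#' @param config configuration object or list (stored as JSON).
#' @param seeds integer seeds used.
#' @param files character vector of emitted file paths (relative to `dir`).
#' @return the manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, command, config, seeds, files) {
  sums <- tools::md5sum(file.path(dir, files))
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("threshdr")),
    config = unclass(config),
    config_class = class(config)[1],
    seeds = seeds,
    inventory = data.frame(file = files, md5 = unname(sums),
                           stringsAsFactors = FALSE)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_manifest
#' @export
read_run_manifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
}

#' Verify that a run directory matches its manifest
#'
#' Recomputes the MD5 checksum of every inventoried file.
#'
#' @param dir run directory containing `manifest.json`.
#' @return `TRUE` invisibly; errors listing any mismatching file.
#' @export
verify_manifest <- function(dir) {
  man <- read_run_manifest(dir)
  inv <- man$inventory
  sums <- unname(tools::md5sum(file.path(dir, inv$file)))
  bad <- which(is.na(sums) | sums != inv$md5)
  if (length(bad)) {
    stop_config("manifest mismatch for: %s",
                paste(inv$file[bad], collapse = ", "))
  }
  invisible(TRUE)
}

# Serialize a simulation (data + slim ground truth) to a directory of TSV
# files plus a JSON manifest. Used by the CLI simulate-* subcommands.
write_simulation <- function(sim, dir, format = "tsv", command = "simulate") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  ext <- if (format == "nifti") ".nii.gz" else ".tsv"
  nested <- is.list(sim$data[[1]])
  for (s in seq_along(sim$data)) {
    if (nested) {
      for (r in seq_along(sim$data[[s]])) {
        f <- sprintf("data_sub%03d_run%02d%s", s, r, ext)
        write_bold(sim$data[[s]][[r]], file.path(dir, f), format = format)
        files <- c(files, f)
      }
    } else {
      f <- sprintf("data_sub%03d%s", s, ext)
      write_bold(sim$data[[s]], file.path(dir, f), format = format)
      files <- c(files, f)
    }
  }
  truth_dir <- file.path(dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  f <- "truth/group_maps.tsv"
  write_matrix_tsv(sim$truth$group_maps, file.path(dir, f))
  files <- c(files, f)
  for (s in seq_along(sim$truth$subject_maps)) {
    f <- sprintf("truth/subject_maps_sub%03d.tsv", s)
    write_matrix_tsv(sim$truth$subject_maps[[s]], file.path(dir, f))
    files <- c(files, f)
    ts <- if (is.null(sim$truth$timecourses)) {
      do.call(rbind, sim$truth$neural[[s]])
    } else {
      sim$truth$timecourses[[s]]
    }
    f <- sprintf("truth/timecourses_sub%03d.tsv", s)
    write_matrix_tsv(ts, file.path(dir, f))
    files <- c(files, f)
    f <- sprintf("truth/tnet_sub%03d.tsv", s)
    write_netmat_tsv(new_netmat(sim$truth$tnet[[s]], "temporal", subject = s),
                     file.path(dir, f))
    files <- c(files, f)
    f <- sprintf("truth/snet_sub%03d.tsv", s)
    write_netmat_tsv(new_netmat(sim$truth$snet[[s]], "spatial", subject = s),
                     file.path(dir, f))
    files <- c(files, f)
  }
  write_run_manifest(dir, command, sim$config,
                     seeds = c(root = sim$config$seed,
                               repeat_seed = sim$truth$seed),
                     files = files)
  invisible(dir)
}
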