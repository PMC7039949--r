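#' @title Trace container
#'
#' @description
#' On-disk container for eABR sweep sets: a directory holding a versioned
#' JSON manifest plus one delimited-text matrix per sweep set, written at
#' full (`%.17g`) precision so the round trip is bit-lossless. Units are
#' fixed (µV samples, µA currents, nC charges, µs times). Unknown manifest
#' fields are preserved on read and rewritten on write.
#'
#' @name container
NULL

CONTAINER_SCHEMA_VERSION <- 1L

fmt_full <- function(x) sprintf("%.17g", x)

write_sweep_matrix <- function(m, path) {
  lines <- apply(m, 1, function(r) paste(fmt_full(r), collapse = "\t"))
  writeLines(lines, path)
}

read_sweep_matrix <- function(path) {
  lines <- readLines(path)
  vals <- strsplit(lines, "\t", fixed = TRUE)
  matrix(as.numeric(unlist(vals)), nrow = length(lines), byrow = TRUE)
}

#' Write a study to a trace container directory
#'
#' @param study list with `sweepsets` (named list of `sweep_set`) and
#'   optionally `ground_truth`, as returned by [simulate_study()], or a
#'   container previously read with [read_container()] (whose extra
#'   manifest fields are preserved).
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_container <- function(study, path) {
  dir.create(file.path(path, "sweeps"), recursive = TRUE,
             showWarnings = FALSE)
  entries <- lapply(names(study$sweepsets), function(id) {
    ss <- study$sweepsets[[id]]
    file <- file.path("sweeps", paste0(id, ".tsv"))
    write_sweep_matrix(ss$sweeps, file.path(path, file))
    list(id = id, file = file, sampling_rate = ss$sampling_rate,
         delay_tag = ss$delay_tag, t_start = ss$t_start,
         n_sweeps = nrow(ss$sweeps), n_samples = ncol(ss$sweeps),
         condition = ss$condition)
  })
  manifest <- study$manifest %||% list()
  manifest$schema_version <- CONTAINER_SCHEMA_VERSION
  manifest$units <- list(samples = "uV", current = "uA", charge = "nC",
                         time = "us")
  manifest$sweepsets <- entries
  if (!is.null(study$ground_truth)) {
    gt <- study$ground_truth
    jsonlite::write_json(
      list(seed = gt$seed, conditions = gt$conditions, levels = gt$levels),
      file.path(path, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    manifest$ground_truth <- "ground_truth.json"
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a trace container directory
#'
#' @param path directory written by [write_container()].
#' @return list with `sweepsets` (named list of `sweep_set`), `manifest`
#'   (including any unknown fields) and `ground_truth` (tables, or
#'   `NULL`).
#' @export
read_container <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", path)
  manifest <- jsonlite::read_json(mf)
  if (is.null(manifest$schema_version)) {
    stop("schema violation: missing field 'schema_version'")
  }
  if (is.null(manifest$sweepsets)) {
    stop("schema violation: missing field 'sweepsets'")
  }
  sweepsets <- list()
  for (e in manifest$sweepsets) {
    for (fld in c("id", "file", "sampling_rate", "delay_tag", "t_start")) {
      if (is.null(e[[fld]])) {
        stop("schema violation: missing field 'sweepsets/", fld, "'")
      }
    }
    m <- read_sweep_matrix(file.path(path, e$file))
    sweepsets[[e$id]] <- structure(
      list(sweeps = m, sampling_rate = e$sampling_rate,
           delay_tag = e$delay_tag,
           condition = lapply(e$condition, function(v) {
             if (is.null(v)) NA else v
           }),
           t_start = e$t_start),
      class = "sweep_set")
  }
  gt <- NULL
  if (!is.null(manifest$ground_truth)) {
    gtp <- file.path(path, manifest$ground_truth)
    if (file.exists(gtp)) {
      raw <- jsonlite::read_json(gtp, simplifyVector = TRUE)
      gt <- list(seed = raw$seed, conditions = raw$conditions,
                 levels = raw$levels)
    }
  }
  keep <- setdiff(names(manifest), "sweepsets")
  list(sweepsets = sweepsets, manifest = manifest[keep], ground_truth = gt)
}
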