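# Persisted artifacts carry a schema tag so that stale or foreign files fail
# with a named error instead of a silent misparse.  All floating-point text
# output uses 17 significant digits so numeric round-trips are exact.

SCHEMAS <- list(rdm = "oscirsa/rdm/1", matrix = "oscirsa/matrix/1",
                epochs = "oscirsa/epochs/1", stack = "oscirsa/stack/1",
                cluster = "oscirsa/cluster/1", scores = "oscirsa/scores/1")

check_schema <- function(found, expected, path) {
  if (!identical(found, expected))
    stopf("schema mismatch in '%s': found '%s', expected '%s'",
          path, found %||% "<missing>", expected)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write / read an RDM as delimited text
#'
#' A square tab-separated matrix with one comment header line carrying the
#' schema tag and a header row of condition labels.  The loader enforces
#' the RDM invariants (symmetry, zero diagonal, range).
#'
#' @param rdm An `rdm` object.
#' @param path Output file.
#' @return `write_rdm` the path, invisibly; `read_rdm` an `rdm`.
#' @export
write_rdm <- function(rdm, path) {
  validate_rdm(rdm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", SCHEMAS$rdm), con)
  writeLines(paste(rdm$labels, collapse = "\t"), con)
  utils::write.table(format(rdm$matrix, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  lines <- readLines(path, n = 1L)
  check_schema(sub("^# ", "", lines[1]), SCHEMAS$rdm, path)
  labels <- strsplit(readLines(path, n = 2L)[2], "\t")[[1]]
  m <- as.matrix(utils::read.table(path, skip = 2L, sep = "\t",
                                   colClasses = "numeric"))
  dimnames(m) <- list(labels, labels)
  validate_rdm(new_rdm(m, labels))
  new_rdm(m, labels)
}

#' Write / read a numeric matrix (e.g. a TF map) as delimited text
#'
#' @param m Numeric matrix.
#' @param path Output file.
#' @param meta Optional named list stored in a JSON sidecar `<path>.json`.
#' @return `write_matrix_txt` the path, invisibly; `read_matrix_txt` the
#'   matrix (sidecar metadata, if present, in `attr(, "meta")`).
#' @export
write_matrix_txt <- function(m, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", SCHEMAS$matrix, " ", nrow(m), " ", ncol(m)), con)
  utils::write.table(format(unname(as.matrix(m)), digits = 17,
                            scientific = TRUE, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(meta)) write_json_file(c(list(schema = SCHEMAS$matrix), meta),
                                      paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path) {
  hdr <- strsplit(sub("^# ", "", readLines(path, n = 1L)), " ")[[1]]
  check_schema(hdr[1], SCHEMAS$matrix, path)
  m <- as.matrix(utils::read.table(path, skip = 1L, sep = "\t",
                                   na.strings = "NA", colClasses = "numeric"))
  dimnames(m) <- NULL
  if (nrow(m) != as.integer(hdr[2]) || ncol(m) != as.integer(hdr[3]))
    stopf("corrupted matrix file '%s': header promises %sx%s, found %dx%d",
          path, hdr[2], hdr[3], nrow(m), ncol(m))
  side <- paste0(path, ".json")
  if (file.exists(side)) attr(m, "meta") <- jsonlite::read_json(side)
  m
}

#' Write / read an epoch set (binary array + JSON sidecar)
#'
#' The sample array is stored as little-endian doubles in `<path>.bin`; all
#' metadata (dimensions, condition labels, sampling rate, epoch window,
#' seed, and an echo of the generator spec) goes to `<path>.json`.  The
#' round trip is lossless.
#'
#' @param epochs An `epoch_set`.
#' @param path Path prefix (without extension).
#' @return `write_epochs` the prefix, invisibly; `read_epochs` an
#'   `epoch_set` (without the planted-truth attachment, which is not
#'   serialized).
#' @export
write_epochs <- function(epochs, path) {
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
  close(con)
  spec <- epochs$spec
  meta <- list(schema = SCHEMAS$epochs, dim = dim(epochs$data),
               conditions = epochs$conditions, sfreq = epochs$sfreq,
               epoch_window = epochs$epoch_window, times = epochs$times,
               seed = spec$seed,
               spec = list(n_conditions = spec$n_conditions,
                           n_sensors = spec$n_sensors, n_trials = spec$n_trials,
                           sfreq = spec$sfreq, epoch_window = spec$epoch_window,
                           noise_exponent = spec$noise_exponent,
                           noise_scale = spec$noise_scale,
                           n_components = length(spec$components)))
  write_json_file(meta, paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  check_schema(meta$schema, SCHEMAS$epochs, paste0(path, ".json"))
  dm <- as.integer(meta$dim)
  con <- file(paste0(path, ".bin"), "rb")
  x <- readBin(con, "double", n = prod(dm), size = 8L, endian = "little")
  close(con)
  if (length(x) != prod(dm))
    stopf("corrupted epoch data '%s.bin': expected %d doubles, found %d",
          path, prod(dm), length(x))
  structure(list(data = array(x, dm), times = meta$times, sfreq = meta$sfreq,
                 epoch_window = meta$epoch_window, conditions = meta$conditions,
                 truth = NULL, spec = meta$spec),
            class = "epoch_set")
}

#' Write / read an RDM stack (vectors as text + JSON index)
#'
#' @param stack An `rdm_stack`.
#' @param path Path prefix.
#' @return `write_stack` the prefix, invisibly; `read_stack` an `rdm_stack`.
#' @export
write_stack <- function(stack, path) {
  write_matrix_txt(stack$vectors, paste0(path, ".tsv"))
  meta <- list(schema = SCHEMAS$stack, index = stack$index,
               labels = stack$labels, n_conditions = stack$n_conditions,
               grid = unclass(stack$grid))
  write_json_file(meta, paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  check_schema(meta$schema, SCHEMAS$stack, paste0(path, ".json"))
  vectors <- read_matrix_txt(paste0(path, ".tsv"))
  grid <- structure(meta$grid, class = "tf_grid")
  structure(list(vectors = vectors, index = meta$index, labels = meta$labels,
                 grid = grid, n_conditions = meta$n_conditions),
            class = "rdm_stack")
}

#' Write / read a cluster result (JSON + centroid matrix)
#'
#' Assignments, the RSS curve, and the selection metadata go to
#' `<path>.json`; centroids to `<path>_centroids.tsv`.  Integer assignments
#' round-trip exactly.
#'
#' @param result A `cluster_result`.
#' @param path Path prefix.
#' @return `write_cluster_result` the prefix, invisibly;
#'   `read_cluster_result` a `cluster_result`.
#' @export
write_cluster_result <- function(result, path) {
  meta <- list(schema = SCHEMAS$cluster, assignments = result$assignments,
               rss_curve = result$rss_curve, chosen_k = result$chosen_k,
               replicates = result$replicates, seed = result$seed,
               rule = result$rule)
  write_json_file(meta, paste0(path, ".json"))
  write_matrix_txt(result$centroids, paste0(path, "_centroids.tsv"))
  invisible(path)
}

#' @rdname write_cluster_result
#' @export
read_cluster_result <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  check_schema(meta$schema, SCHEMAS$cluster, paste0(path, ".json"))
  structure(list(assignments = as.integer(meta$assignments),
                 centroids = read_matrix_txt(paste0(path, "_centroids.tsv")),
                 rss_curve = meta$rss_curve, chosen_k = meta$chosen_k,
                 replicates = meta$replicates, seed = meta$seed,
                 rule = meta$rule, index = NULL),
            class = "cluster_result")
}
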