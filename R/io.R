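#' Write a complex matrix as paired real/imaginary CSV files
#'
#' `<stem>_real.csv` and `<stem>_imag.csv`, each a dense numeric CSV with
#' node labels as header.
#'
#' @param m complex matrix.
#' @param stem output path stem (without suffix).
#' @return the two paths, invisibly.
#' @export
write_complex_csv <- function(m, stem) {
  m <- as.matrix(m)
  paths <- paste0(stem, c("_real.csv", "_imag.csv"))
  utils::write.csv(Re(m), paths[1], row.names = FALSE)
  utils::write.csv(Im(m), paths[2], row.names = FALSE)
  invisible(paths)
}

#' Read a complex matrix from paired real/imaginary CSV files
#'
#' @param stem path stem used by [write_complex_csv()].
#' @return complex matrix with column labels from the header.
#' @export
read_complex_csv <- function(stem) {
  re <- as.matrix(utils::read.csv(paste0(stem, "_real.csv"), check.names = FALSE))
  im <- as.matrix(utils::read.csv(paste0(stem, "_imag.csv"), check.names = FALSE))
  if (!all(dim(re) == dim(im)))
    stopf("real and imaginary parts have different dimensions")
  m <- re + 1i * im
  colnames(m) <- colnames(re)
  m
}

#' Read a binary network from an edge-list TSV or dense 0/1 CSV
#'
#' Edge lists are two-column TSV files (`node_a<TAB>node_b`, no header
#' required; a header line is detected and skipped when its entries are not
#' previously seen labels).  Dense files are square 0/1 CSV matrices whose
#' header gives the labels.
#'
#' @param path file path.
#' @param labels node labels defining the node set (and order) for edge
#'   lists; optional for dense matrices.
#' @param format `"auto"` (by extension), `"edgelist"` or `"dense"`.
#' @return a [binary_network()].
#' @export
read_network <- function(path, labels = NULL, format = c("auto", "edgelist", "dense")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tsv$", path)) "edgelist" else "dense"
  if (format == "dense") {
    A <- as.matrix(utils::read.csv(path, check.names = FALSE))
    labels <- labels %||% colnames(A)
    return(binary_network(A, labels = labels))
  }
  el <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  if (ncol(el) < 2L) stopf("edge list must have two tab-separated columns")
  if (is.null(labels)) stopf("an edge list needs explicit node labels")
  # tolerate a header row
  if (!(el[1, 1] %in% labels) && !(el[1, 2] %in% labels))
    el <- el[-1, , drop = FALSE]
  bad <- setdiff(unique(c(el[, 1], el[, 2])), labels)
  if (length(bad))
    stopf("edge list references unknown node(s): %s",
          paste(head(bad, 5L), collapse = ", "))
  n <- length(labels)
  A <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (r in seq_len(nrow(el))) A[el[r, 1], el[r, 2]] <- 1L
  binary_network(A, labels = labels)
}

#' Write a binary network as an edge-list TSV
#'
#' @param network a [binary_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  A <- as_adjacency(network)
  labels <- colnames(A)
  idx <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  el <- data.frame(node_a = labels[idx[, 1L]], node_b = labels[idx[, 2L]])
  utils::write.table(el, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an AGL fit summary to JSON
#'
#' Writes the selected penalties, constraint verdict and deviance table (and
#' optionally the fitted matrices as paired CSVs next to the JSON file).
#'
#' @param fit an `agl` object.
#' @param path output JSON path.
#' @param matrices also write `Phi` and the partial coherence as paired
#'   CSVs using the JSON path (minus extension) as stem.
#' @return `path`, invisibly.
#' @export
write_agl_json <- function(fit, path, matrices = TRUE) {
  out <- list(lambda1 = unname(fit$lambda["lambda1"]),
              lambda2 = unname(fit$lambda["lambda2"]),
              constraint_used = fit$constraint_used,
              n_nodes = fit$n_nodes,
              n_samples = fit$n_samples,
              n_edges = fit$support$n_edges,
              deviance = fit$cv_min,
              cv_table = fit$cv_table)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (matrices) {
    stem <- sub("\\.json$", "", path)
    write_complex_csv(fit$Phi, paste0(stem, "_precision"))
    write_complex_csv(fit$partial_coherence, paste0(stem, "_pc"))
  }
  invisible(path)
}

#' Write a run-provenance record
#'
#' Machine-readable record (config, master seed, package version) written
#' alongside run outputs so deterministic stages can be reproduced
#' bit-for-bit.
#'
#' @param config named list of run parameters (must include `seed`).
#' @param dir output directory (created if needed).
#' @return the provenance path, invisibly.
#' @export
write_provenance <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec <- list(config = config,
              package = "aglasso",
              version = as.character(utils::packageVersion("aglasso")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "provenance.json")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' @param path JSON file of run parameters.
#' @param required character vector of fields that must be present.
#' @return named list.
#' @export
read_run_config <- function(path, required = "seed") {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stopf("config %s is missing required field(s): %s", path,
          paste(missing, collapse = ", "))
  cfg
}
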