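#' Read a long-format plate OD time series
#'
#' The canonical plate format is long CSV: one OD reading per row with
#' columns `strain`, `environment`, `replicate`, `time_h`, `od`. Rows are
#' sorted by culture and time; duplicate time points within a culture are
#' an error. Cultures with fewer than 3 readings are kept but flagged as
#' unusable in the `"unusable"` attribute (with a warning) rather than
#' silently dropped.
#'
#' @param path CSV file path.
#' @return A `data.frame` of class `plate_data`.
#' @seealso [write_plate_timeseries()], [generate_od_curves()]
#' @export
read_plate_timeseries <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "environment", "replicate", "time_h", "od")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("plate CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in c("time_h", "od")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v) & !is.na(x[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric %s at data row %d: '%s'", col, bad[1L],
                   x[[col]][bad[1L]]))
    }
    x[[col]] <- v
  }
  ord <- order(x$strain, x$environment, x$replicate, x$time_h)
  x <- x[ord, need, drop = FALSE]
  key <- interaction(x$strain, x$environment, x$replicate, drop = TRUE)
  dup <- unsplit(lapply(split(x$time_h, key), function(t) duplicated(t)), key)
  if (any(dup)) {
    stop(sprintf("duplicate time point within a culture (e.g. %s at t = %g h)",
                 as.character(key[which(dup)[1L]]), x$time_h[which(dup)[1L]]))
  }
  counts <- table(key)
  unusable <- names(counts)[counts < 3L]
  if (length(unusable)) {
    warning(sprintf("%d culture(s) have fewer than 3 time points and are unusable: %s",
                    length(unusable), paste(unusable, collapse = ", ")))
  }
  rownames(x) <- NULL
  attr(x, "unusable") <- unusable
  class(x) <- c("plate_data", "data.frame")
  x
}

#' @rdname read_plate_timeseries
#' @param x a plate table.
#' @param path output CSV path.
#' @export
write_plate_timeseries <- function(x, path) {
  need <- c("strain", "environment", "replicate", "time_h", "od")
  stopifnot(all(need %in% names(x)))
  utils::write.csv(as.data.frame(x)[, need], path, row.names = FALSE)
  invisible(path)
}

#' Read strain metadata
#'
#' @param path CSV with columns `strain_id`, `origin` (each origin either
#'   `"wild"` or `"domesticated"`; strain ids unique).
#' @return A `data.frame(strain_id, origin)`.
#' @export
read_strain_metadata <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("strain_id", "origin"), names(x))
  if (length(miss)) {
    stop("metadata CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(x$strain_id)) {
    stop("duplicate strain_id in metadata: ",
         paste(unique(x$strain_id[duplicated(x$strain_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(x$origin), c("wild", "domesticated"))
  if (length(bad)) {
    stop("origin must be 'wild' or 'domesticated'; found: ",
         paste(bad, collapse = ", "))
  }
  x[, c("strain_id", "origin")]
}

#' Read a cross design
#'
#' @param path CSV with columns `hybrid_id`, `parent1`, `parent2` (and
#'   optionally `cross_class`). Self-crosses and duplicate unordered
#'   parent pairs are errors.
#' @return The cross design `data.frame`.
#' @export
read_cross_design <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("hybrid_id", "parent1", "parent2"), names(x))
  if (length(miss)) {
    stop("cross design CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (any(x$parent1 == x$parent2)) {
    stop("self-cross in design (parent1 == parent2): ",
         x$hybrid_id[which(x$parent1 == x$parent2)[1L]])
  }
  pair <- paste(pmin(x$parent1, x$parent2), pmax(x$parent1, x$parent2))
  if (anyDuplicated(pair)) {
    stop("duplicate unordered parent pair in design: ",
         pair[duplicated(pair)][1L])
  }
  x
}

#' Read a pairwise divergence matrix
#'
#' Accepts a labelled square CSV (first column = row labels, header = the
#' same labels), a PHYLIP-style square matrix (first line the dimension,
#' then label + row), or a newick tree (converted to patristic
#' distances). Symmetry is enforced to 1e-9 — asymmetric input is an
#' error, not averaged; the diagonal must be zero to 1e-9; distances must
#' be nonnegative.
#'
#' @param path input file.
#' @param format `"auto"` (by extension/content), `"csv"`, `"phylip"` or
#'   `"newick"`.
#' @return A labelled symmetric numeric matrix with zero diagonal.
#' @export
read_divergence_matrix <- function(path,
                                   format = c("auto", "csv", "phylip",
                                              "newick")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^\\s*\\(", first)) "newick"
              else if (grepl("^\\s*\\d+\\s*$", first)) "phylip"
              else "csv"
  }
  d <- switch(format,
    newick = {
      tr <- ape::read.tree(path)
      ape::cophenetic.phylo(tr)
    },
    phylip = {
      lines <- readLines(path)
      n <- as.integer(trimws(lines[1L]))
      if (is.na(n) || length(lines) < n + 1L) stop("malformed PHYLIP matrix")
      parts <- strsplit(trimws(lines[2:(n + 1L)]), "\\s+")
      labels <- vapply(parts, `[[`, character(1), 1L)
      vals <- lapply(parts, function(p) as.numeric(p[-1L]))
      if (any(vapply(vals, length, integer(1)) != n)) {
        stop("PHYLIP matrix is not square")
      }
      m <- do.call(rbind, vals)
      dimnames(m) <- list(labels, labels)
      m
    },
    csv = {
      x <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
      m <- as.matrix(x)
      if (nrow(m) != ncol(m)) stop("divergence matrix is not square")
      if (!all(rownames(m) == colnames(m))) {
        stop("row and column labels of the divergence matrix differ")
      }
      m
    })
  validate_divergence(d)
}

validate_divergence <- function(d, tol = 1e-9) {
  if (anyDuplicated(rownames(d))) stop("divergence matrix labels are not unique")
  if (!is.numeric(d)) stop("divergence matrix must be numeric")
  asym <- max(abs(d - t(d)))
  if (asym > tol) {
    stop(sprintf("divergence matrix is asymmetric (max |d_ij - d_ji| = %g)",
                 asym))
  }
  if (max(abs(diag(d))) > tol) {
    stop("divergence matrix diagonal is not zero")
  }
  diag(d) <- 0
  d <- (d + t(d)) / 2  # removes sub-tolerance floating asymmetry only
  if (any(d < 0)) stop("divergence distances must be nonnegative")
  d
}

#' @rdname read_divergence_matrix
#' @param d a labelled symmetric matrix.
#' @export
write_divergence_matrix <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = TRUE)
  invisible(path)
}

#' Read a replicate-level MGR table
#'
#' @param path CSV with columns `strain`, `environment`, `replicate`,
#'   `mgr_per_h` and optionally `pearson_r`, `n_points`, `od_lower`,
#'   `od_upper`, `qc_pass` (as written by the pipeline; `qc_pass` defaults
#'   to `TRUE` when absent).
#' @return A `data.frame` usable by [fitness_matrix()],
#'   [heterosis_scores()] and [icc_average()].
#' @export
read_mgr_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "environment", "replicate", "mgr_per_h")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("MGR table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!"qc_pass" %in% names(x)) x$qc_pass <- TRUE
  x$qc_pass <- as.logical(x$qc_pass)
  x
}

#' Write a JSON run manifest
#'
#' Records the parameters, seed and MD5 hashes of the input files of a
#' pipeline run, for provenance.
#'
#' @param path output JSON path.
#' @param params named list of parameters used.
#' @param seed the seed used (or `NULL`).
#' @param inputs character vector of input file paths to hash.
#' @export
write_run_manifest <- function(path, params = list(), seed = NULL,
                               inputs = character()) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(timestamp = format(Sys.time(), tz = "UTC"),
                   seed = seed, params = params, input_md5 = hashes)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
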