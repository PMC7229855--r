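#' Write a conformation to XYZ or PDB-trace format
#'
#' XYZ: one pseudo-atom per base-pair origin (element `C`), optionally
#' followed by the backbone attachment points of both strands (`P`).
#' PDB trace: fixed-column ATOM records with one P pseudo-atom per base
#' pair, 1-based residue numbering, coordinates in Angstrom.
#'
#' @param conf A `dna_conformation`.
#' @param path Output file path.
#' @param format `"xyz"` or `"pdb_trace"`.
#' @param backbone Include backbone points (XYZ only)?
#' @return `path`, invisibly.
#' @export
write_conformation <- function(conf, path, format = c("xyz", "pdb_trace"),
                               backbone = FALSE) {
  stopifnot(inherits(conf, "dna_conformation"))
  format <- match.arg(format)
  o <- conf$origins
  n <- nrow(o)
  if (format == "xyz") {
    pts <- o
    elem <- rep("C", n)
    if (backbone) {
      pts <- rbind(o, conf$backbone_a, conf$backbone_b)
      elem <- c(elem, rep("P", 2 * n))
    }
    lines <- c(
      as.character(nrow(pts)),
      "base-pair origins (nm)",
      sprintf("%s %.6f %.6f %.6f", elem, pts[, 1], pts[, 2], pts[, 3])
    )
  } else {
    # PDB uses Angstrom
    lines <- sprintf(
      "ATOM  %5d  P   DA  A%4d    %8.3f%8.3f%8.3f  1.00  0.00           P",
      seq_len(n), seq_len(n), o[, 1] * 10, o[, 2] * 10, o[, 3] * 10
    )
    lines <- c(lines, "END")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a conformation written by [write_conformation()]
#'
#' @param path File path.
#' @param format `"xyz"` or `"pdb_trace"`.
#' @return Tibble with columns `x_nm`, `y_nm`, `z_nm` (origins only; XYZ
#'   backbone points, if present, get `point = "backbone_a"/"backbone_b"`).
#' @export
read_conformation <- function(path, format = c("xyz", "pdb_trace")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "xyz") {
    n <- as.integer(lines[1])
    body <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
    elem <- vapply(body, `[[`, character(1), 1)
    m <- t(vapply(body, function(x) as.numeric(x[2:4]), numeric(3)))
    n_bp <- sum(elem == "C")
    point <- c(rep("origin", n_bp),
               if (n > n_bp) rep(c("backbone_a", "backbone_b"), each = n_bp))
    tibble::tibble(point = point, x_nm = m[, 1], y_nm = m[, 2], z_nm = m[, 3])
  } else {
    rec <- lines[startsWith(lines, "ATOM")]
    tibble::tibble(
      point = "origin",
      x_nm = as.numeric(substr(rec, 31, 38)) / 10,
      y_nm = as.numeric(substr(rec, 39, 46)) / 10,
      z_nm = as.numeric(substr(rec, 47, 54)) / 10
    )
  }
}

#' Write / read an energy landscape or rate profile as CSV
#'
#' Plain CSV with unit-bearing column names, round-tripping the tibbles
#' produced by [energy_landscape()] and [looping_rate_profile()].
#'
#' @param x The tibble to write.
#' @param path File path.
#' @return `path` invisibly (writers); the tibble (readers).
#' @export
write_landscape_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_landscape_csv
#' @export
read_landscape_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (all(c("length_bp", "theta_rad", "energy_kT") %in% names(out))) {
    class(out) <- c("energy_landscape", class(out))
  } else if (all(c("length_bp", "k_rel") %in% names(out))) {
    class(out) <- c("rate_profile", class(out))
  }
  out
}

#' Write an analysis result as a reproducible JSON record
#'
#' Serializes a named list of results together with the full parameter block
#' and seed that produced them, so a run can be reproduced from its output
#' alone.
#'
#' @param results Named list of result values (numbers, vectors, tibbles).
#' @param path Output path.
#' @param parameters Named list of input parameters.
#' @param seed The seed used (or `NA`).
#' @return `path`, invisibly.
#' @export
write_result_json <- function(results, path, parameters = list(),
                              seed = NA) {
  payload <- list(results = results, parameters = parameters, seed = seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write / read first-passage samples as CSV
#'
#' Columns `trace_id`, `fpt_s`, `censored` (0/1), `censor_time_s` -- the
#' interchange format between the FRET analyzer and the rate fitter.
#'
#' @param samples An `fpt_sample` tibble.
#' @param path File path.
#' @export
write_fpt_csv <- function(samples, path) {
  out <- dplyr::mutate(samples, censored = as.integer(.data$censored))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_fpt_csv
#' @export
read_fpt_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::mutate(censored = as.logical(.data$censored))
  class(out) <- c("fpt_sample", class(out))
  out
}
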