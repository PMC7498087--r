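#' Trap arrays
#'
#' A trap array is a tibble with one row per trap and columns `trap_id`
#' (unique identifier), `x` and `y` (planar coordinates in meters, any
#' projected frame). Geographic lat/lon input is not supported: the methods
#' here operate on study areas a few hundred meters across, where a planar
#' frame is exact for all practical purposes.
#'
#' @param traps A data frame with columns `trap_id`, `x`, `y`.
#' @return A tibble of class `trap_array`.
#' @examples
#' trap_array(data.frame(trap_id = c("A", "B"), x = c(0, 10), y = c(0, 0)))
#' @export
trap_array <- function(traps) {
  traps <- tibble::as_tibble(traps)
  need <- c("trap_id", "x", "y")
  miss <- setdiff(need, names(traps))
  if (length(miss)) {
    abort(paste0("trap table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(traps) < 1L) abort("a trap array needs at least one trap")
  traps$trap_id <- as.character(traps$trap_id)
  if (anyDuplicated(traps$trap_id)) {
    dup <- unique(traps$trap_id[duplicated(traps$trap_id)])
    abort(paste0("duplicated trap_id: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (!all(is.finite(traps$x)) || !all(is.finite(traps$y))) {
    abort("trap coordinates must be finite numbers")
  }
  class(traps) <- c("trap_array", class(tibble::tibble()))
  traps
}

#' Capture histories
#'
#' Capture data hold one row per capture event: `individual_id`, `occasion`
#' (1-based), `trap_id`, plus per-individual attributes `sex`
#' (`"M"`, `"F"` or `"unknown"`) and `species`. An individual can be caught in
#' at most one trap per occasion (single- or multi-catch live trapping).
#' The number of occasions is carried as an attribute so that occasions with
#' zero captures still count toward effort.
#'
#' @param captures Data frame with columns `individual_id`, `occasion`,
#'   `trap_id` and optionally `sex`, `species`.
#' @param traps A [trap_array()]; every `trap_id` in `captures` must occur in it.
#' @param n_occasions Integer number of trapping occasions. Defaults to the
#'   largest occasion seen.
#' @return A tibble of class `capture_data` with attribute `n_occasions`.
#' @export
capture_data <- function(captures, traps, n_occasions = NULL) {
  traps <- trap_array(traps)
  captures <- tibble::as_tibble(captures)
  need <- c("individual_id", "occasion", "trap_id")
  miss <- setdiff(need, names(captures))
  if (length(miss)) {
    abort(paste0("capture table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"sex" %in% names(captures)) captures$sex <- "unknown"
  if (!"species" %in% names(captures)) captures$species <- "unknown"
  captures$individual_id <- as.character(captures$individual_id)
  captures$trap_id <- as.character(captures$trap_id)
  captures$sex <- as.character(captures$sex)
  captures$species <- as.character(captures$species)
  captures$occasion <- as.integer(captures$occasion)

  if (nrow(captures)) {
    bad <- which(!captures$trap_id %in% traps$trap_id)
    if (length(bad)) {
      abort(paste0(
        "capture row ", bad[1], " refers to unknown trap_id '",
        captures$trap_id[bad[1]], "'"
      ))
    }
    if (any(!is.finite(captures$occasion)) || any(captures$occasion < 1L)) {
      abort("occasions must be integers >= 1")
    }
    dup <- duplicated(captures[, c("individual_id", "occasion")])
    if (any(dup)) {
      i <- which(dup)[1]
      abort(paste0(
        "capture row ", i, ": individual '", captures$individual_id[i],
        "' has more than one capture in occasion ", captures$occasion[i],
        " (at most one trap per occasion)"
      ))
    }
    for (col in c("sex", "species")) {
      k <- tapply(captures[[col]], captures$individual_id,
                  function(v) length(unique(v)))
      if (any(k > 1L)) {
        abort(paste0(
          "individual '", names(k)[which(k > 1)[1]],
          "' has conflicting ", col, " labels across rows"
        ))
      }
    }
    bad_sex <- setdiff(unique(captures$sex), c("M", "F", "unknown"))
    if (length(bad_sex)) {
      abort(paste0("sex must be 'M', 'F' or 'unknown'; found: ",
                   paste(bad_sex, collapse = ", ")))
    }
  }

  n_occasions <- as.integer(n_occasions %||%
                              (if (nrow(captures)) max(captures$occasion) else 1L))
  if (nrow(captures) && max(captures$occasion) > n_occasions) {
    abort("captures contain occasions beyond n_occasions")
  }
  attr(captures, "n_occasions") <- n_occasions
  class(captures) <- c("capture_data", class(tibble::tibble()))
  captures
}

#' @rdname capture_data
#' @param x A `capture_data` object.
#' @export
n_occasions <- function(x) {
  attr(x, "n_occasions") %||% abort("object carries no n_occasions attribute")
}

#' Read and write pipeline input tables
#'
#' Comma-delimited text with a header row. `read_traps()` expects columns
#' `trap_id,x,y`; `read_captures()` expects
#' `individual_id,occasion,trap_id[,sex,species]`; `read_samples()` expects
#' `sample_id,grid,x,y,analyte,concentration,detection_limit,censored`.
#' Writers are exact inverses: `read_*(write_*(x))` reproduces `x`.
#'
#' @param path File path.
#' @param traps A [trap_array()] used to validate capture records.
#' @param n_occasions Passed to [capture_data()].
#' @return `read_traps()` a [trap_array()]; `read_captures()` a
#'   [capture_data()]; `read_samples()` a tibble of soil-sample records.
#' @name io
NULL

read_delim_quiet <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname io
#' @export
read_traps <- function(path) trap_array(read_delim_quiet(path))

#' @rdname io
#' @export
write_traps <- function(traps, path) {
  readr::write_csv(trap_array(traps), path)
  invisible(path)
}

#' @rdname io
#' @export
read_captures <- function(path, traps, n_occasions = NULL) {
  capture_data(read_delim_quiet(path), traps, n_occasions = n_occasions)
}

#' @rdname io
#' @export
write_captures <- function(captures, path) {
  readr::write_csv(tibble::as_tibble(captures), path)
  invisible(path)
}

#' Soil-sample records
#'
#' One row per (composite sample, analyte): `sample_id`, `grid` (trapping-grid
#' or group label), `x`, `y` (meters), `analyte`, `concentration` (ppm for
#' metals and PCBs, ppt for TEQ), `detection_limit`, and logical `censored`.
#' A censored record is a nondetect reported *at* its detection limit -- the
#' substitution convention carried through all downstream statistics -- so
#' `censored` implies `concentration == detection_limit`.
#'
#' @param samples Data frame of sample records.
#' @return A validated tibble.
#' @export
chem_samples <- function(samples) {
  samples <- tibble::as_tibble(samples)
  need <- c("sample_id", "grid", "x", "y", "analyte", "concentration",
            "detection_limit", "censored")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    abort(paste0("sample table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  samples$censored <- as.logical(samples$censored)
  if (any(!is.finite(samples$concentration)) || any(samples$concentration <= 0)) {
    abort("concentrations must be finite and > 0")
  }
  bad <- which(samples$censored &
                 samples$concentration != samples$detection_limit)
  if (length(bad)) {
    abort(paste0(
      "sample row ", bad[1], ": censored record must carry concentration ",
      "equal to its detection limit"
    ))
  }
  samples
}

#' @rdname io
#' @export
read_samples <- function(path) chem_samples(read_delim_quiet(path))

#' @rdname io
#' @param samples A tibble of soil-sample records.
#' @export
write_samples <- function(samples, path) {
  readr::write_csv(chem_samples(samples), path)
  invisible(path)
}

#' Read and write ESRI ASCII grids
#'
#' Minimal reader/writer for the plain-text ESRI ASCII raster format
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header followed by
#' rows north to south). Values are returned as a long tibble of cell centers,
#' the layout used by habitat masks and kriging surfaces.
#'
#' @param path File path.
#' @return `read_asc()`: tibble with `x`, `y`, `value`; cell size and origin
#'   as attributes `cellsize`, `xllcorner`, `yllcorner`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7L) abort("not an ESRI ASCII grid: too few lines")
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  if (any(lengths(hdr) < 2L)) {
    abort("not an ESRI ASCII grid: malformed header")
  }
  keys <- tolower(vapply(hdr, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(vapply(hdr, `[[`, "", 2L)))
  h <- setNames(vals, keys)
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys)) {
    abort(paste0("not an ESRI ASCII grid: missing header field(s) ",
                 paste(setdiff(need, keys), collapse = ", ")))
  }
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != h["ncols"] * h["nrows"]) {
    abort("ESRI ASCII grid body does not match ncols x nrows")
  }
  if ("nodata_value" %in% keys) body[body == h["nodata_value"]] <- NA_real_
  nc <- h[["ncols"]]; nr <- h[["nrows"]]; cs <- h[["cellsize"]]
  # rows are written north to south
  xs <- h[["xllcorner"]] + (seq_len(nc) - 0.5) * cs
  ys <- h[["yllcorner"]] + (rev(seq_len(nr)) - 0.5) * cs
  out <- tibble::tibble(
    x = rep(xs, times = nr),
    y = rep(ys, each = nc),
    value = body
  )
  attr(out, "cellsize") <- cs
  attr(out, "xllcorner") <- h[["xllcorner"]]
  attr(out, "yllcorner") <- h[["yllcorner"]]
  out
}

#' @rdname read_asc
#' @param grid Long tibble with `x`, `y`, `value` on a regular lattice.
#' @param na_value Value written for missing cells.
#' @export
write_asc <- function(grid, path, na_value = -9999) {
  xs <- sort(unique(grid$x)); ys <- sort(unique(grid$y))
  csx <- if (length(xs) > 1) min(diff(xs)) else attr(grid, "cellsize") %||% 1
  mat <- matrix(NA_real_, nrow = length(ys), ncol = length(xs))
  mat[cbind(match(grid$y, ys), match(grid$x, xs))] <- grid$value
  mat[is.na(mat)] <- na_value
  hdr <- c(
    paste("ncols", length(xs)),
    paste("nrows", length(ys)),
    paste("xllcorner", format(min(xs) - csx / 2, digits = 15)),
    paste("yllcorner", format(min(ys) - csx / 2, digits = 15)),
    paste("cellsize", format(csx, digits = 15)),
    paste("NODATA_value", na_value)
  )
  rows <- vapply(rev(seq_along(ys)), function(i) {
    paste(format(mat[i, ], digits = 10, trim = TRUE, scientific = FALSE),
          collapse = " ")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a key = value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values that parse as
#' numbers are returned numeric, `true`/`false` as logical, comma-separated
#' values as vectors.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      abort(paste0("config line is not 'key = value': '", ln, "'"))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    parsed <- if (!anyNA(num)) {
      num
    } else if (all(tolower(parts) %in% c("true", "false"))) {
      tolower(parts) == "true"
    } else {
      parts
    }
    out[[key]] <- parsed
  }
  out
}
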