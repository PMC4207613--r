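#' Read a per-nucleus record table
#'
#' Reads a comma-separated, headered, UTF-8 table of per-nucleus records
#' (one row per nucleus). `gonad_id`, `nucleus_id` and `axial_pos` are
#' required; the quantitation columns (`stage`, `dapi_count`, `cosa_count`,
#' `rad51_count`, `paired`, locus coordinates `l1_x .. l2_z` in um, marker
#' booleans) are optional and validated when present. Axial positions must
#' be normalised to `[0, 1]`; malformed rows are reported with their row
#' numbers.
#'
#' @param path CSV file path.
#' @return a data frame of validated records (possibly empty).
#' @export
read_nucleus_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gonad_id", "nucleus_id", "axial_pos")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) return(df)
  bad <- which(is.na(df$axial_pos) | df$axial_pos < 0 | df$axial_pos > 1)
  if (length(bad) > 0)
    stop("axial_pos outside [0, 1] in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  for (cc in intersect(c("dapi_count", "cosa_count", "rad51_count"),
                       names(df))) {
    v <- df[[cc]]
    bad <- which(!is.na(v) & (v < 0 | v != floor(v)))
    if (length(bad) > 0)
      stop(cc, " must be a non-negative integer; bad row(s): ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  if ("paired" %in% names(df)) df$paired <- as.logical(df$paired)
  df
}

#' Write a per-nucleus record table
#'
#' @param records data frame of per-nucleus records.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_nucleus_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text key:value configuration file
#'
#' One `key: value` pair per line; blank lines and `#` comments ignored.
#' Values that parse as numbers are returned numeric; comma-separated
#' values become vectors.
#'
#' @param path file path.
#' @return a named list.
#' @export
read_keyval <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):(.*)$", ln))[[1]]
    if (length(m) != 3)
      stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(m[2])
    parts <- trimws(strsplit(m[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

write_keyval <- function(x, path) {
  lines <- vapply(names(x), function(k)
    paste0(k, ": ", paste(x[[k]], collapse = ", ")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a 3D stack as a multi-page TIFF with a voxel-size sidecar
#'
#' Pages are z-slices (ZYX order). TIFF stores values in `[0, 1]`, so the
#' stack is divided by its maximum and the scale factor recorded in the
#' sidecar (`<path>.cfg`) together with the voxel size, which the reader
#' uses to restore the original intensities.
#'
#' @param stack 3D numeric array `(z, y, x)`.
#' @param path output TIFF path; the sidecar is written at `<path>.cfg`.
#' @param voxel_size_nm named numeric `(z, y, x)` in nm.
#' @return the path, invisibly.
#' @export
write_stack <- function(stack, path, voxel_size_nm) {
  stopifnot(length(dim(stack)) == 3L, length(voxel_size_nm) == 3L)
  scale <- max(stack, 1)
  pages <- lapply(seq_len(dim(stack)[1]), function(z) stack[z, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  write_keyval(list(voxel_size_z_nm = voxel_size_nm[1],
                    voxel_size_y_nm = voxel_size_nm[2],
                    voxel_size_x_nm = voxel_size_nm[3],
                    intensity_scale = scale),
               paste0(path, ".cfg"))
  invisible(path)
}

#' Read a 3D stack and its voxel size
#'
#' Reads a multi-page TIFF into a `(z, y, x)` array. The physical voxel
#' size is never guessed: it must be present in the sidecar configuration
#' (`<path>.cfg` by default, `key: value` format with keys
#' `voxel_size_z_nm`, `voxel_size_y_nm`, `voxel_size_x_nm`, optionally
#' `intensity_scale`). A single-page file is treated as a one-slice stack
#' with a warning.
#'
#' @param path TIFF path.
#' @param config_path sidecar path (default `<path>.cfg`).
#' @return list with `stack` (3D array) and `voxel_size_nm`.
#' @export
read_stack <- function(path, config_path = paste0(path, ".cfg")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!file.exists(config_path))
    stop("no voxel-size sidecar at ", config_path,
         "; create it with lines like 'voxel_size_z_nm: 125' (z, y, x)",
         call. = FALSE)
  cfg <- read_keyval(config_path)
  need <- c("voxel_size_z_nm", "voxel_size_y_nm", "voxel_size_x_nm")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0)
    stop("sidecar missing: ", paste(miss, collapse = ", "), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 1)
    warning("single-page file treated as a one-slice stack")
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1)
    stop("pages have differing shapes", call. = FALSE)
  arr <- aperm(simplify2array(pages), c(3, 1, 2))
  scale <- if (!is.null(cfg$intensity_scale)) cfg$intensity_scale else 1
  list(stack = arr * scale,
       voxel_size_nm = c(z = cfg$voxel_size_z_nm, y = cfg$voxel_size_y_nm,
                         x = cfg$voxel_size_x_nm))
}

#' Write a JSON provenance sidecar for a run
#'
#' Records the package version, timestamp, seed and the fully resolved
#' parameters next to a run's outputs, so any output can be regenerated.
#'
#' @param path output JSON path.
#' @param params named list of resolved parameters.
#' @param seed integer seed used (or `NULL`).
#' @return the path, invisibly.
#' @export
write_provenance <- function(path, params, seed = NULL) {
  obj <- list(package = "meioquant",
              version = as.character(packageVersion("meioquant")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed, params = params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
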