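#' Read a force-distance curve from a TSV file
#'
#' The on-disk dialect is UTF-8 TSV: header lines of the form
#' `# key<TAB>value` carrying the mandatory metadata keys `curve_id`,
#' `spring_constant_pN_per_nm`, `retract_speed_um_per_s`, `temperature_K` and
#' `setpoint_pN` (plus optional `probe_label` and `distance_mode`), followed
#' by a column header `segment  time_s  height_nm  force_pN` and one row per
#' sample.  [write_curve()] emits exactly this dialect, and numbers are
#' written with round-trip precision so `read_curve(write_curve(x))`
#' reproduces the samples.
#'
#' @param path Path to a curve file.
#' @return A [force_curve()].
#' @export
read_curve <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_header <- grepl("^#", lines)
  n_header <- if (any(!is_header)) which(!is_header)[1] - 1L else length(lines)
  header <- lines[seq_len(n_header)]
  meta <- list()
  for (h in header) {
    kv <- strsplit(sub("^#\\s*", "", h), "\t", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  mandatory <- c("curve_id", "spring_constant_pN_per_nm",
                 "retract_speed_um_per_s", "temperature_K", "setpoint_pN")
  for (key in mandatory) {
    if (is.null(meta[[key]])) {
      stop("curve file '", path, "' is missing mandatory header key '", key, "'")
    }
  }
  body <- paste(lines[!is_header], collapse = "\n")
  samples <- readr::read_tsv(I(body), show_col_types = FALSE, progress = FALSE,
                             col_types = readr::cols(
                               segment = readr::col_character(),
                               time_s = readr::col_double(),
                               height_nm = readr::col_double(),
                               force_pN = readr::col_double()))
  force_curve(
    samples,
    spring_constant = as.numeric(meta$spring_constant_pN_per_nm),
    retract_speed = as.numeric(meta$retract_speed_um_per_s),
    temperature = as.numeric(meta$temperature_K),
    setpoint = as.numeric(meta$setpoint_pN),
    curve_id = meta$curve_id,
    probe_label = meta$probe_label %||% "",
    distance_mode = meta$distance_mode %||% "height"
  )
}

#' Write a force-distance curve to a TSV file
#'
#' @param curve A [force_curve()] with a non-empty retract segment.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @rdname read_curve
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  if (sum(curve$segment == "retract") == 0) {
    stop("refusing to write curve '", attr(curve, "curve_id"),
         "': no retract samples")
  }
  m <- curve_meta(curve)
  header <- c(
    paste0("# curve_id\t", m$curve_id),
    paste0("# spring_constant_pN_per_nm\t", format(m$spring_constant_pN_per_nm, digits = 15)),
    paste0("# retract_speed_um_per_s\t", format(m$retract_speed_um_per_s, digits = 15)),
    paste0("# temperature_K\t", format(m$temperature_K, digits = 15)),
    paste0("# setpoint_pN\t", format(m$setpoint_pN, digits = 15)),
    paste0("# probe_label\t", m$probe_label),
    paste0("# distance_mode\t", m$distance_mode)
  )
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  readr::write_tsv(as_tibble(as.data.frame(curve)), con, progress = FALSE)
  invisible(path)
}

#' Read or write a force-volume grid index
#'
#' The index is a CSV file with columns `row`, `col`, `curve_path`
#' (0-based pixel coordinates, row-major).  The curve identifier of each
#' pixel is taken from the file name unless a `curve_id` column is present.
#'
#' @param path Index CSV path.
#' @param n_rows,n_cols Grid dimensions; inferred from the maximum indices
#'   when omitted.
#' @return A [force_volume_grid()].
#' @export
read_grid_index <- function(path, n_rows = NULL, n_cols = NULL) {
  idx <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("row", "col", "curve_path") %in% names(idx)))
  if (is.null(idx$curve_id)) {
    idx$curve_id <- sub("\\.[^.]*$", "", basename(idx$curve_path))
  }
  force_volume_grid(idx,
                    n_rows = n_rows %||% (max(idx$row) + 1L),
                    n_cols = n_cols %||% (max(idx$col) + 1L))
}

#' @param grid A [force_volume_grid()] with a `curve_path` column.
#' @rdname read_grid_index
#' @export
write_grid_index <- function(grid, path) {
  stopifnot(inherits(grid, "force_volume_grid"))
  if (is.null(grid$curve_path)) stop("grid has no curve_path column")
  readr::write_csv(as_tibble(as.data.frame(grid)), path, progress = FALSE)
  invisible(path)
}
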