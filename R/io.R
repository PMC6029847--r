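## Plain-text readers and writers. All formats are TSV or whitespace
## matrix text with "#"-prefixed metadata lines ("# key: value");
## generators' ground truth goes to JSON sidecars.

write_meta_lines <- function(meta, con) {
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
}

read_meta_lines <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    k <- sub(":.*$", "", kv)
    v <- trimws(sub("^[^:]*:", "", kv))
    meta[[trimws(k)]] <- v
  }
  list(meta = meta, n_skip = length(meta_lines))
}

#' Write / read a force curve as TSV
#'
#' Columns `z_nm`, `deflection_nm`, `segment`; metadata lines carry the
#' spring constant and medium.
#'
#' @param curve A [force_curve()].
#' @param path File path.
#' @return `read_force_curve` returns a [force_curve()].
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  con <- file(path, "w"); on.exit(close(con))
  write_meta_lines(list(k_N_per_m = curve$k, medium = curve$medium), con)
  df <- data.frame(z_nm = curve$z, deflection_nm = curve$d,
                   segment = curve$segments)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  m <- read_meta_lines(path)
  df <- utils::read.delim(path, skip = m$n_skip)
  force_curve(z = df$z_nm, d = df$deflection_nm,
              k = as.numeric(m$meta$k_N_per_m),
              segments = df$segment,
              medium = m$meta$medium %||% "hydrated")
}

#' Write / read a topography grid
#'
#' Whitespace-separated height matrix (nm) with metadata lines for the
#' pixel size and medium. With `format = "tiff"` a 32-bit float
#' single-channel TIFF is written/read instead (requires the `tiff`
#' package); pixel size must then be given to the reader.
#'
#' @param topo A [topography()].
#' @param path File path.
#' @param format `"text"` or `"tiff"`.
#' @param pixel_nm Pixel size when reading TIFF.
#' @param medium Medium tag when reading TIFF.
#' @return `read_topography` returns a [topography()].
#' @export
write_topography <- function(topo, path, format = c("text", "tiff")) {
  stopifnot(inherits(topo, "topography"))
  format <- match.arg(format)
  if (format == "tiff") {
    cm_check(requireNamespace("tiff", quietly = TRUE), "cm_configuration_error",
             "the 'tiff' package is required for TIFF output")
    sc <- max(abs(topo$height), 1e-12)
    tiff::writeTIFF(topo$height / sc, path, bits.per.sample = 32L)
    return(invisible(path))
  }
  con <- file(path, "w"); on.exit(close(con))
  write_meta_lines(list(pixel_nm = topo$pixel_nm, medium = topo$medium), con)
  utils::write.table(topo$height, con, sep = " ", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_topography
#' @export
read_topography <- function(path, format = c("text", "tiff"),
                            pixel_nm = NULL, medium = "hydrated") {
  format <- match.arg(format)
  if (format == "tiff") {
    cm_check(requireNamespace("tiff", quietly = TRUE), "cm_configuration_error",
             "the 'tiff' package is required for TIFF input")
    cm_check(!is.null(pixel_nm), "cm_configuration_error",
             "pixel_nm must be supplied when reading TIFF")
    h <- tiff::readTIFF(path)
    return(topography(h, pixel_nm = pixel_nm, medium = medium))
  }
  m <- read_meta_lines(path)
  h <- as.matrix(utils::read.table(path, skip = m$n_skip))
  dimnames(h) <- NULL
  topography(h, pixel_nm = as.numeric(m$meta$pixel_nm),
             medium = m$meta$medium %||% "hydrated")
}

#' Write / read a compression trace as TSV
#'
#' Columns `time_s`, `force_uN`, `displacement_um`; metadata carries the
#' two radii and the pre-test horizontal diameter.
#'
#' @param test A [compression_test()].
#' @param path File path.
#' @return `read_compression_test` returns a [compression_test()].
#' @export
write_compression_test <- function(test, path) {
  stopifnot(inherits(test, "compression_test"))
  con <- file(path, "w"); on.exit(close(con))
  write_meta_lines(list(R_h_um = test$R_h_um, R_v_um = test$R_v_um,
                        d0_um = test$d0_um,
                        n_cycles = test$protocol$n_cycles,
                        phases_s = test$protocol$phases), con)
  df <- data.frame(time_s = test$time, force_uN = test$force,
                   displacement_um = test$displacement)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_compression_test
#' @export
read_compression_test <- function(path) {
  m <- read_meta_lines(path)
  df <- utils::read.delim(path, skip = m$n_skip)
  phases <- as.numeric(strsplit(m$meta$phases_s %||% "15 2 15 2", " +")[[1]])
  names(phases) <- c("compress", "hold", "recover", "rest")
  compression_test(time = df$time_s, force = df$force_uN,
                   displacement = df$displacement_um,
                   R_h_um = as.numeric(m$meta$R_h_um),
                   R_v_um = as.numeric(m$meta$R_v_um),
                   d0_um = as.numeric(m$meta$d0_um),
                   protocol = list(n_cycles = as.integer(m$meta$n_cycles %||% 5L),
                                   phases = phases, strain_max = 0.25))
}

#' Write a generator's ground-truth sidecar as JSON
#'
#' @param x A generator output carrying a `truth` attribute.
#' @param path File path (conventionally `<data>.truth.json`).
#' @export
write_truth_json <- function(x, path) {
  truth <- attr(x, "truth")
  cm_check(!is.null(truth), "cm_validation_error", "object carries no truth sidecar")
  drop_cls <- function(v) if (is.object(v)) unclass(v) else v
  jsonlite::write_json(rapply(truth, drop_cls, how = "replace"), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(path)
}

#' Write / read a cohort table as TSV
#'
#' @param cohort Data.frame from [synth_cohort()] or user data.
#' @param path File path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
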