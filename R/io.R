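# NRRD dose-grid files. Attached-header NRRD with raw little-endian data;
# no NRRD reader exists among the available R packages, so a minimal
# writer/parser for exactly this dialect lives here. Provenance travels as a
# JSON-encoded NRRD key-value pair and is mirrored in a .json sidecar.

#' Write a dose grid to an NRRD file
#'
#' Attached-header NRRD, raw little-endian encoding, `double` precision by
#' default so that write/read round trips are bit-exact (`float` available
#' for compactness). The full provenance list is stored as a JSON string in
#' the `braggshift_provenance` key-value field and mirrored to
#' `<path>.json`.
#'
#' @param grid A `dose_grid`.
#' @param path Output file path.
#' @param precision `"double"` (lossless) or `"float"`.
#' @return `path`, invisibly.
#' @export
write_dose_grid <- function(grid, path, precision = c("double", "float")) {
  stopifnot(inherits(grid, "dose_grid"))
  precision <- match.arg(precision)
  g <- grid$grid
  prov_json <- jsonlite::toJSON(grid$provenance, auto_unbox = TRUE,
                                digits = NA, null = "null")
  header <- c(
    "NRRD0004",
    "# braggshift dose grid",
    sprintf("type: %s", precision),
    "dimension: 3",
    sprintf("sizes: %d %d %d", g$n[1], g$n[2], g$n[3]),
    "encoding: raw",
    "endian: little",
    "space dimension: 3",
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            g$origin[1], g$origin[2], g$origin[3]),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            g$voxel[1], g$voxel[2], g$voxel[3]),
    "space units: \"cm\" \"cm\" \"cm\"",
    sprintf("braggshift_provenance:=%s", prov_json),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  writeBin(as.vector(grid$values), con,
           size = if (precision == "double") 8L else 4L,
           endian = "little")
  jsonlite::write_json(grid$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a dose grid from an NRRD file
#'
#' Reads files produced by [write_dose_grid()]. The header must carry sizes,
#' raw little-endian encoding, voxel spacings (`space directions`) and the
#' `braggshift_provenance` key; a missing field is an error naming it.
#'
#' @param path NRRD file path.
#' @return A `dose_grid`.
#' @export
read_dose_grid <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("truncated NRRD header (no blank line)")
    if (ln == "") break
    lines <- c(lines, ln)
  }
  if (!grepl("^NRRD", lines[1])) stop("not an NRRD file")
  fields <- lines[!grepl("^#", lines)][-1]
  get_field <- function(key, kv = FALSE) {
    sep <- if (kv) ":=" else ": "
    hit <- fields[startsWith(fields, paste0(key, sep))]
    if (length(hit) == 0L)
      stop(sprintf("NRRD header is missing required field '%s'", key))
    sub(paste0("^", key, sep), "", hit[1], fixed = FALSE)
  }
  type <- get_field("type")
  if (!type %in% c("double", "float"))
    stop("unsupported NRRD type: ", type)
  sizes <- as.integer(strsplit(get_field("sizes"), "\\s+")[[1]])
  if (length(sizes) != 3L) stop("expected 3 sizes")
  if (get_field("encoding") != "raw") stop("unsupported NRRD encoding")
  if (get_field("endian") != "little") stop("unsupported NRRD endianness")
  dirs <- regmatches(get_field("space directions"),
                     gregexpr("\\(([^)]*)\\)",
                              get_field("space directions")))[[1]]
  voxel <- vapply(seq_along(dirs), function(k) {
    as.numeric(strsplit(gsub("[()]", "", dirs[k]), ",")[[1]])[k]
  }, numeric(1))
  origin <- as.numeric(strsplit(gsub("[()]", "",
                                     get_field("space origin")), ",")[[1]])
  prov <- jsonlite::fromJSON(get_field("braggshift_provenance", kv = TRUE),
                             simplifyVector = TRUE)
  n_vox <- prod(sizes)
  vals <- readBin(con, "double", n = n_vox,
                  size = if (type == "double") 8L else 4L, endian = "little")
  if (length(vals) != n_vox) stop("truncated NRRD data block")
  grid <- structure(list(n = sizes, voxel = voxel, origin = origin,
                         extent = sizes * voxel),
                    class = "phantom_grid")
  .new_dose_grid(array(vals, dim = sizes), grid, prov)
}
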