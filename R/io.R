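#' Write / read a cortical surface as GIfTI
#'
#' ASCII-encoded GIfTI surface files (`.surf.gii`): one POINTSET data array
#' (vertex coordinates, mm — declared in the array metadata) and one
#' TRIANGLE array (0-based face indices, converted to and from this
#' package's 1-based convention).
#'
#' @param mesh a [cortical_mesh()].
#' @param path file path (conventionally `*.surf.gii`).
#' @return `write_surface_gifti` returns `path` invisibly;
#'   `read_surface_gifti` returns a [cortical_mesh()].
#' @export
write_surface_gifti <- function(mesh, path) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "2")
  .gii_add_array(doc, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
                 mesh$vertices, meta = c(Units = "mm"))
  .gii_add_array(doc, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                 mesh$faces - 1L)
  xml2::write_xml(doc, path)
  invisible(path)
}

.gii_add_array <- function(doc, intent, dtype, mat, meta = NULL) {
  da <- xml2::xml_add_child(doc, "DataArray", Intent = intent,
                            DataType = dtype, ArrayIndexingOrder = "RowMajorOrder",
                            Dimensionality = "2",
                            Dim0 = as.character(nrow(mat)),
                            Dim1 = as.character(ncol(mat)),
                            Encoding = "ASCII", Endian = "LittleEndian")
  if (!is.null(meta)) {
    md <- xml2::xml_add_child(da, "MetaData")
    for (nm in names(meta)) {
      entry <- xml2::xml_add_child(md, "MD")
      xml2::xml_add_child(entry, "Name", nm)
      xml2::xml_add_child(entry, "Value", meta[[nm]])
    }
  }
  vals <- if (is.integer(mat)) as.character(t(mat)) else
    format(t(mat), digits = 9, trim = TRUE, scientific = FALSE)
  xml2::xml_add_child(da, "Data", paste(vals, collapse = " "))
  invisible(da)
}

.gii_read_array <- function(da) {
  dim0 <- as.integer(xml2::xml_attr(da, "Dim0"))
  dim1 <- as.integer(xml2::xml_attr(da, "Dim1"))
  raw <- xml2::xml_text(xml2::xml_find_first(da, "./Data"))
  vals <- as.numeric(strsplit(trimws(raw), "\\s+")[[1L]])
  if (length(vals) != dim0 * dim1) stop("GIfTI data length mismatch")
  matrix(vals, nrow = dim0, ncol = dim1, byrow = TRUE)
}

#' @rdname write_surface_gifti
#' @export
read_surface_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  intents <- xml2::xml_attr(arrays, "Intent")
  ip <- which(intents == "NIFTI_INTENT_POINTSET")
  it <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (!length(ip) || !length(it)) stop("not a GIfTI surface file")
  vertices <- .gii_read_array(arrays[[ip[1L]]])
  faces <- .gii_read_array(arrays[[it[1L]]]) + 1L
  storage.mode(faces) <- "integer"
  cortical_mesh(vertices, faces)
}

#' Write / read a per-vertex functional map as GIfTI
#'
#' Single-column ASCII GIfTI functional file (`.func.gii`) carrying one
#' value per mesh vertex; method and study identifiers travel in the array
#' metadata.
#'
#' @param map a [source_map()].
#' @param path file path (conventionally `*.func.gii`).
#' @return `write_map_gifti` returns `path` invisibly; `read_map_gifti`
#'   returns a [source_map()].
#' @export
write_map_gifti <- function(map, path) {
  stopifnot(inherits(map, "source_map"))
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "1")
  .gii_add_array(doc, "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32",
                 matrix(map$amplitudes, ncol = 1L),
                 meta = c(method = map$method_label,
                          study = as.character(map$study_id)))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_map_gifti
#' @export
read_map_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  da <- xml2::xml_find_first(doc, ".//DataArray")
  vals <- .gii_read_array(da)[, 1L]
  meta_names <- xml2::xml_text(xml2::xml_find_all(da, ".//MD/Name"))
  meta_vals <- xml2::xml_text(xml2::xml_find_all(da, ".//MD/Value"))
  meta <- stats::setNames(as.list(meta_vals), meta_names)
  source_map(vals, meta$method %||% "MNE",
             study_id = meta$study %||% NA_character_)
}

#' Write / read a source map as CSV
#'
#' Two columns: `vertex_id` (1-based) and `value`.
#'
#' @param map a [source_map()].
#' @param path file path.
#' @return `write_map_csv` returns `path` invisibly; `read_map_csv` a
#'   numeric vector of per-vertex values.
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(data.frame(vertex_id = seq_along(map$amplitudes),
                              value = map$amplitudes),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  d <- utils::read.csv(path)
  v <- numeric(max(d$vertex_id))
  v[d$vertex_id] <- d$value
  v
}

#' Write / read a focus region as a plain-text label file
#'
#' One 1-based vertex index per line; lines starting with `#` are comments
#' (the label text is stored in the first comment line).
#'
#' @param region a [focus_region()].
#' @param path file path.
#' @param mesh mesh used to validate indices on read.
#' @return `write_region_label` returns `path` invisibly;
#'   `read_region_label` a [focus_region()].
#' @export
write_region_label <- function(region, path) {
  writeLines(c(paste0("# ", region$label),
               as.character(region$vertex_ids)), path)
  invisible(path)
}

#' @rdname write_region_label
#' @export
read_region_label <- function(path, mesh) {
  lines <- readLines(path)
  label <- sub("^#\\s*", "", lines[grepl("^#", lines)][1L])
  if (is.na(label)) label <- "focus"
  ids <- as.integer(lines[!grepl("^#", lines) & nzchar(lines)])
  focus_region(ids, mesh, label = label)
}
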