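# Surface and label file I/O.
#
# No neuroimaging I/O package ships with the target environment, so minimal
# readers/writers are implemented here: the FreeSurfer binary triangle
# surface (big-endian, magic 0xFFFFFE), FreeSurfer ASCII .label files, and a
# small GIFTI dialect (ASCII or Base64Binary encodings, optional gzip).
# On-disk vertex indices are 0-based in both formats; everything in memory
# is 1-based.

FS_TRIANGLE_MAGIC <- as.raw(c(0xff, 0xff, 0xfe))

#' Read a FreeSurfer binary triangle surface
#'
#' @param path file path (e.g. `lh.white`).
#' @return A `cortical_mesh`.
#' @export
read_freesurfer_surface <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 3L || !identical(raw[1:3], FS_TRIANGLE_MAGIC))
    stop("not a FreeSurfer triangle surface (bad magic at byte offset 0): ", path)
  # comment line terminated by "\n\n"
  nl <- which(raw == as.raw(0x0a))
  end_comment <- NA_integer_
  for (i in nl) {
    if (i + 1L <= length(raw) && raw[i + 1L] == as.raw(0x0a)) { end_comment <- i + 1L; break }
  }
  if (is.na(end_comment))
    stop("malformed FreeSurfer surface: comment terminator not found ",
         "(searched from byte offset 3): ", path)
  con <- rawConnection(raw[(end_comment + 1L):length(raw)])
  on.exit(close(con))
  counts <- readBin(con, "integer", n = 2L, size = 4L, endian = "big")
  nv <- counts[1]; nf <- counts[2]
  if (is.na(nv) || is.na(nf) || nv < 3L || nf < 1L)
    stop("malformed FreeSurfer surface: implausible counts at byte offset ",
         end_comment, ": ", path)
  need <- end_comment + 8L + nv * 12L + nf * 12L
  if (length(raw) < need)
    stop("truncated FreeSurfer surface: expected ", need, " bytes, got ",
         length(raw), " (failed at byte offset ", length(raw), "): ", path)
  coords <- readBin(con, "double", n = 3L * nv, size = 4L, endian = "big")
  faces <- readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big")
  coords <- matrix(coords, ncol = 3L, byrow = TRUE)
  faces <- matrix(faces, ncol = 3L, byrow = TRUE) + 1L
  cortical_mesh(coords, faces)
}

#' Write a FreeSurfer binary triangle surface
#'
#' @param mesh a `cortical_mesh`.
#' @param path output path.
#' @export
write_freesurfer_surface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(FS_TRIANGLE_MAGIC, con)
  writeChar("created by confield\n\n", con, eos = NULL)
  writeBin(c(mesh$n_vertices, nrow(mesh$triangles)), con, size = 4L, endian = "big")
  writeBin(as.numeric(t(mesh$coords)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$triangles) - 1L), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read a FreeSurfer ASCII label file
#'
#' @param path `.label` file path.
#' @return Integer vector of 1-based vertex ids.
#' @export
read_freesurfer_label <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 2L) stop("malformed label file (no vertex rows): ", path)
  n <- suppressWarnings(as.integer(lines[1]))
  if (is.na(n)) stop("malformed label file (bad count line): ", path)
  if (n == 0L) stop("empty label: ", path)
  body <- utils::read.table(text = lines[-1])
  if (nrow(body) != n)
    warning("label file declares ", n, " vertices but contains ", nrow(body))
  as.integer(body[[1]]) + 1L
}

#' Write a FreeSurfer ASCII label file
#'
#' @param vertex_ids 1-based vertex ids.
#' @param mesh `cortical_mesh` providing coordinates for the label rows.
#' @param path output path.
#' @export
write_freesurfer_label <- function(vertex_ids, mesh, path) {
  vertex_ids <- as.integer(vertex_ids)
  xyz <- mesh$coords[vertex_ids, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#!ascii label, written by confield", as.character(length(vertex_ids))), con)
  write.table(data.frame(v = vertex_ids - 1L, x = xyz[, 1], y = xyz[, 2],
                         z = xyz[, 3], stat = 0),
              con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- GIFTI ------------------------------------------------------------------

gifti_decode_data <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  endian <- xml2::xml_attr(node, "Endian")
  dim0 <- as.integer(xml2::xml_attr(node, "Dim0"))
  dim1 <- xml2::xml_attr(node, "Dim1")
  dim1 <- if (is.na(dim1)) 1L else as.integer(dim1)
  txt <- xml2::xml_text(xml2::xml_find_first(node, ".//*[local-name()='Data']"))
  vals <- switch(enc,
    "ASCII" = as.numeric(scan(text = txt, quiet = TRUE)),
    "Base64Binary" = ,
    "GZipBase64Binary" = {
      bytes <- jsonlite::base64_dec(gsub("\\s", "", txt))
      if (enc == "GZipBase64Binary") bytes <- memDecompress(bytes, type = "gzip")
      size <- 4L
      what <- if (dtype == "NIFTI_TYPE_INT32") "integer" else "double"
      readBin(bytes, what, n = dim0 * dim1, size = size,
              endian = if (identical(endian, "BigEndian")) "big" else "little")
    },
    stop("unsupported GIFTI encoding: ", enc))
  order <- xml2::xml_attr(node, "ArrayIndexingOrder")
  m <- matrix(vals, nrow = dim0, ncol = dim1,
              byrow = !identical(order, "ColumnMajorOrder"))
  m
}

#' Read a GIFTI surface file
#'
#' Supports the common surface dialect: one POINTSET (float) and one
#' TRIANGLE (int32) data array, ASCII or Base64 encoded.
#'
#' @param path `.surf.gii` file path.
#' @return A `cortical_mesh`.
#' @export
read_gifti_surface <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, "//*[local-name()='DataArray']")
  intents <- xml2::xml_attr(arrays, "Intent")
  ip <- which(intents == "NIFTI_INTENT_POINTSET")
  it <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (length(ip) != 1L || length(it) != 1L)
    stop("GIFTI surface must contain exactly one POINTSET and one TRIANGLE array: ", path)
  coords <- gifti_decode_data(arrays[[ip]])
  tris <- gifti_decode_data(arrays[[it]]) + 1L
  cortical_mesh(coords, tris)
}

gifti_array_xml <- function(values, intent, dtype) {
  dim0 <- nrow(values); dim1 <- ncol(values)
  fmt <- if (dtype == "NIFTI_TYPE_INT32") "%d" else "%.7g"
  rows <- apply(values, 1, function(r) paste(sprintf(fmt, r), collapse = " "))
  paste0(
    '<DataArray Intent="', intent, '" DataType="', dtype,
    '" ArrayIndexingOrder="RowMajorOrder" Dimensionality="2" Dim0="', dim0,
    '" Dim1="', dim1, '" Encoding="ASCII" Endian="LittleEndian" ',
    'ExternalFileName="" ExternalFileOffset="">\n<Data>',
    paste(rows, collapse = "\n"), "</Data>\n</DataArray>")
}

#' Write a GIFTI surface file (ASCII encoding)
#'
#' @param mesh a `cortical_mesh`.
#' @param path output `.surf.gii` path.
#' @export
write_gifti_surface <- function(mesh, path) {
  body <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="2">\n',
    gifti_array_xml(mesh$coords, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32"), "\n",
    gifti_array_xml(mesh$triangles - 1L, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32"),
    "\n</GIFTI>\n")
  writeLines(body, path)
  invisible(path)
}

#' Read a GIFTI label file (node-index dialect)
#'
#' @param path `.label.gii` path holding one int32 node-index array.
#' @return Integer vector of 1-based vertex ids.
#' @export
read_gifti_label <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, "//*[local-name()='DataArray']")
  if (length(arrays) < 1L) stop("no data array in GIFTI label: ", path)
  idx <- as.integer(gifti_decode_data(arrays[[1]])) + 1L
  if (length(idx) == 0L) stop("empty label: ", path)
  idx
}

#' Write a GIFTI label file (node-index dialect)
#'
#' @param vertex_ids 1-based vertex ids.
#' @param path output `.label.gii` path.
#' @export
write_gifti_label <- function(vertex_ids, path) {
  body <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="1">\n',
    gifti_array_xml(matrix(as.integer(vertex_ids) - 1L, ncol = 1),
                    "NIFTI_INTENT_NODE_INDEX", "NIFTI_TYPE_INT32"),
    "\n</GIFTI>\n")
  writeLines(body, path)
  invisible(path)
}

# ---- patch assembly ---------------------------------------------------------

#' Build an analysis patch from surface and label files
#'
#' Reads a surface (FreeSurfer binary or GIFTI, chosen by extension) and a
#' set of label files, restricts the mesh to the union of the labels plus an
#' optional geodesic collar, and remaps the ROIs onto the restricted mesh.
#'
#' @param surface_file surface path (`*.gii` treated as GIFTI, anything else
#'   as FreeSurfer binary).
#' @param label_files named character vector of label paths; names become
#'   ROI names (basenames are used when unnamed).
#' @param collar_mm vertices within this geodesic distance of the label
#'   union are kept as context (default 0: the union only).
#' @param require_connected check that each ROI induces a connected
#'   subgraph (default TRUE; source ROIs must be connected).
#' @return `list(mesh, rois, vertex_map)` where `vertex_map[i]` is the
#'   original surface vertex id of patch vertex `i`.
#' @export
build_patch_from_files <- function(surface_file, label_files, collar_mm = 0,
                                   require_connected = TRUE) {
  mesh <- if (grepl("\\.gii$", surface_file)) read_gifti_surface(surface_file)
          else read_freesurfer_surface(surface_file)
  if (is.null(names(label_files)) || any(names(label_files) == ""))
    names(label_files) <- sub("\\.(label|label\\.gii)$", "", basename(label_files))
  labels <- lapply(label_files, function(p) {
    ids <- if (grepl("\\.gii$", p)) read_gifti_label(p) else read_freesurfer_label(p)
    bad <- ids[ids < 1L | ids > mesh$n_vertices]
    if (length(bad))
      stop("label '", p, "' references vertices absent from the surface: ",
           paste(head(bad - 1L, 5), collapse = ", "), " (0-based)")
    ids
  })
  keep <- sort(unique(unlist(labels)))
  if (collar_mm > 0) {
    d <- igraph::distances(mesh$graph, v = keep, algorithm = "dijkstra")
    near <- which(apply(d, 2, min) <= collar_mm)
    keep <- sort(unique(c(keep, near)))
  }
  remap <- integer(mesh$n_vertices)
  remap[keep] <- seq_along(keep)
  tri <- mesh$triangles
  tri_keep <- rowSums(matrix(tri %in% keep, ncol = 3)) == 3L
  if (!any(tri_keep))
    stop("no triangle survives the patch restriction; labels too sparse?")
  patch <- cortical_mesh(mesh$coords[keep, , drop = FALSE],
                         matrix(remap[tri[tri_keep, ]], ncol = 3))
  rois <- lapply(names(labels), function(nm)
    cf_roi(nm, remap[labels[[nm]]], mesh = patch))
  names(rois) <- names(labels)
  if (require_connected) for (r in rois) assert_roi_connected(patch, r)
  list(mesh = patch, rois = rois, vertex_map = keep)
}
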