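# On-disk format support. TrackVis .trk (v2, 1000-byte header), BrainVISA
# .bundles/.bundlesdata, NIfTI-1 (.nii/.nii.gz via RNifti), GIfTI XML (.gii),
# and BrainVISA .mesh/.mesh.minf. All binary payloads are float32; in-memory
# objects hold doubles that round-trip exactly through float32.

# ---- tractography ----------------------------------------------------------

#' Read a tractography file
#'
#' Supports TrackVis `.trk` and BrainVISA `.bundles` (with its companion
#' `.bundlesdata`). Fibers are returned in file order at float32 precision.
#' For `.bundles`, bundle names and index ranges come from the header; for
#' `.trk`, a valid (non-zero) voxel-to-RAS header matrix is applied to the
#' points and kept on the object.
#'
#' @param path file path ending in `.trk` or `.bundles`.
#' @return A [tractography()].
#' @export
read_tractography <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         trk = read_trk(path),
         bundles = read_bundles(path),
         stopf("unknown tractography extension '.%s' (expected .trk or .bundles)",
               ext))
}

#' Write a tractography file
#'
#' The extension selects the dialect: `.trk` writes a TrackVis v2 file with
#' an identity voxel-to-RAS matrix (points are stored world-space); `.bundles`
#' writes the text header plus the `.bundlesdata` payload. An unlabeled
#' tractography written to `.bundles` becomes a single bundle named `"all"`.
#'
#' @param t a [tractography()].
#' @param path destination path ending in `.trk` or `.bundles`.
#' @return `path`, invisibly.
#' @export
write_tractography <- function(t, path) {
  stopifnot(inherits(t, "tractography"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         trk = write_trk(t, path),
         bundles = write_bundles(t, path),
         stopf("unknown tractography extension '.%s'", ext))
  invisible(path)
}

TRK_HEADER_SIZE <- 1000L

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", TRK_HEADER_SIZE)
  if (length(hdr_raw) < TRK_HEADER_SIZE) stopf("truncated .trk header")
  magic <- rawToChar(hdr_raw[1:5])
  if (magic != "TRACK") stopf("not a TrackVis file (bad magic '%s')", magic)
  endian <- "little"
  hdr_size <- readBin(hdr_raw[997:1000], "integer", 1L, 4L, endian = endian)
  if (hdr_size != TRK_HEADER_SIZE) {
    endian <- "big"
    hdr_size <- readBin(hdr_raw[997:1000], "integer", 1L, 4L, endian = endian)
    if (hdr_size != TRK_HEADER_SIZE) stopf("unrecognized .trk header size")
  }
  rd <- function(bytes, what, n, size)
    readBin(hdr_raw[bytes], what, n, size, endian = endian)
  voxel_size <- rd(13:24, "numeric", 3L, 4L)
  n_scalars <- rd(37:38, "integer", 1L, 2L)
  n_properties <- rd(239:240, "integer", 1L, 2L)
  vox_to_ras <- matrix(rd(441:504, "numeric", 16L, 4L), 4L, 4L, byrow = TRUE)
  n_count <- rd(989:992, "integer", 1L, 4L)
  payload <- readBin(con, "raw", file.size(path))
  pos <- 0L
  nbytes <- length(payload)
  fibers <- list()
  read_one <- function() {
    if (pos + 4L > nbytes) return(NULL)
    np <- readBin(payload[pos + 1:4], "integer", 1L, 4L, endian = endian)
    pos <<- pos + 4L
    need <- np * (3L + n_scalars) * 4L + n_properties * 4L
    if (np < 2L || pos + need > nbytes)
      stopf("truncated .trk payload: declared counts exceed bytes available")
    vals <- readBin(payload[pos + seq_len(np * (3L + n_scalars) * 4L)],
                    "numeric", np * (3L + n_scalars), 4L, endian = endian)
    pos <<- pos + need
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    m
  }
  if (n_count > 0L) {
    fibers <- vector("list", n_count)
    for (i in seq_len(n_count)) {
      f <- read_one()
      if (is.null(f))
        stopf("truncated .trk payload: header declares %d tracks, found %d",
              n_count, i - 1L)
      fibers[[i]] <- f
    }
  } else {
    repeat {
      f <- read_one()
      if (is.null(f)) break
      fibers[[length(fibers) + 1L]] <- f
    }
  }
  transform <- vox_to_ras
  apply_tf <- any(vox_to_ras != 0) && abs(det(vox_to_ras)) > 1e-12 &&
    !isTRUE(all.equal(vox_to_ras, diag(4), tolerance = 1e-12))
  if (apply_tf)
    fibers <- lapply(fibers, function(f)
      t(vox_to_ras %*% rbind(t(f), 1))[, 1:3, drop = FALSE])
  tractography(fibers, transform = if (any(vox_to_ras != 0)) transform,
               source_format = "trk")
}

write_trk <- function(t, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  writeBin(c(charToRaw("TRACK"), as.raw(0L)), con)           # id_string[6]
  wb(integer(3L), 2L)                                        # dim
  wb(c(1, 1, 1), 4L)                                         # voxel_size
  wb(c(0, 0, 0), 4L)                                         # origin
  wb(0L, 2L)                                                 # n_scalars
  writeBin(raw(200L), con)                                   # scalar_name
  wb(0L, 2L)                                                 # n_properties
  writeBin(raw(200L), con)                                   # property_name
  wb(as.numeric(t(diag(4))), 4L)                             # vox_to_ras
  writeBin(raw(444L), con)                                   # reserved
  writeBin(c(charToRaw("RAS"), as.raw(0L)), con)             # voxel_order
  writeBin(raw(4L), con)                                     # pad2
  wb(c(1, 0, 0, 0, 1, 0), 4L)                                # orientation
  writeBin(raw(2L), con)                                     # pad1
  writeBin(raw(6L), con)                                     # invert/swap flags
  wb(length(t$fibers), 4L)                                   # n_count
  wb(2L, 4L)                                                 # version
  wb(TRK_HEADER_SIZE, 4L)                                    # hdr_size
  for (f in t$fibers) {
    wb(nrow(f), 4L)
    wb(as.numeric(t(f)), 4L)
  }
  invisible(path)
}

read_bundles <- function(path) {
  hdr <- paste(readLines(path, warn = FALSE), collapse = "\n")
  grab <- function(key) {
    m <- regmatches(hdr, regexec(paste0("'", key, "'\\s*:\\s*([^],}]+)"), hdr))[[1L]]
    if (length(m) < 2L) NA_character_ else trimws(m[2L])
  }
  curves <- grab("curves_count")
  if (is.na(curves)) stopf(".bundles header lacks 'curves_count'")
  n <- as.integer(curves)
  byte_order <- gsub("'", "", grab("byte_order"))
  endian <- if (identical(byte_order, "ABCD")) "big" else "little"
  data_file <- gsub("'", "", grab("data_file_name"))
  if (is.na(data_file) || data_file == "*.bundlesdata" || data_file == "")
    data_file <- paste0(basename(path), "data")
  data_path <- file.path(dirname(path), data_file)
  if (!file.exists(data_path)) stopf("missing companion file: %s", data_path)
  # bundle list: alternating 'name', start_index (0-based fiber offsets)
  bl <- regmatches(hdr, regexec("'bundles'\\s*:\\s*\\[([^]]*)\\]", hdr))[[1L]]
  bundles <- list()
  if (length(bl) == 2L && nzchar(trimws(bl[2L]))) {
    items <- trimws(strsplit(bl[2L], ",")[[1L]])
    nm <- gsub("'", "", items[c(TRUE, FALSE)])
    starts <- as.integer(items[c(FALSE, TRUE)])
    ends <- c(starts[-1L], n)
    bundles <- lapply(seq_along(nm), function(i)
      if (ends[i] > starts[i]) seq.int(starts[i] + 1L, ends[i]) else integer())
    names(bundles) <- nm
  }
  payload <- readBin(data_path, "raw", file.size(data_path))
  pos <- 0L
  nbytes <- length(payload)
  fibers <- vector("list", n)
  for (i in seq_len(n)) {
    if (pos + 4L > nbytes)
      stopf("truncated .bundlesdata: expected %d fibers, found %d", n, i - 1L)
    np <- readBin(payload[pos + 1:4], "integer", 1L, 4L, endian = endian)
    pos <- pos + 4L
    need <- np * 12L
    if (np < 2L || pos + need > nbytes)
      stopf("truncated .bundlesdata: declared point count exceeds bytes available")
    vals <- readBin(payload[pos + seq_len(need)], "numeric", np * 3L, 4L,
                    endian = endian)
    pos <- pos + need
    fibers[[i]] <- matrix(vals, ncol = 3L, byrow = TRUE)
  }
  if (length(bundles) == 1L && identical(names(bundles), "all"))
    bundles <- list()
  tractography(fibers, bundles = bundles, source_format = "bundles")
}

write_bundles <- function(t, path) {
  n <- n_fibers(t)
  bundles <- t$bundles
  if (!length(bundles)) bundles <- list(all = seq_len(n))
  # the format stores bundles as contiguous ranges: reorder fibers by bundle
  ord <- unlist(bundles, use.names = FALSE)
  starts <- cumsum(c(0L, utils::head(lengths(bundles), -1L)))
  fibers <- t$fibers[ord]
  items <- paste(sprintf("'%s', %d", names(bundles), starts), collapse = ", ")
  hdr <- paste0(
    "attributes = {\n",
    "    'binary' : 1,\n",
    sprintf("    'bundles' : [ %s ],\n", items),
    "    'byte_order' : 'DCBA',\n",
    sprintf("    'curves_count' : %d,\n", n),
    "    'data_file_name' : '*.bundlesdata',\n",
    "    'format' : 'bundles_1.0',\n",
    "    'space_dimension' : 3\n",
    "  }\n")
  writeLines(hdr, path)
  con <- file(paste0(path, "data"), "wb")
  on.exit(close(con))
  for (f in fibers) {
    writeBin(nrow(f), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(f)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

# ---- volumes ---------------------------------------------------------------

#' Read a NIfTI-1 volume
#'
#' Accepts `.nii` and gzip-compressed `.nii.gz`, 3D only. Data are promoted
#' to floating point with any header intensity scaling (scl_slope/scl_inter)
#' applied; voxel size comes from the header pixdims and the affine from the
#' sform/qform.
#'
#' @param path NIfTI-1 file path.
#' @return A [brain_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("not a readable NIfTI file: %s",
                                            conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L)
    stopf("unsupported dimensionality: expected a 3D volume, got %dD", length(d))
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = dim(affine))
  data <- array(as.vector(img), dim = d)   # strip niftiImage attributes
  brain_volume(data, voxel_size = RNifti::pixdim(img)[1:3], affine = affine)
}

#' Write a NIfTI-1 volume
#'
#' Writes float32 data, gzip-compressed iff the path ends in `.nii.gz`; the
#' volume affine is stored as the sform.
#'
#' @param v a [brain_volume()].
#' @param path destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "brain_volume"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$voxel_size
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

# ---- meshes ----------------------------------------------------------------

#' Read a surface mesh
#'
#' Supports GIfTI (`.gii`, XML with ASCII / Base64Binary / GZipBase64Binary
#' arrays) and BrainVISA binary `.mesh` with its `.mesh.minf` companion.
#' Normals are loaded when present in the file and left absent otherwise
#' (see [compute_vertex_normals()]).
#'
#' @param path file path ending in `.gii` or `.mesh`.
#' @return A [tri_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         gii = read_gifti(path),
         mesh = read_brainvisa_mesh(path),
         stopf("unknown mesh extension '.%s' (expected .gii or .mesh)", ext))
}

#' Write a surface mesh
#'
#' The extension selects the dialect; normals are persisted when present.
#'
#' @param m a [tri_mesh()].
#' @param path destination `.gii` or `.mesh` path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(m, path) {
  stopifnot(inherits(m, "tri_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         gii = write_gifti(m, path),
         mesh = write_brainvisa_mesh(m, path),
         stopf("unknown mesh extension '.%s'", ext))
  invisible(path)
}

gifti_decode <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  n <- prod(as.integer(c(xml2::xml_attr(node, "Dim0"),
                         xml2::xml_attr(node, "Dim1"))))
  txt <- xml2::xml_text(xml2::xml_find_first(node, ".//Data"))
  what <- if (grepl("FLOAT", dtype)) "numeric" else "integer"
  vals <- switch(enc,
                 ASCII = as.numeric(strsplit(trimws(txt), "\\s+")[[1L]]),
                 Base64Binary = readBin(jsonlite::base64_dec(gsub("\\s", "", txt)),
                                        what, n, 4L, endian = "little"),
                 GZipBase64Binary = readBin(
                   memDecompress(jsonlite::base64_dec(gsub("\\s", "", txt)),
                                 type = "gzip"),
                   what, n, 4L, endian = "little"),
                 stopf("unsupported GIfTI encoding '%s'", enc))
  order_attr <- xml2::xml_attr(node, "ArrayIndexingOrder")
  byrow <- !identical(order_attr, "ColumnMajorOrder")
  matrix(vals, ncol = 3L, byrow = byrow)
}

read_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, "//DataArray")
  intents <- xml2::xml_attr(arrays, "Intent")
  pt <- which(intents == "NIFTI_INTENT_POINTSET")
  tr <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (!length(pt)) stopf("GIfTI file lacks a point-set array")
  if (!length(tr)) stopf("GIfTI file lacks a triangle array")
  vertices <- gifti_decode(arrays[[pt[1L]]])
  triangles <- gifti_decode(arrays[[tr[1L]]]) + 1L   # 0-based on disk
  normals <- NULL
  nv <- which(intents == "NIFTI_INTENT_VECTOR")
  if (length(nv)) normals <- gifti_decode(arrays[[nv[1L]]])
  tri_mesh(vertices, triangles, normals = normals)
}

gifti_array_xml <- function(values, intent, dtype) {
  n <- nrow(values)
  raw_payload <- if (dtype == "NIFTI_TYPE_FLOAT32")
    writeBin(as.numeric(t(values)), raw(), size = 4L, endian = "little")
  else writeBin(as.integer(t(values)), raw(), size = 4L, endian = "little")
  b64 <- jsonlite::base64_enc(raw_payload)
  sprintf(paste0(
    '  <DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder"',
    ' Dimensionality="2" Dim0="%d" Dim1="3" Encoding="Base64Binary"',
    ' Endian="LittleEndian" ExternalFileName="" ExternalFileOffset="">\n',
    "    <Data>%s</Data>\n  </DataArray>\n"),
    intent, dtype, n, gsub("\n", "", b64))
}

write_gifti <- function(m, path) {
  parts <- c(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<GIFTI Version="1.0" NumberOfDataArrays="%d">\n',
            2L + !is.null(m$normals)),
    gifti_array_xml(as_float32(m$vertices), "NIFTI_INTENT_POINTSET",
                    "NIFTI_TYPE_FLOAT32"),
    gifti_array_xml(m$triangles - 1L, "NIFTI_INTENT_TRIANGLE",
                    "NIFTI_TYPE_INT32"),
    if (!is.null(m$normals))
      gifti_array_xml(as_float32(m$normals), "NIFTI_INTENT_VECTOR",
                      "NIFTI_TYPE_FLOAT32"),
    "</GIFTI>\n")
  writeLines(paste(parts, collapse = ""), path, sep = "")
  invisible(path)
}

read_brainvisa_mesh <- function(path) {
  minf <- paste0(path, ".minf")
  if (!file.exists(minf)) stopf("missing companion file: %s", minf)
  payload <- readBin(path, "raw", file.size(path))
  if (length(payload) < 29L || rawToChar(payload[1:5]) != "binar")
    stopf("not a BrainVISA binary mesh")
  endian <- if (rawToChar(payload[6:9]) == "ABCD") "big" else "little"
  pos <- 9L
  ri <- function(n = 1L) {
    out <- readBin(payload[pos + seq_len(4L * n)], "integer", n, 4L,
                   endian = endian)
    pos <<- pos + 4L * n
    out
  }
  rf <- function(n) {
    out <- readBin(payload[pos + seq_len(4L * n)], "numeric", n, 4L,
                   endian = endian)
    pos <<- pos + 4L * n
    out
  }
  tex_len <- ri()
  pos <- pos + tex_len                 # texture type string, e.g. "VOID"
  poly_dim <- ri()
  if (poly_dim != 3L)
    stopf("unsupported polygon dimension %d (only triangles)", poly_dim)
  ri()                                 # time step count
  ri()                                 # instant
  nv <- ri()
  vertices <- matrix(rf(3L * nv), ncol = 3L, byrow = TRUE)
  nn <- ri()
  normals <- if (nn > 0L) matrix(rf(3L * nn), ncol = 3L, byrow = TRUE)
  ri()                                 # texture count
  np <- ri()
  triangles <- matrix(ri(3L * np), ncol = 3L, byrow = TRUE) + 1L
  if (!is.null(normals)) {
    len <- row_norms(normals)
    normals <- normals / ifelse(len > 0, len, 1)
  }
  tri_mesh(vertices, triangles, normals = normals)
}

write_brainvisa_mesh <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  writeBin(charToRaw("binarDCBA"), con)
  wi(4L); writeBin(charToRaw("VOID"), con)
  wi(3L)                               # polygon dimension
  wi(1L); wi(0L)                       # one time step, instant 0
  wi(nrow(m$vertices)); wf(as.numeric(t(m$vertices)))
  if (is.null(m$normals)) wi(0L)
  else { wi(nrow(m$normals)); wf(as.numeric(t(m$normals))) }
  wi(0L)                               # texture count
  wi(nrow(m$triangles)); wi(as.integer(t(m$triangles)) - 1L)
  minf <- sprintf(
    "attributes = {'vertex_number' : %d, 'polygon_number' : %d, 'polygon_dimension' : 3}\n",
    nrow(m$vertices), nrow(m$triangles))
  writeLines(minf, paste0(path, ".minf"), sep = "")
  invisible(path)
}
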