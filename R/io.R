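#' Read/write FreeSurfer binary surface files
#'
#' The classic big-endian triangle-surface format (magic 0xFFFFFE): comment
#' line, vertex and face counts, float32 coordinates, int32 0-based faces.
#'
#' @param path File path.
#' @return A `triangle_mesh`.
#' @export
read_freesurfer_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 3, size = 1, signed = FALSE)
  if (!identical(as.integer(magic), c(255L, 255L, 254L))) {
    stop("not a FreeSurfer triangle surface file: ", path)
  }
  # comment: terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (length(b) == 0) stop("unexpected end of file in comment")
    if (prev == as.raw(10) && b == as.raw(10)) break
    prev <- b
  }
  nv <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  v <- readBin(con, "numeric", n = 3 * nv, size = 4, endian = "big")
  f <- readBin(con, "integer", n = 3 * nf, size = 4, endian = "big")
  triangle_mesh(matrix(v, ncol = 3, byrow = TRUE),
                matrix(f, ncol = 3, byrow = TRUE) + 1L)
}

#' @rdname read_freesurfer_surface
#' @param mesh A `triangle_mesh`.
#' @param comment Comment string stored in the header.
#' @export
write_freesurfer_surface <- function(mesh, path, comment = "created by megorient") {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(255, 255, 254)), con)
  writeBin(c(charToRaw(comment), as.raw(c(10, 10))), con)
  writeBin(as.integer(c(mesh$n_vertices, mesh$n_faces)), con, size = 4, endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4, endian = "big")
  invisible(path)
}

gifti_encode <- function(x, type) {
  raw <- if (type == "NIFTI_TYPE_FLOAT32") {
    writeBin(as.numeric(x), raw(), size = 4, endian = "little")
  } else {
    writeBin(as.integer(x), raw(), size = 4, endian = "little")
  }
  jsonlite::base64_enc(memCompress(raw, "gzip"))
}

gifti_data_array <- function(doc, intent, type, data_matrix) {
  da <- xml2::xml_add_child(doc, "DataArray",
    Intent = intent, DataType = type, ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = "2", Dim0 = as.character(nrow(data_matrix)),
    Dim1 = as.character(ncol(data_matrix)),
    Encoding = "GZipBase64Binary", Endian = "LittleEndian")
  xml2::xml_add_child(da, "Data", gifti_encode(as.numeric(t(data_matrix)), type))
  da
}

#' Read/write GIFTI surface files
#'
#' Minimal GIFTI (.surf.gii) support: one POINTSET and one TRIANGLE data
#' array, GZipBase64Binary or Base64Binary encoded, little endian, row-major.
#'
#' @param path File path.
#' @return A `triangle_mesh`.
#' @export
read_gifti_surface <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  get_array <- function(intent) {
    da <- arrays[xml2::xml_attr(arrays, "Intent") == intent]
    if (length(da) == 0) stop("GIFTI file lacks intent ", intent)
    da <- da[[1]]
    dims <- c(as.integer(xml2::xml_attr(da, "Dim0")), as.integer(xml2::xml_attr(da, "Dim1")))
    enc <- xml2::xml_attr(da, "Encoding")
    type <- xml2::xml_attr(da, "DataType")
    raw <- jsonlite::base64_dec(gsub("\\s", "", xml2::xml_text(xml2::xml_find_first(da, ".//Data"))))
    if (enc == "GZipBase64Binary") raw <- memDecompress(raw, "gzip")
    vals <- if (type == "NIFTI_TYPE_FLOAT32") {
      readBin(raw, "numeric", n = prod(dims), size = 4, endian = "little")
    } else {
      readBin(raw, "integer", n = prod(dims), size = 4, endian = "little")
    }
    order <- xml2::xml_attr(da, "ArrayIndexingOrder")
    m <- if (identical(order, "ColumnMajorOrder")) matrix(vals, dims[1], dims[2])
         else matrix(vals, dims[1], dims[2], byrow = TRUE)
    m
  }
  v <- get_array("NIFTI_INTENT_POINTSET")
  f <- get_array("NIFTI_INTENT_TRIANGLE")
  triangle_mesh(v, f + 1L)
}

#' @rdname read_gifti_surface
#' @param mesh A `triangle_mesh`.
#' @export
write_gifti_surface <- function(mesh, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0", NumberOfDataArrays = "2")
  gifti_data_array(doc, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32", mesh$vertices)
  gifti_data_array(doc, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32", mesh$faces - 1L)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write/read an orientation field as TSV plus JSON sidecar
#'
#' Three-column TSV (`vx`, `vy`, `vz`) with a `<path>.json` sidecar recording
#' method, surface, and parameters.
#'
#' @param field An `orientation_field`.
#' @param path TSV path (sidecar written next to it).
#' @export
write_orientation_field <- function(field, path) {
  df <- as.data.frame(field$vectors)
  names(df) <- c("vx", "vy", "vz")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(method = field$method, surface = field$surface,
                            parameters = field$parameters),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_orientation_field
#' @export
read_orientation_field <- function(path) {
  df <- read.delim(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  orientation_field(normalize_rows(as.matrix(df)), method = meta$method,
                    surface = meta$surface,
                    parameters = as.list(meta$parameters))
}

#' Write/read a decimation map as TSV
#'
#' Two files: `<path>` holds (decimated_index, original_index) pairs,
#' `<path>.faces.tsv` the decimated face list; indices 1-based.
#'
#' @param dmap A `decimation_map`.
#' @param path TSV path.
#' @export
write_decimation_map <- function(dmap, path) {
  write.table(data.frame(decimated_index = seq_along(dmap$retained),
                         original_index = dmap$retained),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  faces <- as.data.frame(dmap$decimated_faces)
  names(faces) <- c("v1", "v2", "v3")
  write.table(faces, paste0(path, ".faces.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(n_original = dmap$n_original), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_decimation_map
#' @export
read_decimation_map <- function(path) {
  m <- read.delim(path)
  f <- as.matrix(read.delim(paste0(path, ".faces.tsv")))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  decimation_map(m$original_index[order(m$decimated_index)],
                 matrix(as.integer(f), ncol = 3,
                        dimnames = NULL),
                 meta$n_original)
}

#' Write/read a sensor array as TSV plus JSON fiducials
#'
#' @param sensors A `sensor_array`.
#' @param path TSV path.
#' @export
write_sensor_array <- function(sensors, path) {
  df <- data.frame(name = sprintf("MEG%03d", seq_len(sensors$n_sensors)),
                   x = sensors$positions[, 1], y = sensors$positions[, 2],
                   z = sensors$positions[, 3],
                   ox = sensors$orientations[, 1], oy = sensors$orientations[, 2],
                   oz = sensors$orientations[, 3],
                   kind = sensors$kind, baseline = sensors$baseline_mm)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  fid <- sensors$fiducials
  jsonlite::write_json(list(nasion = fid[1, ], LPA = fid[2, ], RPA = fid[3, ]),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_sensor_array
#' @export
read_sensor_array <- function(path) {
  df <- read.delim(path)
  fid <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sensor_array(positions = as.matrix(df[, c("x", "y", "z")]),
               orientations = as.matrix(df[, c("ox", "oy", "oz")]),
               kind = df$kind[1], baseline_mm = df$baseline[1],
               fiducials = rbind(nasion = fid$nasion, LPA = fid$LPA, RPA = fid$RPA))
}

#' Write/read a simulated dataset as a plain-text directory container
#'
#' Directory layout: `data.tsv` (trials*channels x samples, trial-major),
#' `noiseless.tsv`, and `meta.json` holding dimensions, sampling rate, and
#' the truth block.
#'
#' @param dataset A `simulated_dataset`.
#' @param path Directory path (created).
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  flat <- matrix(aperm(dataset$data, c(3, 2, 1)),
                 nrow = dataset$n_trials * dataset$n_channels, byrow = TRUE)
  write.table(flat, file.path(path, "data.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write.table(dataset$noiseless, file.path(path, "noiseless.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(n_trials = dataset$n_trials,
                            n_channels = dataset$n_channels,
                            n_samples = dataset$n_samples,
                            fs = dataset$fs, truth = dataset$truth),
                       file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  flat <- as.matrix(read.delim(file.path(path, "data.tsv"), header = FALSE))
  noiseless <- as.matrix(read.delim(file.path(path, "noiseless.tsv"), header = FALSE))
  dimnames(noiseless) <- NULL
  arr <- aperm(array(t(flat), dim = c(meta$n_samples, meta$n_channels, meta$n_trials)),
               c(3, 2, 1))
  structure(list(data = arr, noiseless = noiseless, fs = meta$fs,
                 n_trials = meta$n_trials, n_channels = meta$n_channels,
                 n_samples = meta$n_samples, truth = meta$truth),
            class = "simulated_dataset")
}

#' Write/read a model evidence table as TSV
#'
#' Long format: subject, model label columns, F.
#'
#' @param table An `evidence_table`.
#' @param path TSV path.
#' @export
write_evidence_table <- function(table, path) {
  long <- do.call(rbind, lapply(seq_len(table$n_subjects), function(s) {
    cbind(data.frame(subject = s), table$model_labels,
          data.frame(F = table$F[s, ]))
  }))
  write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_evidence_table
#' @export
read_evidence_table <- function(path) {
  long <- read.delim(path)
  subjects <- sort(unique(long$subject))
  labels <- unique(long[, setdiff(names(long), c("subject", "F")), drop = FALSE])
  rownames(labels) <- NULL
  F <- matrix(NA_real_, length(subjects), nrow(labels))
  for (s in seq_along(subjects)) {
    d <- long[long$subject == subjects[s], ]
    F[s, ] <- d$F
  }
  evidence_table(F, labels)
}

#' Write/read a lead field as a plain-text directory container
#'
#' Directory layout: `gain.tsv` (channels x sources, fT per nA·m),
#' `sources.tsv` (position + orientation per source), `meta.json`.
#'
#' @param leadfield A `lead_field`.
#' @param path Directory path (created).
#' @export
write_lead_field <- function(leadfield, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.table(leadfield$gain, file.path(path, "gain.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  src <- data.frame(x = leadfield$source_positions[, 1],
                    y = leadfield$source_positions[, 2],
                    z = leadfield$source_positions[, 3],
                    ox = leadfield$source_orientations[, 1],
                    oy = leadfield$source_orientations[, 2],
                    oz = leadfield$source_orientations[, 3])
  write.table(src, file.path(path, "sources.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(sphere_center = leadfield$sphere_center,
                            units = "fT per nA*m"),
                       file.path(path, "meta.json"), digits = NA)
  invisible(path)
}

#' @rdname write_lead_field
#' @export
read_lead_field <- function(path) {
  gain <- as.matrix(read.delim(file.path(path, "gain.tsv"), header = FALSE))
  dimnames(gain) <- NULL
  src <- read.delim(file.path(path, "sources.tsv"))
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  structure(list(gain = gain,
                 source_positions = unname(as.matrix(src[, c("x", "y", "z")])),
                 source_orientations = unname(as.matrix(src[, c("ox", "oy", "oz")])),
                 sphere_center = meta$sphere_center),
            class = "lead_field")
}
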