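#' Read and write image volumes (NIfTI-1, NRRD)
#'
#' NIfTI goes through the RNifti package; NRRD (raw little-endian
#' encoding) is handled natively.  Geometry — spacing, origin of the first
#' voxel centre, direction cosines — survives the NRRD round trip exactly
#' and the NIfTI-1 round trip to the format's float32 header precision.
#'
#' @param path file path; format chosen by extension (`.nii`, `.nii.gz`,
#'   `.nrrd`).
#' @param vol an [image_volume] (or [label_volume]).
#' @return `read_volume` returns an [image_volume].
#' @export
write_volume <- function(vol, path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    aff <- rbind(cbind(vol$orientation %*% diag(vol$spacing), vol$origin),
                 c(0, 0, 0, 1))
    img <- RNifti::asNifti(vol$values)
    RNifti::sform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, path)
  } else if (ext == "nrrd") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- c("NRRD0004", "type: double", "dimension: 3",
             sprintf("sizes: %s", paste(dim(vol$values), collapse = " ")),
             "endian: little", "encoding: raw",
             "space: right-anterior-superior",
             sprintf("space directions: %s",
                     paste(apply(vol$orientation %*% diag(vol$spacing), 2,
                                 function(c) sprintf("(%.17g,%.17g,%.17g)",
                                                     c[1], c[2], c[3])),
                           collapse = " ")),
             sprintf("space origin: (%.17g,%.17g,%.17g)", vol$origin[1],
                     vol$origin[2], vol$origin[3]), "")
    writeLines(hdr, con)
    writeBin(as.vector(vol$values), con, size = 8, endian = "little")
  } else stop_historeg(paste0("unknown volume format: .", ext),
                       "historeg_format_error")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    aff <- RNifti::xform(img)
    vals <- array(as.numeric(img), dim(img))
    sp <- sqrt(colSums(aff[1:3, 1:3]^2))
    image_volume(vals, sp, aff[1:3, 4], aff[1:3, 1:3] %*% diag(1 / sp))
  } else if (ext == "nrrd") {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- character(0)
    repeat {
      ln <- readLines(con, n = 1)
      if (length(ln) == 0 || ln == "") break
      hdr <- c(hdr, ln)
    }
    fields <- list()
    for (ln in hdr[-1]) {
      if (grepl("^#", ln) || !grepl(":", ln)) next
      kv <- strsplit(ln, ": ", fixed = TRUE)[[1]]
      fields[[kv[1]]] <- paste(kv[-1], collapse = ": ")
    }
    sizes <- as.integer(strsplit(fields$sizes, " ")[[1]])
    if (!identical(fields$encoding, "raw"))
      stop_historeg("only raw NRRD encoding is supported", "historeg_format_error")
    type_size <- switch(fields$type, double = 8, float = 4,
                        stop_historeg("unsupported NRRD type", "historeg_format_error"))
    vals <- readBin(con, "numeric", n = prod(sizes), size = type_size,
                    endian = fields$endian %||% "little")
    parse_vecs <- function(s) {
      m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
      vapply(m, function(v)
        as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
    }
    dirs <- parse_vecs(fields[["space directions"]])
    origin <- as.vector(parse_vecs(fields[["space origin"]]))
    sp <- sqrt(colSums(dirs^2))
    image_volume(array(vals, sizes), sp, origin, dirs %*% diag(1 / sp))
  } else stop_historeg(paste0("unknown volume format: .", ext),
                       "historeg_format_error")
}

#' Read and write triangular meshes (PLY, legacy VTK)
#'
#' PLY is written in `binary_little_endian` with double-precision vertex
#' coordinates (exact round trip) and read in both ASCII and binary forms;
#' VTK uses the legacy ASCII POLYDATA format.
#'
#' @param mesh a [triangle_mesh].
#' @param path file path (`.ply` or `.vtk`).
#' @param format `"binary"` or `"ascii"` (PLY only).
#' @return `read_mesh` returns a [triangle_mesh].
#' @export
write_mesh <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  ext <- tolower(tools::file_ext(path))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  if (ext == "ply") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- c("ply",
             if (format == "binary") "format binary_little_endian 1.0"
             else "format ascii 1.0",
             sprintf("element vertex %d", nv),
             "property double x", "property double y", "property double z",
             sprintf("element face %d", nf),
             "property list uchar int vertex_indices", "end_header")
    writeLines(hdr, con)
    if (format == "binary") {
      writeBin(as.vector(t(mesh$vertices)), con, size = 8, endian = "little")
      f0 <- mesh$faces - 1L
      for (i in seq_len(nf)) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f0[i, ]), con, size = 4, endian = "little")
      }
    } else {
      writeLines(apply(mesh$vertices, 1, function(v)
        sprintf("%.17g %.17g %.17g", v[1], v[2], v[3])), con)
      writeLines(apply(mesh$faces - 1L, 1, function(f)
        sprintf("3 %d %d %d", f[1], f[2], f[3])), con)
    }
  } else if (ext == "vtk") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0", "triangle mesh", "ASCII",
                 "DATASET POLYDATA", sprintf("POINTS %d double", nv)), con)
    writeLines(apply(mesh$vertices, 1, function(v)
      sprintf("%.17g %.17g %.17g", v[1], v[2], v[3])), con)
    writeLines(sprintf("POLYGONS %d %d", nf, 4 * nf), con)
    writeLines(apply(mesh$faces - 1L, 1, function(f)
      sprintf("3 %d %d %d", f[1], f[2], f[3])), con)
  } else stop_historeg(paste0("unknown mesh format: .", ext),
                       "historeg_format_error")
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") read_ply(path)
  else if (ext == "vtk") read_vtk(path)
  else stop_historeg(paste0("unknown mesh format: .", ext),
                     "historeg_format_error")
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0)
      stop_historeg("truncated PLY header", "historeg_parse_error")
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
  }
  fmt <- sub("^format ", "", grep("^format", hdr, value = TRUE))
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  vprops <- grep("^property (double|float)", hdr, value = TRUE)
  vsize <- ifelse(grepl("double", vprops), 8, 4)
  if (grepl("^binary_little_endian", fmt)) {
    verts <- matrix(0, nv, length(vprops))
    raw <- readBin(con, "numeric", n = nv * length(vprops), size = vsize[1],
                   endian = "little")
    verts <- matrix(raw, nv, length(vprops), byrow = TRUE)
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1))
      idx <- readBin(con, "integer", n = cnt, size = 4, endian = "little")
      if (cnt != 3) stop_historeg("non-triangular PLY face", "historeg_parse_error")
      faces[i, ] <- idx
    }
  } else if (grepl("^ascii", fmt)) {
    txt <- readLines(con)
    vl <- strsplit(trimws(txt[seq_len(nv)]), "\\s+")
    verts <- do.call(rbind, lapply(vl, function(x) as.numeric(x[1:3])))
    fl <- strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+")
    faces <- do.call(rbind, lapply(fl, function(x) {
      if (as.integer(x[1]) != 3)
        stop_historeg("non-triangular PLY face", "historeg_parse_error")
      as.integer(x[2:4])
    }))
  } else stop_historeg("unsupported PLY format variant", "historeg_parse_error")
  triangle_mesh(verts[, 1:3, drop = FALSE], faces + 1L, check_degenerate = FALSE)
}

read_vtk <- function(path) {
  txt <- readLines(path)
  ip <- grep("^POINTS", txt)
  if (!length(ip)) stop_historeg("no POINTS in VTK file", "historeg_parse_error")
  nv <- as.integer(strsplit(txt[ip], "\\s+")[[1]][2])
  nums <- as.numeric(unlist(strsplit(trimws(
    txt[(ip + 1):length(txt)][seq_len(ceiling(nv * 3 / 3))]), "\\s+")))
  ## points may wrap lines; collect until 3*nv numbers are read
  acc <- c(); i <- ip + 1
  while (length(acc) < 3 * nv) {
    acc <- c(acc, as.numeric(strsplit(trimws(txt[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  verts <- matrix(acc[seq_len(3 * nv)], ncol = 3, byrow = TRUE)
  ipoly <- grep("^POLYGONS", txt)
  nf <- as.integer(strsplit(txt[ipoly], "\\s+")[[1]][2])
  facc <- c(); i <- ipoly + 1
  while (length(facc) < 4 * nf) {
    facc <- c(facc, as.integer(strsplit(trimws(txt[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  fm <- matrix(facc[seq_len(4 * nf)], ncol = 4, byrow = TRUE)
  if (any(fm[, 1] != 3))
    stop_historeg("non-triangular VTK polygon", "historeg_parse_error")
  triangle_mesh(verts, fm[, 2:4] + 1L, check_degenerate = FALSE)
}

#' Read and write landmark sets (CSV)
#'
#' Columns `label,x,y,z,space`; coordinates in mm.
#'
#' @param lm a [landmark_set].
#' @param path CSV file path.
#' @return `read_landmarks` returns a [landmark_set].
#' @export
write_landmarks <- function(lm, path) {
  df <- data.frame(label = lm$labels, x = lm$points[, 1], y = lm$points[, 2],
                   z = lm$points[, 3], space = lm$space)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z", "space")
  if (!all(need %in% names(df)))
    stop_historeg("landmark CSV must have columns label,x,y,z,space",
                  "historeg_parse_error")
  landmark_set(as.matrix(df[, c("x", "y", "z")]), df$label, df$space[1])
}

## ---- transform serialization (JSON header + array payload) -------------

transform_to_list <- function(tr) {
  if (inherits(tr, "affine_transform")) {
    list(type = "affine", linear = tr$linear, translation = tr$translation)
  } else if (inherits(tr, "diffeomorphism")) {
    list(type = "diffeomorphism", dim = tr$dim,
         domain_bounds = tr$domain_bounds,
         steps = lapply(tr$steps, function(s) {
           if (s$type == "grid")
             list(type = "grid", dims = dim(s$v), v = as.vector(s$v),
                  spacing = s$spacing, origin = s$origin, dt = s$dt)
           else
             list(type = "kernel", q = s$q, alpha = s$alpha, sigma = s$sigma,
                  drift = s$drift, dt = s$dt)
         }))
  } else if (inherits(tr, "transform_chain")) {
    list(type = "chain",
         elements = lapply(tr$elements, function(el)
           list(direction = el$direction,
                transform = transform_to_list(el$transform))))
  } else stop_historeg("unsupported transform type", "historeg_format_error")
}

transform_from_list <- function(x) {
  ## jsonlite writes matrices as nested row arrays; rebuild row-major
  rowmat <- function(m, ncol) matrix(unlist(m), ncol = ncol, byrow = TRUE)
  if (x$type == "affine") {
    d <- length(x$translation)
    affine_transform(rowmat(x$linear, d), unlist(x$translation))
  } else if (x$type == "diffeomorphism") {
    steps <- lapply(x$steps, function(s) {
      if (s$type == "grid")
        grid_velocity_step(array(unlist(s$v), unlist(s$dims)),
                           unlist(s$spacing), unlist(s$origin), s$dt)
      else
        kernel_velocity_step(rowmat(s$q, x$dim), rowmat(s$alpha, x$dim),
                             s$sigma, unlist(s$drift), s$dt)
    })
    diffeomorphism(steps, rowmat(x$domain_bounds, x$dim),
                   dim = x$dim, validate = FALSE)
  } else if (x$type == "chain") {
    do.call(transform_chain, lapply(x$elements, function(el)
      chain_element(transform_from_list(el$transform), el$direction)))
  } else stop_historeg("unknown transform record", "historeg_parse_error")
}

#' Read and write spatial transforms (JSON)
#'
#' Affine transforms, velocity-flow diffeomorphisms and transform chains
#' are serialized to a documented JSON structure (float64 throughout); no
#' standard medical-imaging format covers velocity flows.
#'
#' @param transform an [affine_transform], [diffeomorphism] or
#'   [transform_chain].
#' @param path JSON file path.
#' @return `read_transform` returns the deserialized transform.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(transform_to_list(transform), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  transform_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' Read and write 2D section images (PNG + JSON sidecar)
#'
#' Pixel values are windowed and quantized to 16 bits, stored as the
#' high/low bytes of an RGB PNG; the sidecar (`<path>.json`) records
#' spacing, origin, section depth and the intensity window.  The round
#' trip restores geometry exactly and intensities to 16-bit precision.
#'
#' @param img an [image2d].
#' @param path PNG file path.
#' @return `read_image2d` returns an [image2d].
#' @export
write_image2d <- function(img, path) {
  lo <- min(img$values); hi <- max(img$values)
  scale <- if (hi > lo) hi - lo else 1
  q <- round((img$values - lo) / scale * 65535)
  ## PNG rows are the y axis; transpose so x runs horizontally; 16-bit
  ## precision via high/low bytes in the R and G channels
  rgb <- array(0, c(ncol(img$values), nrow(img$values), 3))
  rgb[, , 1] <- t(q %/% 256) / 255
  rgb[, , 2] <- t(q %% 256) / 255
  png::writePNG(rgb, path)
  jsonlite::write_json(list(spacing = img$spacing, origin = img$origin,
                            section_depth = img$section_depth,
                            window = c(lo, hi), encoding = "rg16"),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_image2d
#' @export
read_image2d <- function(path) {
  m <- png::readPNG(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lo <- meta$window[1]; hi <- meta$window[2]
  scale <- if (hi > lo) hi - lo else 1
  q <- t(m[, , 1]) * 255 * 256 + t(m[, , 2]) * 255
  image2d(q / 65535 * scale + lo, meta$spacing, meta$origin,
          meta$section_depth)
}
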