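# Point-cloud readers/writers: whitespace/comma-delimited text, LAS 1.2
# (point format 0), and PLY (ascii or binary little-endian). LAS carries
# coordinates + classification only; temperature and scalar fields need the
# text or PLY routes.

LAS_CLASS_TO_LABEL <- c(`2` = "ground", `5` = "canopy", `7` = "noise")
LABEL_TO_LAS_CLASS <- c(ground = 2L, canopy = 5L, noise = 7L, unassigned = 1L)

#' Read a point cloud
#'
#' @param path Input file.
#' @param format `"xyz"` (delimited text), `"las"`, or `"ply"`. Defaults to a
#'   guess from the file extension.
#' @param column_map Named integer vector of 1-based column indices for the
#'   text format, e.g. `c(x = 1, y = 2, z = 3, temperature = 4)`. Recognised
#'   names: `x`, `y`, `z`, `temperature`, `red`, `green`, `blue`, `class`;
#'   any other name becomes a scalar field. Files written by [write_cloud()]
#'   embed their own column map in a header comment, so `column_map` may be
#'   omitted for them.
#' @param temp_unit Unit of the temperature column (`"celsius"` or
#'   `"kelvin"`). Must be declared by the caller for text files without an
#'   embedded header; never inferred from magnitude.
#' @param crs CRS label to attach.
#' @return A [point_cloud()]; row order matches the file.
#' @export
read_cloud <- function(path, format = NULL, column_map = NULL,
                       temp_unit = NULL, crs = "local metric") {
  if (!file.exists(path)) stop("cloud file does not exist: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     las = "las", ply = "ply", "xyz")
  }
  switch(format,
         xyz = read_cloud_xyz(path, column_map, temp_unit, crs),
         las = read_cloud_las(path, crs),
         ply = read_cloud_ply(path, crs),
         stop("unknown point-cloud format: ", format))
}

#' Write a point cloud
#'
#' @param cloud A [point_cloud()].
#' @param path Output file.
#' @param format `"xyz"`, `"las"`, or `"ply"` (guessed from the extension by
#'   default). LAS stores coordinates and class labels only; asking it to
#'   carry temperature, color, or scalars is an error. PLY stores coordinates
#'   as float32 (round-trip within 1e-6 m); text is lossless.
#' @param attributes Which attributes to write. `NULL` writes everything the
#'   cloud carries that the format supports -- except for LAS, where
#'   unsupported attributes must be deselected explicitly.
#' @param binary For PLY: write `binary_little_endian` instead of ascii.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = NULL, attributes = NULL,
                        binary = FALSE) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     las = "las", ply = "ply", "xyz")
  }
  present <- c(
    if (!is.null(cloud$temperature)) "temperature",
    if (!is.null(cloud$color)) "color",
    if (!is.null(cloud$class_label)) "class_label",
    names(cloud$scalars))
  if (is.null(attributes)) attributes <- present
  missing_attr <- setdiff(attributes, present)
  if (length(missing_attr))
    stop("cloud does not carry attribute(s): ", paste(missing_attr, collapse = ", "))
  switch(format,
         xyz = write_cloud_xyz(cloud, path, attributes),
         las = write_cloud_las(cloud, path, attributes),
         ply = write_cloud_ply(cloud, path, attributes, binary),
         stop("unknown point-cloud format: ", format))
  invisible(path)
}

## ---- delimited text ----

read_cloud_xyz <- function(path, column_map, temp_unit, crs) {
  lines <- readLines(path)
  header <- grep("^\\s*#", lines, value = TRUE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), header, value = TRUE)
    if (length(hit)) trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1])) else NULL
  }
  if (is.null(column_map)) {
    cols <- meta("columns")
    if (is.null(cols))
      stop("column_map is required for text clouds without an embedded header")
    nm <- strsplit(cols, "\\s+")[[1]]
    column_map <- stats::setNames(seq_along(nm), nm)
  }
  if (is.null(temp_unit)) temp_unit <- meta("temperature_unit")
  hdr_crs <- meta("crs")
  if (!is.null(hdr_crs)) crs <- hdr_crs

  if (!all(c("x", "y", "z") %in% names(column_map)))
    stop("column_map must name x, y and z columns")
  if (!length(lines)) {
    return(point_cloud(matrix(numeric(0), 0, 3), crs = crs))
  }
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  nfield <- lengths(parts)
  if (length(unique(nfield)) != 1)
    stop(sprintf("ragged rows in %s: %d to %d fields", path,
                 min(nfield), max(nfield)))
  if (max(column_map) > nfield[1])
    stop(sprintf("column_map asks for column %d but rows have %d fields",
                 max(column_map), nfield[1]))
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = nfield[1], byrow = TRUE)
  if (anyNA(m[, column_map[!names(column_map) %in% "class"], drop = FALSE]))
    stop("non-numeric fields in ", path)
  grab <- function(name) if (name %in% names(column_map)) m[, column_map[[name]]] else NULL
  coords <- cbind(grab("x"), grab("y"), grab("z"))
  color <- if (all(c("red", "green", "blue") %in% names(column_map)))
    cbind(grab("red"), grab("green"), grab("blue"))
  class_label <- NULL
  if ("class" %in% names(column_map)) {
    raw_cls <- vapply(parts, `[[`, "", column_map[["class"]])
    class_label <- if (all(grepl("^[0-9]+$", raw_cls))) {
      lab <- LAS_CLASS_TO_LABEL[raw_cls]
      lab[is.na(lab)] <- "unassigned"
      lab
    } else raw_cls
  }
  known <- c("x", "y", "z", "temperature", "red", "green", "blue", "class")
  scalar_names <- setdiff(names(column_map), known)
  scalars <- stats::setNames(lapply(scalar_names, grab), scalar_names)
  temperature <- grab("temperature")
  if (!is.null(temperature) && is.null(temp_unit))
    stop("temperature column present but no unit declared (temp_unit)")
  point_cloud(coords, temperature = temperature, temp_unit = temp_unit,
              color = color, class_label = class_label, scalars = scalars,
              crs = crs)
}

write_cloud_xyz <- function(cloud, path, attributes) {
  cols <- list(x = cloud$coords[, 1], y = cloud$coords[, 2],
               z = cloud$coords[, 3])
  if ("temperature" %in% attributes) cols$temperature <- cloud$temperature
  if ("color" %in% attributes) {
    cols$red <- cloud$color[, 1]; cols$green <- cloud$color[, 2]
    cols$blue <- cloud$color[, 3]
  }
  if ("class_label" %in% attributes)
    cols$class <- LABEL_TO_LAS_CLASS[as.character(cloud$class_label)]
  for (nm in intersect(names(cloud$scalars), attributes))
    cols[[nm]] <- cloud$scalars[[nm]]
  header <- c(paste("# columns:", paste(names(cols), collapse = " ")),
              paste("# crs:", cloud$crs))
  if ("temperature" %in% attributes)
    header <- c(header, paste("# temperature_unit:", cloud$temp_unit))
  fmt1 <- function(v) {
    if (is.integer(v) || all(v == round(v))) sprintf("%d", as.integer(v))
    else sprintf("%.17g", v)
  }
  body <- if (n_points(cloud) == 0) character(0) else
    do.call(paste, lapply(cols, fmt1))
  writeLines(c(header, body), path)
  path
}

## ---- LAS 1.2, point format 0 ----

read_cloud_las <- function(path, crs) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readBin(con, "raw", 4)
  if (!identical(sig, charToRaw("LASF"))) stop("not a LAS file: ", path)
  seek(con, 24)
  ver <- readBin(con, "integer", 2, size = 1, signed = FALSE)
  seek(con, 94)
  readBin(con, "integer", 1, size = 2, signed = FALSE)       # header size
  offset <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 4)                       # n VLRs
  fmt <- readBin(con, "integer", 1, size = 1, signed = FALSE)
  rec_len <- readBin(con, "integer", 1, size = 2, signed = FALSE)
  npts <- readBin(con, "integer", 1, size = 4)
  seek(con, 131)
  scales <- readBin(con, "double", 3, size = 8)
  offs <- readBin(con, "double", 3, size = 8)
  if (fmt > 1) stop("only LAS point formats 0 and 1 are supported, got ", fmt)

  seek(con, offset)
  rec <- readBin(con, "raw", npts * rec_len)
  if (length(rec) < npts * rec_len) stop("truncated LAS payload: ", path)
  dim(rec) <- c(rec_len, npts)
  int32 <- function(rows) readBin(as.vector(rec[rows, ]), "integer", npts,
                                  size = 4, endian = "little")
  xs <- int32(1:4) * scales[1] + offs[1]
  ys <- int32(5:8) * scales[2] + offs[2]
  zs <- int32(9:12) * scales[3] + offs[3]
  cls_codes <- as.integer(rec[16, ])
  lab <- LAS_CLASS_TO_LABEL[as.character(cls_codes)]
  lab[is.na(lab)] <- "unassigned"
  point_cloud(cbind(xs, ys, zs), class_label = lab, crs = crs)
}

write_cloud_las <- function(cloud, path, attributes) {
  unsupported <- setdiff(attributes, "class_label")
  if (length(unsupported))
    stop("LAS point format 0 cannot carry attribute(s): ",
         paste(unsupported, collapse = ", "),
         " (use the text or ply format)")
  n <- n_points(cloud)
  xyz <- cloud$coords
  scale <- 0.001
  offs <- if (n > 0) floor(apply(xyz, 2, min)) else c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  writeBin(charToRaw("LASF"), con)
  wb(0L, 2); wb(0L, 2)                      # source id, global encoding
  writeBin(raw(16), con)                    # GUID
  writeBin(as.raw(c(1, 2)), con)            # version 1.2
  writeBin(raw(64), con)                    # system id + software
  wb(1L, 2); wb(2026L, 2)                   # day, year
  wb(227L, 2)                               # header size
  wb(227L, 4)                               # offset to point data
  wb(0L, 4)                                 # number of VLRs
  writeBin(as.raw(0), con)                  # point format 0
  wb(20L, 2)                                # record length
  wb(n, 4)
  wb(c(n, 0L, 0L, 0L, 0L), 4)               # points by return
  wb(rep(scale, 3), 8)
  wb(as.numeric(offs), 8)
  ranges <- if (n > 0) as.numeric(rbind(apply(xyz, 2, max), apply(xyz, 2, min)))
            else numeric(6)
  wb(ranges, 8)

  cls <- if (is.null(cloud$class_label)) rep(1L, n)
         else unname(LABEL_TO_LAS_CLASS[as.character(cloud$class_label)])
  if (n > 0) {
    ints <- round(sweep(xyz, 2, offs) / scale)
    if (any(abs(ints) > 2^31 - 1)) stop("coordinates overflow LAS int32 range")
    rec <- raw(20 * n)
    dim(rec) <- c(20, n)
    rec[1:4, ] <- writeBin(as.integer(ints[, 1]), raw(), size = 4, endian = "little")
    rec[5:8, ] <- writeBin(as.integer(ints[, 2]), raw(), size = 4, endian = "little")
    rec[9:12, ] <- writeBin(as.integer(ints[, 3]), raw(), size = 4, endian = "little")
    rec[16, ] <- as.raw(cls)
    writeBin(as.vector(rec), con)
  }
  path
}

## ---- PLY ----

ply_property_defs <- function(cloud, attributes) {
  props <- list(list(name = "x", type = "float"),
                list(name = "y", type = "float"),
                list(name = "z", type = "float"))
  if ("temperature" %in% attributes)
    props <- c(props, list(list(name = "temperature", type = "float")))
  if ("color" %in% attributes)
    props <- c(props, list(list(name = "red", type = "uchar"),
                           list(name = "green", type = "uchar"),
                           list(name = "blue", type = "uchar")))
  if ("class_label" %in% attributes)
    props <- c(props, list(list(name = "classification", type = "uchar")))
  for (nm in intersect(names(cloud$scalars), attributes))
    props <- c(props, list(list(name = nm, type = "float")))
  props
}

ply_column <- function(cloud, name) {
  switch(name,
         x = cloud$coords[, 1], y = cloud$coords[, 2], z = cloud$coords[, 3],
         temperature = cloud$temperature,
         red = cloud$color[, 1], green = cloud$color[, 2],
         blue = cloud$color[, 3],
         classification = unname(LABEL_TO_LAS_CLASS[as.character(cloud$class_label)]),
         cloud$scalars[[name]])
}

write_cloud_ply <- function(cloud, path, attributes, binary) {
  n <- n_points(cloud)
  props <- ply_property_defs(cloud, attributes)
  header <- c("ply",
              paste("format", if (binary) "binary_little_endian" else "ascii", "1.0"),
              paste("comment crs", cloud$crs),
              if ("temperature" %in% attributes)
                paste("comment temperature_unit", cloud$temp_unit),
              paste("element vertex", n),
              vapply(props, function(p) paste("property", p$type, p$name), ""),
              "end_header")
  cols <- lapply(props, function(p) ply_column(cloud, p$name))
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
    if (n > 0) {
      sizes <- vapply(props, function(p) if (p$type == "uchar") 1L else 4L, 0L)
      rec_len <- sum(sizes)
      rec <- raw(rec_len * n)
      dim(rec) <- c(rec_len, n)
      at <- 1L
      for (j in seq_along(props)) {
        enc <- if (sizes[j] == 1) as.raw(as.integer(cols[[j]]))
               else writeBin(as.numeric(cols[[j]]), raw(), size = 4,
                             endian = "little")
        rec[at:(at + sizes[j] - 1L), ] <- enc
        at <- at + sizes[j]
      }
      writeBin(as.vector(rec), con)
    }
  } else {
    body <- if (n == 0) character(0) else do.call(paste, lapply(seq_along(props), function(j) {
      if (props[[j]]$type == "uchar") sprintf("%d", as.integer(cols[[j]]))
      else sprintf("%.9g", cols[[j]])
    }))
    writeLines(c(header, body), path)
  }
  path
}

read_cloud_ply <- function(path, crs) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- character(0)
    repeat {  # read one newline-terminated line from the binary stream
      ch <- readBin(con, "raw", 1)
      if (!length(ch) || ch == as.raw(10)) break
      ln <- c(ln, rawToChar(ch))
    }
    line <- paste(ln, collapse = "")
    header <- c(header, line)
    if (identical(line, "end_header")) break
    if (length(header) > 1000) stop("unterminated PLY header: ", path)
  }
  if (!identical(header[1], "ply")) stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt_line)
  n <- as.integer(sub("^element vertex ", "",
                      grep("^element vertex ", header, value = TRUE)[1]))
  prop_lines <- grep("^property ", header, value = TRUE)
  parts <- strsplit(prop_lines, "\\s+")
  types <- vapply(parts, `[[`, "", 2)
  names_ <- vapply(parts, `[[`, "", 3)
  if (any(types == "list")) stop("PLY list properties are not supported")
  crs_line <- grep("^comment crs ", header, value = TRUE)
  if (length(crs_line)) crs <- sub("^comment crs ", "", crs_line[1])
  unit_line <- grep("^comment temperature_unit ", header, value = TRUE)
  temp_unit <- if (length(unit_line))
    sub("^comment temperature_unit ", "", unit_line[1]) else NULL

  sizes <- ifelse(types %in% c("uchar", "char", "uint8", "int8"), 1L,
           ifelse(types %in% c("double", "float64"), 8L, 4L))
  cols <- vector("list", length(names_))
  if (binary) {
    rec_len <- sum(sizes)
    rec <- readBin(con, "raw", rec_len * n)
    if (length(rec) < rec_len * n) stop("truncated PLY payload: ", path)
    dim(rec) <- c(rec_len, max(n, 1L))
    at <- 1L
    for (j in seq_along(names_)) {
      bytes <- as.vector(rec[at:(at + sizes[j] - 1L), seq_len(n), drop = FALSE])
      cols[[j]] <- if (sizes[j] == 1) as.integer(bytes)
        else if (types[j] %in% c("int", "int32", "uint", "uint32"))
          readBin(bytes, "integer", n, size = 4, endian = "little")
        else readBin(bytes, "double", n, size = sizes[j], endian = "little")
      at <- at + sizes[j]
    }
  } else {
    lines <- readLines(con)
    lines <- lines[nzchar(trimws(lines))][seq_len(n)]
    m <- matrix(as.numeric(unlist(strsplit(trimws(lines), "\\s+"))),
                ncol = length(names_), byrow = TRUE)
    for (j in seq_along(names_)) cols[[j]] <- m[, j]
  }
  names(cols) <- names_
  coords <- cbind(cols$x, cols$y, cols$z)
  if (n == 0) coords <- matrix(numeric(0), 0, 3)
  color <- if (all(c("red", "green", "blue") %in% names_))
    cbind(cols$red, cols$green, cols$blue)
  class_label <- if ("classification" %in% names_) {
    lab <- LAS_CLASS_TO_LABEL[as.character(cols$classification)]
    lab[is.na(lab)] <- "unassigned"
    lab
  }
  known <- c("x", "y", "z", "temperature", "red", "green", "blue",
             "classification")
  scalar_names <- setdiff(names_, known)
  point_cloud(coords, temperature = cols$temperature, temp_unit = temp_unit,
              color = color, class_label = class_label,
              scalars = cols[scalar_names], crs = crs)
}
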