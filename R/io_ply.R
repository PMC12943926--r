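# Minimal PLY point-cloud reader/writer (ascii and binary_little_endian).
# Vertex properties understood: x y z (any float type), red green blue (uchar
# or float), semantic + instance (any integer type). Coordinates are stored as
# float64 so round trips are exact to well below 1e-6 m.

.ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_is_float <- function(t) t %in% c("float", "float32", "double", "float64")

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "ply")) stop("'", path, "' is not a PLY file")
  fmt <- NULL; nvert <- NULL
  props <- character(0); ptypes <- character(0)
  in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of PLY header in '", path, "'")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L) next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) nvert <- as.integer(tok[3])
      else if (as.integer(tok[3]) > 0L)
        stop("PLY element '", tok[2], "' in '", path, "' is not supported")
    } else if (tok[1] == "property" && in_vertex) {
      if (tok[2] == "list") stop("PLY list properties are not supported ('", path, "')")
      ptypes <- c(ptypes, tok[2]); props <- c(props, tok[3])
    } else if (tok[1] == "end_header") break
  }
  if (is.null(nvert)) stop("PLY file '", path, "' has no vertex element")
  if (!all(c("x", "y", "z") %in% props)) stop("PLY file '", path, "' lacks x/y/z")
  cols <- vector("list", length(props))
  names(cols) <- props
  if (nvert > 0L) {
    if (fmt == "ascii") {
      body <- readLines(con)
      body <- body[nzchar(trimws(body))]
      if (length(body) < nvert) stop("PLY file '", path, "' truncated: expected ",
                                     nvert, " vertices, got ", length(body))
      dt <- data.table::fread(text = body[seq_len(nvert)], header = FALSE, data.table = FALSE)
      if (ncol(dt) != length(props))
        stop("malformed PLY vertex record in '", path, "' (column count mismatch)")
      for (j in seq_along(props)) cols[[j]] <- dt[[j]]
    } else if (fmt == "binary_little_endian") {
      sizes <- .ply_type_size[ptypes]
      if (anyNA(sizes)) stop("unknown PLY property type in '", path, "'")
      stride <- sum(sizes)
      raw <- readBin(con, "raw", n = stride * nvert)
      if (length(raw) < stride * nvert) stop("PLY file '", path, "' truncated")
      off <- cumsum(c(0L, sizes[-length(sizes)]))
      base <- (seq_len(nvert) - 1L) * stride
      for (j in seq_along(props)) {
        idx <- rep(base, each = sizes[j]) + rep(seq_len(sizes[j]) + off[j], times = nvert)
        bytes <- raw[idx]
        tj <- ptypes[j]
        cols[[j]] <- if (.ply_is_float(tj)) {
          readBin(bytes, "double", n = nvert, size = sizes[j], endian = "little")
        } else if (tj %in% c("uchar", "uint8")) {
          as.integer(bytes[seq(1L, length(bytes), by = 1L)])
        } else {
          readBin(bytes, "integer", n = nvert, size = sizes[j],
                  signed = !(tj %in% c("uint", "uint16", "uint32", "ushort")), endian = "little")
        }
      }
    } else stop("unsupported PLY format '", fmt, "' in '", path, "'")
  } else {
    for (j in seq_along(props)) cols[[j]] <- numeric(0)
  }
  coords <- cbind(as.numeric(cols$x), as.numeric(cols$y), as.numeric(cols$z))
  if (nvert == 0L) coords <- matrix(numeric(0), 0, 3)
  col <- NULL
  if (all(c("red", "green", "blue") %in% props)) {
    sc <- if (.ply_is_float(ptypes[match("red", props)])) 1 else 255
    col <- cbind(as.numeric(cols$red), as.numeric(cols$green), as.numeric(cols$blue)) / sc
  }
  sem <- if ("semantic" %in% props) as.integer(cols$semantic) else NULL
  inst <- if ("instance" %in% props) as.integer(cols$instance) else NULL
  point_cloud(coords, sem, inst, col)
}

write_ply <- function(cloud, path, binary = TRUE) {
  n <- n_points(cloud)
  labelled <- any(cloud$semantic >= 0L) || any(cloud$instance >= 0L) || n == 0L
  props <- c("double x", "double y", "double z")
  if (labelled) props <- c(props, "int semantic", "int instance")
  has_col <- !is.null(cloud$color)
  if (has_col) props <- c(props, "uchar red", "uchar green", "uchar blue")
  hdr <- c("ply",
           paste("format", if (binary) "binary_little_endian" else "ascii", "1.0"),
           paste("element vertex", n),
           paste("property", props),
           "end_header")
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot write PLY file '", path, "': ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(hdr, con)
  if (n > 0L) {
    colb <- if (has_col) round(pmin(pmax(cloud$color, 0), 1) * 255) else NULL
    if (!binary) {
      rows <- sprintf("%.10g %.10g %.10g", cloud$coords[, 1], cloud$coords[, 2], cloud$coords[, 3])
      if (labelled) rows <- paste(rows, cloud$semantic, cloud$instance)
      if (has_col) rows <- paste(rows, colb[, 1], colb[, 2], colb[, 3])
      writeLines(rows, con)
    } else {
      sizes <- c(8L, 8L, 8L)
      if (labelled) sizes <- c(sizes, 4L, 4L)
      if (has_col) sizes <- c(sizes, 1L, 1L, 1L)
      stride <- sum(sizes)
      off <- cumsum(c(0L, sizes[-length(sizes)]))
      raw <- raw(stride * n)
      base <- (seq_len(n) - 1L) * stride
      put <- function(j, bytes_per_row) {
        idx <- rep(base, each = sizes[j]) + rep(seq_len(sizes[j]) + off[j], times = n)
        raw[idx] <<- bytes_per_row
      }
      for (j in 1:3) put(j, writeBin(cloud$coords[, j], raw(), size = 8L, endian = "little"))
      if (labelled) {
        put(4L, writeBin(cloud$semantic, raw(), size = 4L, endian = "little"))
        put(5L, writeBin(cloud$instance, raw(), size = 4L, endian = "little"))
      }
      if (has_col) {
        j0 <- if (labelled) 5L else 3L
        for (k in 1:3) put(j0 + k, as.raw(colb[, k]))
      }
      writeBin(raw, con)
    }
  }
  invisible(path)
}
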