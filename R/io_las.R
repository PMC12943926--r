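# Minimal uncompressed LAS reader (1.2-1.4, point formats 0-3 and 6-8) and
# LAS 1.2 / point-format-0 writer. Coordinates use a 1e-7 m scale relative to
# the cloud minimum corner, so round trips are exact to well below 1e-6 m.
# Classification codes map to semantic classes through a class map
# (ASPRS code 2 = ground by default, everything else = tree); instance ids
# are carried in the point-source-id field as instance + 1 (0 = unassigned).

#' LAS classification-code to semantic-class map
#'
#' LAS dialects vary in how vegetation is coded, so the mapping is explicit
#' configuration rather than hard-wired.
#'
#' @param codes named integer vector: names are LAS classification codes,
#'   values are semantic classes (0 ground, 1 tree).
#' @param default semantic class for codes not listed.
#' @return a class-map object used by [read_point_cloud()].
#' @export
las_class_map <- function(codes = c("0" = -1L, "1" = -1L, "2" = 0L), default = 1L) {
  list(codes = codes, default = as.integer(default))
}

read_las <- function(path, class_map = las_class_map()) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 375L)
  if (length(hdr) < 227L || rawToChar(hdr[1:4]) != "LASF")
    stop("'", path, "' is not a LAS file")
  u16 <- function(o) readBin(hdr[(o + 1):(o + 2)], "integer", size = 2, signed = FALSE, endian = "little")
  u32 <- function(o) {
    b <- as.numeric(as.integer(hdr[(o + 1):(o + 4)]))
    b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
  }
  dbl <- function(o) readBin(hdr[(o + 1):(o + 8)], "double", size = 8, endian = "little")
  ver <- paste0(as.integer(hdr[25]), ".", as.integer(hdr[26]))
  pt_offset <- u32(96L)
  fmt <- as.integer(hdr[105])
  if (fmt >= 128L) stop("'", path, "' is LAZ-compressed; only uncompressed LAS is supported")
  rec_len <- u16(105L)
  npts <- u32(107L)
  if (npts == 0 && ver >= "1.4" && length(hdr) >= 255L) {
    lo <- u32(247L); hi <- u32(251L)
    npts <- lo + hi * 4294967296
  }
  scale <- c(dbl(131L), dbl(139L), dbl(147L))
  offset <- c(dbl(155L), dbl(163L), dbl(171L))
  cls_off <- if (fmt <= 5L) 15L else if (fmt %in% 6:10) 16L else
    stop("LAS point format ", fmt, " is not supported")
  seek(con, where = pt_offset, origin = "start")
  raw <- readBin(con, "raw", n = rec_len * npts)
  if (length(raw) < rec_len * npts) stop("LAS file '", path, "' truncated")
  if (npts == 0) return(point_cloud(matrix(numeric(0), 0, 3)))
  base <- (seq_len(npts) - 1) * rec_len
  geti32 <- function(o) {
    idx <- rep(base, each = 4L) + rep((o + 1L):(o + 4L), times = npts)
    readBin(raw[idx], "integer", n = npts, size = 4L, endian = "little")
  }
  x <- geti32(0L) * scale[1] + offset[1]
  y <- geti32(4L) * scale[2] + offset[2]
  z <- geti32(8L) * scale[3] + offset[3]
  cls <- as.integer(raw[base + cls_off + 1L])
  if (fmt <= 5L) cls <- bitwAnd(cls, 31L)  # strip synthetic/key-point/withheld bits
  sem <- rep(class_map$default, npts)
  hit <- match(as.character(cls), names(class_map$codes))
  sem[!is.na(hit)] <- as.integer(class_map$codes[hit[!is.na(hit)]])
  inst <- rep(-1L, npts)
  if (fmt <= 5L && rec_len >= 20L) {
    psid_off <- 18L
    idx <- rep(base, each = 2L) + rep((psid_off + 1L):(psid_off + 2L), times = npts)
    psid <- readBin(raw[idx], "integer", n = npts, size = 2L, signed = FALSE, endian = "little")
    inst <- psid - 1L
  }
  inst[sem < 0L] <- -1L  # points without a semantic class cannot carry an instance
  point_cloud(cbind(x, y, z), sem, inst)
}

write_las <- function(cloud, path, class_codes = c(ground = 2L, tree = 5L)) {
  n <- n_points(cloud)
  scale <- 1e-7
  offset <- if (n > 0L) col_mins(cloud$coords) else c(0, 0, 0)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot write LAS file '", path, "': ", conditionMessage(e)))
  on.exit(close(con))
  hdr <- raw(227L)
  hdr[1:4] <- charToRaw("LASF")
  hdr[25] <- as.raw(1L); hdr[26] <- as.raw(2L)           # version 1.2
  hdr[95:96] <- writeBin(227L, raw(), size = 2L, endian = "little")[1:2]  # header size
  hdr[97:100] <- writeBin(227L, raw(), size = 4L, endian = "little")      # point data offset
  hdr[105] <- as.raw(0L)                                  # point format 0
  hdr[106:107] <- writeBin(20L, raw(), size = 2L, endian = "little")[1:2]
  hdr[108:111] <- writeBin(as.integer(n), raw(), size = 4L, endian = "little")
  hdr[112:115] <- writeBin(as.integer(n), raw(), size = 4L, endian = "little")
  putd <- function(pos, v) hdr[(pos + 1):(pos + 8)] <<- writeBin(v, raw(), size = 8L, endian = "little")
  putd(131L, scale); putd(139L, scale); putd(147L, scale)
  putd(155L, offset[1]); putd(163L, offset[2]); putd(171L, offset[3])
  if (n > 0L) {
    mx <- col_maxs(cloud$coords)
    putd(179L, mx[1]); putd(187L, offset[1])
    putd(195L, mx[2]); putd(203L, offset[2])
    putd(211L, mx[3]); putd(219L, offset[3])
  }
  writeBin(hdr, con)
  if (n > 0L) {
    xi <- as.integer(round((cloud$coords[, 1] - offset[1]) / scale))
    yi <- as.integer(round((cloud$coords[, 2] - offset[2]) / scale))
    zi <- as.integer(round((cloud$coords[, 3] - offset[3]) / scale))
    cls <- ifelse(cloud$semantic == 0L, class_codes[["ground"]],
                  ifelse(cloud$semantic == 1L, class_codes[["tree"]], 0L))
    psid <- pmin(pmax(cloud$instance + 1L, 0L), 65535L)
    rec <- raw(20L * n)
    base <- (seq_len(n) - 1L) * 20L
    put <- function(o, bytes, s) rec[rep(base, each = s) + rep((o + 1L):(o + s), times = n)] <<- bytes
    put(0L, writeBin(xi, raw(), size = 4L, endian = "little"), 4L)
    put(4L, writeBin(yi, raw(), size = 4L, endian = "little"), 4L)
    put(8L, writeBin(zi, raw(), size = 4L, endian = "little"), 4L)
    put(15L, as.raw(cls), 1L)
    put(18L, writeBin(as.integer(psid), raw(), size = 2L, endian = "little"), 2L)
    writeBin(rec, con)
  }
  invisible(path)
}
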