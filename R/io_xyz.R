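# Whitespace-delimited XYZ with optional integer label columns.
# Column order on write: x y z [semantic instance] [r g b].

read_xyz <- function(path) {
  if (file.size(path) == 0) return(point_cloud(matrix(numeric(0), 0, 3)))
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = FALSE, sep = " ", strip.white = TRUE,
                        blank.lines.skip = TRUE, data.table = FALSE)),
    error = function(e) stop("failed to parse XYZ file '", path, "': ", conditionMessage(e))
  )
  if (nrow(dt) == 0L) return(point_cloud(matrix(numeric(0), 0, 3)))
  nc <- ncol(dt)
  if (nc < 3L) stop("XYZ file '", path, "' has ", nc, " columns; need at least x y z")
  coords <- suppressWarnings(
    cbind(as.numeric(dt[[1]]), as.numeric(dt[[2]]), as.numeric(dt[[3]])))
  bad <- which(!is.finite(rowSums(coords)))
  if (length(bad))
    stop("malformed record in '", path, "' at data row ", bad[1])
  sem <- inst <- NULL
  col <- NULL
  if (nc >= 5L) {
    sem <- as.integer(dt[[4]])
    inst <- as.integer(dt[[5]])
  }
  if (nc >= 8L) col <- as.matrix(dt[, 6:8])
  point_cloud(coords, sem, inst, col)
}

write_xyz <- function(cloud, path) {
  n <- n_points(cloud)
  labelled <- any(cloud$semantic >= 0L) || any(cloud$instance >= 0L)
  cols <- list(cloud$coords[, 1], cloud$coords[, 2], cloud$coords[, 3])
  if (labelled || !is.null(cloud$color)) cols <- c(cols, list(cloud$semantic, cloud$instance))
  if (!is.null(cloud$color)) cols <- c(cols, list(cloud$color[, 1], cloud$color[, 2], cloud$color[, 3]))
  df <- as.data.frame(cols, col.names = paste0("V", seq_along(cols)))
  ok <- tryCatch({
    data.table::fwrite(df, path, sep = " ", col.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write XYZ file '", path, "'")
  if (n == 0L && !file.exists(path)) file.create(path)
  invisible(path)
}
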