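#' Read and write MRC/CCP4 voxel maps
#'
#' Minimal MRC2014 support for mode-2 (float32) maps, the form in which
#' EMD-style density maps are distributed.  Voxel spacing is `cella/m{x,y,z}`
#' and the grid origin is taken from (and written to) the `xorigin/yorigin/
#' zorigin` header words.  Values round-trip within float32 precision.
#'
#' @param path file path.
#' @return `readMRC` returns a [VoxelMap-class].
#' @export
readMRC <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  seek(con, 52 * 4)
  map_tag <- rawToChar(readBin(con, "raw", n = 4))
  if (!identical(map_tag, "MAP "))
    stop("malformed MRC header: missing 'MAP ' tag (word 53)")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  if (any(c(nx, ny, nz) < 1)) stop("malformed MRC header: bad dims nx/ny/nz")
  if (hdr_int[4] != 2L)
    stop(sprintf("unsupported MRC mode %d (field 'mode'; only float32 mode 2)",
                 hdr_int[4]))
  m <- hdr_int[8:10]
  if (any(m < 1)) stop("malformed MRC header: bad sampling mx/my/mz")
  cella <- hdr_num[11:13]
  spacing <- cella / m
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("malformed MRC header: non-positive cell dimensions (field 'cella')")
  if (!all(hdr_int[17:19] == c(1L, 2L, 3L)))
    stop("unsupported axis order (fields mapc/mapr/maps must be 1,2,3)")
  origin <- hdr_num[50:52]
  nsymbt <- hdr_int[24]
  seek(con, 1024 + nsymbt)
  n <- nx * ny * nz
  vals <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(vals) != n) stop("truncated MRC data section")
  voxelMap(array(vals, c(nx, ny, nz)), origin = origin, spacing = spacing)
}

#' @param map a [VoxelMap-class] to write.
#' @rdname readMRC
#' @export
writeMRC <- function(map, path) {
  stopifnot(is(map, "VoxelMap"))
  d <- dim(map@values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- as.numeric(map@values)
  wi(d)                      # nx ny nz
  wi(2L)                     # mode 2 = float32
  wi(c(0L, 0L, 0L))          # nxstart
  wi(d)                      # mx my mz
  wf(map@spacing * d)        # cella
  wf(c(90, 90, 90))          # cellb
  wi(c(1L, 2L, 3L))          # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))
  wi(c(1L, 0L))              # ispg, nsymbt
  wi(integer(25))            # extra -> fills words 25..49
  wf(map@origin)             # xorigin yorigin zorigin (words 50..52)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(v))
  wi(0L)                     # nlabl
  writeBin(raw(800), con)    # labels
  wf(v)
  invisible(path)
}

#' Read and write Gaussian-mixture text files
#'
#' Plain-text mixture dialect: one component per line with ten
#' whitespace-separated numbers — weight, the three mean coordinates (nm) and
#' the six upper-triangle covariance entries (nm^2) in the order
#' `xx xy xz yy yz zz`.  Lines starting with `#` are comments.  Values are
#' written at full decimal precision so a write/read round trip is exact.
#'
#' @param path file path.
#' @param label mixture label to assign on read.
#' @return `readGMM` returns a [GaussianMixtureMap-class].
#' @export
readGMM <- function(path, label = "data") {
  raw <- trimws(readLines(path))
  recLine <- which(nzchar(raw) & !startsWith(raw, "#"))
  if (!length(recLine)) stop("GMM file contains no component records")
  K <- length(recLine)
  w <- numeric(K); mu <- matrix(0, K, 3); covs <- array(0, c(3, 3, K))
  for (i in seq_len(K)) {
    fields <- suppressWarnings(
      as.numeric(strsplit(raw[recLine[i]], "[[:space:]]+")[[1]]))
    if (length(fields) != 10 || any(is.na(fields)))
      stop(sprintf("GMM record at line %d: expected 10 numeric fields (weight, mean x3, upper-triangle covariance x6)", recLine[i]))
    w[i] <- fields[1]
    mu[i, ] <- fields[2:4]
    S <- matrix(0, 3, 3)
    # file order xx xy xz yy yz zz -> R's column-major slots xx xy yy xz yz zz
    S[upper.tri(S, diag = TRUE)] <- fields[c(5, 6, 8, 7, 9, 10)]
    S <- S + t(S) - diag(diag(S))
    msg <- .check_spd(S)
    if (!is.null(msg))
      stop(sprintf("GMM record at line %d: %s", recLine[i], msg))
    if (w[i] <= 0)
      stop(sprintf("GMM record at line %d: weight must be positive", recLine[i]))
    covs[, , i] <- S
  }
  gmmMap(w, mu, covs, label = label)
}

#' @param gmm a [GaussianMixtureMap-class] to write.
#' @rdname readGMM
#' @export
writeGMM <- function(gmm, path) {
  stopifnot(is(gmm, "GaussianMixtureMap"))
  K <- nComponents(gmm)
  lines <- c("# memmi Gaussian mixture map",
             sprintf("# label: %s  components: %d", gmm@label, K),
             "# weight mean_x mean_y mean_z cov_xx cov_xy cov_xz cov_yy cov_yz cov_zz (nm, nm^2)")
  for (i in seq_len(K)) {
    S <- gmm@covs[, , i]
    ut <- S[upper.tri(S, diag = TRUE)]        # xx xy yy xz yz zz in R order
    ut <- ut[c(1, 2, 4, 3, 5, 6)]             # reorder to xx xy xz yy yz zz
    lines <- c(lines, paste(sprintf("%.17g",
               c(gmm@weights[i], gmm@means[i, ], ut)), collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}
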