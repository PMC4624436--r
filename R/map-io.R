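# CCP4/MRC map I/O (mode 2, float32, orthogonal P1 boxes). The reader
# normalizes any axis permutation (MAPC/MAPR/MAPS) so values are stored
# fast-to-slow = x,y,z internally; the writer emits x,y,z order.

#' Write a density map in CCP4/MRC format (mode 2)
#'
#' @param map a [density_map()].
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_map <- function(map, path) {
  dims <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  cell <- dims * map$spacing
  start <- round(map$origin / map$spacing)
  wi(dims)                     # NC NR NS
  wi(2)                        # MODE 2 = float32
  wi(start)                    # NCSTART NRSTART NSSTART
  wi(dims)                     # NX NY NZ sampling intervals
  wf(cell); wf(c(90, 90, 90))  # cell
  wi(c(1, 2, 3))               # MAPC MAPR MAPS = x,y,z
  wf(c(min(map$values), max(map$values), mean(map$values)))
  wi(1)                        # ISPG (P1)
  wi(0)                        # NSYMBT
  wi(rep(0, 12))               # words 25-36 extra
  wf(map$resolution)           # word 37: stash nominal resolution
  wi(rep(0, 12))               # words 38-49
  wf(map$origin)               # words 50-52: MRC2014 ORIGIN
  writeChar("MAP ", con, 4, eos = NULL)
  wi(16708)                    # MACHST little-endian stamp
  wf(stats::sd(as.numeric(map$values)))
  wi(0)                        # NLABL
  writeBin(raw(800), con)      # labels
  wf(as.numeric(map$values))
  invisible(path)
}

#' Read a CCP4/MRC density map
#'
#' @param path map file (mode 0/1/2; mode 2 recommended).
#' @param resolution nominal resolution override; if NULL, taken from the
#'   header word this package writes, else 2.0.
#' @return a [density_map()], axes normalized to x,y,z.
#' @export
read_map <- function(path, resolution = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  ncrs <- ri(3); mode <- ri(1); start <- ri(3); mxyz <- ri(3)
  cell <- rf(3); ang <- rf(3); mapcrs <- ri(3)
  rf(3); ri(1); nsymbt <- ri(1)
  ri(12); res_word <- rf(1); ri(12)
  origin_mrc <- rf(3)
  readChar(con, 4); ri(1); rf(1); ri(1)
  readBin(con, "raw", 800)
  if (max(abs(ang - 90)) > 1e-3) stop("non-orthogonal cells are unsupported")
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  nvox <- prod(ncrs)
  vals <- switch(as.character(mode),
                 "2" = readBin(con, "numeric", nvox, size = 4, endian = "little"),
                 "1" = as.numeric(readBin(con, "integer", nvox, size = 2, endian = "little")),
                 "0" = as.numeric(readBin(con, "integer", nvox, size = 1, signed = TRUE)),
                 stop("unsupported map mode: ", mode))
  arr <- array(vals, ncrs)
  # permute from (col,row,sec) axis assignment to (x,y,z)
  perm <- order(mapcrs)        # position of x,y,z among col/row/sec
  arr <- aperm(arr, perm)
  spacing_xyz <- (cell / mxyz)[mapcrs][perm]
  start_xyz <- start[perm]
  origin <- if (any(origin_mrc != 0)) origin_mrc else start_xyz * spacing_xyz
  if (is.null(resolution)) resolution <- if (res_word > 0) res_word else 2.0
  density_map(arr, origin, spacing_xyz, resolution)
}
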