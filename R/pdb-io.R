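# Fixed-column PDB reading and writing with altloc, occupancy and ANISOU
# support. The writer emits coordinates to 3 decimals and occupancies to 2,
# so a write/read round trip is lossless to that precision.

parse_num <- function(s, what, lineno) {
  s <- trimws(s)
  if (s == "") return(NA_real_)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop(sprintf("malformed %s field on line %d: '%s'", what, lineno, s))
  v
}

guess_element <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  if (nm == "") return("C")
  two <- toupper(substr(nm, 1, 2))
  if (two %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA") && nchar(trimws(name)) > 3) {
    return(substr(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))), 1, 2))
  }
  substr(nm, 1, 1)
}

#' Read a PDB file into a protein model
#'
#' Handles `ATOM`/`HETATM`, `ANISOU` (attached to the matching atom by chain,
#' residue, atom name and altloc), `TER`, and `CRYST1` records. Altloc groups
#' may be interleaved; insertion codes are preserved.
#'
#' @param path path to a fixed-column PDB file.
#' @return a [protein_model()].
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- substr(lines, 1, 6)
  cell <- NULL
  cr <- which(recs == "CRYST1")
  if (length(cr) > 0) {
    l <- lines[cr[1]]
    cell <- c(a = parse_num(substr(l, 7, 15), "cell a", cr[1]),
              b = parse_num(substr(l, 16, 24), "cell b", cr[1]),
              c = parse_num(substr(l, 25, 33), "cell c", cr[1]),
              alpha = parse_num(substr(l, 34, 40), "alpha", cr[1]),
              beta = parse_num(substr(l, 41, 47), "beta", cr[1]),
              gamma = parse_num(substr(l, 48, 54), "gamma", cr[1]))
  }
  idx <- which(recs %in% c("ATOM  ", "HETATM"))
  n <- length(idx)
  if (n == 0) stop("no ATOM/HETATM records in ", path)
  out <- vector("list", n)
  for (j in seq_len(n)) {
    i <- idx[j]
    l <- lines[i]
    if (nchar(l) < 54) stop("malformed ATOM line ", i, ": too short")
    name <- trimws(substr(l, 13, 16))
    altloc <- trimws(substr(l, 17, 17))
    resid <- trimws(substr(l, 18, 20))
    chain <- trimws(substr(l, 22, 22))
    resno <- parse_num(substr(l, 23, 26), "residue number", i)
    if (is.na(resno)) stop("malformed ATOM line ", i, ": missing residue number")
    icode <- trimws(substr(l, 27, 27))
    x <- parse_num(substr(l, 31, 38), "x", i)
    y <- parse_num(substr(l, 39, 46), "y", i)
    z <- parse_num(substr(l, 47, 54), "z", i)
    if (anyNA(c(x, y, z))) stop("malformed ATOM line ", i, ": bad coordinates")
    occ <- parse_num(substr(l, 55, 60), "occupancy", i)
    b <- parse_num(substr(l, 61, 66), "B-factor", i)
    elem <- trimws(substr(l, 77, 78))
    if (elem == "" || is.na(elem)) elem <- guess_element(name)
    out[[j]] <- list(chain = chain, resno = as.integer(resno), icode = icode,
                     resid = resid, name = name, element = elem,
                     altloc = altloc, x = x, y = y, z = z,
                     occ = ifelse(is.na(occ), 1, occ),
                     b = ifelse(is.na(b), 0, b),
                     het = recs[i] == "HETATM")
  }
  atoms <- dplyr::bind_rows(lapply(out, tibble::as_tibble))
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, atoms$altloc, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate atom record: ", gsub("\r", " ", d))
  }
  for (u in c("u11", "u22", "u33", "u12", "u13", "u23")) atoms[[u]] <- NA_real_
  ai <- which(recs == "ANISOU")
  for (i in ai) {
    l <- lines[i]
    name <- trimws(substr(l, 13, 16))
    altloc <- trimws(substr(l, 17, 17))
    chain <- trimws(substr(l, 22, 22))
    resno <- as.integer(parse_num(substr(l, 23, 26), "residue number", i))
    icode <- trimws(substr(l, 27, 27))
    k <- paste(chain, resno, icode, name, altloc, sep = "\r")
    m <- match(k, key)
    if (is.na(m)) next
    u <- vapply(seq_len(6), function(f) {
      parse_num(substr(l, 29 + 7 * (f - 1), 28 + 7 * f), "ANISOU", i)
    }, 0)
    atoms[m, c("u11", "u22", "u33", "u12", "u13", "u23")] <- as.list(u * 1e-4)
  }
  atoms$het <- NULL
  protein_model(atoms, cell)
}

fmt_atom_name <- function(name, element) {
  # element symbol occupies columns 13-14 for standard names
  if (nchar(name) >= 4) return(substr(name, 1, 4))
  if (nchar(element) == 1) sprintf(" %-3s", name) else sprintf("%-4s", name)
}

#' Write a protein model to a PDB file
#'
#' Conformers within a residue are emitted with their altloc letters;
#' occupancies are printed with 2 decimals and coordinates with 3; `ANISOU`
#' records are written for atoms carrying an anisotropic tensor.
#'
#' @param model a [protein_model()].
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  if (any(nchar(a$altloc) > 1) || length(setdiff(unique(a$altloc), c("", LETTERS))) > 0) {
    stop("altloc labels beyond 'A'..'Z' are unsupported")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(model$cell)) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       model$cell[1], model$cell[2], model$cell[3],
                       model$cell[4], model$cell[5], model$cell[6]), con)
  }
  serial <- 0L
  for (i in seq_len(nrow(a))) {
    serial <- serial + 1L
    nm <- fmt_atom_name(a$name[i], a$element[i])
    writeLines(sprintf("ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       serial %% 100000L, nm, a$altloc[i], a$resid[i], a$chain[i],
                       a$resno[i], a$icode[i], a$x[i], a$y[i], a$z[i],
                       a$occ[i], a$b[i], toupper(a$element[i])), con)
    if (!is.na(a$u11[i])) {
      u <- round(unlist(a[i, c("u11", "u22", "u33", "u12", "u13", "u23")]) * 1e4)
      writeLines(sprintf("ANISOU%5d %s%1s%-3s %1s%4d%1s %7d%7d%7d%7d%7d%7d      %2s",
                         serial %% 100000L, nm, a$altloc[i], a$resid[i], a$chain[i],
                         a$resno[i], a$icode[i], u[1], u[2], u[3], u[4], u[5], u[6],
                         toupper(a$element[i])), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}
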