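# Rotamer library handling. The shipped library covers all 18 chi-bearing
# residue types with penultimate-style rotameric chi values; glycine and
# alanine have no sidechain chi and return empty lists.

SMALL_SIDECHAINS <- c("ASN", "ASP", "CYS", "ILE", "LEU", "PRO", "SER", "THR", "VAL")
LARGE_SIDECHAINS <- c("ARG", "GLU", "GLN", "HIS", "LYS", "MET", "PHE", "TRP", "TYR")

#' Number of sidechain chi angles for a residue type
#' @param resid 3-letter residue code.
#' @return integer count (0 for GLY/ALA).
#' @export
chi_count <- function(resid) {
  counts <- c(ALA = 0, GLY = 0,
              SER = 1, CYS = 1, THR = 1, VAL = 1,
              ILE = 2, LEU = 2, PRO = 2, ASP = 2, ASN = 2,
              PHE = 2, TYR = 2, TRP = 2, HIS = 2,
              MET = 3, GLU = 3, GLN = 3,
              LYS = 4, ARG = 4)
  if (!resid %in% names(counts)) stop("unknown residue type: ", resid)
  unname(counts[resid])
}

#' Load a rotamer library
#'
#' @param path whitespace-delimited text file: residue, rotamer name, chi
#'   angles (degrees); `#` comments allowed. Defaults to the library shipped
#'   with the package.
#' @return a list of entries `list(resid, rotamer, chi)`.
#' @export
load_rotamer_library <- function(path = system.file("extdata", "rotamers.txt",
                                                    package = "altconf")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  entries <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    resid <- toupper(f[1])
    if (!resid %in% AA3) stop("unknown residue type in rotamer library: ", resid)
    chi <- as.numeric(f[-(1:2)])
    if (anyNA(chi)) stop("bad chi value on rotamer library line ", i)
    if (any(chi <= -180 | chi > 180)) stop("chi out of (-180,180] on line ", i)
    if (length(chi) != chi_count(resid)) {
      stop(sprintf("rotamer library line %d: %s needs %d chi angles, got %d",
                   i, resid, chi_count(resid), length(chi)))
    }
    list(resid = resid, rotamer = f[2], chi = chi)
  })
  types <- unique(vapply(entries, `[[`, "", "resid"))
  missing <- setdiff(setdiff(AA3, c("GLY", "ALA")), types)
  if (length(missing) > 0) stop("rotamer library missing residue types: ",
                                paste(missing, collapse = ", "))
  entries
}

#' Rotamers for one residue type
#'
#' @param library result of [load_rotamer_library()].
#' @param resid 3-letter residue code; GLY/ALA yield an empty list.
#' @return list of rotamer entries.
#' @export
rotamers_for <- function(library, resid) {
  resid <- toupper(resid)
  if (chi_count(resid) == 0) return(list())
  library[vapply(library, function(e) e$resid == resid, TRUE)]
}
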