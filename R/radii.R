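#' Element van der Waals radii (Angstrom)
#'
#' Bundled table used for SASA, clash and density calculations. Unknown
#' elements fall back to 1.70 A (carbon) with a warning.
#'
#' @param element character vector of element symbols
#' @return numeric vector of radii in Angstrom
#' @export
vdw_radius <- function(element) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
           SE = 1.90, FE = 2.00, MG = 1.73, ZN = 1.39, CA = 2.31, `NA` = 2.27,
           K = 2.75, CL = 1.75, F = 1.47, BR = 1.85, I = 1.98)
  el <- toupper(trimws(element))
  r <- unname(tab[el])
  unk <- is.na(r)
  if (any(unk)) {
    warning(sprintf("%d atom(s) with unknown element (%s): default radius 1.70 A",
                    sum(unk), paste(unique(el[unk]), collapse = ",")))
    r[unk] <- 1.70
  }
  r
}

#' Atomic numbers used as density weights
#' @param element character vector of element symbols
#' @return numeric vector of atomic numbers (unknown elements count as carbon)
#' @export
atomic_number <- function(element) {
  tab <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, SE = 34, FE = 26,
           MG = 12, ZN = 30, CA = 20, `NA` = 11, K = 19, CL = 17, F = 9)
  z <- unname(tab[toupper(trimws(element))])
  z[is.na(z)] <- 6
  z
}

# Infer an element symbol from a PDB atom name when the element column is
# blank: strip digits/primes, handle two-letter metals appearing in columns
# 13-14, else first alphabetic character.
element_from_name <- function(name) {
  vapply(name, function(nm) {
    s <- gsub("[0-9'\"]", "", trimws(nm))
    if (nchar(s) == 0) return("C")
    two <- toupper(substr(s, 1, 2))
    if (two %in% c("FE", "MG", "ZN", "CL", "BR", "SE", "NA")) return(two)
    toupper(substr(s, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}
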