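#' Read an atomic coordinate file
#'
#' PDB files are parsed with bio3d; mmCIF files with a bundled `atom_site`
#' loop reader. Every ATOM/HETATM record becomes one atom row; coordinates are
#' in Angstrom and residue numbering is preserved verbatim. Van der Waals
#' radii are assigned from the bundled element table.
#'
#' @param path file path
#' @param format one of "auto", "pdb", "mmcif" ("auto" decides by extension,
#'   falling back to content sniffing)
#' @return structure_model
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else if (ext %in% c("pdb", "ent")) "pdb" else {
      head <- readLines(path, n = 5, warn = FALSE)
      if (any(grepl("^data_|^loop_", head))) "mmcif" else "pdb"
    }
  }
  atoms <- if (format == "pdb") read_pdb_atoms(path) else read_mmcif_atoms(path)
  if (nrow(atoms) == 0) stop("no ATOM/HETATM records parsed from ", path)
  blank <- is.na(atoms$element) | atoms$element == ""
  if (any(blank)) atoms$element[blank] <- element_from_name(atoms$name[blank])
  structure_model(atoms, metadata = list(source = path, format = format))
}

read_pdb_atoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  a <- pdb$atom
  data.frame(serial = as.integer(a$eleno), name = trimws(a$elety),
             element = toupper(trimws(ifelse(is.na(a$elesy), "", a$elesy))),
             resname = trimws(a$resid), resno = as.integer(a$resno),
             chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
             x = a$x, y = a$y, z = a$z,
             occ = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
             stringsAsFactors = FALSE)
}

read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  for (ls in loop_starts) {
    i <- ls + 1
    fields <- character(0)
    while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
      fields <- c(fields, trimws(lines[i]))
      i <- i + 1
    }
    if (!any(grepl("^_atom_site\\.", fields))) next
    cols <- sub("^_atom_site\\.", "", fields)
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || grepl("^(#|loop_|_|data_)", ln)) break
      rows[[length(rows) + 1]] <- scan(text = ln, what = character(),
                                       quiet = TRUE)
      i <- i + 1
    }
    if (length(rows) == 0) stop("empty atom_site loop in ", path)
    nf <- lengths(rows)
    if (any(nf != length(cols))) {
      stop(sprintf("mmCIF parse error in %s near line %d: %d fields, expected %d",
                   path, i - which(nf != length(cols))[1], nf[nf != length(cols)][1],
                   length(cols)))
    }
    m <- do.call(rbind, rows)
    colnames(m) <- cols
    get <- function(nm, alt = NULL) {
      if (nm %in% cols) m[, nm] else if (!is.null(alt) && alt %in% cols) m[, alt] else NA
    }
    und <- function(v) ifelse(v %in% c("?", "."), NA, v)
    return(data.frame(
      serial = as.integer(und(get("id"))),
      name = gsub('"', "", und(get("label_atom_id", "auth_atom_id"))),
      element = toupper(ifelse(is.na(und(get("type_symbol"))), "",
                               und(get("type_symbol")))),
      resname = und(get("label_comp_id", "auth_comp_id")),
      resno = as.integer(und(get("auth_seq_id", "label_seq_id"))),
      chain = und(get("auth_asym_id", "label_asym_id")),
      x = as.numeric(und(get("Cartn_x"))),
      y = as.numeric(und(get("Cartn_y"))),
      z = as.numeric(und(get("Cartn_z"))),
      occ = ifelse(is.na(und(get("occupancy"))), 1,
                   as.numeric(und(get("occupancy")))),
      b = ifelse(is.na(und(get("B_iso_or_equiv"))), 0,
                 as.numeric(und(get("B_iso_or_equiv")))),
      stringsAsFactors = FALSE))
  }
  stop("no atom_site loop found in ", path)
}

#' Write an atomic coordinate file
#'
#' Round-trips through [read_structure()] reproduce coordinates to 0.001 A and
#' all identifiers. Models that do not fit strict PDB (chain ids longer than
#' one character, atom serials > 99999 or residue numbers > 9999) are written
#' as mmCIF with a warning when PDB was requested.
#'
#' @param model structure_model
#' @param path output path
#' @param format "pdb" or "mmcif"
#' @return invisibly, the path actually written
#' @export
write_structure <- function(model, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  if (n_atoms(model) == 0) stop("refusing to write an empty model")
  a <- model$atoms
  pdb_ok <- all(nchar(a$chain) == 1) && nrow(a) <= 99999 &&
    max(a$resno) <= 9999 && min(a$resno) >= -999
  if (format == "pdb" && !pdb_ok) {
    warning("model does not fit strict PDB; writing mmCIF instead")
    format <- "mmcif"
    if (tolower(tools::file_ext(path)) == "pdb") {
      path <- sub("\\.pdb$", ".cif", path, ignore.case = TRUE)
    }
  }
  if (format == "pdb") write_pdb_atoms(a, path) else write_mmcif_atoms(a, path)
  invisible(path)
}

write_pdb_atoms <- function(a, path) {
  name4 <- ifelse(nchar(a$name) <= 3, sprintf(" %-3s", a$name),
                  sprintf("%-4s", a$name))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000, name4, substr(a$resname, 1, 3), a$chain, a$resno,
    a$x, a$y, a$z, a$occ, a$b, a$element)
  writeLines(c(lines, "END"), path)
}

write_mmcif_atoms <- function(a, path) {
  hdr <- c("data_model", "#", "loop_",
           paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                   "label_atom_id", "label_comp_id",
                                   "auth_asym_id", "auth_seq_id",
                                   "Cartn_x", "Cartn_y", "Cartn_z",
                                   "occupancy", "B_iso_or_equiv")))
  body <- sprintf("ATOM %d %s %s %s %s %d %.3f %.3f %.3f %.2f %.2f",
                  a$serial, a$element, a$name, a$resname, a$chain, a$resno,
                  a$x, a$y, a$z, a$occ, a$b)
  writeLines(c(hdr, body, "#"), path)
}
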