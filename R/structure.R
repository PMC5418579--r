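#' Atomic structure model
#'
#' A `structure_model` holds an ordered table of atoms together with source
#' metadata and, for generated lattices, a ground-truth table describing which
#' protofilament / dimer / subunit each chain belongs to. Coordinates are in
#' Angstrom throughout; residue numbering is kept verbatim from the source.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain`, `x`, `y`, `z`, `occ`, `b`. A `vdw` column is
#'   added from the bundled element table when absent.
#' @param metadata named list (e.g. `source`, `title`).
#' @param truth optional data.frame of generator ground truth with one row per
#'   chain (columns `chain`, `tubule`, `pf`, `dimer`, `subunit`).
#' @return object of class `structure_model`
#' @export
structure_model <- function(atoms, metadata = list(), truth = NULL) {
  required <- c("serial", "name", "element", "resname", "resno", "chain",
                "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    stop("atoms table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$vdw)) atoms$vdw <- vdw_radius(atoms$element)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  if (any(atoms$vdw <= 0)) stop("van der Waals radii must be positive")
  atoms$chain <- as.character(atoms$chain)
  atoms$name <- as.character(atoms$name)
  atoms$element <- as.character(atoms$element)
  atoms$resname <- as.character(atoms$resname)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, metadata = metadata, truth = truth),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat(sprintf("structure_model: %d atoms, %d chain(s)\n",
              nrow(x$atoms), length(ch)))
  if (!is.null(x$metadata$source)) cat("  source:", x$metadata$source, "\n")
  if (!is.null(x$truth)) cat("  generator ground truth attached\n")
  invisible(x)
}

#' Number of atoms in a model
#' @param model structure_model
#' @return integer
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Atom coordinates as an n x 3 matrix (Angstrom)
#' @param model structure_model
#' @return numeric matrix with columns x, y, z
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z"), drop = FALSE])
}

#' Replace coordinates of a model
#' @param model structure_model
#' @param value n x 3 numeric matrix
#' @return model with new coordinates
#' @export
`coords<-` <- function(model, value) {
  stopifnot(nrow(value) == n_atoms(model), ncol(value) == 3)
  model$atoms$x <- value[, 1]
  model$atoms$y <- value[, 2]
  model$atoms$z <- value[, 3]
  model
}

#' Chain index of a model
#' @param model structure_model
#' @return named list mapping chain id to atom row indices
#' @export
chain_index <- function(model) {
  split(seq_len(n_atoms(model)), factor(model$atoms$chain,
                                        levels = unique(model$atoms$chain)))
}

#' Centroids of every chain
#' @param model structure_model
#' @return matrix (chains x 3) with chain ids as rownames
#' @export
chain_centroids <- function(model) {
  idx <- chain_index(model)
  xyz <- coords(model)
  t(vapply(idx, function(i) colMeans(xyz[i, , drop = FALSE]), numeric(3)))
}

#' Select a sub-model
#'
#' Selection is by chain id, residue number range, atom name and/or element.
#' All criteria are combined with AND; atom order and numbering are preserved.
#' An empty selection is allowed and returns a 0-atom model.
#'
#' @param model structure_model
#' @param chain character vector of chain ids, or NULL for all
#' @param resno integer vector of residue numbers (e.g. `56:60`), or NULL
#' @param name atom-name vector (e.g. "CA"), or NULL
#' @param element element symbols, or NULL
#' @return structure_model with the matching atoms
#' @export
select_atoms <- function(model, chain = NULL, resno = NULL, name = NULL,
                         element = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(element)) keep <- keep & a$element %in% element
  truth <- model$truth
  if (!is.null(truth) && !is.null(chain)) {
    truth <- truth[truth$chain %in% chain, , drop = FALSE]
  }
  structure_model(a[keep, , drop = FALSE], model$metadata, truth)
}

#' Parse a selection expression string
#'
#' Mini-language used by the command-line interface:
#' `"chain A,B resno 56-60 name CA element C"`. Each keyword is optional;
#' ranges use `-`, lists use `,`.
#'
#' @param model structure_model
#' @param expr selection string
#' @return structure_model
#' @export
select_expr <- function(model, expr) {
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  if (length(toks) == 0) return(model)
  args <- list(model = model)
  i <- 1
  while (i <= length(toks)) {
    key <- toks[i]
    if (!key %in% c("chain", "resno", "name", "element")) {
      stop(sprintf("selection syntax error at token %d ('%s')", i, key))
    }
    if (i + 1 > length(toks)) {
      stop(sprintf("selection syntax error: '%s' lacks a value", key))
    }
    val <- strsplit(toks[i + 1], ",")[[1]]
    if (key == "resno") {
      val <- unlist(lapply(val, function(v) {
        if (grepl("-", v)) {
          r <- as.integer(strsplit(v, "-")[[1]])
          seq(r[1], r[2])
        } else as.integer(v)
      }))
    }
    args[[key]] <- val
    i <- i + 2
  }
  do.call(select_atoms, args)
}

#' One-letter amino-acid sequence of a chain
#' @param model structure_model
#' @param chain chain id
#' @return character vector of one-letter codes in residue order
#' @export
chain_sequence <- function(model, chain) {
  a <- model$atoms[model$atoms$chain == chain, ]
  res <- a[!duplicated(a$resno), ]
  aa321(res$resname)
}

aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

aa321 <- function(resname) {
  out <- unname(aa3[toupper(resname)])
  out[is.na(out)] <- "X"
  out
}

aa123 <- function(one) {
  inv <- names(aa3)
  names(inv) <- unname(aa3)
  out <- unname(inv[toupper(one)])
  out[is.na(out)] <- "UNK"
  out
}

#' Merge several models into one
#' @param ... structure_model objects
#' @return combined structure_model (serials renumbered, chains must be unique)
#' @export
merge_models <- function(...) {
  models <- list(...)
  models <- models[vapply(models, n_atoms, 1L) > 0]
  if (length(models) == 1) return(models[[1]])
  chains <- unlist(lapply(models, function(m) unique(m$atoms$chain)))
  if (anyDuplicated(chains)) stop("chain ids collide when merging models")
  atoms <- do.call(rbind, lapply(models, function(m) m$atoms))
  atoms$serial <- seq_len(nrow(atoms))
  truths <- Filter(Negate(is.null), lapply(models, function(m) m$truth))
  truth <- if (length(truths) > 0) do.call(rbind, truths) else NULL
  structure_model(atoms, models[[1]]$metadata, truth)
}
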