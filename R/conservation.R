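#' Read a labelled multiple sequence alignment
#'
#' FASTA or Clustal alignments are accepted. Every sequence must carry a group
#' label ("ciliated" / "non-ciliated" in the standard use, but labels are
#' free-form), and one sequence is designated the reference whose ungapped
#' residue numbering (1-based) anchors all downstream reports.
#'
#' @param path alignment file
#' @param groups a data.frame with columns `id` and `group`, or the path to a
#'   two-column TSV (id TAB group, no header)
#' @param reference id of the reference sequence
#' @param format "auto", "fasta" or "clustal"
#' @return object of class `alignment_set`: list(seqs = named vector of
#'   aligned sequences, groups = named vector, reference, ref_map = per-column
#'   reference residue number (NA at reference gaps), ref_residues)
#' @export
read_alignment <- function(path, groups, reference,
                           format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    head <- readLines(path, n = 1, warn = FALSE)
    format <- if (grepl("^>", head)) "fasta" else "clustal"
  }
  aln <- seqinr::read.alignment(path, format = format, forceToLower = FALSE)
  seqs <- toupper(gsub("\\s", "", unlist(aln$seq)))
  names(seqs) <- aln$nam
  if (length(unique(nchar(seqs))) != 1) {
    stop("alignment parse error: rows have different lengths (",
         paste(unique(nchar(seqs)), collapse = ", "), ")")
  }
  if (is.character(groups) && length(groups) == 1) {
    groups <- utils::read.table(groups, sep = "\t", header = FALSE,
                                col.names = c("id", "group"),
                                stringsAsFactors = FALSE)
  }
  alignment_set(seqs, stats::setNames(groups$group, groups$id), reference)
}

#' Construct an alignment set from in-memory sequences
#' @param seqs named character vector of equal-length aligned sequences
#' @param groups named character vector id -> group covering all sequences
#' @param reference reference sequence id
#' @return alignment_set
#' @export
alignment_set <- function(seqs, groups, reference) {
  if (length(unique(nchar(seqs))) != 1) stop("aligned lengths differ")
  unlab <- setdiff(names(seqs), names(groups))
  if (length(unlab) > 0) {
    stop("unlabelled sequence(s): ", paste(unlab, collapse = ", "))
  }
  if (!reference %in% names(seqs)) stop("reference sequence absent: ", reference)
  ref <- strsplit(seqs[[reference]], "")[[1]]
  notgap <- !(ref %in% c("-", "."))
  ref_map <- rep(NA_integer_, length(ref))
  ref_map[notgap] <- seq_len(sum(notgap))
  structure(list(seqs = seqs, groups = groups[names(seqs)],
                 reference = reference, ref_map = ref_map,
                 ref_residues = ref[notgap]),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("alignment_set: %d sequences x %d columns; reference %s (%d residues)\n",
              length(x$seqs), nchar(x$seqs[[1]]), x$reference,
              length(x$ref_residues)))
  print(table(x$groups))
  invisible(x)
}

#' Per-residue conservation profile by group
#'
#' For every alignment column mapped to a reference residue and every group,
#' the conservation score is the normalised Shannon-entropy complement
#' `1 - H / log(20)` of the within-group residue frequencies (gaps excluded):
#' 1 for an identical column, 0 for 20 equifrequent residues. Columns that are
#' all-gap within a group score NA; columns with > 50% gaps in a group are
#' flagged. A fraction-identity-to-consensus alternative is available for
#' sensitivity checks.
#'
#' @param a alignment_set with >= 2 sequences per group
#' @param metric "entropy" (default) or "identity"
#' @return object of class `conservation_profile`: data.frame with resno,
#'   column, residue, then per group: score_<group>, gapfrac_<group>,
#'   flagged_<group>
#' @export
conservation_profile <- function(a, metric = c("entropy", "identity")) {
  metric <- match.arg(metric)
  gtab <- table(a$groups)
  if (any(gtab < 2)) {
    stop("group(s) with fewer than 2 sequences: ",
         paste(names(gtab)[gtab < 2], collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(unname(a$seqs), ""))
  rownames(mat) <- names(a$seqs)
  cols <- which(!is.na(a$ref_map))
  out <- data.frame(resno = a$ref_map[cols], column = cols,
                    residue = a$ref_residues)
  for (g in sort(unique(a$groups))) {
    sub <- mat[a$groups == g, cols, drop = FALSE]
    score <- numeric(length(cols))
    gapf <- numeric(length(cols))
    for (k in seq_along(cols)) {
      col <- sub[, k]
      isgap <- col %in% c("-", ".", "X")
      gapf[k] <- mean(isgap)
      res <- col[!isgap]
      if (length(res) == 0) {
        score[k] <- NA_real_
      } else if (metric == "entropy") {
        p <- table(res) / length(res)
        H <- -sum(p * log(p))
        score[k] <- 1 - H / log(20)
      } else {
        cons <- names(sort(table(res), decreasing = TRUE))[1]
        score[k] <- mean(res == cons)
      }
    }
    out[[paste0("score_", g)]] <- score
    out[[paste0("gapfrac_", g)]] <- gapf
    out[[paste0("flagged_", g)]] <- gapf > 0.5
  }
  attr(out, "reference") <- a$reference
  attr(out, "ref_residues") <- a$ref_residues
  attr(out, "metric") <- metric
  class(out) <- c("conservation_profile", class(out))
  out
}

#' Tubulin regions contacting filamentous MIPs
#'
#' The bundled default region set: four alpha-tubulin and four beta-tubulin
#' stretches lining the inter-PF furrows, with their expected reference
#' subsequences (Tetrahymena numbering) used to guard against numbering drift.
#'
#' @param subunit "alpha" or "beta"
#' @return data.frame(name, start, end, expected)
#' @export
tubulin_regions <- function(subunit = c("alpha", "beta")) {
  subunit <- match.arg(subunit)
  if (subunit == "alpha") {
    # the fourth region is published as V362-V372 but its 10-residue
    # subsequence spans 362-371; the subsequence is authoritative here
    data.frame(name = c("T56-K60", "S277-Q285", "P32-T41", "V362-V372"),
               start = c(56, 277, 32, 362), end = c(60, 285, 41, 371),
               expected = c("TGAGK", "SAEKAYHEQ", "PDGQMPSDKT", "VVPGGDLAKV"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(name = c("A54-R58", "R276-A283", "D31-G38", "P358-K362"),
               start = c(54, 276, 31, 358), end = c(58, 283, 38, 362),
               expected = c("ATGGR", "RGSQQYRA", "DPTGTYHG", "PKGLK"),
               stringsAsFactors = FALSE)
  }
}

#' Mean conservation per region and group
#'
#' Region ranges are mapped onto alignment columns through the reference; each
#' region's expected reference subsequence is verified and a mismatch is a
#' hard error (guards against numbering drift). Mean scores are over defined
#' (non-all-gap) columns only.
#'
#' @param profile conservation_profile
#' @param regions data.frame(name, start, end, expected); defaults to the
#'   bundled alpha-tubulin set, see [tubulin_regions()]
#' @return data.frame: region, start, end, expected, then mean_<group> per
#'   group and `difference` (first group minus second) when exactly two groups
#' @export
region_report <- function(profile, regions = tubulin_regions("alpha")) {
  refres <- attr(profile, "ref_residues")
  score_cols <- grep("^score_", names(profile), value = TRUE)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    if (r$end > length(refres) || r$start < 1) {
      stop("region ", r$name, " is outside the reference (length ",
           length(refres), ")")
    }
    got <- paste(refres[r$start:r$end], collapse = "")
    if (!identical(got, r$expected)) {
      stop(sprintf("region %s: reference has '%s' at %d-%d, expected '%s' (numbering drift?)",
                   r$name, got, r$start, r$end, r$expected))
    }
    sel <- profile$resno >= r$start & profile$resno <= r$end
    out <- data.frame(region = r$name, start = r$start, end = r$end,
                      expected = r$expected, stringsAsFactors = FALSE)
    for (sc in score_cols) {
      out[[sub("^score_", "mean_", sc)]] <- mean(profile[[sc]][sel], na.rm = TRUE)
    }
    out
  })
  out <- do.call(rbind, rows)
  means <- grep("^mean_", names(out), value = TRUE)
  if (length(means) == 2) out$difference <- out[[means[1]]] - out[[means[2]]]
  out
}

#' Write conservation scores into a structure's B-factor column
#'
#' Per-residue scores (one group's profile, or the between-group difference)
#' are scaled to [0, 100] and written to the b-factor of every atom of the
#' matching residue of one chain, enabling surface colouring in any molecular
#' viewer. Residues without a defined score get 0 and are counted in a
#' warning.
#'
#' @param profile conservation_profile
#' @param model structure_model
#' @param chain chain id whose residue numbering matches the reference
#' @param which score column: a group name, or "difference" for the
#'   first-minus-second group contrast
#' @return structure_model with updated b-factors
#' @export
export_scores_to_structure <- function(profile, model, chain, which) {
  score_cols <- grep("^score_", names(profile), value = TRUE)
  sc <- if (which == "difference") {
    if (length(score_cols) != 2) stop("difference needs exactly two groups")
    profile[[score_cols[1]]] - profile[[score_cols[2]]]
  } else {
    col <- paste0("score_", which)
    if (!col %in% names(profile)) stop("no group named ", which)
    profile[[col]]
  }
  lut <- stats::setNames(sc, profile$resno)
  idx <- which(model$atoms$chain == chain)
  if (length(idx) == 0) stop("no chain ", chain, " in the model")
  v <- lut[as.character(model$atoms$resno[idx])]
  n_unmapped <- sum(is.na(v))
  if (n_unmapped > 0) {
    warning(n_unmapped, " atom(s) in residues without a defined score; b-factor 0")
    v[is.na(v)] <- 0
  }
  model$atoms$b[idx] <- pmin(pmax(v, 0), 1) * 100
  model
}
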