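#' Extract outer-junction templates from a doublet
#'
#' Returns the A10 dimer as one template and the A11 dimer together with the
#' B1 dimer as a single rigid complex, each as a structure_model. These are
#' the two units grafted onto other A-tubule PF pairs to build hypothetical
#' outer junctions.
#'
#' @param doublet structure_model
#' @param assignment pf_assignment labelling A10, A11 and B1
#' @return list(A10_template, A11B1_complex, a11_chains = chains of the A11
#'   region used for fitting)
#' @export
extract_junction_templates <- function(doublet, assignment) {
  for (pf in c("A10", "A11", "B1")) {
    if (!pf %in% assignment$chains$pf) stop("assignment lacks PF ", pf)
  }
  ch10 <- rep_dimer_chains(assignment, "A10")
  z10 <- mean(assignment$chains$z[match(ch10, assignment$chains$chain)])
  ch11 <- rep_dimer_chains(assignment, "A11", near_z = z10)
  chB1 <- rep_dimer_chains(assignment, "B1", near_z = z10)
  list(A10_template = select_atoms(doublet, chain = ch10),
       A11B1_complex = select_atoms(doublet, chain = c(ch11, chB1)),
       a11_chains = ch11, b1_chains = chB1)
}

#' Build a hypothetical outer junction on an A-tubule PF pair
#'
#' The A10 template is superposed onto the host `pf_i` dimer and the rigid
#' A11/B1 complex onto the host `pf_j` dimer using only its A11-region CA-level
#' atoms, carrying B1 along rigidly. Fit RMSDs are recorded.
#'
#' @param doublet structure_model
#' @param assignment pf_assignment
#' @param host_pair character(2), adjacent A-tubule PF labels, e.g.
#'   c("A12", "A13")
#' @param templates from [extract_junction_templates()] (computed when NULL)
#' @return object of class `junction_model`: list(host_pair, model = grafted
#'   structure_model with chains renamed g10*/g11*/gB1*, graft_labels,
#'   rmsd_A10, rmsd_A11)
#' @export
build_hypothetical_junction <- function(doublet, assignment, host_pair,
                                        templates = NULL) {
  ap <- adjacent_pairs(assignment, "A")
  ok <- any((ap[, 1] == host_pair[1] & ap[, 2] == host_pair[2]) |
            (ap[, 1] == host_pair[2] & ap[, 2] == host_pair[1]))
  if (!ok) stop("host pair ", host_pair[1], "/", host_pair[2],
                " is not adjacent in the A-tubule")
  if (is.null(templates)) {
    templates <- extract_junction_templates(doublet, assignment)
  }
  ch_i <- rep_dimer_chains(assignment, host_pair[1])
  zi <- mean(assignment$chains$z[match(ch_i, assignment$chains$chain)])
  ch_j <- rep_dimer_chains(assignment, host_pair[2], near_z = zi)
  host_i <- select_atoms(doublet, chain = ch_i)
  host_j <- select_atoms(doublet, chain = ch_j)

  t10 <- templates$A10_template
  fit10 <- superpose(t10, host_i,
                     pairing = dimer_pairing(t10, host_i,
                                             unique(t10$atoms$chain), ch_i))
  g10 <- apply_transform(fit10$transform, t10)

  cplx <- templates$A11B1_complex
  a11 <- select_atoms(cplx, chain = templates$a11_chains)
  # CA-level atoms of the A11 region only
  a11_ca <- select_atoms(a11, name = "CA")
  host_j_ca <- select_atoms(host_j, name = "CA")
  if (n_atoms(a11_ca) < 3 || n_atoms(host_j_ca) < 3) {
    a11_ca <- a11; host_j_ca <- host_j
  }
  fit11 <- superpose(a11_ca, host_j_ca,
                     pairing = dimer_pairing(a11_ca, host_j_ca,
                                             unique(a11_ca$atoms$chain),
                                             unique(host_j_ca$atoms$chain)))
  gcplx <- apply_transform(fit11$transform, cplx)

  rename <- function(m, prefix) {
    map <- stats::setNames(paste0(prefix, seq_along(unique(m$atoms$chain))),
                           unique(m$atoms$chain))
    m$atoms$chain <- unname(map[m$atoms$chain])
    m$truth <- NULL
    m
  }
  g10r <- rename(g10, "g10_")
  gB1 <- rename(select_atoms(gcplx, chain = templates$b1_chains), "gB1_")
  gA11 <- rename(select_atoms(gcplx, chain = templates$a11_chains), "g11_")
  model <- merge_models(g10r, gA11, gB1)
  structure(list(host_pair = host_pair, model = model,
                 graft_labels = list(A10 = unique(g10r$atoms$chain),
                                     A11 = unique(gA11$atoms$chain),
                                     B1 = unique(gB1$atoms$chain)),
                 rmsd_A10 = fit10$rmsd, rmsd_A11 = fit11$rmsd),
            class = "junction_model")
}

#' Score a hypothetical outer junction
#'
#' Salt bridges and clashes are evaluated between the grafted A10-template
#' chains and the carried-along B1 chains. Verdict: "clash" if any steric
#' clash; otherwise "no-bridge-gap" if no salt bridge forms; otherwise
#' "compatible".
#'
#' @param jm junction_model
#' @param salt_bridge_cutoff A (default 4.0)
#' @param clash_overlap A (default 0.4)
#' @return one-row data.frame: pf_i, pf_j, n_salt_bridges, n_clashes, min_gap,
#'   verdict
#' @export
score_junction <- function(jm, salt_bridge_cutoff = 4.0, clash_overlap = 0.4) {
  chA <- jm$graft_labels$A10
  chB <- jm$graft_labels$B1
  sb <- detect_salt_bridges(jm$model, chA, chB, salt_bridge_cutoff)
  cl <- count_clashes(jm$model, chA, chB, clash_overlap)
  a <- jm$model$atoms
  gap <- min_cross_distance(
    as.matrix(a[a$chain %in% chA & a$element != "H", c("x", "y", "z")]),
    as.matrix(a[a$chain %in% chB & a$element != "H", c("x", "y", "z")]))
  verdict <- if (cl$n > 0) "clash" else if (nrow(sb) == 0) "no-bridge-gap" else "compatible"
  data.frame(pf_i = jm$host_pair[1], pf_j = jm$host_pair[2],
             n_salt_bridges = nrow(sb), n_clashes = cl$n, min_gap = gap,
             verdict = verdict, stringsAsFactors = FALSE)
}

#' Scan all A-tubule PF pairs as hypothetical outer-junction hosts
#'
#' Grafts the native A10 template and rigid A11/B1 complex onto every adjacent
#' A-tubule PF pair and scores each graft. The native pair is flagged.
#'
#' @param doublet structure_model
#' @param assignment pf_assignment (computed when NULL)
#' @param salt_bridge_cutoff,clash_overlap thresholds shared with
#'   [score_junction()]
#' @return data.frame, one row per adjacent pair, deterministic order;
#'   column `native` marks the deposited A10/A11 host
#' @export
junction_scan <- function(doublet, assignment = NULL, salt_bridge_cutoff = 4.0,
                          clash_overlap = 0.4) {
  if (is.null(assignment)) assignment <- assign_pfs(doublet)
  templates <- extract_junction_templates(doublet, assignment)
  ap <- adjacent_pairs(assignment, "A")
  rows <- lapply(seq_len(nrow(ap)), function(r) {
    jm <- build_hypothetical_junction(doublet, assignment, ap[r, ], templates)
    s <- score_junction(jm, salt_bridge_cutoff, clash_overlap)
    s$rmsd_A10 <- jm$rmsd_A10
    s$rmsd_A11 <- jm$rmsd_A11
    s
  })
  out <- do.call(rbind, rows)
  out$native <- (out$pf_i == "A10" & out$pf_j == "A11") |
    (out$pf_i == "A11" & out$pf_j == "A10")
  rownames(out) <- NULL
  out
}
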