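#' Group tubulin chains into protofilaments and tubules
#'
#' Chains are clustered into protofilaments (PFs) by angular position about
#' the estimated longitudinal axis. For a doublet, chains are first split into
#' the complete A-tubule and the open B-arc by iterative circle fitting in the
#' plane perpendicular to the axis. PF labels follow the standard doublet
#' numbering anchored at the outer junction: the B PF in lateral contact with
#' the A-tubule exterior is B1, its two A-tubule partners are A10 and A11, and
#' the A1/B10 pair meets at the inner junction.
#'
#' @param model structure_model containing at least 2 tubulin dimers; each
#'   chain is one tubulin monomer
#' @param max_tubules 2 to allow doublet detection (default), 1 to force a
#'   single tubule
#' @return object of class `pf_assignment`: list with `chains` (data.frame of
#'   chain, tubule, pf, pf_index, dimer, angle_deg, radius, z), `pf_order`
#'   (list per tubule of PF labels in circular order), `closed` (named logical
#'   per tubule), `axis` (lattice_axis) and `centers` (per-tubule in-plane
#'   circle centres)
#' @export
assign_pfs <- function(model, max_tubules = 2) {
  chains <- unique(model$atoms$chain)
  if (length(chains) < 4) stop("need at least 2 tubulin dimers (4 chains)")
  axis <- estimate_axis(model)
  cc <- chain_centroids(model)
  n <- axis$direction
  basis <- plane_basis(n)
  rel <- sweep(cc, 2, axis$point)
  p2d <- cbind(rel %*% basis$u, rel %*% basis$v)
  zax <- as.numeric(rel %*% n)
  rownames(p2d) <- rownames(cc)

  memb <- split_tubules(p2d, max_tubules)
  tubule_of <- memb$membership          # integer 1 (A candidate) / 2
  out_rows <- list()
  pf_order <- list()
  closed <- logical(0)
  centers <- list()
  tub_ids <- sort(unique(tubule_of))
  tub_names <- if (length(tub_ids) == 1) "A" else c("A", "B")
  pf_index_of <- integer(length(chains))
  names(pf_index_of) <- rownames(p2d)

  for (ti in seq_along(tub_ids)) {
    sel <- which(tubule_of == tub_ids[ti])
    ctr <- fit_circle(p2d[sel, , drop = FALSE])$center
    ang <- atan2(p2d[sel, 2] - ctr[2], p2d[sel, 1] - ctr[1])
    rad <- sqrt((p2d[sel, 1] - ctr[1])^2 + (p2d[sel, 2] - ctr[2])^2)
    cl <- cluster_angles(ang)
    k <- cl$k
    # circular order of PF clusters by mean angle
    pf_mean <- vapply(seq_len(k), function(i) {
      circ_mean(ang[cl$cluster == i])
    }, numeric(1))
    ord <- order(pf_mean)
    rank_of <- match(seq_len(k), ord)   # cluster id -> circular rank
    gaps <- diff(c(sort(pf_mean), sort(pf_mean)[1] + 2 * pi))
    is_closed <- max(gaps) <= 1.7 * stats::median(gaps)
    tub <- tub_names[ti]
    closed[tub] <- is_closed
    centers[[tub]] <- ctr
    start <- if (is_closed) 1 else which.max(gaps) %% k + 1
    circ_rank <- ((rank_of - start) %% k) + 1   # 1..k along the arc
    out_rows[[tub]] <- data.frame(
      chain = rownames(p2d)[sel], tubule = tub,
      pf_index = circ_rank[cl$cluster],
      angle_deg = ang * 180 / pi, radius = rad, z = zax[sel],
      stringsAsFactors = FALSE)
    pf_order[[tub]] <- seq_len(k)
  }

  df <- do.call(rbind, out_rows)
  rownames(df) <- NULL
  # dimers: within each PF, chains sorted axially, paired consecutively;
  # generator ground truth overrides when present
  df$dimer <- NA_integer_
  for (key in unique(paste(df$tubule, df$pf_index))) {
    i <- which(paste(df$tubule, df$pf_index) == key)
    io <- i[order(df$z[i])]
    df$dimer[io] <- (seq_along(io) + 1) %/% 2
  }
  tr <- model$truth
  if (!is.null(tr) && "dimer" %in% names(tr)) {
    df$dimer <- tr$dimer[match(df$chain, tr$chain)]
  }

  asg <- structure(list(chains = df, pf_order = pf_order, closed = closed,
                        axis = axis, centers = centers, basis = basis),
                   class = "pf_assignment")
  label_pfs(asg)
}

#' @export
print.pf_assignment <- function(x, ...) {
  for (tub in names(x$pf_order)) {
    cat(sprintf("tubule %s: %d PFs (%s), %d chains\n", tub,
                length(x$pf_order[[tub]]),
                if (x$closed[tub]) "closed" else "open",
                sum(x$chains$tubule == tub)))
  }
  invisible(x)
}

# Orthonormal in-plane basis perpendicular to n.
plane_basis <- function(n) {
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(u = u, v = v)
}

# Algebraic (Kasa) circle fit; returns center and radius.
fit_circle <- function(p, w = NULL) {
  if (nrow(p) < 3) return(list(center = colMeans(p), radius = 0))
  if (is.null(w)) w <- rep(1, nrow(p))
  A <- cbind(2 * p[, 1], 2 * p[, 2], 1) * sqrt(w)
  b <- (p[, 1]^2 + p[, 2]^2) * sqrt(w)
  sol <- tryCatch(qr.solve(A, b), error = function(e) c(colMeans(p), 0))
  ctr <- sol[1:2]
  list(center = ctr, radius = sqrt(max(sol[3] + sum(ctr^2), 0)))
}

# Dominant circle in a contaminated 2D cloud: deterministic RANSAC (fixed
# internal seed) followed by inlier-only refits. Returns fit plus inlier mask.
dominant_circle <- function(p, n_trials = 300, tol_rel = 0.1, tol_abs = 12) {
  n <- nrow(p)
  trips <- with_seed(202406L, {
    matrix(sample.int(n, 3 * n_trials, replace = TRUE), ncol = 3)
  })
  trips <- trips[apply(trips, 1, function(t) length(unique(t)) == 3), ,
                 drop = FALSE]
  best <- NULL
  for (r in seq_len(nrow(trips))) {
    f <- fit_circle(p[trips[r, ], , drop = FALSE])
    if (f$radius <= 0) next
    res <- abs(sqrt(rowSums(sweep(p, 2, f$center)^2)) - f$radius)
    inl <- res < min(tol_rel * f$radius, tol_abs)
    if (is.null(best) || sum(inl) > sum(best$inliers)) {
      best <- list(fit = f, inliers = inl)
    }
  }
  if (is.null(best)) return(list(fit = fit_circle(p), inliers = rep(TRUE, n)))
  for (i in 1:3) {
    f <- fit_circle(p[best$inliers, , drop = FALSE])
    res <- abs(sqrt(rowSums(sweep(p, 2, f$center)^2)) - f$radius)
    best <- list(fit = f, inliers = res < min(tol_rel * f$radius, tol_abs))
  }
  best
}

# Split chains into 1 or 2 tubules by iterative circle fitting in-plane:
# a robust fit locks onto the dominant (complete) ring, the rest seeds the
# second tubule, then membership is relaxed by nearest-circle reassignment.
split_tubules <- function(p2d, max_tubules) {
  nchain <- nrow(p2d)
  one <- fit_circle(p2d)
  res1 <- abs(sqrt(rowSums(sweep(p2d, 2, one$center)^2)) - one$radius)
  if (max_tubules == 1 || max(res1) < 0.15 * one$radius) {
    return(list(membership = rep(1L, nchain)))
  }
  dom <- dominant_circle(p2d)
  memb <- ifelse(dom$inliers, 1L, 2L)
  if (min(table(factor(memb, levels = 1:2))) < 3) {
    return(list(membership = rep(1L, nchain)))
  }
  for (iter in 1:6) {
    fits <- lapply(1:2, function(g) fit_circle(p2d[memb == g, , drop = FALSE]))
    d <- vapply(1:2, function(g) {
      abs(sqrt(rowSums(sweep(p2d, 2, fits[[g]]$center)^2)) - fits[[g]]$radius)
    }, numeric(nchain))
    new <- max.col(-d)
    if (all(new == memb)) break
    memb <- new
  }
  if (min(table(memb)) < 2) return(list(membership = rep(1L, nchain)))
  # A = complete tubule: the cluster whose points span the full circle
  span <- vapply(1:2, function(g) {
    ctr <- fit_circle(p2d[memb == g, , drop = FALSE])$center
    a <- sort(atan2(p2d[memb == g, 2] - ctr[2], p2d[memb == g, 1] - ctr[1]))
    2 * pi - max(diff(c(a, a[1] + 2 * pi)))
  }, numeric(1))
  if (span[2] > span[1]) memb <- 3L - memb
  list(membership = memb)
}

# Cluster angles (radians) into PFs by the largest drop in sorted circular
# gap sizes. Errors when the clustering is ambiguous.
cluster_angles <- function(ang) {
  m <- length(ang)
  o <- order(ang)
  sa <- ang[o]
  gaps <- diff(c(sa, sa[1] + 2 * pi))     # gap after each sorted point
  gs <- sort(gaps, decreasing = TRUE)
  # the boundary/within-cluster divide is the largest ratio between
  # consecutive sorted gaps (robust to one huge gap at an open-arc mouth)
  eps <- 1e-8
  ratios <- (gs + eps) / (c(gs[-1], 0) + eps)
  k <- which.max(ratios)
  if (k < 2) stop("angular clustering found a single protofilament")
  thr <- (gs[k] + if (k < m) gs[k + 1] else 0) / 2
  if (gs[k] < 2 * pi / 180) {
    e <- simpleError("ambiguous protofilament clustering (no clear angular gaps)")
    attr(e, "angles_deg") <- ang * 180 / pi
    stop(e)
  }
  cluster <- integer(m)
  cl <- 1L
  for (i in seq_len(m)) {
    cluster[o[i]] <- cl
    if (gaps[i] > thr && i < m) cl <- cl + 1L
  }
  # points before the first boundary belong with the trailing cluster (wrap)
  if (gaps[m] <= thr && cl > 1) cluster[cluster == cl] <- 1L
  ids <- unique(cluster)
  cluster <- match(cluster, ids)
  list(cluster = cluster, k = length(ids))
}

circ_mean <- function(a) atan2(mean(sin(a)), mean(cos(a)))

# Apply doublet PF labelling anchored at the outer junction, or plain
# A1..An labels for a singlet.
label_pfs <- function(asg) {
  df <- asg$chains
  tubs <- names(asg$pf_order)
  nA <- max(df$pf_index[df$tubule == "A"])
  if (!"B" %in% tubs) {
    df$pf <- paste0("A", df$pf_index)
    asg$chains <- df
    asg$pf_order$A <- paste0("A", seq_len(nA))
    return(asg)
  }
  nB <- max(df$pf_index[df$tubule == "B"])
  # in-plane PF positions reconstructed from angle/radius about tubule centre
  xy_of <- function(tub, idx) {
    ctr <- asg$centers[[tub]]
    i <- df$tubule == tub & df$pf_index == idx
    th <- mean(df$angle_deg[i]) * pi / 180
    r <- mean(df$radius[i])
    ctr + r * c(cos(th), sin(th))
  }
  Axy <- t(vapply(seq_len(nA), function(i) xy_of("A", i), numeric(2)))
  Bxy <- t(vapply(seq_len(nB), function(i) xy_of("B", i), numeric(2)))
  # B1 = arc end closer to the A tubule
  d_ends <- c(min(sqrt(rowSums(sweep(Axy, 2, Bxy[1, ])^2))),
              min(sqrt(rowSums(sweep(Axy, 2, Bxy[nB, ])^2))))
  b_rev <- d_ends[2] < d_ends[1]
  b_seq <- if (b_rev) rev(seq_len(nB)) else seq_len(nB)   # pf_index in B1..BnB order
  B1xy <- Bxy[b_seq[1], ]
  B10xy <- Bxy[b_seq[length(b_seq)], ]
  # two A partners of B1
  dA <- sqrt(rowSums(sweep(Axy, 2, B1xy)^2))
  cand <- order(dA)[1:2]
  # candidate labelling: direction +1 (increasing pf_index) or -1, anchor = A10
  best <- NULL
  for (anchor in cand) for (dir in c(1L, -1L)) {
    other <- ((anchor - 1 + dir) %% nA) + 1
    if (!other %in% cand) next
    # A1 sits 4 steps from the anchor (A10) in direction dir
    a1 <- ((anchor - 1 + 4 * dir) %% nA) + 1
    score <- sqrt(sum((Axy[a1, ] - B10xy)^2))
    if (is.null(best) || score < best$score) {
      best <- list(anchor = anchor, dir = dir, score = score)
    }
  }
  if (is.null(best)) stop("could not anchor outer-junction labels: ",
                          "the two A partners of B1 are not adjacent")
  lab_num <- (( (seq_len(nA) - best$anchor) * best$dir + 10 - 1) %% nA) + 1
  a_label <- paste0("A", lab_num)
  b_label <- character(nB)
  b_label[b_seq] <- paste0("B", seq_len(nB))
  df$pf <- ifelse(df$tubule == "A", a_label[df$pf_index], b_label[df$pf_index])
  asg$chains <- df
  asg$pf_order$A <- a_label           # circular order preserved
  asg$pf_order$B <- b_label[b_seq]
  asg
}

#' Chains belonging to one PF
#' @param assignment pf_assignment
#' @param pf PF label such as "A10"
#' @return character vector of chain ids (axial order)
#' @export
pf_chains <- function(assignment, pf) {
  df <- assignment$chains
  i <- which(df$pf == pf)
  if (length(i) == 0) stop("no PF labelled ", pf)
  df$chain[i[order(df$z[i])]]
}

# Adjacent PF pairs of one tubule, in circular order (wrapping when closed).
adjacent_pairs <- function(assignment, tubule) {
  ord <- assignment$pf_order[[tubule]]
  k <- length(ord)
  idx <- if (assignment$closed[tubule]) {
    cbind(seq_len(k), c(seq_len(k)[-1], 1))
  } else {
    cbind(seq_len(k - 1), seq_len(k)[-1])
  }
  cbind(ord[idx[, 1]], ord[idx[, 2]])
}

# Representative dimer of a PF: chains of the axially lowest complete dimer.
rep_dimer_chains <- function(assignment, pf, near_z = NULL) {
  df <- assignment$chains
  i <- which(df$pf == pf)
  dz <- tapply(df$z[i], df$dimer[i], mean)
  counts <- table(df$dimer[i])
  full <- names(counts)[counts == 2]
  if (length(full) == 0) stop("PF ", pf, " has no complete dimer")
  dz <- dz[full]
  pick <- if (is.null(near_z)) names(dz)[which.min(dz)] else
    names(dz)[which.min(abs(dz - near_z))]
  ch <- df$chain[i][df$dimer[i] == as.integer(pick)]
  ch[order(df$z[i][df$dimer[i] == as.integer(pick)])]
}

#' Rotation angle and axial shift between two adjacent protofilaments
#'
#' One dimer of `pf_i` is superposed (Kabsch, equivalent atoms paired within
#' matched subunits) onto the axially nearest dimer of `pf_j`; the resulting
#' transform is decomposed into twist about the lattice axis, axial shift and
#' axis deviation. The theoretical PF number of an ideal microtubule with this
#' local curvature is 360 / |angle|.
#'
#' @param model structure_model
#' @param assignment pf_assignment from [assign_pfs()]
#' @param pf_i,pf_j adjacent PF labels (e.g. "A10", "A11")
#' @param axis lattice_axis; defaults to the assignment's axis
#' @return one-row data.frame (class `pf_pair_geometry`): pf_i, pf_j,
#'   angle_deg, z_shift, axis_deviation_deg, theoretical_pf_number, pf_class,
#'   rmsd, reliable
#' @export
pf_pair_geometry <- function(model, assignment, pf_i, pf_j, axis = NULL) {
  if (is.null(axis)) axis <- assignment$axis
  pairs <- rbind(adjacent_pairs(assignment, "A"),
                 if ("B" %in% names(assignment$pf_order))
                   adjacent_pairs(assignment, "B"))
  ok <- any((pairs[, 1] == pf_i & pairs[, 2] == pf_j) |
            (pairs[, 1] == pf_j & pairs[, 2] == pf_i))
  if (!ok) stop(pf_i, " and ", pf_j, " are not adjacent protofilaments")
  ch_i <- rep_dimer_chains(assignment, pf_i)
  zi <- mean(assignment$chains$z[match(ch_i, assignment$chains$chain)])
  ch_j <- rep_dimer_chains(assignment, pf_j, near_z = zi)
  mi <- select_atoms(model, chain = ch_i)
  mj <- select_atoms(model, chain = ch_j)
  pairing <- dimer_pairing(mi, mj, ch_i, ch_j)
  fit <- superpose(mi, mj, pairing = pairing)
  tw <- twist_about_axis(fit$transform, axis)
  angle <- tw$twist_deg
  theo <- if (abs(angle) < 1e-9) Inf else 360 / abs(angle)
  out <- data.frame(pf_i = pf_i, pf_j = pf_j, angle_deg = angle,
                    z_shift = tw$z_shift,
                    axis_deviation_deg = tw$axis_deviation_deg,
                    theoretical_pf_number = theo,
                    pf_class = round_half_away(theo),
                    rmsd = fit$rmsd,
                    reliable = tw$axis_deviation_deg <= 20,
                    stringsAsFactors = FALSE)
  class(out) <- c("pf_pair_geometry", class(out))
  out
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Pair atoms of two dimers: subunits matched by axial rank, atoms by name.
dimer_pairing <- function(mi, mj, ch_i, ch_j) {
  rows <- lapply(seq_along(ch_i), function(k) {
    ai <- which(mi$atoms$chain == ch_i[k])
    aj <- which(mj$atoms$chain == ch_j[k])
    key_i <- paste(mi$atoms$resno[ai], mi$atoms$name[ai])
    key_j <- paste(mj$atoms$resno[aj], mj$atoms$name[aj])
    common <- intersect(key_i, key_j)
    cbind(ai[match(common, key_i)], aj[match(common, key_j)])
  })
  do.call(rbind, rows)
}

#' Classify lateral lattice contacts (B-lattice vs seam)
#'
#' For each adjacent PF pair, the lateral neighbour of every alpha subunit of
#' `pf_i` is the chain of `pf_j` with minimal centroid distance; the pair is a
#' seam when those neighbours are beta subunits (majority vote), otherwise
#' B-lattice. The alpha-alpha axial offset is also reported.
#'
#' Only alpha subunits with a clear lateral partner (axial offset at most
#' `max_offset`) vote, which keeps subunits at the cut ends of a finite
#' lattice segment from corrupting the register call.
#'
#' @param model structure_model
#' @param assignment pf_assignment
#' @param subunits optional named chain -> "alpha"/"beta" vector (generator
#'   ground truth is used when present)
#' @param max_offset largest axial offset (A) counted as a lateral contact
#'   (default 10, a quarter of the 40 A monomer rise)
#' @return data.frame with pf_i, pf_j, tubule, register, alpha_alpha_offset
#' @export
classify_lattice_contacts <- function(model, assignment, subunits = NULL,
                                      max_offset = 10) {
  sub <- subunit_labels(model, subunits, required = TRUE)
  cc <- chain_centroids(model)
  df <- assignment$chains
  n <- assignment$axis$direction
  zax <- as.numeric(sweep(cc, 2, assignment$axis$point) %*% n)
  names(zax) <- rownames(cc)
  rows <- list()
  for (tub in names(assignment$pf_order)) {
    for (r in seq_len(nrow(adjacent_pairs(assignment, tub)))) {
      pr <- adjacent_pairs(assignment, tub)[r, ]
      ch_i <- df$chain[df$pf == pr[1]]
      ch_j <- df$chain[df$pf == pr[2]]
      al_i <- ch_i[sub[ch_i] == "alpha"]
      votes <- character(0)
      offs <- numeric(0)
      for (a in al_i) {
        dz_all <- zax[ch_j] - zax[a]
        nearest <- which.min(abs(dz_all))
        if (abs(dz_all[nearest]) > max_offset) next   # cut-end subunit
        votes <- c(votes, sub[ch_j[nearest]])
        al_j <- ch_j[sub[ch_j] == "alpha"]
        dz <- zax[al_j] - zax[a]
        offs <- c(offs, dz[which.min(abs(dz))])
      }
      if (length(votes) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        pf_i = pr[1], pf_j = pr[2], tubule = tub,
        register = if (mean(votes == "beta") > 0.5) "seam" else "B-lattice",
        alpha_alpha_offset = mean(offs), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Full lattice geometry report
#'
#' One row per adjacent PF pair in both tubules: rotation angle, axial shift,
#' axis deviation, theoretical PF number and class, plus lateral register when
#' subunit identities are known. A per-tubule summary (min/max/median
#' pf_class) is attached as attribute `"summary"`.
#'
#' @param model structure_model
#' @param assignment optional pf_assignment (computed when NULL)
#' @param subunits optional chain -> "alpha"/"beta" labels for register
#' @return data.frame of per-pair geometry, deterministic ordering
#' @export
lattice_report <- function(model, assignment = NULL, subunits = NULL) {
  if (is.null(assignment)) assignment <- assign_pfs(model)
  rows <- list()
  for (tub in names(assignment$pf_order)) {
    ap <- adjacent_pairs(assignment, tub)
    for (r in seq_len(nrow(ap))) {
      g <- pf_pair_geometry(model, assignment, ap[r, 1], ap[r, 2])
      g$tubule <- tub
      rows[[length(rows) + 1]] <- g
    }
  }
  out <- do.call(rbind, rows)
  reg <- tryCatch(classify_lattice_contacts(model, assignment, subunits),
                  error = function(e) NULL)
  out$register <- if (!is.null(reg)) {
    reg$register[match(paste(out$pf_i, out$pf_j), paste(reg$pf_i, reg$pf_j))]
  } else NA_character_
  summ <- do.call(rbind, lapply(split(out, out$tubule), function(d) {
    data.frame(tubule = d$tubule[1], min_class = min(d$pf_class),
               max_class = max(d$pf_class),
               median_class = stats::median(d$pf_class))
  }))
  rownames(out) <- NULL
  attr(out, "summary") <- summ
  out
}
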