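test_that("a lone carbon atom has the analytic probe-expanded sphere area", {
  s <- compute_sasa(single_atom("C"))
  expect_equal(s$total, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.005)
  expect_error(compute_sasa(single_atom(), n_sphere_points = 10), ">= 24")
})

test_that("well-separated atoms have additive SASA", {
  r_exp <- 2 * (1.70 + 1.4)
  m <- two_chain_atoms(sep = r_exp * 2 + 1)
  s <- compute_sasa(m)
  expect_equal(s$total, 2 * compute_sasa(single_atom())$total, tolerance = 1e-9)
})

test_that("SASA matches a Monte-Carlo oracle within 2% on random clusters", {
  set.seed(11)
  for (case in 1:5) {
    n <- sample(5:12, 1)
    m <- toy_model(rep("CA", n), sample(c("C", "N", "O", "S"), n, TRUE),
                   "GLY", "A", matrix(runif(n * 3, 0, 7), ncol = 3))
    s <- compute_sasa(m)$total
    o <- mc_sasa(m, n_samples = 40000, seed = case)
    expect_lt(abs(s - o) / o, 0.02)
  }
})

test_that("SASA monotonicity: adding an atom never increases another's SASA", {
  set.seed(5)
  n <- 10
  m <- toy_model(rep("CA", n), "C", "GLY", "A",
                 matrix(runif(n * 3, 0, 8), ncol = 3))
  base <- compute_sasa(select_atoms(m, resno = 1:(n - 1)))$atom_sasa
  grown <- compute_sasa(m)$atom_sasa
  expect_true(all(grown[1:(n - 1)] <= base + 1e-9))
})

test_that("buried surface area: separated chains bury nothing", {
  m <- two_chain_atoms(sep = 10 + 2 * (1.7 + 1.4))
  expect_equal(buried_surface_area(m, "A", "B")$bsa, 0)
})

test_that("coincident identical atoms bury exactly one sphere's area", {
  m <- two_chain_atoms(sep = 0)
  b <- buried_surface_area(m, "A", "B")
  expect_equal(b$bsa, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.005)
  expect_equal(b$bsa_halved, b$bsa / 2)
})

test_that("BSA is symmetric under swapping the chain sets", {
  d <- build_doublet()
  a <- assign_pfs(d)
  chA <- pf_chains(a, "A10")[1:2]
  chB <- pf_chains(a, "B1")[1:2]
  b1 <- buried_surface_area(d, chA, chB, n_sphere_points = 240)
  b2 <- buried_surface_area(d, chB, chA, n_sphere_points = 240)
  expect_identical(b1$bsa, b2$bsa)
  expect_error(buried_surface_area(d, character(0), chB), "empty")
  expect_error(buried_surface_area(d, chA, chA), "disjoint")
})

test_that("salt bridges respect the distance cutoff and deduplicate", {
  expect_equal(nrow(detect_salt_bridges(arg_glu_pair(3.5), "A", "B")), 1)
  expect_equal(nrow(detect_salt_bridges(arg_glu_pair(4.5), "A", "B")), 0)
  expect_equal(nrow(detect_salt_bridges(arg_glu_pair(4.0), "A", "B")), 1)
  # two donor atoms of one Arg near one Glu -> a single residue-pair record
  m <- toy_model(name = c("NH1", "NH2", "OE1"),
                 element = c("N", "N", "O"),
                 resname = c("ARG", "ARG", "GLU"),
                 chain = c("A", "A", "B"), resno = c(1, 1, 2),
                 xyz = rbind(c(0, 0, 0), c(1.8, 0, 0), c(3.2, 0, 0)))
  sb <- detect_salt_bridges(m, "A", "B")
  expect_equal(nrow(sb), 1)
  expect_equal(sb$distance, 1.4)          # minimum distance kept (NH2-OE1)
  expect_equal(sb$donor_atom, "NH2")
})

test_that("histidine counts as a donor and OXT as an acceptor", {
  m <- toy_model(name = c("NE2", "OD1"), element = c("N", "O"),
                 resname = c("HIS", "ASP"), chain = c("A", "B"),
                 resno = c(283, 306),
                 xyz = rbind(c(0, 0, 0), c(3.8, 0, 0)))
  sb <- detect_salt_bridges(m, "A", "B")
  expect_equal(nrow(sb), 1)
  expect_equal(sb$donor_resname, "HIS")
  m2 <- toy_model(name = c("NZ", "OXT"), element = c("N", "O"),
                  resname = c("LYS", "GLY"), chain = c("A", "B"), resno = 1:2,
                  xyz = rbind(c(0, 0, 0), c(3.0, 0, 0)))
  expect_equal(nrow(detect_salt_bridges(m2, "A", "B")), 1)
})

test_that("clash counting honours the overlap threshold exactly", {
  # r_C + r_C = 3.40: at 3.4 A separation the overlap is 0 -> no clash
  expect_equal(count_clashes(two_chain_atoms(3.4), "A", "B")$n, 0)
  res <- count_clashes(two_chain_atoms(2.0), "A", "B")
  expect_equal(res$n, 1)
  expect_equal(res$records$overlap, 1.4)
  # just under / over the 0.4 A threshold
  expect_equal(count_clashes(two_chain_atoms(3.01), "A", "B")$n, 0)
  expect_equal(count_clashes(two_chain_atoms(2.99), "A", "B")$n, 1)
})

test_that("neighbour-list clash counting agrees with the all-pairs oracle", {
  set.seed(21)
  n <- 500
  m <- toy_model(rep("CA", n), sample(c("C", "N", "O"), n, TRUE), "GLY",
                 rep(c("A", "B"), length.out = n),
                 matrix(runif(n * 3, 0, 30), ncol = 3))
  fast <- count_clashes(m, "A", "B")$n
  expect_gt(fast, 0)        # dense enough to actually clash
  expect_equal(fast, brute_clashes(m, "A", "B"))
})

test_that("the electrostatic shift function vanishes exactly at the cutoff", {
  mk_charges <- function(sep) {
    toy_model(name = c("NZ", "OE1", "CD", "OE2"),
              element = c("N", "O", "C", "O"),
              resname = c("LYS", "GLU", "GLU", "GLU"),
              chain = c("A", "B", "B", "B"), resno = c(1, 2, 2, 2),
              xyz = rbind(c(0, 0, 0), c(sep, 0, 0), c(sep, 0, 0), c(sep, 0, 0)))
  }
  expect_equal(nonbonded_score(mk_charges(8.5), "A", "B")$eelec, 0)
  expect_equal(nonbonded_score(mk_charges(9.0), "A", "B")$eelec, 0)
  expect_lt(nonbonded_score(mk_charges(5.0), "A", "B")$eelec, 0)  # attractive
  # continuity approaching the cutoff
  expect_lt(abs(nonbonded_score(mk_charges(8.499), "A", "B")$eelec), 1e-4)
})

test_that("pairs beyond the cutoff contribute nothing at all", {
  m <- two_chain_atoms(sep = 9)
  nb <- nonbonded_score(m, "A", "B")
  expect_equal(nb$eelec, 0)
  expect_equal(nb$evdw, 0)
})

test_that("the cutoff score approaches the plain unswitched sum as cutoff grows", {
  set.seed(31)
  n <- 12
  m <- toy_model(rep(c("NZ", "OE1"), n / 2), rep(c("N", "O"), n / 2),
                 rep(c("LYS", "GLU"), n / 2), rep(c("A", "B"), each = n / 2),
                 matrix(runif(n * 3, 0, 12), ncol = 3), resno = seq_len(n))
  big <- nonbonded_score(m, "A", "B", cutoff = 1e4, switch_on = 9e3)
  # brute-force unswitched sums
  a <- m$atoms[m$atoms$chain == "A", ]
  b <- m$atoms[m$atoms$chain == "B", ]
  ee <- 0; ev <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    r <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - c(b$x[j], b$y[j], b$z[j]))^2))
    qi <- if (a$resname[i] == "LYS") 1 else -1
    qj <- if (b$resname[j] == "LYS") 1 else -1
    ee <- ee + 332.0636 * qi * qj / r
    eps <- sqrt(c(N = 0.17, O = 0.21)[a$element[i]] *
                c(N = 0.17, O = 0.21)[b$element[j]])
    sig <- (c(N = 3.25, O = 2.96)[a$element[i]] +
            c(N = 3.25, O = 2.96)[b$element[j]]) / 2
    ev <- ev + 4 * eps * ((sig / r)^12 - (sig / r)^6)
  }
  expect_equal(big$eelec, ee, tolerance = 1e-5)
  expect_equal(big$evdw, unname(ev), tolerance = 1e-5)
})

test_that("interface reports aggregate and stay deterministic", {
  m <- arg_glu_pair(3.5)
  r1 <- interface_report(m, "A", "B")
  expect_equal(r1$n_salt_bridges, 1)
  expect_gt(r1$bsa, 0)
  r2 <- interface_report(m, "A", "B")
  r1$bridges <- r2$bridges <- NULL
  expect_identical(r1, r2)
  far <- two_chain_atoms(20)
  rf <- interface_report(far, "A", "B")
  expect_equal(rf$bsa, 0)
  expect_equal(rf$n_salt_bridges, 0)
  expect_equal(rf$n_clashes, 0)
  expect_equal(rf$eelec, 0)
  expect_equal(rf$evdw, 0)
})

test_that("the six outer-junction interfaces are produced from one call", {
  d <- build_doublet()
  a <- assign_pfs(d)
  tab <- outer_junction_interfaces(d, a, n_sphere_points = 120)
  expect_equal(nrow(tab), 6)
  expect_setequal(tab$interface,
                  c("A10a-A11a", "A10b-A11b", "A10a-B1a",
                    "A10b-B1b", "A11a-B1a", "A11b-B1b"))
})
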