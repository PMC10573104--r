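# RESP fitting, charge normalization, parameter coverage, library/mol2 I/O.

test_that("unrestrained RESP recovers generating charges exactly", {
  # single nucleus: the total-charge constraint fixes the single unknown
  g1 <- make_esp_grid(charge_set(c(S1 = -1)), rbind(c(0, 0, 0)), seed = 2)
  f1 <- fit_resp(g1, resp_config(total_charge = -1, a1 = 0))
  expect_equal(unname(f1[["S1"]]), -1, tolerance = 1e-9)

  # two point charges on a shell grid
  q <- charge_set(c(N1 = 0.3, O1 = -0.3))
  g <- make_esp_grid(q, rbind(c(0, 0, 0), c(1.4, 0, 0)), seed = 3)
  fit <- fit_resp(g, resp_config(total_charge = 0, a1 = 0))
  expect_lt(max(abs(fit[names(q)] - q)), 1e-6)

  # four-charge molecule-like case
  q4 <- charge_set(c(C1 = 0.45, O1 = -0.55, N1 = -0.35, H1 = 0.45))
  pos4 <- rbind(c(0, 0, 0), c(1.23, 0, 0), c(-0.7, 1.1, 0), c(-0.6, -1.0, 0.4))
  g4 <- make_esp_grid(q4, pos4, seed = 5)
  fit4 <- fit_resp(g4, resp_config(total_charge = 0, a1 = 0))
  expect_lt(max(abs(fit4[names(q4)] - q4)), 1e-6)
})

test_that("hyperbolic restraint shrinks charges toward zero", {
  q <- charge_set(c(N1 = 0.3, O1 = -0.3))
  g <- make_esp_grid(q, rbind(c(0, 0, 0), c(1.4, 0, 0)), seed = 3)
  free <- fit_resp(g, resp_config(total_charge = 0, a1 = 0))
  tight <- fit_resp(g, resp_config(total_charge = 0, a1 = 0.0005))
  expect_true(all(abs(tight) <= abs(free) + 1e-12))
  expect_lt(abs(tight[["N1"]]), abs(free[["N1"]]))
})

test_that("RESP is invariant under rigid motion of nuclei and grid", {
  q <- charge_set(c(C1 = 0.2, O1 = -0.6, H1 = 0.4))
  pos <- rbind(c(0, 0, 0), c(1.2, 0.1, 0), c(-0.9, 0.8, 0.3))
  g <- make_esp_grid(q, pos, seed = 8)
  fit0 <- fit_resp(g, resp_config(total_charge = 0, a1 = 0.0005))
  set.seed(21)
  rt <- random_rigid_motion()
  g2 <- esp_grid(apply_rigid(g$atom_positions, rt), g$atom_names,
                 apply_rigid(g$points, rt), g$potentials)
  fit1 <- fit_resp(g2, resp_config(total_charge = 0, a1 = 0.0005))
  expect_lt(max(abs(fit0 - fit1[names(fit0)])), 1e-8)
})

test_that("frozen charges and equivalence groups are honored", {
  q <- charge_set(c(C1 = -0.3, H1 = 0.11, H2 = 0.08, H3 = 0.11))
  pos <- rbind(c(0, 0, 0), c(1.09, 0, 0), c(-0.36, 1.03, 0),
               c(-0.36, -0.51, 0.89))
  g <- make_esp_grid(q, pos, seed = 6)
  cfg <- resp_config(total_charge = 0, a1 = 0.0005,
                     frozen = c(C1 = -0.3),
                     equivalence_groups = list(c("H1", "H2", "H3")))
  fit <- fit_resp(g, cfg)
  expect_identical(unname(fit[["C1"]]), -0.3)
  expect_identical(fit[["H1"]], fit[["H2"]])  # bit-identical
  expect_identical(fit[["H1"]], fit[["H3"]])
  expect_equal(sum(fit), 0, tolerance = 1e-9)
})

test_that("two-stage protocol refits only the stage-2 set", {
  q <- charge_set(c(C1 = -0.25, H1 = 0.1, H2 = 0.1, H3 = 0.1, O1 = -0.05))
  pos <- rbind(c(0, 0, 0), c(1.09, 0, 0), c(-0.36, 1.03, 0),
               c(-0.36, -0.51, 0.89), c(2.5, 0.5, 0))
  g <- make_esp_grid(q, pos, seed = 9)
  cfg1 <- resp_config(total_charge = 0, a1 = 0.0005)
  stage1 <- fit_resp(g, cfg1)
  cfg2 <- resp_config(total_charge = 0, a1 = 0.0005, a2 = 0.001,
                      equivalence_groups = list(c("H1", "H2", "H3")),
                      stage2_refit_set = c("C1", "H1", "H2", "H3"))
  stage2 <- fit_resp(g, cfg2)
  expect_identical(stage2[["O1"]], stage1[["O1"]])  # frozen at stage-1 value
  expect_identical(stage2[["H1"]], stage2[["H2"]])
  expect_equal(sum(stage2), 0, tolerance = 1e-9)
})

test_that("RESP convergence and singularity failures are hard errors", {
  q <- charge_set(c(N1 = 0.3, O1 = -0.3))
  g <- make_esp_grid(q, rbind(c(0, 0, 0), c(1.4, 0, 0)), seed = 3)
  cfg <- resp_config(total_charge = 0, a1 = 0.01, max_iter = 1L)
  expect_error(fit_resp(g, cfg), "did not converge")
})

test_that("normalize_charges freezes backbone, spreads residual, hits total", {
  bb <- ff14sb_cys_backbone()
  # residual engineered to -0.009 e over 5 side-chain atoms
  sc_target <- -1 - sum(bb) + 0.009
  sc <- c(SG = -0.35, CB = -0.12, HB2 = 0.1, HB3 = 0.1, SG2 = 0)
  sc["SG2"] <- sc_target - sum(sc[-5])
  raw <- c(stats::setNames(rep(0, length(bb)), names(bb)), sc)
  out <- normalize_charges(raw, bb, cap_atoms = character(0),
                           sidechain_atoms = names(sc), total_charge = -1)
  expect_equal(attr(out, "delta"), -0.0018, tolerance = 1e-12)
  expect_equal(unname(out[names(bb)]), unname(bb[names(bb)]))
  expect_equal(sum(out), -1, tolerance = 1e-9)
  expect_equal(unname(out[names(sc)] - sc), rep(-0.0018, 5), tolerance = 1e-12)
})

test_that("normalize_charges is exact over random inputs and flags overlap", {
  set.seed(14)
  bb <- ff14sb_cys_backbone()
  for (rep in 1:25) {
    nsc <- sample(3:12, 1)
    sc_names <- paste0("X", seq_len(nsc))
    caps <- paste0("CAP", 1:3)
    raw <- charge_set(stats::setNames(
      stats::rnorm(length(bb) + nsc + 3),
      c(names(bb), sc_names, caps)
    ))
    total <- sample(-2:1, 1)
    out <- normalize_charges(raw, bb, cap_atoms = caps,
                             sidechain_atoms = sc_names, total_charge = total)
    expect_equal(sum(out), total, tolerance = 1e-9)
    expect_false(any(caps %in% names(out)))
    expect_identical(unname(out[names(bb)]), unname(as.numeric(bb)))
  }
  expect_error(
    normalize_charges(charge_set(c(A = 1, B = -1)), bb,
                      cap_atoms = "A", sidechain_atoms = "A",
                      total_charge = 0),
    "two categories"
  )
  # raw side chain already consistent: unchanged charges
  sc <- c(S1 = -0.5, S2 = -0.5193)
  raw <- c(stats::setNames(rep(0, length(bb)), names(bb)), sc)
  out <- normalize_charges(raw, bb, character(0), names(sc), -1)
  expect_equal(attr(out, "delta"), 0, tolerance = 1e-12)
  expect_equal(unname(out[names(sc)]), unname(sc))
})

test_that("parameter coverage enumerates bonds, angles and dihedrals", {
  atoms <- data.frame(name = c("A1", "B1", "C1"),
                      atype = c("ta", "tb", "tc"), charge = 0)
  bonds <- rbind(c("A1", "B1"), c("B1", "C1"))
  tm <- residue_template("TST", atoms, bonds, head = "A1", tail = "C1")
  full <- parameter_set(
    bond = data.frame(t1 = c("ta", "tb"), t2 = c("tb", "tc")),
    angle = data.frame(t1 = "ta", t2 = "tb", t3 = "tc")
  )
  expect_equal(nrow(check_parameter_coverage(tm, full)), 0L)
  noang <- parameter_set(bond = data.frame(t1 = c("ta", "tb"),
                                           t2 = c("tb", "tc")))
  miss <- check_parameter_coverage(tm, noang)
  expect_equal(miss$term, "angle")
  expect_equal(miss$types, "ta-tb-tc")
})

test_that("wildcard dihedrals satisfy coverage", {
  atoms <- data.frame(name = c("A1", "B1", "C1", "D1"),
                      atype = c("ta", "tb", "tc", "td"), charge = 0)
  bonds <- rbind(c("A1", "B1"), c("B1", "C1"), c("C1", "D1"))
  tm <- residue_template("TST", atoms, bonds, head = "A1", tail = "D1")
  ps <- parameter_set(
    bond = data.frame(t1 = c("ta", "tb", "tc"), t2 = c("tb", "tc", "td")),
    angle = data.frame(t1 = c("ta", "tb"), t2 = c("tb", "tc"),
                       t3 = c("tc", "td")),
    dihedral = data.frame(t1 = "X", t2 = "tb", t3 = "tc", t4 = "X")
  )
  expect_equal(nrow(check_parameter_coverage(tm, ps)), 0L)
  ps2 <- parameter_set(
    bond = data.frame(t1 = c("ta", "tb", "tc"), t2 = c("tb", "tc", "td")),
    angle = data.frame(t1 = c("ta", "tb"), t2 = c("tb", "tc"),
                       t3 = c("tc", "td"))
  )
  miss <- check_parameter_coverage(tm, ps2)
  expect_equal(miss$term, "dihedral")
})

test_that("coverage agrees with a brute-force oracle on random trees", {
  set.seed(99)
  types_pool <- c("t1", "t2", "t3")
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    nm <- paste0("A", seq_len(n))
    # random labelled tree: connect each node to a random earlier node
    bonds <- do.call(rbind, lapply(2:n, function(i) {
      c(nm[sample(i - 1, 1)], nm[i])
    }))
    aty <- sample(types_pool, n, replace = TRUE)
    atoms <- data.frame(name = nm, atype = aty, charge = 0)
    tm <- residue_template("RND", atoms, bonds, head = nm[1], tail = nm[n])
    # random parameter tables over the type pool
    rnd_tab <- function(k, prob = 0.7) {
      combs <- expand.grid(rep(list(types_pool), k), stringsAsFactors = FALSE)
      keep <- combs[stats::runif(nrow(combs)) < prob, , drop = FALSE]
      if (nrow(keep) == 0) keep <- combs[1, , drop = FALSE]
      stats::setNames(keep, paste0("t", seq_len(k)))
    }
    ps <- parameter_set(bond = rnd_tab(2), angle = rnd_tab(3),
                        dihedral = rnd_tab(4, prob = 0.5))
    got <- check_parameter_coverage(tm, ps)
    want <- oracle_coverage(nm, aty, bonds, ps)
    expect_equal(sort(paste(got$term, got$types)), want)
  }
})

test_that("coverage requires atom types", {
  atoms <- data.frame(name = c("A1", "B1"), atype = c("ta", NA), charge = 0)
  tm <- residue_template("TST", atoms, rbind(c("A1", "B1")),
                         head = "A1", tail = "B1")
  expect_error(check_parameter_coverage(tm, parameter_set()),
               "without an atom type")
})

test_that("frcmod parsing feeds coverage checking", {
  f <- tempfile(fileext = ".frcmod")
  writeLines(c(
    "toy parameters",
    "MASS",
    "ta 12.01",
    "",
    "BOND",
    "ta-tb  300.0   1.50",
    "tb-tc  300.0   1.50",
    "",
    "ANGLE",
    "ta-tb-tc   50.0  109.50",
    "",
    "DIHE",
    "X -tb-tc-X    1    0.00          0.0             2.0",
    ""
  ), f)
  ps <- read_frcmod(f)
  expect_equal(nrow(ps$bond), 2L)
  expect_equal(nrow(ps$angle), 1L)
  expect_equal(ps$dihedral$t1, "X")
  # round-trip through write_frcmod
  f2 <- tempfile(fileext = ".frcmod")
  write_frcmod(ps, f2)
  ps2 <- read_frcmod(f2)
  expect_equal(ps2$bond_keys, ps$bond_keys)
  expect_equal(ps2$angle_keys, ps$angle_keys)
  expect_equal(ps2$dihedral_keys, ps$dihedral_keys)
})

test_that("the CSG template is covered by its own enumerated terms", {
  tm <- csg_template()
  # parameter set built from the template's own bond graph: coverage must
  # close the loop with zero missing terms
  paths <- csgkit:::.bond_graph_paths(as.matrix(tm$bonds))
  ty <- stats::setNames(tm$atoms$atype, tm$atoms$name)
  bond_tab <- unique(data.frame(t1 = ty[tm$bonds$a1], t2 = ty[tm$bonds$a2],
                                row.names = NULL))
  ang_tab <- unique(do.call(rbind, lapply(paths$angles, function(p) {
    data.frame(t1 = ty[[p[1]]], t2 = ty[[p[2]]], t3 = ty[[p[3]]])
  })))
  dih_tab <- unique(do.call(rbind, lapply(paths$dihedrals, function(p) {
    data.frame(t1 = "X", t2 = ty[[p[2]]], t3 = ty[[p[3]]], t4 = "X")
  })))
  ps <- parameter_set(bond = bond_tab, angle = ang_tab, dihedral = dih_tab)
  expect_equal(nrow(check_parameter_coverage(tm, ps)), 0L)
  # removing every row of one canonical angle class is detected
  keys <- vapply(seq_len(nrow(ang_tab)), function(i) {
    csgkit:::.canon_types(as.character(unlist(ang_tab[i, ])))
  }, character(1))
  ps_broken <- parameter_set(bond = bond_tab,
                             angle = ang_tab[keys != keys[1], ],
                             dihedral = dih_tab)
  expect_gt(nrow(check_parameter_coverage(tm, ps_broken)), 0L)
})

test_that("OFF library round-trips and is deterministic", {
  tm <- csg_template()
  f <- tempfile(fileext = ".lib")
  write_library(tm, f)
  back <- read_library(f)
  expect_equal(nrow(back$atoms), nrow(tm$atoms))
  expect_identical(back$atoms$name, tm$atoms$name)
  expect_identical(back$atoms$atype, tm$atoms$atype)
  expect_lt(max(abs(back$atoms$charge - tm$atoms$charge)), 1e-6)
  expect_equal(sum(back$atoms$charge), -1, tolerance = 1e-4)
  expect_equal(back$head, "N")
  expect_equal(back$tail, "C")
  key <- function(b) sort(paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2)))
  expect_identical(key(back$bonds), key(tm$bonds))
  # residueconnect entries name the chain-link atoms
  txt <- readLines(f)
  rc <- txt[grep("residueconnect", txt) + 1]
  expect_equal(as.integer(strsplit(trimws(rc), "\\s+")[[1]])[1:2],
               match(c("N", "C"), tm$atoms$name))
  f2 <- tempfile(fileext = ".lib")
  write_library(tm, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("library writing rejects non-integer total charge", {
  atoms <- data.frame(name = c("A1", "B1"), atype = c("ta", "tb"),
                      charge = c(0.3, 0.2))
  tm <- residue_template("BAD", atoms, rbind(c("A1", "B1")),
                         head = "A1", tail = "B1")
  expect_error(write_library(tm, tempfile()), "integer")
})

test_that("mol2 output carries the template charges and bonds", {
  tm <- csg_template()
  f <- tempfile(fileext = ".mol2")
  write_mol2(tm, f)
  txt <- readLines(f)
  at0 <- grep("@<TRIPOS>ATOM", txt, fixed = TRUE)
  bd0 <- grep("@<TRIPOS>BOND", txt, fixed = TRUE)
  atom_lines <- txt[(at0 + 1):(bd0 - 1)]
  expect_equal(length(atom_lines), nrow(tm$atoms))
  q <- as.numeric(vapply(strsplit(trimws(atom_lines), "\\s+"),
                         function(x) x[length(x)], character(1)))
  expect_lt(max(abs(q - tm$atoms$charge)), 1e-4 + 1e-12)
  expect_equal(sum(q), -1, tolerance = 1e-3)
  expect_equal(length(txt) - bd0, nrow(tm$bonds))
})

test_that("stage-2 set detection finds methyl/methylene groups", {
  tm <- csg_template()
  s2 <- stage2_set_from_template(tm)
  expect_true(all(c("CB", "HB2", "HB3") %in% s2$refit))
  expect_true(all(c("CA3", "HA31", "HA32") %in% s2$refit))
  expect_false("CA" %in% s2$refit)  # one hydrogen only
  expect_true(all(vapply(s2$equivalence_groups, length, integer(1)) >= 2))
})

test_that("charge CSV round-trips", {
  q <- charge_set(c(N = -0.4157, SG = -0.3, H11 = 0.28))
  f <- tempfile(fileext = ".csv")
  write_charge_csv(q, f)
  expect_equal(read_charge_csv(f), q, tolerance = 1e-12)
})
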