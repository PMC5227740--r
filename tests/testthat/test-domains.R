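test_that("models round-trip through PDB at format precision", {
  m <- synthetic_chain_model(20)
  path <- tempfile(fileext = ".pdb")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(nrow(back$atoms), nrow(m$atoms))
  expect_lt(max(abs(back$atoms$x - m$atoms$x)), 5e-4)
  expect_lt(max(abs(back$atoms$z - m$atoms$z)), 5e-4)
  ca <- helixrec:::select_atoms(back, "A:1-10", elety = "CA")
  expect_equal(nrow(ca), 10)
})

test_that("alternate locations resolve to the highest occupancy", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      4  C   ALA A   1       2.000   1.000   0.000  1.00  0.00           C",
    "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  m <- read_model(path)
  ca <- m$atoms[trimws(m$atoms$elety) == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.000)
})

test_that("superposition recovers constructed rigid transforms exactly", {
  m <- synthetic_chain_model(60)
  R <- rotation_about_axis(c(0, 0, 1), 30)
  a <- m$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + 5; a$y <- xyz[, 2] + 5; a$z <- xyz[, 3] + 5
  moved <- atomic_model(a)
  sp <- superpose(m, moved, "A:1-60")
  expect_lt(sp$rmsd, 1e-8)
  expect_equal(sp$n, 60)
  expect_lt(max(abs(sp$transform$R - R)), 1e-8)
  expect_equal(sp$transform$angle_deg, 30, tolerance = 1e-6)
  # forward and reverse fits are mutually inverse with equal rmsd
  sp_rev <- superpose(moved, m, "A:1-60")
  expect_lt(max(abs(sp$transform$R %*% sp_rev$transform$R - diag(3))), 1e-8)
  expect_equal(sp$rmsd, sp_rev$rmsd, tolerance = 1e-8)
  expect_error(superpose(m, moved, "A:1-2"), "3 C-alpha")

  # independent oracle: bio3d's least-squares fit gives the same rmsd
  set.seed(44)
  jit <- a
  jit$x <- jit$x + rnorm(nrow(jit), sd = 0.3)
  jm <- atomic_model(jit)
  sp2 <- superpose(jm, m, "A:1-60")
  ca_m <- helixrec:::select_atoms(m, "A:1-60", "CA")
  ca_j <- helixrec:::select_atoms(jm, "A:1-60", "CA")
  fixed <- as.numeric(t(as.matrix(ca_m[, c("x", "y", "z")])))
  mob <- as.numeric(t(as.matrix(ca_j[, c("x", "y", "z")])))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed, mob))
  # bio3d rounds fitted coordinates to 3 decimals
  expect_equal(sp2$rmsd, bio3d::rmsd(fixed, fitted), tolerance = 1e-3)
})

test_that("post-fit rmsd of jittered copies matches the closed form", {
  m <- synthetic_chain_model(50)
  sdj <- 0.5
  rmsds <- vapply(1:40, function(s) {
    pair <- make_rotated_domain_pair(m, "A:1-50", 0, c(0, 0, 1),
                                     jitter_sd_A = sdj, seed = s)
    superpose(pair$rotated, pair$reference, "A:1-50")$rmsd
  }, 0)
  expected <- sdj * sqrt(3 * (1 - 1 / 50))
  expect_lt(abs(mean(rmsds) - expected) / expected, 0.2)
})

test_that("the per-domain rmsd table isolates a perturbed domain", {
  m <- synthetic_chain_model(120)
  doms <- list(D1 = "A:1-40", D2 = "A:41-80", D3 = "A:81-120")
  self <- domain_rmsd_table(m, m, doms)
  expect_equal(self$rmsd_A, c(0, 0, 0), tolerance = 1e-10)
  # jitter only the middle domain
  a <- m$atoms
  set.seed(9)
  i <- a$resno >= 41 & a$resno <= 80
  jit <- rnorm(sum(i) * 3, sd = 1.2 / sqrt(3))
  a[i, c("x", "y", "z")] <- a[i, c("x", "y", "z")] +
    matrix(jit, ncol = 3)
  tab <- domain_rmsd_table(m, atomic_model(a), doms)
  expect_lt(tab$rmsd_A[1], 0.01)
  expect_lt(tab$rmsd_A[3], 0.01)
  expect_gt(tab$rmsd_A[2], 0.8)
  expect_lt(tab$rmsd_A[2], 1.6)
  # unresolvable domains are skipped with a warning
  expect_warning(
    tab2 <- domain_rmsd_table(m, m, c(doms, list(DX = "B:1-40"))),
    "skipped")
  expect_equal(nrow(tab2), 3)
})

test_that("myosin subdomain definitions cover the head residue ranges", {
  doms <- myosin_subdomains("M")
  expect_named(doms, c("N25D", "U50D", "L50D", "CD", "LAD"))
  sel <- residue_selection(doms$U50D)
  expect_equal(sel$start, c(206, 603))
  expect_equal(sel$end, c(466, 627))
  sel2 <- residue_selection(doms$L50D)
  expect_equal(sel2$start, c(467, 628))
  expect_equal(sel2$end, c(602, 680))
})

test_that("relative domain rotation recovers constructed motions", {
  m <- synthetic_chain_model(120)
  axis <- c(sin(40 * pi / 180), 0, cos(40 * pi / 180))
  pair <- make_rotated_domain_pair(m, "A:61-120", 21, axis)
  rot <- relative_domain_rotation(pair$reference, pair$rotated,
                                  anchor = "A:1-60", mobile = "A:61-120")
  expect_equal(rot$angle_deg, 21, tolerance = 0.1)
  expect_equal(rot$axis_tilt_deg, 40, tolerance = 0.1)

  # unrotated mobile: angle ~ 0 with undefined axis
  pair0 <- make_rotated_domain_pair(m, "A:61-120", 0, axis)
  rot0 <- relative_domain_rotation(pair0$reference, pair0$rotated,
                                   "A:1-60", "A:61-120")
  expect_lt(rot0$angle_deg, 0.5)
  expect_true(all(is.na(rot0$axis)))

  # two successive 10-degree rotations compose to 20 degrees
  p1 <- make_rotated_domain_pair(m, "A:61-120", 10, axis)
  p2 <- make_rotated_domain_pair(p1$rotated, "A:61-120", 10, axis)
  rot2 <- relative_domain_rotation(m, p2$rotated, "A:1-60", "A:61-120")
  expect_equal(rot2$angle_deg, 20, tolerance = 0.1)

  # invariant to a rigid transform applied jointly to one whole model
  Rg <- rotation_about_axis(c(1, 2, 3), 77)
  b <- pair$rotated$atoms
  xyz <- as.matrix(b[, c("x", "y", "z")]) %*% t(Rg)
  b$x <- xyz[, 1] + 30; b$y <- xyz[, 2] - 12; b$z <- xyz[, 3] + 4
  rotg <- relative_domain_rotation(pair$reference, atomic_model(b),
                                   "A:1-60", "A:61-120")
  expect_equal(rotg$angle_deg, rot$angle_deg, tolerance = 1e-6)
  expect_equal(rotg$axis_tilt_deg, rot$axis_tilt_deg, tolerance = 1e-6)

  expect_error(make_rotated_domain_pair(m, "A:200-300", 10, axis), "empty")
  expect_error(make_rotated_domain_pair(m, "A:61-120", 10, c(0, 0, 0)),
               "non-zero")
})

test_that("rotation recovery tolerates coordinate jitter", {
  m <- synthetic_chain_model(120)
  axis <- c(sin(40 * pi / 180), 0, cos(40 * pi / 180))
  angs <- vapply(1:30, function(s) {
    pair <- make_rotated_domain_pair(m, "A:61-120", 21, axis,
                                     jitter_sd_A = 0.2, seed = s)
    relative_domain_rotation(pair$reference, pair$rotated,
                             "A:1-60", "A:61-120")$angle_deg
  }, 0)
  expect_lt(max(abs(angs - 21)), 1)
})

test_that("contact listing is inclusive, classified and cutoff-monotone", {
  mk_res <- function(chain, resno, resid, atoms) {
    do.call(rbind, lapply(seq_along(atoms$elety), function(i)
      data.frame(chain = chain, resno = resno, resid = resid,
                 elety = atoms$elety[i], elesy = atoms$elesy[i],
                 x = atoms$x[i], y = atoms$y[i], z = atoms$z[i],
                 o = 1, b = 0, insert = "")))
  }
  # Lys NZ at exactly 3.0 A from Glu OE1; CB pair at exactly 4.5 A
  lys <- mk_res("A", 1, "LYS", list(elety = c("CA", "CB", "NZ"),
                                    elesy = c("C", "C", "N"),
                                    x = c(0, 0, 0), y = c(0, 0, 0),
                                    z = c(0, 1, 2)))
  glu <- mk_res("B", 1, "GLU", list(elety = c("CA", "CB", "OE1"),
                                    elesy = c("C", "C", "O"),
                                    x = c(0, 0, 0), y = c(8, 5.5, 3),
                                    z = c(0, 1, 2)))
  m <- atomic_model(rbind(lys, glu))
  ct <- contact_pairs(m, "A:1", "B:1", cutoff_A = 3.0)
  expect_equal(nrow(ct), 1)                 # boundary is inclusive
  expect_equal(ct$min_dist_A, 3.0, tolerance = 1e-12)
  expect_equal(ct$class, "salt-bridge")
  # hydrophobic pair: side-chain carbons within 4.5
  ala1 <- mk_res("A", 2, "ALA", list(elety = c("CA", "CB"),
                                     elesy = c("C", "C"),
                                     x = c(20, 20), y = c(0, 0),
                                     z = c(0, 1)))
  ala2 <- mk_res("B", 2, "LEU", list(elety = c("CA", "CD1"),
                                     elesy = c("C", "C"),
                                     x = c(20, 20), y = c(8, 4.5),
                                     z = c(0, 1)))
  m2 <- atomic_model(rbind(ala1, ala2))
  ct2 <- contact_pairs(m2, "A:2", "B:2", cutoff_A = 4.5)
  expect_equal(ct2$class, "hydrophobic")
  expect_error(contact_pairs(m, "A:1", "A:1", 4), "disjoint")

  # doubling the cutoff never removes pairs
  set.seed(77)
  for (i in 1:10) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    mm <- atomic_model(rbind(
      do.call(rbind, lapply(seq_len(n1), function(r)
        mk_res("A", r, "ALA", list(elety = c("CA", "CB"),
                                   elesy = c("C", "C"),
                                   x = rnorm(2, 0, 4), y = rnorm(2, 0, 4),
                                   z = rnorm(2, 0, 4))))),
      do.call(rbind, lapply(seq_len(n2), function(r)
        mk_res("B", r, "ALA", list(elety = c("CA", "CB"),
                                   elesy = c("C", "C"),
                                   x = rnorm(2, 6, 4), y = rnorm(2, 0, 4),
                                   z = rnorm(2, 0, 4)))))))
    small <- contact_pairs(mm, sprintf("A:1-%d", n1), sprintf("B:1-%d", n2),
                           cutoff_A = 4)
    big <- contact_pairs(mm, sprintf("A:1-%d", n1), sprintf("B:1-%d", n2),
                         cutoff_A = 8)
    key <- function(d) paste(d$residue_a, d$residue_b)
    expect_true(all(key(small) %in% key(big)))
  }
})
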