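# WCN, distance-to-catalytic, Shrake-Rupley ASA, RSA, interfaces,
# site-table assembly

test_that("weighted contact number matches hand sums and scales as 1/r^2", {
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(weighted_contact_number(two), c(0.25, 0.25))

  collinear <- cbind(c(0, 2, 4), 0, 0)
  expect_equal(weighted_contact_number(collinear),
               c(0.25 + 1 / 16, 0.5, 0.25 + 1 / 16))

  set.seed(42)
  cloud <- matrix(rnorm(30 * 3, sd = 8), ncol = 3)
  w <- weighted_contact_number(cloud)
  expect_equal(weighted_contact_number(cloud * 2), w / 4)

  expect_error(weighted_contact_number(rbind(c(1, 1, 1), c(1, 1, 1))),
               "coincident")
  expect_warning(w1 <- weighted_contact_number(matrix(1, 1, 3)), "single")
  expect_equal(w1, 0)
})

test_that("WCN equals the brute-force pairwise oracle on random clouds", {
  set.seed(7)
  for (n in c(5, 40, 120)) {
    cloud <- matrix(runif(n * 3, -20, 20), ncol = 3)
    expect_equal(weighted_contact_number(cloud), wcn_oracle(cloud),
                 tolerance = 1e-12)
  }
})

test_that("distance to the nearest catalytic residue is a true minimum", {
  ctr <- rbind(c(3, 4, 0), c(0, 0, 0), c(10, 0, 0))
  expect_equal(distance_to_catalytic(ctr, 2), c(5, 0, 10))
  # minimum over two catalytic residues
  ctr2 <- rbind(c(0, 0, 0), c(6, 0, 0), c(-9, 0, 0))
  expect_equal(distance_to_catalytic(ctr2, c(2, 3))[1], 6)
  expect_error(distance_to_catalytic(ctr, integer()), "empty")

  # triangle property: |d_i - d_j| <= ||center_i - center_j||
  set.seed(3)
  cloud <- matrix(rnorm(50 * 3, sd = 15), ncol = 3)
  d <- distance_to_catalytic(cloud, c(4, 17))
  pd <- as.matrix(dist(cloud))
  expect_true(all(abs(outer(d, d, "-")) <= pd + 1e-9))
})

test_that("Shrake-Rupley reproduces closed-form and occlusion limits", {
  # isolated sphere: full expanded area 4*pi*(1.9+1.4)^2
  a1 <- shrake_rupley_asa(matrix(0, 1, 3), 1.9)
  expect_equal(a1, 4 * pi * 3.3^2, tolerance = 0.02)

  # two far-apart spheres: no occlusion
  a2 <- shrake_rupley_asa(rbind(c(0, 0, 0), c(100, 0, 0)), 1.9)
  expect_equal(a2, rep(4 * pi * 3.3^2, 2), tolerance = 0.02)

  # tight 26-neighbor cage: central sphere almost fully buried
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  cage <- rbind(c(0, 0, 0), offs * 3.5)
  a3 <- shrake_rupley_asa(cage, 1.9)
  expect_lt(a3[1], 0.05 * 4 * pi * 3.3^2)

  expect_error(shrake_rupley_asa(matrix(0, 1, 3), -1), "radius")
  expect_error(shrake_rupley_asa(matrix(0, 1, 3), 1.9, n_points = 50),
               "92")
})

test_that("Shrake-Rupley quadrature converges when points double", {
  s <- generate_structure(synthetic_config(n_sites = 100, seed = 8))
  a960 <- structure_asa(s, n_points = 960, uniform_radius = 3)
  a1920 <- structure_asa(s, n_points = 1920, uniform_radius = 3)
  # per-residue change bounded by 1% of the full expanded-sphere area
  full <- 4 * pi * (3 + 1.4)^2
  expect_true(all(abs(a960 - a1920) < 0.01 * full))
})

test_that("fully caged synthetic residues have RSA below 0.05", {
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cage <- offs * 4  # center residue surrounded by 26 neighbors at 4 A
  asa <- shrake_rupley_asa(cage, 3)
  center <- which(rowSums(abs(offs)) == 0)
  rsa <- suppressMessages(relative_solvent_accessibility(
    asa, rep("ALA", nrow(cage))))
  expect_lt(rsa[center], 0.05)
})

test_that("RSA normalizes by Gly-X-Gly maxima with the cross-chain zero rule", {
  mx <- max_asa_table()
  expect_equal(
    relative_solvent_accessibility(c(0, mx[["ALA"]]), c("VAL", "ALA")),
    c(0, 1))
  # cross-chain linked residues forced to zero regardless of area
  expect_equal(
    relative_solvent_accessibility(c(50, 80), c("CYS", "CYS"),
                                   cross_chain_linked = 2L),
    c(50 / mx[["CYS"]], 0))
  expect_error(relative_solvent_accessibility(1, "ZZZ"), "lookup error")
  expect_message(
    relative_solvent_accessibility(mx[["GLY"]] * 2, "GLY"), "RSA > 1")
})

test_that("interface detection uses an absolute 0.10 RSA drop by default", {
  expect_equal(detect_interface(c(0.30, 0.5, 0.199), c(0.15, 0.5, 0.10)),
               c(TRUE, FALSE, FALSE))  # 0.15 >= 0.1; 0; 0.099 < 0.1
  expect_true(all(!detect_interface(c(0.2, 0.8), c(0.2, 0.8))))
  # relative reading flags a 10% proportional drop instead
  expect_true(detect_interface(0.05, 0.04, relative = TRUE))
  expect_error(detect_interface(c(0.1, 0.2), 0.1), "length")
})

test_that("cross-chain covalent links are detected between chains only", {
  # two CYS SG atoms 2.05 A apart on different chains; a third residue far
  lines <- c(
    pdb_atom_line(1, "CA", "CYS", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "SG", "CYS", "A", 1, 1, 0, 0, element = "S"),
    pdb_atom_line(3, "CA", "CYS", "B", 1, 4, 0, 0),
    pdb_atom_line(4, "SG", "CYS", "B", 1, 3.05, 0, 0, element = "S"),
    pdb_atom_line(5, "CB", "ALA", "B", 2, 20, 0, 0),
    "END")
  s <- parse_structure(paste(lines, collapse = "\n"))
  expect_equal(detect_cross_chain_links(s), c(1L, 2L))
})

test_that("build_site_table assembles all metrics with mean-1 rates", {
  cfg <- synthetic_config(n_sites = 40, n_catalytic = 1, seed = 5)
  s <- generate_structure(cfg)
  ann <- plant_catalytic_site(s, cfg)
  rates <- generate_rates(s, ann, cfg)
  tab <- suppressMessages(
    build_site_table(s, ann, rates, n_points = 240,
                     uniform_radius = 3))
  expect_s3_class(tab, "enzgrad_site_table")
  expect_equal(nrow(tab), 40)
  expect_equal(sum(tab$d == 0), 1)
  expect_identical(tab$is_catalytic, tab$d == 0)
  expect_equal(mean(tab$K), 1, tolerance = 1e-9)
  expect_true(all(tab$shell == assign_shell(tab$d)))
  expect_true(all(tab$wcn > 0))

  # monomer: excluding interfaces changes nothing
  tab2 <- suppressMessages(
    build_site_table(s, ann, rates, interfaces = "exclude",
                     n_points = 240, uniform_radius = 3))
  expect_equal(as.data.frame(tab2), as.data.frame(tab), ignore_attr = TRUE)

  # rate/residue length mismatch is an error
  expect_error(suppressMessages(
    build_site_table(s, ann, rates$raw[-1], n_points = 240,
                     uniform_radius = 3)), "mapping error")
})

test_that("site tables round-trip through the fixed-column TSV", {
  cfg <- synthetic_config(n_sites = 20, seed = 9)
  sim <- quiet_sim(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(sim$table, path)
  back <- read_site_table(path)
  expect_equal(names(back),
               c("protein_id", "chain", "residue_number", "residue_type",
                 "K", "wcn", "asa", "rsa", "d", "shell", "is_catalytic",
                 "is_interface"))
  expect_equal(back$K, sim$table$K, tolerance = 1e-12)
  expect_equal(back$d, sim$table$d, tolerance = 1e-12)
})

test_that("DSSP ACC columns parse from classic-format output", {
  dssp <- paste(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N",
    "    1    2 A M              0   0  178      0, 0.0   2,-0.3",
    "    2    3 A K  E     -A   28   0A  82     26,-1.4  26,-1.6",
    sep = "\n")
  acc <- read_dssp_acc(dssp)
  expect_equal(acc$acc, c(178, 82))
  expect_equal(acc$chain, c("A", "A"))
  expect_equal(acc$resno, c(2, 3))
  expect_error(read_dssp_acc("not dssp"), "header")
})
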