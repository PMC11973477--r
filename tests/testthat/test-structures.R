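test_that("XYZ files read, round-trip, and carry charge metadata", {
  path <- withr::local_tempfile(fileext = ".xyz")
  write_water_xyz(path)
  s <- read_structure(path)
  expect_equal(s$atoms$element, c("O", "H", "H"))
  expect_equal(s$net_charge, 0L)
  # explicit charge token on the comment line wins
  write_water_xyz(path, charge = -1)
  expect_equal(read_xyz(path)$net_charge, -1L)
  # round trip to 6 decimal places
  out <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(s, out, microstate = "101")
  s2 <- read_xyz(out)
  expect_equal(s2$atoms$element, s$atoms$element)
  expect_equal(s2$atoms$x, s$atoms$x, tolerance = 1e-6)
  expect_equal(s2$atoms$z, s$atoms$z, tolerance = 1e-6)
  expect_match(s2$title, "microstate=101")
})

test_that("malformed XYZ input raises parse errors with line context", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "short file", "O 0 0 0", "H 1 0 0", "H 0 1 0", "H 0 0 1"), path)
  expect_error(read_xyz(path), "promises 5 atoms", class = "polypka_parse_error")
  writeLines(c("2", "bad coords", "O 0 0 0", "H one 0 0"), path)
  expect_error(read_xyz(path), "line 4", class = "polypka_parse_error")
  expect_error(read_structure("/nonexistent/file.xyz"), class = "polypka_input_error")
  writeLines(c("1", "bad element", "Xx 0 0 0"), path)
  expect_error(read_xyz(path), "element", class = "polypka_input_error")
})

test_that("SDF V2000 reads the CHG block and round-trips the net charge", {
  s <- toy_template()   # net charge +2
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(s, path)
  s2 <- read_sdf(path)
  expect_equal(s2$net_charge, 2L)
  expect_equal(s2$atoms$element, s$atoms$element)
  expect_equal(s2$atoms$x, s$atoms$x, tolerance = 1e-4)
  # a +4 CHG block gives net_charge 4 regardless of fallback
  lines <- readLines(path)
  lines <- sub("^M  CHG  1   1   2$", "M  CHG  2   1   2   5   2", lines)
  writeLines(lines, path)
  expect_equal(read_structure(path, format = "sdf", charge = 0)$net_charge, 4L)
})

test_that("strip_protons removes exactly the requested site protons", {
  s <- toy_template(); sites <- toy_sites(s)
  # empty removal is the identity
  expect_identical(strip_protons(s, sites, character(0)), s)
  one <- strip_protons(s, sites, "N1")
  expect_equal(nrow(one$atoms), nrow(s$atoms) - 1)
  expect_equal(one$net_charge, 1L)
  both <- strip_protons(s, sites, c("N1", "N2"))
  expect_equal(nrow(both$atoms), nrow(s$atoms) - 2)
  expect_equal(both$net_charge, 0L)
  # atom multiset conservation: result + removed protons = template
  expect_equal(sort(c(both$atoms$element, "H", "H")), sort(s$atoms$element))
  # remaining atom order preserved
  keep <- setdiff(seq_len(nrow(s$atoms)), sites$proton_atom)
  expect_equal(both$atoms$x, s$atoms$x[keep])
  expect_error(strip_protons(s, sites, "N9"), class = "polypka_key_error")
  expect_error(strip_protons(s, sites, c("N1", "N1")), class = "polypka_input_error")
  # a site list pointing at a non-H atom is a precondition violation
  bad <- sites; bad$proton_atom[1] <- 3L
  expect_error(strip_protons(s, bad, "N1"), class = "polypka_input_error")
})

test_that("proton site lists are validated against the structure", {
  s <- toy_template()
  expect_error(proton_sites(s, c("a", "a"), c(1, 5), c(2, 6)),
               class = "polypka_input_error")
  expect_error(proton_sites(s, c("a", "b"), c(1, 5), c(3, 6)),   # C, not H
               class = "polypka_input_error")
  expect_error(proton_sites(s, c("a", "b"), c(1, 5), c(2, 2)),   # duplicate proton
               class = "polypka_input_error")
  expect_error(proton_sites(s, c("a", "b"), c(1, 99), c(2, 6)),  # out of bounds
               class = "polypka_input_error")
})

test_that("per-microstate geometries enumerate completely with conserved charges", {
  s <- toy_template(); sites <- toy_sites(s)
  dir <- withr::local_tempdir()
  man <- prepare_microstate_geometries(s, sites, dir)
  expect_equal(nrow(man), 4)                       # 2^2
  expect_true(all(file.exists(man$path)))
  n <- nrow(sites)
  expect_equal(man$charge,
               s$net_charge - (n - man$n_protons))  # charge conservation
  # the all-ones file equals the template geometry (title aside)
  full <- read_xyz(man$path[man$microstate == "11"])
  expect_equal(full$atoms, s$atoms, tolerance = 1e-6)
  expect_equal(full$net_charge, s$net_charge)
  # deterministic ordering: descending proton count, lexicographic within
  expect_equal(man$microstate, c("11", "01", "10", "00"))
  # stripped file parses with the right atom count
  none <- read_xyz(man$path[man$microstate == "00"])
  expect_equal(nrow(none$atoms), nrow(s$atoms) - 2)
})
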