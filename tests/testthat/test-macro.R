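test_that("a single-site ladder is the microscopic pKa", {
  tc <- thermo_constants()
  m <- site_interaction_model(9.0)
  tab <- surrogate_free_energies(m, tc)
  for (mode in c("min_state", "boltzmann")) {
    lad <- macro_pka_ladder(tab, tc, mode = mode)
    expect_equal(nrow(lad), 1)
    expect_equal(lad$pka, 9.0, tolerance = 1e-9)
  }
})

test_that("two identical non-interacting sites split by the statistical factor log10(2)", {
  tc <- thermo_constants()
  p <- 7.4
  m <- site_interaction_model(c(p, p))
  tab <- surrogate_free_energies(m, tc)
  lad <- macro_pka_ladder(tab, tc, mode = "boltzmann")
  expect_equal(lad$pka[1], p + log10(2), tolerance = 1e-9)  # most basic step
  expect_equal(lad$pka[2], p - log10(2), tolerance = 1e-9)
})

test_that("min-state and Boltzmann ladders agree within log10(max protomers per charge)", {
  tc <- thermo_constants()
  for (seed in 1:5) {
    m <- rand_model(4, seed + 100)
    tab <- surrogate_free_energies(m, tc)
    l1 <- macro_pka_ladder(tab, tc, mode = "min_state")
    l2 <- macro_pka_ladder(tab, tc, mode = "boltzmann")
    bound <- log10(6) + 1e-12   # binom(4, 2) = 6 protomers at worst
    expect_true(all(abs(l1$pka - l2$pka) <= 2 * bound))
  }
  # exact equality when every charge has a single state (N = 1)
  m1 <- site_interaction_model(5)
  t1 <- surrogate_free_energies(m1, tc)
  expect_equal(macro_pka_ladder(t1, tc, "min_state")$pka,
               macro_pka_ladder(t1, tc, "boltzmann")$pka, tolerance = 1e-12)
})

test_that("the ladder is invariant under a global energy shift", {
  tc <- thermo_constants()
  m <- rand_model(3, 9)
  tab <- surrogate_free_energies(m, tc)
  shifted <- free_energy_table(
    data.frame(molecule = tab$molecule, microstate = tab$microstate,
               conformer = tab$conformer, G = tab$G + 1234.5,
               method = tab$method),
    site_count = 3, reference_charge = 3)
  for (mode in c("min_state", "boltzmann"))
    expect_equal(macro_pka_ladder(tab, tc, mode)$pka,
                 macro_pka_ladder(shifted, tc, mode)$pka, tolerance = 1e-9)
})

test_that("an empty charge level is a ladder-gap error naming the charge", {
  tc <- thermo_constants()
  m <- rand_model(2, 5)
  tab <- surrogate_free_energies(m, tc)
  gap <- tab[tab$charge != 1, ]   # drop every charge +1 protomer
  attr(gap, "site_count") <- 2L; attr(gap, "reference_charge") <- 2L
  class(gap) <- c("free_energy_table", "data.frame")
  expect_error(macro_pka_ladder(gap, tc), "\\+1",
               class = "polypka_missing_state_error")
})

test_that("dominant protomers pick the minimum-G microstate with deterministic tie-breaks", {
  tc <- thermo_constants()
  # site strengths (9, 6, 8, 3), no interactions: charge +2 keeps the two
  # strongest sites protonated -> "1010"
  m <- site_interaction_model(c(9, 6, 8, 3))
  tab <- surrogate_free_energies(m, tc)
  dp <- dominant_protomers(tab, tc)
  expect_equal(dp$microstate[dp$charge == 2], "1010")
  expect_true(all(dp$gap >= 0))
  # single state per charge reports an infinite gap
  d1 <- dominant_protomers(surrogate_free_energies(site_interaction_model(5), tc), tc)
  expect_true(all(is.infinite(d1$gap)))
  # exact tie: two identical sites -> lexicographically smaller id, with warning
  meq <- site_interaction_model(c(7, 7))
  expect_warning(dpe <- dominant_protomers(surrogate_free_energies(meq, tc), tc),
                 "tie")
  expect_equal(dpe$microstate[dpe$charge == 1], "01")
})

test_that("speciation fractions are normalized, continuous, and hit the Henderson-Hasselbalch midpoint", {
  tc <- thermo_constants()
  p <- 6.8
  tab <- surrogate_free_energies(site_interaction_model(p), tc)
  sp <- speciation_curves(tab, tc, pH_grid = seq(0, 14, 0.05))
  expect_true(all(abs(rowSums(sp$fractions) - 1) < 1e-12))
  at_pka <- speciation_curves(tab, tc, pH_grid = c(p - 0.1, p, p + 0.1))
  expect_equal(unname(at_pka$fractions[2, ]), c(0.5, 0.5), tolerance = 1e-9)
  # far below every pKa the fully protonated fraction -> 1
  expect_gt(sp$fractions[1, "1"], 1 - 1e-4)
  # charge aggregates are sums of their members
  expect_equal(unname(sp$charge_fractions[, "+1"]), unname(sp$fractions[, "1"]))
  expect_error(speciation_curves(tab, tc, pH_grid = c(3, 2, 5)),
               class = "polypka_input_error")
})

test_that("charge-fraction crossings coincide with the Boltzmann ladder", {
  tc <- thermo_constants()
  m <- rand_model(3, 42)
  tab <- surrogate_free_energies(m, tc)
  lad <- macro_pka_ladder(tab, tc, mode = "boltzmann")
  sp <- speciation_curves(tab, tc, pH_grid = seq(-2, 16, 0.001))
  mids <- titration_midpoints(sp, quiet = TRUE)
  # midpoints come out ordered highest charge pair first; ladder step 1 is
  # the most basic (lowest charge pair)
  expect_equal(rev(mids$pH), lad$pka, tolerance = 1e-6)
})

test_that("titration midpoints interpolate the crossing and warn when it is outside the grid", {
  tc <- thermo_constants()
  p <- 6.5
  tab <- surrogate_free_energies(site_interaction_model(p), tc)
  sp <- speciation_curves(tab, tc, pH_grid = seq(4, 9, 0.05))
  mids <- titration_midpoints(sp)
  expect_equal(mids$pH, p, tolerance = 1e-6)
  sp2 <- speciation_curves(tab, tc, pH_grid = seq(8, 14, 0.5))
  expect_warning(mids2 <- titration_midpoints(sp2), "does not cross")
  expect_equal(nrow(mids2), 0)
})

test_that("speciation and ladder exports are readable", {
  tc <- thermo_constants()
  tab <- surrogate_free_energies(rand_model(2, 77), tc)
  sp <- speciation_curves(tab, tc, pH_grid = seq(0, 14, 0.5))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_speciation_csv(sp, csv)
  back <- read.csv(csv, check.names = FALSE)
  expect_equal(nrow(back), length(sp$pH))
  expect_true(all(c("pH", "charge_+2") %in% names(back)))
  lad <- macro_pka_ladder(tab, tc)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_macro_ladder(lad, tsv, "tsv")
  write_macro_ladder(lad, jsn, "json")
  expect_equal(read.delim(tsv)$pka, lad$pka, tolerance = 1e-9)
  expect_equal(jsonlite::read_json(jsn)$mode, "min_state")
})
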