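test_that("proton free-energy components reproduce their reference values", {
  tc <- thermo_constants()
  # (5/2)RT - T*S0 at 298.15 K, S0 = 26.05 cal/(mol K)
  expect_equal(gas_phase_proton_G(tc), -6.2856, tolerance = 1e-4)
  expect_equal(round(gas_phase_proton_G(tc), 2), -6.29)
  expect_lt(abs(gas_phase_proton_G(tc) - (-6.28)), 0.01)
  expect_equal(standard_state_correction(tc), 1.8942, tolerance = 1e-4)
  expect_lt(abs(standard_state_correction(tc) - 1.89), 0.01)
  expect_equal(proton_free_energy(tc), -270.29, tolerance = 1e-4)
  expect_equal(tc$RT_ln10, 1.3642, tolerance = 1e-4)
})

test_that("proton free energy responds correctly to its parameters", {
  tc <- thermo_constants()
  # doubling the gas-phase entropy lowers G0 by T*S0/1000
  tc2 <- thermo_constants(S0_gas_proton = 2 * 26.05)
  expect_equal(gas_phase_proton_G(tc) - gas_phase_proton_G(tc2),
               298.15 * 26.05 / 1000, tolerance = 1e-9)
  # T -> 0 limit: both terms vanish
  t0 <- thermo_constants(T = 1e-9)
  expect_lt(abs(gas_phase_proton_G(t0)), 1e-6)
  expect_lt(abs(standard_state_correction(t0)), 1e-6)
  # standard-state correction is monotone increasing in T
  Ts <- c(100, 200, 298.15, 400)
  ss <- vapply(Ts, function(T) standard_state_correction(thermo_constants(T = T)),
               numeric(1))
  expect_true(all(diff(ss) > 0))
  # removing the solvation term: -6.286 + 1.894
  expect_equal(proton_free_energy(thermo_constants(dG_solv_proton = 0)),
               -4.39, tolerance = 0.005)
  # linear in dG_solv_proton with unit slope
  d <- proton_free_energy(thermo_constants(dG_solv_proton = -260)) -
    proton_free_energy(thermo_constants(dG_solv_proton = -265))
  expect_equal(d, 5, tolerance = 1e-12)
  expect_error(thermo_constants(T = -1), class = "polypka_input_error")
})

test_that("micro_pka implements the proton-based cycle", {
  tc <- thermo_constants()
  # zero numerator by construction
  expect_equal(micro_pka(0, -proton_free_energy(tc), tc), 0, tolerance = 1e-12)
  # inverse arithmetic: (284.93 - 270.2914)/1.364244
  expect_equal(micro_pka(0, 284.93, tc), 10.73, tolerance = 0.005)
  # global shift invariance and antisymmetry
  set.seed(41)
  for (i in 1:20) {
    gd <- runif(1, -1000, 0); ga <- runif(1, -1000, 0); c0 <- runif(1, -500, 500)
    expect_equal(micro_pka(gd + c0, ga + c0, tc), micro_pka(gd, ga, tc),
                 tolerance = 1e-9)
    expect_equal(micro_pka(ga, gd, tc), -micro_pka(gd, ga, tc) +
                   2 * proton_free_energy(tc) / tc$RT_ln10, tolerance = 1e-9)
  }
  expect_error(micro_pka(NA_real_, 0, tc), class = "polypka_input_error")
})

test_that("water-referenced cycle coincides with the proton cycle when the hydronium/water gap equals G(H+)", {
  tc <- thermo_constants()
  gd <- -431.7; ga <- -157.2
  gw <- -47911.0
  gh3o <- gw + proton_free_energy(tc)
  expect_equal(micro_pka_water_cycle(gd, ga, gw, gh3o, tc),
               micro_pka(gd, ga, tc), tolerance = 1e-9)
  # shifting all four energies changes nothing; swapping donor/acceptor flips sign
  expect_equal(micro_pka_water_cycle(gd + 3, ga + 3, gw + 3, gh3o + 3, tc),
               micro_pka_water_cycle(gd, ga, gw, gh3o, tc), tolerance = 1e-9)
  expect_equal(micro_pka_water_cycle(ga, gd, gw, gh3o, tc, offset = -0),
               -(micro_pka_water_cycle(gd, ga, gw, gh3o, tc)) +
                 2 * (gh3o - gw) / tc$RT_ln10, tolerance = 1e-9)
  # the offset hook is linear with slope 1/(RT ln10)
  expect_equal(micro_pka_water_cycle(gd, ga, gw, gh3o, tc, offset = tc$RT_ln10) -
                 micro_pka_water_cycle(gd, ga, gw, gh3o, tc), 1, tolerance = 1e-12)
})

test_that("state free energy selects the lowest conformer, or the Boltzmann ensemble value", {
  tc <- thermo_constants()
  tab <- free_energy_table(
    data.frame(molecule = "m", microstate = c("1", "1", "1", "0"),
               conformer = c(1L, 2L, 3L, 1L), G = c(10, 12, 11, 5)),
    site_count = 1, reference_charge = 1)
  expect_equal(state_free_energy(tab, "1"), 10)
  gb <- state_free_energy(tab, "1", mode = "boltzmann", constants = tc)
  expect_lt(gb, 10)                          # log-sum-exp bound
  expect_gt(gb, 10 - tc$RT * log(3))         # at most RT log(m) below the min
  expect_error(state_free_energy(tab, "1", molecule = "zzz"),
               class = "polypka_key_error")
  tab2 <- suppressWarnings(tab[tab$microstate == "1", ])
  attr(tab2, "site_count") <- 1L
  expect_error(state_free_energy(tab2, "0"), class = "polypka_missing_state_error")
})

test_that("a Hartree table and its kcal/mol conversion give identical pKa", {
  tc <- thermo_constants()
  set.seed(7)
  ms <- enumerate_microstates(c("a", "b"), 2)
  Gh <- -runif(4, 100, 101)   # Hartree-scale energies
  rec_h <- data.frame(molecule = "m", microstate = ms$microstate,
                      conformer = 1L, G = Gh, unit = "hartree")
  rec_k <- data.frame(molecule = "m", microstate = ms$microstate,
                      conformer = 1L, G = Gh * tc$hartree_to_kcal,
                      unit = "kcal_mol")
  t1 <- free_energy_table(rec_h, 2, 2)
  t2 <- free_energy_table(rec_k, 2, 2)
  p1 <- all_micro_pkas(t1, constants = tc)
  p2 <- all_micro_pkas(t2, constants = tc)
  expect_equal(p1$pka, p2$pka, tolerance = 1e-9)
})

test_that("thermodynamic cycle closure holds on every hypercube square", {
  tc <- thermo_constants()
  for (seed in 1:5) {
    m <- rand_model(4, seed)
    tab <- surrogate_free_energies(m, tc)
    mp <- all_micro_pkas(tab, constants = tc)
    key <- paste(mp$donor, mp$acceptor)
    pka <- setNames(mp$pka, key)
    ms <- enumerate_microstates(paste0("s", 1:4), 4)
    for (id in ms$microstate) {
      on <- which(strsplit(id, "")[[1]] == "1")
      if (length(on) < 2) next
      for (pair in utils::combn(on, 2, simplify = FALSE)) {
        flip <- function(s, i) { b <- strsplit(s, "")[[1]]; b[i] <- "0"; paste(b, collapse = "") }
        i <- pair[1]; j <- pair[2]
        lhs <- pka[paste(id, flip(id, i))] + pka[paste(flip(id, i), flip(flip(id, i), j))]
        rhs <- pka[paste(id, flip(id, j))] + pka[paste(flip(id, j), flip(flip(id, j), i))]
        expect_lt(abs(lhs - rhs), 1e-9)
      }
    }
  }
})
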