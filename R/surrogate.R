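#' Site-interaction surrogate model
#'
#' A synthetic stand-in for the external conformer-sampling + DFT stages:
#' each of N titratable sites has an intrinsic pKa `p_i`, and simultaneous
#' protonation of sites i and j costs an interaction penalty `eps_ij` (log
#' units, symmetric, zero diagonal). The implied microstate free energies
#' are constructed so that the microscopic pKa of deprotonating site i from
#' microstate s is exactly
#' \deqn{pK_a(s, i) = p_i - \sum_{j \ne i} s_j \epsilon_{ij}}
#' which gives every downstream stage a known ground truth. Optionally,
#' extra conformers offset by U(0, `conformer_spread`) and per-conformer
#' Gaussian noise N(0, `noise_sd`) emulate conformational-sampling error,
#' the dominant stochastic stage of the real pipeline.
#'
#' @param intrinsic_pk numeric vector of per-site intrinsic pKa (log units);
#'   its length sets N.
#' @param interaction symmetric N x N matrix of pairwise penalties in log
#'   units with zero diagonal, or a single number applied to every pair.
#' @param conformer_spread nonnegative width (kcal/mol) of the uniform
#'   offset of extra conformers.
#' @param noise_sd nonnegative sd (kcal/mol) of per-conformer Gaussian noise.
#' @param n_conformers conformers emitted per microstate (>= 1).
#' @param seed integer RNG seed; fixing it makes the emitted table
#'   reproducible record-for-record.
#' @return object of class `site_interaction_model`.
#' @examples
#' m <- site_interaction_model(c(9, 6, 8, 3))
#' tab <- surrogate_free_energies(m)
#' macro_pka_ladder(tab)
#' @export
site_interaction_model <- function(intrinsic_pk, interaction = 0,
                                   conformer_spread = 0, noise_sd = 0,
                                   n_conformers = 1L, seed = 1L) {
  p <- as.numeric(intrinsic_pk)
  n <- length(p)
  if (!n || !all(is.finite(p))) pk_input_error("intrinsic_pk must be finite and nonempty")
  if (length(interaction) == 1L) {
    eps <- matrix(as.numeric(interaction), n, n); diag(eps) <- 0
  } else eps <- as.matrix(interaction)
  if (!identical(dim(eps), c(n, n)) || !isSymmetric(unname(eps)) ||
      any(diag(eps) != 0) || !all(is.finite(eps)))
    pk_input_error("interaction must be a finite symmetric %dx%d matrix with zero diagonal", n, n)
  if (conformer_spread < 0 || noise_sd < 0)
    pk_input_error("conformer_spread and noise_sd must be nonnegative")
  n_conformers <- as.integer(n_conformers)
  if (n_conformers < 1L) pk_input_error("n_conformers must be >= 1")
  out <- list(intrinsic_pk = p, interaction = eps,
              conformer_spread = conformer_spread, noise_sd = noise_sd,
              n_conformers = n_conformers, seed = as.integer(seed))
  class(out) <- "site_interaction_model"
  out
}

#' @export
print.site_interaction_model <- function(x, ...) {
  cat(sprintf("Site-interaction surrogate: %d sites, intrinsic pKa = %s\n",
              length(x$intrinsic_pk),
              paste(format(x$intrinsic_pk), collapse = ", ")))
  if (any(x$interaction != 0)) {
    cat("  pairwise penalties (log units):\n")
    print(x$interaction)
  } else cat("  non-interacting sites\n")
  if (x$noise_sd > 0 || x$n_conformers > 1L)
    cat(sprintf("  %d conformer(s)/state, spread U(0, %.2f), noise sd %.2f kcal/mol, seed %d\n",
                x$n_conformers, x$conformer_spread, x$noise_sd, x$seed))
  invisible(x)
}

# Noiseless microstate free energy implied by the model, kcal/mol; the fully
# deprotonated state sits at 0 (ladders are shift-invariant, so the anchor
# is arbitrary but fixed).
surrogate_state_G <- function(model, occupancy, tc) {
  GH <- proton_free_energy(tc)
  s <- as.numeric(occupancy)
  inter <- 0
  if (sum(s) > 1) {
    on <- which(s == 1)
    pairs <- utils::combn(on, 2L)
    inter <- sum(model$interaction[t(pairs)])
  }
  -sum(s * (model$intrinsic_pk * tc$RT_ln10 - GH)) + inter * tc$RT_ln10
}

#' Ground-truth microscopic pKa of a surrogate model
#'
#' Closed form `p_i - sum_{j != i} s_j eps_ij` for deprotonating site `i`
#' out of microstate `s` (which must have site `i` protonated).
#'
#' @param model a [site_interaction_model()].
#' @param donor bitstring id of the protonated microstate.
#' @param site index (1-based) of the site being deprotonated.
#' @return pKa in log units.
#' @export
surrogate_micro_pka <- function(model, donor, site) {
  s <- as.integer(strsplit(donor, "")[[1]])
  if (length(s) != length(model$intrinsic_pk))
    pk_input_error("donor bitstring length does not match the model")
  if (s[site] != 1L) pk_input_error("site %d is not protonated in '%s'", site, donor)
  others <- setdiff(which(s == 1L), site)
  model$intrinsic_pk[site] - sum(model$interaction[site, others])
}

#' Generate a synthetic free-energy table from a surrogate model
#'
#' Emits a [free_energy_table()] over all 2^N microstates whose implied
#' microscopic pKa equal the model's closed form exactly (when noiseless
#' with a single conformer). The table is indistinguishable in format from
#' one produced by the real quantum-chemistry pipeline, so every downstream
#' stage can be exercised against known ground truth.
#'
#' @param model a [site_interaction_model()].
#' @param constants a [thermo_constants()].
#' @param molecule molecule id recorded in the table.
#' @return a [free_energy_table()] with `reference_charge = N` (all sites
#'   protonated = charge +N, fully deprotonated neutral).
#' @export
surrogate_free_energies <- function(model, constants = thermo_constants(),
                                    molecule = "surrogate") {
  tc <- as_thermo_constants(constants)
  n <- length(model$intrinsic_pk)
  ms <- enumerate_microstates(paste0("s", seq_len(n)), reference_charge = n)
  stochastic <- model$noise_sd > 0 || model$n_conformers > 1L
  if (stochastic) {
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      old <- get(".Random.seed", envir = .GlobalEnv)
      on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
    }
    set.seed(model$seed)
  }
  recs <- vector("list", nrow(ms))
  for (i in seq_len(nrow(ms))) {
    occ <- as.integer(strsplit(ms$microstate[i], "")[[1]])
    G0 <- surrogate_state_G(model, occ, tc)
    G <- rep(G0, model$n_conformers)
    if (model$n_conformers > 1L)
      G[-1L] <- G[-1L] + stats::runif(model$n_conformers - 1L, 0, model$conformer_spread)
    if (model$noise_sd > 0)
      G <- G + stats::rnorm(model$n_conformers, 0, model$noise_sd)
    recs[[i]] <- data.frame(molecule = molecule, microstate = ms$microstate[i],
                            conformer = seq_len(model$n_conformers), G = G,
                            method = "surrogate", stringsAsFactors = FALSE)
  }
  free_energy_table(do.call(rbind, recs), site_count = n, reference_charge = n)
}

#' Reference macroscopic ladder of a surrogate model
#'
#' Computes the model's exact macroscopic ladder by the titration
#' (binding) polynomial, entirely in log10 space and without ever forming
#' free energies: the cumulative association weight of microstate s is
#' `w(s) = sum_i s_i p_i - sum_{i<j} s_i s_j eps_ij`, the k-proton
#' cumulative constant is `log10 beta_k = log10 sum_{|s|=k} 10^w(s)`
#' (`max` instead of the sum in `min_state` mode), and step k of the
#' ladder is `log10 beta_k - log10 beta_(k-1)`. This is the independent
#' route against which the free-energy pipeline is checked in
#' [roundtrip_recovery()].
#'
#' @param model a [site_interaction_model()].
#' @param mode `"boltzmann"` or `"min_state"`.
#' @return numeric vector of step pKa, step 1 = most basic.
#' @export
surrogate_reference_ladder <- function(model, mode = c("boltzmann", "min_state")) {
  mode <- match.arg(mode)
  n <- length(model$intrinsic_pk)
  occ <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- apply(occ, 1L, function(s) {
    inter <- 0
    on <- which(s == 1)
    if (length(on) > 1) inter <- sum(model$interaction[t(utils::combn(on, 2L))])
    sum(s * model$intrinsic_pk) - inter
  })
  k <- rowSums(occ)
  log10beta <- vapply(0:n, function(kk) {
    wk <- w[k == kk]
    if (mode == "min_state") max(wk) else logsumexp(wk * log(10)) / log(10)
  }, numeric(1))
  diff(log10beta)   # step j = log10 beta_j - log10 beta_(j-1), j = 1..n
}

#' Round-trip recovery check: surrogate -> pipeline -> ladder
#'
#' Generates a free-energy table from the model, runs it through the full
#' thermodynamic-cycle + macroscopic-aggregation pipeline, and compares the
#' recovered ladder against the model's exact titration-polynomial ladder
#' ([surrogate_reference_ladder()]). For a noiseless model in Boltzmann
#' mode the two must agree to numerical precision; in min-state mode they
#' agree within the log-sum-exp bound `log10(m)` (m = largest number of
#' protomers per charge), which collapses to ~0 when sites are well
#' separated.
#'
#' @param model a [site_interaction_model()].
#' @param constants a [thermo_constants()].
#' @param mode ladder mode, as [macro_pka_ladder()].
#' @return list with `ladder` (pipeline steps), `reference` (polynomial
#'   steps), and `max_abs_deviation`, plus the generating `model`.
#' @export
roundtrip_recovery <- function(model, constants = thermo_constants(),
                               mode = c("boltzmann", "min_state")) {
  mode <- match.arg(mode)
  tc <- as_thermo_constants(constants)
  tab <- surrogate_free_energies(model, tc)
  lad <- macro_pka_ladder(tab, tc, mode = mode)
  ref <- surrogate_reference_ladder(model, mode = mode)
  list(ladder = lad$pka, reference = ref,
       max_abs_deviation = max(abs(lad$pka - ref)), model = model)
}
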