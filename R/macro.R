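#' Macroscopic stepwise pKa ladder
#'
#' Aggregates microstate free energies into the experimentally observable
#' stepwise pKa between adjacent total-charge states. In `"min_state"` mode
#' (the default) each charge state is represented by its lowest-energy
#' protomer, `pKa = [G_min(c-1) + G(H+) - G_min(c)] / (RT ln 10)`; in
#' `"boltzmann"` mode `G_min` is replaced by the per-charge ensemble free
#' energy `-RT log(sum_states exp(-G/RT))`, i.e. all protomers of a charge
#' contribute with Boltzmann weights. The two modes agree within
#' `log10(m)` where `m` is the largest number of protomers in any charge
#' state, and coincide when every charge has a single state.
#'
#' Steps are indexed from the most basic end: step 1 is the deprotonation of
#' the least-charged protonated species (charge `c_min+1 -> c_min`), step N
#' the deprotonation of the fully protonated species, matching the usual
#' ordering of stepwise protonation constants (pKa1 >= pKa2 >= ...).
#'
#' @param table a [free_energy_table()].
#' @param constants a [thermo_constants()].
#' @param mode `"min_state"` or `"boltzmann"`.
#' @param molecule molecule id (optional for single-molecule tables).
#' @param conformer_mode conformer aggregation within a microstate, as
#'   [state_free_energy()].
#' @return object of class `macro_ladder`: data.frame with columns `step`,
#'   `donor_charge`, `acceptor_charge`, `donor_microstate`,
#'   `acceptor_microstate` (the dominant protomer on each side) and `pka`,
#'   ordered step 1..N; attributes `mode`, `molecule`.
#' @examples
#' m <- site_interaction_model(intrinsic_pk = 9)
#' tab <- surrogate_free_energies(m)
#' macro_pka_ladder(tab)   # single step at pKa 9
#' @export
macro_pka_ladder <- function(table, constants = thermo_constants(),
                             mode = c("min_state", "boltzmann"),
                             molecule = NULL,
                             conformer_mode = c("min", "boltzmann")) {
  mode <- match.arg(mode)
  conformer_mode <- match.arg(conformer_mode)
  tc <- as_thermo_constants(constants)
  molecule <- table_molecule(table, molecule)
  cs <- charge_state_energies(table, tc, molecule, conformer_mode)
  n_steps <- nrow(cs) - 1L
  if (n_steps < 1L)
    pk_input_error("need at least two charge states to build a ladder")
  # cs is ordered by ascending charge; step k: charge cs[k+1] -> cs[k]
  Gq <- if (mode == "min_state") cs$G_min else cs$G_boltzmann
  steps <- data.frame(
    step = seq_len(n_steps),
    donor_charge = cs$charge[-1L],
    acceptor_charge = cs$charge[-nrow(cs)],
    donor_microstate = cs$microstate[-1L],
    acceptor_microstate = cs$microstate[-nrow(cs)],
    pka = (Gq[-nrow(cs)] + proton_free_energy(tc) - Gq[-1L]) / tc$RT_ln10,
    stringsAsFactors = FALSE)
  attr(steps, "mode") <- mode
  attr(steps, "molecule") <- molecule
  class(steps) <- c("macro_ladder", "data.frame")
  steps
}

#' @export
print.macro_ladder <- function(x, digits = 2, ...) {
  cat(sprintf("Macroscopic pKa ladder for '%s' (%s mode):\n",
              attr(x, "molecule"), attr(x, "mode")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  pKa%d = %s   (charge %+d -> %+d, %s -> %s)\n",
                x$step[i], formatC(x$pka[i], digits = digits, format = "f", width = digits + 4L),
                x$donor_charge[i], x$acceptor_charge[i],
                x$donor_microstate[i], x$acceptor_microstate[i]))
  invisible(x)
}

# Per-charge aggregate free energies, ascending charge; errors if any charge
# level of the enumeration has no record at all ("ladder gap").
charge_state_energies <- function(table, tc, molecule, conformer_mode = "min") {
  rows <- table[table$molecule == molecule, , drop = FALSE]
  n <- attr(table, "site_count")
  ref <- attr(table, "reference_charge")
  all_charges <- (ref - n):ref
  gap <- setdiff(all_charges, unique(rows$charge))
  if (length(gap))
    pk_missing_state("no free energies at charge state(s) %s; cannot bridge the ladder",
                     paste(sprintf("%+d", gap), collapse = ", "))
  res <- lapply(all_charges, function(ch) {
    ids <- sort(unique(rows$microstate[rows$charge == ch]))
    G <- vapply(ids, function(id)
      state_free_energy(table, id, molecule, conformer_mode, tc), numeric(1))
    o <- order(G, ids)   # lexicographic tie-break on equal G
    data.frame(charge = ch, microstate = ids[o[1L]],
               G_min = G[o[1L]],
               G_boltzmann = -tc$RT * logsumexp(-G / tc$RT),
               n_states = length(ids), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Most stable protomer at each charge state
#'
#' For every charge level, the microstate with minimal free energy, its G,
#' and the gap to the runner-up (an `Inf` sentinel when the charge has a
#' single state). Exact ties are broken deterministically towards the
#' lexicographically smallest bitstring, with a warning carrying the gap —
#' relevant for the symmetry-redundant microstates the enumeration
#' deliberately retains.
#'
#' @inheritParams macro_pka_ladder
#' @return data.frame of class `protomer_assignment` with columns `charge`,
#'   `microstate`, `G`, `gap`, `n_states`, ordered by descending charge.
#' @export
dominant_protomers <- function(table, constants = thermo_constants(),
                               molecule = NULL,
                               conformer_mode = c("min", "boltzmann")) {
  conformer_mode <- match.arg(conformer_mode)
  tc <- as_thermo_constants(constants)
  molecule <- table_molecule(table, molecule)
  rows <- table[table$molecule == molecule, , drop = FALSE]
  charges <- sort(unique(rows$charge), decreasing = TRUE)
  res <- lapply(charges, function(ch) {
    ids <- sort(unique(rows$microstate[rows$charge == ch]))
    G <- vapply(ids, function(id)
      state_free_energy(table, id, molecule, conformer_mode, tc), numeric(1))
    o <- order(G, ids)
    gap <- if (length(ids) > 1L) G[o[2L]] - G[o[1L]] else Inf
    if (length(ids) > 1L && gap == 0)
      warning(sprintf("charge %+d: exact tie (gap = 0); choosing lexicographically smallest protomer '%s'",
                      ch, ids[o[1L]]), call. = FALSE)
    data.frame(charge = ch, microstate = ids[o[1L]], G = G[o[1L]],
               gap = gap, n_states = length(ids), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "molecule") <- molecule
  class(out) <- c("protomer_assignment", "data.frame")
  out
}

#' pH-dependent microstate populations
#'
#' Grand-canonical speciation: the population of microstate s at a given pH
#' is proportional to `exp(-[G(s) - n_s * mu_H] / RT)` where `n_s` is its
#' proton count and `mu_H(pH) = G(H+, aq) - RT ln10 * pH` is the proton
#' chemical potential. All arithmetic is done in log space (state energies
#' are hundreds of kcal/mol in real tables, far beyond naive `exp()`
#' range), and fractions at each pH sum to exactly 1 after normalization.
#'
#' @inheritParams macro_pka_ladder
#' @param pH_grid ascending numeric grid (default 0..14 step 0.05).
#' @param allow_missing acknowledge a table covering only a subset of the
#'   2^N microstates; absent states are treated as unpopulated.
#' @return object of class `speciation_profile`: list with `pH`,
#'   `fractions` (matrix pH x microstate), `charge_fractions` (matrix pH x
#'   charge, columns named by charge), `charges` (per-microstate charge),
#'   `molecule`.
#' @export
speciation_curves <- function(table, constants = thermo_constants(),
                              pH_grid = seq(0, 14, by = 0.05),
                              molecule = NULL, allow_missing = FALSE,
                              conformer_mode = c("min", "boltzmann")) {
  conformer_mode <- match.arg(conformer_mode)
  tc <- as_thermo_constants(constants)
  molecule <- table_molecule(table, molecule)
  if (length(pH_grid) < 2L || any(diff(pH_grid) <= 0))
    pk_input_error("pH_grid must be strictly ascending with >= 2 points")
  miss <- missing_microstates(table, molecule)[[molecule]]
  if (length(miss) && !allow_missing)
    pk_missing_state("table lacks microstate(s) %s; pass allow_missing = TRUE to speciate over the subset",
                     paste(miss, collapse = ", "))
  rows <- table[table$molecule == molecule, , drop = FALSE]
  ids <- sort(unique(rows$microstate))
  G <- vapply(ids, function(id)
    state_free_energy(table, id, molecule, conformer_mode, tc), numeric(1))
  np <- popcount_bits(ids)
  charge <- rows$charge[match(ids, rows$microstate)]
  muH <- proton_free_energy(tc) - tc$RT_ln10 * pH_grid
  # log-weight matrix: states x pH
  lw <- outer(-G / tc$RT, rep(1, length(pH_grid))) +
    outer(np / tc$RT, muH)
  fractions <- matrix(0, length(pH_grid), length(ids),
                      dimnames = list(NULL, ids))   # pH x states
  for (j in seq_along(pH_grid)) {
    w <- exp(lw[, j] - logsumexp(lw[, j]))
    fractions[j, ] <- w / sum(w)
  }
  uch <- sort(unique(charge), decreasing = TRUE)
  charge_fractions <- vapply(uch, function(ch)
    rowSums(fractions[, charge == ch, drop = FALSE]), numeric(length(pH_grid)))
  colnames(charge_fractions) <- sprintf("%+d", uch)
  out <- list(pH = pH_grid, fractions = fractions,
              charge_fractions = charge_fractions,
              charges = charge, molecule = molecule)
  class(out) <- "speciation_profile"
  out
}

#' @export
print.speciation_profile <- function(x, ...) {
  cat(sprintf("Speciation profile for '%s': %d microstates, %d charge states, pH %.2f..%.2f (%d points)\n",
              x$molecule, ncol(x$fractions), ncol(x$charge_fractions),
              min(x$pH), max(x$pH), length(x$pH)))
  mids <- titration_midpoints(x, quiet = TRUE)
  if (nrow(mids))
    cat("  charge-fraction crossings:",
        paste(sprintf("%s/%s at pH %.2f", mids$donor_charge, mids$acceptor_charge, mids$pH),
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @rdname speciation_curves
#' @param x a `speciation_profile`.
#' @param by plot per-charge aggregates (default) or per-microstate curves.
#' @param ... passed to [graphics::matplot()].
plot.speciation_profile <- function(x, by = c("charge", "microstate"), ...) {
  by <- match.arg(by)
  y <- if (by == "charge") x$charge_fractions else x$fractions
  graphics::matplot(x$pH, y, type = "l", lty = 1, lwd = 2,
                    xlab = "pH", ylab = "population fraction",
                    main = sprintf("Speciation of %s", x$molecule), ...)
  graphics::legend("right", legend = colnames(y), lty = 1, lwd = 2,
                   col = seq_len(ncol(y)), bty = "n", cex = 0.8)
  invisible(x)
}

#' Titration midpoints from a speciation profile
#'
#' The pH at which adjacent charge fractions are equal, located by linear
#' interpolation on the profile's grid. For a Boltzmann-mode system each
#' crossing coincides with the corresponding macroscopic ladder step. Pairs
#' that do not cross within the grid are omitted with a warning.
#'
#' @param profile a [speciation_curves()] result.
#' @param quiet suppress the no-crossing warning.
#' @return data.frame with columns `donor_charge`, `acceptor_charge`, `pH`.
#' @export
titration_midpoints <- function(profile, quiet = FALSE) {
  cf <- profile$charge_fractions
  chs <- colnames(cf)          # descending charge
  out <- list()
  for (i in seq_len(ncol(cf) - 1L)) {
    d <- cf[, i] - cf[, i + 1L]   # donor (higher charge) minus acceptor
    s <- which(d[-length(d)] * d[-1L] <= 0 & d[-length(d)] != d[-1L])
    if (!length(s)) {
      if (!quiet)
        warning(sprintf("charge pair %s/%s does not cross within the pH grid",
                        chs[i], chs[i + 1L]), call. = FALSE)
      next
    }
    j <- s[1L]
    pH <- profile$pH[j] + (0 - d[j]) * (profile$pH[j + 1L] - profile$pH[j]) /
      (d[j + 1L] - d[j])
    out[[length(out) + 1L]] <- data.frame(donor_charge = chs[i],
                                          acceptor_charge = chs[i + 1L],
                                          pH = pH, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(donor_charge = character(0),
                      acceptor_charge = character(0), pH = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export speciation and ladder results
#'
#' `write_speciation_csv()` writes pH, one column per microstate, and the
#' per-charge aggregates (columns `charge_<c>`); `write_macro_ladder()`
#' writes a ladder as TSV or JSON.
#'
#' @param profile a [speciation_curves()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_speciation_csv <- function(profile, path) {
  df <- data.frame(pH = profile$pH, check.names = FALSE)
  df <- cbind(df, as.data.frame(profile$fractions, check.names = FALSE))
  agg <- as.data.frame(profile$charge_fractions, check.names = FALSE)
  names(agg) <- paste0("charge_", names(agg))
  df <- cbind(df, agg)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_speciation_csv
#' @param ladder a [macro_pka_ladder()] result.
#' @param format `"tsv"` or `"json"`.
#' @export
write_macro_ladder <- function(ladder, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(ladder), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(list(molecule = attr(ladder, "molecule"),
                              mode = attr(ladder, "mode"),
                              steps = as.data.frame(ladder)),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
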