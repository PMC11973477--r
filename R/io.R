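# Packaged benchmark data: md5 checksums of the shipped TSVs, verified on
# every load so silent corruption of the reference values is impossible.
.reference_checksums <- c(
  table1 = "301dba4abd6df5108f1396a3082d7b81",
  table2 = "ca4ad49b549f506389dffb6434ffcfd7")

.reference_files <- c(
  table1 = "table1_macrocycle_benchmark.tsv",
  table2 = "table2_macrocycle_predictions.tsv")

#' Load the packaged tetra-aza macrocycle reference datasets
#'
#' `"table1"` is the experimental benchmark: 32 measured pKa across ten
#' substituted tetra-aza macrocycles paired with the computed (QM) values
#' of the preferred model chemistry (M06-2X/def2-TZVP/SMD, proton-based
#' cycle); step 1 is the most basic pKa of each molecule. The `source`
#' column preserves the literature citation tags of the measured values.
#' `"table2"` holds the published predictions (QM + LEC) for four
#' not-yet-synthesized macrocycles (molecules 11-14, two pKa each); these
#' require external quantum-chemistry runs to recompute and are packaged
#' for display/regression only.
#'
#' @param name `"table1"` or `"table2"`.
#' @param path optional override of the packaged file (still
#'   checksum-verified) — intended for tests.
#' @return data.frame: for table1 columns `molecule`, `step`,
#'   `experimental`, `computed`, `source`; for table2 `molecule`, `step`,
#'   `predicted`.
#' @export
load_reference_dataset <- function(name = c("table1", "table2"), path = NULL) {
  if (length(name) != 1L || !name %in% names(.reference_files))
    pk_key_error("unknown reference dataset '%s' (use 'table1' or 'table2')",
                 paste(name, collapse = ","))
  if (is.null(path))
    path <- system.file("extdata", .reference_files[[name]],
                        package = "polypka", mustWork = TRUE)
  sum_got <- unname(tools::md5sum(path))
  if (!identical(sum_got, unname(.reference_checksums[[name]])))
    pk_integrity("reference dataset '%s' failed its integrity check (md5 %s, expected %s)",
                 name, sum_got, .reference_checksums[[name]])
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  df$step <- as.integer(df$step)
  for (col in intersect(c("experimental", "computed", "predicted"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  df
}

#' Extract the Gibbs free energy from a quantum-chemistry log
#'
#' Scans a Gaussian-style text log for the marker line
#' `Sum of electronic and thermal Free Energies=` (whitespace-insensitive)
#' and returns the value of the LAST occurrence — i.e. the free energy of
#' the final (converged) evaluation — together with the number of matches.
#' Only this single marker is parsed; frequencies, thermal corrections and
#' the rest of the log are out of scope.
#'
#' @param path path to the log file, or a character vector of log lines
#'   via `text`.
#' @param text character vector of lines (alternative to `path`).
#' @return list with `G` (Hartree) and `n` (number of marker lines found).
#' @export
extract_free_energy <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path)) pk_input_error("supply path or text")
    if (!file.exists(path)) pk_input_error("file not found: %s", path)
    text <- readLines(path, warn = FALSE)
  }
  label <- if (is.null(path)) "<text>" else path
  pat <- "Sum\\s+of\\s+electronic\\s+and\\s+thermal\\s+Free\\s+Energies\\s*=\\s*(\\S+)"
  hits <- regmatches(text, regexec(pat, text))
  idx <- which(lengths(hits) == 2L)
  if (!length(idx))
    pk_stop("polypka_extraction_error",
            "%s: no 'Sum of electronic and thermal Free Energies=' marker found", label)
  raw <- hits[[idx[length(idx)]]][2L]
  G <- suppressWarnings(as.numeric(sub("[Dd]", "e", raw)))
  if (is.na(G))
    pk_parse_error("%s line %d: cannot parse free energy '%s'",
                   label, idx[length(idx)], raw)
  list(G = G, n = length(idx))
}

#' Pipeline run configuration
#'
#' Collects everything one pKa-prediction run needs: the site list, the
#' reference charge, thermodynamic constants, the ladder mode, the LEC
#' source, an optional output directory and the seed. Atom indices in the
#' site list are 1-based.
#'
#' @param site_labels ordered site labels (nonempty).
#' @param reference_charge charge of the fully protonated species.
#' @param constants a [thermo_constants()].
#' @param ladder_mode `"min_state"` or `"boltzmann"`.
#' @param lec `"none"`, `"fit_from_reference"` (refit on the packaged
#'   benchmark), or a list `list(a =, b =)` of explicit coefficients.
#' @param pH_grid speciation grid.
#' @param molecule molecule id the free-energy table is keyed by.
#' @param out_dir optional directory for TSV/CSV/JSON outputs.
#' @param seed integer seed recorded in the bundle (the deterministic
#'   pipeline itself consumes no randomness).
#' @return list of class `run_config`.
#' @export
run_config <- function(site_labels, reference_charge,
                       constants = thermo_constants(),
                       ladder_mode = c("min_state", "boltzmann"),
                       lec = "none",
                       pH_grid = seq(0, 14, by = 0.05),
                       molecule = NULL, out_dir = NULL, seed = 1L) {
  ladder_mode <- match.arg(ladder_mode)
  if (!length(site_labels)) pk_input_error("site_labels must be nonempty")
  if (is.list(lec)) {
    if (is.null(lec$a) || is.null(lec$b))
      pk_input_error("an explicit LEC needs both a and b")
  } else if (!lec %in% c("none", "fit_from_reference"))
    pk_input_error("lec must be 'none', 'fit_from_reference', or list(a=, b=)")
  out <- list(site_labels = as.character(site_labels),
              reference_charge = as.integer(reference_charge),
              constants = as_thermo_constants(constants),
              ladder_mode = ladder_mode, lec = lec, pH_grid = pH_grid,
              molecule = molecule, out_dir = out_dir, seed = as.integer(seed))
  class(out) <- "run_config"
  out
}

#' Run the full pKa pipeline on a free-energy table
#'
#' Chains enumeration, microscopic pKa, the macroscopic ladder, protomer
#' assignment, speciation and (optionally) the linear empirical correction
#' into one result bundle. Missing microstate energies are tolerated:
#' affected hypercube edges are skipped with a warning naming the states,
#' and speciation runs over the covered subset. When `config$out_dir` is
#' set, the roster, micro-pKa table, ladder (TSV + JSON), speciation CSV
#' and a machine-readable JSON summary are written there. The pipeline is
#' deterministic: identical config + table give an identical bundle.
#'
#' @param config a [run_config()].
#' @param energies a [free_energy_table()].
#' @return list of class `pka_pipeline_result` with elements `roster`,
#'   `micro_pkas`, `ladder`, `corrected_ladder` (NULL without LEC), `lec`,
#'   `protomers`, `speciation`, `midpoints`, `summary`.
#' @export
run_pipeline <- function(config, energies) {
  if (!inherits(config, "run_config")) pk_input_error("config must be a run_config()")
  if (!inherits(energies, "free_energy_table"))
    pk_input_error("energies must be a free_energy_table()")
  if (attr(energies, "site_count") != length(config$site_labels))
    pk_input_error("free-energy table has N = %d but config lists %d sites",
                   attr(energies, "site_count"), length(config$site_labels))
  tc <- config$constants
  molecule <- table_molecule(energies, config$molecule)

  roster <- enumerate_microstates(config$site_labels, config$reference_charge)
  edges <- deprotonation_edges(roster)
  micro <- all_micro_pkas(energies, edges, tc, molecule = molecule)
  ladder <- macro_pka_ladder(energies, tc, mode = config$ladder_mode,
                             molecule = molecule)
  protomers <- dominant_protomers(energies, tc, molecule = molecule)
  missing <- missing_microstates(energies, molecule)[[molecule]]
  spec <- speciation_curves(energies, tc, pH_grid = config$pH_grid,
                            molecule = molecule,
                            allow_missing = length(missing) > 0)
  mids <- titration_midpoints(spec, quiet = TRUE)

  lec_fit <- NULL; corrected <- NULL
  if (is.list(config$lec)) {
    lec_fit <- lec_model(config$lec$a, config$lec$b)
  } else if (config$lec == "fit_from_reference") {
    lec_fit <- fit_lec(load_reference_dataset("table1"))
  }
  if (!is.null(lec_fit)) {
    corrected <- ladder
    corrected$pka <- predict(lec_fit, ladder$pka)
  }

  summary <- list(
    molecule = molecule,
    n_sites = length(config$site_labels),
    reference_charge = config$reference_charge,
    ladder_mode = config$ladder_mode,
    missing_microstates = as.character(missing),
    ladder = as.data.frame(ladder),
    corrected_ladder = if (!is.null(corrected)) as.data.frame(corrected),
    lec = if (!is.null(lec_fit)) list(a = lec_fit$a, b = lec_fit$b),
    protomers = as.data.frame(protomers),
    titration_midpoints = mids,
    seed = config$seed)

  bundle <- list(roster = roster, micro_pkas = micro, ladder = ladder,
                 corrected_ladder = corrected, lec = lec_fit,
                 protomers = protomers, speciation = spec, midpoints = mids,
                 summary = summary)
  class(bundle) <- "pka_pipeline_result"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    write_microstate_roster(roster, file.path(od, "microstates.tsv"))
    utils::write.table(as.data.frame(micro), file.path(od, "micro_pkas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_macro_ladder(ladder, file.path(od, "macro_ladder.tsv"), "tsv")
    write_macro_ladder(ladder, file.path(od, "macro_ladder.json"), "json")
    if (!is.null(corrected))
      write_macro_ladder(corrected, file.path(od, "macro_ladder_corrected.tsv"), "tsv")
    write_speciation_csv(spec, file.path(od, "speciation.csv"))
    jsonlite::write_json(summary, file.path(od, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  bundle
}

#' @export
print.pka_pipeline_result <- function(x, ...) {
  cat(sprintf("pKa pipeline result for '%s'\n", x$summary$molecule))
  if (length(x$summary$missing_microstates))
    cat("  (partial table; missing microstates:",
        paste(x$summary$missing_microstates, collapse = " "), ")\n")
  print(x$ladder)
  if (!is.null(x$corrected_ladder)) {
    cat(sprintf("After LEC (a = %.3f, b = %.3f):\n", x$lec$a, x$lec$b))
    print(x$corrected_ladder)
  }
  invisible(x)
}
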