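#' Per-microstate, per-conformer free-energy table
#'
#' The pipeline's central exchange format: one row per (molecule,
#' microstate, conformer, method) with a Gibbs free energy. This is the
#' product of the external conformer-sampling + DFT stages (or of
#' [surrogate_free_energies()]); the package converts everything to
#' kcal/mol on ingest and works in kcal/mol internally.
#'
#' @param records data.frame with columns `molecule`, `microstate`,
#'   `conformer` (integer rank >= 1), `G` and optionally `unit`
#'   (`"kcal_mol"` or `"hartree"`, default kcal/mol) and `method`.
#' @param site_count number of exchangeable sites N; every microstate id
#'   must be a bitstring of this length.
#' @param reference_charge net charge of the all-ones microstate.
#' @return object of class `free_energy_table`: a data.frame with columns
#'   `molecule`, `microstate`, `charge`, `conformer`, `G` (kcal/mol),
#'   `method`, with attributes `site_count` and `reference_charge`.
#' @export
free_energy_table <- function(records, site_count, reference_charge) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("molecule", "microstate", "conformer", "G")
  miss <- setdiff(need, names(records))
  if (length(miss))
    pk_input_error("records lack column(s): %s", paste(miss, collapse = ", "))
  site_count <- as.integer(site_count)
  reference_charge <- as.integer(reference_charge)
  records$molecule <- as.character(records$molecule)
  records$microstate <- as.character(records$microstate)
  records$conformer <- as.integer(records$conformer)
  if (any(records$conformer < 1L)) pk_input_error("conformer ranks must be >= 1")
  if (is.null(records$method)) records$method <- "unspecified"
  if (!is.null(records$unit)) {
    unit <- as.character(records$unit)
    bad <- !unit %in% c("kcal_mol", "hartree")
    if (any(bad)) pk_input_error("unknown unit(s): %s",
                                 paste(unique(unit[bad]), collapse = ", "))
    h <- unit == "hartree"
    records$G[h] <- records$G[h] * thermo_constants()$hartree_to_kcal
    records$unit <- NULL
  }
  if (!all(is.finite(records$G))) pk_input_error("free energies must be finite")
  ok_id <- grepl("^[01]+$", records$microstate) & nchar(records$microstate) == site_count
  if (any(!ok_id))
    pk_input_error("microstate id(s) not %d-bit strings: %s", site_count,
                   paste(unique(records$microstate[!ok_id]), collapse = ", "))
  key <- paste(records$molecule, records$microstate, records$conformer, records$method)
  if (anyDuplicated(key))
    pk_input_error("duplicate (molecule, microstate, conformer, method) rows")
  k <- popcount_bits(records$microstate)
  out <- data.frame(molecule = records$molecule,
                    microstate = records$microstate,
                    charge = reference_charge - (site_count - k),
                    conformer = records$conformer,
                    G = records$G,
                    method = as.character(records$method),
                    stringsAsFactors = FALSE)
  attr(out, "site_count") <- site_count
  attr(out, "reference_charge") <- reference_charge
  class(out) <- c("free_energy_table", "data.frame")
  out
}

#' @export
print.free_energy_table <- function(x, ...) {
  cat(sprintf("Free-energy table: %d record(s), %d molecule(s), N = %d sites, reference charge %+d\n",
              nrow(x), length(unique(x$molecule)),
              attr(x, "site_count"), attr(x, "reference_charge")))
  miss <- missing_microstates(x)
  for (mol in names(miss))
    if (length(miss[[mol]]))
      cat(sprintf("  molecule %s missing %d microstate(s): %s\n", mol,
                  length(miss[[mol]]), paste(miss[[mol]], collapse = " ")))
  print.data.frame(utils::head(as.data.frame(x), 8L), row.names = FALSE)
  if (nrow(x) > 8L) cat(sprintf("  ... %d more rows\n", nrow(x) - 8L))
  invisible(x)
}

#' Read / write the free-energy TSV interchange format
#'
#' Tab-separated with a mandatory header and `#` comment lines; columns
#' `molecule`, `microstate`, `charge`, `conformer`, `G`, `unit`
#' (`hartree` or `kcal_mol`), `method`. Hartree values are converted to
#' kcal/mol on ingest. The `charge` column is redundant (derivable from the
#' bitstring) and is cross-checked against `reference_charge`.
#'
#' @param path file path.
#' @param site_count,reference_charge as in [free_energy_table()]; when
#'   `NULL`, `site_count` is inferred from the id length and the reference
#'   charge from the `charge` column of a fully protonated row.
#' @return a [free_energy_table()].
#' @export
read_free_energy_tsv <- function(path, site_count = NULL, reference_charge = NULL) {
  if (!file.exists(path)) pk_input_error("file not found: %s", path)
  # everything as character first: bitstring ids like "0011" must keep
  # their leading zeros
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) pk_parse_error("%s: %s", path, conditionMessage(e)))
  need <- c("molecule", "microstate", "charge", "conformer", "G", "unit", "method")
  miss <- setdiff(need, names(df))
  if (length(miss))
    pk_parse_error("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  for (col in c("charge", "conformer", "G")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v)))
      pk_parse_error("%s: non-numeric value in column '%s' (row %d)",
                     path, col, which(is.na(v))[1L])
    df[[col]] <- v
  }
  df$microstate <- gsub("\\s", "", as.character(df$microstate))
  if (is.null(site_count)) site_count <- nchar(df$microstate[1L])
  if (is.null(reference_charge)) {
    full <- df$microstate == strrep("1", site_count)
    if (!any(full))
      pk_input_error("%s: cannot infer reference charge (no fully protonated row); pass reference_charge=", path)
    reference_charge <- df$charge[which(full)[1L]]
  }
  tab <- free_energy_table(df, site_count = site_count,
                           reference_charge = reference_charge)
  if (any(tab$charge != df$charge))
    pk_input_error("%s: charge column inconsistent with microstate bitstrings", path)
  tab
}

#' @rdname read_free_energy_tsv
#' @param table a `free_energy_table` to write (always written in kcal/mol).
#' @export
write_free_energy_tsv <- function(table, path) {
  df <- as.data.frame(table)
  df$unit <- "kcal_mol"
  df <- df[, c("molecule", "microstate", "charge", "conformer", "G", "unit", "method")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# polypka free-energy table; G in kcal/mol", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

table_molecule <- function(table, molecule = NULL) {
  mols <- unique(table$molecule)
  if (is.null(molecule)) {
    if (length(mols) != 1L)
      pk_input_error("table contains %d molecules (%s); pass molecule=",
                     length(mols), paste(mols, collapse = ", "))
    return(mols)
  }
  if (!molecule %in% mols) pk_key_error("molecule '%s' not in table", molecule)
  molecule
}

missing_microstates <- function(table, molecule = NULL) {
  n <- attr(table, "site_count")
  all_ids <- enumerate_microstates(paste0("s", seq_len(n)),
                                   attr(table, "reference_charge"))$microstate
  mols <- if (is.null(molecule)) unique(table$molecule) else molecule
  out <- lapply(mols, function(m)
    setdiff(all_ids, table$microstate[table$molecule == m]))
  names(out) <- mols
  out
}

#' Free energy of one protonation state
#'
#' Aggregates the conformer ensemble of a microstate into a single state
#' free energy: by default the minimum over conformers (i.e. the lowest
#' energy conformation represents the protonation state); optionally the
#' Boltzmann ensemble free energy `-RT log(sum(exp(-G_i/RT)))`, which is
#' always <= the minimum.
#'
#' @param table a [free_energy_table()].
#' @param molecule molecule id (may be omitted for single-molecule tables).
#' @param microstate bitstring id.
#' @param mode `"min"` or `"boltzmann"`.
#' @param constants [thermo_constants()] (Boltzmann mode only).
#' @return kcal/mol.
#' @export
state_free_energy <- function(table, microstate, molecule = NULL,
                              mode = c("min", "boltzmann"),
                              constants = thermo_constants()) {
  mode <- match.arg(mode)
  molecule <- table_molecule(table, molecule)
  g <- table$G[table$molecule == molecule & table$microstate == microstate]
  if (!length(g))
    pk_missing_state("no free-energy record for molecule '%s' microstate '%s'",
                     molecule, microstate)
  if (mode == "min") return(min(g))
  tc <- as_thermo_constants(constants)
  -tc$RT * logsumexp(-g / tc$RT)
}

#' Microscopic pKa of every deprotonation edge
#'
#' Applies the proton-based thermodynamic cycle across the whole microstate
#' hypercube: one microscopic pKa per (donor, acceptor) edge, in edge order.
#' In the default non-strict mode, edges touching microstates absent from
#' the table are skipped with a warning naming them; `strict = TRUE` turns
#' that into an error.
#'
#' @param table a [free_energy_table()].
#' @param edges a [deprotonation_edges()] result; computed from the table's
#'   own site count when omitted.
#' @param constants a [thermo_constants()].
#' @param molecule molecule id (optional for single-molecule tables).
#' @param mode conformer aggregation, as [state_free_energy()].
#' @param strict error (rather than warn) on missing microstates.
#' @return data.frame of class `micro_pka_set`: columns `donor`, `acceptor`,
#'   `site`, `pka`.
#' @export
all_micro_pkas <- function(table, edges = NULL, constants = thermo_constants(),
                           molecule = NULL, mode = c("min", "boltzmann"),
                           strict = FALSE) {
  mode <- match.arg(mode)
  tc <- as_thermo_constants(constants)
  molecule <- table_molecule(table, molecule)
  n <- attr(table, "site_count")
  if (is.null(edges)) {
    ms <- enumerate_microstates(paste0("s", seq_len(n)),
                                attr(table, "reference_charge"))
    edges <- deprotonation_edges(ms)
  }
  present <- unique(table$microstate[table$molecule == molecule])
  needed <- union(edges$donor, edges$acceptor)
  absent <- setdiff(needed, present)
  if (length(absent)) {
    if (strict)
      pk_missing_state("missing free energies for microstate(s): %s",
                       paste(absent, collapse = ", "))
    warning(sprintf("skipping %d edge(s); missing microstate(s): %s",
                    sum(edges$donor %in% absent | edges$acceptor %in% absent),
                    paste(absent, collapse = ", ")), call. = FALSE)
    edges <- edges[!(edges$donor %in% absent | edges$acceptor %in% absent), , drop = FALSE]
  }
  G <- vapply(unique(c(edges$donor, edges$acceptor)), function(id)
    state_free_energy(table, id, molecule, mode, tc), numeric(1))
  out <- data.frame(donor = edges$donor, acceptor = edges$acceptor,
                    site = edges$site,
                    pka = micro_pka(G[edges$donor], G[edges$acceptor], tc),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("micro_pka_set", "data.frame")
  out
}
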