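#' Molecular structure container
#'
#' A minimal 3D structure: an ordered atom table (element symbol, Cartesian
#' coordinates in Angstrom), a net charge in elementary charges, and a free
#' text title. This is all the downstream microstate machinery needs; bond
#' perception, conformer generation and protonation-site auto-detection are
#' deliberately out of scope.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`.
#' @param net_charge integer net charge.
#' @param title free-text title.
#' @return object of class `molecular_structure`.
#' @export
molecular_structure <- function(atoms, net_charge = 0L, title = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    pk_input_error("atoms must have columns element, x, y, z")
  atoms <- atoms[, need]
  if (nrow(atoms) < 1L) pk_input_error("structure must contain at least one atom")
  atoms$element <- as.character(atoms$element)
  bad <- !atoms$element %in% .periodic_symbols
  if (any(bad))
    pk_input_error("invalid element symbol(s): %s",
                   paste(unique(atoms$element[bad]), collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!is.numeric(xyz) || !all(is.finite(xyz)))
    pk_input_error("coordinates must be finite numbers")
  out <- list(atoms = atoms, net_charge = as.integer(net_charge),
              title = as.character(title))
  class(out) <- "molecular_structure"
  out
}

#' @export
print.molecular_structure <- function(x, ...) {
  comp <- table(x$atoms$element)
  cat(sprintf("Molecular structure '%s': %d atoms (%s), net charge %+d\n",
              x$title, nrow(x$atoms),
              paste(sprintf("%s%d", names(comp), as.integer(comp)), collapse = " "),
              x$net_charge))
  invisible(x)
}

# IUPAC element symbols 1..118
.periodic_symbols <- c(
  "H","He","Li","Be","B","C","N","O","F","Ne","Na","Mg","Al","Si","P","S",
  "Cl","Ar","K","Ca","Sc","Ti","V","Cr","Mn","Fe","Co","Ni","Cu","Zn","Ga",
  "Ge","As","Se","Br","Kr","Rb","Sr","Y","Zr","Nb","Mo","Tc","Ru","Rh","Pd",
  "Ag","Cd","In","Sn","Sb","Te","I","Xe","Cs","Ba","La","Ce","Pr","Nd","Pm",
  "Sm","Eu","Gd","Tb","Dy","Ho","Er","Tm","Yb","Lu","Hf","Ta","W","Re","Os",
  "Ir","Pt","Au","Hg","Tl","Pb","Bi","Po","At","Rn","Fr","Ra","Ac","Th","Pa",
  "U","Np","Pu","Am","Cm","Bk","Cf","Es","Fm","Md","No","Lr","Rf","Db","Sg",
  "Bh","Hs","Mt","Ds","Rg","Cn","Nh","Fl","Mc","Lv","Ts","Og")

#' Read a molecular structure from XYZ or SDF
#'
#' XYZ files are plain Angstrom coordinates; since XYZ has no native charge
#' field, a `charge=<int>` token on the comment line (as written by
#' [write_xyz()]) is honoured, else `charge` is used, else 0. SDF V2000 files
#' take the net charge from the `M  CHG` block when present (sum of formal
#' charges).
#'
#' @param path file path.
#' @param format `"xyz"`, `"sdf"`, or `"auto"` (resolve from extension).
#' @param charge fallback net charge when the file does not carry one.
#' @return a [molecular_structure()].
#' @export
read_structure <- function(path, format = c("auto", "xyz", "sdf"), charge = 0L) {
  format <- match.arg(format)
  if (!file.exists(path)) pk_input_error("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", sdf = "sdf", mol = "sdf",
                     pk_input_error("cannot resolve format from extension '.%s' (use format=)", ext))
  }
  switch(format, xyz = read_xyz(path, charge = charge), sdf = read_sdf(path, charge = charge))
}

#' @rdname read_structure
#' @export
read_xyz <- function(path, charge = 0L) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) pk_parse_error("%s: truncated XYZ (need count + comment lines)", path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    pk_parse_error("%s line 1: expected positive atom count, got '%s'", path, lines[1L])
  title <- lines[2L]
  if (length(lines) < 2L + n)
    pk_parse_error("%s: header promises %d atoms but only %d atom lines present",
                   path, n, length(lines) - 2L)
  el <- character(n); xyz <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ln <- 2L + i
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4L)
      pk_parse_error("%s line %d: malformed atom line '%s'", path, ln, lines[ln])
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(v)))
      pk_parse_error("%s line %d: non-numeric coordinate in '%s'", path, ln, lines[ln])
    el[i] <- tok[1L]; xyz[i, ] <- v
  }
  m <- regmatches(title, regexec("charge=(-?[0-9]+)", title))[[1]]
  if (length(m) == 2L) charge <- as.integer(m[2L])
  molecular_structure(data.frame(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                      net_charge = charge, title = title)
}

#' @rdname read_structure
#' @export
read_sdf <- function(path, charge = 0L) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L) pk_parse_error("%s: truncated SDF", path)
  title <- lines[1L]
  counts <- lines[4L]
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  if (is.na(natoms) || natoms < 1L)
    pk_parse_error("%s line 4: bad counts line '%s'", path, counts)
  if (length(lines) < 4L + natoms)
    pk_parse_error("%s: counts line promises %d atoms but block is short", path, natoms)
  el <- character(natoms); xyz <- matrix(NA_real_, natoms, 3L)
  for (i in seq_len(natoms)) {
    ln <- 4L + i
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4L)
      pk_parse_error("%s line %d: malformed atom line '%s'", path, ln, lines[ln])
    v <- suppressWarnings(as.numeric(tok[1:3]))
    if (any(is.na(v)))
      pk_parse_error("%s line %d: non-numeric coordinate", path, ln)
    xyz[i, ] <- v; el[i] <- tok[4L]
  }
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    total <- 0L
    for (cl in chg_lines) {
      tok <- strsplit(trimws(sub("^M  CHG\\s+[0-9]+", "", cl)), "\\s+")[[1]]
      vals <- suppressWarnings(as.integer(tok))
      # entries are (atom index, charge) pairs; sum the charges
      if (length(vals) %% 2L != 0L || any(is.na(vals)))
        pk_parse_error("%s: malformed M CHG line '%s'", path, cl)
      total <- total + sum(vals[seq(2L, length(vals), by = 2L)])
    }
    charge <- total
  }
  molecular_structure(data.frame(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                      net_charge = charge, title = title)
}

#' Write a structure as XYZ or SDF V2000
#'
#' XYZ comment lines carry `charge=<int>` (and `microstate=<bitstring>` when
#' given) so downstream tools can recover metadata XYZ cannot natively hold.
#' SDF output is V2000 with an explicit `M  CHG` entry (the whole net charge
#' on atom 1 — a carrier for the net charge, not a chemical assignment) so
#' the charge round-trips bit-exactly. Coordinates are written to 6 decimal
#' places in XYZ and 4 in SDF (the V2000 fixed-width field).
#'
#' @param structure a [molecular_structure()].
#' @param path output path.
#' @param microstate optional bitstring recorded on the XYZ comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path, microstate = NULL) {
  a <- structure$atoms
  comment <- sprintf("charge=%d", structure$net_charge)
  if (!is.null(microstate)) comment <- sprintf("%s microstate=%s", comment, microstate)
  lines <- c(sprintf("%d", nrow(a)), comment,
             sprintf("%-3s %14.6f %14.6f %14.6f", a$element, a$x, a$y, a$z))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
write_sdf <- function(structure, path) {
  a <- structure$atoms
  lines <- c(structure$title, "  polypka", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), 0L),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     a$x, a$y, a$z, a$element))
  if (structure$net_charge != 0L)
    lines <- c(lines, sprintf("M  CHG  1 %3d %3d", 1L, structure$net_charge))
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, path)
  invisible(path)
}

#' Define exchangeable proton sites on a structure
#'
#' Each site names a heavy atom and the exchangeable proton bonded to it.
#' Atom indices are 1-based (both here and in user-facing config files).
#'
#' @param structure the fully protonated template [molecular_structure()].
#' @param labels distinct short site labels, e.g. `c("N1","N2")`. Their
#'   order defines microstate bitstring positions.
#' @param heavy_atom integer indices of the heavy atoms.
#' @param proton_atom integer indices of the exchangeable protons (must be H).
#' @param site_class per-site chemical class, one of `"aliphatic_amine"`,
#'   `"pyridine"`, `"oxygen"`, `"other"` (recycled).
#' @return data.frame of class `proton_sites` with columns `label`,
#'   `heavy_atom`, `proton_atom`, `site_class`.
#' @export
proton_sites <- function(structure, labels, heavy_atom, proton_atom,
                         site_class = "other") {
  n <- length(labels)
  if (anyDuplicated(labels)) pk_input_error("site labels must be distinct")
  if (length(heavy_atom) != n || length(proton_atom) != n)
    pk_input_error("labels, heavy_atom, proton_atom must have equal length")
  heavy_atom <- as.integer(heavy_atom); proton_atom <- as.integer(proton_atom)
  natoms <- nrow(structure$atoms)
  if (any(heavy_atom < 1L | heavy_atom > natoms | proton_atom < 1L | proton_atom > natoms))
    pk_input_error("atom index out of bounds (structure has %d atoms)", natoms)
  if (any(heavy_atom == proton_atom))
    pk_input_error("heavy_atom and proton_atom must differ")
  if (anyDuplicated(proton_atom))
    pk_input_error("proton_atom indices must be distinct across sites")
  notH <- structure$atoms$element[proton_atom] != "H"
  if (any(notH))
    pk_input_error("proton_atom of site(s) %s is not a hydrogen",
                   paste(labels[notH], collapse = ", "))
  cls <- rep_len(as.character(site_class), n)
  ok <- c("aliphatic_amine", "pyridine", "oxygen", "other")
  if (!all(cls %in% ok))
    pk_input_error("site_class must be one of %s", paste(ok, collapse = ", "))
  out <- data.frame(label = as.character(labels), heavy_atom = heavy_atom,
                    proton_atom = proton_atom, site_class = cls,
                    stringsAsFactors = FALSE)
  class(out) <- c("proton_sites", "data.frame")
  out
}

#' Remove exchangeable protons from a template structure
#'
#' Deletes exactly the protons of the named sites; all other atoms keep
#' their relative order, and the net charge drops by one per removed proton.
#' The geometry is written as-is — no re-optimization; relaxing the
#' deprotonated structures is the job of the external conformer-sampling /
#' DFT stages.
#'
#' @param template the fully protonated [molecular_structure()].
#' @param sites a [proton_sites()] table for the template.
#' @param remove character vector (a set) of site labels to deprotonate.
#' @return a [molecular_structure()] with `length(remove)` fewer atoms.
#' @export
strip_protons <- function(template, sites, remove = character(0)) {
  remove <- as.character(remove)
  if (anyDuplicated(remove))
    pk_input_error("duplicate labels in remove: %s",
                   paste(unique(remove[duplicated(remove)]), collapse = ", "))
  unknown <- setdiff(remove, sites$label)
  if (length(unknown))
    pk_key_error("unknown site label(s): %s", paste(unknown, collapse = ", "))
  if (!length(remove)) return(template)
  idx <- sites$proton_atom[match(remove, sites$label)]
  if (any(template$atoms$element[idx] != "H"))
    pk_input_error("site removal targets a non-hydrogen atom; sites do not match this structure")
  molecular_structure(template$atoms[-idx, , drop = FALSE],
                      net_charge = template$net_charge - length(remove),
                      title = template$title)
}

#' Write one geometry per protonation microstate
#'
#' Enumerates all 2^N microstates of the template (which must carry every
#' site's proton), strips the protons of the unoccupied sites of each, and
#' writes one XYZ file per microstate named by its occupancy bitstring.
#' Files are written in deterministic order: descending proton count, then
#' lexicographic bitstring. A TSV manifest (`manifest.tsv` in `out_dir`)
#' records microstate, charge, n_protons and path; the file charge always
#' satisfies `charge = template charge - (N - popcount)`.
#'
#' @param template fully protonated [molecular_structure()].
#' @param sites a [proton_sites()] table.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest data.frame.
#' @export
prepare_microstate_geometries <- function(template, sites, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    pk_stop("polypka_io_error", "cannot create output directory %s", out_dir)
  ms <- enumerate_microstates(sites$label, reference_charge = template$net_charge)
  paths <- character(nrow(ms))
  for (i in seq_len(nrow(ms))) {
    bits <- strsplit(ms$microstate[i], "")[[1]]
    off <- sites$label[bits == "0"]
    s <- strip_protons(template, sites, off)
    stem <- if (nzchar(ms$microstate[i])) ms$microstate[i] else "template"
    paths[i] <- file.path(out_dir, paste0(stem, ".xyz"))
    write_xyz(s, paths[i], microstate = ms$microstate[i])
  }
  manifest <- data.frame(microstate = ms$microstate, charge = ms$charge,
                         n_protons = ms$n_protons, path = paths,
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
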