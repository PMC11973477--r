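#' Enumerate protonation microstates
#'
#' Generates every assignment of protons to the N exchangeable sites of a
#' polyprotic molecule — all 2^N microstates — by removing all possible
#' combinations of protons from the fully protonated reference species.
#' Each microstate is identified by an occupancy bitstring in user site
#' order ("1" = site protonated), e.g. `"1011"`, and carries net charge
#' `reference_charge - (N - popcount)`.
#'
#' Spatial symmetry is deliberately not used: microstates that are redundant
#' by molecular symmetry (e.g. protonation on either of two symmetry
#' equivalent amines) are all retained, so per-charge counts are exactly
#' binomial. For a 4-site molecule that means 1/4/6/4/1 states at charges
#' +4..0 — 16 in total. (The statistical-factor consequences of retaining
#' redundant states are discussed in the package vignette.)
#'
#' @param site_labels character vector of distinct site labels, in the order
#'   that defines bitstring positions (e.g. `c("N1","N2","N3","N4")`).
#' @param reference_charge integer net charge of the fully protonated
#'   (all-ones) species.
#'
#' @return An object of class `microstate_set`: a data.frame with columns
#'   `microstate` (bitstring id), `n_protons`, `charge`, and
#'   `sites_protonated` (comma-joined labels), ordered by descending proton
#'   count then lexicographic bitstring; attributes `site_labels`,
#'   `n_sites`, `reference_charge`.
#' @examples
#' ms <- enumerate_microstates(c("N1", "N2", "N3", "N4"), reference_charge = 4)
#' table(ms$charge)   # 1 4 6 4 1
#' @export
enumerate_microstates <- function(site_labels, reference_charge = length(site_labels)) {
  site_labels <- as.character(site_labels)
  n <- length(site_labels)
  if (anyDuplicated(site_labels))
    pk_input_error("site labels must be distinct")
  if (n > 20L)
    pk_capacity("N = %d sites would give %.3g microstates; the enumeration is capped at N = 20. Split the titratable sites or treat subsets independently.",
                n, 2^n)
  reference_charge <- as.integer(reference_charge)

  if (n == 0L) {
    occ <- matrix(integer(0), nrow = 1L, ncol = 0L)
  } else {
    # rows of the occupancy matrix: one microstate per row
    occ <- as.matrix(expand.grid(rep(list(c(1L, 0L)), n))[, n:1, drop = FALSE])
  }
  ids <- apply(occ, 1L, paste, collapse = "")
  if (n == 0L) ids <- ""
  k <- as.integer(rowSums(occ))
  ord <- order(-k, ids)
  occ <- occ[ord, , drop = FALSE]
  ids <- ids[ord]
  k <- k[ord]

  sites_prot <- vapply(seq_along(ids), function(i) {
    paste(site_labels[occ[i, ] == 1L], collapse = ",")
  }, character(1))

  out <- data.frame(microstate = ids,
                    n_protons = k,
                    charge = reference_charge - (n - k),
                    sites_protonated = sites_prot,
                    stringsAsFactors = FALSE)
  attr(out, "site_labels") <- site_labels
  attr(out, "n_sites") <- n
  attr(out, "reference_charge") <- reference_charge
  attr(out, "symmetry_annotation") <- NULL
  class(out) <- c("microstate_set", "data.frame")
  out
}

#' @export
print.microstate_set <- function(x, ...) {
  cat(sprintf("Microstate set: %d sites (%s), reference charge %+d, %d microstates\n",
              attr(x, "n_sites"), paste(attr(x, "site_labels"), collapse = ","),
              attr(x, "reference_charge"), nrow(x)))
  tab <- table(factor(x$charge, levels = sort(unique(x$charge), decreasing = TRUE)))
  cat("  per-charge counts:",
      paste(sprintf("%+d:%d", as.integer(names(tab)), as.integer(tab)), collapse = "  "),
      "\n")
  ann <- attr(x, "symmetry_annotation")
  if (!is.null(ann) && length(ann))
    cat(sprintf("  symmetry annotation: %d group(s), enumeration NOT reduced\n", length(ann)))
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Deprotonation edges between microstates
#'
#' All ordered (donor, acceptor) pairs of microstates that differ by removal
#' of exactly one proton, labelled by the site that changes. The edges form
#' the N-dimensional hypercube: every microstate has degree N and there are
#' `N * 2^(N-1)` edges in total. Each edge realizes one microscopic
#' deprotonation `HA^n -> H+ + A^(n-1)`.
#'
#' @param set a [enumerate_microstates()] result.
#' @return data.frame with columns `donor`, `acceptor`, `site`, ordered by
#'   the set's microstate order (donors) then site order.
#' @export
deprotonation_edges <- function(set) {
  if (!inherits(set, "microstate_set"))
    pk_input_error("expected a 'microstate_set'; see enumerate_microstates()")
  labels <- attr(set, "site_labels")
  n <- attr(set, "n_sites")
  if (n == 0L)
    return(data.frame(donor = character(0), acceptor = character(0),
                      site = character(0), stringsAsFactors = FALSE))
  res <- vector("list", nrow(set))
  for (i in seq_len(nrow(set))) {
    id <- set$microstate[i]
    bits <- strsplit(id, "")[[1]]
    on <- which(bits == "1")
    if (!length(on)) next
    acceptors <- vapply(on, function(j) {
      b <- bits; b[j] <- "0"; paste(b, collapse = "")
    }, character(1))
    res[[i]] <- data.frame(donor = id, acceptor = acceptors,
                           site = labels[on], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Annotate symmetry-equivalent microstates (reporting only)
#'
#' Enumeration never deduplicates symmetry-equivalent microstates; this
#' helper only attaches a user-supplied annotation marking groups of
#' equivalent ids so reports can flag them. The set itself — including
#' `|states| = 2^N` — is unchanged.
#'
#' @param set a [enumerate_microstates()] result.
#' @param groups list of character vectors, each a group of
#'   symmetry-equivalent microstate ids (may be empty).
#' @return the same `microstate_set` with a `symmetry_annotation` attribute.
#' @export
annotate_symmetry_equivalents <- function(set, groups = list()) {
  if (!inherits(set, "microstate_set"))
    pk_input_error("expected a 'microstate_set'")
  if (!is.list(groups)) pk_input_error("groups must be a list of id vectors")
  for (g in groups) {
    unknown <- setdiff(g, set$microstate)
    if (length(unknown))
      pk_key_error("unknown microstate id(s) in annotation: %s",
                   paste(unknown, collapse = ", "))
  }
  attr(set, "symmetry_annotation") <- groups
  set
}

#' Write a microstate roster as TSV
#'
#' Columns: microstate, charge, n_protons, sites_protonated.
#'
#' @param set a `microstate_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_microstate_roster <- function(set, path) {
  if (!inherits(set, "microstate_set"))
    pk_input_error("expected a 'microstate_set'")
  df <- data.frame(microstate = set$microstate, charge = set$charge,
                   n_protons = set$n_protons,
                   sites_protonated = set$sites_protonated)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

popcount_bits <- function(id) {
  vapply(strsplit(id, ""), function(b) sum(b == "1"), numeric(1))
}
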