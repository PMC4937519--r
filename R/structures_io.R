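#' Van der Waals radii table
#'
#' Bondi-style van der Waals radii (in Angstrom) for the elements that occur
#' in crystallographic protein structures. Elements absent from the table fall
#' back to the carbon radius, which is conservative for occupancy marking.
#'
#' @param extra Optional named numeric vector of additional or overriding
#'   radii, names are element symbols (upper case).
#' @return Named numeric vector of radii in Angstrom.
#' @export
#' @examples
#' vdw_table()[["C"]]
vdw_table <- function(extra = NULL) {
  r <- c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
    P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
    I = 1.98, FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.31,
    MN = 2.00, CU = 1.40, "NA" = 2.27, K = 2.75
  )
  if (!is.null(extra)) r[toupper(names(extra))] <- extra
  stopifnot(all(r > 0))
  r
}

#' Look up van der Waals radii for element symbols
#'
#' @param elements Character vector of element symbols.
#' @param vdw Radii table from [vdw_table()].
#' @return Numeric vector of radii; unknown elements get the carbon radius.
#' @export
vdw_radius <- function(elements, vdw = vdw_table()) {
  r <- vdw[toupper(elements)]
  r[is.na(r)] <- vdw[["C"]]
  unname(r)
}

#' Half the van der Waals radius of a water molecule
#'
#' The increment added to each atomic radius when marking the solvent-excluded
#' volume, and to the probe sphere used for the lysine accessibility test:
#' half of the 2.8 A water diameter's vdW radius, 1.4 / 2 = 0.7 A.
#'
#' @return 0.7 (Angstrom).
#' @export
water_probe_increment <- function() {
  1.4 / 2
}

#' Maximum physical crosslink length
#'
#' The longest backbone-to-backbone (Calpha-Calpha) span a lysine-reactive
#' crosslinker can bridge in a rigid structure: the linker arm length plus one
#' fully extended lysine side chain at each end.
#'
#' @param linker_length Linker arm length in Angstrom (11.4 for BS3/DSS).
#' @param side_chain_length Length of an extended lysine side chain
#'   (~5.5 A).
#' @return Maximum physical crosslink length in Angstrom (22.4 for BS3/DSS).
#' @export
#' @examples
#' max_crosslink_length()  # 22.4
max_crosslink_length <- function(linker_length = 11.4, side_chain_length = 5.5) {
  stopifnot(linker_length > 0, side_chain_length >= 0)
  linker_length + 2 * side_chain_length
}

.water_resnames <- c("HOH", "WAT", "DOD", "H2O")

#' Construct a structure object from an atom table
#'
#' Low-level constructor used by the PDB reader and the synthetic-structure
#' generators. Performs altloc resolution (highest occupancy wins, ties go to
#' altloc "A" then file order) and validates uniqueness.
#'
#' @param atoms data.frame with columns serial, name, altloc, resname, chain,
#'   resno, x, y, z, occupancy, element, record ("ATOM"/"HETATM").
#' @param resolve_altloc Apply the altloc resolution rule (default TRUE).
#' @return An object of class `xl_structure`: list with `atoms` (the resolved
#'   atom table) and `nterm` (named integer, first residue number per chain,
#'   in file order).
#' @export
xl_structure <- function(atoms, resolve_altloc = TRUE) {
  need <- c("serial", "name", "altloc", "resname", "chain", "resno",
            "x", "y", "z", "occupancy", "element", "record")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("structure has no atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atomic coordinates")
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$occupancy <- pmin(pmax(atoms$occupancy, 0), 1)
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$resno <- as.integer(atoms$resno)
  atoms$serial <- as.integer(atoms$serial)

  if (resolve_altloc) {
    key <- paste(atoms$chain, atoms$resno, atoms$resname, atoms$name, sep = "|")
    if (anyDuplicated(key)) {
      # highest occupancy; tie -> altloc "A"; then first occurrence
      pref <- order(key,
                    -atoms$occupancy,
                    atoms$altloc != "A",
                    seq_len(nrow(atoms)))
      atoms <- atoms[pref, , drop = FALSE]
      atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno,
                                       atoms$resname, atoms$name, sep = "|")), ,
                     drop = FALSE]
      atoms <- atoms[order(match(atoms$serial, atoms$serial),
                           atoms$serial), , drop = FALSE]
    }
  } else {
    key <- paste(atoms$chain, atoms$resno, atoms$name, atoms$altloc, sep = "|")
    if (anyDuplicated(key)) stop("duplicate (chain, resno, name, altloc) atoms")
  }
  rownames(atoms) <- NULL

  chains <- unique(atoms$chain)
  nterm <- vapply(chains, function(ch) atoms$resno[atoms$chain == ch][1L],
                  integer(1))
  structure(list(atoms = atoms, nterm = nterm), class = "xl_structure")
}

#' @export
print.xl_structure <- function(x, ...) {
  a <- x$atoms
  cat("xl_structure:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno))), "residues,",
      length(x$nterm), "chain(s):", paste(names(x$nterm), collapse = " "), "\n")
  invisible(x)
}

#' Read a protein structure from a PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] that applies the conventions used
#' throughout the package: altlocs resolved to a single location (highest
#' occupancy, ties to "A"), hydrogens dropped, waters always dropped, other
#' heteroatoms dropped unless `include_het = TRUE` (in which case they act as
#' obstacles only). Element symbols missing from the file are inferred from
#' atom names.
#'
#' @param file Path to a PDB file.
#' @param remove_hydrogens Drop H/D atoms (default TRUE).
#' @param include_het Keep non-water HETATM records (default FALSE).
#' @return An [xl_structure()] object.
#' @export
read_structure <- function(file, remove_hydrogens = TRUE, include_het = FALSE) {
  pdb <- suppressWarnings(bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  a <- pdb$atom
  ele <- a$elesy
  bad <- is.na(ele) | ele == ""
  if (any(bad)) ele[bad] <- suppressWarnings(bio3d::atom2ele(a$elety[bad]))
  atoms <- data.frame(
    serial = a$eleno, name = a$elety, altloc = a$alt, resname = a$resid,
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    resno = a$resno, x = a$x, y = a$y, z = a$z,
    occupancy = a$o, element = toupper(ele), record = a$type,
    stringsAsFactors = FALSE
  )
  atoms <- atoms[!(atoms$record == "HETATM" & atoms$resname %in% .water_resnames), ,
                 drop = FALSE]
  if (!include_het) atoms <- atoms[atoms$record == "ATOM", , drop = FALSE]
  if (remove_hydrogens) atoms <- atoms[!(atoms$element %in% c("H", "D")), ,
                                       drop = FALSE]
  if (!nrow(atoms)) stop("no usable ATOM records in ", file)
  xl_structure(atoms)
}

#' Parse a protein structure from PDB-format text
#'
#' @param pdb_text Character vector (one element per line, or a single string
#'   with embedded newlines) of PDB-format text.
#' @inheritParams read_structure
#' @return An [xl_structure()] object.
#' @export
parse_structure <- function(pdb_text, remove_hydrogens = TRUE,
                            include_het = FALSE) {
  lines <- unlist(strsplit(paste(pdb_text, collapse = "\n"), "\n", fixed = TRUE))
  rec <- grepl("^(ATOM|HETATM)", lines)
  if (!any(rec)) {
    first <- if (length(lines)) lines[1L] else "<empty input>"
    stop("no ATOM/HETATM records; first line: ", first)
  }
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  writeLines(lines, f)
  read_structure(f, remove_hydrogens = remove_hydrogens,
                 include_het = include_het)
}

#' Write a structure to a PDB file
#'
#' @param structure An [xl_structure()] object.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_structure <- function(structure, file) {
  a <- structure$atoms
  bio3d::write.pdb(
    file = file,
    type = a$record, eleno = a$serial, elety = a$name, resid = a$resname,
    chain = a$chain, resno = a$resno,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    o = a$occupancy, b = rep(0, nrow(a)), elesy = a$element
  )
  invisible(file)
}

# --- crosslink records -------------------------------------------------------

.canonical_pairs <- function(chain_a, res_a, chain_b, res_b) {
  key_a <- sprintf("%s|%09d", chain_a, res_a)
  key_b <- sprintf("%s|%09d", chain_b, res_b)
  swap <- key_a > key_b
  data.frame(
    chain_a = ifelse(swap, chain_b, chain_a),
    res_a = ifelse(swap, res_b, res_a),
    chain_b = ifelse(swap, chain_a, chain_b),
    res_b = ifelse(swap, res_a, res_b),
    stringsAsFactors = FALSE
  )
}

.pair_id <- function(df) {
  paste(df$chain_a, df$res_a, df$chain_b, df$res_b, sep = ":")
}

#' Construct a crosslink dataset
#'
#' Canonicalizes each unordered residue pair (lexicographic by chain then
#' residue number) and records provenance. Duplicates and self-links are
#' rejected here; use [curate_crosslinks()] to filter raw tables instead.
#'
#' @param records data.frame with columns chain_a, res_a, chain_b, res_b and
#'   optionally linker (linker length in Angstrom).
#' @param provenance One of "experimental", "theoretical", "bootstrap".
#' @return Object of class `xl_dataset` (a data.frame with attributes).
#' @export
xl_dataset <- function(records,
                       provenance = c("experimental", "theoretical", "bootstrap")) {
  provenance <- match.arg(provenance)
  need <- c("chain_a", "res_a", "chain_b", "res_b")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("crosslink table lacks columns: ",
                         paste(miss, collapse = ", "))
  canon <- .canonical_pairs(as.character(records$chain_a),
                            as.integer(records$res_a),
                            as.character(records$chain_b),
                            as.integer(records$res_b))
  canon$linker <- if ("linker" %in% names(records))
    as.numeric(records$linker) else rep(NA_real_, nrow(canon))
  canon$link_type <- ifelse(canon$chain_a == canon$chain_b, "intra", "inter")
  if (any(canon$chain_a == canon$chain_b & canon$res_a == canon$res_b))
    stop("self-links present; curate the table first")
  if (anyDuplicated(.pair_id(canon)))
    stop("duplicate crosslink pairs present; curate the table first")
  structure(canon, class = c("xl_dataset", "data.frame"),
            provenance = provenance)
}

#' Read a crosslink table from CSV
#'
#' Expected header: `chain_a,res_a,chain_b,res_b[,linker]`.
#'
#' @param file CSV path.
#' @return data.frame of raw records (not yet curated).
#' @export
read_crosslinks <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("chain_a", "res_a", "chain_b", "res_b")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("crosslink CSV lacks columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Residues that can carry a lysine-reactive crosslink
#'
#' All lysines plus the first residue of every polypeptide chain (the
#' N-terminus). A chain-first residue without a CA atom (e.g. a het group or
#' obstacle pseudo-residue) is not a target.
#'
#' @param structure An [xl_structure()].
#' @return data.frame with chain, resno, resname, kind ("lysine"/"nterm").
#' @export
crosslinkable_residues <- function(structure) {
  a <- structure$atoms[structure$atoms$record == "ATOM", , drop = FALSE]
  res <- unique(a[, c("chain", "resno", "resname")])
  has_ca <- paste(res$chain, res$resno) %in%
    paste(a$chain, a$resno)[a$name == "CA"]
  is_lys <- res$resname == "LYS"
  is_nterm <- res$resno == structure$nterm[res$chain] & has_ca
  out <- res[is_lys | is_nterm, , drop = FALSE]
  out$kind <- ifelse(out$resname == "LYS", "lysine", "nterm")
  rownames(out) <- NULL
  out
}

#' Curate a raw crosslink table against a structure
#'
#' Applies, in order, the filtering rules used to clean literature-curated
#' crosslink databases: (1) drop records whose residues are absent from the
#' structure; (2) drop self-links; (3) drop records with an endpoint that is
#' neither a lysine nor a chain N-terminus; (4) drop duplicate unordered
#' pairs; (5) when `domains` is given, drop pairs whose endpoints fall in
#' different domains (inter-domain links).
#'
#' @param records Raw crosslink data.frame (chain_a, res_a, chain_b, res_b,
#'   optional linker), or an `xl_dataset`.
#' @param structure An [xl_structure()] the records refer to.
#' @param domains Optional data.frame with columns chain, start, end (one row
#'   per domain). An endpoint matching no domain is treated as outside every
#'   domain, so any pair involving it is removed when a filter is supplied.
#' @param provenance Provenance tag for the surviving set.
#' @return List with `dataset` (an [xl_dataset()]) and `removed`, a named
#'   integer vector of per-rule removal counts.
#' @export
curate_crosslinks <- function(records, structure, domains = NULL,
                              provenance = "experimental") {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  canon <- .canonical_pairs(as.character(df$chain_a), as.integer(df$res_a),
                            as.character(df$chain_b), as.integer(df$res_b))
  canon$linker <- if ("linker" %in% names(df)) as.numeric(df$linker)
                  else rep(NA_real_, nrow(canon))

  removed <- c(missing_residue = 0L, self_link = 0L, non_lysine = 0L,
               duplicate = 0L, interdomain = 0L)

  res <- unique(structure$atoms[, c("chain", "resno", "resname")])
  res_key <- paste(res$chain, res$resno)
  key_a <- paste(canon$chain_a, canon$res_a)
  key_b <- paste(canon$chain_b, canon$res_b)

  present <- key_a %in% res_key & key_b %in% res_key
  removed["missing_residue"] <- sum(!present)
  canon <- canon[present, , drop = FALSE]

  self <- canon$chain_a == canon$chain_b & canon$res_a == canon$res_b
  removed["self_link"] <- sum(self)
  canon <- canon[!self, , drop = FALSE]

  ok_res <- crosslinkable_residues(structure)
  ok_key <- paste(ok_res$chain, ok_res$resno)
  linkable <- paste(canon$chain_a, canon$res_a) %in% ok_key &
    paste(canon$chain_b, canon$res_b) %in% ok_key
  removed["non_lysine"] <- sum(!linkable)
  canon <- canon[linkable, , drop = FALSE]

  dup <- duplicated(.pair_id(canon))
  removed["duplicate"] <- sum(dup)
  canon <- canon[!dup, , drop = FALSE]

  if (!is.null(domains)) {
    dom_of <- function(chain, resno) {
      hit <- which(domains$chain == chain & domains$start <= resno &
                     domains$end >= resno)
      if (length(hit)) hit[1L] else NA_integer_
    }
    da <- mapply(dom_of, canon$chain_a, canon$res_a)
    db <- mapply(dom_of, canon$chain_b, canon$res_b)
    cross <- is.na(da) | is.na(db) | da != db
    removed["interdomain"] <- sum(cross)
    canon <- canon[!cross, , drop = FALSE]
  }

  rownames(canon) <- NULL
  list(dataset = xl_dataset(canon, provenance = provenance), removed = removed)
}

# --- scoring distribution ----------------------------------------------------

#' Fit the SASD scoring distribution
#'
#' Mean and sample standard deviation of the SASD values at or below the
#' fit cutoff; values above the cutoff are excluded. This is the normal
#' distribution MNXL uses to reward matched crosslinks (the reference table is
#' typically a curated crosslink database, e.g. an XLdb-style SASD column).
#'
#' @param sasd_values Numeric vector of SASDs in Angstrom.
#' @param fit_cutoff Only values `<= fit_cutoff` enter the fit (default 33).
#' @return Object of class `sasd_normal`: list(mu, sigma, fit_cutoff, n).
#' @export
#' @examples
#' fit_sasd_distribution(c(10, 20, 30, 40))  # mu 20, sigma 10
fit_sasd_distribution <- function(sasd_values, fit_cutoff = 33) {
  v <- sasd_values[is.finite(sasd_values) & sasd_values <= fit_cutoff]
  if (length(v) < 2)
    stop("need at least 2 SASD values <= ", fit_cutoff, " to fit; got ",
         length(v))
  sigma <- stats::sd(v)
  if (sigma <= 0) stop("degenerate fit: all retained SASD values are equal")
  structure(list(mu = mean(v), sigma = sigma, fit_cutoff = fit_cutoff,
                 n = length(v)),
            class = "sasd_normal")
}

#' @export
print.sasd_normal <- function(x, ...) {
  cat(sprintf("sasd_normal: mu = %.3f A, sigma = %.3f A (n = %d, cutoff %g A)\n",
              x$mu, x$sigma, x$n, x$fit_cutoff))
  invisible(x)
}

#' Write / read fitted distribution parameters as JSON
#'
#' @param params A `sasd_normal` object.
#' @param file Path to a JSON file.
#' @return `read_sasd_distribution` returns a `sasd_normal`.
#' @export
write_sasd_distribution <- function(params, file) {
  jsonlite::write_json(unclass(params), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_sasd_distribution
#' @export
read_sasd_distribution <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  structure(list(mu = x$mu, sigma = x$sigma, fit_cutoff = x$fit_cutoff,
                 n = x$n), class = "sasd_normal")
}

#' Fetch a PDB entry from the RCSB (network required)
#'
#' Convenience wrapper over [bio3d::get.pdb()] used for benchmark
#' reproduction; fails when offline.
#'
#' @param id 4-character PDB identifier.
#' @param path Download directory.
#' @return An [xl_structure()].
#' @export
fetch_structure <- function(id, path = tempdir()) {
  f <- suppressWarnings(bio3d::get.pdb(id, path = path, verbose = FALSE))
  if (!file.exists(f) || file.size(f) == 0)
    stop("could not retrieve PDB entry ", id, " (no network?)")
  read_structure(f)
}

#' Count lysines of one chain within a residue range
#'
#' @param structure An [xl_structure()].
#' @param chain Chain identifier.
#' @param range Length-2 integer vector of residue bounds (inclusive);
#'   NULL for the whole chain.
#' @return Integer count of distinct lysine residues.
#' @export
count_lysines <- function(structure, chain, range = NULL) {
  a <- structure$atoms
  sel <- a$chain == chain & a$resname == "LYS" & a$record == "ATOM"
  if (!is.null(range)) sel <- sel & a$resno >= range[1] & a$resno <= range[2]
  length(unique(a$resno[sel]))
}
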