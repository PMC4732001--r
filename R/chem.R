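# Molecular graph model: parsing, formulas, monoisotopic masses, InChIKeys.
#
# Structures are stored as plain lists (class "structure_graph") holding the
# heavy-atom graph with per-atom implicit hydrogen counts. OpenBabel (via
# ChemmineOB) does the SMILES/InChI/InChIKey heavy lifting; mass arithmetic
# uses an embedded isotope table so it is reproducible bit-for-bit.

# Principal-isotope exact masses (Da). CODATA/IUPAC monoisotopic values.
.ISOTOPE_MASS <- c(
  H = 1.0078250319, B = 11.0093054, C = 12.0, N = 14.0030740052,
  O = 15.9949146221, F = 18.9984032, Na = 22.98976928, Mg = 23.985041697,
  Al = 26.98153853, Si = 27.9769265347, P = 30.97376151, S = 31.97207069,
  Cl = 34.968852682, K = 38.9637069, Ca = 39.962590863, Fe = 55.934936,
  Cu = 62.929597, Zn = 63.929142, Se = 79.9165218, Br = 78.9183376,
  I = 126.904468
)

.ELECTRON_MASS <- 0.00054857990946
.PROTON_MASS <- .ISOTOPE_MASS[["H"]] - .ELECTRON_MASS  # 1.0072764520

# Allowed valences used to assign implicit hydrogens (smallest valence that
# accommodates the bond order sum wins). Metals get no implicit hydrogens.
.VALENCES <- list(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5),
  S = c(2, 4, 6), Cl = 1, Se = c(2, 4, 6), Br = 1, I = 1,
  Na = 0, Mg = 0, Al = 0, K = 0, Ca = 0, Fe = 0, Cu = 0, Zn = 0
)

#' Exact mass of a principal isotope
#'
#' @param element Element symbol (e.g. `"C"`).
#' @return Monoisotopic mass in Da.
#' @export
isotope_mass <- function(element) {
  m <- .ISOTOPE_MASS[element]
  if (anyNA(m)) {
    stop("no principal-isotope mass for element(s): ",
         paste(element[is.na(m)], collapse = ", "))
  }
  unname(m)
}

#' Mass of the proton and electron
#'
#' Constants used to convert between neutral and ionic masses.
#' @return Mass in Da.
#' @export
proton_mass <- function() .PROTON_MASS

#' @rdname proton_mass
#' @export
electron_mass <- function() .ELECTRON_MASS

.implicit_h <- function(element, bond_order_sum, charge = 0L) {
  vals <- .VALENCES[[element]]
  if (is.null(vals) || max(vals) == 0) return(0L)  # metals: never any H
  # Effective valence under formal charge: N+ -> 4, O- -> 1, C+ -> 3 ...
  vals <- if (element == "C") vals - abs(charge) else vals + charge
  need <- ceiling(bond_order_sum - 1e-9)
  ok <- vals[vals >= need]
  if (length(ok) == 0L) return(0L)
  as.integer(min(ok) - need)
}

.new_structure <- function(source_text, elements, charges, bonds_from,
                           bonds_to, bond_orders) {
  n <- length(elements)
  stopifnot(length(charges) == n, length(bonds_from) == length(bonds_to),
            length(bonds_from) == length(bond_orders))
  if (length(bonds_from)) {
    if (any(bonds_from < 1L | bonds_from > n | bonds_to < 1L | bonds_to > n))
      stop("bond references an invalid atom index")
    if (any(bonds_from == bonds_to)) stop("self-bond in structure")
    key <- paste(pmin(bonds_from, bonds_to), pmax(bonds_from, bonds_to))
    if (anyDuplicated(key)) stop("duplicate bond in structure")
  }
  osum <- numeric(n)
  for (k in seq_along(bonds_from)) {
    o <- if (bond_orders[k] >= 4) 1.5 else bond_orders[k]
    osum[bonds_from[k]] <- osum[bonds_from[k]] + o
    osum[bonds_to[k]] <- osum[bonds_to[k]] + o
  }
  hyd <- vapply(seq_len(n), function(i) {
    .implicit_h(elements[i], osum[i], charges[i])
  }, integer(1))
  structure(list(
    source_text = source_text,
    elements = elements,
    charges = as.integer(charges),
    hydrogens = hyd,
    bonds = cbind(from = as.integer(bonds_from), to = as.integer(bonds_to)),
    bond_orders = as.numeric(bond_orders)
  ), class = "structure_graph")
}

#' Number of heavy atoms / bonds in a structure
#' @param s A `structure_graph`.
#' @return Integer count.
#' @export
n_atoms <- function(s) length(s$elements)

#' @rdname n_atoms
#' @export
n_bonds <- function(s) nrow(s$bonds)

# Parse a V2000 MOL block (as emitted by OpenBabel) into a structure_graph.
.parse_molblock <- function(molblock, source_text = NULL) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) stop("truncated MOL block")
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nb)) stop("unreadable MOL counts line")
  atom_lines <- lines[4L + seq_len(na)]
  elements <- trimws(substr(atom_lines, 32, 34))
  charges <- integer(na)
  bond_lines <- if (nb > 0) lines[4L + na + seq_len(nb)] else character(0)
  bf <- as.integer(substr(bond_lines, 1, 3))
  bt <- as.integer(substr(bond_lines, 4, 6))
  bo <- as.integer(substr(bond_lines, 7, 9))
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    k <- toks[1]
    for (i in seq_len(k)) charges[toks[2 * i]] <- toks[2 * i + 1]
  }
  .new_structure(source_text %||% "", elements, charges, bf, bt, bo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a SMILES or InChI string into a molecular graph
#'
#' InChI input is recognised by its `InChI=` prefix; anything else is treated
#' as SMILES. Implicit hydrogens are assigned by standard valence rules on
#' the heavy-atom graph; hydrogens are never graph nodes.
#'
#' @param text A single SMILES or standard InChI string.
#' @param id Optional identifier used in error messages.
#' @return An object of class `structure_graph` with fields `source_text`,
#'   `elements`, `charges`, `hydrogens`, `bonds` (two-column index matrix)
#'   and `bond_orders` (1, 2, 3; 4 denotes aromatic).
#' @export
#' @examples
#' s <- parse_structure("CCO")
#' n_atoms(s)  # 3 heavy atoms
parse_structure <- function(text, id = NULL) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  fmt <- if (startsWith(text, "InChI=")) "INCHI" else "SMI"
  mol <- suppressWarnings(
    tryCatch(ChemmineOB::convertFormat(fmt, "SDF", text),
             error = function(e) "")
  )
  if (!nzchar(mol) || !grepl("V2000", mol, fixed = TRUE)) {
    stop("cannot parse structure",
         if (!is.null(id)) paste0(" for record '", id, "'") else "",
         ": ", text)
  }
  s <- .parse_molblock(mol, source_text = text)
  if (n_atoms(s) == 0L) {
    stop("structure has no heavy atoms",
         if (!is.null(id)) paste0(" (record '", id, "')") else "")
  }
  s
}

#' Net formal charge of a structure
#' @param s A `structure_graph`.
#' @return Integer net charge.
#' @export
net_charge <- function(s) sum(s$charges)

#' Molecular formula of a structure
#'
#' Counts include implicit hydrogens.
#'
#' @param s A `structure_graph`.
#' @return Named integer vector of element counts (class `chem_formula`),
#'   ordered by Hill convention (C, H, then alphabetical).
#' @export
#' @examples
#' molecular_formula(parse_structure("CCO"))  # C2 H6 O1
molecular_formula <- function(s) {
  counts <- table(s$elements)
  f <- setNames(as.integer(counts), names(counts))
  hs <- sum(s$hydrogens)
  if (hs > 0) f["H"] <- (if ("H" %in% names(f)) f[["H"]] else 0L) + hs
  as_formula(f)
}

#' Build a formula object from element counts
#' @param counts Named integer vector, element symbol -> count.
#' @return Named integer vector of class `chem_formula` in Hill order with
#'   zero counts dropped.
#' @export
as_formula <- function(counts) {
  counts <- counts[counts > 0]
  els <- names(counts)
  bad <- setdiff(els, names(.ISOTOPE_MASS))
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  structure(as.integer(counts[hill]), names = hill, class = "chem_formula")
}

#' @export
format.chem_formula <- function(x, ...) {
  if (length(x) == 0L) return("")
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Parse a molecular formula string
#' @param text Formula string such as `"C9H12O3S"`.
#' @return A `chem_formula`.
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks) || sum(nchar(toks)) != nchar(text))
    stop("cannot parse formula: ", text)
  counts <- integer(0)
  for (t in toks) {
    el <- sub("[0-9]*$", "", t)
    k <- sub("^[A-Z][a-z]?", "", t)
    k <- if (nzchar(k)) as.integer(k) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + k
  }
  as_formula(counts)
}

#' Monoisotopic mass of a formula
#'
#' Sum of principal-isotope exact masses over the element counts.
#'
#' @param f A `chem_formula` (or named count vector), or a `structure_graph`.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass(parse_formula("H2O"))  # 18.0106
monoisotopic_mass <- function(f) {
  if (inherits(f, "structure_graph")) f <- molecular_formula(f)
  if (length(f) == 0L) return(0)
  sum(isotope_mass(names(f)) * as.numeric(f))
}

#' Standard InChIKey of a structure
#'
#' @param s A `structure_graph` or a character vector of SMILES/InChI.
#' @return 27-character InChIKey(s).
#' @export
inchikey <- function(s) {
  texts <- if (inherits(s, "structure_graph")) s$source_text else s
  stopifnot(is.character(texts))
  out <- character(length(texts))
  is_inchi <- startsWith(texts, "InChI=")
  for (grp in unique(is_inchi)) {
    idx <- which(is_inchi == grp)
    res <- suppressWarnings(ChemmineOB::convertFormat(
      if (grp) "INCHI" else "SMI", "INCHIKEY",
      paste0(texts[idx], collapse = "\n")))
    keys <- strsplit(res, "\n", fixed = TRUE)[[1]]
    keys <- trimws(keys)
    if (length(keys) != length(idx) || any(nchar(keys) != 27L)) {
      stop("InChIKey generation failed for ",
           length(idx) - sum(nchar(keys) == 27L), " record(s)")
    }
    out[idx] <- keys
  }
  out
}

#' First block of the InChIKey
#'
#' The first 14 characters of the standard InChIKey encode the molecular
#' skeleton (connectivity) without stereochemistry; stereoisomers of the same
#' skeleton share a first block.
#'
#' @inheritParams inchikey
#' @return 14-character uppercase string(s).
#' @export
inchikey_first_block <- function(s) substr(inchikey(s), 1L, 14L)

#' Is the heavy-atom bond graph connected?
#'
#' Salts and other multi-component records return `FALSE`.
#'
#' @param s A `structure_graph`.
#' @return Logical scalar.
#' @export
is_connected <- function(s) {
  n <- n_atoms(s)
  if (n <= 1L) return(TRUE)
  .is_connected_graph(seq_len(n), s$bonds)
}

# Connectivity of the subgraph induced by `atoms` using rows of `bonds`
# (two-column matrix) whose endpoints are both in `atoms`.
.is_connected_graph <- function(atoms, bonds) {
  n <- length(atoms)
  if (n <= 1L) return(TRUE)
  pos <- integer(max(atoms))
  pos[atoms] <- seq_len(n)
  adj <- vector("list", n)
  if (nrow(bonds)) {
    keep <- bonds[, 1] %in% atoms & bonds[, 2] %in% atoms
    for (k in which(keep)) {
      i <- pos[bonds[k, 1]]; j <- pos[bonds[k, 2]]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  all(seen)
}

# Serialize a structure_graph to a V2000 MOL block (no coordinates); used to
# hand programmatically built structures (e.g. decoys) back to OpenBabel.
.to_molblock <- function(s, title = "") {
  n <- n_atoms(s)
  nb <- n_bonds(s)
  hdr <- c(title, " fragrank", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, s$elements)
  bonds <- character(0)
  if (nb > 0) {
    ord <- ifelse(s$bond_orders >= 4, 4L, as.integer(s$bond_orders))
    bonds <- sprintf("%3d%3d%3d  0  0  0  0", s$bonds[, 1], s$bonds[, 2], ord)
  }
  chg <- character(0)
  nz <- which(s$charges != 0L)
  if (length(nz)) {
    chg <- paste0("M  CHG", sprintf("%3d", length(nz)),
                  paste0(sprintf("%4d%4d", nz, s$charges[nz]), collapse = ""))
  }
  paste(c(hdr, atoms, bonds, chg, "M  END", "$$$$", ""), collapse = "\n")
}

#' Canonical SMILES of a structure
#'
#' @param s A `structure_graph`.
#' @return SMILES string (via OpenBabel canonicalisation of the stored graph
#'   when no source text is available).
#' @export
structure_smiles <- function(s) {
  stopifnot(inherits(s, "structure_graph"))
  if (nzchar(s$source_text) && !startsWith(s$source_text, "InChI=")) {
    return(s$source_text)
  }
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SDF", "SMI", .to_molblock(s)))
  smi <- trimws(strsplit(out, "\t|\n")[[1]][1])
  if (!nzchar(smi)) stop("SMILES generation failed")
  smi
}

#' Standard InChI of a structure
#' @param s A `structure_graph`.
#' @return InChI string.
#' @export
structure_inchi <- function(s) {
  stopifnot(inherits(s, "structure_graph"))
  if (startsWith(s$source_text, "InChI=")) return(s$source_text)
  src <- if (nzchar(s$source_text)) s$source_text else structure_smiles(s)
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "INCHI", src))
  inchi <- trimws(out)
  if (!startsWith(inchi, "InChI=")) stop("InChI generation failed")
  inchi
}

#' Octanol-water partition coefficient descriptor
#'
#' Atom-contribution logP computed by OpenBabel for candidate retention-time
#' scoring when no externally supplied logP column is configured.
#'
#' @param s A `structure_graph` or character vector of SMILES/InChI.
#' @return Numeric logP value(s).
#' @export
compute_logp <- function(s) {
  texts <- if (inherits(s, "structure_graph")) structure_smiles(s) else s
  if (is.null(.fragrank_cache$logp)) {
    .fragrank_cache$logp <- new.env(parent = emptyenv())
  }
  cache <- .fragrank_cache$logp
  vapply(texts, function(txt) {
    hit <- get0(txt, envir = cache)
    if (!is.null(hit)) return(hit)
    smi <- txt
    if (startsWith(txt, "InChI=")) {
      smi <- trimws(strsplit(suppressWarnings(
        ChemmineOB::convertFormat("INCHI", "SMI", txt)), "\t|\n")[[1]][1])
      if (is.na(smi) || !nzchar(smi)) stop("cannot parse InChI: ", txt)
    }
    res <- suppressWarnings(ChemmineOB::forEachMol("SMILES", smi,
      function(mol) {
        ChemmineOB::prop_OB(list(mol))
      }))
    v <- as.numeric(res[[1]]$logP)
    assign(txt, v, envir = cache)
    v
  }, numeric(1), USE.NAMES = FALSE)
}

#' @export
print.structure_graph <- function(x, ...) {
  cat("<structure_graph> ", format(molecular_formula(x)),
      ": ", n_atoms(x), " heavy atoms, ", n_bonds(x), " bonds\n", sep = "")
  if (nzchar(x$source_text)) cat("  source: ", x$source_text, "\n", sep = "")
  invisible(x)
}
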