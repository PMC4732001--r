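# Combinatorial bond-dissociation fragmentation.
#
# Top-down generation: starting from the whole heavy-atom graph, bonds are
# removed one at a time up to a configurable tree depth. Fragments are stored
# compactly as index sets over the parent's atoms and bonds together with the
# cumulative dissociation energy of the bonds cleaved along the cheapest path
# that produced them.

.BDE_FALLBACK <- 348

#' Read a bond-dissociation energy table
#'
#' The file holds whitespace-separated `element1 element2 order energy`
#' records (energies in kJ/mol, `#` comments allowed). Energies are symmetric
#' in the element pair. For an aromatic bond the mean of the pair's single
#' and double entries is used; pairs without an entry fall back to
#' `fallback` kJ/mol.
#'
#' @param path Path to the table file; defaults to the table shipped with
#'   the package.
#' @param fallback Energy for unknown pairs, kJ/mol.
#' @return An object of class `bde_table`.
#' @export
read_bde_table <- function(path = system.file("extdata", "bde_table.txt",
                                              package = "fragrank"),
                           fallback = .BDE_FALLBACK) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  tab <- new.env(parent = emptyenv())
  for (ln in lines) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) != 4L) stop("malformed BDE table line: ", ln)
    e <- as.numeric(tok[4])
    if (is.na(e) || e <= 0) stop("non-positive BDE in line: ", ln)
    els <- sort(c(tok[1], tok[2]))
    assign(paste(els[1], els[2], tok[3], sep = "|"), e, envir = tab)
  }
  structure(list(table = tab, fallback = fallback), class = "bde_table")
}

#' Default bond-dissociation energy table
#' @return A `bde_table` built from the table shipped with the package.
#' @export
default_bde_table <- function() {
  if (is.null(.fragrank_cache$bde)) {
    .fragrank_cache$bde <- read_bde_table()
  }
  .fragrank_cache$bde
}

.fragrank_cache <- new.env(parent = emptyenv())

#' Dissociation energy of a bond
#'
#' Symmetric in the element pair; aromatic bonds (order 4 or `"ar"`) use the
#' mean of the pair's single and double entries; unknown pairs return the
#' table's fallback energy.
#'
#' @param t A `bde_table`.
#' @param a,b Element symbols of the bonded atoms.
#' @param order Bond order: 1, 2, 3, or 4/`"ar"` for aromatic.
#' @return Energy in kJ/mol.
#' @export
#' @examples
#' bond_energy(default_bde_table(), "C", "C", 1)  # 348
bond_energy <- function(t, a, b, order) {
  stopifnot(inherits(t, "bde_table"))
  els <- sort(c(a, b))
  lookup <- function(o) {
    get0(paste(els[1], els[2], o, sep = "|"), envir = t$table,
         ifnotfound = NA_real_)
  }
  if (identical(order, "ar") || (is.numeric(order) && order >= 4)) {
    s <- lookup("1"); d <- lookup("2")
    if (!is.na(s) && !is.na(d)) return((s + d) / 2)
    return(t$fallback)
  }
  v <- lookup(as.character(as.integer(order)))
  if (is.na(v)) t$fallback else v
}

# Connected component containing `start` within the subgraph induced by
# `atoms` using only the bond indices in `bond_idx` of structure `s`.
.component_of <- function(s, start, atoms, bond_idx) {
  inset <- logical(length(s$elements))
  inset[atoms] <- TRUE
  adj <- vector("list", length(s$elements))
  for (k in bond_idx) {
    i <- s$bonds[k, 1]; j <- s$bonds[k, 2]
    if (inset[i] && inset[j]) {
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  seen <- logical(length(s$elements))
  seen[start] <- TRUE
  stack <- start
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
  which(seen)
}

.frag_key <- function(atoms, bonds) {
  paste(paste(atoms, collapse = ","), paste(bonds, collapse = ","), sep = ";")
}

#' Generate fragments by successive bond removal
#'
#' Starting from the connected parent graph, every bond of every current
#' fragment is removed in turn. Cleaving an acyclic bond splits a fragment in
#' two; removing a ring bond keeps the atom set intact and yields an
#' intermediate opened ring that is fragmented further but is only reported
#' as matchable once its atom set differs from the parent's (its neutral mass
#' is unchanged until then). Duplicate fragments (same atom and bond sets)
#' are merged keeping the minimal cumulative dissociation energy over the
#' alternative cleavage paths.
#'
#' @param s A connected `structure_graph`.
#' @param tree_depth Maximum number of successive bond removals (default 2).
#' @param bde A `bde_table` used to price each cleaved bond.
#' @return An object of class `fragment_set`: a list with the parent
#'   structure and a list of fragments, each holding `atoms` and `bonds`
#'   (index vectors into the parent), `bde` (cumulative kJ/mol), `depth`,
#'   `mass` (neutral monoisotopic Da) and `matchable`.
#' @export
generate_fragments <- function(s, tree_depth = 2L, bde = default_bde_table()) {
  stopifnot(inherits(s, "structure_graph"), tree_depth >= 0)
  if (!is_connected(s)) {
    stop("structure is not connected; apply the unconnected filter first")
  }
  n <- n_atoms(s)
  nb <- n_bonds(s)
  bond_e <- vapply(seq_len(nb), function(k) {
    bond_energy(bde, s$elements[s$bonds[k, 1]], s$elements[s$bonds[k, 2]],
                s$bond_orders[k])
  }, numeric(1))

  atom_masses <- isotope_mass(s$elements) +
    s$hydrogens * .ISOTOPE_MASS[["H"]]

  store <- new.env(parent = emptyenv())
  parent <- list(atoms = seq_len(n), bonds = seq_len(nb), bde = 0,
                 depth = 0L)
  assign(.frag_key(parent$atoms, parent$bonds), parent, envir = store)
  frontier <- list(parent)
  depth <- 0L
  while (depth < tree_depth && length(frontier)) {
    depth <- depth + 1L
    nxt <- list()
    for (f in frontier) {
      for (bidx in f$bonds) {
        rest <- f$bonds[f$bonds != bidx]
        newbde <- f$bde + bond_e[bidx]
        i <- s$bonds[bidx, 1]
        comp_i <- .component_of(s, i, f$atoms, rest)
        children <- if (length(comp_i) == length(f$atoms)) {
          list(list(atoms = f$atoms, bonds = rest, bde = newbde,
                    depth = depth))
        } else {
          comp_j <- setdiff(f$atoms, comp_i)
          in_i <- s$bonds[rest, 1] %in% comp_i & s$bonds[rest, 2] %in% comp_i
          list(
            list(atoms = comp_i, bonds = rest[in_i], bde = newbde,
                 depth = depth),
            list(atoms = comp_j, bonds = rest[!in_i], bde = newbde,
                 depth = depth)
          )
        }
        for (ch in children) {
          key <- .frag_key(ch$atoms, ch$bonds)
          old <- get0(key, envir = store)
          if (is.null(old) || ch$bde < old$bde) {
            if (!is.null(old)) ch$depth <- min(old$depth, ch$depth)
            assign(key, ch, envir = store)
            nxt[[length(nxt) + 1L]] <- ch
          }
        }
      }
    }
    frontier <- nxt
  }

  frags <- as.list(store)
  ord <- order(vapply(frags, function(f) length(f$atoms), integer(1)),
               names(frags))
  frags <- frags[ord]
  frags <- lapply(frags, function(f) {
    f$mass <- sum(atom_masses[f$atoms])
    f$matchable <- length(f$atoms) < n
    f
  })
  names(frags) <- NULL
  structure(list(structure = s, fragments = frags, tree_depth = tree_depth),
            class = "fragment_set")
}

#' Neutral mass and formula of a fragment
#'
#' Retained heavy atoms keep their implicit hydrogens; cleaved bonds do not
#' transfer hydrogens, so the two fragments of an acyclic cleavage have
#' masses summing exactly to the parent mass.
#'
#' @param f A fragment entry from a [generate_fragments()] result.
#' @param s The parent `structure_graph`.
#' @return `fragment_mass`: neutral monoisotopic mass in Da;
#'   `fragment_formula`: a `chem_formula`.
#' @export
fragment_mass <- function(f, s) {
  sum(isotope_mass(s$elements[f$atoms])) +
    sum(s$hydrogens[f$atoms]) * .ISOTOPE_MASS[["H"]]
}

#' @rdname fragment_mass
#' @export
fragment_formula <- function(f, s) {
  counts <- table(s$elements[f$atoms])
  out <- setNames(as.integer(counts), names(counts))
  hs <- sum(s$hydrogens[f$atoms])
  if (hs > 0) out["H"] <- (if ("H" %in% names(out)) out[["H"]] else 0L) + hs
  as_formula(out)
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("<fragment_set> ", length(x$fragments), " fragments (",
      sum(vapply(x$fragments, `[[`, logical(1), "matchable")),
      " matchable) at tree depth ", x$tree_depth, "\n", sep = "")
  invisible(x)
}
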