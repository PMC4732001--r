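# Independent oracles used by the tests. These deliberately avoid the
# package's internal graph routines: connectivity comes from igraph and the
# score formulas are re-evaluated directly.

# Enumerate every fragment reachable by removing at most `depth` bonds
# sequentially, tracking the minimal cumulative bond energy per distinct
# (atom set, bond set). Returns a named numeric vector key -> min energy.
oracle_fragments <- function(s, depth, bde = default_bde_table()) {
  nb <- n_bonds(s)
  be <- vapply(seq_len(nb), function(k) {
    bond_energy(bde, s$elements[s$bonds[k, 1]], s$elements[s$bonds[k, 2]],
                s$bond_orders[k])
  }, numeric(1))
  res <- new.env(parent = emptyenv())
  key_of <- function(atoms, bonds) {
    paste(paste(sort(atoms), collapse = ","),
          paste(sort(bonds), collapse = ","), sep = ";")
  }
  comps_of <- function(atoms, bond_idx) {
    g <- igraph::make_empty_graph(n = length(atoms), directed = FALSE)
    pos <- match(seq_len(n_atoms(s)), atoms)
    if (length(bond_idx)) {
      ed <- rbind(pos[s$bonds[bond_idx, 1]], pos[s$bonds[bond_idx, 2]])
      g <- igraph::add_edges(g, as.vector(ed))
    }
    mem <- igraph::components(g)$membership
    lapply(unique(mem), function(m) atoms[mem == m])
  }
  recurse <- function(atoms, bonds, cost, d) {
    key <- key_of(atoms, bonds)
    old <- get0(key, envir = res)
    if (is.null(old) || cost < old) assign(key, cost, envir = res)
    if (d == 0L) return(invisible())
    for (b in bonds) {
      rest <- setdiff(bonds, b)
      for (comp in comps_of(atoms, rest)) {
        cb <- rest[s$bonds[rest, 1] %in% comp & s$bonds[rest, 2] %in% comp]
        recurse(comp, cb, cost + be[b], d - 1L)
      }
    }
  }
  recurse(seq_len(n_atoms(s)), seq_len(nb), 0, depth)
  out <- unlist(as.list(res))
  out[order(names(out))]
}

# Convert a fragment_set to the oracle's key -> bde representation.
fragset_keys <- function(fs) {
  out <- vapply(fs$fragments, `[[`, numeric(1), "bde")
  names(out) <- vapply(fs$fragments, function(f) {
    paste(paste(sort(f$atoms), collapse = ","),
          paste(sort(f$bonds), collapse = ","), sep = ";")
  }, character(1))
  out[order(names(out))]
}

# Direct re-evaluation of the fragmenter score on an assignment table.
oracle_fragmenter_score <- function(assignments, prec_ion_mz, max_int,
                                    alpha = 1.84, beta = 0.59,
                                    gamma = 0.47) {
  if (nrow(assignments) == 0L) return(0)
  total <- 0
  for (i in seq_len(nrow(assignments))) {
    total <- total + exp(
      alpha * log(assignments$mz[i] / prec_ion_mz) +
      beta * log(assignments$intensity[i] / max_int) -
      gamma * log(assignments$bde[i]))
  }
  total
}

# Closed-form normal-equation OLS for logp = a*rt + b.
oracle_ols <- function(rt, logp) {
  a <- sum((rt - mean(rt)) * (logp - mean(logp))) / sum((rt - mean(rt))^2)
  c(a = a, b = mean(logp) - a * mean(rt))
}

toy_record <- function(id) {
  lib <- make_toy_library()
  lib[[match(id, candidate_ids(lib))]]
}
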