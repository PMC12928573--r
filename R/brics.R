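# BRICS fragmentation (Degen et al., ChemMedChem 2008, 1503-1507).
#
# A molecule is cleaved at acyclic bonds whose two end atoms match a
# compatible pair of BRICS link environments (L1, L3-L16; L2 is folded into
# L5 and L7 cleaves double bonds). Each fragment keeps an ATTACH pseudo-atom
# at every cleavage site, recording where it was connected. Fragments are the
# "pharmacophore subgraphs" consumed by the graph-view encoder.

# --- link-environment predicates -------------------------------------------
# Each predicate receives the 1-based atom position, the atom table and the
# neighbour list, and mirrors the published SMARTS definition of that
# environment. Degrees are heavy-atom degrees (implicit H never counts).

.atom_in_ring <- function(nbs, a) any(nbs[[a]]$in_ring)

.envs_of_atom <- function(a, atoms, nbs) {
  sym <- atoms$symbol[a]
  arom <- atoms$aromatic[a]
  nb <- nbs[[a]]
  deg <- length(nb$nb)
  envs <- integer(0)
  nsym <- atoms$symbol[nb$nb]
  narom <- atoms$aromatic[nb$nb]

  if (sym == "C" && !arom) {
    dbl_O <- nb$order == "double" & nsym == "O"
    if (deg == 3L && any(dbl_O)) {
      other_CNO <- which(!dbl_O & nsym %in% c("C", "N", "O"))
      has_dbl <- which(dbl_O)
      # L1: carbonyl carbon with a further C/N/O neighbour
      if (length(other_CNO) > 0L || length(has_dbl) > 1L) envs <- c(envs, 1L)
      # L6: same pattern but acyclic, single bond to the C/N/O neighbour
      if (!.atom_in_ring(nbs, a) &&
          any(!dbl_O & nb$order == "single" & !nb$in_ring &
              nsym %in% c("C", "N", "O"))) {
        envs <- c(envs, 6L)
      }
    }
    no_double <- !any(nb$order == "double")
    # L4: sp3-like carbon with an acyclic single bond to carbon
    if (deg >= 2L && no_double &&
        any(nb$order == "single" & !nb$in_ring & nsym == "C")) {
      envs <- c(envs, 4L)
    }
    # L7: vinylic carbon (pairs over the double bond itself)
    if (deg %in% c(2L, 3L) && any(nb$order == "single" & nsym == "C")) {
      envs <- c(envs, 7L)
    }
    # L8: acyclic all-single carbon, degree >= 2
    if (!.atom_in_ring(nbs, a) && deg >= 2L && all(nb$order == "single")) {
      envs <- c(envs, 8L)
    }
    ring_single <- nb$order == "single" & nb$in_ring
    # L13: ring carbon bridging to a ring heteroatom
    cand_any <- which(ring_single & !narom & nsym %in% c("C", "N", "O", "S"))
    cand_het <- which(ring_single & !narom & nsym %in% c("N", "O", "S"))
    if (length(cand_het) > 0L &&
        (length(setdiff(cand_any, cand_het)) > 0L || length(cand_het) > 1L)) {
      envs <- c(envs, 13L)
    }
    # L15: ring carbon between two ring carbons
    if (sum(ring_single & !narom & nsym == "C") >= 2L) envs <- c(envs, 15L)
  }

  if (sym == "C" && arom) {
    ar <- nb$order == "aromatic" & narom
    full <- which(ar & nsym %in% c("C", "N", "O", "S"))
    het <- which(ar & nsym %in% c("N", "O", "S"))
    # L14: aromatic carbon next to an aromatic heteroatom
    if (length(het) > 0L &&
        (length(setdiff(full, het)) > 0L || length(het) > 1L)) {
      envs <- c(envs, 14L)
    }
    # L16: aromatic carbon flanked by two aromatic carbons
    if (sum(ar & nsym == "C") >= 2L) envs <- c(envs, 16L)
  }

  if (sym == "O" && !arom && deg == 2L &&
      any(nb$order == "single" & !nb$in_ring & nsym %in% c("C", "H"))) {
    envs <- c(envs, 3L)  # L3: ether oxygen
  }

  if (sym == "N" && !arom) {
    allowed <- all(nsym %in% c("C", "S", "H"))
    no_double <- !any(nb$order == "double")
    lactam <- FALSE
    if (.atom_in_ring(nbs, a)) {
      for (k in which(nb$in_ring & !narom & nsym == "C")) {
        x <- nb$nb[k]
        xnb <- nbs[[x]]
        if (any(xnb$order == "double" & atoms$symbol[xnb$nb] == "O")) {
          lactam <- TRUE
          break
        }
      }
    }
    # L5: amine nitrogen (unified amine definition; excludes lactam N)
    if (deg >= 2L && no_double && allowed && !lactam) envs <- c(envs, 5L)
    # L10: cyclic imide/lactam nitrogen
    if (.atom_in_ring(nbs, a)) {
      carbonyl <- integer(0)
      for (k in which(nb$in_ring & !narom & nsym == "C")) {
        x <- nb$nb[k]
        xnb <- nbs[[x]]
        if (any(xnb$order == "double" & atoms$symbol[xnb$nb] == "O")) {
          carbonyl <- c(carbonyl, k)
        }
      }
      others <- which(nb$in_ring & !narom & nsym %in% c("C", "N", "O", "S"))
      if (length(carbonyl) > 0L && length(setdiff(others, carbonyl[1])) > 0L) {
        envs <- c(envs, 10L)
      }
    }
  }

  if (sym == "N" && arom && atoms$charge[a] == 0L) {
    ar <- nb$order == "aromatic" & narom & nsym %in% c("C", "N", "O", "S")
    if (sum(ar) >= 2L) envs <- c(envs, 9L)
  }

  if (sym == "S" && !arom) {
    if (deg == 2L &&
        any(nb$order == "single" & !nb$in_ring & nsym == "C")) {
      envs <- c(envs, 11L)  # L11: thioether sulfur
    }
    if (deg == 4L && sum(nb$order == "double" & nsym == "O") >= 2L &&
        any(nb$order == "single" & nsym == "C")) {
      envs <- c(envs, 12L)  # L12: sulfonyl sulfur
    }
  }

  envs
}

# Compatible environment pairs cleaved over a SINGLE acyclic bond; (7,7) is
# handled separately over double bonds.
.brics_pairs <- matrix(c(
  1, 3,  1, 5,  1, 10,
  3, 4,  3, 13,  3, 14,  3, 15,  3, 16,
  4, 5,  4, 11,
  5, 12,  5, 13,  5, 14,  5, 15,  5, 16,
  6, 13,  6, 14,  6, 15,  6, 16,
  8, 9,  8, 10,  8, 13,  8, 14,  8, 15,  8, 16,
  9, 13,  9, 14,  9, 15,  9, 16,
  10, 13,  10, 14,  10, 15,  10, 16,
  11, 13,  11, 14,  11, 15,  11, 16,
  13, 14,  13, 15,  13, 16,
  14, 14,  14, 15,  14, 16,
  15, 16,
  16, 16), ncol = 2, byrow = TRUE)

.pair_compatible <- function(e1, e2) {
  if (length(e1) == 0L || length(e2) == 0L) return(FALSE)
  for (r in seq_len(nrow(.brics_pairs))) {
    a <- .brics_pairs[r, 1]; b <- .brics_pairs[r, 2]
    if ((a %in% e1 && b %in% e2) || (b %in% e1 && a %in% e2)) return(TRUE)
  }
  FALSE
}

#' Find BRICS-cleavable bonds of a molecule
#'
#' @param mol A `molecule_record` from [parse_smiles()].
#' @return Integer vector of row indices into `mol$bonds` marking the bonds
#'   that BRICS cleaves (always acyclic; single bonds between compatible link
#'   environments, plus L7-L7 double bonds).
#' @export
find_brics_bonds <- function(mol) {
  stopifnot(inherits(mol, "molecule_record"))
  bonds <- mol$bonds
  if (nrow(bonds) == 0L) return(integer(0))
  nbs <- .neighbours(mol)
  envs <- lapply(seq_len(nrow(mol$atoms)), .envs_of_atom,
                 atoms = mol$atoms, nbs = nbs)
  out <- integer(0)
  for (b in seq_len(nrow(bonds))) {
    if (bonds$in_ring[b]) next
    a1 <- bonds$i[b] + 1L; a2 <- bonds$j[b] + 1L
    if (bonds$order[b] == "single") {
      if (.pair_compatible(envs[[a1]], envs[[a2]])) out <- c(out, b)
    } else if (bonds$order[b] == "double") {
      if (7L %in% envs[[a1]] && 7L %in% envs[[a2]]) out <- c(out, b)
    }
  }
  out
}

#' Decompose a molecule into BRICS pharmacophore subgraphs
#'
#' Cleaves every BRICS bond simultaneously and returns the resulting
#' fragments. Atoms are partitioned across fragments; each cleaved bond
#' leaves one ATTACH pseudo-atom on each side, bonded (single) to the atom it
#' was cleaved from. A molecule with no cleavable bond yields a single
#' pharmacophore equal to the whole molecule, so `N >= 1` always holds.
#'
#' @param mol A `molecule_record`.
#' @return A `decomposed_molecule`: list with `molecule`, `pharmacophores`
#'   (each a list with `atoms` and `bonds` data.frames in local order;
#'   `atoms$orig_index` is the 0-based index into the parent molecule, `NA`
#'   for ATTACH atoms), `N`, and `cleaved` (data.frame of cleaved bonds).
#' @examples
#' dec <- brics_decompose(parse_smiles("CC(=O)Oc1ccccc1C(=O)O", "aspirin"))
#' dec$N
#' @export
brics_decompose <- function(mol) {
  stopifnot(inherits(mol, "molecule_record"))
  cle <- find_brics_bonds(mol)
  n <- nrow(mol$atoms)
  bonds <- mol$bonds
  keep <- setdiff(seq_len(nrow(bonds)), cle)

  # Connected components over the kept bonds.
  comp <- seq_len(n)
  find <- function(x) {
    while (comp[x] != x) {
      comp[x] <<- comp[comp[x]]
      x <- comp[x]
    }
    x
  }
  for (b in keep) {
    r1 <- find(bonds$i[b] + 1L); r2 <- find(bonds$j[b] + 1L)
    if (r1 != r2) comp[max(r1, r2)] <- min(r1, r2)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  # Fragment order: by smallest original atom index (deterministic).
  frag_ids <- unique(roots[order(seq_len(n))])
  frag_of_atom <- match(roots, frag_ids)

  frags <- vector("list", length(frag_ids))
  for (f in seq_along(frag_ids)) {
    members <- which(frag_of_atom == f)           # 1-based, ascending
    local_of <- integer(n); local_of[members] <- seq_along(members)
    fa <- data.frame(
      orig_index = members - 1L,
      symbol = mol$atoms$symbol[members],
      aromatic = mol$atoms$aromatic[members],
      charge = mol$atoms$charge[members],
      is_attach = FALSE,
      stringsAsFactors = FALSE
    )
    fb_rows <- keep[frag_of_atom[bonds$i[keep] + 1L] == f]
    fb <- data.frame(
      a = local_of[bonds$i[fb_rows] + 1L],
      b = local_of[bonds$j[fb_rows] + 1L],
      order = bonds$order[fb_rows],
      is_attach = logical(length(fb_rows)),
      stringsAsFactors = FALSE
    )
    frags[[f]] <- list(atoms = fa, bonds = fb)
  }

  # ATTACH pseudo-atoms at cleavage sites.
  for (b in cle) {
    for (endp in c(bonds$i[b], bonds$j[b])) {
      f <- frag_of_atom[endp + 1L]
      fr <- frags[[f]]
      local <- match(endp, fr$atoms$orig_index)
      fr$atoms <- rbind(fr$atoms, data.frame(
        orig_index = NA_integer_, symbol = "*", aromatic = FALSE,
        charge = 0L, is_attach = TRUE, stringsAsFactors = FALSE))
      fr$bonds <- rbind(fr$bonds, data.frame(
        a = local, b = nrow(fr$atoms), order = "single", is_attach = TRUE,
        stringsAsFactors = FALSE))
      frags[[f]] <- fr
    }
  }

  structure(list(
    molecule = mol,
    pharmacophores = frags,
    N = length(frags),
    cleaved = bonds[cle, c("i", "j", "order"), drop = FALSE]
  ), class = "decomposed_molecule")
}

#' @export
print.decomposed_molecule <- function(x, ...) {
  cat(sprintf("<decomposed_molecule> %s: N = %d pharmacophore(s), %d cleaved bond(s)\n",
              if (nzchar(x$molecule$drug_id)) x$molecule$drug_id else "<unnamed>",
              x$N, nrow(x$cleaved)))
  invisible(x)
}
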