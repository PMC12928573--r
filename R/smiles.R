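# SMILES tokenization and molecular-graph construction.
#
# The sequence view and the graph view of a drug are derived from the same
# atom-level token stream, so the two views always agree on atom identity,
# ordering and aromaticity. Aromaticity follows the SMILES annotation itself
# (lowercase atoms / ':' bonds); no aromaticity perception is performed.

# Elements recognised inside bracket atoms. Bare (organic-subset) atoms are
# restricted to B, C, N, O, P, S, F, Cl, Br, I and their aromatic forms.
.known_elements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Fe", "Co", "Ni", "Cu", "Zn",
  "As", "Se", "Br", "Kr", "Mo", "Ag", "Sn", "Sb", "Te", "I", "Xe", "Pt",
  "Au", "Hg", "Pb", "Bi"
)

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.aromatic_subset <- c("b", "c", "n", "o", "p", "s")

#' Tokenize a SMILES string into atom-level tokens
#'
#' Splits a SMILES string into the token alphabet used by the sequence
#' encoder: bracket atoms (`[...]`) are single tokens, the two-character
#' elements `Cl` and `Br` are single tokens, and every other character
#' (organic-subset atoms, aromatic lowercase atoms, ring-closure digits,
#' `%nn` ring labels, bond symbols, branch parentheses, and the dot
#' separator) is one token. Concatenating the returned tokens reproduces the
#' input exactly.
#'
#' @param smiles A single non-empty SMILES string.
#' @return Character vector of tokens.
#' @examples
#' tokenize_smiles("CCO")
#' tokenize_smiles("c1ccccc1")
#' @export
tokenize_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("tokenize_smiles: 'smiles' must be a single non-empty string",
         call. = FALSE)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  single_ok <- c(.organic_subset[nchar(.organic_subset) == 1L],
                 .aromatic_subset, as.character(0:9),
                 "-", "=", "#", ":", "/", "\\", "~", "(", ")", ".")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) {
        stop(sprintf("tokenize_smiles: unclosed '[' at position %d in \"%s\"",
                     i, smiles), call. = FALSE)
      }
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      tokens <- c(tokens, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L]))) {
        stop(sprintf(
          "tokenize_smiles: '%%' must be followed by two digits at position %d in \"%s\"",
          i, smiles), call. = FALSE)
      }
      tokens <- c(tokens, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch %in% single_ok || ch %in% c("N", "O", "P", "S", "F", "I", "C", "B")) {
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else {
      stop(sprintf(
        "tokenize_smiles: unrecognized character '%s' at position %d in \"%s\"",
        ch, i, smiles), call. = FALSE)
    }
  }
  tokens
}

# Parse the interior of a bracket-atom token such as "[NH4+]" or "[nH]".
# Returns list(symbol, aromatic, charge, is_hydrogen).
.parse_bracket <- function(token, smiles) {
  body <- sub("^\\[", "", sub("\\]$", "", token))
  m <- regexec(
    "^([0-9]*)([A-Z][a-z]?|[a-z]{1,2})(@{1,2}|@TH[12])?(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?(:[0-9]+)?$",
    body)
  parts <- regmatches(body, m)[[1]]
  if (length(parts) == 0L) {
    stop(sprintf("parse_smiles: malformed bracket atom '%s' in \"%s\"",
                 token, smiles), call. = FALSE)
  }
  elem_raw <- parts[3]
  aromatic <- elem_raw %in% c(.aromatic_subset, "se", "as")
  symbol <- if (aromatic) {
    paste0(toupper(substr(elem_raw, 1, 1)), substring(elem_raw, 2))
  } else {
    elem_raw
  }
  if (!symbol %in% .known_elements) {
    stop(sprintf("parse_smiles: unknown element '%s' in bracket atom '%s' of \"%s\"",
                 elem_raw, token, smiles), call. = FALSE)
  }
  chg_str <- parts[6]
  charge <- 0L
  if (nzchar(chg_str)) {
    if (grepl("^[+-][0-9]+$", chg_str)) {
      charge <- as.integer(chg_str)
    } else {
      charge <- (if (substr(chg_str, 1, 1) == "+") 1L else -1L) * nchar(chg_str)
    }
  }
  list(symbol = symbol, aromatic = aromatic, charge = charge,
       is_hydrogen = identical(symbol, "H"))
}

.bond_order_of_symbol <- function(sym) {
  switch(sym,
         "-" = "single", "/" = "single", "\\" = "single",
         "=" = "double", "#" = "triple", ":" = "aromatic",
         stop(sprintf("parse_smiles: unsupported bond symbol '%s'", sym),
              call. = FALSE))
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds a `molecule_record`: heavy atoms as nodes (implicit hydrogens are
#' not nodes; an explicit bracketed `[H]` is) and bonds as edges with type
#' `single`, `double`, `triple` or `aromatic`. A bond written without a
#' symbol between two aromatic atoms is aromatic when it lies in a ring and
#' single otherwise (e.g. the biphenyl junction). Disconnected SMILES
#' (`A.B` salts) are reduced to the largest connected component with a
#' warning.
#'
#' @param smiles SMILES string.
#' @param drug_id Identifier attached to the record (default `""`).
#' @return An object of class `molecule_record`: a list with `drug_id`,
#'   `smiles`, `atoms` (data.frame: `index` 0-based, `symbol`, `aromatic`,
#'   `charge`, `is_attach`) and `bonds` (data.frame: `i`, `j` 0-based atom
#'   indices with `i < j`, `order`, `is_attach`, `in_ring`).
#' @examples
#' mol <- parse_smiles("CCO", "ethanol")
#' mol$atoms$symbol
#' @export
parse_smiles <- function(smiles, drug_id = "") {
  tokens <- tokenize_smiles(smiles)

  atom_symbol <- character(0)
  atom_arom <- logical(0)
  atom_charge <- integer(0)
  atom_comp <- integer(0)

  bi <- integer(0); bj <- integer(0)
  border <- character(0)   # "single","double","triple","aromatic","auto"

  prev <- NA_integer_
  stack <- integer(0)
  pending <- NA_character_
  rings <- list()          # digit label -> list(atom, bond)
  comp <- 1L

  add_atom <- function(symbol, aromatic, charge) {
    atom_symbol[[length(atom_symbol) + 1L]] <<- symbol
    atom_arom[[length(atom_arom) + 1L]] <<- aromatic
    atom_charge[[length(atom_charge) + 1L]] <<- charge
    atom_comp[[length(atom_comp) + 1L]] <<- comp
    length(atom_symbol)
  }
  add_bond <- function(a, b, order) {
    if (a == b) {
      stop(sprintf("parse_smiles: self-bond on atom %d in \"%s\"", a - 1L,
                   smiles), call. = FALSE)
    }
    bi[[length(bi) + 1L]] <<- min(a, b)
    bj[[length(bj) + 1L]] <<- max(a, b)
    border[[length(border) + 1L]] <<- order
  }

  for (tok in tokens) {
    first <- substr(tok, 1, 1)
    if (first == "[") {
      at <- .parse_bracket(tok, smiles)
      idx <- add_atom(at$symbol, at$aromatic, at$charge)
      if (!is.na(prev)) {
        ord <- if (!is.na(pending)) pending else "auto"
        add_bond(prev, idx, ord)
      }
      prev <- idx; pending <- NA_character_
    } else if (tok %in% .organic_subset) {
      idx <- add_atom(tok, FALSE, 0L)
      if (!is.na(prev)) {
        ord <- if (!is.na(pending)) pending else "auto"
        add_bond(prev, idx, ord)
      }
      prev <- idx; pending <- NA_character_
    } else if (tok %in% .aromatic_subset) {
      idx <- add_atom(toupper(tok), TRUE, 0L)
      if (!is.na(prev)) {
        ord <- if (!is.na(pending)) pending else "auto"
        add_bond(prev, idx, ord)
      }
      prev <- idx; pending <- NA_character_
    } else if (grepl("^[0-9]$", tok) || first == "%") {
      if (is.na(prev)) {
        stop(sprintf("parse_smiles: ring-closure '%s' before any atom in \"%s\"",
                     tok, smiles), call. = FALSE)
      }
      lbl <- if (first == "%") substring(tok, 2) else tok
      if (is.null(rings[[lbl]])) {
        rings[[lbl]] <- list(atom = prev, bond = pending)
        pending <- NA_character_
      } else {
        open <- rings[[lbl]]
        rings[lbl] <- list(NULL)
        ord <- if (!is.na(pending)) pending else if (!is.na(open$bond)) open$bond else "auto"
        if (open$atom == prev) {
          stop(sprintf("parse_smiles: ring label '%s' closes onto its own atom in \"%s\"",
                       lbl, smiles), call. = FALSE)
        }
        add_bond(open$atom, prev, ord)
        pending <- NA_character_
      }
    } else if (tok %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- .bond_order_of_symbol(tok)
    } else if (tok == "~") {
      stop(sprintf("parse_smiles: wildcard bond '~' not supported in \"%s\"",
                   smiles), call. = FALSE)
    } else if (tok == "(") {
      if (is.na(prev)) {
        stop(sprintf("parse_smiles: branch '(' before any atom in \"%s\"",
                     smiles), call. = FALSE)
      }
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (length(stack) == 0L) {
        stop(sprintf("parse_smiles: unmatched ')' in \"%s\"", smiles),
             call. = FALSE)
      }
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok == ".") {
      prev <- NA_integer_
      pending <- NA_character_
      comp <- comp + 1L
    } else {
      stop(sprintf("parse_smiles: unexpected token '%s' in \"%s\"", tok,
                   smiles), call. = FALSE)
    }
  }

  if (length(stack) > 0L) {
    stop(sprintf("parse_smiles: %d unclosed branch parenthes%s in \"%s\"",
                 length(stack), if (length(stack) == 1L) "is" else "es",
                 smiles), call. = FALSE)
  }
  open_rings <- names(rings)[!vapply(rings, is.null, logical(1))]
  if (length(open_rings) > 0L) {
    stop(sprintf("parse_smiles: unbalanced ring closure label(s) %s in \"%s\"",
                 paste(open_rings, collapse = ", "), smiles), call. = FALSE)
  }
  if (!is.na(pending)) {
    stop(sprintf("parse_smiles: dangling bond symbol at end of \"%s\"", smiles),
         call. = FALSE)
  }
  if (length(atom_symbol) == 0L) {
    stop(sprintf("parse_smiles: no atoms in \"%s\"", smiles), call. = FALSE)
  }

  # Drop explicit hydrogens? Explicit [H] atoms are retained as nodes by
  # design; implicit H never became nodes. Reduce multi-component input to
  # the largest component.
  n_atoms <- length(atom_symbol)
  if (comp > 1L) {
    sizes <- tabulate(atom_comp, nbins = comp)
    keep_comp <- which.max(sizes)
    warning(sprintf(
      "parse_smiles: \"%s\" has %d disconnected components; keeping the largest (%d atoms)",
      smiles, comp, sizes[keep_comp]), call. = FALSE)
    keep <- which(atom_comp == keep_comp)
    remap <- rep(NA_integer_, n_atoms)
    remap[keep] <- seq_along(keep)
    sel <- !is.na(remap[bi]) & !is.na(remap[bj])
    bi <- remap[bi[sel]]; bj <- remap[bj[sel]]; border <- border[sel]
    atom_symbol <- atom_symbol[keep]
    atom_arom <- atom_arom[keep]
    atom_charge <- atom_charge[keep]
    n_atoms <- length(keep)
  }

  # Duplicate bonds (e.g. ring closure repeating an existing bond) are invalid.
  if (length(bi) > 0L && anyDuplicated(paste(bi, bj)) > 0L) {
    stop(sprintf("parse_smiles: duplicate bond specification in \"%s\"", smiles),
         call. = FALSE)
  }

  in_ring <- .ring_bonds(n_atoms, bi, bj)

  # Resolve "auto" bond orders: aromatic when both atoms are aromatic and the
  # bond lies in a ring; single otherwise.
  auto <- border == "auto"
  if (any(auto)) {
    both_arom <- atom_arom[bi] & atom_arom[bj]
    border[auto] <- ifelse(both_arom[auto] & in_ring[auto], "aromatic", "single")
  }

  atoms <- data.frame(
    index = seq_len(n_atoms) - 1L,
    symbol = atom_symbol,
    aromatic = atom_arom,
    charge = atom_charge,
    is_attach = FALSE,
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(
    i = if (length(bi)) bi - 1L else integer(0),
    j = if (length(bj)) bj - 1L else integer(0),
    order = border,
    is_attach = logical(length(bi)),
    in_ring = in_ring,
    stringsAsFactors = FALSE
  )
  structure(list(drug_id = drug_id, smiles = smiles, atoms = atoms,
                 bonds = bonds),
            class = "molecule_record")
}

# Ring-bond detection: a bond is in a ring iff it is not a bridge, i.e. its
# endpoints stay connected after removing it. Molecules are small, so a
# per-bond BFS is plenty fast.
.ring_bonds <- function(n_atoms, bi, bj) {
  n_bonds <- length(bi)
  if (n_bonds == 0L) return(logical(0))
  adj <- vector("list", n_atoms)
  for (b in seq_len(n_bonds)) {
    adj[[bi[b]]] <- c(adj[[bi[b]]], b)
    adj[[bj[b]]] <- c(adj[[bj[b]]], b)
  }
  out <- logical(n_bonds)
  for (b in seq_len(n_bonds)) {
    src <- bi[b]; dst <- bj[b]
    seen <- logical(n_atoms)
    seen[src] <- TRUE
    queue <- src
    found <- FALSE
    while (length(queue) > 0L && !found) {
      v <- queue[1L]; queue <- queue[-1L]
      for (eb in adj[[v]]) {
        if (eb == b) next
        w <- if (bi[eb] == v) bj[eb] else bi[eb]
        if (!seen[w]) {
          if (w == dst) { found <- TRUE; break }
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    out[b] <- found
  }
  out
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule_record> %s: %d atoms, %d bonds (%s)\n",
              if (nzchar(x$drug_id)) x$drug_id else "<unnamed>",
              nrow(x$atoms), nrow(x$bonds), x$smiles))
  invisible(x)
}

# Heavy-atom neighbour list of a molecule_record: list over atoms (1-based)
# of data.frames with columns nb (1-based neighbour), order, in_ring.
.neighbours <- function(mol) {
  n <- nrow(mol$atoms)
  out <- vector("list", n)
  for (k in seq_len(n)) out[[k]] <- list(nb = integer(0), order = character(0),
                                         in_ring = logical(0))
  bonds <- mol$bonds
  for (b in seq_len(nrow(bonds))) {
    a1 <- bonds$i[b] + 1L; a2 <- bonds$j[b] + 1L
    out[[a1]]$nb <- c(out[[a1]]$nb, a2)
    out[[a1]]$order <- c(out[[a1]]$order, bonds$order[b])
    out[[a1]]$in_ring <- c(out[[a1]]$in_ring, bonds$in_ring[b])
    out[[a2]]$nb <- c(out[[a2]]$nb, a1)
    out[[a2]]$order <- c(out[[a2]]$order, bonds$order[b])
    out[[a2]]$in_ring <- c(out[[a2]]$in_ring, bonds$in_ring[b])
  }
  out
}
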