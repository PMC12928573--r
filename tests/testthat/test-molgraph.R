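# SMILES parsing, BRICS decomposition and one-hot featurization.

test_that("tokenizer follows the atom-level rules and round-trips", {
  expect_equal(tokenize_smiles("CCO"), c("C", "C", "O"))
  expect_equal(tokenize_smiles("ClCCl"), c("Cl", "C", "Cl"))
  expect_equal(tokenize_smiles("c1ccccc1"),
               c("c", "1", "c", "c", "c", "c", "c", "1"))
  expect_equal(tokenize_smiles("[nH]1cccc1"),
               c("[nH]", "1", "c", "c", "c", "c", "1"))
  expect_equal(tokenize_smiles("CC(=O)N"), c("C", "C", "(", "=", "O", ")", "N"))
  expect_error(tokenize_smiles(""), "non-empty")
  expect_error(tokenize_smiles("CQO"), "unrecognized character 'Q' at position 2")
  expect_error(tokenize_smiles("C[NH4"), "unclosed")
})

test_that("tokenization is lossless over generated molecules", {
  drugs <- gen_molecules(250, seed = 41)
  smiles <- c(drugs$smiles, gen_molecules(250, seed = 42)$smiles)
  for (s in smiles) {
    expect_identical(paste(tokenize_smiles(s), collapse = ""), s)
  }
})

test_that("parse_smiles builds the expected adjacency", {
  m <- parse_smiles("CCO", "ethanol")
  expect_equal(m$atoms$symbol, c("C", "C", "O"))
  expect_equal(nrow(m$bonds), 2L)
  expect_equal(m$bonds$i, c(0L, 1L))
  expect_equal(m$bonds$j, c(1L, 2L))
  expect_true(all(m$bonds$order == "single"))

  tri <- parse_smiles("C1CC1")
  expect_equal(nrow(tri$atoms), 3L)
  expect_equal(nrow(tri$bonds), 3L)
  expect_true(all(tri$bonds$order == "single"))
  expect_true(all(tri$bonds$in_ring))

  benz <- parse_smiles("c1ccccc1")
  expect_true(all(benz$atoms$aromatic))
  expect_true(all(benz$bonds$order == "aromatic"))
  # biphenyl junction: unannotated bond between aromatic atoms outside a ring
  biph <- parse_smiles("c1ccccc1c1ccccc1")
  junction <- biph$bonds[biph$bonds$i == 5 & biph$bonds$j == 6, ]
  expect_equal(junction$order, "single")
})

test_that("malformed SMILES produce named parse errors", {
  expect_error(parse_smiles("C("), "unclosed branch")
  expect_error(parse_smiles("C1CC"), "ring closure")
  expect_error(parse_smiles("[Zz]C"), "unknown element")
  expect_error(parse_smiles("CC="), "dangling bond")
  expect_error(parse_smiles("C11"), "closes onto its own atom")
})

test_that("disconnected SMILES keep the largest component with a warning", {
  expect_warning(m <- parse_smiles("CCO.[Na]"), "disconnected")
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(m$atoms$symbol, c("C", "C", "O"))
})

test_that("BRICS handles non-cleavable and degenerate molecules", {
  d <- brics_decompose(parse_smiles("CCO"))
  expect_equal(d$N, 1L)
  expect_equal(nrow(d$pharmacophores[[1]]$atoms), 3L)

  methane <- brics_decompose(parse_smiles("C"))
  expect_equal(methane$N, 1L)
  expect_equal(nrow(methane$pharmacophores[[1]]$atoms), 1L)
  expect_equal(nrow(methane$pharmacophores[[1]]$bonds), 0L)
})

test_that("aspirin decomposes into pharmacophores partitioning its atoms", {
  mol <- parse_smiles("CC(=O)Oc1ccccc1C(=O)O", "aspirin")
  dec <- brics_decompose(mol)
  expect_gte(dec$N, 2L)
  expect_equal(dec$N, 4L)
  covered <- sort(unlist(lapply(dec$pharmacophores, function(f)
    f$atoms$orig_index[!f$atoms$is_attach])))
  expect_equal(covered, 0:12)
  # two ATTACH pseudo-atoms per cleaved bond
  n_attach <- sum(vapply(dec$pharmacophores, function(f)
    sum(f$atoms$is_attach), 1L))
  expect_equal(n_attach, 2L * nrow(dec$cleaved))
})

test_that("cleaved bond sets match the frozen reference battery", {
  ref <- utils::read.delim(test_path("brics-reference.tsv"),
                           colClasses = "character")
  for (r in seq_len(nrow(ref))) {
    m <- parse_smiles(ref$smiles[r])
    cl <- find_brics_bonds(m)
    got <- sort(paste(m$bonds$i[cl], m$bonds$j[cl], sep = "-"))
    exp <- sort(setdiff(strsplit(ref$cleaved_bonds[r], ";")[[1]], ""))
    expect_equal(got, exp, label = ref$smiles[r])
  }
})

test_that("decomposition conserves atoms and bonds over random molecules", {
  drugs <- gen_molecules(200, seed = 99)
  for (s in drugs$smiles) {
    mol <- parse_smiles(s)
    dec <- brics_decompose(mol)
    heavy <- unlist(lapply(dec$pharmacophores, function(f)
      f$atoms$orig_index[!f$atoms$is_attach]))
    expect_equal(sort(heavy), seq_len(nrow(mol$atoms)) - 1L)   # partition
    n_real_bonds <- sum(vapply(dec$pharmacophores, function(f)
      sum(!f$bonds$is_attach), 1L))
    expect_equal(n_real_bonds + nrow(dec$cleaved), nrow(mol$bonds))
  }
})

test_that("decomposition is deterministic", {
  s <- gen_molecules(5, seed = 12)$smiles[4]
  expect_identical(brics_decompose(parse_smiles(s)),
                   brics_decompose(parse_smiles(s)))
})

test_that("featurization is one-hot with OTHER/ATTACH fallback and round-trips", {
  vocab <- feature_vocab()
  dec <- brics_decompose(parse_smiles("CCO"))
  f <- featurize_subgraph(dec$pharmacophores[[1]], vocab)
  expect_equal(dim(f$X_V), c(3L, vocab$D_V))
  expect_true(all(rowSums(f$X_V) == 1))
  expect_equal(vocab$atom_symbols[apply(f$X_V, 1, which.max)],
               c("C", "C", "O"))
  expect_equal(dim(f$X_E), c(2L, vocab$D_E))
  expect_equal(unname(colSums(f$X_E)[["single"]]), 2)

  se <- brics_decompose(parse_smiles("CC[Se]C"))
  fs <- featurize_subgraph(se$pharmacophores[[1]], vocab)
  expect_equal(sum(fs$X_V[, "OTHER"]), 1)

  asp <- brics_decompose(parse_smiles("CC(=O)Oc1ccccc1C(=O)O"))
  fa <- featurize_subgraph(asp$pharmacophores[[1]], vocab)
  expect_equal(sum(fa$X_V[, "ATTACH"]),
               sum(asp$pharmacophores[[1]]$atoms$is_attach))

  expect_error(featurize_subgraph(list(atoms = data.frame()), vocab),
               "empty subgraph")
})

test_that("featurize-then-argmax recovers every symbol and bond type", {
  vocab <- feature_vocab()
  for (s in gen_molecules(20, seed = 5)$smiles) {
    dec <- brics_decompose(parse_smiles(s))
    for (ph in dec$pharmacophores) {
      f <- featurize_subgraph(ph, vocab)
      sym <- ifelse(ph$atoms$is_attach, "ATTACH", ph$atoms$symbol)
      sym[!sym %in% vocab$atom_symbols] <- "OTHER"
      expect_equal(vocab$atom_symbols[apply(f$X_V, 1, which.max)], sym)
      if (nrow(ph$bonds) > 0) {
        expect_equal(vocab$bond_types[apply(f$X_E, 1, which.max)],
                     ph$bonds$order)
      }
    }
  }
})

test_that("parsing agrees with an independent cheminformatics parser", {
  skip_if_not_installed("ChemmineR")
  smiles <- c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "c1ccncc1CC", "CCN(CC)C(=O)C",
              "C1CCNCC1c1ccccc1")
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  for (k in seq_along(smiles)) {
    mine <- parse_smiles(smiles[k])
    ab <- ChemmineR::atomblock(sdf[[k]])
    bb <- ChemmineR::bondblock(sdf[[k]])
    expect_equal(nrow(mine$atoms), nrow(ab), label = smiles[k])
    expect_equal(nrow(mine$bonds), nrow(bb), label = smiles[k])
    # same heavy-atom connectivity (undirected edge sets, 1-based)
    mine_edges <- sort(paste(pmin(mine$bonds$i, mine$bonds$j) + 1,
                             pmax(mine$bonds$i, mine$bonds$j) + 1))
    ob_edges <- sort(paste(pmin(bb[, 1], bb[, 2]), pmax(bb[, 1], bb[, 2])))
    expect_equal(mine_edges, ob_edges, label = smiles[k])
  }
})
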