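test_that("PDB and mmCIF round-trips preserve coordinates", {
  p <- ideal_pentamer(n_res = 3, id = "RT")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  cif <- withr::local_tempfile(fileext = ".cif")
  write_pentamer(p, pdb, "pdb")
  write_pentamer(p, cif, "cif")

  q_pdb <- read_pentamer(pdb)
  q_cif <- read_pentamer(cif)
  expect_equal(nrow(q_pdb$atoms), nrow(p$atoms))
  expect_equal(sort(unique(q_pdb$atoms$chain)), LETTERS[1:5])
  expect_equal(dplyr::n_distinct(q_pdb$atoms$res_seq), 3)

  key <- function(a) a[order(a$chain, a$res_seq, a$atom_name), ]
  a_pdb <- key(q_pdb$atoms)
  a_cif <- key(q_cif$atoms)
  # both dialects agree with the in-memory model to format precision
  expect_lt(max(abs(a_pdb$x - a_cif$x), abs(a_pdb$y - a_cif$y),
                abs(a_pdb$z - a_cif$z)), 1e-3)
  a_src <- key(p$atoms)
  expect_lt(max(abs(a_pdb$x - a_src$x)), 1e-3 + 1e-9)

  # parse -> write -> parse is idempotent once at format precision
  pdb2 <- withr::local_tempfile(fileext = ".pdb")
  write_pentamer(q_pdb, pdb2, "pdb")
  q2 <- read_pentamer(pdb2)
  expect_identical(key(q2$atoms)[, c("x", "y", "z")],
                   a_pdb[, c("x", "y", "z")])
})

test_that("missing and extra chains are reported by name", {
  p <- ideal_pentamer(n_res = 3)
  # drop chain E entirely
  p4 <- p
  p4$atoms <- p4$atoms[p4$atoms$chain != "E", ]
  pdb <- withr::local_tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = pdb,
                   xyz = as.numeric(t(as.matrix(p4$atoms[, c("x", "y", "z")]))),
                   resno = p4$atoms$res_seq, resid = p4$atoms$res_name,
                   eleno = seq_len(nrow(p4$atoms)),
                   elety = p4$atoms$atom_name, chain = p4$atoms$chain,
                   o = rep(1, nrow(p4$atoms)), b = rep(0, nrow(p4$atoms)),
                   elesy = p4$atoms$element)
  expect_error(read_pentamer(pdb), "E")

  # a sixth chain is ignored with a warning
  p6 <- p$atoms
  extra <- p6[p6$chain == "A", ]
  extra$chain <- "F"
  p6 <- rbind(p6, extra)
  pdb6 <- withr::local_tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = pdb6,
                   xyz = as.numeric(t(as.matrix(p6[, c("x", "y", "z")]))),
                   resno = p6$res_seq, resid = p6$res_name,
                   eleno = seq_len(nrow(p6)), elety = p6$atom_name,
                   chain = p6$chain, o = rep(1, nrow(p6)),
                   b = rep(0, nrow(p6)), elesy = p6$element)
  expect_warning(q <- read_pentamer(pdb6), "F")
  expect_setequal(unique(q$atoms$chain), LETTERS[1:5])
})

test_that("nonexistent and unparseable files raise parse errors", {
  expect_error(read_pentamer("no/such/file.pdb"), "not found")
  bad <- withr::local_tempfile(fileext = ".cif")
  writeLines("this is not a structure", bad)
  expect_error(read_pentamer(bad, format = "cif"))
})

test_that("altloc collapse follows occupancy with blank and tie rules", {
  p <- ideal_pentamer(n_res = 3)
  a <- p$atoms
  # duplicate one CB with altlocs A (0.6) / B (0.4)
  i <- which(a$chain == "A" & a$res_seq == 2 & a$atom_name == "CB")
  dup <- a[i, ]
  dup$altloc <- "B"; dup$occupancy <- 0.4; dup$x <- dup$x + 1
  a$altloc[i] <- "A"; a$occupancy[i] <- 0.6
  # duplicate a CG with a 0.5/0.5 tie
  j <- which(a$chain == "B" & a$res_seq == 1 & a$atom_name == "CG")
  tie <- a[j, ]
  tie$altloc <- "B"; tie$occupancy <- 0.5; tie$x <- tie$x + 1
  a$altloc[j] <- "A"; a$occupancy[j] <- 0.5
  # blank-altloc beats a higher-occupancy lettered conformer
  k <- which(a$chain == "C" & a$res_seq == 1 & a$atom_name == "CD1")
  blk <- a[k, ]
  blk$altloc <- "A"; blk$occupancy <- 0.9; blk$x <- blk$x + 1
  q <- pentamer("ALT", rbind(a, dup, tie, blk))

  r <- resolve_altlocs(q)
  expect_equal(nrow(r$atoms), nrow(p$atoms))
  expect_true(all(r$atoms$altloc == ""))
  # highest occupancy wins (kept coordinates are those of altloc A)
  expect_equal(r$atoms$x[r$atoms$chain == "A" & r$atoms$res_seq == 2 &
                           r$atoms$atom_name == "CB"],
               p$atoms$x[i])
  # tie broken by lowest altloc character
  expect_equal(r$atoms$x[r$atoms$chain == "B" & r$atoms$res_seq == 1 &
                           r$atoms$atom_name == "CG"],
               p$atoms$x[j])
  # blank conformer always kept
  expect_equal(r$atoms$x[r$atoms$chain == "C" & r$atoms$res_seq == 1 &
                           r$atoms$atom_name == "CD1"],
               p$atoms$x[k])
  # idempotent, and identity on altloc-free input
  expect_identical(resolve_altlocs(r)$atoms, r$atoms)
  expect_equal(resolve_altlocs(p)$atoms[, names(p$atoms)],
               p$atoms)
})

test_that("residue matching reports mutations and unmatched residues", {
  a <- ideal_pentamer(n_res = 4, id = "A")
  m <- match_residues(a, a)
  expect_true(all(m$status == "matched"))
  expect_true(all(purrr::map_int(m$common_atoms, length) == 8))

  # alanine substitution at position 2: side chain truncated at CB
  b <- a
  drop <- b$atoms$res_seq == 2 & !(b$atoms$atom_name %in%
                                     c("N", "CA", "C", "O", "CB"))
  b$atoms <- b$atoms[!drop, ]
  b$atoms$res_name[b$atoms$res_seq == 2] <- "ALA"
  m2 <- match_residues(a, b)
  at2 <- m2[m2$res_seq == 2, ]
  expect_true(all(at2$status == "mutated"))
  expect_true(all(purrr::map_lgl(at2$common_atoms, setequal,
                                 c("N", "CA", "C", "O", "CB"))))
  expect_equal(mutated_positions(a, b), 2L)

  # an extra C-terminal residue in a is unmatched
  c_str <- a
  c_str$atoms <- c_str$atoms[!(c_str$atoms$res_seq == 4), ]
  m3 <- match_residues(a, c_str)
  expect_true(all(m3$status[m3$res_seq == 4] == "only_a"))
  expect_true(all(m3$status[m3$res_seq < 4] == "matched"))
})
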