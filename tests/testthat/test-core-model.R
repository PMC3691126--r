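test_that("structure round trip preserves the atom table and coordinates", {
  cx <- make_two_chain_complex(3, 3, res_types_a = c("ALA", "LYS", "ALA"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(cx$topology, cx$coords, f)
  s <- read_structure(f)
  cols <- c("serial", "name", "element", "res_name", "res_id", "chain_id")
  expect_identical(s$topology$atoms[cols], cx$topology$atoms[cols])
  expect_lt(max(abs(s$coords - cx$coords)), 1e-3)  # writer precision
  # chains become partitions and receptor/gprotein never overlap
  expect_length(intersect(cx$topology$partitions$receptor,
                          cx$topology$partitions$gprotein), 0)
})

test_that("malformed and ambiguous PDB input is rejected with context", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1      11.000  2.000",
               "END"), f)
  expect_error(read_structure(f), "line 1")
  writeLines(c(
    "ATOM      1  CA  ALA A   1A     11.000   2.000   3.000  1.00  0.00           C",
    "END"), f)
  expect_error(read_structure(f), "insertion")
  atoms <- data.frame(serial = 1:2, name = c("CA", "CA"),
                      element = "C", res_name = "ALA", res_id = 1L,
                      chain_id = "A")
  expect_error(topology(atoms), "duplicate")
})

test_that("multi-model trajectories are delimited and atom-checked", {
  cx <- make_two_chain_complex(2, 2)
  traj <- make_static_trajectory(cx, 3, dt = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, cx$topology, f)
  rt <- read_trajectory(f, cx$topology, dt = 2)
  expect_equal(rt$n_frames, 3)
  expect_lt(max(abs(rt$coords - traj$coords)), 1e-3)
  expect_equal(rt$times, c(0, 2, 4))
  small <- make_two_chain_complex(2, 3)
  expect_error(read_trajectory(f, small$topology, dt = 2),
               "atom-count mismatch")
})

test_that("generated trajectories carry an arithmetic time axis", {
  cx <- make_two_chain_complex(4, 4)
  traj <- make_contact_trajectory(
    cx, data.frame(res_a = 2, res_b = 2, occupancy = 0.5),
    n_frames = 200, dt = 100)
  expect_equal(traj$times, 100 * (0:199))
  expect_error(trajectory(traj$coords, times = rev(traj$times)),
               "strictly increasing")
})

test_that("parameter loading matches by residue/name with wildcards", {
  cx <- make_two_chain_complex(3, 3,
                               res_types_a = c("ALA", "LYS", "ALA"),
                               res_types_b = c("ALA", "GLU", "ALA"))
  top <- cx$topology
  f <- withr::local_tempfile(fileext = ".json")

  # all-zero charges through a pure wildcard entry
  write_parameters(list(atoms = data.frame(
    res_name = "*", name = "*", charge = 0, gb_radius = 1.5,
    lj_rmin_half = 1.9, lj_epsilon = 0.1)), f)
  flat <- load_parameters(f, top)
  expect_equal(sum(flat$atoms$charge), 0)

  # the synthetic entry set reproduces per-residue charge sums
  write_parameters(list(atoms = synthetic_parameter_entries()), f)
  full <- load_parameters(f, top)
  sums <- tapply(full$atoms$charge,
                 paste(full$atoms$chain_id, full$atoms$res_id), sum)
  expect_equal(as.numeric(sums[c("R 2", "G 2")]), c(1, -1))
  expect_equal(sum(abs(full$atoms$charge)), 2)

  # strict mode names the unmatched atom
  entries <- synthetic_parameter_entries()
  entries <- entries[!(entries$res_name == "LYS" & entries$name == "NZ"), ]
  write_parameters(list(atoms = entries), f)
  expect_error(load_parameters(f, top), "LYS NZ")
  expect_warning(load_parameters(f, top, strict = FALSE), "LYS NZ")
})

test_that("generic numbers annotate residues and collide loudly", {
  cx <- make_two_chain_complex(3, 2)
  top <- cx$topology
  map <- data.frame(chain_id = "R", res_id = 2L, generic = "6.55")
  ann <- apply_generic_numbers(top, map)
  rt <- residue_table(ann)
  expect_equal(rt$generic[rt$chain_id == "R" & rt$res_id == 2], "6.55")
  expect_equal(residue_label("HIS", 393, "6.55"), "H393^6.55")
  # empty map leaves everything untouched
  expect_identical(apply_generic_numbers(top, map[0, ]), top)
  # absent residue skipped with a warning
  expect_warning(
    apply_generic_numbers(top, data.frame(chain_id = "R", res_id = 99L,
                                          generic = "1.50")), "skipped")
  # duplicate label within a chain is an error
  expect_error(apply_generic_numbers(top, data.frame(
    chain_id = "R", res_id = c(1L, 2L), generic = "6.55")), "collision")
  # TSV round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(map, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_generic_number_map(f), map)
})

test_that("exclusion derivation finds 1-2/1-3 and 1-4 paths", {
  # linear chain 1-2-3-4-5
  bonds <- data.frame(i = 1:4, j = 2:5, k = 1, r0 = 1)
  ex <- derive_exclusions(5, bonds)
  expect_setequal(apply(ex$excl12_13, 1, paste, collapse = "-"),
                  c("1-2", "2-3", "3-4", "4-5", "1-3", "2-4", "3-5"))
  expect_setequal(apply(ex$pairs14, 1, paste, collapse = "-"),
                  c("1-4", "2-5"))
})
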