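test_that("FASTA and Clustal encodings load identically", {
  ids <- c("b2ar", "d2r")
  seqs <- c("QKAL-RE", "QRAL-KD")
  ff <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(ids, seqs, ff)
  fc <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "",
               sprintf("%-16s%s", ids[1], substr(seqs[1], 1, 4)),
               sprintf("%-16s%s", ids[2], substr(seqs[2], 1, 4)),
               "                *.**", "",
               sprintf("%-16s%s", ids[1], substr(seqs[1], 5, 7)),
               sprintf("%-16s%s", ids[2], substr(seqs[2], 5, 7)),
               "                  : ", ""), fc)
  a1 <- read_alignment(ff, "fasta")
  a2 <- read_alignment(fc, "clustal")
  expect_equal(a1$ids, a2$ids)
  expect_equal(unname(a1$mat), unname(a2$mat))
  expect_equal(ncol(a1$mat), 7)
})

test_that("ragged alignments are rejected", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(c("a", "b"), c("QKAL", "QKALR"), f)
  expect_error(read_alignment(f), "ragged")
})

test_that("residue numbering maps through gaps onto alignment columns", {
  f <- withr::local_tempfile(fileext = ".fasta")
  # ref has a 3-gap insertion before its 3rd residue
  write_fasta_alignment(c("ref", "oth"),
                        c("QK---ALRE", "QKWWWALKD"), f)
  aln <- read_alignment(f)
  cols <- alignment_columns(aln, "ref")
  expect_equal(cols, c(1, 2, 6, 7, 8, 9))
  # ungapped sequence: column equals residue index
  expect_equal(alignment_columns(aln, "oth"), 1:9)
})

test_that("interface tables project onto the alignment with flags", {
  fx <- fixture_saltbridge(2)
  cfg <- analysis_config()
  tab <- residue_contact_occupancy(fx$traj, fx$cx$topology, cfg)
  tab <- annotate_interactions(fx$traj, fx$cx$topology, tab, cfg)
  f <- withr::local_tempfile(fileext = ".fasta")
  # chain R sequence is A A K A L A; insert a gap column to shift it
  write_fasta_alignment(c("recA", "recB"), c("AA-KALA", "AASRLLA"), f)
  aln <- read_alignment(f)
  mapped <- map_interface_to_alignment(tab, aln, "recA", side = "a")
  expect_setequal(mapped$res_id, c(2, 3, 4))
  # residue 3 (K) lands past the gap at column 4
  expect_equal(mapped$column[mapped$res_id == 3], 4)
  expect_true(mapped$ionic[mapped$res_id == 3])
  expect_equal(mapped$aligned_aa[mapped$res_id == 3], "K")
  # residues beyond the sequence range are named in the error
  short <- aln; short$mat <- short$mat[, 1:3]
  expect_error(map_interface_to_alignment(tab, short, "recA"), "K3")
})

test_that("conservation follows the identical/similar/different/gap rules", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(c("ref", "s1"), c("QRFA-", "QKM-W"), f)
  aln <- read_alignment(f)
  cls <- conservation_classes(aln, "ref")
  expect_equal(unname(cls["s1", ]),
               c("identical",       # Q vs Q
                 "similar",         # R vs K (the Arg/Lys rule)
                 "different",       # F vs M
                 "not_applicable",  # other gapped
                 "not_applicable")) # reference gapped
  expect_error(conservation_classes(aln, "nope"), "not in alignment")
})

test_that("conservation classes are permutation-invariant across sequences", {
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(c("ref", "x", "y"), c("QRF", "QKM", "ARF"), f1)
  write_fasta_alignment(c("ref", "y", "x"), c("QRF", "ARF", "QKM"), f2)
  c1 <- conservation_classes(read_alignment(f1), "ref")
  c2 <- conservation_classes(read_alignment(f2), "ref")
  expect_equal(c1[c("x", "y"), ], c2[c("x", "y"), ])
})

test_that("growing the similarity groups never adds selectivity candidates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(c("A", "B"), c("QRFDE", "QKMED"), f)
  aln <- read_alignment(f)
  mk_map <- function(ids, cols) {
    data.frame(chain_id = "R", res_id = cols, res_name = "ALA",
               generic = NA_character_, column = cols, aligned_aa = "A",
               degree = 1L, tier = "low", ionic = FALSE, hbond = FALSE,
               stringsAsFactors = FALSE)
  }
  m <- mk_map("A", 1:5)
  narrow <- compare_complexes(m, m, aln, "A", "B",
                              similarity_groups = list(c("R", "K")))
  wide <- compare_complexes(m, m, aln, "A", "B",
                            similarity_groups = list(c("R", "K"),
                                                     c("D", "E")))
  expect_true(all(wide$selectivity_candidate <= narrow$selectivity_candidate))
  expect_true(sum(wide$selectivity_candidate) <=
                sum(narrow$selectivity_candidate))
})

test_that("complex comparison labels shared and unique interface columns", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(c("A", "B"), c("QRFDE", "QKMED"), f)
  aln <- read_alignment(f)
  mk <- function(cols) data.frame(
    chain_id = "R", res_id = cols, res_name = "ALA",
    generic = NA_character_, column = cols, aligned_aa = "A",
    degree = 1L, tier = "low", ionic = FALSE, hbond = FALSE,
    stringsAsFactors = FALSE)
  cmp <- compare_complexes(mk(c(1, 3)), mk(c(1, 4)), aln, "A", "B")
  expect_equal(cmp$status[cmp$column == 1], "shared")
  expect_equal(cmp$status[cmp$column == 3], "A_only")
  expect_equal(cmp$status[cmp$column == 4], "B_only")
  # identical tables give zero unique columns
  cmp2 <- compare_complexes(mk(1:3), mk(1:3), aln, "A", "B")
  expect_true(all(cmp2$status == "shared"))
  # identical residues in both references are never candidates
  expect_false(cmp$selectivity_candidate[cmp$column == 1])  # Q vs Q
  expect_true(cmp$selectivity_candidate[cmp$column == 3])   # F vs M
})

test_that("selectivity reports mark unscanned residues n.d. and rerun identically", {
  fx <- fixture_saltbridge(2)
  cfg <- analysis_config(sasa_points = 240)
  tab <- residue_contact_occupancy(fx$traj, fx$cx$topology, cfg)
  tab <- annotate_interactions(fx$traj, fx$cx$topology, tab, cfg)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(c("recA", "recB"), c("AAKALA", "AARLLA"), f)
  aln <- read_alignment(f)
  mapped <- map_interface_to_alignment(tab, aln, "recA", side = "a")
  scan <- alanine_scan(fx$traj, fx$cx$topology,
                       data.frame(chain_id = "R", res_id = 3L), cfg)
  cmp <- compare_complexes(mapped, mapped, aln, "recA", "recB")
  rep1 <- selectivity_report(cmp, mapped, mapped, scan, NULL)
  # the scanned lysine reports a number, its alanine neighbours n.d.
  expect_match(rep1$ddG_a[rep1$residue_a == "K3"], "^-?\\d")
  expect_equal(unique(rep1$ddG_a[rep1$residue_a != "K3"]), "n.d.")
  # ionic contact renders as polar interaction type
  expect_equal(rep1$type_a[rep1$residue_a == "K3"], "polar")
  expect_equal(rep1$type_a[rep1$residue_a == "A2"], "hydrophobic")
  # byte-identical re-run
  o1 <- withr::local_tempfile(fileext = ".tsv")
  o2 <- withr::local_tempfile(fileext = ".tsv")
  selectivity_report(cmp, mapped, mapped, scan, NULL, path = o1)
  selectivity_report(cmp, mapped, mapped, scan, NULL, path = o2)
  expect_identical(readLines(o1), readLines(o2))
})
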