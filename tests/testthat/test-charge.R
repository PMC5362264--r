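# residue-charge model: net charge, composition, mutagenesis

test_that("net_charge counts K/R minus D/E over the window", {
  expect_identical(net_charge("KKCCKK"), 4L)
  expect_identical(net_charge("DEKR"), 0L)
  expect_identical(net_charge("KDCCEK", c(2, 5)), -2L)
  # empty window
  expect_identical(net_charge("KKKK", c(3, 2)), 0L)
  # histidine is never counted
  expect_identical(net_charge("HHHH"), 0L)
})

test_that("net_charge rejects non-canonical residues, naming the position", {
  expect_error(net_charge("KKXK"), "position 3")
  expect_error(net_charge("KKKK", c(0, 2)), "bounds")
  expect_error(net_charge("KKKK", c(2, 9)), "bounds")
})

test_that("net_charge is additive over disjoint adjacent windows", {
  set.seed(42)
  for (i in 1:20) {
    seq <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        60, replace = TRUE), collapse = "")
    cut <- sample(2:58, 1)
    expect_identical(
      net_charge(seq, c(1, cut)) + net_charge(seq, c(cut + 1, 60)),
      net_charge(seq, c(1, 60)))
  }
})

test_that("charge_composition reports raw and half-up-rounded percentages", {
  cc <- charge_composition("DEKR")
  expect_identical(cc$length, 4L)
  expect_equal(cc$percent_negative, 50)
  expect_equal(cc$percent_positive, 50)
  cc0 <- charge_composition("GGGGGGGGGG")
  expect_equal(cc0$percent_negative, 0)
  expect_equal(cc0$percent_positive, 0)
  expect_error(charge_composition(""), "non-empty")
})

test_that("charge_composition percentages are invariant under reversal", {
  set.seed(7)
  for (i in 1:10) {
    seq <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        30, replace = TRUE), collapse = "")
    rev_seq <- paste(rev(strsplit(seq, "")[[1]]), collapse = "")
    expect_equal(charge_composition(seq)$percent_negative,
                 charge_composition(rev_seq)$percent_negative)
    expect_equal(charge_composition(seq)$percent_positive,
                 charge_composition(rev_seq)$percent_positive)
  }
})

test_that("round_half_up rounds .5 away from zero", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, 14.563)), c(1, 2, 3, 15))
  expect_equal(round_half_up(-0.5), -1)
})

test_that("mutations validate the from-residue and apply in place", {
  pc <- protein_construct("toy", "KKCCKK", mutations = c("K1A", "K6A"))
  expect_identical(construct_sequence(pc), "AKCCKA")
  # from-residue mismatch names position and found residue
  expect_error(protein_construct("bad", "KKCCKK", mutations = c("C1A")),
               "position 1")
  # idempotent with empty mutation list
  pc0 <- protein_construct("id", "KKCCKK")
  expect_identical(construct_sequence(pc0), "KKCCKK")
})

test_that("each K->A inside the window lowers the charge by exactly 1; C->G never does", {
  seq <- "DKEKCCGKCKD"
  base <- net_charge(seq)
  kpos <- which(strsplit(seq, "")[[1]] == "K")
  for (n_mut in seq_along(kpos)) {
    mut <- mutations_k_to_a(seq, kpos[seq_len(n_mut)])
    pc <- protein_construct("m", seq, mutations = mut)
    expect_identical(net_charge(construct_sequence(pc)), base - n_mut)
  }
  # K->L behaves identically (both targets neutral)
  mut_l <- mutations_k_to_l(seq, kpos[1:2])
  pc_l <- protein_construct("l", seq, mutations = mut_l)
  expect_identical(net_charge(construct_sequence(pc_l)), base - 2L)
  # C->G leaves the window charge unchanged
  pc_cg <- protein_construct("cg", seq, crr_window = c(1, 11),
                             mutations = mutations_c_to_g(seq, c(1, 11)))
  expect_identical(net_charge(construct_sequence(pc_cg)), base)
})

test_that("crr_charge_table gives one row per construct and enforces contracts", {
  seq <- "KKCCKKDD"
  a <- protein_construct("a", seq, crr_window = c(1, 8))
  b <- protein_construct("b", seq, crr_window = c(1, 6))
  tab <- crr_charge_table(list(a, b))
  expect_identical(tab$label, c("a", "b"))
  expect_identical(tab$net_charge, c(2L, 4L))
  # whole-sequence window agrees with charge_composition net charge
  expect_identical(tab$net_charge[1], charge_composition(seq)$net_charge)
  # missing window and duplicate labels are rejected
  expect_error(crr_charge_table(list(protein_construct("c", seq))),
               "no CRR window")
  expect_error(crr_charge_table(list(a, a)), "duplicate")
})

test_that("FASTA round trip preserves label and sequence", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seq1 test protein", "MKKCC", "KKDE"), path)
  tab <- read_protein_fasta(path)
  expect_identical(tab$label, "seq1")
  expect_identical(tab$sequence, "MKKCCKKDE")
})

test_that("bundled SNAP25B sequence matches its published composition", {
  seq <- snap25b_sequence()
  cc <- charge_composition(seq)
  expect_identical(cc$length, 206L)
  expect_identical(cc$n_acidic, 43L)   # 21% of 206
  expect_identical(cc$n_basic, 30L)    # 14.6% of 206
  expect_identical(cc$net_charge, -13L)
})
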