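test_that("dihedrals from constructed coordinates recover the torsions", {
  phi <- c(0, -63, 120, -170, 48)
  psi <- c(-42, 155, -60, 90, 0)
  bb <- build_backbone(phi, psi)
  d <- compute_backbone_dihedrals(bb$n_xyz, bb$ca_xyz, bb$c_xyz)
  expect_true(is.na(d$phi[1]))
  expect_true(is.na(d$psi[5]))
  expect_equal(d$phi[-1], phi[-1], tolerance = 1e-6)
  expect_equal(d$psi[-5], psi[-5], tolerance = 1e-6)
})

test_that("mirror imaging negates all dihedrals", {
  bb <- build_backbone(c(0, -60, 120), c(140, -45, 0))
  flip <- function(m) { m[, 3] <- -m[, 3]; m }
  d <- compute_backbone_dihedrals(bb$n_xyz, bb$ca_xyz, bb$c_xyz)
  dm <- compute_backbone_dihedrals(flip(bb$n_xyz), flip(bb$ca_xyz),
                                   flip(bb$c_xyz))
  expect_equal(dm$phi, -d$phi, tolerance = 1e-9)
  expect_equal(dm$psi, -d$psi, tolerance = 1e-9)
})

test_that("termini, missing atoms and chain breaks leave dihedrals undefined", {
  bb <- build_backbone(c(0, -60), c(140, 0))
  d <- compute_backbone_dihedrals(bb$n_xyz, bb$ca_xyz, bb$c_xyz)
  expect_true(is.na(d$phi[1]) && is.na(d$psi[2]))
  expect_false(is.na(d$psi[1]) || is.na(d$phi[2]))
  # missing CA on residue 2
  bb2 <- build_backbone(c(0, -60, 120), c(140, -45, 0))
  bb2$ca_xyz[2, ] <- NA
  d2 <- compute_backbone_dihedrals(bb2$n_xyz, bb2$ca_xyz, bb2$c_xyz)
  expect_true(all(is.na(c(d2$phi[2], d2$psi[2]))))
  # break the 2-3 peptide bond by translating the tail
  bb3 <- build_backbone(c(0, -60, 120, -70), c(140, -45, 60, 0))
  bb3$n_xyz[3:4, ] <- bb3$n_xyz[3:4, ] + 10
  bb3$ca_xyz[3:4, ] <- bb3$ca_xyz[3:4, ] + 10
  bb3$c_xyz[3:4, ] <- bb3$c_xyz[3:4, ] + 10
  d3 <- compute_backbone_dihedrals(bb3$n_xyz, bb3$ca_xyz, bb3$c_xyz)
  expect_true(is.na(d3$psi[2]) && is.na(d3$phi[3]))
  expect_false(is.na(d3$phi[2]) || is.na(d3$psi[3]))
})

test_that("backbones written to PDB read back with the same dihedrals", {
  path <- withr::local_tempfile(fileext = ".pdb")
  phi <- c(0, -60, -65, -58); psi <- c(-45, -40, -48, 0)
  write_toy_pdb(path, list(A = list(phi = phi, psi = psi, seq = "MKVL")))
  ch <- read_structure_backbone(path, "A")
  expect_equal(ch$sequence, "MKVL")
  d <- compute_backbone_dihedrals(ch$n_xyz, ch$ca_xyz, ch$c_xyz)
  expect_equal(d$phi[-1], phi[-1], tolerance = 1e-3)  # PDB stores 3 decimals
  expect_equal(d$psi[-4], psi[-4], tolerance = 1e-3)
})

test_that("secondary-structure labels parse from tables and DSSP output", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain_id\tresidue_index\tlabel", "S1:A\t2\tH", "S1:A\t3\tE"),
             tsv)
  tab <- read_ss_labels(tsv)
  expect_equal(tab$label, c("H", "E"))
  dssp <- withr::local_tempfile(fileext = ".dssp")
  writeLines(c(
    "==== Secondary Structure Definition ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    2 A M  H  >  S+ ",
    "    2    3 A K  E     S+ ",
    "    3    4 A V         + "), dssp)
  lab <- read_ss_labels(dssp)
  expect_equal(lab$chain_id, c("A", "A", "A"))
  expect_equal(lab$residue_index, c(2L, 3L, 4L))
  expect_equal(lab$label, c("H", "E", "C"))
})

test_that("normalized similarity equals the LCS-based formula", {
  ns <- normalized_similarity(c(a = "MKVL", b = "MVL"))
  expect_equal(diag(ns$s_tilde), c(a = 1, b = 1))
  expect_equal(ns$s["a", "b"], 3)
  expect_equal(ns$s_tilde["a", "b"], 3 / sqrt(4 * 3))
  # disjoint alphabets share nothing
  expect_equal(normalized_similarity(c("MKVL", "WYHE"))$s_tilde[1, 2], 0)
  expect_error(normalized_similarity(c("MK", "")), "non-empty")
  # random sequences against the DP oracle
  set.seed(31)
  aas <- c("A", "C", "D", "E", "M", "K", "V", "L")
  seqs <- replicate(5, paste(sample(aas, sample(3:8, 1), replace = TRUE),
                             collapse = ""))
  ns2 <- normalized_similarity(seqs)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(ns2$s[i, j], lcs_dp(seqs[i], seqs[j]))
})

test_that("farthest-first filtering caps pairwise similarity at tau", {
  # all off-diagonal similarities above tau: only the start survives
  st <- matrix(0.9, 4, 4); diag(st) <- 1
  expect_equal(fps_filter(st, tau = 0.7), "1")
  # all-zero similarities: everything survives
  st0 <- diag(4)
  expect_equal(fps_filter(st0, tau = 0.7), as.character(1:4))
  # random matrices against the greedy oracle
  set.seed(37)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    st <- matrix(runif(n * n), n)
    st <- (st + t(st)) / 2; diag(st) <- 1
    sel <- as.integer(fps_filter(st, tau = 0.7))
    expect_equal(sel, greedy_fps(st, 0.7))
    off <- st[sel, sel][upper.tri(diag(length(sel)))]
    if (length(off) > 0) expect_lte(max(off), 0.7)
  }
})

test_that("aggregation applies the torus mean and unanimity rules", {
  base <- data.frame(accession = "P1", accession_index = 1L,
                     chain_id = "a", phi = 170, psi = 170, ss = "H",
                     codon = "ATG", stringsAsFactors = FALSE)
  two <- rbind(base, within(base, { chain_id <- "b"; phi <- -170
                                    psi <- -130 }))
  agg <- aggregate_records(two)
  expect_equal(agg$records$phi, 180)
  expect_equal(agg$records$psi, -160)
  expect_equal(agg$records$n_chains, 2L)
  # single chain passes through unchanged
  one <- aggregate_records(base)
  expect_equal(one$records[, c("phi", "psi", "codon", "ss")],
               base[, c("phi", "psi", "codon", "ss")])
  # conflicting secondary structure drops the position
  sslab <- two; sslab$ss[2] <- "E"
  expect_equal(nrow(aggregate_records(sslab)$records), 0L)
  expect_equal(unname(aggregate_records(sslab)$report["ss_conflict"]), 1L)
})

test_that("aggregation report is lossless over positions", {
  set.seed(41)
  n <- 40
  obs <- data.frame(
    accession = "P1", accession_index = rep(1:20, 2),
    chain_id = rep(c("a", "b"), each = 20),
    phi = runif(n, -180, 180), psi = runif(n, -180, 180),
    ss = sample(c("H", "E"), n, replace = TRUE),
    codon = sample(c("ATG", "AAA", "AMBIGUOUS", "UNASSIGNED"), n,
                   replace = TRUE),
    stringsAsFactors = FALSE)
  obs$phi[sample(n, 5)] <- NA
  agg <- aggregate_records(obs)
  rep_ <- agg$report
  expect_equal(unname(rep_["input_rows"]), n)
  reasons <- c("dihedral_undefined", "codon_unassigned", "codon_ambiguous",
               "codon_conflict", "ss_conflict", "retained")
  expect_equal(sum(rep_[reasons]), unname(rep_["positions"]))
  expect_equal(nrow(agg$records), unname(rep_["retained"]))
  # aggregated dihedrals stay canonical
  if (nrow(agg$records) > 0) {
    expect_true(all(agg$records$phi > -180 & agg$records$phi <= 180))
    expect_true(all(agg$records$psi > -180 & agg$records$psi <= 180))
  }
})

test_that("codon samples pool only E/H residues with valid sense codons", {
  rec <- data.frame(
    accession = "P1", index = 1:10,
    phi = runif(10, -180, 180), psi = runif(10, -180, 180),
    codon = c(rep("GAA", 8), "AMBIGUOUS", "UNASSIGNED"),
    ss = c("E", "E", "E", "E", "H", "T", "C", "B", "E", "H"),
    n_chains = 1L, stringsAsFactors = FALSE)
  obs <- extract_codon_samples(rec)
  expect_equal(sum(obs$ss == "E"), 4L)
  expect_equal(sum(obs$ss == "H"), 1L)
  expect_true(all(obs$codon == "GAA"))
  # fully ambiguous records yield an empty pool
  rec$codon <- "AMBIGUOUS"
  expect_equal(nrow(extract_codon_samples(rec)), 0L)
})

test_that("the build pipeline filters, assigns and aggregates end to end", {
  fx <- make_pipeline_fixture(withr::local_tempdir())
  mf <- read.delim(fx$manifest, stringsAsFactors = FALSE)
  built <- build_protein_records(mf, read_ss_labels(fx$ss),
                                 read_cds_fasta(fx$fasta),
                                 default_config())
  # P2 duplicates P1's sequence and is removed by redundancy filtering;
  # quality gates drop the 2.5-Angstrom structure
  expect_setequal(built$selected_accessions, c("P1", "P3"))
  expect_equal(unname(built$report["manifest_chains"]), 5L)
  expect_equal(unname(built$report["chains_after_quality_and_fps"]), 3L)
  # residues 2..5 of each retained accession have defined dihedrals,
  # unanimous labels and assigned codons: 4 positions each
  expect_equal(nrow(built$records), 8L)
  expect_equal(sum(built$records$accession == "P1"), 4L)
  expect_true(all(built$records$index %in% 2:5))
  # P1's two chains aggregated per position
  expect_true(all(built$records$n_chains[built$records$accession == "P1"]
                  == 2L))
  expect_setequal(unique(built$records$ss[built$records$accession == "P1"]),
                  "H")
  # assigned codons translate back to the reference residues
  code <- standard_genetic_code()
  aa_of <- function(acc, seqs) substring(seqs[[acc]], built$records$index,
                                         built$records$index)
  seqs <- list(P1 = fx$seq1, P3 = fx$seq3)
  expect_equal(unname(code[built$records$codon]),
               substring(unlist(seqs[built$records$accession]),
                         built$records$index, built$records$index),
               ignore_attr = TRUE)
})

test_that("protein records round-trip through the text format", {
  rec <- data.frame(accession = c("P1", "P1"), index = 1:2,
                    phi = c(-60.5, 120), psi = c(-45.25, 130),
                    codon = c("ATG", "AAA"), ss = c("H", "E"),
                    n_chains = c(2L, 1L), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_protein_records(rec, path)
  back <- read_protein_records(path)
  expect_equal(back, rec)
})
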