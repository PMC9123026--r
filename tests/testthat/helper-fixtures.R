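# Construction of synthetic backbone coordinates with prescribed torsions
# (the oracle for dihedral computation) and tiny PDB/label/FASTA fixtures
# for the data-preparation pipeline.

# place atom D given A-B-C, bond length |C-D|, angle B-C-D and torsion
# A-B-C-D (right-handed convention matching compute_backbone_dihedrals)
place_atom <- function(A, B, C, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180; ta <- torsion_deg * pi / 180
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  unit <- function(v) v / sqrt(sum(v^2))
  bc <- unit(C - B); n <- unit(cross(B - A, bc)); m <- cross(n, bc)
  d <- bond * c(-cos(th), sin(th) * cos(ta), -sin(th) * sin(ta))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# ideal-geometry backbone with the requested phi/psi (phi[1], psi[R] unused)
build_backbone <- function(phi, psi, omega = 180) {
  R <- length(phi)
  stopifnot(length(psi) == R)
  n_xyz <- ca_xyz <- c_xyz <- matrix(NA_real_, R, 3)
  n_xyz[1, ] <- c(0, 0, 0)
  ca_xyz[1, ] <- c(1.458, 0, 0)
  c_xyz[1, ] <- ca_xyz[1, ] + 1.525 * c(-cos(111 * pi / 180),
                                        sin(111 * pi / 180), 0)
  for (i in seq_len(R - 1)) {
    n_xyz[i + 1, ] <- place_atom(n_xyz[i, ], ca_xyz[i, ], c_xyz[i, ],
                                 1.329, 116.2, psi[i])
    ca_xyz[i + 1, ] <- place_atom(ca_xyz[i, ], c_xyz[i, ], n_xyz[i + 1, ],
                                  1.458, 121.7, omega)
    c_xyz[i + 1, ] <- place_atom(c_xyz[i, ], n_xyz[i + 1, ], ca_xyz[i + 1, ],
                                 1.525, 111, phi[i + 1])
  }
  list(n_xyz = n_xyz, ca_xyz = ca_xyz, c_xyz = c_xyz)
}

# minimal but column-correct PDB writer for N/CA/C backbones
write_toy_pdb <- function(path, chains) {
  lines <- character(0)
  serial <- 0L
  for (ch in names(chains)) {
    spec <- chains[[ch]]
    bb <- build_backbone(spec$phi, spec$psi)
    aa3 <- bio3d::aa123(strsplit(spec$seq, "")[[1]])
    for (i in seq_along(aa3)) {
      for (atom in c("N", "CA", "C")) {
        xyz <- switch(atom, N = bb$n_xyz, CA = bb$ca_xyz, C = bb$c_xyz)[i, ]
        serial <- serial + 1L
        lines <- c(lines, paste0(
          "ATOM  ", sprintf("%5d", serial), " ", sprintf(" %-3s", atom), " ",
          sprintf("%3s", aa3[i]), " ", ch, sprintf("%4d", i), "    ",
          sprintf("%8.3f%8.3f%8.3f", xyz[1], xyz[2], xyz[3]),
          sprintf("%6.2f%6.2f", 1, 0)))
      }
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# reverse-translate an amino-acid string with a fixed codon choice
reverse_translate <- function(aa, code = standard_genetic_code()) {
  sense <- code[code != "*"]
  pick <- vapply(strsplit(aa, "")[[1]],
                 function(a) sort(names(sense)[sense == a])[1], character(1))
  paste(pick, collapse = "")
}

# three-accession pipeline fixture: P1 with two chains (aggregation), P2 a
# duplicate of P1's sequence (removed by redundancy filtering), P3 distinct.
# Residues 2..5 of each 6-residue chain have defined (phi, psi).
make_pipeline_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seq1 <- "MKVLAG"; seq3 <- "MWYHED"
  helix <- c(-60, -45); strand <- c(-120, 130)
  ang1 <- list(phi = c(0, rep(helix[1], 5)), psi = c(rep(helix[2], 5), 0))
  ang1b <- list(phi = c(0, rep(helix[1] + 8, 5)),
                psi = c(rep(helix[2] - 8, 5), 0))
  ang3 <- list(phi = c(0, rep(strand[1], 5)), psi = c(rep(strand[2], 5), 0))
  p <- function(f) file.path(dir, f)
  write_toy_pdb(p("s1.pdb"), list(A = c(ang1, seq = seq1)))
  write_toy_pdb(p("s2.pdb"), list(A = c(ang1b, seq = seq1)))
  write_toy_pdb(p("s3.pdb"), list(A = c(ang1, seq = seq1)))   # P2 duplicate
  write_toy_pdb(p("s4.pdb"), list(A = c(ang3, seq = seq3)))
  write_toy_pdb(p("s5.pdb"), list(A = c(ang3, seq = seq3)))   # fails gates
  manifest <- data.frame(
    path = c(p("s1.pdb"), p("s2.pdb"), p("s3.pdb"), p("s4.pdb"), p("s5.pdb")),
    structure_id = c("S1", "S2", "S3", "S4", "S5"),
    chain = "A",
    accession = c("P1", "P1", "P2", "P3", "P3"),
    resolution = c(1.5, 1.6, 1.5, 1.7, 2.5),
    rfree = c(0.20, 0.21, 0.20, 0.22, 0.20))
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # labels: H for P1 chains, E for P3, on the defined residues 2..5
  lab <- do.call(rbind, lapply(
    list(c("S1:A", "H"), c("S2:A", "H"), c("S3:A", "H"),
         c("S4:A", "E"), c("S5:A", "E")),
    function(x) data.frame(chain_id = x[1], residue_index = 1:6,
                           label = c("C", rep(x[2], 4), "C"))))
  utils::write.table(lab, p("ss.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c(">P1 cds", paste0(reverse_translate(seq1), "TAA"),
               ">P2 cds", paste0(reverse_translate(seq1), "TAA"),
               ">P3 cds", paste0(reverse_translate(seq3), "TAA")),
             p("cds.fasta"))
  list(dir = dir, manifest = p("manifest.tsv"), ss = p("ss.tsv"),
       fasta = p("cds.fasta"), seq1 = seq1, seq3 = seq3)
}
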