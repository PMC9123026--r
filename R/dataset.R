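# Signed dihedral angle (degrees) defined by four points, rows of a 4 x 3
# matrix. Right-handed convention: atan2(dot(cross(n1, u2), n2), dot(n1, n2)).
.dihedral4 <- function(p) {
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(sum(b2^2)))
  wrap_angle(atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi)
}

#' Backbone dihedral angles from per-residue N/CA/C coordinates
#'
#' phi(i) = dihedral(C(i-1), N(i), CA(i), C(i)) and psi(i) = dihedral(N(i),
#' CA(i), C(i), N(i+1)). The first residue has no phi, the last no psi. A
#' missing backbone atom leaves the affected dihedrals `NA`, and a peptide
#' bond longer than `break_cutoff` (C(i)-N(i+1) distance) is treated as a
#' chain break, i.e. both flanking residues behave like termini.
#'
#' @param n_xyz,ca_xyz,c_xyz numeric R x 3 matrices of N, CA and C atom
#'   coordinates (Angstrom), one row per residue in chain order; missing
#'   atoms as `NA` rows.
#' @param break_cutoff maximum C-N peptide-bond length in Angstrom
#'   (default 2.5).
#' @return data.frame with columns `phi`, `psi` (degrees, wrapped, `NA`
#'   where undefined).
#' @export
compute_backbone_dihedrals <- function(n_xyz, ca_xyz, c_xyz,
                                       break_cutoff = 2.5) {
  n_xyz <- as.matrix(n_xyz); ca_xyz <- as.matrix(ca_xyz)
  c_xyz <- as.matrix(c_xyz)
  R <- nrow(n_xyz)
  stopifnot(nrow(ca_xyz) == R, nrow(c_xyz) == R)
  ok <- function(m, i) all(is.finite(m[i, ]))
  bonded <- function(i) {            # peptide bond between residues i, i+1
    if (!ok(c_xyz, i) || !ok(n_xyz, i + 1L)) return(FALSE)
    sqrt(sum((c_xyz[i, ] - n_xyz[i + 1L, ])^2)) <= break_cutoff
  }
  phi <- psi <- rep(NA_real_, R)
  for (i in seq_len(R)) {
    if (i > 1L && bonded(i - 1L) && ok(n_xyz, i) && ok(ca_xyz, i) &&
        ok(c_xyz, i))
      phi[i] <- .dihedral4(rbind(c_xyz[i - 1L, ], n_xyz[i, ], ca_xyz[i, ],
                                 c_xyz[i, ]))
    if (i < R && bonded(i) && ok(n_xyz, i) && ok(ca_xyz, i) && ok(c_xyz, i))
      psi[i] <- .dihedral4(rbind(n_xyz[i, ], ca_xyz[i, ], c_xyz[i, ],
                                 n_xyz[i + 1L, ]))
  }
  data.frame(phi = phi, psi = psi)
}

#' Read the backbone of one chain from a structure file
#'
#' Reads a PDB or mmCIF file (dispatched on the file extension) and extracts
#' per-residue N, CA and C coordinates for one chain, keeping the
#' highest-occupancy conformer at alternate locations.
#'
#' @param path structure file (`.pdb` or `.cif`).
#' @param chain chain identifier (default: first chain in lexicographic
#'   order).
#' @return list with `sequence` (one-letter amino-acid string), `resno`
#'   (author residue numbers), and `n_xyz`, `ca_xyz`, `c_xyz` coordinate
#'   matrices suitable for [compute_backbone_dihedrals()].
#' @export
read_structure_backbone <- function(path, chain = NULL) {
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety %in% c("N", "CA", "C"), , drop = FALSE]
  if (is.null(chain)) chain <- sort(unique(at$chain))[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop(sprintf("chain '%s' not found in %s", chain, path))
  # highest-occupancy conformer per (residue, atom)
  occ <- if ("o" %in% names(at) && !all(is.na(at$o))) at$o else rep(1, nrow(at))
  at <- at[order(at$resno, at$elety, -occ), , drop = FALSE]
  at <- at[!duplicated(at[, c("resno", "elety")]), , drop = FALSE]
  resno <- sort(unique(at$resno))
  pick <- function(elety) {
    m <- matrix(NA_real_, length(resno), 3L)
    sel <- at[at$elety == elety, , drop = FALSE]
    m[match(sel$resno, resno), ] <- as.matrix(sel[, c("x", "y", "z")])
    m
  }
  ca <- at[at$elety == "CA", , drop = FALSE]
  aa <- rep("X", length(resno))
  aa[match(ca$resno, resno)] <- bio3d::aa321(ca$resid)
  list(sequence = paste(aa, collapse = ""), resno = resno,
       n_xyz = pick("N"), ca_xyz = pick("CA"), c_xyz = pick("C"))
}

#' Read secondary-structure labels
#'
#' Accepts either a tab-delimited 3-column table (`chain_id`,
#' `residue_index`, `label`, with a header) or classic DSSP output
#' (auto-detected). DSSP blank (loop) labels are returned as `"C"`;
#' `residue_index` is the author residue number.
#'
#' @param path label file.
#' @return data.frame with columns `chain_id`, `residue_index`, `label`.
#' @export
read_ss_labels <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("chain_id", "residue_index", "label") %in% names(df)))
    return(df[, c("chain_id", "residue_index", "label")])
  }
  body <- lines[(hdr[1] + 1L):length(lines)]
  body <- body[nchar(body) >= 17 & substr(body, 14, 14) != "!"]
  data.frame(
    chain_id = trimws(substr(body, 12, 12)),
    residue_index = as.integer(trimws(substr(body, 6, 10))),
    label = ifelse(trimws(substr(body, 17, 17)) == "", "C",
                   substr(body, 17, 17)),
    stringsAsFactors = FALSE)
}

#' Normalized pairwise sequence similarity
#'
#' Aligns every pair of sequences globally with match score 1 and all
#' penalties zero (so the score equals the longest-common-subsequence
#' length), then normalizes: s~_ij = s_ij / sqrt(s_ii s_jj). By construction
#' s~ is in [0, 1] with unit diagonal, regardless of sequence lengths.
#'
#' @param sequences character vector of non-empty amino-acid strings,
#'   optionally named.
#' @return object of class `similarity_matrix`: list with `ids`, `s` (raw
#'   scores; `s_ii` is the sequence length) and `s_tilde`.
#' @export
normalized_similarity <- function(sequences) {
  if (length(sequences) == 0L || any(nchar(sequences) == 0L))
    stop("sequences must be non-empty")
  ids <- if (!is.null(names(sequences))) names(sequences)
         else as.character(seq_along(sequences))
  letters_all <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  subst <- diag(1, length(letters_all))
  dimnames(subst) <- list(letters_all, letters_all)
  n <- length(sequences)
  s <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(s) <- nchar(sequences)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    s[i, j] <- s[j, i] <- Biostrings::score(Biostrings::pairwiseAlignment(
      sequences[i], sequences[j], type = "global",
      substitutionMatrix = subst, gapOpening = 0, gapExtension = 0))
  }
  structure(list(ids = ids, s = s, s_tilde = s / sqrt(outer(diag(s), diag(s)))),
            class = "similarity_matrix")
}

#' Redundancy filtering by farthest-first traversal
#'
#' Greedily orders sequences so that each newly selected sequence has the
#' lowest maximum normalized similarity to all previously selected ones,
#' starting from `start`. The traversal stops when the next pick's maximum
#' similarity exceeds `tau` (that pick is not retained), which guarantees
#' that no two retained sequences have normalized similarity above `tau`.
#' Ties in the argmin are broken toward the lowest index.
#'
#' @param sim a `similarity_matrix` (or a plain normalized similarity
#'   matrix).
#' @param tau similarity threshold in [0, 1] (default 0.7).
#' @param start index of the arbitrarily chosen first sequence (default 1).
#' @return character vector of retained ids, in selection order.
#' @export
fps_filter <- function(sim, tau = 0.7, start = 1L) {
  st <- if (inherits(sim, "similarity_matrix")) sim$s_tilde else as.matrix(sim)
  ids <- if (inherits(sim, "similarity_matrix")) sim$ids
         else if (!is.null(rownames(st))) rownames(st)
         else as.character(seq_len(nrow(st)))
  n <- nrow(st)
  selected <- start
  unselected <- setdiff(seq_len(n), start)
  while (length(unselected) > 0L) {
    S_k <- apply(st[selected, unselected, drop = FALSE], 2L, max)
    j <- unselected[which.min(S_k)]
    if (min(S_k) > tau) break
    selected <- c(selected, j)
    unselected <- setdiff(unselected, j)
  }
  ids[selected]
}

#' Aggregate per-chain residue observations into protein records
#'
#' Residues of different chains mapping to the same (accession, position) are
#' treated as experimental realizations of one protein residue: their
#' dihedral pairs are combined with the torus mean, and the codon and
#' secondary-structure label are retained only when unanimous across chains
#' (with no ambiguous or unassigned codon). Positions failing any rule are
#' dropped and counted in the run report.
#'
#' @param observations data.frame with columns `accession`,
#'   `accession_index`, `chain_id`, `phi`, `psi`, `ss`, `codon`.
#' @return list with `records` (data.frame: accession, index, phi, psi,
#'   codon, ss, n_chains) and `report` (named exclusion counts; positions
#'   are counted once, under the first failing rule).
#' @export
aggregate_records <- function(observations) {
  need <- c("accession", "accession_index", "chain_id", "phi", "psi", "ss",
            "codon")
  stopifnot(all(need %in% names(observations)))
  keys <- split(seq_len(nrow(observations)),
                paste(observations$accession, observations$accession_index,
                      sep = "@"))
  report <- c(input_rows = nrow(observations), positions = length(keys),
              dihedral_undefined = 0L, codon_unassigned = 0L,
              codon_ambiguous = 0L, codon_conflict = 0L, ss_conflict = 0L,
              retained = 0L)
  rows <- vector("list", length(keys))
  for (k in seq_along(keys)) {
    o <- observations[keys[[k]], , drop = FALSE]
    def <- is.finite(o$phi) & is.finite(o$psi)
    reason <- NULL
    if (!any(def)) reason <- "dihedral_undefined"
    else if (any(o$codon == "UNASSIGNED")) reason <- "codon_unassigned"
    else if (any(o$codon == "AMBIGUOUS")) reason <- "codon_ambiguous"
    else if (length(unique(o$codon)) > 1L) reason <- "codon_conflict"
    else if (length(unique(o$ss)) > 1L) reason <- "ss_conflict"
    if (!is.null(reason)) { report[reason] <- report[reason] + 1L; next }
    m <- tryCatch(torus_mean(dihedral_pairs(o$phi[def], o$psi[def])),
                  error = function(e) NULL)
    if (is.null(m)) {
      report["dihedral_undefined"] <- report["dihedral_undefined"] + 1L
      next
    }
    report["retained"] <- report["retained"] + 1L
    rows[[k]] <- data.frame(
      accession = o$accession[1], index = o$accession_index[1],
      phi = m[["phi"]], psi = m[["psi"]], codon = o$codon[1], ss = o$ss[1],
      n_chains = sum(def), stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  if (!is.null(records)) {
    records <- records[order(records$accession, records$index), , drop = FALSE]
    rownames(records) <- NULL
  } else {
    records <- data.frame(accession = character(), index = integer(),
                          phi = numeric(), psi = numeric(),
                          codon = character(), ss = character(),
                          n_chains = integer())
  }
  list(records = records, report = report)
}

#' Pool per-codon dihedral samples by secondary structure
#'
#' Restricts aggregated protein records to the requested structure classes
#' (by default E, extended strand, and H, alpha-helix) and to residues with
#' a defined dihedral pair and an unambiguously assigned sense codon, and
#' pools the (phi, psi) observations per (codon, class).
#'
#' @param records aggregated records data.frame (see [aggregate_records()]).
#' @param ss_classes structure classes to keep (default `c("E", "H")`).
#' @param code genetic code (defines the sense codons).
#' @return data.frame with columns `codon`, `ss`, `phi`, `psi`.
#' @export
extract_codon_samples <- function(records, ss_classes = c("E", "H"),
                                  code = standard_genetic_code()) {
  sense <- names(code)[code != "*"]
  keep <- records$ss %in% ss_classes & records$codon %in% sense &
    is.finite(records$phi) & is.finite(records$psi)
  out <- records[keep, c("codon", "ss", "phi", "psi"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read coding sequences grouped by accession
#'
#' Reads a (multi-record) FASTA of nucleotide coding sequences whose record
#' names start with the protein accession (anything after the first space or
#' `|` is ignored), and groups the sequences per accession.
#'
#' @param path FASTA file.
#' @return named list: accession -> character vector of coding sequences.
#' @export
read_cds_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  acc <- sub("[ |].*$", "", names(set))
  split(as.character(set), acc)
}

#' Build aggregated protein records from structures, labels and sequences
#'
#' Runs the data-preparation pipeline: per-chain backbone dihedrals,
#' optional structure-quality gates (resolution and R_free columns of the
#' manifest), redundancy filtering of the accession reference sequences by
#' farthest-first traversal, codon assignment from the coding sequences,
#' secondary-structure annotation, and multi-chain aggregation. The
#' reference sequence of an accession is taken from its lexicographically
#' first chain.
#'
#' @param manifest data.frame with columns `path`, `structure_id`, `chain`,
#'   `accession` and optionally `resolution`, `rfree`.
#' @param ss_labels label table from [read_ss_labels()] (chain_id =
#'   "structure_id:chain", residue_index = author residue number).
#' @param cds named list of coding sequences per accession
#'   ([read_cds_fasta()]).
#' @param config run configuration (uses `tau`, `fps_start`, and the quality
#'   gates `max_resolution`, `max_rfree`).
#' @return list with `records`, `report`, `selected_accessions` and the
#'   echoed `config`.
#' @export
build_protein_records <- function(manifest, ss_labels, cds,
                                  config = default_config()) {
  config <- validate_config(config)
  stopifnot(all(c("path", "structure_id", "chain", "accession") %in%
                  names(manifest)))
  n_manifest <- nrow(manifest)
  if ("resolution" %in% names(manifest))
    manifest <- manifest[manifest$resolution <= config$max_resolution, ,
                         drop = FALSE]
  if ("rfree" %in% names(manifest))
    manifest <- manifest[manifest$rfree <= config$max_rfree, , drop = FALSE]
  if (nrow(manifest) == 0L) stop("no structure passes the quality gates")
  manifest <- manifest[order(manifest$accession, manifest$structure_id,
                             manifest$chain), , drop = FALSE]
  chains <- lapply(seq_len(nrow(manifest)), function(i)
    read_structure_backbone(manifest$path[i], manifest$chain[i]))
  names(chains) <- paste(manifest$structure_id, manifest$chain, sep = ":")
  # one reference sequence per accession: lexicographically first chain
  first <- !duplicated(manifest$accession)
  refs <- stats::setNames(
    vapply(chains[first], `[[`, character(1), "sequence"),
    manifest$accession[first])
  selected <- fps_filter(normalized_similarity(refs), tau = config$tau,
                         start = config$fps_start)
  keep <- manifest$accession %in% selected
  manifest <- manifest[keep, , drop = FALSE]
  chains <- chains[keep]
  assignments <- lapply(selected, function(acc) {
    if (is.null(cds[[acc]])) stop(sprintf("no coding sequence for %s", acc))
    assign_codons(refs[[acc]], cds[[acc]])
  })
  names(assignments) <- selected
  obs <- lapply(seq_len(nrow(manifest)), function(i) {
    ch <- chains[[i]]
    cid <- names(chains)[i]
    acc <- manifest$accession[i]
    dih <- compute_backbone_dihedrals(ch$n_xyz, ch$ca_xyz, ch$c_xyz)
    al <- global_align(ch$sequence, refs[[acc]])
    map <- al$mapping[al$mapping$match, , drop = FALSE]
    ss <- ss_labels[ss_labels$chain_id == cid, , drop = FALSE]
    ss_of <- stats::setNames(ss$label, ss$residue_index)
    data.frame(
      accession = acc, accession_index = map$b_pos, chain_id = cid,
      phi = dih$phi[map$a_pos], psi = dih$psi[map$a_pos],
      ss = ifelse(is.na(ss_of[as.character(ch$resno[map$a_pos])]), "-",
                  ss_of[as.character(ch$resno[map$a_pos])]),
      codon = assignments[[acc]]$codon[map$b_pos],
      stringsAsFactors = FALSE)
  })
  agg <- aggregate_records(do.call(rbind, obs))
  agg$report <- c(manifest_chains = n_manifest,
                  chains_after_quality_and_fps = nrow(manifest), agg$report)
  list(records = agg$records, report = agg$report,
       selected_accessions = selected, config = config)
}

#' Write aggregated protein records
#'
#' Tab-delimited with a header line; readable back with
#' [read_protein_records()].
#'
#' @param records records data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_protein_records
#' @export
read_protein_records <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(accession = "character",
                                   codon = "character", ss = "character"))
}
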