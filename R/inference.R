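#' Two-sample permutation test on the KDE L1 statistic
#'
#' Tests whether two dihedral-angle samples come from the same torus
#' distribution. The statistic is the L1 distance between the kernel density
#' estimates of the two samples. The null distribution is built by pooling
#' the observations, drawing K random permutations, re-splitting at the size
#' of the first sample, and recomputing the statistic. With eta the number of
#' permutations whose statistic is at least the base statistic, the one-sided
#' p-value is (1 + eta) / (1 + K); its smallest attainable value is
#' 1 / (1 + K).
#'
#' @param x,y dihedral-pair matrices (columns phi, psi), at least one row each.
#' @param K number of permutations (default 200).
#' @param bandwidth,grid_size KDE parameters (defaults 2 degrees, 128 bins).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return object of class `perm_test`: list with `base_statistic`, `eta`,
#'   `K`, `p_value` and the vector of `permuted` statistics.
#' @export
permutation_test <- function(x, y, K = 200L, bandwidth = 2, grid_size = 128L,
                             seed = NULL) {
  x <- .as_dihedral_matrix(x); y <- .as_dihedral_matrix(y)
  if (nrow(x) == 0L || nrow(y) == 0L) stop("samples must be non-empty")
  K <- as.integer(K)
  if (K < 1L) stop("'K' must be >= 1")
  nx <- nrow(x); n <- nx + nrow(y)
  pooled <- rbind(x, y)
  grid <- density_grid(grid_size)
  kphi <- .kernel_matrix(pooled[, 1], grid, bandwidth)
  kpsi <- .kernel_matrix(pooled[, 2], grid, bandwidth)
  stat_for <- function(ix, iy) {
    dx <- crossprod(kphi[ix, , drop = FALSE], kpsi[ix, , drop = FALSE])
    dy <- crossprod(kphi[iy, , drop = FALSE], kpsi[iy, , drop = FALSE])
    sum(abs(dx / sum(dx) - dy / sum(dy)))
  }
  base <- stat_for(seq_len(nx), (nx + 1L):n)
  permuted <- with_seed(seed, {
    vapply(seq_len(K), function(k) {
      perm <- sample.int(n)
      stat_for(perm[seq_len(nx)], perm[(nx + 1L):n])
    }, numeric(1))
  })
  eta <- sum(base <= permuted)
  structure(list(base_statistic = base, eta = eta, K = K,
                 p_value = (1 + eta) / (1 + K), permuted = permuted),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test: L1 = %.4f, eta = %d / K = %d, p = %.4g\n",
              x$base_statistic, x$eta, x$K, x$p_value))
  invisible(x)
}

#' Equalized sample size for a synonymous codon group
#'
#' Within an amino acid's codon group all densities are estimated from the
#' same number of observations, so that a fixed kernel bandwidth compares
#' like with like: the minimum codon count, capped at `n_max` (default 200).
#'
#' @param counts named integer vector of per-codon observation counts.
#' @param n_max upper cap on the common sample size.
#' @return integer common sample size.
#' @export
equalized_sample_size <- function(counts, n_max = 200L) {
  if (length(counts) == 0L) stop("'counts' must be non-empty")
  if (any(counts < 1L)) stop("codon with zero observations is untestable")
  as.integer(min(n_max, min(counts)))
}

#' Bootstrap-aggregated permutation test for a codon pair
#'
#' Runs B independent bootstrap rounds. Each round draws N observations with
#' replacement from each codon's pool (self-comparisons draw two independent
#' resamples from the same pool) and applies a K-permutation test. The
#' aggregate p-value pools all exceedance counts:
#' p = (1 + sum_b eta_b) / (1 + B * K).
#'
#' @param x,y dihedral-pair matrices for the two codons (may be identical).
#' @param N bootstrap resample size (resampling is with replacement, so N may
#'   exceed the pool size).
#' @param B bootstrap rounds (default 25).
#' @param K permutations per round (default 200; B = 25, K = 200 gives the
#'   aggregate denominator 1 + 5000).
#' @param bandwidth,grid_size KDE parameters.
#' @param seed optional master seed; each round uses a derived child seed.
#' @return object of class `pair_test`: list with `per_bootstrap` (list of
#'   `perm_test`), `mean_distance` (mean base statistic), `eta_total`, `B`,
#'   `K`, `N` and `p_value`.
#' @export
bootstrap_pair_test <- function(x, y, N, B = 25L, K = 200L, bandwidth = 2,
                                grid_size = 128L, seed = NULL) {
  x <- .as_dihedral_matrix(x); y <- .as_dihedral_matrix(y)
  if (nrow(x) == 0L || nrow(y) == 0L) stop("samples must be non-empty")
  B <- as.integer(B); K <- as.integer(K); N <- as.integer(N)
  if (B < 1L || K < 1L || N < 1L) stop("'N', 'B' and 'K' must be >= 1")
  rounds <- lapply(seq_len(B), function(b) {
    sb <- child_seed(seed, b)
    idx <- with_seed(sb, list(sample.int(nrow(x), N, replace = TRUE),
                              sample.int(nrow(y), N, replace = TRUE)))
    permutation_test(x[idx[[1]], , drop = FALSE], y[idx[[2]], , drop = FALSE],
                     K = K, bandwidth = bandwidth, grid_size = grid_size,
                     seed = child_seed(seed, b, 1L))
  })
  eta_total <- sum(vapply(rounds, `[[`, numeric(1), "eta"))
  structure(list(per_bootstrap = rounds,
                 mean_distance = mean(vapply(rounds, `[[`, numeric(1),
                                             "base_statistic")),
                 eta_total = eta_total, B = B, K = K, N = N,
                 p_value = (1 + eta_total) / (1 + B * K)),
            class = "pair_test")
}

#' @export
print.pair_test <- function(x, ...) {
  cat(sprintf(
    "bootstrap pair test: B = %d, K = %d, N = %d, mean L1 = %.4f, p = %.4g\n",
    x$B, x$K, x$N, x$mean_distance, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate decision
#'
#' Sorts the M p-values, finds i0 = max{i : p(i) <= q i / M}, sets the
#' adaptive threshold alpha_M = p(i0), and rejects the hypotheses with
#' p < alpha_M (strict inequality). The textbook step-up variant, which
#' rejects all sorted hypotheses up to i0 (p <= alpha_M), is available via
#' `textbook = TRUE`.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @param ids optional identifiers for the tests (defaults to names or index).
#' @param textbook logical; use the standard step-up rejection rule.
#' @return object of class `fdr_decision`: list with `q`, `M`, `i0`,
#'   `alpha_M`, `rejected` (ids) and a logical `reject` vector aligned with
#'   the input.
#' @export
bh_procedure <- function(p_values, q = 0.05, ids = NULL, textbook = FALSE) {
  if (length(p_values) == 0L) stop("'p_values' must be non-empty")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
  if (is.null(ids)) ids <- if (!is.null(names(p_values))) names(p_values)
                           else as.character(seq_along(p_values))
  M <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  ok <- which(ps <= q * seq_len(M) / M)
  if (length(ok) == 0L) {
    reject <- rep(FALSE, M)
    alpha_M <- NA_real_; i0 <- 0L
  } else {
    i0 <- max(ok)
    alpha_M <- ps[i0]
    reject <- if (textbook) p_values <= alpha_M else p_values < alpha_M
  }
  structure(list(q = q, M = M, i0 = i0, alpha_M = alpha_M,
                 rejected = ids[reject], reject = reject),
            class = "fdr_decision")
}

#' @export
print.fdr_decision <- function(x, ...) {
  cat(sprintf("BH procedure: M = %d, q = %g, alpha_M = %s, %d rejected\n",
              x$M, x$q, format(x$alpha_M), sum(x$reject)))
  invisible(x)
}

#' Normalize a codon distance matrix by its self-distances
#'
#' Rescales d(c, c') to d(c, c') / sqrt(d(c, c) d(c', c')), so that every
#' self-distance becomes exactly 1. Invariant to a positive rescaling of the
#' input.
#'
#' @param raw square matrix of mean distances with a strictly positive
#'   diagonal.
#' @return normalized matrix with unit diagonal.
#' @export
normalize_distance_matrix <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) != ncol(raw)) stop("'raw' must be square")
  d <- diag(raw)
  if (any(d <= 0)) stop("self-distances must be strictly positive")
  raw / sqrt(outer(d, d))
}

#' Run all synonymous-pair and self-pair tests over a dataset
#'
#' For each secondary-structure class and each amino acid whose codons all
#' have observations, computes the equalized sample size, runs the
#' bootstrap-aggregated permutation test for every unordered synonymous codon
#' pair and every self-pair (the controls), and applies the
#' Benjamini-Hochberg procedure to the pooled p-values of each structure
#' class. With the full standard code present this yields 61 self tests plus
#' 87 synonymous pair tests, 148 hypotheses per structure.
#'
#' @param observations data.frame with columns `codon`, `ss`, `phi`, `psi`
#'   (one row per residue observation), e.g. from [extract_codon_samples()].
#' @param config run configuration, see [default_config()].
#' @param ss_classes secondary-structure classes to analyse (default E and H).
#' @param code genetic code table, see [standard_genetic_code()].
#' @return object of class `codon_test_results`: list with `results` (one row
#'   per test: amino_acid, codon_a, codon_b, ss, N, B, K, mean_distance,
#'   normalized_distance, p_value, rejected), `fdr` (per-structure
#'   `fdr_decision`), `skipped` (amino acid / structure groups without full
#'   codon coverage) and the echoed `config`.
#' @export
run_all_pairwise_tests <- function(observations, config = default_config(),
                                   ss_classes = c("E", "H"),
                                   code = standard_genetic_code()) {
  stopifnot(all(c("codon", "ss", "phi", "psi") %in% names(observations)))
  config <- validate_config(config)
  groups <- split(names(code), code)
  groups <- groups[names(groups) != "*"]
  out <- list(); skipped <- list()
  for (ss in ss_classes) {
    obs_ss <- observations[observations$ss == ss, , drop = FALSE]
    counts <- table(obs_ss$codon)
    for (aa in names(groups)) {
      codons <- sort(groups[[aa]])
      have <- codons[codons %in% names(counts)]
      if (length(have) < length(codons)) {
        # warn only when the group is partially observed; wholly absent
        # amino acids are silently outside the dataset
        if (length(have) > 0L)
          warning(sprintf(
            "skipping amino acid %s in structure %s: codon(s) %s unobserved",
            aa, ss, paste(setdiff(codons, have), collapse = ",")))
        skipped[[length(skipped) + 1L]] <- data.frame(
          amino_acid = aa, ss = ss,
          reason = if (length(have) > 0L) "partial" else "unobserved")
        next
      }
      N <- equalized_sample_size(as.integer(counts[codons]), config$n_max)
      pools <- lapply(codons, function(co)
        dihedral_pairs(obs_ss$phi[obs_ss$codon == co],
                       obs_ss$psi[obs_ss$codon == co]))
      names(pools) <- codons
      pairs <- synonymous_pairs(code[codons], include_self = TRUE)
      for (r in seq_len(nrow(pairs))) {
        ca <- pairs$codon_a[r]; cb <- pairs$codon_b[r]
        fit <- bootstrap_pair_test(
          pools[[ca]], pools[[cb]], N = N, B = config$b_test,
          K = config$k_perm, bandwidth = config$bandwidth,
          grid_size = config$grid_size,
          seed = child_seed(config$seed,
                            match(ss, ss_classes) * 4096L +
                              match(ca, names(code)),
                            match(cb, names(code))))
        out[[length(out) + 1L]] <- data.frame(
          amino_acid = aa, codon_a = ca, codon_b = cb, ss = ss, N = N,
          B = config$b_test, K = config$k_perm,
          mean_distance = fit$mean_distance, p_value = fit$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) stop("no testable amino-acid group in the dataset")
  results <- do.call(rbind, out)
  # self-distance normalization within each (structure, amino acid) group
  self_d <- results[results$codon_a == results$codon_b, ]
  key <- function(ss, co) paste(ss, co)
  self_map <- stats::setNames(self_d$mean_distance,
                              key(self_d$ss, self_d$codon_a))
  results$normalized_distance <- results$mean_distance /
    sqrt(self_map[key(results$ss, results$codon_a)] *
         self_map[key(results$ss, results$codon_b)])
  fdr <- list()
  results$rejected <- FALSE
  for (ss in ss_classes) {
    idx <- which(results$ss == ss)
    if (length(idx) == 0L) next
    dec <- bh_procedure(results$p_value[idx], q = config$q,
                        ids = paste(results$codon_a[idx],
                                    results$codon_b[idx], sep = ":"),
                        textbook = config$textbook_bh)
    results$rejected[idx] <- dec$reject
    fdr[[ss]] <- dec
  }
  structure(list(results = results, fdr = fdr,
                 skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
                 config = config),
            class = "codon_test_results")
}

#' @export
print.codon_test_results <- function(x, ...) {
  cat(sprintf("codon pairwise tests: %d hypotheses (%s)\n",
              nrow(x$results),
              paste(sprintf("%s: %d", names(x$fdr),
                            vapply(x$fdr, function(f) f$M, integer(1))),
                    collapse = ", ")))
  for (ss in names(x$fdr))
    cat(sprintf("  %s: %d rejected at q = %g\n", ss, sum(x$fdr[[ss]]$reject),
                x$fdr[[ss]]$q))
  invisible(x)
}

#' Mean-distance matrix for one amino acid and structure class
#'
#' Assembles the symmetric matrix of bootstrap-mean L1 distances (including
#' the self-distance diagonal) from a [run_all_pairwise_tests()] result.
#'
#' @param x a `codon_test_results` object.
#' @param amino_acid single amino-acid letter.
#' @param ss secondary-structure class.
#' @return square matrix of mean distances with codon dimnames.
#' @export
distance_matrix <- function(x, amino_acid, ss) {
  stopifnot(inherits(x, "codon_test_results"))
  r <- x$results[x$results$amino_acid == amino_acid & x$results$ss == ss, ]
  if (nrow(r) == 0L) stop("no results for that amino acid / structure")
  codons <- sort(unique(c(r$codon_a, r$codon_b)))
  m <- matrix(NA_real_, length(codons), length(codons),
              dimnames = list(codons, codons))
  m[cbind(r$codon_a, r$codon_b)] <- r$mean_distance
  m[cbind(r$codon_b, r$codon_a)] <- r$mean_distance
  m
}

#' Write a pairwise-test results table
#'
#' Tab-delimited, with the run configuration echoed as `#`-prefixed header
#' lines.
#'
#' @param x a `codon_test_results` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  stopifnot(inherits(x, "codon_test_results"))
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- x$config
  writeLines(sprintf("# %s: %s", names(cfg),
                     vapply(cfg, function(v) paste(format(v), collapse = ","),
                            character(1))), con)
  utils::write.table(x$results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
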