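# shared fixture builders; everything is generated in code at test time

frobenius <- function(X) sqrt(sum(X^2))

toy_probe_matrix <- function() {
  Y <- matrix(c(4, 9, 16, 25,
                2, 3, 4, 5), nrow = 2, byrow = TRUE)
  rownames(Y) <- c("p1", "p2")
  colnames(Y) <- paste0("s", 1:4)
  Y
}

toy_annotation <- function(probes = c("p1", "p2", "p3", "p4"),
                           probesets = c("ps1", "ps1", "ps2", "ps2")) {
  tibble::tibble(
    probe_id = probes, probeset_id = probesets, gene_id = "g1",
    chrom = "chr1",
    start = 100L + 10L * seq_along(probes),
    end = 100L + 10L * seq_along(probes) + 24L,
    strand = "+"
  )
}

# a gene whose exact recovery is well-posed: each isoform has an exclusive
# (anchor) probeset and each sample is dominated by one isoform, so the
# noiseless non-negative factorization is essentially unique
make_identifiable_gene <- function(n_transcripts, n_probesets = 8,
                                   n_samples = 33, seed = 1,
                                   noise = noise_params(0, 0)) {
  withr::with_seed(seed, {
    repeat {
      pat <- matrix(
        as.numeric(runif((n_probesets - n_transcripts) * n_transcripts) < 0.7),
        n_probesets - n_transcripts, n_transcripts
      )
      pat[rowSums(pat) == 0, ] <- 1
      pat <- rbind(diag(n_transcripts), pat)
      if (ncol(unique(pat, MARGIN = 2)) == n_transcripts &&
          all(colSums(pat) > 0)) break
    }
    ppp <- sample(3:4, n_probesets, replace = TRUE)
    G <- pat[rep(seq_len(n_probesets), ppp), , drop = FALSE]
    rownames(G) <- paste0("probe_", seq_len(nrow(G)))
    colnames(G) <- paste0("tr_", seq_len(n_transcripts))
    probeset <- rep(paste0("ps_", seq_len(n_probesets)), ppp)
    dominant <- rep_len(seq_len(n_transcripts), n_samples)
    T_mat <- matrix(runif(n_transcripts * n_samples, 0, 0.08),
                    n_transcripts, n_samples)
    for (s in seq_len(n_samples)) T_mat[dominant[s], s] <- runif(1, 0.5, 1)
    dimnames(T_mat) <- list(colnames(G), paste0("sample_", seq_len(n_samples)))
    A <- simulate_affinities(nrow(G))
    Y <- simulate_probe_signal(A, G, T_mat, noise)
    annotation <- tibble::tibble(
      probe_id = rownames(G), probeset_id = probeset, gene_id = "gene_fix",
      chrom = "chrF",
      start = 1000L + 100L * seq_len(nrow(G)),
      end = 1000L + 100L * seq_len(nrow(G)) + 24L,
      strand = "+"
    )
    list(Y = Y, A = A, G = G, T = T_mat, probeset = probeset,
         annotation = annotation, n_transcripts = n_transcripts)
  })
}

# brute-force matcher: minimise total per-column L1 distance over all
# permutations (reference oracle for match_transcript_columns)
brute_force_match <- function(G_hat, G_ref) {
  k <- max(ncol(G_hat), ncol(G_ref))
  pad <- function(M) cbind(M, matrix(0, nrow(M), k - ncol(M)))
  Gh <- pad(G_hat); Gr <- pad(G_ref)
  perms <- isodeconv:::all_permutations(k)
  costs <- apply(perms, 1, function(p) sum(abs(Gh[, p] - Gr)))
  perms[which.min(costs), ]
}
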