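# Independent brute-force oracles. These deliberately share no code with the
# package's simulator or analytic expectations: positions are drawn and cut
# with plain vector arithmetic, so they can arbitrate both.

# Conditional spacings oracle: fragment lengths of a circle of length L cut
# at exactly k uniform positions, pooled over n independent plasmids.
oracle_conditional_spacings <- function(k, L, n, seed) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    m <- matrix(stats::runif(n * k, 0, L), nrow = n)
    out <- vapply(seq_len(n), function(i) {
      p <- sort(m[i, ])
      c(diff(p), L - p[k] + p[1])
    }, numeric(k))
    as.numeric(out)
  })
}

# Monte-Carlo oracle for the uniform null: expected fragments per plasmid
# per bin, with a batch-based standard error. Fully vectorised so 1e6
# plasmids are feasible; plasmids with k = 0 contribute no fragments and
# k = 1 contributes one full-length fragment (the wrap-around of a
# single-element group).
oracle_mc_bin_expectation <- function(mu, L, w, n, seed, batches = 100) {
  stopifnot(n %% batches == 0)
  nb <- as.integer(round(L / w))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  k <- stats::rpois(n, mu)
  N <- sum(k)
  if (N == 0) {
    return(list(mean = numeric(nb), se = numeric(nb)))
  }
  ids <- rep.int(seq_len(n), k)
  pos <- stats::runif(N, 0, L)
  ord <- order(ids, pos, method = "radix")
  ps <- pos[ord]
  same <- ids[-1L] == ids[-N]
  st <- which(c(TRUE, !same))
  en <- which(c(!same, TRUE))
  lens <- c(ps[-1L][same] - ps[-N][same], (L - ps[en]) + ps[st])
  fids <- c(ids[-1L][same], ids[st])
  b <- as.integer(ceiling(lens / w))
  b[b < 1L] <- 1L
  b[b > nb] <- nb
  per_batch <- n %/% batches
  batch <- (fids - 1L) %/% per_batch          # 0 .. batches-1
  counts <- tabulate(batch * nb + b, nbins = batches * nb)
  cm <- matrix(counts, nrow = nb)             # bins x batches
  means <- cm / per_batch
  list(mean = rowMeans(means),
       se = apply(means, 1, stats::sd) / sqrt(batches))
}

# Small record-table builders for unit tests.
recs <- function(lengths, topology = "linear") {
  fragment_records(lengths, topology = topology, sample_id = "t")
}
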