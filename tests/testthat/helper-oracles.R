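# Independent brute-force oracles used across the suite. Each deliberately
# re-derives its quantity with the most literal loop available, never by
# calling the implementation under test.

rand_seqs <- function(n, len = 25, gc = 0.5) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }, character(1))
}

# Literal loop-and-lookup nearest-neighbor summation.
naive_dg37 <- function(s, params = nn_unified_dg37()) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  total <- 0
  for (i in seq_len(length(ch) - 1)) {
    total <- total + params$stack_dg37[[paste0(ch[i], ch[i + 1])]]
  }
  nterm <- sum(ch[c(1, length(ch))] %in% c("A", "T"))
  params$init_dg37 + total + nterm * params$terminal_at_penalty
}

# O(n * w) windowed mean over |pos_j - pos_i| <= half.
naive_window_mean <- function(values, positions, half) {
  vapply(seq_along(values), function(i) {
    mean(values[abs(positions - positions[i]) <= half])
  }, numeric(1))
}

# Literal run finder over per-probe windowed medians.
naive_deletion_runs <- function(ratio, position, window, threshold, min_run) {
  n <- length(ratio)
  h <- floor(window / 2)
  wmed <- vapply(seq_len(n), function(i) {
    median(ratio[max(1, i - h):min(n, i + h)])
  }, numeric(1))
  below <- wmed < threshold
  runs <- list()
  i <- 1
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1]) j <- j + 1
      if (j - i + 1 >= min_run) {
        runs[[length(runs) + 1]] <- c(start = position[i],
                                      end = position[j] + 1)
      }
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

# Column-by-column identity counter over a gapped alignment.
naive_probe_matches <- function(alignment, start, len) {
  r <- strsplit(alignment$ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alignment$alt, "", fixed = TRUE)[[1]]
  idx <- 0; count <- 0
  for (col in seq_along(r)) {
    if (r[col] != "-") {
      idx <- idx + 1
      if (idx > start && idx <= start + len && a[col] == r[col]) {
        count <- count + 1
      }
    }
  }
  count
}

# Exhaustive enumeration of global alignments (affine gaps: a length-L gap
# scores open + (L - 1) * ext). Feasible for sequences of length <= 6.
enum_align_score <- function(a, b, match = 1, mismatch = -1, open = -5,
                             ext = -1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i == length(A) && j == length(B)) {
      best <<- max(best, sc)
      return(invisible(NULL))
    }
    if (i < length(A) && j < length(B)) {
      rec(i + 1, j + 1, "D",
          sc + if (A[i + 1] == B[j + 1]) match else mismatch)
    }
    if (i < length(A)) rec(i + 1, j, "U", sc + if (prev == "U") ext else open)
    if (j < length(B)) rec(i, j + 1, "L", sc + if (prev == "L") ext else open)
  }
  rec(0, 0, "", 0)
  best
}

# Sliding-window exact occurrence count (single strand).
naive_kmer_count <- function(genome_strings, pattern) {
  total <- 0L
  k <- nchar(pattern)
  for (g in genome_strings) {
    L <- nchar(g)
    if (L < k) next
    subs <- substring(g, 1:(L - k + 1), k:L)
    total <- total + sum(subs == pattern)
  }
  total
}

# Small ready-made experiment for IO / pipeline tests.
small_sim <- function(seed = 42, ...) {
  generate_dataset(sim_config(
    n_target_probes = 240, n_control_probes = 60, probes_per_gene = 8,
    intergenic_probes = 4, divergence_per_site = 0.1,
    conserved_fraction = 0.2, seed = seed, ...))
}
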