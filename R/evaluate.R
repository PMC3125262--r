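# Evaluation procedures: conserved-gene calling on adjusted intensities,
# deletion-sensitivity ratio scans, and specificity analysis relating probe
# intensity ratios to probe-ortholog sequence identity and to genome k-mer
# frequency.

#' Per-gene conserved-sequence test
#'
#' A gene is called conserved when the mean adjusted intensity of its exon
#' probes is significantly greater than zero: a one-sample, one-sided t-test
#' per gene with Bonferroni control of the family-wise error rate over the
#' genes tested. Genes with fewer than 2 exon probes are excluded (reported
#' via the `excluded` attribute), not an error.
#'
#' @param ai data.frame `probe_id`, `ai` for one species (e.g. one species'
#'   rows of [normalize_experiment()]'s output).
#' @param probes ProbeSet data.frame with `probe_id`, `category`, `gene_id`,
#'   `region`; exon probes of target category are tested.
#' @param alpha_fw family-wise error level, default 0.05.
#' @param alternative `"greater"` (default, conserved = above the
#'   non-specific baseline) or `"two.sided"`.
#' @return data.frame `gene_id`, `n_exon_probes`, `mean_ai`, `t_stat`,
#'   `p_raw`, `significant`, sorted by `gene_id`; attribute `excluded` lists
#'   genes dropped for having < 2 exon probes.
#' @export
conserved_gene_test <- function(ai, probes, alpha_fw = 0.05,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  abort_if(!all(c("probe_id", "ai") %in% names(ai)),
           "ai must have probe_id and ai columns")
  keep <- probes$category == "target" & !is.na(probes$gene_id) &
    probes$region %in% "exon"
  ann <- probes[keep, c("probe_id", "gene_id")]
  x <- merge(ann, ai[, c("probe_id", "ai")], by = "probe_id")
  abort_if(nrow(x) == 0, "no exon probes with adjusted intensities")

  g <- factor(x$gene_id)
  n <- as.vector(table(g))
  sums <- as.vector(rowsum(x$ai, g))
  sq <- as.vector(rowsum(x$ai^2, g))
  mean_ai <- sums / n
  # unbiased variance; genes with n < 2 are excluded below
  varr <- (sq - n * mean_ai^2) / (n - 1)
  varr[varr < 0] <- 0  # guard fp cancellation
  genes <- levels(g)

  excluded <- genes[n < 2]
  ok <- n >= 2
  se <- sqrt(varr[ok] / n[ok])
  t_stat <- ifelse(se > 0, mean_ai[ok] / se,
                   ifelse(mean_ai[ok] == 0, 0, sign(mean_ai[ok]) * Inf))
  p_raw <- if (alternative == "greater") {
    stats::pt(t_stat, df = n[ok] - 1, lower.tail = FALSE)
  } else {
    2 * stats::pt(abs(t_stat), df = n[ok] - 1, lower.tail = FALSE)
  }
  m <- sum(ok)
  res <- data.frame(
    gene_id = genes[ok], n_exon_probes = n[ok], mean_ai = mean_ai[ok],
    t_stat = t_stat, p_raw = p_raw,
    significant = p_raw <= alpha_fw / m,
    stringsAsFactors = FALSE
  )
  res <- res[order(res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  if (length(excluded) > 0) {
    message(length(excluded), " gene(s) excluded with < 2 exon probes")
  }
  attr(res, "excluded") <- excluded
  attr(res, "n_tested") <- m
  res
}

#' Test-over-reference intensity ratio track
#'
#' Per-probe ratio of back-transformed adjusted intensities,
#' `exp(ai_test - ai_reference)`, ordered by chromosome and position. A
#' track centered at 1.0 marks equal signal; dips below 1.0 mark sequence
#' absent from the test sample (deletions).
#'
#' @param test,reference data.frames `probe_id`, `ai` for the two samples.
#' @param probes ProbeSet data.frame with `probe_id`, `chromosome`, `start`.
#' @return data.frame `probe_id`, `chromosome`, `position`, `ratio`. Probes
#'   present in only one table are excluded with a message.
#' @export
ratio_track <- function(test, reference, probes) {
  shared <- intersect(test$probe_id, reference$probe_id)
  dropped <- length(union(test$probe_id, reference$probe_id)) - length(shared)
  if (dropped > 0) {
    message(dropped, " probe(s) present in only one table were excluded")
  }
  p <- probes[match(shared, probes$probe_id), , drop = FALSE]
  keep <- !is.na(p$chromosome) & !is.na(p$start)
  shared <- shared[keep]; p <- p[keep, , drop = FALSE]
  out <- data.frame(
    probe_id = shared,
    chromosome = p$chromosome,
    position = p$start,
    ratio = exp(test$ai[match(shared, test$probe_id)] -
                  reference$ai[match(shared, reference$probe_id)]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chromosome, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a ratio track for candidate deletions
#'
#' Computes a running median of the ratio over a window of `window_probes`
#' probes (shrinking at chromosome ends) and reports maximal runs of at
#' least `min_run` consecutive probes whose windowed median falls below
#' `ratio_threshold`, as half-open genomic intervals. Positions are probe
#' start coordinates; the interval end is the last qualifying probe's start
#' + 1.
#'
#' @param track data.frame from [ratio_track()].
#' @param window_probes running-median window (probes), default 5.
#' @param ratio_threshold dip threshold below baseline 1.0, default 0.5.
#' @param min_run minimum consecutive qualifying probes, default 10.
#' @return data.frame `chromosome`, `start`, `end`, `n_probes`,
#'   `mean_ratio` (empty when nothing qualifies).
#' @export
deletion_scan <- function(track, window_probes = 5, ratio_threshold = 0.5,
                          min_run = 10) {
  abort_if(window_probes < 1, "window_probes must be >= 1")
  abort_if(!(ratio_threshold > 0 && ratio_threshold < 1),
           "ratio_threshold must be in (0, 1)")
  empty <- data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      mean_ratio = numeric(0))
  if (nrow(track) == 0) return(empty)
  out <- list()
  for (chr in unique(track$chromosome)) {
    tr <- track[track$chromosome == chr, , drop = FALSE]
    wmed <- running_median(tr$ratio, window_probes)
    below <- wmed < ratio_threshold
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      i <- starts[k]:ends[k]
      out[[length(out) + 1]] <- data.frame(
        chromosome = chr,
        start = tr$position[starts[k]],
        end = tr$position[ends[k]] + 1L,
        n_probes = length(i),
        mean_ratio = mean(tr$ratio[i]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Centered running median with shrinking windows at the edges.
running_median <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n == 0) return(x)
  h <- floor(w / 2)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Classify probe identity counts
#'
#' Maps identical-nucleotide counts to the specificity classes used in the
#' accumulation curves: `true` = perfect match, `semi-true` = within
#' `semi_min` to probe length - 1 matches, `false` below. With the default
#' boundaries on 25-mers: false <= 22, semi-true 23-24, true 25.
#'
#' @param matches integer vector of identical-nucleotide counts.
#' @param probe_length probe length, default 25.
#' @param semi_min smallest match count classed semi-true, default
#'   `probe_length - 2`.
#' @return character vector: `"false"`, `"semi-true"`, `"true"`.
#' @export
identity_class <- function(matches, probe_length = 25,
                           semi_min = probe_length - 2) {
  abort_if(any(matches > probe_length), "matches exceed probe length")
  ifelse(matches == probe_length, "true",
         ifelse(matches >= semi_min, "semi-true", "false"))
}

#' Probe identity against an ortholog alignment
#'
#' Counts, for each probe tiled on the ungapped reference, the alignment
#' columns within the probe's span where the reference and the ortholog
#' carry the identical nucleotide. Gap columns count as mismatch.
#'
#' @param alignment a list (or character vector of length 2) with the gapped
#'   reference and ortholog strings, e.g. from [align_orthologs()] or the
#'   truth alignment of [generate_ortholog_pair()].
#' @param probe_starts 0-based probe offsets in the ungapped reference.
#' @param probe_length probe length, default 25.
#' @param probe_ids optional ids carried to the output (defaults to
#'   `probe_<start>`).
#' @param semi_min see [identity_class()].
#' @return data.frame `probe_id`, `start`, `matches`, `class`.
#' @export
probe_identity <- function(alignment, probe_starts, probe_length = 25,
                           probe_ids = NULL, semi_min = probe_length - 2) {
  aln <- as_alignment(alignment)
  ref_c <- strsplit(aln$ref, "", fixed = TRUE)[[1]]
  alt_c <- strsplit(aln$alt, "", fixed = TRUE)[[1]]
  abort_if(length(ref_c) != length(alt_c),
           "alignment strings differ in length")
  non_gap <- ref_c != "-"
  ref_len <- sum(non_gap)
  over <- which(probe_starts + probe_length > ref_len | probe_starts < 0)
  abort_if(length(over) > 0,
           "probe %s spans beyond the ungapped reference (length %d)",
           (probe_ids %||% paste0("probe_", probe_starts))[over[1]], ref_len)
  # cumulative ungapped index per column; identical-match indicator
  ref_idx <- cumsum(non_gap)                  # 1-based ungapped position
  hit <- as.integer(non_gap & ref_c == alt_c & alt_c != "-")
  # matches in ungapped span (s, s+L]: count hits at columns whose ref_idx
  # falls in that range. Since hits only occur at non-gap columns, aggregate
  # per ungapped position then cumulative-sum.
  per_pos <- integer(ref_len)
  per_pos[ref_idx[non_gap]] <- hit[non_gap]
  cps <- cumsum(per_pos)
  s <- probe_starts
  matches <- cps[s + probe_length] - ifelse(s > 0, cps[pmax(s, 1)], 0)
  data.frame(
    probe_id = probe_ids %||% paste0("probe_", probe_starts),
    start = probe_starts,
    matches = as.integer(matches),
    class = identity_class(matches, probe_length, semi_min),
    stringsAsFactors = FALSE
  )
}

as_alignment <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 2) {
    alignment <- list(ref = alignment[1], alt = alignment[2])
  }
  abort_if(!is.list(alignment) || is.null(alignment$ref) ||
             is.null(alignment$alt), "alignment must carry ref and alt strings")
  alignment
}

#' Global pairwise alignment of an ortholog pair
#'
#' Needleman-Wunsch global alignment with affine gaps under the default
#' scoring match +1, mismatch -1, and gap cost -5 for the first gapped
#' position and -1 for each extension (a length-L gap scores
#' `-5 - (L - 1)`). Backed by [Biostrings::pairwiseAlignment()];
#' the optimum is unique up to co-optimal paths and the returned alignment
#' is deterministic.
#'
#' @param a,b DNA sequences (character), both nonempty.
#' @param match,mismatch,gap_open,gap_extend scoring (see above; `gap_open`
#'   is the cost of a gap's first position, `gap_extend` of each further
#'   position).
#' @return list of class `ortholog_alignment`: `ref`, `alt` (gapped
#'   strings), `score`.
#' @export
align_orthologs <- function(a, b, match = 1, mismatch = -1, gap_open = -5,
                            gap_extend = -1) {
  abort_if(!nzchar(a) || !nzchar(b), "sequences must be nonempty")
  sub <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = toupper(a), subject = toupper(b), type = "global",
    substitutionMatrix = sub,
    gapOpening = -(gap_open - gap_extend),  # open cost excl. first extension
    gapExtension = -gap_extend)
  structure(
    list(ref = as.character(Biostrings::alignedPattern(aln)),
         alt = as.character(Biostrings::alignedSubject(aln)),
         score = Biostrings::score(aln)),
    class = c("ortholog_alignment", "list")
  )
}

#' Accumulation of identity classes over ratio thresholds
#'
#' For each threshold, counts the probes whose intensity ratio is at or
#' above the threshold, split by identity class, and the ratio of mismatch
#' probes (matches < probe length) to perfect-match probes. That
#' mismatch-to-perfect ratio is the specificity figure of merit: a
#' normalization with fewer false accumulations at matched true-positive
#' counts discriminates homology better.
#'
#' @param ratios data.frame `probe_id`, `ratio`.
#' @param identities data.frame `probe_id`, `matches`, `class` (from
#'   [probe_identity()]).
#' @param thresholds ascending numeric grid of ratio thresholds.
#' @return data.frame per threshold: `threshold`, `n_true`, `n_semi_true`,
#'   `n_false`, `mismatch_to_perfect` (`NA` when no perfect match
#'   qualifies).
#' @export
threshold_accumulation <- function(ratios, identities, thresholds) {
  abort_if(is.unsorted(thresholds), "thresholds must be ascending")
  x <- merge(ratios[, c("probe_id", "ratio")],
             identities[, c("probe_id", "class")], by = "probe_id")
  rows <- lapply(thresholds, function(t) {
    sel <- x$ratio >= t
    n_true <- sum(sel & x$class == "true")
    n_semi <- sum(sel & x$class == "semi-true")
    n_false <- sum(sel & x$class == "false")
    data.frame(
      threshold = t, n_true = n_true, n_semi_true = n_semi, n_false = n_false,
      mismatch_to_perfect = if (n_true > 0) (n_semi + n_false) / n_true
      else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Mismatch accumulation at matched true-positive counts
#'
#' Summarizes how well an intensity-ratio ranking discriminates perfect-match
#' probes: for each requested sensitivity level, the threshold is set at the
#' ratio of the k-th highest-ranking perfect-match probe (k = fraction of
#' all perfect-match probes), and the mismatch-to-perfect ratio among probes
#' at or above that threshold is recorded. The mean over the sensitivity
#' grid is a matched-sensitivity partial-AUC-style figure: comparing it
#' between two normalizations compares their false accumulation at equal
#' true-positive counts, independent of the (non-equivalent) ratio scales
#' the two methods produce.
#'
#' @param ratios numeric intensity ratios, one per probe.
#' @param matches integer identical-nucleotide counts, aligned with
#'   `ratios`.
#' @param probe_length probe length (perfect match = `probe_length`).
#' @param tp_fractions grid of true-positive fractions to match (default
#'   0.05 to 0.5).
#' @return list: `mean_m2p`, and `by_k` data.frame (`k`, `threshold`,
#'   `n_true`, `n_mismatch`, `m2p`).
#' @export
matched_tp_mismatch <- function(ratios, matches, probe_length = 25,
                                tp_fractions = seq(0.05, 0.5, by = 0.05)) {
  abort_if(length(ratios) != length(matches),
           "ratios and matches differ in length")
  perfect <- matches == probe_length
  n_perfect <- sum(perfect)
  abort_if(n_perfect == 0, "no perfect-match probes to match against")
  true_sorted <- sort(ratios[perfect], decreasing = TRUE)
  ks <- unique(pmax(1, round(tp_fractions * n_perfect)))
  by_k <- do.call(rbind, lapply(ks, function(k) {
    t <- true_sorted[k]
    n_true <- sum(perfect & ratios >= t)
    n_mis <- sum(!perfect & ratios >= t)
    data.frame(k = k, threshold = t, n_true = n_true, n_mismatch = n_mis,
               m2p = n_mis / n_true)
  }))
  list(mean_m2p = mean(by_k$m2p), by_k = by_k)
}

#' Genome occurrence counts of probe sequences
#'
#' Counts exact occurrences of each probe sequence in a genome, forward plus
#' reverse complement (labeled gDNA is double-stranded), overlaps included.
#' Genome positions containing ambiguity codes never match and are
#' effectively skipped (reported once with a message).
#'
#' @param genome a `Biostrings::DNAStringSet`, a named character vector of
#'   chromosome sequences, or a FASTA path.
#' @param probes ProbeSet data.frame (`probe_id`, `sequence`) or a named
#'   character vector of probe sequences.
#' @param both_strands count the reverse complement too (default `TRUE`).
#' @return data.frame `probe_id`, `count_in_genome`.
#' @export
kmer_frequency <- function(genome, probes, both_strands = TRUE) {
  genome <- as_genome(genome)
  if (is.data.frame(probes)) {
    seqs <- stats::setNames(probes$sequence, probes$probe_id)
  } else {
    seqs <- probes
    if (is.null(names(seqs))) names(seqs) <- paste0("probe_", seq_along(seqs))
  }
  seqs <- toupper(seqs)
  abort_if(any(grepl("[^ACGT]", seqs)), "probe sequences must be unambiguous")
  if (any(grepl("[^ACGT]", as.character(genome)))) {
    message("genome contains ambiguous bases; such positions never match")
  }
  count_all <- function(pats) {
    widths <- nchar(pats)
    total <- numeric(length(pats))
    for (w in unique(widths)) {
      i <- widths == w
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats[i]))
      total[i] <- rowSums(Biostrings::vcountPDict(pd, genome))
    }
    total
  }
  counts <- count_all(unname(seqs))
  if (both_strands) counts <- counts + count_all(revcomp(unname(seqs)))
  data.frame(probe_id = names(seqs), count_in_genome = as.integer(counts),
             stringsAsFactors = FALSE)
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  Biostrings::DNAStringSet(toupper(genome))
}
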