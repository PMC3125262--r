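# Conventional aCGH comparison pipeline: quantile normalization across
# chips, per-array scaling to a common mean (500 intensity units), and
# positional smoothing over a 50-bp bandwidth. This pipeline assumes all
# chips share an intensity distribution — the assumption heterologous
# hybridization violates — and exists here as the comparison baseline whose
# artifacts (inflated non-specific signal after scaling, smoothing bleed
# from high- into low-intensity neighbors) the evaluation module measures.

#' Quantile normalization across chips
#'
#' Forces every column (chip) of the intensity matrix to share the same
#' distribution: each column's sorted values are replaced by the
#' across-column mean of order statistics, preserving within-column ranks.
#' Tied values receive the mean of the order-statistic values they span.
#' Delegates to [limma::normalizeQuantiles()].
#'
#' @param m numeric matrix, probes x chips, no missing cells, values >= 0.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  abort_if(ncol(m) < 2, "quantile normalization needs >= 2 chips (got %d)",
           ncol(m))
  abort_if(anyNA(m), "intensity matrix contains missing cells")
  abort_if(any(m < 0), "intensity matrix contains negative values")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Scale each chip to a common mean
#'
#' Multiplies every column by `target / column mean`. The heterologous-chip
#' artifact: a chip whose raw mean is low (fewer perfect matches) receives a
#' larger factor, inflating its non-specific signal relative to a homologous
#' chip.
#'
#' @param m numeric matrix, probes x chips.
#' @param target target mean intensity, default 500.
#' @return matrix with every column mean equal to `target`.
#' @export
scale_to_mean <- function(m, target = 500) {
  m <- as.matrix(m)
  abort_if(!is.numeric(target) || target <= 0, "target mean must be positive")
  mu <- colMeans(m)
  abort_if(any(mu <= 0), "chip %s has non-positive mean intensity",
           (colnames(m) %||% as.character(seq_len(ncol(m))))[which(mu <= 0)[1]])
  sweep(m, 2, target / mu, `*`)
}

#' Positional smoothing of a per-probe track
#'
#' Replaces each probe's value by a local estimate over probes within
#' `bandwidth_bp / 2` base pairs of its position (a windowed mean over a
#' total bandwidth of `bandwidth_bp`). A probe with no neighbors in its
#' window, and any constant stretch, are fixed points. `method = "haar"`
#' gives a translation-invariant Haar soft-threshold alternative (cycle
#' spinning over all shifts, universal threshold from the MAD of the finest
#' detail coefficients); it ignores inter-probe distances and is provided
#' because the conventional workflow describes its smoother only as
#' wavelet-based.
#'
#' @param values numeric signal, one per probe, ordered by position.
#' @param positions strictly increasing base-pair coordinates.
#' @param bandwidth_bp total window width in bp (default 50).
#' @param method `"window"` (default) or `"haar"`.
#' @return numeric vector of smoothed values.
#' @export
smooth_track <- function(values, positions, bandwidth_bp = 50,
                         method = c("window", "haar")) {
  method <- match.arg(method)
  abort_if(length(values) != length(positions),
           "values and positions differ in length")
  if (length(values) == 0) return(numeric(0))
  abort_if(any(diff(positions) <= 0),
           "positions must be strictly increasing within a chromosome")
  if (method == "haar") return(haar_ti_smooth(values))
  half <- bandwidth_bp / 2
  n <- length(values)
  # window [pos - half, pos + half]; two-pointer cumulative sum, O(n)
  cs <- c(0, cumsum(values))
  lo <- findInterval(positions - half, positions, left.open = TRUE) + 1L
  hi <- findInterval(positions + half, positions)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Translation-invariant Haar wavelet soft-threshold denoiser.
haar_ti_smooth <- function(x) {
  n <- length(x)
  if (n < 4) return(x)
  # noise scale from first-difference MAD (finest Haar details)
  sigma <- stats::mad(diff(x)) / sqrt(2)
  if (sigma == 0) return(x)
  lambda <- sigma * sqrt(2 * log(n))
  nshift <- min(n, 16L)
  acc <- numeric(n)
  for (s in seq_len(nshift) - 1L) {
    xs <- c(x[(s + 1L):n], if (s > 0) x[1:s])
    acc <- acc + haar_shrink_shifted(xs, lambda, s, n)
  }
  acc / nshift
}

haar_shrink_shifted <- function(xs, lambda, s, n) {
  # pad to a power of two by symmetric extension
  n2 <- 2^ceiling(log2(n))
  pad <- c(xs, rev(xs)[seq_len(n2 - n)])
  coef <- list(); a <- pad
  while (length(a) > 1) {
    odd <- a[seq(1, length(a), 2)]; even <- a[seq(2, length(a), 2)]
    coef[[length(coef) + 1]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  soft <- function(d) sign(d) * pmax(abs(d) - lambda, 0)
  for (k in seq_along(coef)) coef[[k]] <- soft(coef[[k]])
  for (k in rev(seq_along(coef))) {
    d <- coef[[k]]
    up <- numeric(2 * length(a))
    up[seq(1, length(up), 2)] <- (a + d) / sqrt(2)
    up[seq(2, length(up), 2)] <- (a - d) / sqrt(2)
    a <- up
  }
  y <- a[seq_len(n)]
  if (s > 0) y <- c(y[(n - s + 1L):n], y[1:(n - s)]) else y
}

#' Run the conventional aCGH baseline pipeline
#'
#' Quantile normalization, per-array scaling to a common mean, then
#' positional smoothing of each chip over target probes ordered by
#' chromosome and position (control probes and probes without coordinates
#' pass through unsmoothed). Stages run in that order.
#'
#' @param intensities long data.frame `probe_id`, `chip_id`, `intensity`.
#' @param chips data.frame `chip_id`, `species`, `replicate`.
#' @param probes ProbeSet data.frame (`probe_id`, `category`, `chromosome`,
#'   `start`).
#' @param target_mean common per-array mean, default 500.
#' @param bandwidth_bp smoothing bandwidth, default 50; `0` disables
#'   smoothing.
#' @return list with `matrix` (probes x chips, processed), `values`
#'   (data.frame `probe_id`, `species`, `value`: per-species replicate
#'   means of the processed intensities).
#' @export
baseline_normalize <- function(intensities, chips, probes, target_mean = 500,
                               bandwidth_bp = 50) {
  m <- intensity_matrix(intensities)
  m <- quantile_normalize(m)
  m <- scale_to_mean(m, target_mean)
  if (bandwidth_bp > 0) {
    p <- probes[match(rownames(m), probes$probe_id), , drop = FALSE]
    tgt <- which(p$category == "target" & !is.na(p$chromosome) & !is.na(p$start))
    for (chr in unique(p$chromosome[tgt])) {
      idx <- tgt[p$chromosome[tgt] == chr]
      idx <- idx[order(p$start[idx])]
      for (j in seq_len(ncol(m))) {
        m[idx, j] <- smooth_track(m[idx, j], p$start[idx], bandwidth_bp)
      }
    }
  }
  sp <- chips$species[match(colnames(m), chips$chip_id)]
  means <- t(rowsum(t(m), sp) / as.vector(table(sp)[sort(unique(sp))]))
  values <- data.frame(
    probe_id = rep(rownames(m), times = ncol(means)),
    species = rep(colnames(means), each = nrow(means)),
    value = as.vector(means),
    stringsAsFactors = FALSE
  )
  list(matrix = m, values = values)
}

# Long intensity table -> probes x chips matrix (complete cases enforced).
intensity_matrix <- function(intensities) {
  probes <- sort(unique(intensities$probe_id))
  chips <- sort(unique(intensities$chip_id))
  m <- matrix(NA_real_, length(probes), length(chips),
              dimnames = list(probes, chips))
  m[cbind(match(intensities$probe_id, probes),
          match(intensities$chip_id, chips))] <- intensities$intensity
  abort_if(anyNA(m), "intensity table is not complete over probes x chips")
  m
}
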