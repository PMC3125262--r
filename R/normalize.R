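# Core method: per-species OLS of log control-probe intensity on dG37,
# followed by adjustment of every probe for the fitted thermodynamic effect
# and a phase shift that centers the median control probe at zero.
#
# Model (natural log throughout):
#   ln(i_c,s) = alpha_s + beta_s * dG37(c) + e,   e ~ N(0, sigma^2)
# fitted over control probes c of species s, and
#   AI_p,s = ln(i_p,s) - beta_s * dG37(p) - shift_s,
#   shift_s = median over controls of (ln(i_c,s) - beta_s * dG37(c)),
# so that AI of the median control probe is exactly zero: AI ~ 0 marks the
# non-specific baseline and AI > 0 suggests specific binding.

#' Fit the control-probe calibration model for one species
#'
#' Ordinary least squares of natural-log intensity on nearest-neighbor dG37
#' over the control probes of a single species. The returned fit carries the
#' intercept, the dG37 slope, the residual standard deviation, and the
#' median-control centering shift used by [adjust_intensities()].
#'
#' @param controls data.frame with columns `probe_id` and `intensity`
#'   (background-subtracted, strictly positive), one row per control probe
#'   (replicate chips already combined; see [collapse_replicates()]).
#' @param dg named numeric vector of dG37 values (kcal/mol) keyed by
#'   `probe_id`, or a data.frame with columns `probe_id` and `dg37`.
#' @param species species label stored in the fit (default `NA`).
#' @param method `"ols"` (default; the model's error term is assumed
#'   normal) or `"theil-sen"` for a robust median-of-pairwise-slopes
#'   alternative.
#' @return Object of class `calibration_fit`: list with `species`, `alpha`,
#'   `beta`, `se_beta`, `resid_sd`, `shift`, `n_controls`, `df`.
#' @examples
#' dg <- c(a = -30, b = -25, c = -20)
#' controls <- data.frame(probe_id = c("a", "b", "c"),
#'                        intensity = exp(5 - 0.15 * dg))
#' fit_control_model(controls, dg)
#' @export
fit_control_model <- function(controls, dg, species = NA_character_,
                              method = c("ols", "theil-sen")) {
  method <- match.arg(method)
  abort_if(!is.data.frame(controls) ||
             !all(c("probe_id", "intensity") %in% names(controls)),
           "controls must be a data.frame with probe_id and intensity")
  dg <- as_dg_vector(dg)
  bad <- which(!(controls$intensity > 0))
  abort_if(length(bad) > 0,
           "non-positive intensity for control probe %s (log undefined)",
           controls$probe_id[bad[1]])
  missing_dg <- setdiff(controls$probe_id, names(dg))
  abort_if(length(missing_dg) > 0, "no dG37 value for control probe %s",
           missing_dg[1])

  x <- unname(dg[controls$probe_id])
  y <- log(controls$intensity)
  n <- length(y)
  abort_if(length(unique(x)) < 3,
           "need >= 3 distinct dG37 values among controls (got %d)",
           length(unique(x)))

  if (method == "ols") {
    xm <- mean(x); ym <- mean(y)
    sxx <- sum((x - xm)^2)
    beta <- sum((x - xm) * (y - ym)) / sxx
    alpha <- ym - beta * xm
    resid <- y - alpha - beta * x
    resid_sd <- sqrt(sum(resid^2) / (n - 2))
    se_beta <- resid_sd / sqrt(sxx)
  } else {
    abort_if(n > 3000,
             "theil-sen fit is exact O(n^2); refusing n = %d controls", n)
    pr <- utils::combn(n, 2)
    dx <- x[pr[2, ]] - x[pr[1, ]]
    keep <- dx != 0
    beta <- stats::median((y[pr[2, ]] - y[pr[1, ]])[keep] / dx[keep])
    alpha <- stats::median(y - beta * x)
    resid <- y - alpha - beta * x
    resid_sd <- sqrt(sum((resid - mean(resid))^2) / max(n - 2, 1))
    se_beta <- NA_real_
  }

  # Midpoint-of-central-order-statistics median (stats::median): guarantees
  # exact zero median of adjusted controls for odd n, 1e-16-level for even n.
  shift <- stats::median(y - beta * x)
  structure(
    list(species = species, alpha = alpha, beta = beta, se_beta = se_beta,
         resid_sd = resid_sd, shift = shift, n_controls = n, df = n - 2,
         method = method),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "Control-probe calibration fit (%s)\n  species: %s\n  alpha: %.4f  beta: %.5f (se %.5f)  resid sd: %.4f\n  centering shift: %.4f  controls: %d\n",
    x$method, x$species, x$alpha, x$beta, x$se_beta, x$resid_sd, x$shift,
    x$n_controls))
  invisible(x)
}

as_dg_vector <- function(dg) {
  if (is.data.frame(dg)) {
    abort_if(!all(c("probe_id", "dg37") %in% names(dg)),
             "dg data.frame must have probe_id and dg37 columns")
    dg <- stats::setNames(dg$dg37, dg$probe_id)
  }
  abort_if(!is.numeric(dg) || is.null(names(dg)),
           "dg must be a named numeric vector or a probe_id/dg37 data.frame")
  dg
}

#' Adjusted intensity for all probes of one species
#'
#' Applies the calibration fit: `ai = ln(intensity) - beta * dG37 - shift`.
#' By construction the median adjusted intensity of the control probes the
#' fit was made from is zero; AI > 0 suggests binding above the non-specific
#' baseline.
#'
#' @param tbl data.frame with `probe_id` and `intensity` for one species
#'   (replicates combined on the log scale, as for the fit).
#' @param fit a `calibration_fit` from [fit_control_model()] for the same
#'   species.
#' @param dg named dG37 vector (or probe_id/dg37 data.frame) covering every
#'   probe in `tbl`.
#' @return data.frame `probe_id`, `species`, `ai`.
#' @export
adjust_intensities <- function(tbl, fit, dg) {
  abort_if(!inherits(fit, "calibration_fit"), "fit must be a calibration_fit")
  dg <- as_dg_vector(dg)
  missing_dg <- setdiff(tbl$probe_id, names(dg))
  abort_if(length(missing_dg) > 0, "no dG37 value for probe %s", missing_dg[1])
  bad <- which(!(tbl$intensity > 0))
  abort_if(length(bad) > 0, "non-positive intensity for probe %s",
           tbl$probe_id[bad[1]])
  data.frame(
    probe_id = tbl$probe_id,
    species = fit$species,
    ai = log(tbl$intensity) - fit$beta * unname(dg[tbl$probe_id]) - fit$shift,
    stringsAsFactors = FALSE
  )
}

#' Combine replicate-chip intensities on the log scale
#'
#' Per-probe mean of natural-log intensities across the chips of each
#' species, producing one log-intensity per (probe, species). The calibration
#' model carries a species index but no chip index, so replicate chips are
#' combined before fitting by default.
#'
#' @param intensities long data.frame `probe_id`, `chip_id`, `intensity`.
#' @param chips data.frame `chip_id`, `species`, `replicate`.
#' @return data.frame `probe_id`, `species`, `intensity` where `intensity`
#'   is the geometric mean of replicate intensities (mean on the ln scale,
#'   back-transformed).
#' @export
collapse_replicates <- function(intensities, chips) {
  abort_if(!all(c("probe_id", "chip_id", "intensity") %in% names(intensities)),
           "intensities must have probe_id, chip_id, intensity")
  abort_if(!all(c("chip_id", "species") %in% names(chips)),
           "chips must have chip_id and species")
  abort_if(anyDuplicated(chips$chip_id) > 0, "duplicate chip_id in metadata")
  unknown <- setdiff(unique(intensities$chip_id), chips$chip_id)
  abort_if(length(unknown) > 0, "chip %s has no metadata", unknown[1])
  bad <- which(!(intensities$intensity > 0))
  abort_if(length(bad) > 0, "non-positive intensity for probe %s on chip %s",
           intensities$probe_id[bad[1]], intensities$chip_id[bad[1]])
  sp <- chips$species[match(intensities$chip_id, chips$chip_id)]
  key <- paste(intensities$probe_id, sp, sep = "\r")
  m <- tapply(log(intensities$intensity), key, mean)
  parts <- strsplit(names(m), "\r", fixed = TRUE)
  out <- data.frame(
    probe_id = vapply(parts, `[`, character(1), 1),
    species = vapply(parts, `[`, character(1), 2),
    intensity = exp(unname(m)),
    stringsAsFactors = FALSE
  )
  out[order(out$species, out$probe_id), , drop = FALSE]
}

#' Average adjusted intensities across chips
#'
#' Per-probe arithmetic mean of per-chip adjusted intensities for a single
#' species (the per-chip calibration mode).
#'
#' @param tables list of data.frames `probe_id`, `ai` (one per chip).
#' @param species species label for the output.
#' @return data.frame `probe_id`, `species`, `ai`.
#' @export
combine_replicates <- function(tables, species = NA_character_) {
  abort_if(length(tables) < 1, "need at least one chip table")
  ids <- sort(tables[[1]]$probe_id)
  for (k in seq_along(tables)[-1]) {
    other <- sort(tables[[k]]$probe_id)
    ndiff <- length(setdiff(ids, other)) + length(setdiff(other, ids))
    abort_if(ndiff > 0,
             "probe universes differ between chips 1 and %d (%d asymmetric probes)",
             k, ndiff)
  }
  ai <- rowMeans(matrix(vapply(tables, function(t) {
    stats::setNames(t$ai, t$probe_id)[ids]
  }, numeric(length(ids))), nrow = length(ids)))
  data.frame(probe_id = ids, species = species, ai = unname(ai),
             stringsAsFactors = FALSE)
}

#' Normalize and center a whole experiment
#'
#' Runs the control-probe calibration and adjustment for every species in
#' the chip metadata: replicate chips are combined on the log scale, the
#' calibration is fitted on that species' control probes, and every probe is
#' adjusted and centered. With `per_chip = TRUE` each chip is calibrated and
#' adjusted separately and the per-chip adjusted intensities averaged
#' ([combine_replicates()]), exposing chip-to-chip variation.
#'
#' @param intensities long data.frame `probe_id`, `chip_id`, `intensity`.
#' @param chips data.frame `chip_id`, `species`, `replicate`.
#' @param probes ProbeSet data.frame (needs `probe_id`, `category`).
#' @param dg named dG37 vector or probe_id/dg37 data.frame; if `NULL`,
#'   computed from `probes$sequence` with [delta_g37()].
#' @param per_chip calibrate per chip instead of per species.
#' @param method regression flavor, see [fit_control_model()].
#' @return list with `ai` (data.frame `probe_id`, `species`, `ai`) and
#'   `fits` (data.frame of per-species — or per-chip — fit parameters).
#' @export
normalize_experiment <- function(intensities, chips, probes, dg = NULL,
                                 per_chip = FALSE,
                                 method = c("ols", "theil-sen")) {
  method <- match.arg(method)
  abort_if(!all(c("probe_id", "category") %in% names(probes)),
           "probes must have probe_id and category")
  if (is.null(dg)) {
    abort_if(!"sequence" %in% names(probes),
             "probes must carry sequences when dg is NULL")
    dg <- stats::setNames(delta_g37(probes$sequence), probes$probe_id)
  }
  dg <- as_dg_vector(dg)
  control_ids <- probes$probe_id[probes$category == "control"]
  abort_if(length(control_ids) < 3, "fewer than 3 control probes")

  fit_row <- function(f, chip = NA_character_) {
    data.frame(species = f$species, chip_id = chip, alpha = f$alpha,
               beta = f$beta, se_beta = f$se_beta, resid_sd = f$resid_sd,
               shift = f$shift, n_controls = f$n_controls,
               stringsAsFactors = FALSE)
  }

  ai_list <- list(); fit_list <- list()
  for (sp in unique(chips$species)) {
    sp_chips <- chips$chip_id[chips$species == sp]
    if (!per_chip) {
      tbl <- collapse_replicates(
        intensities[intensities$chip_id %in% sp_chips, , drop = FALSE],
        chips)
      ctl <- tbl[tbl$probe_id %in% control_ids, c("probe_id", "intensity")]
      fit <- fit_control_model(ctl, dg, species = sp, method = method)
      ai_list[[sp]] <- adjust_intensities(tbl, fit, dg)
      fit_list[[sp]] <- fit_row(fit)
    } else {
      per <- lapply(sp_chips, function(ch) {
        tbl <- intensities[intensities$chip_id == ch,
                           c("probe_id", "intensity"), drop = FALSE]
        ctl <- tbl[tbl$probe_id %in% control_ids, , drop = FALSE]
        fit <- fit_control_model(ctl, dg, species = sp, method = method)
        list(ai = adjust_intensities(tbl, fit, dg), fit = fit_row(fit, ch))
      })
      ai_list[[sp]] <- combine_replicates(lapply(per, `[[`, "ai"),
                                          species = sp)
      fit_list[[sp]] <- do.call(rbind, lapply(per, `[[`, "fit"))
    }
  }
  list(ai = do.call(rbind, c(ai_list, list(make.row.names = FALSE))),
       fits = do.call(rbind, c(fit_list, list(make.row.names = FALSE))))
}
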