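# Nearest-neighbor duplex thermodynamics: dG37 of a probe hybridized to its
# exact complement. dG37 is the covariate of the control-probe regression; any
# affine change of parameter set is absorbed by the fitted slope and intercept,
# so no salt or temperature correction is applied.

#' Unified nearest-neighbor dG37 parameter table
#'
#' The unified oligonucleotide nearest-neighbor free-energy parameters at
#' 37 degrees C and 1 M NaCl: the ten unique Watson-Crick stacks expanded to
#' all sixteen dinucleotide steps, a duplex initiation term, and a terminal
#' A.T penalty applied once per A/T duplex end. Units are kcal/mol; more
#' negative means stronger binding. The shipped initiation term is the sum of
#' the two per-end initiation values for G.C ends (2 x 0.98), with the
#' terminal A.T penalty (0.05) converting an end to the A.T initiation value;
#' the self-complementarity symmetry term is omitted because probes are
#' scored against their exact complement. Alternative tables can be loaded
#' with [read_nn_params()].
#'
#' @return An object of class `nn_parameter_table`: a list with `stack_dg37`
#'   (named numeric, 16 steps), `init_dg37`, `terminal_at_penalty`.
#' @seealso [delta_g37()], [read_nn_params()]
#' @export
nn_unified_dg37 <- function() {
  stacks <- c(
    AA = -1.00, AC = -1.44, AG = -1.28, AT = -0.88,
    CA = -1.45, CC = -1.84, CG = -2.17, CT = -1.28,
    GA = -1.30, GC = -2.24, GG = -1.84, GT = -1.44,
    TA = -0.58, TC = -1.30, TG = -1.45, TT = -1.00
  )
  params <- list(stack_dg37 = stacks, init_dg37 = 1.96,
                 terminal_at_penalty = 0.05)
  class(params) <- "nn_parameter_table"
  validate_nn_params(params)
}

#' @export
print.nn_parameter_table <- function(x, ...) {
  cat("Nearest-neighbor dG37 parameter table (kcal/mol)\n")
  cat("  initiation:", x$init_dg37,
      " terminal A.T penalty (per end):", x$terminal_at_penalty, "\n")
  print(round(matrix(x$stack_dg37[order(names(x$stack_dg37))], 4, 4,
                     byrow = TRUE,
                     dimnames = list(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"))), 2))
  invisible(x)
}

# All 16 WC steps present and finite; dG(step) must equal dG(revcomp step)
# (strand symmetry of duplex energy).
validate_nn_params <- function(params) {
  steps <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           paste0))
  missing <- setdiff(steps, names(params$stack_dg37))
  abort_if(length(missing) > 0, "parameter table lacks stack(s): %s",
           paste(missing, collapse = ", "))
  vals <- c(params$stack_dg37, params$init_dg37, params$terminal_at_penalty)
  abort_if(!all(is.finite(vals)), "parameter table contains non-finite values")
  asym <- abs(params$stack_dg37[steps] - params$stack_dg37[revcomp(steps)])
  abort_if(any(asym > 1e-6),
           "parameter table violates reverse-complement symmetry at step(s): %s",
           paste(steps[asym > 1e-6], collapse = ", "))
  if (any(params$stack_dg37 >= 0)) {
    warning("one or more stack dG37 values are non-negative (destabilizing)",
            call. = FALSE)
  }
  params
}

#' Nearest-neighbor duplex free energy at 37 degrees C
#'
#' Computes dG37 (kcal/mol) for each probe sequence hybridized to its exact
#' complement: initiation term + sum of stacking terms over consecutive
#' dinucleotide steps + terminal A.T penalties. Vectorized over sequences.
#'
#' @param sequences character vector of DNA sequences over A/C/G/T
#'   (case-insensitive), each of length >= 2. Names, if present, are carried
#'   to the result.
#' @param params an `nn_parameter_table`, by default [nn_unified_dg37()].
#' @return named numeric vector of dG37 values (negative = stronger binding).
#' @examples
#' delta_g37(c(p1 = "ACGTACGTACGTACGTACGTACGTA"))
#' @export
delta_g37 <- function(sequences, params = nn_unified_dg37()) {
  seqs <- toupper(as.character(sequences))
  abort_if(length(seqs) == 0, "no sequences supplied")
  bad <- regexpr("[^ACGT]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop(sprintf(
      "ambiguous or invalid base '%s' at position %d of sequence %s",
      substr(seqs[i], bad[i], bad[i]), bad[i],
      if (!is.null(names(sequences))) names(sequences)[i] else as.character(i)
    ), call. = FALSE)
  }
  lens <- nchar(seqs)
  abort_if(any(lens < 2), "sequence %s is shorter than 2 bases",
           as.character(which(lens < 2)[1]))

  out <- numeric(length(seqs))
  stacks <- params$stack_dg37
  for (len in unique(lens)) {
    idx <- which(lens == len)
    m <- matrix(unlist(strsplit(seqs[idx], "", fixed = TRUE), use.names = FALSE),
                nrow = length(idx), ncol = len, byrow = TRUE)
    stack_sum <- numeric(length(idx))
    for (j in seq_len(len - 1)) {
      stack_sum <- stack_sum + stacks[paste0(m[, j], m[, j + 1])]
    }
    term <- (m[, 1] %in% c("A", "T")) + (m[, len] %in% c("A", "T"))
    out[idx] <- params$init_dg37 + stack_sum +
      term * params$terminal_at_penalty
  }
  names(out) <- names(sequences)
  out
}

#' Read / write a nearest-neighbor parameter table
#'
#' TSV format: two columns `step` and `dg37_kcal_per_mol`, one row per
#' dinucleotide step (16 rows) plus rows `initiation` and `terminal_AT`.
#'
#' @param path file path.
#' @return `read_nn_params()` returns a validated `nn_parameter_table`;
#'   `write_nn_params()` returns `path` invisibly.
#' @export
read_nn_params <- function(path) {
  df <- read_tsv_checked(path, c("step", "dg37_kcal_per_mol"),
                         "nearest-neighbor parameter")
  vals <- stats::setNames(df$dg37_kcal_per_mol, df$step)
  special <- c("initiation", "terminal_AT")
  abort_if(!all(special %in% names(vals)),
           "parameter file %s lacks the initiation and/or terminal_AT rows",
           path)
  params <- list(
    stack_dg37 = vals[setdiff(names(vals), special)],
    init_dg37 = unname(vals[["initiation"]]),
    terminal_at_penalty = unname(vals[["terminal_AT"]])
  )
  class(params) <- "nn_parameter_table"
  validate_nn_params(params)
}

#' @rdname read_nn_params
#' @param params an `nn_parameter_table`.
#' @export
write_nn_params <- function(params, path) {
  df <- data.frame(
    step = c(names(params$stack_dg37), "initiation", "terminal_AT"),
    dg37_kcal_per_mol = c(unname(params$stack_dg37), params$init_dg37,
                          params$terminal_at_penalty)
  )
  write_tsv_plain(df, path)
}
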