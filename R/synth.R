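# Seeded generator of synthetic hybridization experiments with the
# statistical structure the normalization model assumes: log-normal probe
# noise around a dG37-dependent non-specific baseline, plus a specific
# binding gain that rises with probe-target sequence identity and copy
# number. Two species are emitted — the reference the probes were tiled
# from, and a derived (heterologous) genome carrying substitutions, indels,
# and planted deletions — with replicate chips per species.

#' Simulation configuration
#'
#' Builds and validates the configuration for [generate_dataset()]. The
#' generative signal model per chip is
#' `ln(i) = alpha_true + beta_true * dG37 + specific_effect * g(identity) *
#' copies + N(0, sigma_noise)`, where `g` is 0 below `identity_floor`
#' (fraction of identical nucleotides) and rises linearly to 1 at perfect
#' identity. Control probes are random sequences with no specific binding
#' for any species (equivalently dissimilar). Gene structure alternates
#' exon blocks of `probes_per_gene` probes with `intergenic_probes`
#' intergenic probes; a `conserved_fraction` of genes is protected from
#' divergence.
#'
#' @param n_target_probes,n_control_probes probe counts.
#' @param probe_length probe length in nt (default 25).
#' @param probe_spacing_bp tiling step between probe starts (default 35).
#' @param alpha_true,beta_true generative intercept and dG37 slope of the
#'   non-specific baseline (log-intensity units; kcal/mol for the slope).
#' @param sigma_noise log-intensity noise SD per chip (> 0).
#' @param specific_effect log-intensity gain of a perfect-match single-copy
#'   probe (default 2).
#' @param identity_floor identity fraction at which partial specific
#'   binding begins (default 0.8, i.e. 20/25).
#' @param divergence_per_site substitution probability per site for the
#'   derived genome (outside conserved genes).
#' @param indel_rate per-site probability of an indel event (length 1-3).
#' @param deletion_intervals list of `c(start, length)` 0-based intervals
#'   deleted from the derived genome.
#' @param copy_number_probes named integer vector, probe id to copy number
#'   in the reference genome (default 1 everywhere); applies to the
#'   reference species' signal.
#' @param chips_per_species biological replicate chips per species
#'   (default 2).
#' @param probes_per_gene,intergenic_probes,conserved_fraction gene layout.
#' @param gc_content reference genome GC fraction (default 0.36).
#' @param gc_exon_boost additive GC increase within gene spans (default 0;
#'   set ~0.09 to emulate the exon GC-content artifact).
#' @param species named character vector `c(reference=, test=)` of species
#'   labels.
#' @param seed RNG seed; a fixed seed makes the dataset byte-identical.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_target_probes = 2000, n_control_probes = 1000,
                       probe_length = 25, probe_spacing_bp = 35,
                       alpha_true = 5, beta_true = -0.15, sigma_noise = 0.5,
                       specific_effect = 2, identity_floor = 0.8,
                       divergence_per_site = 0, indel_rate = 0,
                       deletion_intervals = NULL, copy_number_probes = NULL,
                       chips_per_species = 2, probes_per_gene = 8,
                       intergenic_probes = 4, conserved_fraction = 0.1,
                       gc_content = 0.36, gc_exon_boost = 0,
                       species = c(reference = "ref", test = "het"),
                       seed = 1) {
  cfg <- as.list(environment())
  probs <- c(identity_floor, divergence_per_site, indel_rate,
             conserved_fraction, gc_content)
  abort_if(any(probs < 0 | probs > 1), "probabilities must lie in [0, 1]")
  abort_if(sigma_noise <= 0, "sigma_noise must be > 0")
  abort_if(n_target_probes < 1 || n_control_probes < 3,
           "need >= 1 target and >= 3 control probes")
  abort_if(chips_per_species < 1, "need >= 1 chip per species")
  abort_if(!all(c("reference", "test") %in% names(species)),
           "species must name 'reference' and 'test' labels")
  class(cfg) <- "sim_config"
  cfg
}

#' Mutate a sequence, keeping the true alignment
#'
#' Applies per-site substitutions, small indels, and planted deletions to a
#' sequence, returning the derived sequence together with the gapped truth
#' alignment that created it (insertions gap the reference, deletions gap
#' the derived side).
#'
#' @param sequence reference DNA string.
#' @param divergence per-site substitution probability (scalar or
#'   per-position vector).
#' @param indel_rate per-site indel event probability (scalar or vector);
#'   events insert or delete 1-3 bases with equal probability.
#' @param deletions list of `c(start, length)` 0-based intervals to delete.
#' @return list `derived` (string), `alignment` (list `ref`, `alt`).
#' @keywords internal
mutate_sequence <- function(sequence, divergence = 0, indel_rate = 0,
                            deletions = NULL) {
  ref_c <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(ref_c)
  bases <- c("A", "C", "G", "T")
  if (length(divergence) == 1) divergence <- rep(divergence, L)
  if (length(indel_rate) == 1) indel_rate <- rep(indel_rate, L)
  abort_if(length(divergence) != L || length(indel_rate) != L,
           "rate vectors must match sequence length")

  alt_c <- ref_c
  sub_at <- which(stats::runif(L) < divergence)
  if (length(sub_at) > 0) {
    off <- sample.int(3, length(sub_at), replace = TRUE)
    alt_c[sub_at] <- bases[(match(ref_c[sub_at], bases) - 1 + off) %% 4 + 1]
  }

  del_mask <- rep(FALSE, L)
  ins_after <- rep("", L)
  ev <- which(stats::runif(L) < indel_rate)
  for (p in ev) {
    len <- sample.int(3, 1)
    if (stats::runif(1) < 0.5) {
      del_mask[p:min(L, p + len - 1)] <- TRUE
    } else {
      ins_after[p] <- paste(sample(bases, len, replace = TRUE),
                            collapse = "")
    }
  }
  for (d in deletions) {
    abort_if(d[1] < 0 || d[1] + d[2] > L,
             "deletion interval [%d, %d) outside the genome (length %d)",
             d[1], d[1] + d[2], L)
    del_mask[(d[1] + 1):(d[1] + d[2])] <- TRUE
  }

  alt_c[del_mask] <- "-"
  has_ins <- nzchar(ins_after)
  if (any(has_ins)) {
    ref_tok <- ref_c; alt_tok <- alt_c
    w <- which(has_ins)
    ref_tok[w] <- paste0(ref_c[w], strrep("-", nchar(ins_after[w])))
    alt_tok[w] <- paste0(alt_c[w], ins_after[w])
    aln_ref <- paste(ref_tok, collapse = "")
    aln_alt <- paste(alt_tok, collapse = "")
  } else {
    aln_ref <- paste(ref_c, collapse = "")
    aln_alt <- paste(alt_c, collapse = "")
  }
  list(derived = gsub("-", "", aln_alt, fixed = TRUE),
       alignment = list(ref = aln_ref, alt = aln_alt))
}

#' Generate a synthetic two-species hybridization experiment
#'
#' Builds a reference genome, tiles target probes from it, derives a
#' heterologous genome (substitutions, indels, planted deletions; conserved
#' genes protected), adds random control probes, and simulates replicate
#' chips for both species under the signal model of [sim_config()]. Probes
#' overlapping deleted or diverged sequence lose identity — and hence
#' specific signal — through the truth alignment, exactly as
#' [probe_identity()] would score them.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_dataset`: `probes` (ProbeSet data.frame),
#'   `intensities` (long `probe_id`, `chip_id`, `intensity`), `chips`
#'   (metadata), `truth` (list: `identity` data.frame, `genes` data.frame
#'   with conserved flags, `deletions`, `copy_number`, `alignment`),
#'   `genomes` (list `reference`, `derived`), `config`.
#' @export
generate_dataset <- function(cfg) {
  abort_if(!inherits(cfg, "sim_config"), "cfg must come from sim_config()")
  with_seed(cfg$seed, generate_dataset_impl(cfg))
}

generate_dataset_impl <- function(cfg) {
  n <- cfg$n_target_probes
  Lp <- cfg$probe_length
  starts <- (seq_len(n) - 1L) * cfg$probe_spacing_bp
  L <- starts[n] + Lp
  target_ids <- sprintf("t%06d", seq_len(n))
  control_ids <- sprintf("c%06d", seq_len(cfg$n_control_probes))

  # gene layout over consecutive probes
  block <- cfg$probes_per_gene + cfg$intergenic_probes
  pos_in_block <- (seq_len(n) - 1L) %% block
  in_gene <- pos_in_block < cfg$probes_per_gene
  gene_num <- ifelse(in_gene, (seq_len(n) - 1L) %/% block + 1L, NA_integer_)
  gene_ids <- ifelse(in_gene, sprintf("g%04d", gene_num), NA_character_)
  n_genes <- max(gene_num, na.rm = TRUE)
  conserved <- stats::runif(n_genes) < cfg$conserved_fraction

  # per-position GC with optional exon boost; per-position divergence rates
  gc_vec <- rep(cfg$gc_content, L)
  rate_vec <- rep(cfg$divergence_per_site, L)
  indel_vec <- rep(cfg$indel_rate, L)
  for (g in seq_len(n_genes)) {
    pidx <- which(!is.na(gene_num) & gene_num == g)
    span <- (starts[pidx[1]] + 1):(starts[pidx[length(pidx)]] + Lp)
    gc_vec[span] <- min(1, cfg$gc_content + cfg$gc_exon_boost)
    if (conserved[g]) {
      rate_vec[span] <- 0
      indel_vec[span] <- 0
    }
  }

  ref_genome <- random_dna(L, gc_vec)
  mut <- mutate_sequence(ref_genome, rate_vec, indel_vec,
                         cfg$deletion_intervals)

  target_seqs <- substring(ref_genome, starts + 1, starts + Lp)
  control_seqs <- vapply(seq_len(cfg$n_control_probes),
                         function(i) random_dna(Lp, 0.5), character(1))

  idrec <- probe_identity(mut$alignment, starts, Lp, probe_ids = target_ids)
  id_frac <- idrec$matches / Lp
  g_het <- pmin(1, pmax(0, (id_frac - cfg$identity_floor) /
                          (1 - cfg$identity_floor)))

  copies <- stats::setNames(rep(1, n), target_ids)
  if (!is.null(cfg$copy_number_probes)) {
    known <- intersect(names(cfg$copy_number_probes), target_ids)
    copies[known] <- cfg$copy_number_probes[known]
  }

  probes <- data.frame(
    probe_id = c(target_ids, control_ids),
    sequence = c(target_seqs, control_seqs),
    chromosome = c(rep("chr1", n), rep(NA_character_, cfg$n_control_probes)),
    start = c(starts, rep(NA_integer_, cfg$n_control_probes)),
    category = c(rep("target", n), rep("control", cfg$n_control_probes)),
    control_origin = c(rep(NA_character_, n),
                       rep_len(c("plant", "bacterial"),
                               cfg$n_control_probes)),
    gene_id = c(gene_ids, rep(NA_character_, cfg$n_control_probes)),
    region = c(ifelse(in_gene, "exon", "intergenic"),
               rep(NA_character_, cfg$n_control_probes)),
    stringsAsFactors = FALSE
  )

  dg <- delta_g37(stats::setNames(probes$sequence, probes$probe_id))
  gain <- list(
    reference = c(cfg$specific_effect * unname(copies),
                  rep(0, cfg$n_control_probes)),
    test = c(cfg$specific_effect * g_het, rep(0, cfg$n_control_probes))
  )
  mu <- lapply(gain, function(gn) cfg$alpha_true + cfg$beta_true * dg + gn)

  chip_rows <- list(); int_rows <- list()
  for (role in c("reference", "test")) {
    sp <- cfg$species[[role]]
    for (r in seq_len(cfg$chips_per_species)) {
      chip <- sprintf("%s_%d", sp, r)
      chip_rows[[chip]] <- data.frame(chip_id = chip, species = sp,
                                      replicate = r, stringsAsFactors = FALSE)
      int_rows[[chip]] <- data.frame(
        probe_id = probes$probe_id, chip_id = chip,
        intensity = exp(mu[[role]] +
                          stats::rnorm(nrow(probes), 0, cfg$sigma_noise)),
        stringsAsFactors = FALSE
      )
    }
  }

  structure(list(
    probes = probes,
    intensities = do.call(rbind, c(unname(int_rows),
                                   list(make.row.names = FALSE))),
    chips = do.call(rbind, c(unname(chip_rows),
                             list(make.row.names = FALSE))),
    truth = list(
      identity = idrec,
      genes = data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
                         conserved = conserved, stringsAsFactors = FALSE),
      deletions = cfg$deletion_intervals,
      copy_number = copies,
      alignment = mut$alignment
    ),
    genomes = list(reference = ref_genome, derived = mut$derived),
    config = cfg
  ), class = "sim_dataset")
}

#' Generate a diverged ortholog pair with its truth alignment
#'
#' @param length reference sequence length (> 0).
#' @param divergence_per_site substitution probability per site.
#' @param indel_rate per-site indel event probability.
#' @param seed RNG seed.
#' @param gc GC fraction of the reference (default 0.5).
#' @return list `reference`, `derived`, `alignment` (list `ref`, `alt`).
#' @export
generate_ortholog_pair <- function(length, divergence_per_site = 0,
                                   indel_rate = 0, seed = 1, gc = 0.5) {
  abort_if(length <= 0, "length must be positive")
  with_seed(seed, {
    ref <- random_dna(length, gc)
    mut <- mutate_sequence(ref, divergence_per_site, indel_rate)
    list(reference = ref, derived = mut$derived, alignment = mut$alignment)
  })
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the fixture files a pipeline run consumes: genome FASTA pair,
#' probe BED + sequence TSV, intensity and chip-metadata TSVs, and truth
#' tables (identity, gene conservation, deletions).
#'
#' @param sim a `sim_dataset` from [generate_dataset()].
#' @param out_dir output directory (created if missing).
#' @return named character vector of file paths, invisibly.
#' @export
write_sim_dataset <- function(sim, out_dir) {
  abort_if(!inherits(sim, "sim_dataset"), "sim must be a sim_dataset")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genomes = file.path(out_dir, "genomes.fasta"),
    probes_bed = file.path(out_dir, "probes.bed"),
    probe_seqs = file.path(out_dir, "probe_seqs.tsv"),
    intensities = file.path(out_dir, "intensities.tsv"),
    chips = file.path(out_dir, "chips.tsv"),
    truth_identity = file.path(out_dir, "truth_identity.tsv"),
    truth_genes = file.path(out_dir, "truth_genes.tsv"),
    truth_deletions = file.path(out_dir, "truth_deletions.bed")
  )
  gset <- Biostrings::DNAStringSet(c(reference = sim$genomes$reference,
                                     derived = sim$genomes$derived))
  Biostrings::writeXStringSet(gset, paths[["genomes"]])
  write_probes(sim$probes, paths[["probes_bed"]], paths[["probe_seqs"]])
  write_tsv_plain(sim$intensities, paths[["intensities"]])
  write_tsv_plain(sim$chips, paths[["chips"]])
  write_tsv_plain(sim$truth$identity, paths[["truth_identity"]])
  write_tsv_plain(sim$truth$genes, paths[["truth_genes"]])
  dels <- sim$truth$deletions
  del_df <- if (length(dels) > 0) {
    data.frame(chrom = "chr1",
               start = vapply(dels, `[`, numeric(1), 1),
               end = vapply(dels, function(d) d[1] + d[2], numeric(1)))
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  }
  data.table::fwrite(del_df, paths[["truth_deletions"]], sep = "\t",
                     col.names = FALSE)
  invisible(paths)
}
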