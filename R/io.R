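# Format readers/writers and the umbrella pipeline. All genomic intervals
# are 0-based half-open in every file read or written.

PROBE_BED_COLS <- c("chrom", "start", "end", "probe_id", "category",
                    "control_origin", "gene_id", "region")

#' Read a ProbeSet from a BED-like file plus sequences
#'
#' The probe BED carries 8 tab-separated columns (no header): chrom, start,
#' end (0-based half-open), probe_id, category (`target`/`control`),
#' control_origin, gene_id, region (`exon`/`intron`/`intergenic`); missing
#' values are `.`. Sequences come from a FASTA file (record names =
#' probe_id) or a TSV with columns `probe_id`, `sequence`. Every probe must
#' have a sequence whose length equals its BED span (probes without
#' coordinates, e.g. controls, use `.` for chrom/start/end).
#'
#' @param bed_path path to the probe BED.
#' @param seq_path path to the FASTA or TSV sequence file.
#' @return ProbeSet data.frame: `probe_id`, `sequence`, `chromosome`,
#'   `start`, `category`, `control_origin`, `gene_id`, `region`.
#' @export
read_probes <- function(bed_path, seq_path) {
  abort_if(!file.exists(bed_path), "probe BED not found: %s", bed_path)
  lines <- readLines(bed_path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(PROBE_BED_COLS))
  abort_if(length(bad) > 0,
           "malformed probe BED line %d in %s: expected %d fields, got %d",
           bad[1], bed_path, length(PROBE_BED_COLS), nf[bad[1]])
  m <- do.call(rbind, fields)
  colnames(m) <- PROBE_BED_COLS
  m[m == "."] <- NA
  start <- suppressWarnings(as.integer(m[, "start"]))
  end <- suppressWarnings(as.integer(m[, "end"]))
  bad <- which(!is.na(m[, "start"]) & (is.na(start) | is.na(end)))
  abort_if(length(bad) > 0,
           "malformed probe BED line %d in %s: non-integer coordinates",
           bad[1], bed_path)
  abort_if(any(start < 0, na.rm = TRUE), "negative start coordinate in %s",
           bed_path)

  seqs <- read_probe_sequences(seq_path)
  ids <- m[, "probe_id"]
  abort_if(anyDuplicated(ids) > 0, "duplicate probe_id in %s: %s", bed_path,
           ids[anyDuplicated(ids)])
  no_seq <- setdiff(ids, names(seqs))
  no_bed <- setdiff(names(seqs), ids)
  abort_if(length(no_seq) > 0, "probe id(s) in BED without sequence: %s",
           paste(utils::head(no_seq, 10), collapse = ", "))
  abort_if(length(no_bed) > 0, "sequence id(s) without BED record: %s",
           paste(utils::head(no_bed, 10), collapse = ", "))
  sequence <- unname(seqs[ids])

  span <- end - start
  mism <- which(!is.na(span) & span != nchar(sequence))
  abort_if(length(mism) > 0,
           "probe %s: BED span %d does not match sequence length %d",
           ids[mism[1]], span[mism[1]], nchar(sequence)[mism[1]])
  is_control <- m[, "category"] == "control"
  abort_if(any(is_control & !is.na(m[, "gene_id"])),
           "control probe %s carries a gene_id",
           ids[which(is_control & !is.na(m[, "gene_id"]))[1]])

  data.frame(
    probe_id = ids, sequence = sequence, chromosome = m[, "chrom"],
    start = start, category = m[, "category"],
    control_origin = m[, "control_origin"], gene_id = m[, "gene_id"],
    region = m[, "region"], stringsAsFactors = FALSE
  )
}

read_probe_sequences <- function(seq_path) {
  abort_if(!file.exists(seq_path), "sequence file not found: %s", seq_path)
  if (grepl("\\.(fa|fasta|fna)$", seq_path, ignore.case = TRUE)) {
    ss <- Biostrings::readDNAStringSet(seq_path)
    stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else {
    df <- read_tsv_checked(seq_path, c("probe_id", "sequence"),
                           "probe sequence")
    stats::setNames(df$sequence, df$probe_id)
  }
}

#' @rdname read_probes
#' @param probes ProbeSet data.frame.
#' @return `write_probes()` returns the two paths invisibly.
#' @export
write_probes <- function(probes, bed_path, seq_path) {
  dot <- function(x) ifelse(is.na(x), ".", as.character(x))
  end <- probes$start + nchar(probes$sequence)
  lines <- paste(dot(probes$chromosome), dot(probes$start), dot(end),
                 probes$probe_id, dot(probes$category),
                 dot(probes$control_origin), dot(probes$gene_id),
                 dot(probes$region), sep = "\t")
  writeLines(lines, bed_path)
  write_tsv_plain(probes[, c("probe_id", "sequence")], seq_path)
  invisible(c(bed_path, seq_path))
}

#' Read intensity and chip-metadata tables
#'
#' Intensities: TSV with header `probe_id`, `chip_id`, `intensity` (raw,
#' background-subtracted, positive). Chips: TSV with header `chip_id`,
#' `species`, `replicate`.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_intensities <- function(path) {
  df <- read_tsv_checked(path, c("probe_id", "chip_id", "intensity"),
                         "intensity")
  abort_if(any(!is.finite(df$intensity)), "non-finite intensity in %s", path)
  df
}

#' @rdname read_intensities
#' @export
read_chips <- function(path) {
  read_tsv_checked(path, c("chip_id", "species", "replicate"),
                   "chip metadata")
}

#' Run a whole analysis pipeline from a config
#'
#' Executes thermo -> normalization (proposed control-probe method or the
#' conventional baseline) -> requested evaluations, writing TSV/BED outputs
#' plus a JSON run manifest (package version, seed, parameters, input
#' checksums, outputs). On any stage error the partial outputs are removed
#' and the error re-raised with the stage name.
#'
#' Config (YAML file or list): `inputs` (`probes_bed`, `probe_seqs`,
#' `intensities`, `chips`, optional `genome_fasta`), `method` (`proposed` |
#' `baseline`), `reference_species`, `test_species`, optional `params`
#' (`per_chip`, `target_mean`, `bandwidth_bp`, `alpha_fw`, `window_probes`,
#' `ratio_threshold`, `min_run`), `evaluations` (subset of `conserved`,
#' `deletions`, `kmerfreq`), `seed`.
#'
#' @param config path to a YAML config or an equivalent named list.
#' @param out_dir output directory.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  abort_if(is.null(config$inputs), "config lacks an inputs section")
  method <- match.arg(config$method %||% "proposed",
                      c("proposed", "baseline"))
  params <- config$params %||% list()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv_plain(df, p)
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  tryCatch({
    stage <- "read inputs"
    probes <- read_probes(config$inputs$probes_bed, config$inputs$probe_seqs)
    intensities <- read_intensities(config$inputs$intensities)
    chips <- read_chips(config$inputs$chips)

    stage <- "thermo"
    dg <- delta_g37(stats::setNames(probes$sequence, probes$probe_id))
    emit(data.frame(probe_id = names(dg), dg37 = unname(dg)), "dg37.tsv")

    if (method == "proposed") {
      stage <- "normalize"
      norm <- normalize_experiment(
        intensities, chips, probes, dg,
        per_chip = isTRUE(params$per_chip))
      ai <- norm$ai
      emit(ai, "ai.tsv")
      emit(norm$fits, "fits.tsv")
    } else {
      stage <- "baseline"
      base <- baseline_normalize(
        intensities, chips, probes,
        target_mean = params$target_mean %||% 500,
        bandwidth_bp = params$bandwidth_bp %||% 50)
      # baseline "ai" on the log scale for downstream ratio computation
      ai <- data.frame(probe_id = base$values$probe_id,
                       species = base$values$species,
                       ai = log(base$values$value))
      emit(base$values, "baseline_values.tsv")
      emit(ai, "ai.tsv")
    }

    evals <- config$evaluations %||% character(0)
    if ("conserved" %in% evals) {
      stage <- "conserved"
      sp <- config$test_species
      res <- conserved_gene_test(ai[ai$species == sp, , drop = FALSE],
                                 probes,
                                 alpha_fw = params$alpha_fw %||% 0.05)
      emit(res, "conserved_genes.tsv")
    }
    if ("deletions" %in% evals) {
      stage <- "deletions"
      tr <- ratio_track(
        ai[ai$species == config$test_species, , drop = FALSE],
        ai[ai$species == config$reference_species, , drop = FALSE],
        probes)
      emit(tr, "ratio_track.tsv")
      dels <- deletion_scan(
        tr,
        window_probes = params$window_probes %||% 5,
        ratio_threshold = params$ratio_threshold %||% 0.5,
        min_run = params$min_run %||% 10)
      del_path <- file.path(out_dir, "deletions.bed")
      data.table::fwrite(
        dels[, c("chromosome", "start", "end", "n_probes", "mean_ratio")],
        del_path, sep = "\t", col.names = FALSE)
      written <- c(written, del_path)
    }
    if ("kmerfreq" %in% evals) {
      stage <- "kmerfreq"
      abort_if(is.null(config$inputs$genome_fasta),
               "kmerfreq evaluation requires inputs$genome_fasta")
      kf <- kmer_frequency(config$inputs$genome_fasta,
                           probes[probes$category == "target", , drop = FALSE])
      emit(kf, "kmer_frequency.tsv")
    }

    stage <- "manifest"
    inputs <- unlist(config$inputs, use.names = TRUE)
    manifest <- list(
      package = "xspecnorm",
      version = as.character(utils::packageVersion("xspecnorm")),
      r_version = R.version.string,
      method = method,
      seed = config$seed %||% NA,
      params = params,
      inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
      outputs = basename(written)
    )
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
    written <- c(written, manifest_path)
    invisible(manifest)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
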