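#' Default run configuration
#'
#' Collects every tunable of the synthetic study in one list: simulation
#' scale and effect sizes, mapper settings, and the fixed differential
#' expression thresholds (FDR < 0.05, FC > 2 up, FC < 0.5 down, per-sample
#' count threshold 1).
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `run_config`.
#' @export
hybrid_config <- function(...) {
  cfg <- list(
    mode = "synthetic",
    n_genes = 1000L,
    gene_length = 1000L,
    divergence_rate = 0.07,
    read_length = 100L,
    fragment_mean = 250,
    fragment_sd = 25,
    fragment_window = c(150L, 350L),
    error_rate = 0.001,
    n_read_pairs = 20000L,
    replicates = 3L,
    dispersion = 0.05,
    baseline_mean = 200,
    direction_mix = c(up = 0.15, down = 0.15, unaltered = 0.70),
    up_in_both = 0.10,
    misregulation_fraction = 0.5,
    effect_size_log2 = 2,
    k = 31L,
    max_mismatches = 2L,
    fdr_alpha = 0.05,
    fc_up = 2,
    fc_down = 0.5,
    count_threshold = 1L,
    seed = 42L,
    outdir = NULL,
    annotations = NULL,   # path to a gene/term TSV, or "simulate"
    design = NULL,        # path to a design TSV in real mode
    reads_dir = NULL,     # directory of per-sample FASTQ pairs in real mode
    ref_a = NULL, ref_b = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (abs(cfg$fc_down - 1 / cfg$fc_up) > 1e-12 && cfg$fc_down != 0.5)
    warning("fc_down is not 1/fc_up")
  stopifnot(cfg$fdr_alpha > 0, cfg$fc_up > 0, cfg$fc_down > 0,
            cfg$count_threshold >= 0)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML key/value file
#'
#' @param path YAML file whose top-level keys are `run_config` fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  vals <- yaml::read_yaml(path)
  do.call(hybrid_config, vals)
}

# Deterministic per-stage child seeds below 2^31 from one global seed.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

stage_log <- function(log, stage, ...) {
  msg <- sprintf(...)
  message(sprintf("[%s] %s", stage, msg))
  rbind(log, data.frame(stage = stage, detail = msg,
                        stringsAsFactors = FALSE))
}

map_sample_calls <- function(reads, index, series, max_mm, window) {
  mode <- switch(series, G = "parental_A", Q = "parental_B", H = "hybrid")
  classify_pairs(reads$r1$seq, reads$r2$seq, index, mode = mode,
                 max_mismatches = max_mm, fragment_window = window,
                 read_id = reads$r1$read_id)
}

#' Run the complete analysis end to end
#'
#' Synthetic mode simulates the parental references, the planted regulatory
#' program, the sample design, and paired-end reads per sample; maps and
#' classifies every read pair against both genomes; counts accepted pairs
#' per gene; applies the per-sample low-count filter within each
#' (series, sex) comparison; runs the stage-contrast NB Wald test for the
#' four expression series in both sexes; computes cross-series concordance;
#' classifies regulatory patterns and the misregulated (pattern D) gene
#' sets; and, when annotations are available, tests the misregulated set
#' for term overrepresentation. All randomness derives from `config$seed`
#' through fixed per-stage child seeds, so rerunning a config reproduces
#' byte-identical outputs.
#'
#' @param config A `run_config` from [hybrid_config()].
#' @return Invisibly, a result bundle: `refs`, `program`, `design`,
#'   `sweep`, `counts` (per series tag x sex), `de`, `universes`,
#'   `concordance`, `profiles`, `sets`, `enrichment`, `manifest`.
#' @export
run_all <- function(config = hybrid_config()) {
  cfg <- config
  log <- data.frame(stage = character(), detail = character(),
                    stringsAsFactors = FALSE)
  outdir <- cfg$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)
  emit <- function(x, name, rn = NULL) {
    if (!is.null(outdir)) write_tsv(x, file.path(outdir, name),
                                    rownames_as = rn)
  }

  if (cfg$mode == "real") {
    for (f in c("design", "ref_a", "ref_b", "reads_dir")) {
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
        stop("pipeline stage 'inputs': missing or unreadable path for '",
             f, "': ", if (is.null(cfg[[f]])) "<unset>" else cfg[[f]])
    }
    refs <- read_ref_fasta(cfg$ref_a, cfg$ref_b)
    design <- read_tsv(cfg$design)
    program <- NULL
  } else {
    refs <- simulate_references(cfg$n_genes, lengths = cfg$gene_length,
                                divergence_rate = cfg$divergence_rate,
                                seed = child_seed(cfg$seed, "references"))
    program <- simulate_program(cfg$n_genes,
                                direction_mix = cfg$direction_mix,
                                up_in_both = cfg$up_in_both,
                                misregulation_fraction =
                                  cfg$misregulation_fraction,
                                effect_size_log2 = cfg$effect_size_log2,
                                baseline_mean = cfg$baseline_mean,
                                seed = child_seed(cfg$seed, "program"))
    design <- simulate_design(cfg$replicates,
                              seed = child_seed(cfg$seed, "design"))
    log <- stage_log(log, "simulate", "%d genes, %d samples",
                     cfg$n_genes, nrow(design))
    if (!is.null(outdir)) {
      write_ref_fasta(refs, file.path(outdir, "ref_A.fasta"),
                      file.path(outdir, "ref_B.fasta"))
      emit(design, "design.tsv")
      emit(as.data.frame(program), "program_truth.tsv")
    }
  }

  index <- build_index(refs, k = cfg$k)
  log <- stage_log(log, "index", "k = %d over %d genes per genome",
                   cfg$k, length(refs$gene_id))

  # per-sample read simulation + classification + counting
  tags <- c("Q", "G", "HQ", "HG")
  counts <- list()
  truth_rows <- list()
  sweep_tab <- NULL
  for (i in seq_len(nrow(design))) {
    smp <- design[i, ]
    sseed <- child_seed(cfg$seed, paste0("reads_", smp$sample_id))
    if (cfg$mode == "real") {
      r1 <- read_fastq(file.path(cfg$reads_dir,
                                 paste0(smp$sample_id, "_1.fastq")))
      r2 <- read_fastq(file.path(cfg$reads_dir,
                                 paste0(smp$sample_id, "_2.fastq")))
      reads <- list(r1 = r1, r2 = r2, truth = NULL)
    } else {
      w <- sample_weights(program, smp$series, smp$stage)
      npairs <- max(1L, as.integer(round(cfg$n_read_pairs *
                                           smp$library_size_factor)))
      reads <- simulate_reads(refs, w$weights_A, w$weights_B, npairs,
                              read_length = cfg$read_length,
                              fragment_mean = cfg$fragment_mean,
                              fragment_sd = cfg$fragment_sd,
                              error_rate = cfg$error_rate, seed = sseed,
                              sample_id = smp$sample_id)
      truth_rows[[smp$sample_id]] <- reads$truth
      if (!is.null(outdir)) {
        write_fastq(reads$r1, file.path(outdir,
                                        paste0(smp$sample_id, "_1.fastq")))
        write_fastq(reads$r2, file.path(outdir,
                                        paste0(smp$sample_id, "_2.fastq")))
      }
    }
    calls <- map_sample_calls(reads, index, smp$series,
                              cfg$max_mismatches, cfg$fragment_window)
    if (is.null(sweep_tab) && smp$series == "H") {
      sweep_tab <- mismatch_sweep(reads$r1$seq, reads$r2$seq, index,
                                  fragment_window = cfg$fragment_window)
      emit(sweep_tab, "mismatch_sweep.tsv")
    }
    if (smp$series == "H") {
      cp <- count_pairs(calls, refs$gene_id, mode = "hybrid")
      counts[["HG"]][[smp$sample_id]] <- cp$HG
      counts[["HQ"]][[smp$sample_id]] <- cp$HQ
    } else {
      counts[[smp$series]][[smp$sample_id]] <-
        count_pairs(calls, refs$gene_id, mode = "parental")
    }
  }
  log <- stage_log(log, "map", "classified %d samples", nrow(design))
  if (length(truth_rows) && !is.null(outdir))
    emit(do.call(rbind, truth_rows), "read_truth.tsv")

  # assemble per (series tag, sex) matrices, filter, DE
  series_of <- c(Q = "Q", G = "G", HQ = "H", HG = "H")
  de <- list()
  retained <- list()
  filt_counts <- list()
  for (tag in tags) {
    samples <- design[design$series == series_of[[tag]], , drop = FALSE]
    mat <- do.call(cbind, counts[[tag]][samples$sample_id])
    rownames(mat) <- refs$gene_id
    for (sx in c("M", "F")) {
      sub <- samples[samples$sex == sx, , drop = FALSE]
      m <- mat[, sub$sample_id, drop = FALSE]
      f <- filter_low_counts(m, cfg$count_threshold)
      keyname <- paste(tag, sx, sep = "_")
      filt_counts[[keyname]] <- f
      retained[[keyname]] <- attr(f, "retained")
      de[[keyname]] <- run_de(f, sub$stage, cfg$fdr_alpha, cfg$fc_up,
                              cfg$fc_down)
      emit(de[[keyname]], paste0("de_", keyname, ".tsv"))
      emit(m, paste0("counts_", keyname, ".tsv"), rn = "gene_id")
      log <- stage_log(log, "de", "%s: %d/%d genes retained", keyname,
                       nrow(f), nrow(m))
    }
  }

  # concordance + patterns per sex
  universes <- list()
  conc <- list()
  profiles <- list()
  for (sx in c("M", "F")) {
    uni <- common_universe(lapply(paste(tags, sx, sep = "_"),
                                  function(k) retained[[k]]))
    universes[[sx]] <- uni
    gk <- function(tag) de[[paste(tag, sx, sep = "_")]]
    conc[[paste0("Q_G_", sx)]] <- concordance(gk("Q"), gk("G"), uni,
                                              labels = c("Q", "G"))
    conc[[paste0("Q_HQ_", sx)]] <- concordance(gk("Q"), gk("HQ"), uni,
                                               labels = c("Q", "HQ"))
    conc[[paste0("G_HG_", sx)]] <- concordance(gk("G"), gk("HG"), uni,
                                               labels = c("G", "HG"))
    profiles[[sx]] <- pattern_profiles(gk("Q"), gk("G"), gk("HQ"),
                                       gk("HG"), uni, sx)
    emit(profiles[[sx]], paste0("profiles_", sx, ".tsv"))
    log <- stage_log(log, "patterns", "%s: universe %d genes", sx,
                     length(uni))
  }
  if (!is.null(outdir)) {
    ctab <- do.call(rbind, lapply(names(conc), function(nm) {
      x <- conc[[nm]]
      data.frame(comparison = nm, universe_size = x$universe_size,
                 percent_same_direction = x$percent_same_direction,
                 pearson_r = x$pearson_r, stringsAsFactors = FALSE)
    }))
    emit(ctab, "concordance.tsv")
  }

  sets <- misregulated_sets(profiles$M, profiles$F)
  emit(sets$provenance, "pattern_sets.tsv")
  log <- stage_log(log, "patterns",
                   "eligible %d, pattern D union %d, intersection %d",
                   length(sets$eligible_union), length(sets$patternD_union),
                   length(sets$patternD_intersection))

  # enrichment of the misregulated set over the analyzed universe
  enrichment <- NULL
  ann <- NULL
  if (identical(cfg$annotations, "simulate") && !is.null(program)) {
    ann <- simulate_annotations(program,
                                seed = child_seed(cfg$seed, "annotations"))
  } else if (!is.null(cfg$annotations)) {
    ann <- read_tsv(cfg$annotations)
  }
  if (!is.null(ann) && length(sets$patternD_union)) {
    population <- union(universes$M, universes$F)
    enrichment <- fisher_overrep(sets$patternD_union, population, ann)
    emit(as.data.frame(enrichment), "enrichment.tsv")
    log <- stage_log(log, "enrich", "%d terms tested, %d significant",
                     nrow(enrichment), sum(enrichment$significant))
  }

  manifest <- data.frame(
    key = c("seed", "mode", "n_genes", "max_mismatches", "k",
            "count_threshold", "fdr_alpha", "fc_up", "fc_down",
            "param_hash"),
    value = c(cfg$seed, cfg$mode, length(refs$gene_id),
              cfg$max_mismatches, cfg$k, cfg$count_threshold,
              cfg$fdr_alpha, cfg$fc_up, cfg$fc_down, config_hash(cfg)),
    stringsAsFactors = FALSE)
  if (!is.null(outdir)) {
    emit(manifest, "manifest.tsv")
    emit(log, "stage_log.tsv")
  }

  invisible(list(refs = refs, program = program, design = design,
                 sweep = sweep_tab, counts = filt_counts, de = de,
                 universes = universes, concordance = conc,
                 profiles = profiles, sets = sets,
                 enrichment = enrichment, manifest = manifest, log = log))
}

# md5 of the deparsed configuration (order-stable; output paths excluded
# so the hash identifies the analysis, not where it was written).
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outdir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}
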