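# End-to-end orchestration: one seeded config drives simulation,
# preprocessing, annotation, known/novel miRNA identification, target
# prediction, degradome validation and relative quantification, writing
# the per-stage tables and a run manifest into the output directory.

#' Default pipeline configuration
#'
#' @param seed integer seed driving every stochastic stage.
#' @param outdir output directory.
#' @return nested configuration list; override entries freely before
#'   passing it to [run_pipeline()]. `simulation`, `criteria`, `rules` are
#'   argument lists for [simulation_spec()], [novel_criteria()] and
#'   [target_rules()].
#' @export
default_pipeline_config <- function(seed = 1L, outdir = "fruitmir_run") {
  list(seed = as.integer(seed), outdir = outdir,
       simulation = list(),
       known_db = list(n = 20L),
       target_mirnas = 3L, novel_target_hairpins = 2L,
       criteria = list(), rules = list(),
       degradome = list(background_rate = 0, min_peak = 1L),
       expression = list(noise_sd = 0, n_replicates = 3L,
                         samples = paste0("fruit_", c(35, 55, 75, 90, 105), "DAFB")),
       skip = character(0))
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with (a subset of) the fields of
#'   [default_pipeline_config()].
#' @return configuration list merged over the defaults.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config(seed = user$seed %||% 1L,
                                 outdir = user$outdir %||% "fruitmir_run")
  for (k in setdiff(names(user), c("seed", "outdir"))) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      for (kk in names(user[[k]])) cfg[[k]][[kk]] <- user[[k]][[kk]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

#' Run the full discovery pipeline on synthetic data
#'
#' Executes simulate -> preprocess -> annotate -> known -> novel -> targets
#' -> degradome -> quantify, writing per-stage TSV/FASTA/FASTQ outputs and a
#' JSON manifest under `config$outdir`. Stages named in `config$skip` are
#' skipped (with their dependants). The run is a pure function of the
#' config: rerunning with the same config reproduces identical outputs.
#'
#' @param config configuration list from [default_pipeline_config()] or
#'   [read_pipeline_config()].
#' @return invisible list of stage results (see [write_report()] for the
#'   summary).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  out <- function(...) file.path(config$outdir, ...)
  run <- function(stage) !(stage %in% config$skip)

  if (run("simulate")) {
    spec <- do.call(simulation_spec, c(list(seed = config$seed), config$simulation))
    ga <- generate_genome(spec)
    planted <- plant_hairpins(ga, spec,
                              do.call(novel_criteria, config$criteria))
    db <- do.call(simulate_known_db,
                  c(config$known_db, list(seed = config$seed)))
    lib <- simulate_srna_library(planted, spec, db)
    rules <- do.call(target_rules, config$rules)
    pass_hp <- planted$truth[planted$truth$label == "pass", , drop = FALSE]
    tmir <- c(db[seq_len(min(config$target_mirnas, length(db)))],
              setNames(pass_hp$mature_seq, pass_hp$hairpin_id)[
                seq_len(min(config$novel_target_hairpins, nrow(pass_hp)))])
    tx <- simulate_transcriptome_with_targets(tmir, rules, seed = config$seed)
    dg <- simulate_degradome(tx$transcripts, tx$truth,
                             background_rate = config$degradome$background_rate,
                             seed = config$seed)
    set.seed(config$seed + 6L)
    genes <- names(tmir)
    samples <- config$expression$samples
    effects <- matrix(round(runif(length(genes) * length(samples), -2, 2), 2),
                      nrow = length(genes), dimnames = list(genes, samples))
    effects[, 1] <- 0
    ct <- simulate_ct_table(effects, noise_sd = config$expression$noise_sd,
                            n_replicates = config$expression$n_replicates,
                            seed = config$seed)
    write_fasta(planted$genome, out("genome.fa"))
    write_gff3(planted$annotation, out("annotation.gff3"))
    write_fastq(lib$reads, out("srna.fastq"))
    write_tsv(lib$truth, out("srna_truth.tsv"))
    write_fasta(db, out("known_mature.fa"))
    write_fasta(tx$transcripts, out("transcripts.fa"))
    write_tsv(tx$truth, out("target_truth.tsv"))
    write_fasta(setNames(dg$reads$sequence, dg$reads$read_id), out("degradome.fa"))
    write_tsv(dg$truth, out("degradome_truth.tsv"))
    write_tsv(planted$truth, out("hairpin_truth.tsv"))
    write_tsv(ct, out("ct_table.tsv"))
    res$simulate <- list(spec = spec, planted = planted, db = db, lib = lib,
                         transcriptome = tx, degradome = dg, ct = ct,
                         effects = effects, rules = rules)
  }

  if (run("preprocess") && !is.null(res$simulate)) {
    fl <- filter_reads(res$simulate$lib$reads)
    tags <- collapse_tags(fl$clean)
    comp <- composition_stats(tags)
    write_tag_fasta(tags, out("tags.fa"))
    smry <- res$simulate$lib$truth  # truth stays on disk; summary here
    write_tsv(data.frame(category = c("total_reads", "high_quality",
                                      FILTER_CATEGORIES, "clean_reads"),
                         count = c(fl$summary$total_reads, fl$summary$high_quality,
                                   vapply(FILTER_CATEGORIES, function(k)
                                     fl$summary[[k]], numeric(1)),
                                   fl$summary$clean_reads),
                         pct_of_high_quality = c(NA, fl$summary$percentages)),
              out("filter_summary.tsv"))
    write_tsv(comp$length_counts, out("length_distribution.tsv"))
    res$preprocess <- list(filter = fl, tags = tags, composition = comp)
  }

  if (run("annotate") && !is.null(res$preprocess)) {
    hits <- map_tags(res$preprocess$tags, res$simulate$planted$genome)
    cls <- classify_tags(res$preprocess$tags, hits,
                         res$simulate$planted$annotation, res$simulate$db)
    write_tsv(cls$category, out("tag_categories.tsv"))
    write_tsv(cls$summary, out("category_summary.tsv"))
    res$annotate <- list(hits = hits, classification = cls)
  }

  if (run("known") && !is.null(res$annotate)) {
    kh <- identify_known(res$preprocess$tags, res$simulate$db)
    write_tsv(kh, out("known_mirnas.tsv"))
    res$known <- list(hits = kh, families = family_counts(kh))
  }

  if (run("novel") && !is.null(res$annotate)) {
    cat_df <- res$annotate$classification$category
    unann <- cat_df$tag_id[cat_df$category == "unannotated"]
    tags <- res$preprocess$tags[res$preprocess$tags$tag_id %in% unann, , drop = FALSE]
    hits <- res$annotate$hits[res$annotate$hits$tag_id %in% unann, , drop = FALSE]
    pn <- predict_novel(res$simulate$planted$genome, tags, hits,
                        do.call(novel_criteria, config$criteria))
    write_tsv(pn$novel, out("novel_mirnas.tsv"))
    if (nrow(pn$novel) > 0L) {
      write_fasta(setNames(rna_to_dna(pn$novel$mature_sequence), pn$novel$id),
                  out("novel_mature.fa"))
      writeLines(paste0(">", pn$novel$id, "\n", pn$novel$precursor, "\n",
                        pn$novel$structure, " (", pn$novel$mfe, ")"),
                 out("novel_structures.txt"))
    }
    res$novel <- pn
  }

  if (run("targets") && !is.null(res$novel)) {
    mirnas <- c(res$simulate$db,
                setNames(rna_to_dna(res$novel$novel$mature_sequence),
                         res$novel$novel$id))
    targets <- scan_transcriptome(mirnas, res$simulate$transcriptome$transcripts,
                                  res$simulate$rules)
    write_tsv(targets, out("targets.tsv"))
    res$targets <- targets
  }

  if (run("degradome") && !is.null(res$targets)) {
    density <- build_density(res$simulate$degradome$reads,
                             res$simulate$transcriptome$transcripts)
    events <- detect_cleavage(res$targets, density,
                              min_peak = config$degradome$min_peak)
    write_tsv(events, out("cleavage_events.tsv"))
    if (nrow(events) > 0L) {
      write_tsv(tplot_data(events$transcript_id[1], density, events),
                out("tplot_example.tsv"))
    }
    res$degradome <- list(density = density, events = events)
  }

  if (run("quantify") && !is.null(res$simulate)) {
    expr <- ddct(res$simulate$ct, reference_gene = "5S_rRNA",
                 calibrator_sample = config$expression$samples[1])
    write_tsv(expr, out("expression.tsv"))
    res$quantify <- expr
  }

  report <- write_report(res, out("report.tsv"))
  res$report <- report
  jsonlite::write_json(
    list(package = "fruitmir",
         version = as.character(utils::packageVersion("fruitmir")),
         seed = config$seed, skip = config$skip,
         config = config[setdiff(names(config), "outdir")]),
    out("manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Summarise a pipeline run
#'
#' Collects the headline numbers of a run (filter accounting, category
#' partition, known/novel miRNA counts, target and validated-cleavage
#' counts) into one table; percentages recompute from the counts.
#'
#' @param res stage-result list from [run_pipeline()].
#' @param path optional TSV path to write the report to.
#' @return data.frame with columns `quantity` and `value`.
#' @export
write_report <- function(res, path = NULL) {
  q <- list()
  if (!is.null(res$preprocess)) {
    s <- res$preprocess$filter$summary
    q$total_reads <- s$total_reads
    q$high_quality_reads <- s$high_quality
    q$clean_reads <- s$clean_reads
    q$clean_pct <- s$percentages[["clean_reads"]]
    q$unique_tags <- nrow(res$preprocess$tags)
  }
  if (!is.null(res$annotate)) {
    cs <- res$annotate$classification$summary
    q$unannotated_unique <- cs$unique_count[cs$category == "unannotated"]
    q$unannotated_pct <- cs$unique_pct[cs$category == "unannotated"]
  }
  if (!is.null(res$known)) {
    q$known_mirna_tags <- nrow(res$known$hits)
    q$known_mirna_families <- nrow(res$known$families)
  }
  if (!is.null(res$novel)) q$novel_mirnas <- nrow(res$novel$novel)
  if (!is.null(res$targets)) {
    q$predicted_targets <- nrow(res$targets)
    q$mirnas_with_targets <- length(unique(res$targets$mirna_id))
  }
  if (!is.null(res$degradome)) {
    q$validated_cleavages <- nrow(res$degradome$events)
  }
  report <- data.frame(quantity = names(q),
                       value = vapply(q, function(x) as.numeric(x[1]), numeric(1)),
                       stringsAsFactors = FALSE)
  if (!is.null(path)) write_tsv(report, path)
  report
}
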