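# End-to-end orchestration of the BSA pipeline:
# simulate -> select bulks -> call/filter -> associate -> cluster -> report.

#' Pipeline configuration
#'
#' Bundles every stage parameter with defaults equal to the study design
#' values where one exists: 100 progeny from a two-backcross, seven-selfing
#' pedigree; 10 individuals per tail bulk; mean depths 53x (high bulk) and
#' 59x (low bulk); bulk calling at 20/20/90%, parent calling at 5/5/100%;
#' phred floor 30; per-bulk chi-square alpha 0.05; high-bulk donor
#' frequency cutoff 90%; 1 Mb clustering gap; 4.76 cM/Mbp map rate.
#' Configurations round-trip through YAML ([write_config()] /
#' [read_config()]).
#'
#' @param ... named overrides of the defaults (unknown names are an error).
#' @return An object of class `bsa_config` (a named list).
#' @export
bsa_config <- function(...) {
  cfg <- list(
    n_progeny = 100,
    n_backcross = 2,
    n_selfing = 7,
    n_per_bulk = 10,
    site_spacing = 250000,
    cm_per_mbp = 4.76,
    baseline_ac = 23.2,
    qtl_chrom = c("chr6", "chr1", "chr11"),
    qtl_pos = c(1769686L, 30038502L, 18288616L),
    qtl_effect = c(2.5, -1.2, 1.0),
    env_sd = 0.8,
    depth_hab = 53,
    depth_lab = 59,
    depth_parent = 30,
    error_rate = 0.001,
    phred_score = 40,
    low_quality_fraction = 0,
    low_phred = 20,
    bulk_min_coverage = 20, bulk_min_count = 20, bulk_min_freq = 0.90,
    parent_min_coverage = 5, parent_min_count = 5, parent_min_freq = 1.00,
    min_phred = 30,
    min_allele_reads = 2,
    alpha = 0.05,
    hab_freq_cutoff = 0.90,
    require_direction = TRUE,
    coverage_expected_min = 20,
    max_gap = 1e6
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "bsa_config")
}

#' @rdname bsa_config
#' @param config a `bsa_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname bsa_config
#' @export
read_config <- function(path) {
  do.call(bsa_config, yaml::read_yaml(path))
}

#' Run the whole synthetic-mode BSA pipeline
#'
#' Executes simulate -> phenotype -> select bulks -> pooled pileups ->
#' filter cascade -> two-step association -> coverage validation ->
#' clustering, and assembles a run manifest (package version, seed, all
#' parameter values, per-stage filter counts). With a fixed seed the whole
#' run is reproducible. If a stage fails, the error names the stage and
#' the results of completed stages are attached to the condition.
#'
#' @param config a [bsa_config()].
#' @param seed integer seed driving every source of randomness.
#' @param out_dir optional directory; when given, phenotypes, bulk
#'   membership, filter log, candidate and region tables (TSV), a BED of
#'   regions, pileups (VCF), the config (YAML) and the manifest (YAML)
#'   are written there.
#' @return list: `genome`, `phenotypes`, `bulks`, `pileups`, `filtered`,
#'   `results`, `candidates` (passing rows), `regions`, `manifest`.
#' @export
run_bsa_pipeline <- function(config = bsa_config(), seed = 1, out_dir = NULL) {
  set.seed(seed)
  done <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(class = c("bsa_pipeline_error", "error", "condition"),
                     list(message = paste0("stage '", name, "' failed: ",
                                           conditionMessage(e)),
                          call = sys.call(-1), partial = done)))
    })
  }

  genome <- stage("genome", rice_genome(site_spacing = config$site_spacing,
                                        cm_per_mbp = config$cm_per_mbp))
  qtl <- qtl_model(config$baseline_ac,
                   data.frame(chrom = config$qtl_chrom, pos = config$qtl_pos,
                              effect = config$qtl_effect),
                   config$env_sd)
  pop <- stage("simulate", {
    p <- breed_bc2f8(genome, config$n_progeny,
                     n_backcross = config$n_backcross,
                     n_selfing = config$n_selfing)
    assign_phenotypes(p, genome, qtl)
  })
  done$phenotypes <- phenotype_table(pop)

  bulks <- stage("select_bulks", select_bulks(done$phenotypes, config$n_per_bulk))
  done$bulks <- bulks

  pileups <- stage("pileup", {
    by_id <- stats::setNames(pop, vapply(pop, `[[`, "", "id"))
    donor <- founder_individual(genome, "donor", id = "P_donor")
    recur <- founder_individual(genome, "recurrent", id = "P_recurrent")
    sim <- function(members, depth, id) {
      simulate_bulk_pileup(members, genome, mean_depth = depth,
                           error_rate = config$error_rate, sample_id = id,
                           phred_score = config$phred_score,
                           low_quality_fraction = config$low_quality_fraction,
                           low_phred = config$low_phred)
    }
    list(HAB = sim(by_id[bulks$HAB$members], config$depth_hab, "HAB"),
         LAB = sim(by_id[bulks$LAB$members], config$depth_lab, "LAB"),
         P_donor = sim(list(donor), config$depth_parent, "P_donor"),
         P_recurrent = sim(list(recur), config$depth_parent, "P_recurrent"))
  })
  done$pileups <- pileups

  filtered <- stage("call_filter", filter_cascade(
    pileups$HAB, pileups$LAB, pileups$P_donor, pileups$P_recurrent, genome,
    bulk_params = call_params(config$bulk_min_coverage, config$bulk_min_count,
                              config$bulk_min_freq),
    parent_params = call_params(config$parent_min_coverage,
                                config$parent_min_count,
                                config$parent_min_freq),
    min_phred = config$min_phred,
    min_allele_reads = config$min_allele_reads))
  done$filtered <- filtered

  results <- stage("associate", {
    cand_sites <- unique(rbind(filtered$hab[, c("chrom", "pos")],
                               filtered$lab[, c("chrom", "pos")]))
    r <- classify_candidates(cand_sites, pileups$HAB, pileups$LAB,
                             filtered$parent1_geno, filtered$parent2_geno,
                             genome, alpha = config$alpha,
                             hab_freq_cutoff = config$hab_freq_cutoff,
                             require_direction = config$require_direction)
    coverage_report(r, config$coverage_expected_min)
  })
  done$results <- results
  candidates <- results[results$pass, , drop = FALSE]

  regions <- stage("cluster", cluster_candidates(
    candidates, max_gap = config$max_gap, cm_per_mbp = config$cm_per_mbp))
  done$regions <- regions

  manifest <- list(
    package = "bsamap",
    version = as.character(utils::packageVersion("bsamap")),
    seed = seed,
    config = unclass(config),
    filter_log = filtered$log,
    n_candidates = nrow(candidates),
    n_regions = nrow(regions)
  )

  out <- list(genome = genome, phenotypes = done$phenotypes, bulks = bulks,
              pileups = pileups, filtered = filtered, results = results,
              candidates = candidates, regions = regions, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_table(done$phenotypes, file.path(out_dir, "phenotypes.tsv"))
    write_tsv_table(data.frame(
      bulk = rep(c("HAB", "LAB"), c(length(bulks$HAB$members),
                                    length(bulks$LAB$members))),
      id = c(bulks$HAB$members, bulks$LAB$members)),
      file.path(out_dir, "bulks.tsv"))
    write_tsv_table(filtered$log, file.path(out_dir, "filter_log.tsv"))
    write_tsv_table(results, file.path(out_dir, "association_results.tsv"))
    write_tsv_table(candidates, file.path(out_dir, "candidates.tsv"))
    write_tsv_table(regions, file.path(out_dir, "regions.tsv"))
    write_regions_bed(regions, file.path(out_dir, "regions.bed"))
    write_pileup_vcf(pileups, genome, file.path(out_dir, "pileups.vcf"))
    write_config(config, file.path(out_dir, "config.yaml"))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  out
}
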