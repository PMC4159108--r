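## End-to-end orchestration: ingest -> annotate -> popgen -> enrichment, with
## per-stage TSV outputs carrying a provenance header (package version, config
## hash, thresholds). Stage outputs are pure functions of (inputs, config,
## seed).

#' Pipeline configuration
#'
#' Defaults match the analysis's stated parameters: 95th/99th percentile
#' outlier thresholds, Welch alpha 0.05, evidence QC r < -0.5 in >= 2
#' datasets, PSMA high-frequency cutoff 0.5, bootstrap sizes B = 2000 (target
#' and process enrichment) and B = 10000 (disease).
#'
#' @param gff,vcf,panel paths to the miRNA GFF3, the genotype VCF and the
#'   sample manifest (required)
#' @param evidence,go,disease optional paths to the target-evidence, GO and
#'   disease tables; when all three are present the enrichment stage runs
#' @param known_sites optional path to a TSV of known sites (chrom, pos, ref,
#'   alt)
#' @param out output directory
#' @param q95,q99,alpha,r_threshold,min_datasets,psma_high_freq thresholds
#' @param B_target,B_process,B_disease bootstrap replicate counts
#' @param n_enrich_set size of the miRNA set fed to target/process enrichment
#'   (the HPD set; top PD variants fill in when fewer HPD miRNAs exist)
#' @param seed RNG seed for the bootstrap stages
#' @return validated `pipeline_config` list
#' @export
pipeline_config <- function(gff, vcf, panel, evidence = NULL, go = NULL,
                            disease = NULL, known_sites = NULL, out = ".",
                            q95 = 0.95, q99 = 0.99, alpha = 0.05,
                            r_threshold = -0.5, min_datasets = 2,
                            psma_high_freq = 0.5, B_target = 2000,
                            B_process = 2000, B_disease = 10000,
                            n_enrich_set = 8, seed = 1) {
  stopifnot(q95 > 0, q95 < 1, q99 > 0, q99 < 1, q95 <= q99,
            alpha > 0, alpha < 1, r_threshold > -1, r_threshold < 1,
            min_datasets >= 1, psma_high_freq > 0, psma_high_freq <= 1,
            B_target >= 1, B_process >= 1, B_disease >= 1)
  enrich <- !is.null(evidence)
  if (enrich && (is.null(go) || is.null(disease)))
    stop("enrichment stage needs evidence, go and disease tables together")
  structure(list(gff = gff, vcf = vcf, panel = panel, evidence = evidence,
                 go = go, disease = disease, known_sites = known_sites,
                 out = out, q95 = q95, q99 = q99, alpha = alpha,
                 r_threshold = r_threshold, min_datasets = min_datasets,
                 psma_high_freq = psma_high_freq, B_target = B_target,
                 B_process = B_process, B_disease = B_disease,
                 n_enrich_set = n_enrich_set, seed = seed,
                 run_enrichment = enrich),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a JSON file
#'
#' JSON is a strict subset of YAML; keys mirror [pipeline_config()] arguments.
#' Relative input paths resolve against the config file's directory.
#'
#' @param path JSON config file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  for (f in c("gff", "vcf", "panel", "evidence", "go", "disease",
              "known_sites", "out"))
    if (!is.null(raw[[f]]) && !grepl("^/", raw[[f]]))
      raw[[f]] <- file.path(base, raw[[f]])
  do.call(pipeline_config, raw)
}

stage_fail <- function(stage, e) {
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
       call. = FALSE)
}

#' Run the full pipeline
#'
#' Stages run in order: ingest (GFF3, VCF, manifest and tables), annotate
#' (region classification, novelty, singleton filter, densities), popgen
#' (theta by class, PSMA scan, hierarchical F_ST, PD/HPD calling) and, when
#' the tables are configured, enrichment (evidence QC, target and process
#' bootstraps, hypergeometric GO over-representation, disease bootstrap).
#' Each stage writes TSVs under `config$out`; the returned summary mirrors
#' the report tables.
#'
#' @param config a [pipeline_config()]
#' @return (invisibly) list with all stage objects and `summary`
#' @export
run_pipeline <- function(config) {
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  # hash the analytic configuration only; the output path is not provenance
  chash <- config_hash(unclass(config)[setdiff(names(config), "out")])
  prov <- c(config_hash = chash, seed = as.character(config$seed))

  ## ingest
  res <- tryCatch({
    panel <- read_panel(config$panel)
    catalog <- read_mirna_gff(config$gff)
    ks <- if (!is.null(config$known_sites))
      read_headered_tsv(config$known_sites, c("chrom", "pos", "ref", "alt"),
                        "known sites") else NULL
    vt <- read_vcf(config$vcf, panel, known_sites = ks)
    list(panel = panel, catalog = catalog, vt = vt)
  }, error = function(e) stage_fail("ingest", e))
  panel <- res$panel; catalog <- res$catalog; vt <- res$vt

  ## annotate
  ann_res <- tryCatch({
    n_before <- nrow(vt$variants)
    vt <- drop_singletons(vt)
    annotated <- classify_variants(vt, catalog)
    annotated$novel <- !annotated$known
    annotated$n_carriers <- n_carriers(vt)[annotated$record]
    density <- region_density(annotated, catalog)
    write_result_tsv(
      annotated[, c("chrom", "pos", "ref", "alt", "variant_type", "mirna_id",
                    "region", "novel", "n_carriers")],
      file.path(config$out, "annotated_variants.tsv"), prov)
    write_result_tsv(density, file.path(config$out, "region_density.tsv"),
                     prov)
    list(vt = vt, annotated = annotated, density = density,
         n_singletons_dropped = n_before - nrow(vt$variants))
  }, error = function(e) stage_fail("annotate", e))
  vt <- ann_res$vt; annotated <- ann_res$annotated

  ## popgen
  pg <- tryCatch({
    theta <- theta_by_class(vt, annotated, catalog, "region")
    psma <- detect_psma(vt, high_freq = config$psma_high_freq)
    fst <- fst_scan(vt)
    pooled <- fst[fst$level == "pooled", , drop = FALSE]
    pd <- classify_pd(pooled, annotated, q95 = config$q95, q99 = config$q99,
                      alpha = config$alpha)
    write_result_tsv(theta, file.path(config$out, "theta.tsv"), prov)
    write_result_tsv(psma$records, file.path(config$out, "psma.tsv"), prov)
    write_result_tsv(psma$density, file.path(config$out, "psma_density.tsv"),
                     prov)
    fst_out <- merge(fst, pd$variants[, c("variant_key", "label")],
                     by = "variant_key", all.x = TRUE)
    fst_out$label[is.na(fst_out$label) | fst_out$level != "pooled"] <- "none"
    write_result_tsv(
      fst_out, file.path(config$out, "fst.tsv"),
      c(prov, q95_threshold = sprintf("%.6g", pd$thresholds[["q95"]]),
        q99_threshold = sprintf("%.6g", pd$thresholds[["q99"]])))
    list(theta = theta, psma = psma, fst = fst, pd = pd)
  }, error = function(e) stage_fail("popgen", e))

  ## enrichment
  enr <- NULL
  if (isTRUE(config$run_enrichment)) {
    enr <- tryCatch({
      evidence <- read_evidence(config$evidence)
      go <- read_go(config$go)
      disease <- read_disease(config$disease)
      vmap <- filter_evidence(evidence, r_threshold = config$r_threshold,
                              min_datasets = config$min_datasets)
      pool <- catalog$hairpins$mirna_id
      ## the observed set: HPD miRNAs first, then PD, trimmed/padded to size
      lab_rank <- c(none = 0, PD = 1, HPD = 2)
      ml <- pg$pd$mirnas
      ml <- ml[order(-lab_rank[ml$label], ml$mirna_id), , drop = FALSE]
      obs_set <- utils::head(ml$mirna_id[ml$label != "none"],
                             config$n_enrich_set)
      pd_set <- ml$mirna_id[ml$label != "none"]
      out <- list(validated = vmap)
      if (length(obs_set) >= 1) {
        tg <- bootstrap_target_enrichment(obs_set, pool, vmap$target_map,
                                          B = config$B_target,
                                          seed = config$seed,
                                          alpha = config$alpha)
        pr <- bootstrap_process_enrichment(obs_set, pool, vmap$target_map, go,
                                           B = config$B_process,
                                           seed = config$seed + 1,
                                           alpha = config$alpha)
        targets <- unique(unlist(vmap$target_map[obs_set], use.names = FALSE))
        hg <- if (length(intersect(targets, go$background)))
          genomic_go_enrichment(intersect(targets, go$background), go)
          else NULL
        write_result_tsv(tg, file.path(config$out, "target_enrichment.tsv"),
                         prov)
        write_result_tsv(pr, file.path(config$out, "process_enrichment.tsv"),
                         c(prov, note = "bootstrap_vs_random_mirna_sets"))
        if (!is.null(hg))
          write_result_tsv(hg, file.path(config$out, "go_enrichment.tsv"),
                           c(prov, note = "hypergeometric_approximation"))
        out$target <- tg; out$process <- pr; out$go <- hg
        out$obs_set <- obs_set
      }
      if (length(pd_set) >= 1) {
        db <- disease_bootstrap(pd_set, disease, pool,
                                B = config$B_disease, seed = config$seed + 2)
        write_result_tsv(
          data.frame(observed = db$observed_count,
                     expectation = db$expectation,
                     ci_lo = db$ci95[1], ci_hi = db$ci95[2],
                     p_emp = db$p_emp, B = db$B),
          file.path(config$out, "disease_bootstrap.tsv"), prov)
        out$disease <- db
      }
      out
    }, error = function(e) stage_fail("enrichment", e))
  }

  summary <- list(
    n_variants = nrow(vt$variants),
    n_snp = sum(vt$variants$variant_type == "SNP"),
    n_indel = sum(vt$variants$variant_type == "indel"),
    n_singletons_dropped = ann_res$n_singletons_dropped,
    n_novel = sum(!vt$variants$known),
    region_counts = setNames(ann_res$density$n_variants,
                             ann_res$density$region),
    region_density = setNames(ann_res$density$density,
                              ann_res$density$region),
    n_psma = nrow(pg$psma$records),
    psma_density = setNames(pg$psma$density$density,
                            pg$psma$density$population),
    thresholds = pg$pd$thresholds,
    pd_mirnas = pg$pd$mirnas$mirna_id[pg$pd$mirnas$label != "none"],
    hpd_mirnas = pg$pd$mirnas$mirna_id[pg$pd$mirnas$label == "HPD"],
    config_hash = chash)
  if (!is.null(enr)) {
    summary$n_enriched_targets <- if (!is.null(enr$target))
      sum(enr$target$enriched) else 0L
    summary$n_enriched_processes <- if (!is.null(enr$process))
      sum(enr$process$enriched) else 0L
    summary$disease_observed <- if (!is.null(enr$disease))
      enr$disease$observed_count else NA_integer_
  }
  jsonlite::write_json(summary, file.path(config$out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(vt = vt, catalog = catalog, panel = panel,
                 annotated = annotated, popgen = pg, enrichment = enr,
                 summary = summary))
}

#' Write a complete simulated fixture directory
#'
#' Emits everything [run_pipeline()] ingests: GFF3, VCF, manifest,
#' known-sites list, evidence/GO/disease tables, a ready-to-run pipeline
#' config (JSON) and a `truth.json` with the planted structure.
#'
#' @param dir output directory
#' @param config a [sim_config()]
#' @param n_mirna hairpins in the simulated catalog
#' @param enrichment_args list of overrides for
#'   [simulate_enrichment_world()]
#' @return (invisibly) list with the simulated objects and file paths
#' @export
write_fixture <- function(dir, config = sim_config(), n_mirna = 30,
                          enrichment_args = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- simulate_catalog(n_mirna, seed = config$seed,
                              path = file.path(dir, "mirna.gff3"))
  sim <- simulate_genotypes(config, catalog)
  write_vcf(sim$vt, file.path(dir, "genotypes.vcf"))
  p <- as.data.frame(config$panel)
  write.table(p, file.path(dir, "panel.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  known <- sim$vt$variants[sim$vt$variants$known,
                           c("chrom", "pos", "ref", "alt")]
  write.table(known, file.path(dir, "known_sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ea <- utils::modifyList(
    list(catalog_ids = catalog$hairpins$mirna_id, seed = config$seed),
    enrichment_args)
  world <- do.call(simulate_enrichment_world, ea)
  write.table(world$evidence, file.path(dir, "evidence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(world$go$annotations, file.path(dir, "go.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(world$disease, file.path(dir, "disease.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- list(gff = "mirna.gff3", vcf = "genotypes.vcf", panel = "panel.tsv",
              known_sites = "known_sites.tsv", evidence = "evidence.tsv",
              go = "go.tsv", disease = "disease.tsv", out = "results",
              seed = config$seed)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  truth <- c(sim$truth, world$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(catalog = catalog, vt = sim$vt, world = world, truth = truth,
                 dir = dir))
}
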