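## Synthetic fixture worlds with known ground truth: miRBase-style catalogs,
## Balding-Nichols structured genotypes with planted private and
## population-differentiated alleles, and evidence/GO/disease tables with a
## planted enriched miRNA set. Everything is deterministic under a fixed seed.

#' The default sample manifest emulated by the simulator
#'
#' 69 diploid individuals from 14 populations: six African (three of them
#' hunter-gatherer), two European, three Asian and three recently admixed
#' populations, so that the non-admixed pools are 32 African and 25
#' non-African individuals.
#'
#' @return a [genome_panel()]
#' @export
default_panel <- function() {
  spec <- data.frame(
    population = c("PYG", "HDZ", "SAN", "YRI", "MKK", "LWK",
                   "CEU", "TSI", "JPT", "CHB", "GIH",
                   "ASW", "MEX", "PUR"),
    region = c(rep("Africa", 6), rep("Europe", 2), rep("Asia", 3),
               rep("Admixed", 3)),
    n = c(5, 5, 5, 9, 4, 4, 9, 4, 4, 4, 4, 5, 5, 2),
    hunter_gatherer = c(TRUE, TRUE, TRUE, rep(FALSE, 11)),
    admixed = c(rep(FALSE, 11), TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  df <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    data.frame(sample_id = sprintf("%s_%02d", spec$population[i],
                                   seq_len(spec$n[i])),
               population = spec$population[i], region = spec$region[i],
               hunter_gatherer = spec$hunter_gatherer[i],
               admixed = spec$admixed[i], stringsAsFactors = FALSE)
  }))
  genome_panel(df)
}

#' Simulation configuration
#'
#' Bundles the generator's parameters with validation. Defaults state the
#' emulated world: the 69-sample/14-population panel, drift F = 0.1 (typical
#' of global human differentiation), 500 loci placed in hairpin regions at
#' rates close to the relative sizes of seed/mature/stem-loop, a handful of
#' planted private and population-differentiated alleles.
#'
#' @param panel a [genome_panel()] (default [default_panel()])
#' @param F Balding-Nichols drift parameter in \[0, 1) (0 = panmixia)
#' @param n_loci total simulated loci
#' @param fractions named fractions of loci in c(seed, mature, `stem-loop`);
#'   must sum to <= 1, the remainder falls outside hairpins
#' @param n_planted_pd loci planted with a large allele-frequency gap between
#'   the African and non-African pools
#' @param pd_gap minimum realised pooled frequency gap for planted PD loci
#' @param planted_private_per_pop private alleles planted per population
#' @param p_known probability a background locus carries a known rs id
#' @param frac_indel fraction of loci simulated as indels rather than SNPs
#' @param seed RNG seed
#' @return a validated `sim_config` list
#' @export
sim_config <- function(panel = default_panel(), F = 0.1, n_loci = 500,
                       fractions = c(seed = 0.15, mature = 0.3,
                                     `stem-loop` = 0.5),
                       n_planted_pd = 5, pd_gap = 0.6,
                       planted_private_per_pop = 1, p_known = 0.75,
                       frac_indel = 0.1, seed = 1) {
  stopifnot(F >= 0, F < 1, n_loci >= 1, sum(fractions) <= 1,
            all(fractions >= 0), pd_gap > 0, pd_gap <= 1,
            p_known >= 0, p_known <= 1)
  sizes <- n_genomes(panel)
  if (any(sizes < 2)) stop("every population needs >= 2 sampled individuals")
  n_planted <- n_planted_pd + planted_private_per_pop * length(sizes)
  if (n_planted > n_loci)
    stop("more planted loci (", n_planted, ") than n_loci (", n_loci, ")")
  structure(list(panel = panel, F = F, n_loci = n_loci, fractions = fractions,
                 n_planted_pd = n_planted_pd, pd_gap = pd_gap,
                 planted_private_per_pop = planted_private_per_pop,
                 p_known = p_known, frac_indel = frac_indel, seed = seed),
            class = "sim_config")
}

#' Simulate a miRNA catalog (and optionally its GFF3 file)
#'
#' Hairpins are placed non-overlapping on synthetic contigs with alternating
#' strands; each carries a 5' and a 3' mature arm (20-23 nt) separated by a
#' loop, with seeds derived from the arms.
#'
#' @param n_mirna number of hairpins
#' @param hairpin_len hairpin length in nt (>= 50)
#' @param seed RNG seed
#' @param path optional GFF3 output file
#' @param mirna_per_chrom hairpins per synthetic contig
#' @return a [mirna_catalog()]
#' @export
simulate_catalog <- function(n_mirna, hairpin_len = 85, seed = 1, path = NULL,
                             mirna_per_chrom = 50) {
  if (hairpin_len < 50) stop("hairpin_len must be >= 50")
  with_seed(seed, {
    gap <- 200L
    idx <- seq_len(n_mirna)
    chrom <- paste0("chr", (idx - 1) %/% mirna_per_chrom + 1)
    within <- (idx - 1) %% mirna_per_chrom
    start <- 1000L + within * (hairpin_len + gap)
    end <- start + hairpin_len - 1L
    strand <- ifelse(idx %% 2 == 1, "+", "-")
    hairpins <- data.frame(mirna_id = sprintf("sim-mir-%d", idx),
                           chrom = chrom, start = start, end = end,
                           strand = strand, stringsAsFactors = FALSE)
    len5 <- sample(20:23, n_mirna, replace = TRUE)
    len3 <- sample(20:23, n_mirna, replace = TRUE)
    if (hairpin_len < max(len5 + len3) + 4)
      stop("impossible placement: hairpin too short for two arms and a loop")
    arms <- rbind(
      data.frame(arm_id = paste0(hairpins$mirna_id, "-5p"),
                 mirna_id = hairpins$mirna_id, chrom = chrom,
                 start = start, end = start + len5 - 1L,
                 strand = strand, stringsAsFactors = FALSE),
      data.frame(arm_id = paste0(hairpins$mirna_id, "-3p"),
                 mirna_id = hairpins$mirna_id, chrom = chrom,
                 start = end - len3 + 1L, end = end,
                 strand = strand, stringsAsFactors = FALSE))
    cat <- mirna_catalog(hairpins, arms)
    if (!is.null(path)) write_mirna_gff(cat, path)
    cat
  })
}

#' Balding-Nichols genotype matrix
#'
#' Ancestral frequency p ~ Uniform(0.05, 0.95); each population's frequency
#' ~ Beta(p(1-F)/F, (1-p)(1-F)/F); genotypes ~ Binomial(2, p_pop). F = 0
#' collapses to panmixia (all populations share the ancestral frequency).
#' The caller owns the RNG state (wrap in [with_seed()] for determinism).
#'
#' @param n_loci number of independent loci
#' @param pop_sizes named integer vector of diploid sample sizes
#' @param F drift parameter in \[0, 1)
#' @return list: `geno` (loci x individuals dosage matrix, columns grouped by
#'   population), `pop_freq` (loci x populations), `ancestral` (length n_loci)
#' @export
bn_genotypes <- function(n_loci, pop_sizes, F) {
  p <- runif(n_loci, 0.05, 0.95)
  pops <- names(pop_sizes)
  pop_freq <- matrix(NA_real_, n_loci, length(pops),
                     dimnames = list(NULL, pops))
  for (j in seq_along(pops)) {
    pop_freq[, j] <- if (F == 0) p else
      rbeta(n_loci, p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  geno <- do.call(cbind, lapply(seq_along(pops), function(j) {
    matrix(rbinom(n_loci * pop_sizes[j], 2, pop_freq[, j]), n_loci,
           pop_sizes[j])
  }))
  colnames(geno) <- unlist(lapply(pops, function(pp)
    sprintf("%s_%02d", pp, seq_len(pop_sizes[[pp]]))))
  list(geno = geno, pop_freq = pop_freq, ancestral = p)
}

sample_locus_positions <- function(config, catalog) {
  # enumerate the bases of each region class and draw locus positions
  enumerate <- function(df) {
    if (!nrow(df)) return(data.frame(chrom = character(), pos = integer()))
    do.call(rbind, lapply(seq_len(nrow(df)), function(i)
      data.frame(chrom = df$chrom[i], pos = df$start[i]:df$end[i],
                 stringsAsFactors = FALSE)))
  }
  seed_b <- enumerate(catalog$seeds)
  arm_b <- enumerate(catalog$arms)
  hp_b <- enumerate(catalog$hairpins)
  bkey <- function(b) paste(b$chrom, b$pos)
  mature_b <- arm_b[!bkey(arm_b) %in% bkey(seed_b), , drop = FALSE]
  stem_b <- hp_b[!bkey(hp_b) %in% bkey(arm_b), , drop = FALSE]
  pools <- list(seed = seed_b, mature = mature_b, `stem-loop` = stem_b)
  n_by <- round(config$fractions * config$n_loci)
  n_none <- config$n_loci - sum(n_by)
  picked <- list()
  for (rc in names(pools)) {
    if (n_by[[rc]] > nrow(pools[[rc]]))
      stop("not enough ", rc, " bases (", nrow(pools[[rc]]),
           ") for ", n_by[[rc]], " loci")
    idx <- sample(nrow(pools[[rc]]), n_by[[rc]])
    picked[[rc]] <- cbind(pools[[rc]][idx, , drop = FALSE], region_truth = rc)
  }
  if (n_none > 0) {
    # intergenic loci: beyond the last hairpin of chr1
    far <- max(catalog$hairpins$end) + 10000L
    picked$none <- data.frame(chrom = "chr1", pos = far + seq_len(n_none) * 10L,
                              region_truth = "none", stringsAsFactors = FALSE)
  }
  pos <- do.call(rbind, picked)
  rownames(pos) <- NULL
  pos[sample(nrow(pos)), , drop = FALSE]
}

#' Simulate structured genotypes over a miRNA catalog
#'
#' Loci are placed inside the catalog's region classes at the configured
#' fractions (the remainder outside any hairpin). Background loci follow the
#' Balding-Nichols model; planted private alleles are present in exactly one
#' population; planted PD loci are resampled until the realised African vs
#' non-African pooled frequency gap reaches `pd_gap`. Known loci carry rs-style
#' ids.
#'
#' @param config a [sim_config()]
#' @param catalog a [mirna_catalog()]
#' @return list: `vt` (a [variant_table()]), `truth` (planted PD keys, private
#'   keys per population, novel keys, per-locus true region)
#' @export
simulate_genotypes <- function(config, catalog) {
  panel <- config$panel
  sizes <- n_genomes(panel)
  with_seed(config$seed, {
    pos <- sample_locus_positions(config, catalog)
    n <- nrow(pos)
    bn <- bn_genotypes(n, sizes, config$F)
    geno <- bn$geno
    # bn_genotypes lays columns out grouped by population in names(sizes)
    # order; relabel with the panel's own sample ids, then restore panel order
    colnames(geno) <- unlist(split(panel$sample_id, panel$population)[names(sizes)],
                             use.names = FALSE)
    geno <- geno[, panel$sample_id, drop = FALSE]

    pop_of <- panel$population
    afr_pools <- panel$region == "Africa" & !panel$admixed
    nonafr_pools <- panel$region != "Africa" & !panel$admixed

    planted_pd <- integer(0)
    planted_private <- list()
    slot <- 0L
    # planted PD loci: large frequency gap between pools
    if (config$n_planted_pd > 0) {
      planted_pd <- slot + seq_len(config$n_planted_pd)
      slot <- slot + config$n_planted_pd
      for (i in planted_pd) {
        repeat {
          pa <- 0.95; pb <- 0.95 - (config$pd_gap + 0.25)
          row <- integer(ncol(geno))
          for (pp in names(sizes)) {
            cols <- which(pop_of == pp)
            pf <- if (panel$region[cols[1]] == "Africa") pa
                  else if (panel$admixed[cols[1]]) (pa + pb) / 2 else pb
            row[cols] <- rbinom(length(cols), 2, pf)
          }
          gap <- abs(sum(row[afr_pools]) / (2 * sum(afr_pools)) -
                     sum(row[nonafr_pools]) / (2 * sum(nonafr_pools)))
          if (gap >= config$pd_gap) break
        }
        geno[i, ] <- row
      }
    }
    # planted private alleles: carriers in exactly one population
    for (pp in names(sizes)) {
      for (j in seq_len(config$planted_private_per_pop)) {
        slot <- slot + 1L
        row <- integer(ncol(geno))
        cols <- which(pop_of == pp)
        repeat {
          row[cols] <- rbinom(length(cols), 2, 0.3)
          if (any(row[cols] > 0)) break
        }
        geno[slot, ] <- row
        planted_private[[pp]] <- c(planted_private[[pp]], slot)
      }
    }

    # alleles: SNPs and simple indels
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    is_indel <- runif(n) < config$frac_indel
    ins <- is_indel & runif(n) < 0.5
    ref[is_indel & !ins] <- paste0(ref[is_indel & !ins],
                                   sample(bases, sum(is_indel & !ins),
                                          replace = TRUE))
    alt[is_indel & !ins] <- substr(ref[is_indel & !ins], 1, 1)
    alt[ins] <- paste0(ref[ins], sample(bases, sum(ins), replace = TRUE))

    known <- runif(n) < config$p_known
    ids <- ifelse(known, sprintf("rs%07d", sample(1e6, n)), NA_character_)

    variants <- data.frame(chrom = pos$chrom, pos = pos$pos, ref = ref,
                           alt = alt,
                           variant_type = ifelse(is_indel, "indel", "SNP"),
                           id = ids, known = known, stringsAsFactors = FALSE)
    # de-duplicate colliding positions (planted rows reuse sampled positions)
    dupe <- duplicated(paste(variants$chrom, variants$pos))
    variants <- variants[!dupe, , drop = FALSE]
    geno <- geno[!dupe, , drop = FALSE]
    region_truth <- pos$region_truth[!dupe]
    vt <- variant_table(variants, geno, panel)
    keys <- variant_key(vt)
    old_idx <- which(!dupe)
    to_key <- function(ix) keys[match(ix, old_idx)]
    list(vt = vt,
         truth = list(
           planted_pd = stats::na.omit(to_key(planted_pd)),
           planted_private = lapply(planted_private, function(ix)
             as.character(stats::na.omit(to_key(ix)))),
           novel_keys = keys[!vt$variants$known],
           region_truth = data.frame(variant_key = keys,
                                     region = region_truth,
                                     stringsAsFactors = FALSE)))
  })
}

#' Write a variant table as a VCF v4.2 file
#'
#' Dosage 0/1/2 becomes 0/0, 0/1, 1/1; `NA` becomes `./.`.
#'
#' @param vt a [variant_table()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_vcf <- function(vt, path) {
  v <- vt$variants
  ord <- order(v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]
  geno <- vt$geno[ord, , drop = FALSE]
  gt <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow(geno), ncol(geno))
  gt[is.na(geno)] <- "./."
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mirpopgen",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(vt$geno)), collapse = "\t"))
  body <- paste(v$chrom, v$pos, ifelse(is.na(v$id), ".", v$id), v$ref, v$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate evidence, GO and disease tables with planted enrichment
#'
#' Background miRNA-gene targeting occurs at rate `q`; a targeted pair passes
#' the evidence QC filter (r < -0.5 in >= 2 datasets) with probability
#' `pass_rate`, otherwise it gets evidence that fails QC. Every miRNA of
#' `planted_set` targets each gene of the planted block with probability
#' `effect` (`effect = 0` gives a pure calibration world). A designated
#' process (`"GO:PLANTED"`) annotates the planted block; other genes get 1-3
#' random processes. Disease flags are assigned at `disease_base_rate`, with
#' the planted set enriched at `disease_planted_rate`.
#'
#' @param catalog_ids character vector of candidate miRNA ids
#' @param n_genes number of genes
#' @param n_processes number of background GO processes
#' @param planted_set miRNA ids carrying the planted signal (subset of
#'   `catalog_ids`)
#' @param effect probability a planted miRNA validly targets a planted gene
#' @param n_planted_genes size of the planted gene block
#' @param q background validated-targeting rate
#' @param pass_rate probability a targeted pair's evidence passes QC
#' @param disease_base_rate,disease_planted_rate association rates
#' @param seed RNG seed
#' @return list: `evidence`, `go`, `disease`, `truth` (planted genes, process,
#'   targeted-pair count and QC-passing count)
#' @export
simulate_enrichment_world <- function(catalog_ids, n_genes = 200,
                                      n_processes = 30,
                                      planted_set = character(),
                                      effect = 1, n_planted_genes = 20,
                                      q = 0.05, pass_rate = 0.8,
                                      disease_base_rate = 0.1,
                                      disease_planted_rate = 0.9,
                                      seed = 1) {
  stopifnot(all(planted_set %in% catalog_ids),
            n_planted_genes <= n_genes)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  planted_genes <- genes[seq_len(n_planted_genes)]
  with_seed(seed, {
    # background targeting
    pairs <- expand.grid(mirna_id = catalog_ids, gene_id = genes,
                         stringsAsFactors = FALSE)
    targeted <- runif(nrow(pairs)) < q
    # planted block targeting
    planted_pair <- pairs$mirna_id %in% planted_set &
      pairs$gene_id %in% planted_genes
    targeted[planted_pair] <- runif(sum(planted_pair)) < effect
    tp <- pairs[targeted, , drop = FALSE]
    passes <- runif(nrow(tp)) < pass_rate
    ev <- lapply(seq_len(nrow(tp)), function(i) {
      if (passes[i]) {
        nd <- sample(2:3, 1)
        data.frame(mirna_id = tp$mirna_id[i], gene_id = tp$gene_id[i],
                   dataset_id = sprintf("D%02d", sample(45, nd)),
                   r = runif(nd, -0.95, -0.55), stringsAsFactors = FALSE)
      } else if (runif(1) < 0.5) {
        # strong correlation but only one dataset
        data.frame(mirna_id = tp$mirna_id[i], gene_id = tp$gene_id[i],
                   dataset_id = sprintf("D%02d", sample(45, 1)),
                   r = runif(1, -0.95, -0.55), stringsAsFactors = FALSE)
      } else {
        # weak correlation in two datasets
        data.frame(mirna_id = tp$mirna_id[i], gene_id = tp$gene_id[i],
                   dataset_id = sprintf("D%02d", sample(45, 2)),
                   r = runif(2, -0.45, 0.2), stringsAsFactors = FALSE)
      }
    })
    evidence <- if (length(ev)) do.call(rbind, ev) else
      data.frame(mirna_id = character(), gene_id = character(),
                 dataset_id = character(), r = numeric())
    # GO annotations
    ann <- do.call(rbind, lapply(genes, function(g) {
      data.frame(gene_id = g,
                 process_id = sprintf("GO:%04d", sample(n_processes,
                                                        sample(1:3, 1))),
                 stringsAsFactors = FALSE)
    }))
    if (n_planted_genes > 0)
      ann <- rbind(ann, data.frame(gene_id = planted_genes,
                                   process_id = "GO:PLANTED",
                                   stringsAsFactors = FALSE))
    go <- list(annotations = unique(ann), background = genes)
    # disease associations
    rate <- ifelse(catalog_ids %in% planted_set, disease_planted_rate,
                   disease_base_rate)
    assoc <- catalog_ids[runif(length(catalog_ids)) < rate]
    disease <- if (length(assoc))
      data.frame(mirna_id = assoc,
                 disease_name = sample(c("cancer", "diabetes", "asthma"),
                                       length(assoc), replace = TRUE),
                 direction = sample(c("up", "down", "both", "unknown"),
                                    length(assoc), replace = TRUE),
                 stringsAsFactors = FALSE)
      else data.frame(mirna_id = character(), disease_name = character(),
                      direction = character())
    list(evidence = evidence, go = go, disease = disease,
         truth = list(planted_genes = planted_genes,
                      planted_process = "GO:PLANTED",
                      n_targeted_pairs = nrow(tp),
                      n_qc_pass_pairs = sum(passes)))
  })
}
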